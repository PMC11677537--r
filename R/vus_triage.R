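#' Consensus driver triage of MET VUSs
#'
#' Variants of uncertain significance are triaged from five precomputed
#' predictor outputs: SIFT, PolyPhen-2, MutationTaster, CADD (Phred-scaled)
#' and the Cancer Genome Interpreter. Each predictor casts a driver /
#' non-driver vote; a VUS is a consensus predicted driver only when every
#' predictor votes driver. Running the predictor engines is out of scope:
#' their outputs are consumed as an annotation table.
#'
#' @name vus_triage
NULL

.sift_levels <- c("deleterious", "tolerated")
.polyphen_levels <- c("benign", "possibly_damaging", "probably_damaging")
.mt_levels <- c("disease_causing", "neutral")
.cgi_levels <- c("known_driver", "predicted_driver", "predicted_passenger")

#' Per-predictor driver votes
#'
#' SIFT votes driver iff `deleterious`; PolyPhen-2 iff `possibly_damaging`
#' or `probably_damaging`; MutationTaster iff `disease_causing`; CADD iff
#' the Phred score is strictly over `cadd_threshold` (high pathogenicity
#' potential is "over 25"); CGI iff `known_driver` or `predicted_driver`.
#'
#' @param sift,polyphen2,mutation_taster,cgi Categorical predictor outputs
#'   (see [read_annotation_table()] for the enumerations).
#' @param cadd_phred Non-negative CADD Phred score.
#' @param cadd_threshold Strict CADD cutoff (default 25).
#' @param missing Policy for a missing/`NA` predictor value: `"error"`
#'   (default) or `"non_driver"` (abstain counts as a non-driver vote).
#' @return Named logical vector of driver votes
#'   (`sift`, `polyphen2`, `mutation_taster`, `cadd`, `cgi`).
#' @export
predictor_votes <- function(sift, polyphen2, mutation_taster, cadd_phred, cgi,
                            cadd_threshold = 25,
                            missing = c("error", "non_driver")) {
  missing <- match.arg(missing)
  vote <- function(value, levels, driver_levels, name) {
    if (is.null(value) || length(value) != 1L || is.na(value) ||
        (is.character(value) && !nzchar(value))) {
      if (missing == "error") {
        .fail(sprintf("missing %s value", name), "metexdx_missing_predictor")
      }
      return(FALSE)
    }
    if (!is.null(levels) && !value %in% levels) {
      .fail(sprintf("unknown %s value '%s'", name, value))
    }
    value %in% driver_levels
  }
  c(sift = vote(sift, .sift_levels, "deleterious", "sift"),
    polyphen2 = vote(polyphen2, .polyphen_levels,
                     c("possibly_damaging", "probably_damaging"), "polyphen2"),
    mutation_taster = vote(mutation_taster, .mt_levels, "disease_causing",
                           "mutation_taster"),
    cadd = if (is.null(cadd_phred) || length(cadd_phred) != 1L ||
               is.na(cadd_phred)) {
      if (missing == "error") {
        .fail("missing cadd_phred value", "metexdx_missing_predictor")
      } else FALSE
    } else {
      if (cadd_phred < 0) .fail("cadd_phred must be >= 0")
      cadd_phred > cadd_threshold
    },
    cgi = vote(cgi, .cgi_levels, c("known_driver", "predicted_driver"), "cgi"))
}

#' Consensus driver call for one variant
#'
#' @inheritParams predictor_votes
#' @param variant_id Protein-level variant label, e.g. `"T992I"`.
#' @param domains Optional domain table ([read_domain_table()]); when
#'   supplied, the affected residue parsed from `variant_id` is mapped to
#'   its domain.
#' @return List with `variant_id`, `is_predicted_driver` (the conjunction
#'   of the five votes), `votes`, `domain`.
#' @export
consensus_driver <- function(variant_id, sift, polyphen2, mutation_taster,
                             cadd_phred, cgi, cadd_threshold = 25,
                             missing = c("error", "non_driver"),
                             domains = NULL) {
  votes <- predictor_votes(sift, polyphen2, mutation_taster, cadd_phred, cgi,
                           cadd_threshold = cadd_threshold, missing = missing)
  dom <- NA_character_
  if (!is.null(domains)) {
    res <- protein_change_residue(variant_id)
    dom <- if (is.na(res)) "other" else map_to_domain(res, domains)
  }
  list(variant_id = variant_id, is_predicted_driver = all(votes),
       votes = votes, domain = dom)
}

#' Residue number of a protein change
#'
#' Parses the residue position out of a simple protein-change label such as
#' `"T992I"`, `"H1094Y"` or `"p.T992I"`. Returns `NA` when no residue
#' number is present.
#'
#' @param protein_change Character vector.
#' @return Integer vector of residue positions.
#' @export
protein_change_residue <- function(protein_change) {
  vapply(protein_change, function(x) {
    if (is.na(x)) return(NA_integer_)
    m <- regmatches(x, regexpr("[0-9]+", x))
    if (length(m) == 0) NA_integer_ else as.integer(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' Map a protein residue to its domain
#'
#' @param protein_residue Residue number (>= 1).
#' @param domains Domain table ([read_domain_table()]).
#' @return The containing domain's name, else `"other"`. Total: exactly one
#'   label for every residue.
#' @export
map_to_domain <- function(protein_residue,
                          domains = read_domain_table()) {
  if (is.na(protein_residue) || protein_residue < 1) return("other")
  hit <- domains$start_residue <= protein_residue &
    domains$end_residue >= protein_residue
  if (any(hit)) domains$domain_name[which(hit)[1]] else "other"
}

#' Triage an annotation table
#'
#' Consensus driver calls for every annotated variant. Variants whose
#' `clinical_significance` is `actionable` or `likely_actionable` bypass
#' prediction: they are already clinically classified and are never
#' downgraded by the consensus (`is_predicted_driver` is `TRUE` with vote
#' source `"clinical"`).
#'
#' @param annotations [read_annotation_table()] output.
#' @param cadd_threshold,missing As in [predictor_votes()].
#' @param domains Domain table for residue mapping.
#' @return `data.frame` with `variant_id`, `gene`, `protein_change`,
#'   `domain`, per-predictor vote columns (`vote_*`), `is_predicted_driver`,
#'   `call_source` (`"consensus"` or `"clinical"`).
#' @export
triage_vus <- function(annotations, cadd_threshold = 25,
                       missing = c("error", "non_driver"),
                       domains = read_domain_table()) {
  missing <- match.arg(missing)
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    clinical <- a$clinical_significance %in% c("actionable", "likely_actionable")
    res <- protein_change_residue(a$protein_change)
    dom <- if (is.na(res)) "other" else map_to_domain(res, domains)
    if (clinical) {
      votes <- setNames(rep(NA, 5),
                        c("sift", "polyphen2", "mutation_taster", "cadd", "cgi"))
      driver <- TRUE
      src <- "clinical"
    } else {
      votes <- predictor_votes(a$sift, a$polyphen2, a$mutation_taster,
                               a$cadd_phred, a$cgi,
                               cadd_threshold = cadd_threshold,
                               missing = missing)
      driver <- all(votes)
      src <- "consensus"
    }
    data.frame(variant_id = a$variant_id, gene = a$gene,
               protein_change = a$protein_change, domain = dom,
               vote_sift = votes[["sift"]],
               vote_polyphen2 = votes[["polyphen2"]],
               vote_mutation_taster = votes[["mutation_taster"]],
               vote_cadd = votes[["cadd"]], vote_cgi = votes[["cgi"]],
               is_predicted_driver = driver, call_source = src,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-domain driver summary matrix
#'
#' Heatmap-style 0/1 matrix (variant x predictor vote) plus a per-domain
#' count summary, mirroring a driver-prediction heatmap over the JM/TK
#' domains.
#'
#' @param triage [triage_vus()] output.
#' @return List with `matrix` (integer matrix, rownames = variant ids) and
#'   `by_domain` (`data.frame` of variant and predicted-driver counts per
#'   domain).
#' @export
driver_summary <- function(triage) {
  vote_cols <- grep("^vote_", names(triage), value = TRUE)
  m <- as.matrix(triage[, vote_cols])
  mode(m) <- "integer"
  rownames(m) <- triage$variant_id
  colnames(m) <- sub("^vote_", "", vote_cols)
  by_dom <- do.call(rbind, lapply(split(triage, triage$domain), function(d) {
    data.frame(domain = d$domain[1], n_variants = nrow(d),
               n_predicted_driver = sum(d$is_predicted_driver),
               stringsAsFactors = FALSE)
  }))
  rownames(by_dom) <- NULL
  list(matrix = m, by_domain = by_dom)
}

#' Screen for co-occurring actionable variants
#'
#' Does a patient's tumour profile contain any *other* (non-MET) variant in
#' an actionable gene? `has_other_any` checks the any-solid-tumor
#' actionability set; `has_other_lung` the lung-specific subset (genes such
#' as ESR1, ERBB4 and PIK3CA are actionable in some solid tumours but not
#' in lung cancer, so a patient can be `has_other_any` without
#' `has_other_lung`). The decision is gene-set membership; the
#' actionability class column of the profile is carried for reporting only.
#'
#' @param genes Character vector of the patient's variant gene symbols
#'   (MET entries are ignored).
#' @param sets Actionability sets ([read_actionable_genes()]).
#' @return List with logicals `has_other_any` and `has_other_lung`.
#' @export
screen_other_actionable <- function(genes, sets = read_actionable_genes()) {
  other <- setdiff(unique(genes), "MET")
  list(has_other_any = any(other %in% sets$any_solid),
       has_other_lung = any(other %in% sets$lung))
}

#' Screen every patient of a cohort
#'
#' @param patient_genes `data.frame` with columns `patient_id`, `gene`
#'   (one row per patient-gene).
#' @param sets Actionability sets ([read_actionable_genes()]).
#' @return `data.frame` with `patient_id`, `has_other_any`,
#'   `has_other_lung`.
#' @export
screen_cohort <- function(patient_genes, sets = read_actionable_genes()) {
  ids <- sort(unique(patient_genes$patient_id))
  other <- patient_genes[patient_genes$gene != "MET", , drop = FALSE]
  agg <- function(hit) {
    if (!nrow(other)) return(setNames(logical(0), character(0)))
    tapply(hit, other$patient_id, any)
  }
  any_hit <- agg(other$gene %in% sets$any_solid)
  lung_hit <- agg(other$gene %in% sets$lung)
  look <- function(tab) {
    v <- unname(tab[match(ids, names(tab))])
    v[is.na(v)] <- FALSE
    v
  }
  data.frame(patient_id = ids, has_other_any = look(any_hit),
             has_other_lung = look(lung_hit), stringsAsFactors = FALSE)
}
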