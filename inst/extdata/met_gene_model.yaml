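# MET gene model (GRCh37.p13), exons flanking the skipped exon 14.
# Transcript: NM_000245 (MET-001). Coordinates are 1-based closed intervals
# in VCF POS semantics. These values are configuration: verify or replace
# them against the annotation release used by your own panel before
# production use. Exon 14 bounds (chr7:116411903-116412043) are the
# canonical METex14 interval.
gene_symbol: MET
chromosome: "7"
strand: "+"
transcript_id: NM_000245
exons:
  - exon_number: 13
    start: 116411552
    end: 116411708
  - exon_number: 14
    start: 116411903
    end: 116412043
  - exon_number: 15
    start: 116414935
    end: 116415165
windows:
  acceptor_intronic_bp: 25
  acceptor_exonic_bp: 2
  donor_exonic_bp: 2
  donor_intronic_bp: 10
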