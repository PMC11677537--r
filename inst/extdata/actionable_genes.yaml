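# Actionability gene sets used by the co-occurring-variant screen.
# any_solid: genes with an approved/guideline targeted-therapy indication in
#   at least one solid-tumor type (ASCO/ESMO NSCLC panel genes plus the
#   named non-lung-actionable genes ESR1, ERBB4, PIK3CA, IDH2, MTOR).
# lung: the subset actionable in lung cancer specifically.
# Edit freely; the screen is driven entirely by these lists.
any_solid:
  - EGFR
  - ALK
  - ROS1
  - ERBB2
  - MET
  - BRAF
  - KRAS
  - RET
  - NTRK1
  - NTRK2
  - NTRK3
  - ESR1
  - ERBB4
  - PIK3CA
  - IDH2
  - MTOR
lung:
  - EGFR
  - ALK
  - ROS1
  - ERBB2
  - MET
  - BRAF
  - KRAS
  - RET
  - NTRK1
  - NTRK2
  - NTRK3
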