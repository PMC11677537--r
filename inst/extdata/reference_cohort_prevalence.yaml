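# External reference-cohort prevalences for two-cohort comparisons
# (count, n) per gene. Values transcribed from published whole-percent
# prevalences of a large Caucasian NSCLC registry cohort (n = 18857);
# counts are n * percentage rounded to the nearest patient. Supply your own
# numbers for other comparators.
cohort_size: 18857
genes:
  MET: 754
  KRAS: 6977
  ALK: 943
  ERBB2: 754
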