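## PEP floor: avoids zero PEPs breaking -log10 sums and divisions.
PEP_EPS <- 1e-6

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

DECOY_PREFIX <- "decoy_"
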