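BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
ALLOWED_CODONS <- setdiff(
  apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = ""),
  STOP_CODONS)
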