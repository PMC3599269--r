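# shared sequence constants (file name keeps them first in load order)
DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                              DNA_BASES, paste0))
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)
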