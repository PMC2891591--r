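# Watson-Crick + wobble pairs, the consensus set used throughout
CONSENSUS_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

NUCS <- c("A", "C", "G", "U")

# 16 dinucleotide states, row-major in the first base: AA AC AG AU CA ... UU
PAIR_STATES <- as.vector(t(outer(NUCS, NUCS, paste0)))

# 4x4 logical lookup: can bases x (rows) and y (cols) form a consensus pair?
CONSENSUS_LOOKUP <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(NUCS, NUCS))
  for (p in CONSENSUS_PAIRS) m[substr(p, 1, 1), substr(p, 2, 2)] <- TRUE
  m
})
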