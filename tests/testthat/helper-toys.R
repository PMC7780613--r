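# Small arms reused across tests. Toys keep the centromere off-arm unless a
# test needs centromere protection.

# 3 LUs x 1 kbp, one nonessential gene each, URA3 marker in LU-2
toy3_with_ura3 <- function() {
  chrom <- make_toy_chromosome(3)
  chrom$markers$URA3 <- "LU-2"
  chrom
}

# deleted LU-id sets (canonical strings) from an enumeration data.frame
deleted_sets <- function(enum) sort(unique(enum$deleted_lus))

# pooled deleted-segment spans (bp) over a list of selected strains
pooled_spans <- function(strains) {
  unlist(lapply(strains, function(s) {
    profile_from_state(s)$deleted_segments$span_bp
  }))
}
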