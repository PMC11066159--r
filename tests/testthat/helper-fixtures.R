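# Shared builders for the test suite. Everything is generated in code;
# no binary fixtures are stored.

# The 15 anticodons of the packaged fixture, in table order.
fixture_anticodons <- c("AAA", "AAG", "AAU", "AAC", "AGA", "AGG", "AGU",
                        "AGC", "AUG", "AUU", "AUC", "ACA", "ACG", "ACU",
                        "ACC")

all_codons <- function() {
  as.vector(outer(outer(RNA_BASES, RNA_BASES, paste0), RNA_BASES, paste0))
}

# A small trace with a known mixed position. The default sequence keeps
# the mixed T (index 9) away from any other T or C so its quantified peak
# picks up no tail leakage from neighbouring same-channel peaks.
toy_trace <- function(fraction = 0, seed = NULL, noise_sd = 0,
                      sequence = "ACGTAGGATAGG", mixed_at = 9L) {
  mixed <- if (fraction > 0) {
    stats::setNames(list(c(T = 1 - fraction, C = fraction)),
                    as.character(mixed_at))
  } else {
    list()
  }
  simulate_trace(trace_spec(sequence, mixed_positions = mixed,
                            noise_sd = noise_sd, seed = seed))
}

# Chromatogram with integer-valued channels (the lossless subset for ABIF).
integer_chrom <- function(chrom) {
  chromatogram(lapply(chrom$channels, round), chrom$peak_locations,
               chrom$called_bases, chrom$channel_order)
}
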