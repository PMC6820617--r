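# Fixture builders shared across test files. All fixtures are built in
# code; nothing is read from disk except files the tests themselves
# write to tempdir().

# Assay whose counts lie exactly on 20 e^{-b t} (non-integer counts,
# so structural validation is bypassed: these probe the optimizer, not
# the data contract).
exact_assay <- function(b, N0 = 20, t = seq(0, 64, by = 8),
                        genotype = "exact", replicate_id = "r1") {
  rit_assay(genotype, replicate_id, time_s = t,
            intact_count = N0 * exp(-b * t), initial_count = N0,
            validate = FALSE)
}

# Small well-formed integer-count assay for IO/validation tests.
toy_assay <- function(genotype = "WT", replicate_id = "r1") {
  rit_assay(genotype, replicate_id, time_s = seq(0, 40, 8),
            intact_count = c(20, 13, 8, 5, 2, 0))
}

# Long-format data frame for 2 genotypes x 3 replicates on 0..64 s.
toy_long_table <- function() {
  grid <- seq(0, 64, 8)
  counts <- list(
    WT  = list(c(20, 12, 8, 5, 3, 2, 1, 1, 0),
               c(20, 13, 7, 4, 3, 1, 1, 0, 0),
               c(20, 11, 8, 6, 2, 2, 0, 0, 0)),
    mut = list(c(20, 17, 13, 11, 9, 7, 6, 5, 4),
               c(20, 16, 14, 12, 8, 8, 6, 4, 3),
               c(20, 18, 15, 11, 10, 8, 7, 5, 5)))
  do.call(rbind, lapply(names(counts), function(g) {
    do.call(rbind, lapply(1:3, function(r) {
      data.frame(genotype = g, replicate = paste0("r", r),
                 time_s = grid, intact_count = counts[[g]][[r]],
                 stringsAsFactors = FALSE)
    }))
  }))
}
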