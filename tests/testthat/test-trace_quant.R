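test_that("chromatogram invariants are enforced", {
  ch <- toy_trace()
  expect_s3_class(ch, "chromatogram")
  expect_error(chromatogram(ch$channels[1:3], ch$peak_locations,
                            ch$called_bases), "A, C, G, T")
  expect_error(chromatogram(ch$channels, rev(ch$peak_locations),
                            ch$called_bases), "strictly increasing")
  expect_error(chromatogram(ch$channels, ch$peak_locations, "ACG"),
               "match peak_locations")
  bad <- ch$channels; bad$A <- bad$A[-1]
  expect_error(chromatogram(bad, ch$peak_locations, ch$called_bases),
               "same non-zero length")
})

test_that("ABIF writer/reader round-trips a chromatogram", {
  ch <- integer_chrom(toy_trace(fraction = 0.3, noise_sd = 5, seed = 2))
  bytes <- write_abif(ch)
  back <- read_abif(bytes)
  expect_equal(back$channels, ch$channels)
  expect_identical(back$peak_locations, ch$peak_locations)
  expect_identical(back$called_bases, ch$called_bases)
  expect_identical(back$channel_order, ch$channel_order)
  # file-path round trip too
  path <- withr::local_tempfile(fileext = ".ab1")
  write_abif(ch, path)
  expect_equal(read_abif(path)$channels, ch$channels)
})

test_that("ABIF channel order follows the FWO_ permutation", {
  ch <- integer_chrom(toy_trace())
  permuted <- chromatogram(ch$channels, ch$peak_locations, ch$called_bases,
                           channel_order = "GATC")
  back <- read_abif(write_abif(permuted))
  expect_identical(back$channel_order, "GATC")
  expect_equal(back$channels$G, ch$channels$G) # keyed by base, not slot
  expect_equal(back$channels$T, ch$channels$T)
})

test_that("malformed ABIF input raises format errors", {
  expect_error(read_abif(charToRaw("XXXXjunkjunkjunk")), "bad magic")
  ch <- integer_chrom(toy_trace())
  bytes <- write_abif(ch)
  expect_error(read_abif(bytes[1:100]), "truncated")
  big <- ch; big$channels$A[1] <- 1e6
  expect_error(write_abif(big), "int16")
})

test_that("XML and CSV trace dialects agree with the ABIF content", {
  ch <- integer_chrom(toy_trace(fraction = 0.2, noise_sd = 8, seed = 9))
  xml <- withr::local_tempfile(fileext = ".xml")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trace_xml(ch, xml)
  write_trace_csv(ch, csv)
  for (back in list(read_trace_xml(xml), read_trace_csv(csv),
                    read_trace(xml), read_trace(csv))) {
    expect_equal(back$channels, ch$channels)
    expect_identical(back$peak_locations, ch$peak_locations)
    expect_identical(back$called_bases, ch$called_bases)
  }
  expect_error(read_trace("trace.fasta"), "unsupported")
})

test_that("malformed XML traces raise format errors", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<trace><channel base='A'>1 2</channel></trace>", path)
  expect_error(read_trace_xml(path), "exactly 4 channel")
  writeLines(paste0("<trace>",
                    "<channel base='A'>1 2</channel>",
                    "<channel base='C'>1 2</channel>",
                    "<channel base='G'>1 2</channel>",
                    "<channel base='T'>1</channel>",
                    "<peak_locations>1</peak_locations>",
                    "<called_bases>A</called_bases></trace>"), path)
  expect_error(read_trace_xml(path), "unequal")
  writeLines("<trace><other/></trace>", path)
  expect_error(read_trace_xml(path), "missing element")
})

test_that("the anticodon locus is found at the constructed offset", {
  ref <- reference_cdna("AAA") # triplet TTT at bases 13-15
  ch <- simulate_trace(trace_spec(toupper(ref), noise_sd = 0))
  locus <- locate_anticodon(ch, ref)
  expect_identical(locus$anticodon_window, 13:15)
  expect_identical(locus$trace_index, 15L) # base 34 is last in read order
  expect_identical(locus$orientation, "reverse_complement")
})

test_that("localization survives one miscalled flank base via alignment", {
  ref <- reference_cdna("AGA")
  ch <- simulate_trace(trace_spec(toupper(ref), noise_sd = 0))
  exact <- locate_anticodon(ch, ref)
  bases <- strsplit(ch$called_bases, "")[[1]]
  bases[5] <- if (bases[5] == "A") "G" else "A" # corrupt one flank call
  mutated <- chromatogram(ch$channels, ch$peak_locations,
                          paste(bases, collapse = ""))
  expect_identical(locate_anticodon(mutated, ref)$anticodon_window,
                   exact$anticodon_window)
})

test_that("absent or ambiguous context is a localization error", {
  ref <- reference_cdna("AAA")
  other <- simulate_trace(trace_spec(strrep("ACGT", 10), noise_sd = 0))
  expect_error(locate_anticodon(other, ref), "edit distance|not found")
  # duplicated context is ambiguous
  dup_seq <- paste0(toupper(reference_cdna("AAA")),
                    toupper(reference_cdna("AAA")))
  dup <- simulate_trace(trace_spec(dup_seq, noise_sd = 0))
  expect_error(locate_anticodon(dup, ref), "more than once|ambiguous")
  expect_error(locate_anticodon(other, "ACGTACGT"), "lowercase|context")
})

test_that("peak integration separates channels and subtracts baseline", {
  ch <- toy_trace() # noise-free, pure bases
  # position 2 is a C: all T signal there is baseline only
  areas_c <- integrate_peak(ch, 2L)
  expect_gt(areas_c$areas[["C"]], 0)
  expect_equal(areas_c$areas[["T"]], 0, tolerance = 1e-6)
  # flat channel integrates to zero after baseline subtraction
  flat <- chromatogram(list(A = rep(5, 60), C = rep(5, 60),
                            G = rep(5, 60), T = rep(5, 60)),
                       c(10, 30, 50), "ACT")
  expect_true(all(integrate_peak(flat, 2L)$areas == 0))
  expect_error(integrate_peak(ch, 99L), "out of range")
})

test_that("identical synthetic peaks in two channels have equal areas", {
  ch <- toy_trace(fraction = 0.5) # exact 50:50 T/C split, noise-free
  areas <- integrate_peak(ch, 9L)
  expect_equal(areas$areas[["T"]], areas$areas[["C"]], tolerance = 1e-9)
})

test_that("a window at the trace edge is truncated with a warning", {
  ch <- toy_trace()
  short <- chromatogram(lapply(ch$channels, function(x) x[1:18]),
                        c(6, 17), "AC")
  expect_warning(integrate_peak(short, 2L), "truncated")
})

test_that("the estimator is exact on noise-free traces", {
  for (f in c(0, 0.05, 0.15, 0.5, 1.0)) {
    ch <- toy_trace(fraction = f)
    areas <- integrate_peak(ch, 9L)
    expect_equal(estimate_inosine_fraction(areas), f, tolerance = 1e-6)
  }
})

test_that("estimated fraction is monotone in the generating fraction", {
  fr <- seq(0, 1, by = 0.1)
  est <- vapply(fr, function(f) {
    ch <- toy_trace(fraction = f, noise_sd = 10, seed = 33)
    estimate_inosine_fraction(integrate_peak(ch, 9L))
  }, numeric(1))
  expect_true(all(diff(est) >= 0))
})

test_that("no T or C signal is an error", {
  # lone A peak: the T and C channels carry baseline only
  x <- seq_len(60)
  a_peak <- 20 + 800 * exp(-(x - 30)^2 / 12.5)
  ch <- chromatogram(list(A = a_peak, C = rep(20, 60), G = rep(20, 60),
                          T = rep(20, 60)),
                     c(10, 30, 50), "GAG")
  areas <- integrate_peak(ch, 2L)
  expect_error(estimate_inosine_fraction(areas), "no T or C signal")
  expect_error(estimate_inosine_fraction(list(T = 1)), "peak_areas")
})

test_that("modification calls need both the 5% and the 3-sigma gate", {
  expect_true(call_modification(0.50, 0.01, 0.005)$modified)
  expect_false(call_modification(0.01, 0.01, 0.005)$modified)
  expect_false(call_modification(0.06, 0.05, 0.01)$modified) # fails 3-sigma
  expect_false(call_modification(0.04, 0.0, 0.0)$modified)   # fails 5% gate
  expect_true(call_modification(0.05, 0.0, 0.0)$modified)    # boundary
  expect_error(call_modification(1.2, 0, 0), "fractions")
})

test_that("trace noise statistics come from unmodified T positions", {
  ch <- simulate_trace(trace_spec(toupper(reference_cdna("AAA")),
                                  noise_sd = 10, seed = 4))
  locus <- locate_anticodon(ch, reference_cdna("AAA"))
  noise <- trace_noise_stats(ch, exclude = locus$anticodon_window)
  expect_gt(noise$n, 3)
  expect_lt(noise$mean, 0.05) # noise floor well under the visibility gate
  expect_gte(noise$sd, 0)
  expect_error(trace_noise_stats(ch, exclude = seq_len(200)), "no unexcluded")
})
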