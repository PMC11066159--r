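test_that("trace specs validate their mixing fractions", {
  expect_error(trace_spec("ACGU"), "DNA string")
  expect_error(trace_spec("ACGT", mixed_positions = list("9" = c(T = 1))),
               "outside the sequence")
  expect_error(trace_spec("ACGT", mixed_positions = list("2" = c(T = 0.6,
                                                                 C = 0.6))),
               "sum to 1")
  expect_error(trace_spec("ACGT", peak_sigma = 15), "smaller than")
})

test_that("simulated traces are deterministic under a fixed seed", {
  a <- toy_trace(fraction = 0.3, noise_sd = 10, seed = 77)
  b <- toy_trace(fraction = 0.3, noise_sd = 10, seed = 77)
  expect_identical(a, b)
  c <- toy_trace(fraction = 0.3, noise_sd = 10, seed = 78)
  expect_false(identical(a$channels, c$channels))
})

test_that("mixed positions split amplitude by the stated fractions", {
  ch <- toy_trace(fraction = 0.5)
  expect_equal(estimate_inosine_fraction(integrate_peak(ch, 9L)), 0.5,
               tolerance = 1e-9)
  pure <- toy_trace()
  expect_equal(estimate_inosine_fraction(integrate_peak(pure, 9L)), 0)
  # majority base calling at the mixed position
  mostly_c <- toy_trace(fraction = 0.8)
  expect_identical(substr(mostly_c$called_bases, 9, 9), "C")
})

test_that("simulated screens are deterministic and anchored", {
  a <- simulate_screen(screen_spec(20, seed = 5))
  b <- simulate_screen(screen_spec(20, seed = 5))
  expect_identical(a, b)
  # n = 12, sd 0.5%, true 20%: aggregated mean within 0.5 of the truth
  re <- screen_efficiencies(
    simulate_screen(screen_spec(20, seed = 5), anticodon = "AGA",
                    codon = "UCU"))
  expect_lt(abs(re$mean - 20), 0.5)
})

test_that("the packaged fixture has 15 anticodons, 3 of them modified", {
  fx <- paper_fixture()
  expect_identical(fx$anticodon, fixture_anticodons)
  expect_equal(nrow(fx), 15L)
  modified <- fx$anticodon[fx$modification_fraction > 0]
  expect_setequal(modified, c("ACG", "AUG", "AAG"))
  expect_equal(fx$modification_fraction[fx$anticodon == "ACG"], 1.0)
  expect_equal(fx$modification_fraction[fx$anticodon == "AUG"], 0.5)
  expect_equal(fx$modification_fraction[fx$anticodon == "AAG"], 0.15)
})

test_that("fixture cells carry values, censoring, and evaluation status", {
  fx <- paper_fixture()
  expect_equal(fx$re_u[fx$anticodon == "AGA"], 19.7)
  # censored cells are NA sentinels (never zero), flagged bd
  auu <- fx[fx$anticodon == "AUU", ]
  expect_identical(auu$re_c_status, "bd")
  expect_true(is.na(auu$re_c))
  # not-evaluated cells are distinct from censored ones
  aaa <- fx[fx$anticodon == "AAA", ]
  expect_identical(aaa$re_a_status, "ne")
  # every targeted codon matches its anticodon by reverse complement
  expect_identical(vapply(fx$anticodon, targeted_codon, character(1),
                          USE.NAMES = FALSE),
                   fx$targeted_codon)
})

test_that("the long-format fixture table keeps censoring semantics", {
  re <- fixture_re_table()
  expect_equal(nrow(re), 60L) # 15 anticodons x 4 third bases
  expect_true(all(re$below_lod[re$status == "bd"]))
  expect_true(all(is.na(re$below_lod[re$status == "ne"])))
  expect_true(all(!re$below_lod[re$status == "ok"]))
  # AAU decodes its G-ending codon just above the LOD (0.27)
  aau_g <- re[re$anticodon == "AAU" & re$position3 == "G", ]
  expect_false(aau_g$below_lod)
})

test_that("synthetic references put tRNA base 34 last in read order", {
  # the sequenced strand is the reverse complement of the tRNA, so the
  # triplet must read as the DNA form of the targeted codon
  for (ac in fixture_anticodons) {
    ref <- reference_cdna(ac)
    triplet <- toupper(substr(ref, 13, 15))
    expect_identical(triplet, chartr("U", "T", targeted_codon(ac)))
  }
  expect_identical(substr(reference_cdna("AAA"), 13, 15), "ttt")
})

test_that("fixture traces are reproducible and carry the set fractions", {
  tr1 <- simulate_fixture_traces(seed = 3)
  tr2 <- simulate_fixture_traces(seed = 3)
  expect_identical(tr1, tr2)
  expect_identical(names(tr1), fixture_anticodons)
  # noise-free versions recover the exact generating fractions where the
  # quantified peak has no same-channel neighbour
  quiet <- simulate_fixture_traces(seed = 3, noise_sd = 0)
  fx <- paper_fixture()
  for (ac in c("ACG", "AUG", "AAA")) {
    locus <- locate_anticodon(quiet[[ac]], reference_cdna(ac))
    f <- estimate_inosine_fraction(
      integrate_peak(quiet[[ac]], locus$trace_index))
    expect_equal(f, fx$modification_fraction[fx$anticodon == ac],
                 tolerance = 1e-6)
  }
  # AAG reads CTT: the neighbouring T peak leaks a small tail into the
  # integration window, so recovery is close but not exact
  locus <- locate_anticodon(quiet[["AAG"]], reference_cdna("AAG"))
  f <- estimate_inosine_fraction(
    integrate_peak(quiet[["AAG"]], locus$trace_index))
  expect_equal(f, 0.15, tolerance = 0.01)
})
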