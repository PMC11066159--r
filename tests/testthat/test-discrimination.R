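test_that("discrimination ratios reproduce the published values", {
  cases <- list( # re_u, re_c, expected U share
    list(50, 5, 91L),     # worked example
    list(7.6, 6.1, 55L),  # Arg CGU/CGC
    list(6.1, 2.9, 68L),  # His CAU/CAC
    list(12.9, 10.3, 56L),# Pro CCU/CCC
    list(0.84, 0.59, 59L),# Val GUU/GUC
    list(1.3, 1.2, 52L),  # Ala GCU/GCC
    list(1.3, 0.40, 76L)  # Gly GGU/GGC
  )
  for (cs in cases) {
    dr <- discrimination_ratio(cs[[1]], cs[[2]])
    expect_identical(dr$u_share, cs[[3]])
    expect_identical(dr$c_share, 100L - cs[[3]])
    expect_false(dr$is_floor)
  }
  expect_identical(format_ratio(discrimination_ratio(7.6, 6.1)), "55:45")
})

test_that("equal efficiencies give 50:50 at any scale", {
  for (x in c(0.3, 1, 7.7, 50)) {
    expect_identical(discrimination_ratio(x, x)$u_share, 50L)
  }
})

test_that("the ratio is invariant under common scaling of both inputs", {
  expect_identical(discrimination_ratio(50, 5)$u_share,
                   discrimination_ratio(4, 0.4)$u_share)
  set.seed(11)
  for (i in 1:50) {
    u <- runif(1, 0.3, 60); cc <- runif(1, 0, 30); k <- runif(1, 0.01, 100)
    expect_identical(discrimination_ratio(k * u, k * cc)$u_share,
                     discrimination_ratio(u, cc)$u_share)
  }
})

test_that("the U share is monotone in both efficiencies", {
  us <- seq(0.5, 30, by = 0.7)
  shares_u <- vapply(us, function(u) discrimination_ratio(u, 5)$u_share,
                     integer(1))
  expect_true(all(diff(shares_u) >= 0L))
  cs <- seq(0, 30, by = 0.7)
  shares_c <- vapply(cs, function(cc) discrimination_ratio(8, cc)$u_share,
                     integer(1))
  expect_true(all(diff(shares_c) <= 0L))
})

test_that("integer shares agree with exact rational arithmetic", {
  # oracle on one-decimal inputs: shares from pure integer arithmetic,
  # round-half-up as floor((200 u10 + s) / (2 s)) with s = u10 + c10
  for (u10 in seq(1L, 300L, by = 13L)) {
    for (c10 in seq(0L, 200L, by = 11L)) {
      s <- u10 + c10
      oracle <- (200L * u10 + s) %/% (2L * s)
      dr <- discrimination_ratio(u10 / 10, c10 / 10)
      expect_identical(dr$u_share, as.integer(oracle))
    }
  }
})

test_that("the censored floor substitutes the LOD and flags itself", {
  acA <- discrimination_floor(3.6)
  expect_identical(acA$u_share, 95L)
  expect_true(acA$is_floor)
  expect_identical(format_ratio(acA), "≥95:5")
  acU <- discrimination_floor(9.4)
  expect_identical(acU$u_share, 98L) # 9.4/9.6 = 0.979 rounds half-up to 98
  # asymptote: u_share -> 100 as re_u grows
  expect_identical(discrimination_floor(1e6)$u_share, 100L)
})

test_that("the floor bounds the true ratio from below for censored re_c", {
  set.seed(5)
  for (i in 1:40) {
    u <- runif(1, 0.5, 40)
    true_c <- runif(1, 0, 0.2 - 1e-9) # true value somewhere under the LOD
    expect_lte(discrimination_floor(u)$u_share,
               discrimination_ratio(u, true_c)$u_share)
  }
})

test_that("domain errors for nonpositive or censored inputs", {
  expect_error(discrimination_ratio(0, 5), "positive")
  expect_error(discrimination_ratio(-1, 5), "positive")
  expect_error(discrimination_ratio(5, -1), ">= 0")
  expect_error(discrimination_floor(0), "positive")
  expect_error(format_ratio(list(u_share = 50)), "discrimination_ratio")
})

test_that("the detectability model reproduces both published anchors", {
  expect_equal(min_detectable_inosine_fraction(20, lod = 0.2, k = 2), 0.02)
  expect_equal(min_detectable_inosine_fraction(1, lod = 0.2, k = 2), 0.40)
  expect_equal(min_detectable_inosine_fraction(0.4, lod = 0.2, k = 2), 1.0)
})

test_that("detectable fraction decreases in efficiency until the cap", {
  res <- seq(0.05, 50, by = 0.05)
  f <- min_detectable_inosine_fraction(res)
  expect_true(all(diff(f) <= 0))
  expect_true(all(f <= 1 & f > 0))
  capped <- f == 1
  expect_true(all(diff(which(capped)) == 1L)) # cap is an initial segment
  expect_error(min_detectable_inosine_fraction(0), "positive")
})
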