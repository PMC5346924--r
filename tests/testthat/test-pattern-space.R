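# The dynamic-programming core: pattern counts, start matrices, expected
# coverage profiles, weighting and the numerical contracts.

test_that("pattern counts match hand-enumerated cases", {
  expect_equal(as.numeric(count_patterns(pattern_space_model(2, 2))), 1)
  expect_equal(as.numeric(count_patterns(pattern_space_model(10, 4))), 7)
  expect_equal(as.numeric(count_patterns(pattern_space_model(5, c(3, 4)))), 5)
  expect_equal(as.numeric(count_patterns(pattern_space_model(10, c(3, 4)))), 33)
  # tiling by unit fragments is unique, for any transcript length
  for (T in c(1, 7, 200)) {
    expect_equal(as.numeric(count_patterns(pattern_space_model(T, 1))), 1)
  }
  # transcript shorter than the smallest fragment: the single empty pattern
  expect_equal(as.numeric(count_patterns(pattern_space_model(3, c(5, 7)))), 1)
})

test_that("model validation rejects degenerate inputs", {
  expect_error(pattern_space_model(0, 2), "positive")
  expect_error(pattern_space_model(10, integer(0)), "non-empty")
  expect_error(pattern_space_model(10, c(3, 3)), "duplicate")
  expect_error(pattern_space_model(10, c(2, 3), weights = c("2" = 1)), "missing weights")
  expect_error(pattern_space_model(10, 2, weights = c("2" = -1)), "nonnegative")
  expect_error(pattern_space_model(10, 2, read_length = 0), "read_length")
})

test_that("start matrix matches brute-force placements", {
  sm <- start_matrix(pattern_space_model(5, 2))
  expect_equal(unname(sm[1, ]), c(2, 1, 1, 2, 0))
  sm2 <- start_matrix(pattern_space_model(5, c(3, 4)))
  expect_equal(unname(sm2["3", ]), c(1, 1, 1, 0, 0))
  expect_equal(unname(sm2["4", ]), c(1, 1, 0, 0, 0))
  # one-fragment transcript: single entry, carrying the weight
  smw <- start_matrix(pattern_space_model(6, 6, weights = c("6" = 0.25)))
  expect_equal(unname(smw[1, ]), c(0.25, 0, 0, 0, 0, 0))
  # rows are zero wherever the fragment no longer fits
  expect_true(all(sm2["4", 3:5] == 0))
})

test_that("expected profiles reproduce hand-derived vectors", {
  expect_equal(expected_profile(pattern_space_model(4, 2), "start_point")$values,
               c(1, 1, 1, 0))
  expect_equal(expected_profile(pattern_space_model(5, 2), "fragment")$values,
               c(2, 3, 2, 3, 2))
  # FCP is constant when the fragment spans the whole transcript
  fcp <- expected_profile(pattern_space_model(9, 9), "fragment")
  expect_equal(fcp$values, rep(1, 9))
})

test_that("read profile equals fragment profile when reads tile the fragment", {
  m <- pattern_space_model(1000, 200, read_length = 100)
  expect_identical(expected_profile(m, "read")$values,
                   expected_profile(m, "fragment")$values)
  # fully overlapping reads double the fragment profile for that length
  m2 <- pattern_space_model(300, 50, read_length = 80)
  expect_identical(expected_profile(m2, "read")$values,
                   2 * expected_profile(m2, "fragment")$values)
})

test_that("starting-point uniformity claims hold", {
  # unit fragments: flat SPP everywhere
  spp1 <- expected_profile(pattern_space_model(400, 1), "start_point")$values
  expect_equal(spp1, rep(1, 400))
  # F/T > 0.5: SPP constant over all potential start positions, zero after
  for (F in c(501, 700, 900)) {
    spp <- expected_profile(pattern_space_model(1000, F), "start_point")$values
    expect_equal(spp[1:(1000 - F + 1)], rep(spp[1], 1000 - F + 1))
    if (F < 1000) expect_equal(spp[(1000 - F + 2):1000], rep(0, F - 1))
  }
})

test_that("fragment coverage profile is reversal-symmetric", {
  for (lens in list(4, c(3, 4), c(2, 5), c(2, 3, 4, 5))) {
    fcp <- expected_profile(pattern_space_model(17, lens), "fragment")$values
    expect_equal(fcp, rev(fcp))
  }
})

test_that("profile sums obey the coverage-vector budgets", {
  m <- pattern_space_model(14, c(3, 5), read_length = 2)
  counts <- per_length_fragment_counts(m)
  spp <- expected_profile(m, "start_point")$values
  fcp <- expected_profile(m, "fragment")$values
  rcp <- expected_profile(m, "read")$values
  expect_equal(sum(spp), sum(counts))            # one SP per fragment
  expect_equal(sum(fcp), sum(counts * c(3, 5)))  # F bases per fragment
  expect_equal(sum(rcp), sum(counts * 2 * pmin(2, c(3, 5))))
})

test_that("per-length fragment counts match brute force", {
  expect_equal(per_length_fragment_counts(pattern_space_model(5, 2)),
               c("2" = 6))
  expect_equal(per_length_fragment_counts(pattern_space_model(5, c(3, 4))),
               c("3" = 3, "4" = 2))
  expect_equal(per_length_fragment_counts(pattern_space_model(8, 8)),
               c("8" = 1))
})

test_that("convolution identity links the start matrix to FCP and RCP", {
  m <- pattern_space_model(16, c(3, 6), read_length = 3)
  sm <- start_matrix(m)
  T <- 16
  fcp_manual <- numeric(T)
  for (j in 1:2) {
    F <- c(3, 6)[j]
    for (p in 0:(T - F)) {
      fcp_manual[(p + 1):(p + F)] <- fcp_manual[(p + 1):(p + F)] + sm[j, p + 1]
    }
  }
  expect_equal(expected_profile(m, "fragment")$values, fcp_manual)
  # reads of length F/2 tile the F=6 fragments: their RCP share equals FCP share
  m6 <- pattern_space_model(16, 6, read_length = 3)
  expect_identical(expected_profile(m6, "read")$values,
                   expected_profile(m6, "fragment")$values)
})

test_that("normalization behaves, including degenerate zero profiles", {
  p <- expected_profile(pattern_space_model(5, 2), "start_point")
  n <- normalize_profile(p)
  expect_equal(n$values, c(2, 1, 1, 2, 0) / 6)
  expect_true(n$normalized)
  expect_equal(sum(n$values), 1, tolerance = 1e-12)
  expect_identical(normalize_profile(n)$values, n$values) # idempotent
  zp <- suppressWarnings(expected_profile(pattern_space_model(2, 5), "fragment"))
  expect_equal(zp$values, c(0, 0))
  expect_warning(nz <- normalize_profile(zp), "all-zero")
  expect_false(nz$normalized)
})

test_that("transcript shorter than every fragment warns and yields zeros", {
  expect_warning(p <- expected_profile(pattern_space_model(3, 4), "start_point"),
                 "empty placement")
  expect_equal(p$values, c(0, 0, 0))
})

test_that("recursion agrees with the base case at the T = F boundary", {
  for (F in 2:6) {
    m <- pattern_space_model(F, F)
    expect_equal(as.numeric(count_patterns(m)), 1)
    expect_equal(expected_profile(m, "start_point")$values,
                 c(1, numeric(F - 1)))
  }
})

test_that("unit weights reproduce the unweighted profiles bit-identically", {
  for (mode in c("contribution", "pattern")) {
    m0 <- pattern_space_model(20, c(3, 4), read_length = 2)
    m1 <- pattern_space_model(20, c(3, 4), weights = c("3" = 1, "4" = 1),
                              read_length = 2, weight_mode = mode)
    for (kind in c("start_point", "fragment", "read")) {
      expect_identical(weighted_profile(m1, kind)$values,
                       expected_profile(m0, kind)$values)
    }
  }
})

test_that("contribution weights scale per-length contributions", {
  m <- pattern_space_model(5, c(3, 4), weights = c("3" = 0, "4" = 1))
  expect_equal(weighted_profile(m, "start_point")$values, c(1, 1, 0, 0, 0))
  m2 <- pattern_space_model(5, c(3, 4), weights = c("3" = 2, "4" = 2))
  base <- expected_profile(pattern_space_model(5, c(3, 4)), "start_point")$values
  expect_equal(weighted_profile(m2, "start_point")$values, 2 * base)
  expect_error(weighted_profile(pattern_space_model(5, 2), "start_point"),
               "no weights")
})

test_that("weighted pattern mass generalizes the pattern count", {
  m <- pattern_space_model(10, 4, weights = c("4" = 1))
  expect_equal(weighted_pattern_mass(m), 7)
  expect_equal(weighted_pattern_mass(
    pattern_space_model(7, 7, weights = c("7" = 0.5))), 0.5)
  expect_equal(weighted_pattern_mass(
    pattern_space_model(12, c(3, 4), weights = c("3" = 0, "4" = 0))), 0)
  # pattern-mode profile with one zero-weight length drops whole patterns: on
  # T = 8 only {4@0, 4@4} and the singleton {4@2} carry mass, and the oracle
  # computed in pattern mode agrees entry for entry
  mp <- pattern_space_model(8, c(3, 4), weights = c("3" = 0, "4" = 1),
                            weight_mode = "pattern")
  spp_mp <- weighted_profile(mp, "start_point")$values
  expect_equal(spp_mp, c(1, 0, 1, 0, 1, 0, 0, 0))
  expect_equal(spp_mp, profile_from_patterns(enumerate_patterns(mp),
                                             "start_point")$values)
})

test_that("float and exact paths agree to 1e-9 up to T = 60", {
  for (lens in list(2, 5, c(2, 5), c(3, 4), c(2, 3, 4, 5))) {
    for (T in c(30, 45, 60)) {
      m <- pattern_space_model(T, lens, read_length = 3)
      exact_fp <- as.numeric(count_patterns(m))
      float_fp <- fragpattern:::.suffix_counts(T, m$lengths)[T + 1]
      expect_equal(float_fp, exact_fp, tolerance = 1e-9)
      for (kind in c("start_point", "fragment", "read")) {
        pf <- expected_profile(m, kind)$values
        pe <- expected_profile(m, kind, exact = TRUE)$values
        expect_equal(pf, pe, tolerance = 1e-9)
      }
    }
  }
})

test_that("log-space fallback matches the double path and survives overflow", {
  v <- fragpattern:::.suffix_counts(200, c(3, 4))
  lv <- fragpattern:::.suffix_counts_log(200, c(3, 4))
  expect_equal(exp(lv), v, tolerance = 1e-9)
  # T chosen so FP overflows doubles: normalized profile must still be finite
  p <- expected_profile(pattern_space_model(5000, 2), "start_point",
                        normalized = TRUE)
  expect_true(all(is.finite(p$values)))
  expect_equal(sum(p$values), 1, tolerance = 1e-12)
  fp <- count_patterns(pattern_space_model(5000, 2))
  expect_gt(nchar(as.character(fp)), 308) # past double range, still exact
})
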