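# The seeded fragmentation -> PCR -> sequencing simulator.

test_that("pattern sampling is exactly uniform over small pattern spaces", {
  m <- pattern_space_model(10, 4)
  oracle <- enumerate_patterns(m)
  keys <- vapply(oracle, function(p) paste(p[, "start"], collapse = ","),
                 character(1))
  draws <- sample_patterns(m, 10000, seed = 424)
  got <- vapply(draws, function(p) paste(p[, "start"], collapse = ","),
                character(1))
  expect_true(all(got %in% keys))
  counts <- table(factor(got, levels = keys))
  gof <- suppressWarnings(chisq.test(counts, p = rep(1 / 7, 7)))
  expect_gt(gof$p.value, 0.001)
})

test_that("weighted sampling follows pattern-mass probabilities", {
  w <- c("3" = 1, "4" = 3)
  m <- pattern_space_model(7, c(3, 4), weights = w, weight_mode = "pattern")
  oracle <- enumerate_patterns(m)
  mass <- vapply(oracle, function(p) prod(w[as.character(p[, "length"])]),
                 numeric(1))
  keys <- vapply(oracle, function(p) paste(p[, "start"], p[, "length"],
                                           collapse = ";"), character(1))
  draws <- sample_patterns(m, 8000, seed = 99)
  got <- vapply(draws, function(p) paste(p[, "start"], p[, "length"],
                                         collapse = ";"), character(1))
  counts <- table(factor(got, levels = keys))
  gof <- suppressWarnings(chisq.test(counts, p = mass / sum(mass)))
  expect_gt(gof$p.value, 0.001)
  # zero-weight lengths are never sampled
  m0 <- pattern_space_model(12, c(3, 4), weights = c("3" = 0, "4" = 1),
                            weight_mode = "pattern")
  d0 <- sample_patterns(m0, 200, seed = 5)
  expect_false(any(vapply(d0, function(p) any(p[, "length"] == 3), logical(1))))
})

test_that("degenerate models fragment deterministically", {
  # transcript equal to the single fragment length: always one fragment at 0
  m <- pattern_space_model(8, 8)
  pats <- sample_patterns(m, 20, seed = 1)
  for (p in pats) expect_equal(unname(p), cbind(0, 8), ignore_attr = TRUE)
  # unit fragments tile every position of every molecule
  cfg <- simulation_config(pattern_space_model(6, 1), molecules = 100, seed = 2)
  lib <- fragment_molecules(cfg)
  expect_equal(sum(lib$multiplicity), 600)
  expect_equal(lib$multiplicity, rep(100, 6))
})

test_that("fragments per molecule match the pattern-space expectation", {
  m <- pattern_space_model(1000, 100)
  expected_rate <- sum(per_length_fragment_counts(m)) /
    as.numeric(count_patterns(m))
  cfg <- simulation_config(m, molecules = 500, seed = 31)
  lib <- fragment_molecules(cfg)
  observed_rate <- sum(lib$multiplicity) / 500
  # ~9 fragments/molecule; allow 3 standard errors of the per-molecule spread
  expect_lt(abs(observed_rate - expected_rate), 3 * 1 / sqrt(500) * 1.5)
})

test_that("uniform amplification multiplies every multiplicity exactly", {
  cfg <- simulation_config(pattern_space_model(20, 4), 50, seed = 8)
  lib <- fragment_molecules(cfg)
  amp <- amplify(lib, 15)
  expect_identical(amp$multiplicity, lib$multiplicity * 32768)
  expect_identical(attr(amp, "stage"), "amplified")
  amp0 <- amplify(lib, 0)
  expect_identical(amp0$multiplicity, lib$multiplicity)
  expect_error(amplify(amp, 2), "fragmented") # stage is enforced
})

test_that("sequencing samples without replacement from the pool", {
  cfg <- simulation_config(pattern_space_model(50, 10), 30, seed = 12)
  amp <- amplify(fragment_molecules(cfg), 3)
  total <- sum(amp$multiplicity)
  whole <- sample_sequenced(amp, total)
  expect_identical(whole$multiplicity, amp$multiplicity) # S == pool: everything
  sub <- sample_sequenced(amp, 17)
  expect_equal(sum(sub$multiplicity), 17)
  expect_true(all(sub$multiplicity <= amp$multiplicity[match(
    paste(sub$start, sub$length), paste(amp$start, amp$length))]))
  expect_error(sample_sequenced(amp, total + 1), "pool")
  # species drawn proportionally to multiplicity: 3:1 two-species pool
  pool <- fragpattern:::.new_library(
    data.frame(start = c(0, 5), length = c(2, 2),
               multiplicity = c(75000, 25000)),
    "amplified", pattern_space_model(10, 2))
  set.seed(77)
  drawn <- sample_sequenced(pool, 20000)
  expect_equal(drawn$multiplicity[1] / sum(drawn$multiplicity), 0.75,
               tolerance = 0.02)
})

test_that("observed profiles sum fragment coverage vectors", {
  m <- pattern_space_model(10, 4, read_length = 2)
  lib <- fragpattern:::.new_library(
    data.frame(start = 3, length = 4, multiplicity = 1), "sequenced", m)
  expect_equal(observed_profile(lib, "start_point")$values,
               c(0, 0, 0, 1, 0, 0, 0, 0, 0, 0))
  lib2 <- fragpattern:::.new_library(
    data.frame(start = 0, length = 4, multiplicity = 1), "sequenced", m)
  expect_equal(observed_profile(lib2, "read")$values[1:4], c(1, 1, 1, 1))
  expect_equal(observed_profile(lib2, "fragment")$values,
               c(1, 1, 1, 1, numeric(6)))
})

test_that("identical seeds give bit-identical simulations", {
  m <- pattern_space_model(300, c(40, 60), read_length = 20)
  cfg <- simulation_config(m, 40, pcr_cycles = 4, n_fragments = 500, seed = 2024)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$values, b$values)
  cfg2 <- cfg; cfg2$seed <- 2025
  expect_false(identical(simulate_experiment(cfg2)$values, a$values))
})

test_that("amplification does not change normalized profiles", {
  cfg <- simulation_config(pattern_space_model(80, 20), 60, seed = 55)
  lib <- fragment_molecules(cfg)
  p0 <- normalize_profile(observed_profile(amplify(lib, 0), "start_point"))
  p9 <- normalize_profile(observed_profile(amplify(lib, 9), "start_point"))
  expect_equal(p0$values, p9$values, tolerance = 1e-12)
})

test_that("simulated SPPs converge to the model SPP as molecules grow", {
  m <- pattern_space_model(1000, 100)
  model_spp <- expected_profile(m, "start_point", normalized = TRUE)$values
  tv <- function(M) {
    cfg <- simulation_config(m, M, pcr_cycles = 0, n_fragments = 1)
    lib <- amplify(fragment_molecules(cfg), 0)
    lib <- sample_sequenced(lib, sum(lib$multiplicity)) # sequence everything
    sim <- observed_profile(lib, "start_point")
    0.5 * sum(abs(norm_values(sim) - model_spp))
  }
  set.seed(909)
  tvs <- vapply(c(500, 5000, 50000), tv, numeric(1))
  expect_true(all(diff(tvs) < 0))
  expect_lt(tvs[3], 0.03)
})
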