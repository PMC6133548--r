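test_that("population tabulation counts animals per bin", {
  # one bin with 5 ASE / 1 AFD / 0 AWA across 6 animals
  labels <- matrix("ASE", nrow = 6, ncol = 3)
  labels[1, 2] <- "AFD"
  pop <- middle_population(labels)
  expect_equal(unname(pop$counts[2, ]), c(0, 1, 5))  # AWA, AFD, ASE
  expect_true(all(rowSums(pop$counts) == 6))

  # single animal: unit vector at each bin
  pop1 <- middle_population(matrix(c("AWA", "ASE"), nrow = 1))
  expect_true(all(rowSums(pop1$counts) == 1))
  expect_equal(unname(pop1$counts[1, "AWA"]), 1)

  expect_error(middle_population(matrix("XXX", 2, 2)), "drawn from")
})

test_that("chi-squared against random uses expected counts of n/3", {
  cs <- chi_squared_vs_random(c(7, 7, 7))
  expect_equal(cs$expected, 7)
  expect_equal(cs$statistic, 0)
  expect_equal(cs$p, 1)

  # hand arithmetic: (81 + 9 + 36) / 6 = 21
  cs <- chi_squared_vs_random(c(15, 3, 0))
  expect_equal(cs$statistic, 21)
  expect_equal(cs$p, pchisq(21, 2, lower.tail = FALSE))

  expect_error(chi_squared_vs_random(c(3, 2, 1)), "permutation")
  expect_error(chi_squared_vs_random(c(7, 7, 7), n = 20), "sum")
})

test_that("the statistic is zero only for perfectly uniform counts", {
  withr::with_seed(14, {
    for (k in 1:50) {
      cnt <- as.integer(rmultinom(1, 21, rep(1 / 3, 3)))
      stat <- chi_squared_vs_random(cnt)$statistic
      if (all(cnt == 7)) expect_equal(stat, 0) else expect_gt(stat, 0)
    }
  })
})

test_that("Fisher 3x2 p-values match the reference exact test", {
  # unique table given margins
  expect_equal(fisher_exact_3x2(rbind(c(9, 0, 0), c(9, 0, 0))), 1)
  # row-swap symmetry
  expect_equal(fisher_exact_3x2(rbind(c(2, 1, 0), c(0, 1, 2))),
               fisher_exact_3x2(rbind(c(0, 1, 2), c(2, 1, 0))))
  # column permutation invariance
  t0 <- rbind(c(5, 2, 1), c(1, 4, 3))
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1)))
    expect_equal(fisher_exact_3x2(t0[, perm]), fisher_exact_3x2(t0))
  # against stats::fisher.test on assorted tables
  tabs <- list(rbind(c(2, 1, 0), c(0, 1, 2)),
               rbind(c(15, 3, 0), c(6, 6, 6)),
               rbind(c(0, 3, 1), c(0, 2, 2)),
               rbind(c(8, 0, 0), c(0, 8, 0)),
               rbind(c(4, 4, 4), c(4, 4, 4)))
  for (tb in tabs)
    expect_equal(fisher_exact_3x2(tb), fisher.test(tb)$p.value,
                 tolerance = 1e-9)
  # always a valid probability
  withr::with_seed(6, {
    for (k in 1:50) {
      tb <- matrix(rpois(6, 4), 2, 3)
      p <- fisher_exact_3x2(tb)
      expect_gt(p, 0); expect_lte(p, 1)
    }
  })
})

test_that("simulated random cohorts are seeded equal-probability multinomials", {
  expect_equal(unname(simulate_random_counts(0)), c(0, 0, 0))
  expect_identical(simulate_random_counts(18, seed = 3),
                   simulate_random_counts(18, seed = 3))
  draws <- vapply(1:10000, function(i) simulate_random_counts(18, seed = i),
                  c(AWA = 0L, AFD = 0L, ASE = 0L))
  expect_true(all(abs(rowMeans(draws) - 6) < 0.1))
})

test_that("count scaling reproduces proportional cohorts", {
  expect_equal(unname(scale_counts(c(0, 1, 5), 18)), c(0, 3, 15))
})

test_that("the permutation comparison yields 501 p-values with a calibrated rank", {
  pr <- permutation_rank(c(15, 3, 0), c(6, 6, 6), iterations = 500, seed = 2)
  expect_length(pr$resampled_p, 500)
  expect_equal(pr$total, 501L)
  expect_true(pr$rank >= 1 && pr$rank <= 501)

  # identical populations: nominal p is maximal, so the rank is maximal
  pr <- permutation_rank(c(6, 6, 6), c(6, 6, 6), iterations = 200, seed = 5)
  expect_equal(pr$nominal_p, 1)
  expect_equal(pr$rank, 201L)

  # fully separated populations rank first across seeds
  for (seed in 1:10) {
    pr <- permutation_rank(c(18, 0, 0), c(0, 18, 0), iterations = 500,
                           seed = seed)
    expect_equal(pr$rank, 1L)
    expect_identical(pr$tier, "p<0.01")
  }
})

test_that("permutation ranks are calibrated and conservative at the tail", {
  reps <- 400
  ranks <- vapply(seq_len(reps), function(i) {
    obs <- simulate_random_counts(20, seed = 2 * i)
    test <- simulate_random_counts(20, seed = 2 * i + 1)
    permutation_rank(obs, test, iterations = 500, seed = 90000 + i)$rank
  }, 1L)
  # significance-tier calibration: binomial 3.5-sigma bands around r/501
  for (r in c(25, 5)) {
    p0 <- r / 501
    expect_lt(abs(mean(ranks <= r) - p0),
              3.5 * sqrt(p0 * (1 - p0) / reps) + 1e-9)
  }
  # validity: empirical P(rank <= r) never exceeds r/total beyond noise
  for (r in c(10, 50, 125, 250, 375)) {
    p0 <- r / 501
    expect_lt(mean(ranks <= r), p0 + 3.5 * sqrt(p0 * (1 - p0) / reps))
  }
})

test_that("rank thresholds follow the largest-r-below-alpha rule", {
  expect_equal(significance_threshold(0.05, 501), 25L)
  expect_equal(significance_threshold(0.01, 501), 5L)
  expect_equal(significance_threshold(1.0, 501), 500L)
  expect_identical(rank_to_significance(5, 501), "p<0.01")
  expect_identical(rank_to_significance(6, 501), "p<0.05")
  expect_identical(rank_to_significance(25, 501), "p<0.05")
  expect_identical(rank_to_significance(26, 501), "ns")
})

test_that("random same-size cohorts rarely reach significance per bin", {
  pa <- generate_population("random", 20, 60, seed = 41)
  pb <- generate_population("random", 20, 60, seed = 42)
  cmp <- compare_populations(pa, pb, iterations = 500, seed = 43)
  expect_lte(mean(cmp$tier != "ns"), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("switch points require persistence beyond a single bin", {
  expect_true(is.na(detect_switch_point(rep("ASE", 50))$bin))

  s <- detect_switch_point(c(rep("AFD", 30), rep("ASE", 70)))
  expect_equal(s$bin, 31)
  expect_identical(s$from, "AFD")
  expect_identical(s$to, "ASE")

  # single-bin blip ignored: AFD x30, ASE x1, AFD x5, ASE x64 -> bin 37
  labs <- c(rep("AFD", 30), "ASE", rep("AFD", 5), rep("ASE", 64))
  s <- detect_switch_point(labs)
  expect_equal(s$bin, 37)
  expect_identical(s$to, "ASE")
})

test_that("majority profiles recover planted switch bins", {
  pop <- generate_population("switch", 18, 100, seed = 4, switch_bin = 44,
                             noise_rate = 0.05)
  s <- detect_switch_point(majority_middle(pop))
  expect_lte(abs(s$bin - 44), 2)
})

test_that("switch-point samples are compared by the two-sample KS test", {
  a <- c(30, 32, 33, 35, 38)
  b <- c(50, 52, 55, 57)
  r <- compare_switch_points(a, b)
  expect_equal(r$statistic, ecdf_gap(a, b))
  expect_equal(r$statistic, 1)  # disjoint supports

  r2 <- compare_switch_points(a, a)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)

  c1 <- c(30, 35, 40, 45, 50); c2 <- c(33, 36, 44, 52)
  expect_equal(compare_switch_points(c1, c2)$statistic, ecdf_gap(c1, c2))

  expect_error(compare_switch_points(numeric(0), b), "non-empty")
})
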