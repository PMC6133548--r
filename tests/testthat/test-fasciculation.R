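make_profile <- function(width, id = "a", n_bins = length(width)) {
  structure(list(animal_id = id, n_bins = as.integer(n_bins),
                 d_bins = cbind(d_AWA_ASE = width, d_AWA_AFD = width / 2,
                                d_AFD_ASE = width / 2),
                 width = width, middle = rep("AFD", n_bins),
                 ambiguous = rep(FALSE, n_bins), n_ambiguous = 0L,
                 head_length_um = NA_real_, stage = "L4",
                 defasciculated = NA),
            class = "bundle_profile")
}

test_that("reference statistics are per-bin sample mean and SD", {
  p1 <- make_profile(rep(1, 100)); p2 <- make_profile(rep(2, 100))
  ref <- reference_stats(list(p1, p2))
  expect_equal(ref$mean, rep(1.5, 100))
  expect_equal(ref$sd, rep(sd(c(1, 2)), 100))  # sample SD ~ 0.707
  expect_equal(ref$sd[1], 0.7071068, tolerance = 1e-6)

  # identical profiles: SD zero everywhere
  ref0 <- reference_stats(list(p1, p1, p1))
  expect_true(all(ref0$sd == 0))

  expect_error(reference_stats(list(p1)), "length")
  expect_error(reference_stats(list(p1, make_profile(rep(1, 50)))),
               "mixed n_bins")
})

test_that("reference recovers the generator's width within two standard errors", {
  profs <- generate_profiles(20, seed = 55, order_model = "fixed",
                             center_spacing_um = 1.0, width_sd_um = 0.1)
  ref <- reference_stats(profs)
  wa <- vapply(profs, function(p) mean(p$width), 1)  # per-animal mean width
  expect_lt(abs(mean(wa) - 1.0), 2 * sd(wa) / sqrt(length(wa)))
  expect_lt(abs(mean(ref$mean) - 1.0), 0.05)
})

test_that("the z-score run rule classifies exactly as stated", {
  ref <- structure(list(mean = rep(1, 100), sd = rep(0.1, 100), n = 20,
                        n_bins = 100L, stage = "L4"),
                   class = "reference_profile")

  # widths equal to the mean: clean
  r <- classify_defasciculation(make_profile(rep(1, 100)), ref)
  expect_false(r$defasciculated)
  expect_equal(nrow(r$flagged_runs), 0)
  expect_true(all(r$z == 0))

  # 12 consecutive bins at mean + 4 SD: defasciculated, run (40, 51)
  w <- rep(1, 100); w[40:51] <- 1 + 4 * 0.1
  r <- classify_defasciculation(make_profile(w), ref)
  expect_true(r$defasciculated)
  expect_equal(r$flagged_runs$start_bin, 40)
  expect_equal(r$flagged_runs$end_bin, 51)

  # same excursion on only 9 bins: below the run length, fasciculated
  w <- rep(1, 100); w[40:48] <- 1 + 4 * 0.1
  expect_false(classify_defasciculation(make_profile(w), ref)$defasciculated)

  # threshold is strict: staying at or below 3.5 SD does not trigger
  w <- rep(1, 100); w[30:60] <- 1 + 3.4999 * 0.1
  expect_false(classify_defasciculation(make_profile(w), ref)$defasciculated)
  w[30:60] <- 1 + 3.51 * 0.1
  expect_true(classify_defasciculation(make_profile(w), ref)$defasciculated)

  # one-sided: narrow bundles never trigger
  expect_false(classify_defasciculation(make_profile(rep(0.1, 100)),
                                        ref)$defasciculated)
})

test_that("zero-SD reference bins use the degenerate z convention", {
  ref <- structure(list(mean = rep(1, 100), sd = rep(0, 100), n = 3,
                        n_bins = 100L, stage = "L4"),
                   class = "reference_profile")
  w <- rep(1, 100); w[10:25] <- 1.2
  r <- classify_defasciculation(make_profile(w), ref)
  expect_true(all(r$z[10:25] == Inf))
  expect_true(all(r$z[-(10:25)] == 0))
  expect_true(r$defasciculated)
})

test_that("classification is monotone in width and degenerate thresholds behave", {
  ref <- structure(list(mean = rep(1, 100), sd = rep(0.1, 100), n = 20,
                        n_bins = 100L, stage = "L4"),
                   class = "reference_profile")
  withr::with_seed(2, {
    w <- 1 + rnorm(100, 0, 0.1)
    base <- classify_defasciculation(make_profile(w), ref)
    # increasing any bin's width never flips defasciculated -> fasciculated
    w2 <- w; w2[50] <- w2[50] + 5
    r2 <- classify_defasciculation(make_profile(w2), ref)
    expect_gte(r2$defasciculated, base$defasciculated)
    # infinite threshold: everything fasciculated
    expect_false(classify_defasciculation(make_profile(w + 100), ref,
                                          z_threshold = Inf)$defasciculated)
    # run_length 1 + threshold 0 flags any bin above the mean
    r0 <- classify_defasciculation(make_profile(pmax(w, 1 + 1e-6)), ref,
                                   z_threshold = 0, run_length = 1)
    expect_true(r0$defasciculated)
  })
})

test_that("defasciculated bundles are partitioned out of the cohort", {
  ref <- structure(list(mean = rep(1, 100), sd = rep(0.1, 100), n = 20,
                        n_bins = 100L, stage = "L4"),
                   class = "reference_profile")
  clean <- lapply(1:16, function(i) make_profile(rep(1, 100), id = paste0("c", i)))
  wide <- lapply(1:5, function(i) {
    w <- rep(1, 100); w[20:39] <- 2
    make_profile(w, id = paste0("d", i))
  })
  profiles <- c(clean, wide)
  results <- lapply(profiles, classify_defasciculation, ref = ref)
  part <- exclude_defasciculated(profiles, results)
  expect_length(part$retained, 16)
  expect_length(part$excluded, 5)
  expect_true(all(vapply(part$excluded, `[[`, TRUE, "defasciculated")))
  expect_true(all(startsWith(vapply(part$excluded, `[[`, "", "animal_id"), "d")))

  # no defasciculated bundles: identity partition
  part2 <- exclude_defasciculated(clean, lapply(clean,
                                                classify_defasciculation,
                                                ref = ref))
  expect_length(part2$retained, 16)
  expect_length(part2$excluded, 0)

  # all defasciculated: downstream tabulation refuses
  part3 <- exclude_defasciculated(wide, lapply(wide,
                                               classify_defasciculation,
                                               ref = ref))
  expect_length(part3$retained, 0)
  expect_error(tabulate_population(part3$retained), "no profiles")

  expect_error(exclude_defasciculated(profiles, results[1:3]), "differ")
})
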