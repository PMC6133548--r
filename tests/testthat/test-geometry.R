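test_that("cropping identical traces returns them unchanged", {
  tr <- helical_traces()
  out <- crop_to_common_extent(tr$AWA, tr$AWA, tr$AWA)
  for (o in out) expect_identical(o$points, tr$AWA$points)
})

test_that("parallel lines of different lengths are cropped to the common extent", {
  z <- function(len) seq(0, len, by = 0.5)
  t1 <- dendrite_trace(cbind(0, 0, z(100)), label = "AWA")
  t2 <- dendrite_trace(cbind(1, 0, z(90)), label = "AFD")
  t3 <- dendrite_trace(cbind(0, 1, z(80)), label = "ASE")
  out <- crop_to_common_extent(t1, t2, t3)
  # shared end at z = 0 stays; far ends pulled back to the shortest (80 um)
  for (o in out) {
    expect_equal(min(o$points[, "z_um"]), 0)
    expect_equal(max(o$points[, "z_um"]), 80)
  }
})

test_that("axially offset traces are cropped to their overlap", {
  t1 <- dendrite_trace(cbind(0, 0, seq(0, 50, by = 0.5)), label = "AWA")
  t2 <- dendrite_trace(cbind(1, 0, seq(5, 55, by = 0.5)), label = "AFD")
  t3 <- dendrite_trace(cbind(0, 1, seq(5, 50, by = 0.5)), label = "ASE")
  out <- crop_to_common_extent(t1, t2, t3)
  for (o in out) {
    expect_equal(min(o$points[, "z_um"]), 5)
    expect_equal(max(o$points[, "z_um"]), 50)
  }
})

test_that("the centroid line is the per-sample mean of the three traces", {
  tr <- parallel_traces()
  ctr <- centroid_line(tr$AWA, tr$AFD, tr$ASE)
  expect_equal(unname(ctr[, 1]), rep(1 / 3, nrow(ctr)))
  expect_equal(unname(ctr[, 2]), rep(1 / 3, nrow(ctr)))

  # three identical traces: centroid equals the (arc-length resampled) trace
  h <- helical_traces()
  ctr2 <- centroid_line(h$AWA, h$AWA, h$AWA)
  expect_equal(unname(ctr2),
               unname(bundleorder:::resample_trace(h$AWA$points, nrow(ctr2))),
               tolerance = 1e-12)

  # helical triplet: centroid is the mean of the resampled triple, hence
  # inside the triangle they span at every sample
  ctr3 <- centroid_line(h$AWA, h$AFD, h$ASE)
  n <- nrow(ctr3)
  res <- lapply(h, function(t) bundleorder:::resample_trace(t$points, n))
  expect_equal(ctr3, (res[[1]] + res[[2]] + res[[3]]) / 3)
})

test_that("parallel-line cross-sections have the plane-geometry distances", {
  tr <- parallel_traces()
  sec <- cross_sections(tr$AWA, tr$AFD, tr$ASE)
  expect_equal(sec$d_AWA_AFD, rep(1, nrow(sec)))
  expect_equal(sec$d_AWA_ASE, rep(1, nrow(sec)))
  expect_equal(sec$d_AFD_ASE, rep(sqrt(2), nrow(sec)))
  expect_equal(sec$width, rep(sqrt(2), nrow(sec)))
  # longest side AFD-ASE, so AWA is in the middle everywhere
  expect_true(all(sec$middle == "AWA"))
})

test_that("distances and middle calls are invariant under rigid transforms", {
  h <- helical_traces(seed = 3)
  sec0 <- cross_sections(h$AWA, h$AFD, h$ASE)
  withr::with_seed(10, {
    for (k in 1:10) {
      rig <- random_rigid()
      moved <- lapply(h, apply_rigid, rig = rig)
      sec <- cross_sections(moved$AWA, moved$AFD, moved$ASE)
      expect_equal(sec$d_AWA_ASE, sec0$d_AWA_ASE, tolerance = 1e-9)
      expect_equal(sec$d_AWA_AFD, sec0$d_AWA_AFD, tolerance = 1e-9)
      expect_equal(sec$d_AFD_ASE, sec0$d_AFD_ASE, tolerance = 1e-9)
      expect_identical(sec$middle, sec0$middle)
    }
  })
})

test_that("nearest section points match an exhaustive per-vertex search", {
  h <- helical_traces(seed = 8)
  ctr <- centroid_line(h$AWA, h$AFD, h$ASE)
  sec <- cross_sections(h$AWA, h$AFD, h$ASE, centroid = ctr)
  near <- attr(sec, "points")
  for (i in seq(1, nrow(ctr), by = 17)) {
    for (d in DENDRITES) {
      p <- h[[d]]$points
      dists <- sqrt(colSums((t(p) - ctr[i, ])^2))
      expect_equal(unname(near[[d]][i, ]), unname(p[which.min(dists), ]))
    }
  }
})

test_that("reversing all traces reverses sections without changing values", {
  h <- helical_traces(seed = 12)
  rev_tr <- lapply(h, function(t)
    dendrite_trace(t$points[nrow(t$points):1, ], label = t$label,
                   source = t$source))
  s1 <- cross_sections(h$AWA, h$AFD, h$ASE)
  s2 <- cross_sections(rev_tr$AWA, rev_tr$AFD, rev_tr$ASE)
  expect_equal(s2$width, rev(s1$width), tolerance = 1e-9)
  expect_identical(s2$middle, rev(s1$middle))
})

test_that("the middle dendrite is the vertex opposite the longest side", {
  # longest distance AWA-ASE -> AFD in the middle
  m <- middle_dendrite(c(d_AWA_ASE = 2, d_AWA_AFD = 1.2, d_AFD_ASE = 1.1))
  expect_identical(m$middle, "AFD")
  expect_false(m$ambiguous)

  # equilateral triangle: ambiguous, resolved by alphabetical priority
  m <- middle_dendrite(c(d_AWA_ASE = 1, d_AWA_AFD = 1, d_AFD_ASE = 1))
  expect_true(m$ambiguous)
  expect_identical(m$middle, "AFD")

  # degenerate all-zero section
  m <- middle_dendrite(c(d_AWA_ASE = 0, d_AWA_AFD = 0, d_AFD_ASE = 0))
  expect_true(m$ambiguous)

  # random triangles against the smallest-incident-sum oracle
  withr::with_seed(77, {
    for (k in 1:1000) {
      s <- sort(runif(3, 0.1, 5), decreasing = TRUE)
      if (s[1] >= s[2] + s[3]) next     # not a triangle
      if (s[1] - s[2] < 1e-6) next      # near-tie: oracle undefined
      d <- c(d_AWA_ASE = NA, d_AWA_AFD = NA, d_AFD_ASE = NA)
      d[sample(3)] <- s
      expect_identical(middle_dendrite(d)$middle,
                       middle_oracle(d["d_AWA_ASE"], d["d_AWA_AFD"],
                                     d["d_AFD_ASE"]))
    }
  })
})

test_that("binning averages pairs of adjacent positions for 200 sections", {
  withr::with_seed(4, {
    n <- 200
    d1 <- runif(n, 0.5, 2); d2 <- runif(n, 0.5, 2); d3 <- runif(n, 0.5, 2)
    sec <- bundleorder:::sections_from_distances(
      data.frame(position = 1:n, d_AWA_ASE = d1, d_AWA_AFD = d2,
                 d_AFD_ASE = d3))
    prof <- bin_profile(sec, n_bins = 100)
    k <- 37
    expect_equal(unname(prof$d_bins[k, "d_AWA_ASE"]),
                 mean(d1[c(2 * k - 1, 2 * k)]))
    expect_equal(prof$width[k], mean(pmax(d1, d2, d3)[c(2 * k - 1, 2 * k)]))
  })
})

test_that("binning conserves the global mean for uneven divisions", {
  withr::with_seed(9, {
    n <- 250
    d1 <- runif(n); d2 <- runif(n); d3 <- runif(n)
    sec <- bundleorder:::sections_from_distances(
      data.frame(position = 1:n, d_AWA_ASE = d1, d_AWA_AFD = d2,
                 d_AFD_ASE = d3))
    prof <- bin_profile(sec, n_bins = 100)
    sizes <- diff(round((0:100) * n / 100))
    expect_equal(sum(prof$d_bins[, "d_AWA_ASE"] * sizes) / n, mean(d1))
    # constant distances: every bin mean equals the constant
    secc <- bundleorder:::sections_from_distances(
      data.frame(position = 1:n, d_AWA_ASE = 1.5, d_AWA_AFD = 1.1,
                 d_AFD_ASE = 0.9))
    pc <- bin_profile(secc, n_bins = 100)
    expect_true(all(pc$d_bins[, "d_AWA_ASE"] == 1.5))
    expect_true(all(pc$width == 1.5))
  })
})

test_that("binning refuses fewer sections than bins", {
  sec <- bundleorder:::sections_from_distances(
    data.frame(position = 1:50, d_AWA_ASE = 1, d_AWA_AFD = 1, d_AFD_ASE = 1))
  expect_error(bin_profile(sec, n_bins = 100), "at least n_bins")
})

test_that("cross-section invariants hold on generated bundles", {
  profs <- generate_profiles(2, seed = 30, order_model = "random",
                             noise_rate = 0.1)
  for (p in profs) {
    truth <- attr(p, "truth")
    sec <- cross_sections(truth$traces$AWA, truth$traces$AFD,
                          truth$traces$ASE)
    expect_equal(sec$width, pmax(sec$d_AWA_ASE, sec$d_AWA_AFD, sec$d_AFD_ASE))
    # triangle inequality for every section
    expect_true(all(sec$d_AWA_ASE + sec$d_AWA_AFD >= sec$d_AFD_ASE - 1e-12))
    expect_true(all(sec$d_AWA_ASE + sec$d_AFD_ASE >= sec$d_AWA_AFD - 1e-12))
    expect_true(all(sec$d_AWA_AFD + sec$d_AFD_ASE >= sec$d_AWA_ASE - 1e-12))
  }
})
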