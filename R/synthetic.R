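#' Specify a synthetic dendrite bundle phantom
#'
#' Collects the parameters of the synthetic three-dendrite bundle generator.
#' Defaults emulate the larval-stage amphid bundle: three ~0.5 um diameter
#' dendrites fasciculated at a bundle width around 1 um, running ~30 um along
#' a gently curving centerline.
#'
#' @param n_positions Number of axial sample positions along the bundle.
#' @param tube_radius_um Dendrite radius (um).
#' @param center_spacing_um Nominal distance between the two flanking dendrite
#'   centerlines; this is the bundle width (longest pairwise distance) of a
#'   clean phantom.
#' @param order_model One of `"fixed"`, `"switch"`, `"random"`: how the planned
#'   middle-dendrite identity varies along the bundle.
#' @param switch_bin Bin (1..`n_bins`) at which the middle identity switches;
#'   required iff `order_model = "switch"`.
#' @param noise_rate Probability that a position's planned middle identity is
#'   replaced by a uniform draw over the three identities.
#' @param defasc_segments List of `c(start_bin, end_bin, extra_width_um)`
#'   triples; within each segment one dendrite is displaced radially outward by
#'   `extra_width_um`, emulating local defasciculation.
#' @param voxel_spacing_um Physical voxel size `c(x, y, z)` used when rendering.
#' @param psf_sigma_um Gaussian blur scale applied when rendering (um).
#' @param snr Signal-to-background ratio of the rendered stack; `Inf` renders a
#'   noise-free stack with zero background.
#' @param seed Integer RNG seed; every stochastic choice flows from it.
#' @param n_bins Number of length-normalized bins (used to place
#'   `switch_bin`/`defasc_segments`).
#' @param curve_length_um Axial length of the bundle (um).
#' @param curve_amp_um Amplitude of the low-frequency centerline curvature (um).
#' @param rotation_turns Number of full turns of the triangular cross-section
#'   frame over the bundle length; non-zero so that middle calls are exercised
#'   under twisting.
#' @param width_sd_um Standard deviation of the smooth per-animal variation of
#'   the bundle width (um).
#' @param middle_offset_frac Perpendicular offset of the middle dendrite, as a
#'   fraction of the local spacing; keeps the cross-section triangle
#'   non-degenerate while the middle dendrite stays opposite the longest side.
#' @param fixed_middle,switch_from,switch_to Dendrite identities used by the
#'   `fixed` and `switch` order models.
#' @param defasc_dendrite Identity displaced inside `defasc_segments`.
#'
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(n_positions = 200L,
                        tube_radius_um = 0.25,
                        center_spacing_um = 1.0,
                        order_model = c("fixed", "switch", "random"),
                        switch_bin = NULL,
                        noise_rate = 0,
                        defasc_segments = list(),
                        voxel_spacing_um = c(0.12, 0.12, 0.25),
                        psf_sigma_um = 0.15,
                        snr = 20,
                        seed = 1L,
                        n_bins = 100L,
                        curve_length_um = 30,
                        curve_amp_um = 1.5,
                        rotation_turns = 0.25,
                        width_sd_um = 0.1,
                        middle_offset_frac = 0.3,
                        fixed_middle = "AFD",
                        switch_from = "AFD",
                        switch_to = "ASE",
                        defasc_dendrite = "AWA") {
  order_model <- match.arg(order_model)
  if (order_model == "switch") {
    if (is.null(switch_bin))
      stop("order_model = 'switch' requires `switch_bin`")
    stopifnot(switch_bin >= 1, switch_bin <= n_bins)
  } else if (!is.null(switch_bin)) {
    stop("`switch_bin` is only meaningful when order_model = 'switch'")
  }
  stopifnot(
    n_positions >= 2, tube_radius_um > 0, center_spacing_um > 0,
    noise_rate >= 0, noise_rate <= 1, all(voxel_spacing_um > 0),
    psf_sigma_um >= 0, snr > 0, curve_length_um > 0, width_sd_um >= 0
  )
  if (center_spacing_um < 2 * tube_radius_um)
    stop("infeasible geometry: center_spacing_um (", center_spacing_um,
         ") < 2 * tube_radius_um (", 2 * tube_radius_um,
         "); the dendrite tubes would overlap completely")
  for (seg in defasc_segments) {
    stopifnot(length(seg) == 3, seg[1] >= 1, seg[2] <= n_bins,
              seg[1] <= seg[2], seg[3] >= 0)
  }
  stopifnot(fixed_middle %in% DENDRITES, switch_from %in% DENDRITES,
            switch_to %in% DENDRITES, defasc_dendrite %in% DENDRITES)
  structure(
    list(n_positions = as.integer(n_positions),
         tube_radius_um = tube_radius_um,
         center_spacing_um = center_spacing_um,
         order_model = order_model,
         switch_bin = if (is.null(switch_bin)) NULL else as.integer(switch_bin),
         noise_rate = noise_rate,
         defasc_segments = defasc_segments,
         voxel_spacing_um = voxel_spacing_um,
         psf_sigma_um = psf_sigma_um,
         snr = snr,
         seed = as.integer(seed),
         n_bins = as.integer(n_bins),
         curve_length_um = curve_length_um,
         curve_amp_um = curve_amp_um,
         rotation_turns = rotation_turns,
         width_sd_um = width_sd_um,
         middle_offset_frac = middle_offset_frac,
         fixed_middle = fixed_middle,
         switch_from = switch_from,
         switch_to = switch_to,
         defasc_dendrite = defasc_dendrite),
    class = "bundle_spec")
}

# Planned per-position middle labels for a spec (before geometric realization).
planned_middle_labels <- function(spec) {
  bins <- bin_assignment(spec$n_positions, spec$n_bins)
  lab <- switch(spec$order_model,
    fixed  = rep(spec$fixed_middle, spec$n_positions),
    switch = ifelse(bins < spec$switch_bin, spec$switch_from, spec$switch_to),
    random = sample(DENDRITES, spec$n_positions, replace = TRUE))
  if (spec$noise_rate > 0) {
    hit <- runif(spec$n_positions) < spec$noise_rate
    lab[hit] <- sample(DENDRITES, sum(hit), replace = TRUE)
  }
  lab
}

# Smooth centerline with an orthonormal cross-section frame (u, v) built by
# projecting a fixed reference out of the tangent; adequate for the gentle,
# z-dominant curves generated here.
bundle_centerline <- function(spec, phase = c(0, 0)) {
  n <- spec$n_positions
  t <- seq(0, 1, length.out = n)
  center <- cbind(
    x = spec$curve_amp_um * sin(2 * pi * (0.7 * t + phase[1])),
    y = spec$curve_amp_um * sin(2 * pi * (0.5 * t + phase[2])),
    z = spec$curve_length_um * t)
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  tang <- center[ip, , drop = FALSE] - center[im, , drop = FALSE]
  tang <- tang / row_norms(tang)
  ref <- c(1, 0, 0)
  u <- -tang * c(tang %*% ref)
  u[, 1] <- u[, 1] + 1
  u <- u / row_norms(u)
  v <- cbind(tang[, 2] * u[, 3] - tang[, 3] * u[, 2],
             tang[, 3] * u[, 1] - tang[, 1] * u[, 3],
             tang[, 1] * u[, 2] - tang[, 2] * u[, 1])
  list(center = center, u = u, v = v, t = t)
}

#' Generate ground-truth dendrite traces for a synthetic bundle
#'
#' Builds three smooth polylines sharing a gently curving centerline, offset on
#' a slowly rotating cross-section frame. At every position the planned middle
#' dendrite sits between the two flankers (perpendicularly offset so the
#' triangle is non-degenerate), so the planned label is realized geometrically:
#' that dendrite lies opposite the longest triangle side. Positions falling in
#' `defasc_segments` have one dendrite displaced radially outward.
#'
#' @param spec A [bundle_spec()].
#' @return An object of class `bundle_truth`: a list with `traces` (named list
#'   of three [dendrite_trace] objects), `middle_labels` (planned per-position
#'   identity), `defasc_flags` (per-position logical), `bins` (per-position bin
#'   index) and the `spec`.
#' @export
generate_bundle_traces <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  with_seed(spec$seed, {
    n <- spec$n_positions
    frame <- bundle_centerline(spec, phase = runif(2, 0, 1))
    labels <- planned_middle_labels(spec)
    s <- spec$center_spacing_um + smooth_noise(n, spec$width_sd_um)
    s <- pmax(s, 2 * spec$tube_radius_um)
    h <- spec$middle_offset_frac * s
    phi <- 2 * pi * spec$rotation_turns * frame$t
    e1 <- frame$u * cos(phi) + frame$v * sin(phi)
    e2 <- -frame$u * sin(phi) + frame$v * cos(phi)

    pts <- lapply(DENDRITES, function(d) matrix(NA_real_, n, 3))
    names(pts) <- DENDRITES
    for (i in seq_len(n)) {
      m <- labels[i]
      fl <- sort(setdiff(DENDRITES, m))
      pts[[fl[1]]][i, ] <- frame$center[i, ] - (s[i] / 2) * e1[i, ]
      pts[[fl[2]]][i, ] <- frame$center[i, ] + (s[i] / 2) * e1[i, ]
      pts[[m]][i, ]     <- frame$center[i, ] + h[i] * e2[i, ]
    }

    bins <- bin_assignment(n, spec$n_bins)
    flags <- rep(FALSE, n)
    for (seg in spec$defasc_segments) {
      idx <- which(bins >= seg[1] & bins <= seg[2])
      if (!length(idx)) next
      flags[idx] <- TRUE
      w <- max(1L, round(0.1 * length(idx)))
      ramp <- rep(1, length(idx))
      if (length(idx) > 2 * w) {
        edge <- (1 - cos(pi * seq_len(w) / w)) / 2
        ramp[seq_len(w)] <- edge
        ramp[length(idx) + 1 - seq_len(w)] <- edge
      }
      p <- pts[[spec$defasc_dendrite]][idx, , drop = FALSE]
      dir <- p - frame$center[idx, , drop = FALSE]
      nrm <- row_norms(dir)
      dir <- dir / ifelse(nrm > 0, nrm, 1)
      pts[[spec$defasc_dendrite]][idx, ] <- p + dir * (seg[3] * ramp)
    }

    traces <- lapply(DENDRITES, function(d)
      dendrite_trace(pts[[d]], label = d, source = "ground_truth"))
    names(traces) <- DENDRITES
    structure(list(traces = traces, middle_labels = labels,
                   defasc_flags = flags, bins = bins, spec = spec),
              class = "bundle_truth")
  })
}

#' Generate a cohort of binned bundle profiles directly
#'
#' Fast path that skips image rendering and tracing: each animal's traces are
#' generated with [generate_bundle_traces()] (independent sub-seed per animal),
#' converted to cross-sections and binned into a [bundle_profile]. Used for
#' cohort-scale simulation where the imaging layer is not under study.
#'
#' @param n_animals Number of animals in the cohort.
#' @param seed Master seed; per-animal seeds are derived deterministically.
#' @param stage Stage label attached to each profile.
#' @param defasc_animals Optional named list mapping animal index (as a name,
#'   e.g. `"3"`) to a `defasc_segments` list planted in that animal only.
#' @param ... Passed on to [bundle_spec()] (per-animal `seed` is overridden).
#' @return A list of `bundle_profile` objects, each carrying the generating
#'   `bundle_truth` as attribute `"truth"`.
#' @export
generate_profiles <- function(n_animals, seed = 1L, stage = "L4",
                              defasc_animals = list(), ...) {
  stopifnot(n_animals >= 1)
  lapply(seq_len(n_animals), function(a) {
    segs <- defasc_animals[[as.character(a)]]
    spec <- if (is.null(segs))
      bundle_spec(..., seed = derive_seed(seed, a))
    else
      bundle_spec(..., defasc_segments = segs, seed = derive_seed(seed, a))
    truth <- generate_bundle_traces(spec)
    sec <- cross_sections(truth$traces$AWA, truth$traces$AFD, truth$traces$ASE)
    prof <- bin_profile(sec, n_bins = spec$n_bins,
                        animal_id = sprintf("animal_%03d", a), stage = stage)
    attr(prof, "truth") <- truth
    prof
  })
}

#' Simulate a per-bin middle-dendrite population directly
#'
#' Draws categorical middle-dendrite labels per animal and bin without any
#' geometry, mirroring the simulated random cohorts used as the comparison
#' population in order statistics.
#'
#' @param order_model `"random"`, `"fixed"` or `"switch"`.
#' @param n_animals Number of animals (may be 0).
#' @param n_bins Number of length-normalized bins.
#' @param seed RNG seed.
#' @param switch_bin,noise_rate,fixed_middle,switch_from,switch_to As in
#'   [bundle_spec()]: labels follow the planned identity, each independently
#'   replaced by a uniform draw with probability `noise_rate`.
#' @return A [middle_population] object.
#' @export
generate_population <- function(order_model = c("random", "fixed", "switch"),
                                n_animals, n_bins = 100L, seed = 1L,
                                switch_bin = NULL, noise_rate = 0,
                                fixed_middle = "AFD",
                                switch_from = "AFD", switch_to = "ASE") {
  order_model <- match.arg(order_model)
  stopifnot(n_animals >= 0, n_bins >= 1)
  if (order_model == "switch" && is.null(switch_bin))
    stop("order_model = 'switch' requires `switch_bin`")
  labels <- with_seed(seed, {
    base <- switch(order_model,
      random = NULL,
      fixed  = rep(fixed_middle, n_bins),
      switch = ifelse(seq_len(n_bins) < switch_bin, switch_from, switch_to))
    m <- matrix(NA_character_, nrow = n_animals, ncol = n_bins)
    for (a in seq_len(n_animals)) {
      lab <- if (is.null(base)) sample(DENDRITES, n_bins, replace = TRUE)
             else base
      if (noise_rate > 0) {
        hit <- runif(n_bins) < noise_rate
        lab[hit] <- sample(DENDRITES, sum(hit), replace = TRUE)
      }
      m[a, ] <- lab
    }
    m
  })
  middle_population(labels, n_bins = n_bins,
                    cohort = paste0("simulated_", order_model))
}
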