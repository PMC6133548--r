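#' Per-bin reference width statistics from a wild-type cohort
#'
#' Computes the per-bin sample mean and sample standard deviation of bundle
#' width over an age-matched reference cohort; mutant bundles are classified
#' against this distribution.
#'
#' @param profiles List of >= 2 [bundle_profile] objects with equal `n_bins`.
#' @param stage Stage label for the reference.
#' @return An object of class `reference_profile` with per-bin `mean`, `sd`
#'   (sample SD), cohort size `n` and `stage`.
#' @export
reference_stats <- function(profiles, stage = NA_character_) {
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, inherits, TRUE, "bundle_profile")))
  nb <- vapply(profiles, `[[`, 1L, "n_bins")
  if (length(unique(nb)) != 1L)
    stop("profiles have mixed n_bins: ", paste(unique(nb), collapse = ", "))
  w <- vapply(profiles, `[[`, numeric(nb[1]), "width")
  structure(list(mean = rowMeans(w), sd = apply(w, 1, sd),
                 n = length(profiles), n_bins = nb[1], stage = stage),
            class = "reference_profile")
}

#' Classify a bundle as fasciculated or defasciculated
#'
#' A bundle is defasciculated when its width exceeds the reference mean by
#' more than `z_threshold` standard deviations for at least `run_length`
#' consecutive bins. The rule is one-sided: only widths above the mean count.
#' In a normally distributed dataset roughly 1 in 2000 points lies more than
#' 3.5 SD from the mean, so sustained excursions, not noise, trigger the call.
#' Zero-SD reference bins contribute z = 0 when the width does not exceed the
#' mean and z = Inf otherwise.
#'
#' @param profile A [bundle_profile].
#' @param ref A [reference_stats()] result with matching `n_bins`.
#' @param z_threshold Z-score threshold (default 3.5).
#' @param run_length Minimum number of consecutive bins above threshold
#'   (default 10).
#' @return An object of class `defasc_result`: `defasciculated` flag,
#'   `flagged_runs` (data.frame of start/end bins of runs meeting the rule)
#'   and the per-bin `z` scores.
#' @export
classify_defasciculation <- function(profile, ref, z_threshold = 3.5,
                                     run_length = 10L) {
  stopifnot(inherits(profile, "bundle_profile"),
            inherits(ref, "reference_profile"))
  if (profile$n_bins != ref$n_bins)
    stop("profile has ", profile$n_bins, " bins but reference has ", ref$n_bins)
  excess <- profile$width - ref$mean
  z <- ifelse(ref$sd > 0, excess / ref$sd, ifelse(excess > 0, Inf, 0))
  above <- z > z_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= run_length
  runs <- data.frame(start_bin = starts[keep], end_bin = ends[keep])
  structure(list(defasciculated = nrow(runs) > 0L, flagged_runs = runs,
                 z = z, z_threshold = z_threshold,
                 run_length = as.integer(run_length)),
            class = "defasc_result")
}

#' Partition a cohort into retained and excluded bundles
#'
#' Defasciculated bundles are excluded from dendrite-order analysis; they are
#' still shown (conventionally in pink) on bundle-width plots.
#'
#' @param profiles List of [bundle_profile] objects.
#' @param results Parallel list of [classify_defasciculation()] results.
#' @return List with `retained` and `excluded` profile lists; each returned
#'   profile has its `defasciculated` field set.
#' @export
exclude_defasciculated <- function(profiles, results) {
  if (length(profiles) != length(results))
    stop("profiles (", length(profiles), ") and results (", length(results),
         ") differ in length")
  flag <- vapply(results, `[[`, TRUE, "defasciculated")
  profiles <- Map(function(p, f) { p$defasciculated <- f; p }, profiles, flag)
  list(retained = profiles[!flag], excluded = profiles[flag])
}

#' Expected rarity of a z-score excursion
#'
#' Odds (one in how many points) that a standard-normal data point lies more
#' than `z` standard deviations from the mean (two-sided). At the default
#' classification threshold of 3.5 SD this is about 1 in 2000, the rationale
#' for treating sustained excursions as genuine defasciculation.
#'
#' @param z Z-score threshold.
#' @return `1 / P(|Z| > z)`.
#' @export
z_exceedance_odds <- function(z = 3.5) 1 / (2 * stats::pnorm(-abs(z)))

#' Total width data points in a cohort
#'
#' Bookkeeping helper: the number of binned width measurements across a set of
#' profiles (bundles x bins).
#'
#' @param profiles List of [bundle_profile] objects.
#' @export
width_data_points <- function(profiles) {
  sum(vapply(profiles, `[[`, 1L, "n_bins"))
}
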