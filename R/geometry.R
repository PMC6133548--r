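# nearest-vertex index on `points` for each row of `query` (vectorized over
# the full distance matrix; trace sizes here are a few hundred points)
nearest_vertex <- function(query, points) {
  d2 <- outer(rowSums(query^2), rowSums(points^2), "+") -
    2 * query %*% t(points)
  max.col(-d2, ties.method = "first")
}

#' Crop three traces to a common extent
#'
#' At each end of the bundle: average the three end coordinates, select the
#' trace whose opposite end is nearest that average tip (the effectively
#' shortest trace), and re-anchor the other two traces at their points closest
#' to the selected trace's end. Applied first to the start (tip) end, then to
#' the other end, so the three traces cover a matched extent.
#'
#' @param t1,t2,t3 [dendrite_trace] objects, oriented the same way.
#' @return A list of three cropped traces, in input order.
#' @export
crop_to_common_extent <- function(t1, t2, t3) {
  traces <- list(t1, t2, t3)
  stopifnot(all(vapply(traces, inherits, TRUE, "dendrite_trace")))
  pts <- lapply(traces, `[[`, "points")

  crop_end <- function(pts, at_start) {
    endpt <- function(p, first) if (first) p[1, ] else p[nrow(p), ]
    # average tip of the opposite end; the trace whose end-to-crop lies
    # nearest to it reaches least far and anchors the crop (the effectively
    # shortest dendrite)
    avg_tip <- colMeans(t(vapply(pts, endpt, numeric(3), first = !at_start)))
    here <- t(vapply(pts, endpt, numeric(3), first = at_start))
    k <- which.min(sqrt(rowSums(sweep(here, 2, avg_tip)^2)))
    anchor <- endpt(pts[[k]], at_start)
    for (j in setdiff(1:3, k)) {
      i <- nearest_vertex(matrix(anchor, 1), pts[[j]])
      pts[[j]] <- if (at_start) pts[[j]][i:nrow(pts[[j]]), , drop = FALSE]
                  else pts[[j]][1:i, , drop = FALSE]
    }
    pts
  }
  pts <- crop_end(pts, at_start = TRUE)
  pts <- crop_end(pts, at_start = FALSE)

  if (any(vapply(pts, nrow, 1L) < 2L))
    stop("cropping reduced a trace below 2 points; traces do not overlap")
  Map(function(p, tr) dendrite_trace(p, label = tr$label, source = tr$source),
      pts, traces)
}

# Resample a polyline to n points equally spaced in arc length.
resample_trace <- function(points, n) {
  if (nrow(points) == 1L) return(points[rep(1, n), , drop = FALSE])
  s <- c(0, cumsum(row_norms(diff(points))))
  target <- seq(0, s[length(s)], length.out = n)
  apply(points, 2, function(v) stats::approx(s, v, xout = target)$y)
}

#' Centroid line of three traces
#'
#' Resamples each trace to a common number of equally spaced arc-length
#' samples and averages corresponding points. The sample count defaults to the
#' finest resolution among the three traces (their maximum point count).
#'
#' @param t1,t2,t3 Cropped [dendrite_trace] objects.
#' @param n Number of samples along the centroid line.
#' @return Numeric matrix (`n` x 3) of um coordinates.
#' @export
centroid_line <- function(t1, t2, t3, n = NULL) {
  traces <- list(t1, t2, t3)
  if (is.null(n)) n <- max(vapply(traces, function(t) nrow(t$points), 1L))
  res <- lapply(traces, function(t) resample_trace(t$points, n))
  (res[[1]] + res[[2]] + res[[3]]) / 3
}

#' Identify the middle dendrite of a cross-section triangle
#'
#' The dendrite opposite the longest triangle side is "in the middle" of the
#' other two. If the two largest pairwise distances agree within `tol` the
#' call is ambiguous; it is resolved by fixed identity priority (alphabetical)
#' and flagged.
#'
#' @param d_pairs Named numeric vector of the three pairwise distances, names
#'   `d_AWA_ASE`, `d_AWA_AFD`, `d_AFD_ASE`.
#' @param tol Distance tolerance (um) for calling a tie.
#' @return List with `middle` (identity) and `ambiguous` (logical).
#' @export
middle_dendrite <- function(d_pairs, tol = 1e-9) {
  stopifnot(length(d_pairs) == 3L, all(PAIR_NAMES %in% names(d_pairs)))
  d <- d_pairs[PAIR_NAMES]
  longest <- names(d)[d >= max(d) - tol]
  cand <- sort(unname(PAIR_OPPOSITE[longest]))
  list(middle = cand[1], ambiguous = length(cand) > 1L)
}

#' Cross-sections of a three-dendrite bundle
#'
#' Walks the centroid line point by point; at each sample, the
#' Euclidean-nearest vertex on each trace defines the cross-section triangle.
#' Pairwise distances, bundle width (the longest pairwise distance) and the
#' middle-dendrite call are computed per section. Because only inter-dendrite
#' distances are used, the results are invariant to rotation or twisting of
#' the bundle.
#'
#' @param t1,t2,t3 [dendrite_trace] objects whose labels cover AWA, AFD, ASE.
#' @param centroid Optional precomputed centroid line; defaults to
#'   [centroid_line()] of the three traces.
#' @return A data.frame of class `cross_sections` with columns `position`,
#'   `d_AWA_ASE`, `d_AWA_AFD`, `d_AFD_ASE`, `width`, `middle`, `ambiguous`.
#'   Per-dendrite triangle coordinates are kept in attribute `"points"`.
#' @export
cross_sections <- function(t1, t2, t3, centroid = NULL) {
  traces <- list(t1, t2, t3)
  labs <- vapply(traces, `[[`, "", "label")
  if (!setequal(labs, DENDRITES))
    stop("traces must be labeled ", paste(DENDRITES, collapse = ", "))
  names(traces) <- labs
  if (is.null(centroid)) centroid <- centroid_line(t1, t2, t3)

  near <- lapply(DENDRITES, function(d) {
    p <- traces[[d]]$points
    p[nearest_vertex(centroid, p), , drop = FALSE]
  })
  names(near) <- DENDRITES

  pd <- function(a, b) row_norms(near[[a]] - near[[b]])
  d1 <- pd("AWA", "ASE"); d2 <- pd("AWA", "AFD"); d3 <- pd("AFD", "ASE")
  width <- pmax(d1, d2, d3)
  mid <- character(length(d1)); amb <- logical(length(d1))
  for (i in seq_along(d1)) {
    m <- middle_dendrite(c(d_AWA_ASE = d1[i], d_AWA_AFD = d2[i],
                           d_AFD_ASE = d3[i]))
    mid[i] <- m$middle; amb[i] <- m$ambiguous
  }
  out <- data.frame(position = seq_along(d1), d_AWA_ASE = d1, d_AWA_AFD = d2,
                    d_AFD_ASE = d3, width = width, middle = mid,
                    ambiguous = amb, stringsAsFactors = FALSE)
  attr(out, "points") <- near
  class(out) <- c("cross_sections", "data.frame")
  out
}

# Rebuild a cross_sections frame from distances alone (e.g. read from CSV):
# width and middle calls are functions of the three distances only.
sections_from_distances <- function(df) {
  stopifnot(all(c("position", PAIR_NAMES) %in% names(df)))
  width <- pmax(df$d_AWA_ASE, df$d_AWA_AFD, df$d_AFD_ASE)
  n <- nrow(df)
  mid <- character(n); amb <- logical(n)
  for (i in seq_len(n)) {
    m <- middle_dendrite(c(d_AWA_ASE = df$d_AWA_ASE[i],
                           d_AWA_AFD = df$d_AWA_AFD[i],
                           d_AFD_ASE = df$d_AFD_ASE[i]))
    mid[i] <- m$middle; amb[i] <- m$ambiguous
  }
  out <- data.frame(position = df$position, d_AWA_ASE = df$d_AWA_ASE,
                    d_AWA_AFD = df$d_AWA_AFD, d_AFD_ASE = df$d_AFD_ASE,
                    width = width, middle = mid, ambiguous = amb,
                    stringsAsFactors = FALSE)
  class(out) <- c("cross_sections", "data.frame")
  out
}

#' Bin cross-sections into a length-normalized bundle profile
#'
#' Segments the section series into `n_bins` contiguous, equally sized bins
#' (boundaries at `round(k * N / n_bins)`) and averages each pairwise distance
#' and the width within each bin. The bin middle-dendrite label is derived
#' from the binned mean distances. Bin 1 is the distal (nose-tip) end,
#' assuming traces start at the dendrite tip. Binning normalizes position
#' along the bundle, so profiles are comparable across animals of different
#' sizes; `head_length_um` is recorded as metadata only.
#'
#' @param sections A `cross_sections` data.frame (>= `n_bins` rows).
#' @param n_bins Number of bins (default 100).
#' @param animal_id Identifier recorded in the profile.
#' @param head_length_um Optional anatomical normalizer (um), metadata only.
#' @param stage Stage label (e.g. `"L4"`).
#' @return An object of class `bundle_profile`: `d_bins` (`n_bins` x 3 matrix
#'   of mean pairwise distances), `width` (per-bin mean width), `middle` and
#'   `ambiguous` (per-bin call from binned distances, ties resolved
#'   alphabetically and counted in `n_ambiguous`), plus metadata.
#' @export
bin_profile <- function(sections, n_bins = 100L, animal_id = NA_character_,
                        head_length_um = NA_real_, stage = NA_character_) {
  n <- nrow(sections)
  if (n < n_bins)
    stop("need at least n_bins (", n_bins, ") sections, got ", n)
  bins <- bin_assignment(n, n_bins)
  bin_mean <- function(v) as.numeric(tapply(v, bins, mean))
  d_bins <- cbind(d_AWA_ASE = bin_mean(sections$d_AWA_ASE),
                  d_AWA_AFD = bin_mean(sections$d_AWA_AFD),
                  d_AFD_ASE = bin_mean(sections$d_AFD_ASE))
  width <- bin_mean(sections$width)
  mid <- character(n_bins); amb <- logical(n_bins)
  for (k in seq_len(n_bins)) {
    m <- middle_dendrite(d_bins[k, ])
    mid[k] <- m$middle; amb[k] <- m$ambiguous
  }
  structure(list(animal_id = animal_id, n_bins = as.integer(n_bins),
                 d_bins = d_bins, width = width, middle = mid,
                 ambiguous = amb, n_ambiguous = sum(amb),
                 head_length_um = head_length_um, stage = stage,
                 defasciculated = NA),
            class = "bundle_profile")
}

#' @export
print.bundle_profile <- function(x, ...) {
  cat("bundle_profile", x$animal_id, "(", x$n_bins, "bins ) mean width",
      signif(mean(x$width), 4), "um; defasciculated:", x$defasciculated, "\n")
  invisible(x)
}
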