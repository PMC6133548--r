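#' Voxel stack container
#'
#' One channel of a 3D fluorescence image: a non-negative intensity grid with
#' anisotropic physical voxel spacing. Arrays are indexed `[x, y, z]`,
#' 1-based; the physical coordinate of voxel `(i, j, k)` is
#' `origin_um + (c(i, j, k) - 1) * spacing_um`.
#'
#' @param intensities 3D numeric array of non-negative intensities.
#' @param spacing_um Physical voxel size `c(x, y, z)` in um; all > 0.
#' @param channel_label Dendrite identity imaged in this channel.
#' @param origin_um Physical coordinate of voxel (1, 1, 1).
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(intensities, spacing_um, channel_label = NA_character_,
                        origin_um = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array (got ",
         length(dim(intensities)), " dimensions)")
  stopifnot(length(spacing_um) == 3L, all(spacing_um > 0),
            all(dim(intensities) >= 1L), length(origin_um) == 3L)
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(list(intensities = intensities,
                 spacing_um = as.numeric(spacing_um),
                 channel_label = channel_label,
                 origin_um = as.numeric(origin_um)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  cat("voxel_stack [", paste(dim(x$intensities), collapse = " x "),
      "] spacing", paste(signif(x$spacing_um, 3), collapse = "/"),
      "um, channel", x$channel_label, "\n")
  invisible(x)
}

#' Dendrite trace container
#'
#' An ordered 3D polyline (physical um coordinates) for one labeled dendrite.
#' Consecutive duplicate points are collapsed.
#'
#' @param points Numeric matrix with 3 columns (x, y, z in um), >= 1 row.
#' @param label Dendrite identity.
#' @param source One of `"traced"`, `"ground_truth"`, `"imported"`.
#' @return An object of class `dendrite_trace`.
#' @export
dendrite_trace <- function(points, label = NA_character_,
                           source = c("traced", "ground_truth", "imported")) {
  source <- match.arg(source)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 1L, is.numeric(points))
  if (nrow(points) > 1L) {
    dup <- c(FALSE, rowSums(abs(diff(points))) == 0)
    points <- points[!dup, , drop = FALSE]
  }
  dimnames(points) <- list(NULL, c("x_um", "y_um", "z_um"))
  structure(list(points = points, label = label, source = source),
            class = "dendrite_trace")
}

#' @export
print.dendrite_trace <- function(x, ...) {
  cat("dendrite_trace", x$label, "(", x$source, "):", nrow(x$points),
      "points,", signif(trace_length(x), 4), "um\n")
  invisible(x)
}

#' Arc length of a trace (um)
#' @param trace A [dendrite_trace].
#' @export
trace_length <- function(trace) {
  p <- trace$points
  if (nrow(p) < 2L) return(0)
  sum(row_norms(diff(p)))
}

#' Trace the brightest path through an image channel
#'
#' Finds the minimum-cost path between two voxels on the 26-connected voxel
#' graph, where an edge costs the mean inverse intensity of its two endpoint
#' voxels times the physical Euclidean step length:
#' `((1/(I(u)+eps) + 1/(I(v)+eps))/2) * ||p(u) - p(v)||` with `eps = 1`
#' intensity unit. Bright voxels are cheap, so the shortest path follows the
#' dendrite. Ties in the priority queue are broken by lexicographic voxel
#' index, making traces reproducible.
#'
#' @param stack A [voxel_stack()].
#' @param start,end Integer voxel index triples (1-based, in bounds).
#' @param eps Intensity offset guarding against zero-intensity voxels.
#' @return A [dendrite_trace] with physical (um) coordinates and
#'   `source = "traced"`. `start == end` yields a single-point trace.
#' @export
brightest_path <- function(stack, start, end, eps = 1) {
  stopifnot(inherits(stack, "voxel_stack"), length(start) == 3L,
            length(end) == 3L, eps > 0)
  dims <- dim(stack$intensities)
  start <- as.integer(round(start)); end <- as.integer(round(end))
  for (pt in list(start = start, end = end)) {
    if (any(pt < 1L) || any(pt > dims))
      stop("endpoint (", paste(pt, collapse = ", "),
           ") is outside the stack dimensions (",
           paste(dims, collapse = " x "), ")")
  }
  idx <- if (all(start == end)) {
    matrix(start, nrow = 1)
  } else {
    dijkstra_brightest_path(as.numeric(stack$intensities), dims,
                            stack$spacing_um, start - 1L, end - 1L, eps)
  }
  pts <- sweep(sweep(idx - 1, 2, stack$spacing_um, "*"), 2, stack$origin_um, "+")
  dendrite_trace(pts, label = stack$channel_label, source = "traced")
}

#' Cost of a voxel path under the brightest-path metric
#'
#' Used to cross-check optimality of [brightest_path()] against alternative
#' paths over the same stack.
#'
#' @param stack A [voxel_stack()].
#' @param idx Integer matrix of 1-based voxel indices (one row per voxel).
#' @param eps Intensity offset, as in [brightest_path()].
#' @export
path_cost <- function(stack, idx, eps = 1) {
  idx <- as.matrix(idx)
  if (nrow(idx) < 2L) return(0)
  inv <- 1 / (stack$intensities[idx] + eps)
  steps <- sweep(diff(idx), 2, stack$spacing_um, "*")
  sum((head(inv, -1) + tail(inv, -1)) / 2 * row_norms(steps))
}

#' Trim points from the ends of a trace
#'
#' Removes the first `n_head` and last `n_tail` points, standardizing trace
#' ends the way rows are deleted from a distance spreadsheet when the traced
#' endpoints overshoot the true dendrite ends.
#'
#' @param trace A [dendrite_trace].
#' @param n_head,n_tail Non-negative counts; `n_head + n_tail` must be smaller
#'   than the number of points.
#' @export
trim_trace <- function(trace, n_head = 0L, n_tail = 0L) {
  stopifnot(inherits(trace, "dendrite_trace"), n_head >= 0, n_tail >= 0)
  n <- nrow(trace$points)
  if (n_head + n_tail >= n)
    stop("over-trim: n_head + n_tail (", n_head + n_tail,
         ") must be < number of points (", n, ")")
  keep <- seq.int(n_head + 1L, n - n_tail)
  dendrite_trace(trace$points[keep, , drop = FALSE],
                 label = trace$label, source = trace$source)
}

#' Maximum deviation of a trace from a reference polyline
#'
#' For each point of `trace`, the Euclidean distance to the nearest point on
#' the `reference` polyline (its segments, not just its vertices); the
#' maximum over points summarizes how far a traced path strays from ground
#' truth.
#'
#' @param trace,reference [dendrite_trace] objects.
#' @return Maximum point-to-polyline distance (um).
#' @export
trace_deviation <- function(trace, reference) {
  p <- trace$points
  r <- reference$points
  if (nrow(r) == 1L)
    return(max(sqrt(colSums((t(p) - r[1, ])^2))))
  a <- r[-nrow(r), , drop = FALSE]
  ab <- diff(r)
  len2 <- pmax(rowSums(ab * ab), 1e-300)
  worst <- 0
  for (i in seq_len(nrow(p))) {
    ap <- sweep(a, 2, p[i, ], "-")
    t_par <- pmin(pmax(-rowSums(ap * ab) / len2, 0), 1)
    d2 <- rowSums((ap + ab * t_par)^2)
    worst <- max(worst, sqrt(min(d2)))
  }
  worst
}

# Voxel index (1-based) of a physical coordinate in a stack's grid.
um_to_voxel <- function(stack, p_um) {
  as.integer(round((p_um - stack$origin_um) / stack$spacing_um)) + 1L
}
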