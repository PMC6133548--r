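# 1-d convolution along the first array dimension with edge replication.
conv_dim1 <- function(arr, kernel) {
  d <- dim(arr)
  hw <- (length(kernel) - 1L) / 2L
  m <- matrix(arr, nrow = d[1])
  mp <- m[c(rep(1L, hw), seq_len(d[1]), rep(d[1], hw)), , drop = FALSE]
  f <- stats::filter(mp, kernel, sides = 2)
  array(f[hw + seq_len(d[1]), , drop = FALSE], dim = d)
}

# Separable 3D Gaussian blur; sigma given per axis in voxels.
gaussian_blur_3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0 || dim(arr)[ax] == 1L) next
    hw <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-hw, hw))^2 / (2 * s^2))
    k <- k / sum(k)
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    arr <- aperm(conv_dim1(aperm(arr, perm), k), order(perm))
  }
  arr
}

#' Render a synthetic bundle as multi-channel voxel stacks
#'
#' Draws each ground-truth dendrite as a tube of the specified radius into its
#' own channel, convolves with a Gaussian approximation of the point-spread
#' function, and adds background plus noise: Poisson-distributed signal and
#' Gaussian read noise (SD 2 intensity units). The signal amplitude is fixed
#' at 200 intensity units and the background level is `amplitude / snr`, so
#' `snr = Inf` gives a noise-free, zero-background stack in which tube voxels
#' carry exactly the foreground amplitude.
#'
#' @param truth A [generate_bundle_traces()] result.
#' @param spec The generating [bundle_spec()] (radius, spacing, blur, snr,
#'   seed).
#' @param margin_um Padding around the trace bounding box; defaults to the
#'   tube radius plus three blur sigmas plus two voxels.
#' @param amplitude Foreground signal level (intensity units).
#' @return Named list of three [voxel_stack] objects (one per dendrite), all
#'   sharing the same grid and origin.
#' @export
render_stack <- function(truth, spec = truth$spec, margin_um = NULL,
                         amplitude = 200) {
  stopifnot(inherits(truth, "bundle_truth"), inherits(spec, "bundle_spec"))
  sp <- spec$voxel_spacing_um
  all_pts <- do.call(rbind, lapply(truth$traces, `[[`, "points"))
  if (is.null(margin_um))
    margin_um <- spec$tube_radius_um + 3 * spec$psf_sigma_um + 2 * max(sp)
  origin <- apply(all_pts, 2, min) - margin_um
  upper <- apply(all_pts, 2, max) + margin_um
  dims <- as.integer(ceiling((upper - origin) / sp)) + 1L

  with_seed(derive_seed(spec$seed, 7919L), {
    stacks <- lapply(DENDRITES, function(d) {
      pts <- truth$traces[[d]]$points
      if (any(pts < rep(origin, each = nrow(pts))) ||
          any(pts > rep(origin + (dims - 1L) * sp, each = nrow(pts)))) {
        bad <- which(apply(pts, 1, function(p)
          any(p < origin) || any(p > origin + (dims - 1L) * sp)))[1]
        stop("trace ", d, " exits the stack bounds at (",
             paste(signif(pts[bad, ], 4), collapse = ", "), ") um")
      }
      mask <- rasterize_tube(pts, dims, origin, sp, spec$tube_radius_um)
      img <- if (spec$psf_sigma_um > 0)
        gaussian_blur_3d(mask, spec$psf_sigma_um / sp) else mask
      if (is.finite(spec$snr)) {
        bg <- amplitude / spec$snr
        expected <- bg + amplitude * img
        noisy <- rpois(length(expected), expected) +
          rnorm(length(expected), 0, 2)
        img <- array(pmax(noisy, 0), dim = dims)
      } else {
        img <- amplitude * img
      }
      voxel_stack(img, spacing_um = sp, channel_label = d, origin_um = origin)
    })
    names(stacks) <- DENDRITES
    stacks
  })
}

# Binary tube mask: voxel centers within `radius` of the densely resampled
# polyline are set to 1. Resampling step <= half the finest voxel spacing
# guarantees coverage without gaps.
rasterize_tube <- function(points, dims, origin, spacing, radius) {
  mask <- array(0, dim = dims)
  step <- min(spacing) / 2
  n <- max(2L, ceiling(sum(row_norms(diff(points))) / step) + 1L)
  dense <- resample_trace(points, n)
  half <- ceiling(radius / spacing)
  for (i in seq_len(nrow(dense))) {
    p <- dense[i, ]
    ctr <- round((p - origin) / spacing) + 1
    lo <- pmax(ctr - half, 1)
    hi <- pmin(ctr + half, dims)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    dx2 <- (origin[1] + (xs - 1) * spacing[1] - p[1])^2
    dy2 <- (origin[2] + (ys - 1) * spacing[2] - p[2])^2
    dz2 <- (origin[3] + (zs - 1) * spacing[3] - p[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
    mask[xs, ys, zs] <- pmax(mask[xs, ys, zs], inside)
  }
  mask
}

#' Ground-truth endpoints of a rendered phantom, as voxel indices
#'
#' Convenience for tracing rendered phantoms: the first and last ground-truth
#' trace points of each dendrite converted to 1-based voxel indices of the
#' rendered grid.
#'
#' @param truth A [generate_bundle_traces()] result.
#' @param stacks The matching [render_stack()] output.
#' @return Named list (per dendrite) of `list(start, end)` integer triples.
#' @export
truth_endpoints <- function(truth, stacks) {
  out <- lapply(DENDRITES, function(d) {
    p <- truth$traces[[d]]$points
    list(start = um_to_voxel(stacks[[d]], p[1, ]),
         end = um_to_voxel(stacks[[d]], p[nrow(p), ]))
  })
  names(out) <- DENDRITES
  out
}
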