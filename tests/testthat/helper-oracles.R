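# Independent oracles and small fixture builders used across the suite.

# Reference shortest-path cost on the 26-connected voxel graph via
# igraph::distances; shares nothing with the package's Dijkstra.
igraph_path_cost <- function(stack, s, e, eps = 1) {
  d <- dim(stack$intensities)
  sp <- stack$spacing_um
  idx <- as.matrix(expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3]))
  lin <- function(v) v[, 1] + d[1] * (v[, 2] - 1) + d[1] * d[2] * (v[, 3] - 1)
  inv <- 1 / (as.numeric(stack$intensities) + eps)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- NULL; w <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    u <- lin(idx[ok, , drop = FALSE]); v <- lin(nb[ok, , drop = FALSE])
    keep <- u < v
    step <- sqrt(sum((offs[k, ] * sp)^2))
    edges <- rbind(edges, cbind(u[keep], v[keep]))
    w <- c(w, (inv[u[keep]] + inv[v[keep]]) / 2 * step)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  igraph::distances(g, v = lin(matrix(s, 1)), to = lin(matrix(e, 1)))[1, 1]
}

# Middle-vertex oracle: the vertex with the smallest sum of incident sides is
# opposite the longest side.
middle_oracle <- function(d_awa_ase, d_awa_afd, d_afd_ase) {
  incident <- c(AWA = unname(d_awa_ase + d_awa_afd),
                AFD = unname(d_awa_afd + d_afd_ase),
                ASE = unname(d_awa_ase + d_afd_ase))
  names(which.min(incident))
}

# Random rigid transform: uniform rotation (QR of a Gaussian matrix, made
# proper) plus a translation.
random_rigid <- function(scale_t = 10) {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = runif(3, -scale_t, scale_t))
}

apply_rigid <- function(trace, rig) {
  dendrite_trace(sweep(trace$points %*% t(rig$R), 2, rig$t, "+"),
                 label = trace$label, source = trace$source)
}

# Three parallel straight-line traces along z at the given xy offsets.
parallel_traces <- function(offsets = list(AWA = c(0, 0), AFD = c(1, 0),
                                           ASE = c(0, 1)),
                            length_um = 20, n = 200) {
  z <- seq(0, length_um, length.out = n)
  out <- lapply(names(offsets), function(d)
    dendrite_trace(cbind(offsets[[d]][1], offsets[[d]][2], z), label = d,
                   source = "ground_truth"))
  names(out) <- names(offsets)
  out
}

# A smooth random trace triplet (helical bundle with per-dendrite phase).
helical_traces <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    z <- seq(0, 25, length.out = n)
    mk <- function(d, phase, r) {
      dendrite_trace(cbind(2 * sin(z / 6) + r * cos(z / 3 + phase),
                           2 * cos(z / 8) + r * sin(z / 3 + phase), z),
                     label = d, source = "ground_truth")
    }
    list(AWA = mk("AWA", 0, 0.5), AFD = mk("AFD", 2 * pi / 3, 0.55),
         ASE = mk("ASE", 4 * pi / 3, 0.45))
  })
}

# Two-sample KS statistic by direct ECDF evaluation.
ecdf_gap <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}
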