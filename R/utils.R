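#' @useDynLib bundleorder, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq pnorm rnorm rpois runif rmultinom ks.test spline
#'   approx sd filter ave
#' @importFrom utils read.csv write.csv write.table head tail
#' @importFrom grDevices png dev.off
NULL

#' Dendrite identities
#'
#' The three labeled amphid dendrites tracked by the pipeline, in the
#' conventional order AWA, AFD, ASE.
#'
#' @format Character vector of length 3.
#' @export
DENDRITES <- c("AWA", "AFD", "ASE")

# pairwise-distance column names and the vertex opposite each pair
PAIR_NAMES <- c("d_AWA_ASE", "d_AWA_AFD", "d_AFD_ASE")
PAIR_OPPOSITE <- c(d_AWA_ASE = "AFD", d_AWA_AFD = "ASE", d_AFD_ASE = "AWA")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL uses (and advances) the global
# stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for unit `i` (e.g. a bin or an animal) of a master
# seed; kept inside the 32-bit signed integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647) + 1L
}

# Map positions 1..n_positions onto bins 1..n_bins with boundaries at
# round(k * N / B): bin k covers positions round((k-1)N/B)+1 .. round(kN/B).
bin_assignment <- function(n_positions, n_bins) {
  b <- round((0:n_bins) * n_positions / n_bins)
  rep.int(seq_len(n_bins), diff(b))
}

# Euclidean norms of matrix rows
row_norms <- function(m) sqrt(rowSums(m * m))

# Smooth 1-d noise: a natural spline through k Gaussian knots, evaluated at n
# equally spaced points. Used for gentle per-animal variation along the bundle.
smooth_noise <- function(n, sd, k = 8L) {
  if (sd <= 0) return(numeric(n))
  knots <- rnorm(k, 0, sd)
  stats::spline(seq(0, 1, length.out = k), knots, xout = seq(0, 1, length.out = n))$y
}
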