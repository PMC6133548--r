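#' Per-bin middle-dendrite population
#'
#' Per-bin counts of which dendrite is in the middle across a cohort, plus the
#' underlying per-animal label matrix (needed by the permutation machinery,
#' which shuffles individual animals).
#'
#' @param labels Character matrix (`n_animals` x `n_bins`) of middle-dendrite
#'   identities (ambiguous ties already resolved).
#' @param n_bins Number of bins; defaults to `ncol(labels)`.
#' @param cohort Cohort label.
#' @return An object of class `middle_population` with `counts` (`n_bins` x 3
#'   matrix, columns AWA/AFD/ASE), `labels`, `n_animals`, `n_bins`, `cohort`.
#' @export
middle_population <- function(labels, n_bins = ncol(labels),
                              cohort = NA_character_) {
  labels <- as.matrix(labels)
  if (nrow(labels) > 0 && !all(labels %in% DENDRITES))
    stop("labels must be drawn from ", paste(DENDRITES, collapse = ", "))
  counts <- t(apply(labels, 2, function(col)
    tabulate(factor(col, levels = DENDRITES), nbins = 3L)))
  if (nrow(labels) == 0L) counts <- matrix(0L, n_bins, 3L)
  if (n_bins == 1L) counts <- matrix(counts, 1L, 3L)
  colnames(counts) <- DENDRITES
  structure(list(counts = counts, labels = labels,
                 n_animals = nrow(labels), n_bins = as.integer(n_bins),
                 cohort = cohort),
            class = "middle_population")
}

#' @export
print.middle_population <- function(x, ...) {
  cat("middle_population", x$cohort, ":", x$n_animals, "animals x", x$n_bins,
      "bins\n")
  invisible(x)
}

#' Tabulate middle-dendrite counts across a cohort of profiles
#'
#' Builds the per-bin categorical population from retained (fasciculated)
#' bundle profiles; each animal contributes its per-bin middle call.
#'
#' @param profiles Non-empty list of [bundle_profile] objects, equal `n_bins`.
#' @param cohort Cohort label.
#' @return A [middle_population].
#' @export
tabulate_population <- function(profiles, cohort = NA_character_) {
  if (!length(profiles)) stop("no profiles to tabulate")
  nb <- unique(vapply(profiles, `[[`, 1L, "n_bins"))
  if (length(nb) != 1L)
    stop("profiles have mixed n_bins: ", paste(nb, collapse = ", "))
  if (any(vapply(profiles, function(p) isTRUE(p$defasciculated), TRUE)))
    stop("defasciculated profiles must be excluded before tabulation")
  labels <- t(vapply(profiles, `[[`, character(nb), "middle"))
  rownames(labels) <- vapply(profiles, `[[`, "", "animal_id")
  middle_population(labels, n_bins = nb, cohort = cohort)
}

#' Per-bin fraction of animals with each dendrite in the middle
#' @param pop A [middle_population].
#' @return `n_bins` x 3 matrix of fractions (rows sum to 1).
#' @export
population_fractions <- function(pop) {
  stopifnot(pop$n_animals > 0)
  pop$counts / pop$n_animals
}

#' Chi-squared test of middle-dendrite counts against a random arrangement
#'
#' Tests observed per-bin counts against the uniform expectation `n/3` per
#' category using `sum((observed - expected)^2 / expected)` with 2 degrees of
#' freedom. Only valid when the expected count is at least 5 (n >= 15); for
#' smaller cohorts, or comparisons between two observed populations, use the
#' permutation test ([permutation_rank()]), which makes no large-count
#' assumption.
#'
#' @param counts Length-3 counts (AWA, AFD, ASE) of middle-dendrite calls.
#' @param n Cohort size; must equal `sum(counts)`.
#' @return List with `statistic`, `p` and the per-category `expected` count.
#' @export
chi_squared_vs_random <- function(counts, n = sum(counts)) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  if (sum(counts) != n)
    stop("counts sum to ", sum(counts), ", not n = ", n)
  expected <- n / 3
  if (expected < 5)
    stop("expected count n/3 = ", signif(expected, 3),
         " is below 5; the chi-squared approximation is unreliable - ",
         "use the permutation test instead")
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       expected = expected)
}

#' Draw a simulated random middle-dendrite cohort at one bin
#'
#' A multinomial draw of `n` animals over the three identities with equal
#' probabilities: the "simulated random sample" that observed populations are
#' compared against. An explicit cohort (not the expected-count vector) is
#' drawn because the permutation machinery shuffles individual animals.
#'
#' @param n Cohort size (>= 0).
#' @param seed Optional RNG seed.
#' @return Named integer triple (AWA, AFD, ASE) summing to `n`.
#' @export
simulate_random_counts <- function(n, seed = NULL) {
  stopifnot(n >= 0)
  cnt <- with_seed(seed, as.integer(rmultinom(1, n, rep(1 / 3, 3))))
  names(cnt) <- DENDRITES
  cnt
}

#' Scale a count distribution to a different cohort size
#'
#' Rescales category counts to cohort size `n`, rounding to integers (e.g. an
#' illustrated 6-animal distribution of 5/1/0 corresponds to 15/3/0 at a
#' typical n = 18).
#'
#' @param counts Length-3 counts.
#' @param n Target cohort size.
#' @export
scale_counts <- function(counts, n) {
  stopifnot(sum(counts) > 0)
  out <- round(counts / sum(counts) * n)
  names(out) <- names(counts)
  out
}

#' Permutation rank of the Fisher 3x2 p-value at one bin
#'
#' Compares two cohorts' middle-dendrite counts at one bin. The nominal
#' p-value is Fisher's exact 3x2 test on the two count triples. Then, for
#' `iterations` rounds, the two cohorts' animal labels are merged, randomly
#' split into two equally sized groups (ceiling/floor halves when the total is
#' odd) and the Fisher p-value recomputed, giving `iterations + 1` p-values in
#' total. The rank of the nominal p-value among them (rank = 1 + number of
#' resampled p-values strictly smaller; ties count toward higher, i.e. more
#' conservative, ranks) measures how extreme the observed difference is
#' relative to sampling error alone.
#'
#' @param obs,test Length-3 count triples (AWA, AFD, ASE) for the two cohorts.
#' @param iterations Number of resampling rounds (default 500).
#' @param seed Optional RNG seed.
#' @return An object of class `permutation_result`: `nominal_p`,
#'   `resampled_p` (length `iterations`), `rank` in `[1, iterations + 1]`,
#'   `total`, and the significance `tier` from [rank_to_significance()].
#' @export
permutation_rank <- function(obs, test, iterations = 500L, seed = NULL) {
  stopifnot(length(obs) == 3L, length(test) == 3L,
            all(obs >= 0), all(test >= 0))
  n1 <- sum(obs); n2 <- sum(test)
  if (n1 == 0 || n2 == 0) stop("both cohorts must be non-empty")
  nominal <- fisher_exact_3x2(rbind(obs, test))

  pooled <- rep.int(1:3, obs + test)
  N <- n1 + n2
  m <- ceiling(N / 2)
  cmar <- as.integer(obs + test)
  enum <- fisher_table_enum(m, N - m, cmar)
  # p-value lookup for first-row cells (a, b) of the resampled margins
  lut <- matrix(NA_real_, min(m, cmar[1]) + 1L, min(m, cmar[2]) + 1L)
  lut[cbind(enum$a + 1L, enum$b + 1L)] <- enum$pval

  resampled <- with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      g1 <- pooled[sample.int(N, m)]
      cnt <- tabulate(g1, 3L)
      lut[cnt[1] + 1L, cnt[2] + 1L]
    }, numeric(1))
  })
  # ties count as "below": a resampled p equal to the nominal p pushes the
  # rank up (conservative); identical cohorts always get the maximal rank
  rank <- 1L + sum(resampled <= nominal + 1e-12)
  structure(list(nominal_p = nominal, resampled_p = resampled,
                 rank = rank, total = iterations + 1L,
                 tier = rank_to_significance(rank, iterations + 1L)),
            class = "permutation_result")
}

#' Map a permutation rank to a significance tier
#'
#' A rank r out of `total` corresponds to a corrected p-value of r/`total`;
#' with the default 501 p-values, ranks up to 25 correspond to p < 0.05 and
#' ranks up to 5 to p < 0.01. The threshold for level `alpha` is the largest
#' integer r with `r / total < alpha`.
#'
#' @param rank Integer rank in `[1, total]`.
#' @param total Total number of p-values (iterations + 1).
#' @return `"p<0.01"`, `"p<0.05"` or `"ns"`.
#' @export
rank_to_significance <- function(rank, total = 501L) {
  stopifnot(rank >= 1, rank <= total)
  if (rank <= significance_threshold(0.01, total)) "p<0.01"
  else if (rank <= significance_threshold(0.05, total)) "p<0.05"
  else "ns"
}

#' @rdname rank_to_significance
#' @param alpha Significance level.
#' @export
significance_threshold <- function(alpha, total = 501L) {
  as.integer(ceiling(alpha * total) - 1L)
}

#' Per-bin permutation comparison of two populations
#'
#' Runs [permutation_rank()] at every bin, deriving an independent sub-seed
#' per bin from the master seed so bins are independent yet reproducible.
#'
#' @param pop_a,pop_b [middle_population] objects with equal `n_bins`.
#' @param iterations Resampling rounds per bin.
#' @param seed Master seed.
#' @return Data.frame with one row per bin: counts of both cohorts,
#'   `nominal_p`, `rank`, `tier`. The full resampled p-value matrix
#'   (`n_bins` x `iterations`) is attached as attribute `"resampled"`.
#' @export
compare_populations <- function(pop_a, pop_b, iterations = 500L, seed = 1L) {
  stopifnot(inherits(pop_a, "middle_population"),
            inherits(pop_b, "middle_population"))
  if (pop_a$n_bins != pop_b$n_bins)
    stop("populations have different n_bins")
  B <- pop_a$n_bins
  res <- vector("list", B)
  for (b in seq_len(B)) {
    res[[b]] <- permutation_rank(pop_a$counts[b, ], pop_b$counts[b, ],
                                 iterations = iterations,
                                 seed = derive_seed(seed, b))
  }
  out <- data.frame(bin = seq_len(B),
                    nominal_p = vapply(res, `[[`, 1, "nominal_p"),
                    rank = vapply(res, `[[`, 1L, "rank"),
                    tier = vapply(res, `[[`, "", "tier"))
  attr(out, "resampled") <- t(vapply(res, `[[`, numeric(iterations),
                                     "resampled_p"))
  out
}

#' Majority middle-dendrite label per bin
#'
#' The modal middle identity at each bin of a population (ties resolved
#' alphabetically), the per-bin summary used for switch-point detection.
#'
#' @param pop A [middle_population] with at least one animal.
#' @return Character vector of length `n_bins`.
#' @export
majority_middle <- function(pop) {
  stopifnot(pop$n_animals > 0)
  apply(pop$counts, 1, function(cnt) {
    cand <- DENDRITES[cnt == max(cnt)]
    sort(cand)[1]
  })
}

#' Detect the switch point of a middle-dendrite label sequence
#'
#' The switch point is the first bin whose label differs from the bin-1 label
#' and persists for more than one bin (a run of at least 2); single-bin blips
#' are ignored.
#'
#' @param labels Non-empty character vector of per-bin labels.
#' @return List with `bin` (`NA` if no switch), `from` (label preceding the
#'   switch) and `to` (label at the switch).
#' @export
detect_switch_point <- function(labels) {
  stopifnot(length(labels) >= 1L)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values != labels[1] & r$lengths >= 2L)
  if (!length(ok)) return(list(bin = NA_integer_, from = NA_character_,
                               to = NA_character_))
  i <- ok[1]
  list(bin = starts[i], from = labels[starts[i] - 1L], to = r$values[i])
}

#' Compare two switch-point samples
#'
#' Two-sample Kolmogorov-Smirnov test (asymptotic p-value) on switch-point
#' positions, appropriate because switch positions are not normally
#' distributed.
#'
#' @param sample_a,sample_b Non-empty numeric vectors of switch positions.
#' @return List with `statistic` (max ECDF gap) and `p`.
#' @export
compare_switch_points <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}
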