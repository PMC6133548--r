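# Exact enumeration of all 2x3 tables with fixed margins.
# Returns the first-row cells (a, b; c = r1 - a - b implied), the log
# conditional probability of each table given the margins
#   P(T) = (prod row!)(prod col!) / (N! prod cells!)
# and each table's exact p-value: the total probability of margin-consistent
# tables no more probable than it.
fisher_table_enum <- function(r1, r2, cmar) {
  N <- r1 + r2
  stopifnot(sum(cmar) == N, all(cmar >= 0), r1 >= 0, r2 >= 0)
  a <- 0:min(r1, cmar[1])
  grid <- do.call(rbind, lapply(a, function(ai) {
    bi <- 0:min(r1 - ai, cmar[2])
    ci <- r1 - ai - bi
    ok <- ci >= 0 & ci <= cmar[3]
    cbind(a = rep(ai, sum(ok)), b = bi[ok])
  }))
  a <- grid[, 1]; b <- grid[, 2]; cc <- r1 - a - b
  const <- lgamma(r1 + 1) + lgamma(r2 + 1) + sum(lgamma(cmar + 1)) -
    lgamma(N + 1)
  logp <- const -
    (lgamma(a + 1) + lgamma(b + 1) + lgamma(cc + 1) +
     lgamma(cmar[1] - a + 1) + lgamma(cmar[2] - b + 1) +
     lgamma(cmar[3] - cc + 1))
  ord <- order(logp)
  p_sorted <- exp(logp[ord])
  cum <- cumsum(p_sorted)
  # tables with equal probability share the p-value of the last of their group
  grp <- cumsum(!duplicated(round(logp[ord], 10)))
  pval_sorted <- cum[stats::ave(seq_along(grp), grp, FUN = max)]
  pval <- numeric(length(logp))
  pval[ord] <- pmin(pval_sorted, 1)
  list(a = a, b = b, logp = logp, pval = pval)
}

#' Fisher's exact test for a 2 x 3 contingency table
#'
#' Exact p-value by full enumeration of margin-consistent tables: the sum of
#' the hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed that of the observed table. Used as the
#' test statistic of the permutation machinery; no asymptotic fallback is
#' applied. When a margin is zero only one table is consistent with the
#' margins and p = 1.
#'
#' @param table 2 x 3 matrix of non-negative integer counts (rows: the two
#'   populations; columns: middle-dendrite categories).
#' @return Exact p-value in (0, 1].
#' @export
fisher_exact_3x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 3L)), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0) return(1)
  enum <- fisher_table_enum(sum(table[1, ]), sum(table[2, ]), colSums(table))
  i <- which(enum$a == table[1, 1] & enum$b == table[1, 2])
  enum$pval[i]
}
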