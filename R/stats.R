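#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the overrepresentation
#' p-value for drawing `n` candidates from a universe of `N` genes of which
#' `K` belong to the set and observing `k` in the overlap. Terms are
#' accumulated in log space (log binomial coefficients) for numerical
#' stability; for small problems the result agrees with exact rational
#' arithmetic to ~1e-12 relative tolerance.
#'
#' @param k observed overlap (integer >= 0).
#' @param K set size within the universe.
#' @param n candidate-list size.
#' @param N universe size.
#' @return The tail probability in `[0, 1]`.
#' @examples
#' hypergeom_upper_tail(3, 5, 4, 20)  # 155/4845
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (any(is.na(c(k, K, n, N))) || K < 0L || n < 0L || N < 0L) {
    stop_validation("hypergeometric parameters must be non-negative integers")
  }
  if (K > N || n > N) stop_validation("K and n must not exceed N (got K=%d n=%d N=%d)", K, n, N)
  if (k > min(K, n)) stop_validation("k (%d) exceeds min(K, n) = %d", k, min(K, n))
  if (k <= 0L) return(1)
  i <- k:min(K, n)
  lo <- max(0L, n - (N - K))   # support lower bound
  if (k <= lo) return(1)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(lp)
  min(1, exp(mx + log(sum(exp(lp - mx)))))
}

# Log point probability P(X = k), same parameterization.
hypergeom_point_log <- function(k, K, n, N) {
  lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
}

#' Point hypergeometric probability
#'
#' `P(X = k)`, companion to [hypergeom_upper_tail()] (used e.g. for
#' randomized-PIT uniformity diagnostics of discrete p-values).
#'
#' @inheritParams hypergeom_upper_tail
#' @export
hypergeom_point <- function(k, K, n, N) {
  if (k < max(0L, n - (N - K)) || k > min(K, n)) return(0)
  exp(hypergeom_point_log(k, K, n, N))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} m p_(j) / j`, clipped at 1, returned in the input
#' order. Output is monotone non-decreasing along the sorted p-values.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Overrepresentation analysis of a candidate list against gene sets
#'
#' For each set: overlap `k`, set size within the universe `K`, candidate
#' count `n`, universe size `N`, upper-tail hypergeometric p, BH q (across
#' all sets tested in this call) and fold enrichment `(k/n)/(K/N)`.
#' Candidates outside the universe are dropped with a message; set members
#' are intersected with the universe before `K` is computed. Symbols are
#' uppercased on all sides. Rows are sorted by p ascending, ties by set
#' name.
#'
#' @param candidates character vector of candidate gene symbols.
#' @param sets named list of gene sets (e.g. [read_gmt()]).
#' @param universe character vector: the gene universe (for a proteome scan,
#'   all genes in the scanned proteome).
#' @return data.frame of class `enrichment_result` with columns `set_name`,
#'   `k`, `K`, `n`, `N`, `p_value`, `q_value`, `fold_enrichment`.
#' @export
ora <- function(candidates, sets, universe) {
  universe <- unique(toupper(universe))
  N <- length(universe)
  if (N == 0L) stop_validation("empty universe")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_validation("gene sets must be named")
  }
  cand <- unique(toupper(candidates))
  outside <- setdiff(cand, universe)
  if (length(outside)) {
    log_msg("ora", "%d candidate(s) outside the universe dropped", length(outside))
    cand <- intersect(cand, universe)
  }
  n <- length(cand)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(toupper(sets[[nm]])), universe)
    K <- length(members)
    k <- length(intersect(cand, members))
    p <- if (K == 0L || n == 0L) 1 else hypergeom_upper_tail(k, K, n, N)
    fold <- if (K == 0L || n == 0L) NA_real_ else (k / n) / (K / N)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N,
               p_value = p, fold_enrichment = fold,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_value)
  res <- res[order(res$p_value, res$set_name),
             c("set_name", "k", "K", "n", "N", "p_value", "q_value",
               "fold_enrichment")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Two-by-two contingency tables
#'
#' @param a,b,c,d non-negative integer cell counts (rows = group,
#'   columns = outcome), or `a` may be a 2x2 matrix.
#' @return list of class `two_by_two`.
#' @export
two_by_two <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop_validation("2x2 cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop_validation("2x2 table must have a positive total")
  structure(as.list(as.integer(cells)), names = names(cells), class = "two_by_two")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood convention: the sum of
#' the probabilities of all tables with the observed margins whose point
#' probability does not exceed the observed table's, with a relative
#' tolerance factor of `1 + 1e-7` on the comparison (the dominant convention
#' in statistical software; two-sided definitions differ, so the rule is
#' stated explicitly).
#'
#' @param t a [two_by_two()] table.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(two_by_two(8, 3, 1, 9))
#' @export
fisher_exact_2x2 <- function(t) {
  if (!inherits(t, "two_by_two")) t <- do.call(two_by_two, as.list(t))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  xs <- max(0L, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1)
  lp_obs <- lp[xs == a]
  keep <- lp <= lp_obs + log1p(1e-7)
  min(1, sum(exp(lp[keep])))
}

#' Odds ratio of a 2x2 table
#'
#' `(a d) / (b c)`; with `haldane`, 0.5 is added to every cell whenever any
#' cell is zero (Haldane-Anscombe correction). Without the correction a zero
#' in `b` or `c` gives `Inf` (or `NaN` when `a d = 0` too), flagged by a
#' warning.
#'
#' @param t a [two_by_two()] table.
#' @param haldane logical; apply the +0.5 correction on zero cells.
#' @return The odds ratio.
#' @examples
#' odds_ratio(two_by_two(10, 5, 2, 8))
#' @export
odds_ratio <- function(t, haldane = FALSE) {
  if (!inherits(t, "two_by_two")) t <- do.call(two_by_two, as.list(t))
  cells <- c(t$a, t$b, t$c, t$d)
  if (haldane && any(cells == 0L)) cells <- cells + 0.5
  if (!haldane && cells[2] * cells[3] == 0) {
    warning("odds ratio undefined/infinite: zero cell without Haldane correction")
  }
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Percentage of a count, rounded half-up
#'
#' `100 count / total`, rounded half-up (not banker's rounding) to
#' `decimals` places, matching the usual printed style of clinical
#' proportions (e.g. 146 of 184 -> 79.3).
#'
#' @param count,total non-negative counts, `total > 0`, `count <= total`.
#' @param decimals decimal places (default 1).
#' @return The rounded percentage.
#' @examples
#' proportion_percent(146, 184)  # 79.3
#' @export
proportion_percent <- function(count, total, decimals = 1L) {
  if (total <= 0) stop_validation("total must be positive")
  if (count < 0 || count > total) stop_validation("count must lie in 0..total")
  x <- 100 * count / total
  scale <- 10^decimals
  floor(x * scale + 0.5 + 1e-12) / scale
}
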