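#' Pairwise divergence matrix
#'
#' Joint state-pair counts for one ordered pair of aligned sequences: entry
#' (a, b) is the number of sites with canonical state a in taxon `i` and b in
#' taxon `j`.  Sites where either sequence carries a gap, missing code, or any
#' ambiguity code are excluded (fractional allocation would break the integer
#' count semantics of the matched-pairs tests).
#'
#' @param a an [alignment()].
#' @param i,j taxon names or indices; must differ.
#' @return Object of class `divergence_matrix`: list with `pair`, `counts`
#'   (m x m integer matrix), `n_effective`, and `empty` flag.
#' @export
divergence_matrix <- function(a, i, j) {
  if (is.numeric(i)) i <- a$taxa[i]
  if (is.numeric(j)) j <- a$taxa[j]
  stopifnot(i %in% a$taxa, j %in% a$taxa)
  if (identical(i, j)) stop("need two distinct taxa")
  canon <- a$alphabet$canonical
  si <- a$matrix[i, ]
  sj <- a$matrix[j, ]
  use <- si %in% canon & sj %in% canon
  counts <- table(factor(si[use], levels = canon),
                  factor(sj[use], levels = canon))
  counts <- matrix(as.integer(counts), nrow = length(canon),
                   dimnames = list(canon, canon))
  structure(list(pair = c(i, j), counts = counts,
                 n_effective = sum(counts), empty = sum(counts) == 0L),
            class = "divergence_matrix")
}

chi2_result <- function(statistic, df, flagged = FALSE) {
  p <- if (df > 0) stats::pchisq(statistic, df, lower.tail = FALSE) else 1
  list(statistic = statistic, df = as.integer(df), p = p, flagged = flagged)
}

#' Bowker's test of symmetry
#'
#' Omnibus matched-pairs test of model-process homogeneity between two
#' sequences: under a stationary, homogeneous, reversible process the
#' divergence matrix is symmetric in expectation.  The statistic is
#' \eqn{\sum_{a<b} (n_{ab}-n_{ba})^2/(n_{ab}+n_{ba})} over off-diagonal pairs
#' with \eqn{n_{ab}+n_{ba}>0}; the degrees of freedom count those pairs
#' (set `fixed_df = TRUE` for the fixed m(m-1)/2 convention).
#'
#' @param d a [divergence_matrix()].
#' @param fixed_df use df = m(m-1)/2 regardless of empty cells.
#' @return List with `statistic`, `df`, `p`, `flagged` (TRUE when df = 0).
#' @export
bowker <- function(d, fixed_df = FALSE) {
  if (d$empty) stop("empty divergence matrix")
  n <- d$counts
  m <- nrow(n)
  stat <- 0
  df <- 0L
  for (x in seq_len(m - 1)) for (y in (x + 1):m) {
    tot <- n[x, y] + n[y, x]
    if (tot > 0) {
      stat <- stat + (n[x, y] - n[y, x])^2 / tot
      df <- df + 1L
    }
  }
  if (fixed_df) df <- as.integer(m * (m - 1) / 2)
  chi2_result(stat, df, flagged = df == 0L)
}

#' Stuart's test of marginal homogeneity
#'
#' Matched-pairs test of stationarity: whether the two sequences share the
#' same composition.  With u the first m-1 elements of (row sums - column
#' sums) and V its estimated covariance (\eqn{V_{aa} = r_a + c_a - 2 n_{aa}},
#' \eqn{V_{ab} = -(n_{ab}+n_{ba})}), the statistic is \eqn{u' V^- u} with a
#' generalized inverse; df = rank(V) (singular values below `tol` dropped).
#'
#' @param d a [divergence_matrix()].
#' @param tol singular-value tolerance for the rank/generalized inverse.
#' @return List with `statistic`, `df`, `p`, `flagged` (TRUE when rank 0).
#' @export
stuart <- function(d, tol = 1e-10) {
  if (d$empty) stop("empty divergence matrix")
  n <- d$counts
  m <- nrow(n)
  u <- (rowSums(n) - colSums(n))[seq_len(m - 1)]
  V <- matrix(0, m - 1, m - 1)
  for (x in seq_len(m - 1)) for (y in seq_len(m - 1)) {
    V[x, y] <- if (x == y) sum(n[x, ]) + sum(n[, x]) - 2 * n[x, x]
               else -(n[x, y] + n[y, x])
  }
  sv <- svd(V)
  keep <- sv$d > tol * max(sv$d, 1)
  rank <- sum(keep)
  if (rank == 0L) return(chi2_result(0, 0L, flagged = TRUE))
  Vinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  chi2_result(drop(t(u) %*% Vinv %*% u), rank)
}

#' Ababneh's internal test
#'
#' The component of Bowker's symmetry statistic not attributable to marginal
#' (composition) inhomogeneity; deviation signals rate-homogeneity violation.
#' Statistic = max(0, Bowker - Stuart); df = df difference.  When the df
#' difference is not positive the test is degenerate and p = 1.
#'
#' @param d a [divergence_matrix()].
#' @param fixed_df passed to [bowker()].
#' @return List with `statistic`, `df`, `p`, `flagged`.
#' @export
ababneh <- function(d, fixed_df = FALSE) {
  b <- bowker(d, fixed_df = fixed_df)
  s <- stuart(d)
  df <- b$df - s$df
  if (df <= 0L) return(chi2_result(0, 0L, flagged = TRUE))
  chi2_result(max(0, b$statistic - s$statistic), df)
}

#' Matched-pairs homogeneity tests over all taxon pairs
#'
#' Runs Bowker's, Stuart's and Ababneh's tests on every unordered taxon pair
#' and summarizes the number and percentage of rejections at `alpha`.
#'
#' @param a an [alignment()] with at least two taxa.
#' @param alpha rejection level for the summary (default 0.05).
#' @param fixed_df passed to [bowker()].
#' @return List with `table` (data.frame: one row per pair, statistic/df/p for
#'   each test) and `summary` (data.frame: per test, n_pairs, n_rejected,
#'   pct_rejected at `alpha`).
#' @examples
#' a <- alignment(c(t1 = "ACGTACGT", t2 = "ACGAACGA", t3 = "ACGTACGA"),
#'                kind = "nucleotide")
#' all_pairs_tests(a)$summary
#' @export
all_pairs_tests <- function(a, alpha = 0.05, fixed_df = FALSE) {
  nt <- n_taxa(a)
  stopifnot(nt >= 2)
  rows <- list()
  for (x in seq_len(nt - 1)) for (y in (x + 1):nt) {
    d <- divergence_matrix(a, x, y)
    if (d$empty) {
      rows[[length(rows) + 1]] <- data.frame(
        taxon_i = a$taxa[x], taxon_j = a$taxa[y], n_effective = 0L,
        bowker_stat = NA, bowker_df = NA, bowker_p = NA,
        stuart_stat = NA, stuart_df = NA, stuart_p = NA,
        ababneh_stat = NA, ababneh_df = NA, ababneh_p = NA)
      next
    }
    b <- bowker(d, fixed_df = fixed_df)
    s <- stuart(d)
    ab <- ababneh(d, fixed_df = fixed_df)
    rows[[length(rows) + 1]] <- data.frame(
      taxon_i = a$taxa[x], taxon_j = a$taxa[y], n_effective = d$n_effective,
      bowker_stat = b$statistic, bowker_df = b$df, bowker_p = b$p,
      stuart_stat = s$statistic, stuart_df = s$df, stuart_p = s$p,
      ababneh_stat = ab$statistic, ababneh_df = ab$df, ababneh_p = ab$p)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tests <- c("bowker", "stuart", "ababneh")
  summ <- do.call(rbind, lapply(tests, function(tst) {
    p <- tab[[paste0(tst, "_p")]]
    data.frame(test = tst, n_pairs = nrow(tab),
               n_rejected = sum(p < alpha, na.rm = TRUE),
               pct_rejected = 100 * sum(p < alpha, na.rm = TRUE) / nrow(tab))
  }))
  list(table = tab, summary = summ, alpha = alpha)
}
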