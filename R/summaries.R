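# Canonical clade key for a rooted tree node: sorted tip labels joined by "|".
clade_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  vapply(pp, function(ix) paste(sort(labs[ix]), collapse = "|"), "")
}

#' Split (clade) posterior supports from one or more traces
#'
#' With `rooted = TRUE` (default) supports are clade frequencies on the
#' sampled rooted trees.  With `rooted = FALSE` supports are unrooted
#' bipartition frequencies: each nontrivial clade is canonicalized to the
#' side of the split not containing the alphabetically first taxon, which is
#' the right view under reversible (CV1) models whose root placement is
#' unidentifiable.
#'
#' @param traces an `mcmc_trace` or list of them (burnin applied per trace).
#' @param rooted report rooted clades (TRUE) or unrooted splits (FALSE).
#' @return Named numeric vector: split key (sorted tip labels joined by `|`)
#'   -> posterior frequency across all post-burnin samples.
#' @export
split_supports <- function(traces, rooted = TRUE) {
  if (inherits(traces, "mcmc_trace")) traces <- list(traces)
  all_taxa <- sort(traces[[1]]$taxa)
  keys <- unlist(lapply(traces, function(tr)
    lapply(trace_samples(tr), function(s) {
      k <- unique(clade_keys(s$tree))
      if (rooted) k else unique(unlist(lapply(k, unroot_key, all_taxa)))
    })))
  n <- sum(vapply(traces, function(tr) length(trace_samples(tr)), 1L))
  tab <- table(keys) / n
  stats::setNames(as.numeric(tab), names(tab))
}

# Canonical unrooted-split key for a clade key; NULL for trivial splits.
unroot_key <- function(key, all_taxa) {
  side <- strsplit(key, "|", fixed = TRUE)[[1]]
  n <- length(all_taxa)
  if (length(side) < 2 || length(side) > n - 2) return(NULL)
  if (all_taxa[1] %in% side) side <- setdiff(all_taxa, side)
  paste(sort(side), collapse = "|")
}

#' Majority-rule consensus tree with posterior split supports
#'
#' @param traces an `mcmc_trace` or list of traces over the same leaf set;
#'   burnin is applied per trace.
#' @return List with `tree` (rooted `phylo`, majority-rule consensus, node
#'   labels = posterior supports), `supports` (full clade support table) and
#'   `mean_tree_length` (mean over sampled trees of the summed branch
#'   lengths, in expected substitutions/site).
#' @export
consensus_tree <- function(traces) {
  if (inherits(traces, "mcmc_trace")) traces <- list(traces)
  leafsets <- unique(lapply(traces, function(tr) sort(tr$taxa)))
  if (length(leafsets) != 1) stop("traces have different leaf sets")
  samples <- unlist(lapply(traces, trace_samples), recursive = FALSE)
  if (!length(samples)) stop("no post-burnin samples")
  trees <- lapply(samples, `[[`, "tree")
  class(trees) <- "multiPhylo"
  supports <- split_supports(traces)
  cons <- ape::consensus(trees, p = 0.5, rooted = TRUE)
  cons$node.label <- vapply(seq_len(cons$Nnode), function(k) {
    nd <- ape::Ntip(cons) + k
    tips <- cons$tip.label[unlist(phangorn_free_descendants(cons, nd))]
    key <- paste(sort(tips), collapse = "|")
    sup <- supports[key]
    sprintf("%.3f", if (is.na(sup)) 1 else sup)
  }, "")
  mtl <- mean(vapply(trees, function(t) sum(t$edge.length), 1))
  list(tree = cons, supports = supports, mean_tree_length = mtl)
}

# Tip indices below a node (small helper; avoids a phangorn dependency).
phangorn_free_descendants <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, phangorn_free_descendants, tree = tree))
}

#' Average standard deviation of split support between independent runs
#'
#' The topological convergence diagnostic: for every split reaching
#' `threshold` support in at least one run, the sample standard deviation
#' (n - 1 denominator) of its supports across runs is computed, counting 0
#' for runs where the split is absent; the average over those splits is
#' returned.  Identical runs give 0; values decrease as independent runs
#' converge on one posterior.
#'
#' @param traces list of >= 2 `mcmc_trace` objects over the same leaf set.
#' @param threshold inclusion threshold (default 0.1).
#' @return Single numeric value.
#' @export
asdoss <- function(traces, threshold = 0.1) {
  if (inherits(traces, "mcmc_trace") || length(traces) < 2)
    stop("asdoss needs at least 2 independent traces")
  per_run <- lapply(traces, split_supports)
  keys <- unique(unlist(lapply(per_run, names)))
  sup <- vapply(per_run, function(s) {
    v <- s[keys]
    v[is.na(v)] <- 0
    v
  }, numeric(length(keys)))
  sup <- matrix(sup, nrow = length(keys))
  keep <- apply(sup, 1, max) >= threshold
  if (!any(keep)) return(0)
  mean(apply(sup[keep, , drop = FALSE], 1, stats::sd))
}

#' Chi-squared statistic of compositional homogeneity
#'
#' Contingency-style statistic over canonical-state counts per taxon
#' (ambiguity, gap and missing codes excluded):
#' \eqn{X^2 = \sum_t \sum_s (c_{ts} - E_{ts})^2 / E_{ts}} with expected
#' counts \eqn{E_{ts}} = (taxon t's total) x (global state proportion).
#' States with zero global count are skipped.
#'
#' @param a an [alignment()] with >= 2 taxa.
#' @return The statistic (single number; 0 when all taxa share one
#'   composition).
#' @examples
#' composition_chi2(alignment(c(t1 = "AAAA", t2 = "CCCC"), "nucleotide")) # 8
#' @export
composition_chi2 <- function(a) {
  stopifnot(n_taxa(a) >= 2)
  canon <- a$alphabet$canonical
  counts <- t(apply(a$matrix, 1, function(s)
    tabulate(factor(s[s %in% canon], levels = canon), nbins = length(canon))))
  if (sum(counts) == 0) stop("empty alignment: no canonical states")
  global <- colSums(counts) / sum(counts)
  keep <- global > 0
  expd <- outer(rowSums(counts), global[keep])
  sum((counts[, keep, drop = FALSE] - expd)^2 / expd)
}

#' Posterior predictive test of compositional homogeneity
#'
#' For `n_reps` evenly thinned post-burnin samples, simulates a gap-free
#' alignment of the original dimensions under the sampled tree, compositions,
#' exchangeabilities and gamma shape (via [simulate_alignment()]), computes
#' [composition_chi2()] on each, and compares the simulated distribution to
#' the observed statistic.  The tail probability is one-sided: the fraction
#' of simulated statistics at least as large as the observed one, so an
#' observed statistic above the whole distribution gives a small p.
#'
#' @param trace an `mcmc_trace` with post-burnin samples.
#' @param a the observed [alignment()] the chain was run on.
#' @param n_reps number of posterior predictive replicates.
#' @param seed RNG seed for the simulations.
#' @return List with `original_statistic`, `simulated_statistics`,
#'   `sample_min`, `sample_max`, `tail_p`.
#' @export
posterior_predictive_chi2 <- function(trace, a, n_reps = 100, seed = 1L) {
  post <- trace_samples(trace)
  if (!length(post)) stop("trace has no post-burnin samples")
  if (n_reps > length(post))
    stop("n_reps (", n_reps, ") exceeds available post-burnin samples (",
         length(post), ")")
  pick <- unique(round(seq(1, length(post), length.out = n_reps)))
  orig <- composition_chi2(a)
  m <- trace$m
  sims <- vapply(seq_along(pick), function(k) {
    s <- post[[pick[k]]]
    spec <- simulation_spec(s$tree, s$node_comp,
                            exch_matrix_from_free(s$exch_free, m),
                            discrete_gamma(s$alpha), n_sites = trace$n_sites,
                            seed = seed + k)
    composition_chi2(simulate_alignment(spec))
  }, 1)
  list(original_statistic = orig, simulated_statistics = sims,
       sample_min = min(sims), sample_max = max(sims),
       tail_p = mean(sims >= orig))
}

#' Harmonic-mean marginal-likelihood estimate
#'
#' The harmonic mean of the sampled likelihoods, computed stably in log
#' space.  This is a crude, high-variance estimator; it is reported for
#' comparison between runs, not as a calibrated marginal likelihood.
#'
#' @param trace an `mcmc_trace` with post-burnin samples.
#' @return List with `estimator_id = "harmonic-mean"`, `value` (log marginal
#'   likelihood estimate), `n_samples`.
#' @export
harmonic_mean_logml <- function(trace) {
  post <- trace_samples(trace)
  if (!length(post)) stop("trace has no post-burnin samples")
  ll <- vapply(post, `[[`, 1, "logL")
  # log HM = -( logmeanexp(-ll) )
  x <- -ll
  mx <- max(x)
  value <- -(mx + log(mean(exp(x - mx))))
  list(estimator_id = "harmonic-mean", value = value, n_samples = length(ll))
}
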