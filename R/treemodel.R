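#' Build a time-reversible rate matrix from exchangeabilities and a composition
#'
#' \eqn{Q_{ab} = R_{ab} \pi_b} for \eqn{a \ne b}, diagonal set so rows sum to
#' zero, and the whole matrix rescaled so the expected substitution rate at
#' stationarity under `pi` is 1 (\eqn{-\sum_a \pi_a Q_{aa} = 1}), so branch
#' lengths keep their expected-substitutions-per-site meaning under any
#' composition regime.
#'
#' @param exch symmetric non-negative exchangeability matrix (zero diagonal
#'   assumed; only off-diagonals used).
#' @param pi composition vector (positive, sums to 1).
#' @return m x m rate matrix.
#' @examples
#' q <- build_q(matrix(1, 4, 4), rep(0.25, 4))  # Jukes-Cantor
#' @export
build_q <- function(exch, pi) {
  m <- length(pi)
  stopifnot(nrow(exch) == m, ncol(exch) == m)
  if (any(pi <= 0)) stop("zero or negative composition entry")
  if (abs(sum(pi) - 1) > 1e-9) stop("composition must sum to 1")
  q <- exch * rep(pi, each = m)   # q[a,b] = R[a,b] * pi[b]
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  rate <- -sum(pi * diag(q))
  if (rate <= 0) stop("degenerate rate matrix (all-zero exchangeabilities?)")
  q / rate
}

#' Transition probability matrix
#'
#' \eqn{P = \exp(Q t r)} computed by symmetric eigendecomposition (Q built by
#' [build_q()] is reversible with respect to its composition, so
#' \eqn{\Pi^{1/2} Q \Pi^{-1/2}} is symmetric).
#'
#' @param q rate matrix from [build_q()].
#' @param t branch length (>= 0).
#' @param rate_multiplier rate-category multiplier (default 1).
#' @param pi the composition `q` was built with; recovered from `q`'s
#'   stationary distribution if omitted.
#' @return m x m probability matrix (rows sum to 1).
#' @export
transition_matrix <- function(q, t, rate_multiplier = 1, pi = NULL) {
  if (t < 0) stop("negative branch length")
  m <- nrow(q)
  if (t * rate_multiplier == 0) return(diag(m))
  if (is.null(pi)) {
    e0 <- eigen(t(q))
    ns <- abs(Re(e0$vectors[, which.min(abs(e0$values))]))
    pi <- ns / sum(ns)
  }
  e <- q_eigen(q, pi)
  p <- trans_prob(e, t * rate_multiplier)
  if (any(!is.finite(p))) stop("non-finite transition probabilities")
  p
}

# Eigendecomposition of a pi-reversible Q via the symmetrized form.
# Returns factors so that P(t) = D1 %*% U %*% diag(exp(lambda t)) %*% t(U) %*% D2.
q_eigen <- function(q, pi) {
  sq <- sqrt(pi)
  s <- q * (sq %o% (1 / sq))          # symmetric
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, sq = sq)
}

trans_prob <- function(e, tt) {
  w <- e$vectors * rep(exp(e$values * tt), each = nrow(e$vectors))
  p <- (1 / e$sq) * (w %*% t(e$vectors)) * rep(e$sq, each = length(e$sq))
  p[p < 0] <- 0
  p / rowSums(p)
}

#' Discrete-gamma rate categories
#'
#' Equal-probability discretization of a Gamma(shape, rate = shape)
#' distribution (mean 1) using the mean of each bin as the category rate; the
#' category rates average exactly 1.
#'
#' @param shape gamma shape parameter alpha (> 0).
#' @param n_categories number of categories (default 4).
#' @return Object of class `rate_model`: list with `shape`, `n_categories`,
#'   `rates`.
#' @examples
#' discrete_gamma(0.5)$rates
#' @export
discrete_gamma <- function(shape, n_categories = 4) {
  stopifnot(shape > 0, n_categories >= 1)
  k <- n_categories
  edges <- stats::qgamma(seq(0, 1, length.out = k + 1), shape, rate = shape)
  # mean within each bin via the shape+1 incomplete-gamma identity
  cum <- stats::pgamma(edges, shape + 1, rate = shape)
  rates <- k * diff(cum)
  rates <- rates / mean(rates) * 1  # guard rounding; mean must be 1
  structure(list(shape = shape, n_categories = k, rates = rates),
            class = "rate_model")
}

#' Assemble a tree-heterogeneous composition phylogenetic model
#'
#' Couples a rooted tree with per-node composition vectors, an
#' exchangeability matrix and discrete-gamma rates.  Composition modes:
#' `"CV1"` (one vector shared by every node: the homogeneous, stationary
#' special case), `"NDCH"` (K shared vectors with a node assignment), and
#' `"NDCH2"` (a separate vector for every node).  The branch above a node
#' evolves under the rate matrix built from that node's (the child's)
#' composition; the root's own vector is the state prior at the root.
#'
#' @param tree rooted `phylo` tree (ape) with branch lengths.
#' @param exch exchangeability matrix (m x m symmetric).
#' @param node_comp matrix of composition vectors, one row per tree node in
#'   ape node numbering (`n_tips + n_internal` rows), or a single vector for
#'   CV1.
#' @param comp_mode `"CV1"`, `"NDCH"`, or `"NDCH2"`.
#' @param rates a [discrete_gamma()] rate model.
#' @param assignment for NDCH: integer vector mapping each node to one of the
#'   K rows of `node_comp`.
#' @return Object of class `phylo_model`.
#' @export
phylo_model <- function(tree, exch, node_comp,
                        comp_mode = c("CV1", "NDCH", "NDCH2"),
                        rates = discrete_gamma(1), assignment = NULL) {
  comp_mode <- match.arg(comp_mode)
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (any(tree$edge.length < 0) || any(!is.finite(tree$edge.length)))
    stop("branch lengths must be finite and non-negative")
  m <- nrow(exch)
  if (!isTRUE(all.equal(exch, t(exch), tolerance = 1e-8)))
    stop("exchangeability matrix must be symmetric")
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  if (is.vector(node_comp)) node_comp <- matrix(node_comp, nrow = 1)
  if (ncol(node_comp) != m) stop("composition dimension mismatch")
  if (any(node_comp <= 0)) stop("composition entries must be positive")
  if (any(abs(rowSums(node_comp) - 1) > 1e-12))
    stop("composition rows must sum to 1 (tolerance 1e-12)")
  assignment <- switch(comp_mode,
    CV1 = {
      if (nrow(node_comp) != 1) stop("CV1 takes exactly one composition vector")
      rep(1L, n_nodes)
    },
    NDCH = {
      if (is.null(assignment) || length(assignment) != n_nodes)
        stop("NDCH needs an assignment of each node to one of the K vectors")
      if (any(assignment < 1 | assignment > nrow(node_comp)))
        stop("assignment indexes outside the composition vectors")
      as.integer(assignment)
    },
    NDCH2 = {
      if (nrow(node_comp) != n_nodes)
        stop("NDCH2 needs one composition vector per node (", n_nodes, ")")
      seq_len(n_nodes)
    })
  structure(list(tree = tree, exch = exch, node_comp = node_comp,
                 comp_mode = comp_mode, assignment = assignment,
                 rates = rates, m = m),
            class = "phylo_model")
}

#' @export
print.phylo_model <- function(x, ...) {
  cat("phylo_model:", x$comp_mode, "composition,", ape::Ntip(x$tree),
      "tips,", nrow(unique(x$node_comp)), "distinct composition vector(s),",
      "gamma shape", signif(x$rates$shape, 4), "x",
      x$rates$n_categories, "categories\n")
  invisible(x)
}

# Composition vector for an ape node id.
node_composition <- function(model, node) {
  model$node_comp[model$assignment[node], ]
}

#' Read a PAML-format empirical amino-acid model file
#'
#' PAML `.dat` layout: 19 lines of lower-triangle exchangeabilities followed
#' by a line (or lines) of 20 equilibrium frequencies.  Used to load
#' empirical matrices such as the green-plant-specific gcpREV from their
#' distributed files; no matrix values ship with this package.
#'
#' @param path file path.
#' @return List with `exch` (20 x 20 symmetric matrix, unit diagonal-free) and
#'   `freq` (length-20 composition), both in the package's amino-acid state
#'   order (translated from PAML's ARNDCQEGHILKMFPSTWYV, which is the same).
#' @export
read_paml_matrix <- function(path) {
  nums <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  need <- 190 + 20
  if (length(nums) < need)
    stop("PAML file has ", length(nums), " numbers; expected at least ", need)
  lower <- nums[1:190]
  freq <- nums[191:210]
  exch <- matrix(0, 20, 20)
  k <- 0
  for (i in 2:20) for (j in 1:(i - 1)) {
    k <- k + 1
    exch[i, j] <- exch[j, i] <- lower[k]
  }
  aa <- state_alphabet("amino-acid")$canonical
  dimnames(exch) <- list(aa, aa)
  if (any(freq < 0) || abs(sum(freq) - 1) > 1e-3)
    stop("PAML frequencies do not sum to 1")
  freq <- freq / sum(freq)
  list(exch = exch, freq = stats::setNames(freq, aa))
}

#' Log-likelihood under a tree-heterogeneous composition model
#'
#' Felsenstein pruning on the rooted tree: the transition matrix for the
#' branch above each node is built from that node's composition via
#' [build_q()] (normalized under its own composition), the root partials are
#' summed against the root node's composition vector, and the discrete-gamma
#' categories are averaged with equal weights.  Ambiguity codes enter as
#' partial indicators over their compatible states; gap/missing as all-ones.
#' Site patterns are compressed and per-node scaling guards against
#' underflow, so the value is exact and independent of site order.
#'
#' @param a an [alignment()] whose taxa match the tree's tip labels.
#' @param model a [phylo_model()].
#' @return Total log-likelihood (single number).
#' @export
log_likelihood <- function(a, model) {
  sum(site_log_likelihoods(a, model)$logl)
}

# Per-pattern log-likelihoods plus pattern weights; the workhorse shared by
# log_likelihood and the MCMC sampler.
site_log_likelihoods <- function(a, model) {
  tree <- model$tree
  m <- model$m
  if (length(model$node_comp[1, ]) != length(a$alphabet$canonical))
    stop("alphabet dimension does not match model")
  if (!setequal(tree$tip.label, a$taxa))
    stop("tree tip labels do not match alignment taxa")
  # pattern compression
  pat_str <- apply(a$matrix, 2, paste, collapse = "\r")
  uq <- match(pat_str, unique(pat_str))
  weights <- tabulate(uq)
  cols <- match(unique(pat_str), pat_str)
  np <- length(cols)
  ind <- code_indicator_matrix(a$alphabet)
  tip_part <- lapply(tree$tip.label, function(tx)
    ind[, a$matrix[tx, cols], drop = FALSE])
  names(tip_part) <- tree$tip.label

  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  edge <- tree$edge
  elen <- tree$edge.length
  # children list per internal node; postorder = decreasing depth
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  internal <- unique(edge[, 1])
  post <- internal[order(-node_depths(tree)[internal])]

  # eigendecomposition per node (branch above node uses child's composition)
  eigs <- vector("list", ntip + tree$Nnode)
  for (nd in unique(as.vector(edge[, 2]))) {
    pi_nd <- node_composition(model, nd)
    eigs[[nd]] <- q_eigen(build_q(model$exch, pi_nd), pi_nd)
  }
  rates <- model$rates$rates
  k <- length(rates)
  log_site <- matrix(-Inf, k, np)
  root_pi <- node_composition(model, root)
  for (ci in seq_len(k)) {
    partial <- vector("list", ntip + tree$Nnode)
    scale_log <- numeric(np)
    for (tx in seq_len(ntip)) partial[[tx]] <- tip_part[[tree$tip.label[tx]]]
    for (nd in post) {
      acc <- matrix(1, m, np)
      for (ei in kids[[as.character(nd)]]) {
        ch <- edge[ei, 2]
        p <- trans_prob(eigs[[ch]], elen[ei] * rates[ci])
        acc <- acc * (p %*% partial[[ch]])
      }
      mx <- apply(acc, 2, max)
      mx[mx == 0] <- 1
      scale_log <- scale_log + log(mx)
      partial[[nd]] <- acc / rep(mx, each = m)
    }
    log_site[ci, ] <- log(colSums(root_pi * partial[[root]])) + scale_log
  }
  # equal-weight mixture over categories, in log space
  top <- apply(log_site, 2, max)
  loglik <- top + log(colMeans(exp(sweep(log_site, 2, top, "-"))))
  if (any(!is.finite(loglik)))
    stop("non-finite site likelihood (underflow or invalid model)")
  list(logl = loglik * weights, weights = weights)
}

# Depth (edges from root) of every node; used for postorder.  Iterative
# relaxation so no particular edge ordering is assumed.
node_depths <- function(tree) {
  depth <- integer(ape::Ntip(tree) + tree$Nnode)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1]
      ch <- tree$edge[i, 2]
      if (depth[ch] != depth[p] + 1L) {
        depth[ch] <- depth[p] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  depth
}
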