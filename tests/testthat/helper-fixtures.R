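# Shared fixture builders: everything is generated in code at test time.

random_exch <- function(m = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ex <- matrix(stats::runif(m * m, 0.5, 2), m, m)
  ex <- (ex + t(ex)) / 2
  diag(ex) <- 0
  ex
}

jc_exch <- function(m = 4) {
  ex <- matrix(1, m, m)
  diag(ex) <- 0
  ex
}

random_simplex <- function(m, conc = 2) {
  x <- stats::rgamma(m, conc)
  x / sum(x)
}

random_alignment <- function(n_taxa = 4, n_sites = 30, kind = "nucleotide",
                             amb_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  al <- state_alphabet(kind)
  pool <- al$canonical
  if (amb_rate > 0) pool <- c(pool, names(al$ambiguity_map), al$gap_codes, "?")
  mat <- matrix(sample(pool, n_taxa * n_sites, replace = TRUE),
                n_taxa, n_sites,
                dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  alignment(mat, kind = kind)
}

# Rooted 4-taxon reference tree used throughout; 7 nodes in ape numbering.
tree4 <- function() ape::read.tree(text = "((A:0.2,B:0.35):0.15,(C:0.4,D:0.1):0.25);")

# Divergence-matrix object straight from a count matrix.
dm_from_counts <- function(counts) {
  canon <- state_alphabet("nucleotide")$canonical[seq_len(nrow(counts))]
  dimnames(counts) <- list(canon, canon)
  structure(list(pair = c("a", "b"), counts = counts,
                 n_effective = sum(counts), empty = sum(counts) == 0),
            class = "divergence_matrix")
}

# Independent likelihood oracle: enumerate internal-node states, transition
# matrices from Matrix::expm (entirely separate from the package's
# eigendecomposition path).
brute_force_loglik <- function(a, tree, exch, node_comp, rates) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  m <- ncol(node_comp)
  n_int <- tree$Nnode
  Ps <- list()
  for (ci in seq_along(rates)) for (ei in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[ei, 2]
    q <- build_q(exch, node_comp[ch, ])
    Ps[[paste(ci, ei)]] <-
      as.matrix(Matrix::expm(q * tree$edge.length[ei] * rates[ci]))
  }
  ind <- ndch:::code_indicator_matrix(a$alphabet)
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), n_int)))
  total <- 0
  for (site in seq_len(n_sites(a))) {
    lik <- 0
    for (ci in seq_along(rates)) {
      for (g in seq_len(nrow(grid))) {
        st <- c(rep(NA_integer_, ntip), grid[g, ])
        pr <- node_comp[root, st[root]]
        for (ei in seq_len(nrow(tree$edge))) {
          par <- tree$edge[ei, 1]
          ch <- tree$edge[ei, 2]
          P <- Ps[[paste(ci, ei)]]
          pr <- pr * if (ch <= ntip) {
            sum(P[st[par], ] * ind[, a$matrix[tree$tip.label[ch], site]])
          } else P[st[par], st[ch]]
        }
        lik <- lik + pr / length(rates)
      }
    }
    total <- total + log(lik)
  }
  total
}

# Hand-built single-sample trace around a list of trees (for counting
# oracles on consensus/asdoss without running chains).
toy_trace <- function(trees, taxa = sort(trees[[1]]$tip.label)) {
  samples <- lapply(seq_along(trees), function(i)
    list(generation = i, logL = -1, log_prior = 0, tree = trees[[i]],
         alpha = 1,
         node_comp = matrix(0.25, ape::Ntip(trees[[i]]) + trees[[i]]$Nnode, 4),
         exch_free = rep(1 / 6, 6)))
  structure(list(samples = samples,
                 acceptance = data.frame(proposed = 0, accepted = 0),
                 swap = c(attempted = 0L, accepted = 0L),
                 cfg = mcmc_config(n_generations = length(trees),
                                   sample_interval = 1, burnin_fraction = 0),
                 comp_mode = "CV1", taxa = taxa, n_sites = 1L, m = 4L),
            class = "mcmc_trace")
}
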