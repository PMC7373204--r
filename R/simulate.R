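#' Generative description of a tree-heterogeneous simulation
#'
#' Bundles everything needed to evolve an alignment under lineage-specific
#' composition: a rooted tree, one composition vector per node, an
#' exchangeability matrix, discrete-gamma rates, the number of sites, a seed,
#' an optional uniform missing-data masking rate, and an optional codon layer
#' for in-frame coding simulation (see [simulate_coding()]).
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param node_comp composition matrix, one row per node (ape numbering).
#' @param exch exchangeability matrix.
#' @param rates a [discrete_gamma()] model.
#' @param n_sites number of sites (amino-acid sites when a codon layer is
#'   present; the nucleotide alignment then has `3 * n_sites` columns).
#' @param seed integer RNG seed.
#' @param missing_rate probability that a simulated leaf character is masked
#'   to the missing code (default 0).
#' @param codon_layer optional list with `usage` (named list: degeneracy-group
#'   label -> codon-usage probability vector over the group's codons) and
#'   `usage_drift` (Dirichlet perturbation magnitude per unit branch length;
#'   0 = usage inherited unchanged).
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, node_comp, exch, rates, n_sites, seed = 1L,
                            missing_rate = 0, codon_layer = NULL) {
  stopifnot(inherits(tree, "phylo"), n_sites > 0,
            missing_rate >= 0, missing_rate < 1)
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  if (is.vector(node_comp))
    node_comp <- matrix(node_comp, n_nodes, length(node_comp), byrow = TRUE)
  if (nrow(node_comp) != n_nodes) stop("need one composition row per node")
  if (any(node_comp <= 0) || any(abs(rowSums(node_comp) - 1) > 1e-9))
    stop("compositions must be positive and sum to 1")
  structure(list(tree = tree, node_comp = node_comp, exch = exch,
                 rates = rates, n_sites = as.integer(n_sites),
                 seed = as.integer(seed), missing_rate = missing_rate,
                 codon_layer = codon_layer),
            class = "simulation_spec")
}

# Simulate character-state indices (1..m) at every node; returns list of
# per-node integer vectors plus the per-site rate category.
sim_states <- function(spec, kind) {
  tree <- spec$tree
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  ns <- spec$n_sites
  m <- ncol(spec$node_comp)
  cat_rates <- spec$rates$rates
  site_cat <- sample.int(length(cat_rates), ns, replace = TRUE)
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- sample.int(m, ns, replace = TRUE,
                               prob = spec$node_comp[root, ])
  depth <- node_depths(tree)
  pre <- order(depth[tree$edge[, 2]])  # parents before children
  for (ei in pre) {
    par <- tree$edge[ei, 1]
    ch <- tree$edge[ei, 2]
    pi_ch <- spec$node_comp[ch, ]
    e <- q_eigen(build_q(spec$exch, pi_ch), pi_ch)
    out <- integer(ns)
    for (ci in seq_along(cat_rates)) {
      sel <- which(site_cat == ci)
      if (!length(sel)) next
      p <- trans_prob(e, tree$edge.length[ei] * cat_rates[ci])
      for (s in seq_len(m)) {
        at <- sel[states[[par]][sel] == s]
        if (length(at))
          out[at] <- sample.int(m, length(at), replace = TRUE, prob = p[s, ])
      }
    }
    states[[ch]] <- out
  }
  list(states = states, site_cat = site_cat)
}

#' Simulate an alignment under tree-heterogeneous composition
#'
#' The root sequence is drawn from the root node's composition; each branch
#' evolves under the transition matrix built from the child node's
#' composition-specific rate matrix; each site keeps one gamma rate category
#' across the whole tree.  Deterministic under the spec's seed.
#'
#' @param spec a [simulation_spec()] (no codon layer needed).
#' @param kind alphabet kind of the output (`"nucleotide"` when m = 4,
#'   `"amino-acid"` when m = 20; inferred by default).
#' @return An [alignment()] over the leaf taxa.
#' @export
simulate_alignment <- function(spec, kind = NULL) {
  m <- ncol(spec$node_comp)
  if (is.null(kind)) kind <- if (m == 4) "nucleotide" else "amino-acid"
  alphabet <- state_alphabet(kind)
  if (length(alphabet$canonical) != m) stop("alphabet/composition mismatch")
  set.seed(spec$seed)
  sim <- sim_states(spec, kind)
  tree <- spec$tree
  mat <- do.call(rbind, lapply(seq_len(ape::Ntip(tree)), function(tx)
    alphabet$canonical[sim$states[[tx]]]))
  rownames(mat) <- tree$tip.label
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(length(mat)) < spec$missing_rate, nrow(mat))
    mat[mask] <- "?"
  }
  alignment(mat, kind = kind)
}

# Sense-codon degeneracy groups usable for back-translation: every amino acid
# is encoded from exactly one group, so degen recoding of the simulated
# nucleotides is a deterministic function of the amino-acid layer.  Serine is
# encoded from its TCN family only (the AGY family would break that mapping).
sense_groups <- function() {
  tab <- build_degen_table()
  codons <- names(tab$mapping)
  aa <- unlist(codon_table())[codons]
  keep <- aa != "*" & !(codons %in% c("AGT", "AGC"))
  split(codons[keep], aa[keep])
}

#' Simulate in-frame coding data with synonymous codon-usage drift
#'
#' An amino-acid alignment is evolved on the tree under the spec's (20-state)
#' model, then each leaf's amino acids are back-translated by sampling codons
#' from that leaf's codon-usage vectors.  Usage vectors drift along branches
#' by Dirichlet perturbation of magnitude `usage_drift`, creating
#' third-position-like variation uncorrelated with the topology; frames stay
#' valid and stop-free by construction.
#'
#' @param spec a [simulation_spec()] with 20-state compositions and a
#'   `codon_layer`; `default_codon_layer()` supplies uniform starting usage.
#' @return List with `nucleotide` and `amino_acid` alignments (leaf taxa;
#'   `3 * n_sites` and `n_sites` columns).
#' @export
simulate_coding <- function(spec) {
  if (ncol(spec$node_comp) != 20)
    stop("simulate_coding needs amino-acid (20-state) compositions")
  if (is.null(spec$codon_layer)) spec$codon_layer <- default_codon_layer()
  aa_aln <- simulate_alignment(spec, kind = "amino-acid")
  groups <- sense_groups()
  tree <- spec$tree
  drift <- spec$codon_layer$usage_drift
  # drift usage along the tree: usage per node, inherited + perturbed
  usage <- vector("list", ape::Ntip(tree) + tree$Nnode)
  usage[[ape::Ntip(tree) + 1L]] <- spec$codon_layer$usage
  pre <- order(node_depths(tree)[tree$edge[, 2]])
  for (ei in pre) {
    par <- tree$edge[ei, 1]
    ch <- tree$edge[ei, 2]
    u <- usage[[par]]
    if (drift > 0) {
      bl <- tree$edge.length[ei]
      conc <- 1 / (drift * max(bl, 1e-6))
      u <- lapply(u, function(v) {
        if (length(v) == 1) return(v)
        g <- stats::rgamma(length(v), shape = v * conc + 1e-3)
        stats::setNames(g / sum(g), names(v))
      })
    }
    usage[[ch]] <- u
  }
  nt <- matrix("-", n_taxa(aa_aln), 3L * spec$n_sites,
               dimnames = list(aa_aln$taxa, NULL))
  for (tx_i in seq_len(ape::Ntip(tree))) {
    tx <- tree$tip.label[tx_i]
    u <- usage[[tx_i]]
    aas <- aa_aln$matrix[tx, ]
    cods <- character(spec$n_sites)
    for (aa in unique(aas)) {
      at <- which(aas == aa)
      if (aa %in% names(groups)) {
        fam <- groups[[aa]]
        prob <- u[[aa]][fam]
        cods[at] <- fam[sample.int(length(fam), length(at), replace = TRUE,
                                   prob = prob)]
      } else cods[at] <- "NNN"   # masked amino acid -> missing codon
    }
    nt[tx, ] <- unlist(strsplit(cods, ""))
  }
  aln_nt <- alignment(nt, kind = "nucleotide")
  list(nucleotide = aln_nt, amino_acid = aa_aln)
}

#' @rdname simulate_coding
#' @param usage_drift per-branch Dirichlet perturbation magnitude (default 0).
#' @export
default_codon_layer <- function(usage_drift = 0) {
  groups <- sense_groups()
  usage <- lapply(groups, function(fam)
    stats::setNames(rep(1 / length(fam), length(fam)), fam))
  list(usage = usage, usage_drift = usage_drift)
}

#' Simulation spec with the statistical structure of a chloroplast-style study
#'
#' Builds a random rooted tree with `n_taxa` leaves and node compositions
#' whose GC content drifts along lineages, affinely rescaled so the leaf GC
#' values span approximately 0.33 to 0.51 (the spread seen across
#' streptophyte plastid coding matrices).  Defaults: 30 taxa, 3000 sites,
#' gamma shape 0.4, a mild transition/transversion-biased GTR, and a few
#' percent uniform missing data.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param seed integer seed (tree shape, compositions, and simulation).
#' @param n_sites alignment length.
#' @param gc_range target leaf GC range (default `c(0.33, 0.51)`).
#' @param alpha gamma shape.
#' @param missing_rate uniform masking rate (default 0.03).
#' @param tree_scale mean root-to-tip path length in expected
#'   substitutions/site (default 3.5, reflecting the strong synonymous
#'   saturation of plastid coding data).
#' @return A [simulation_spec()] with 4-state compositions.
#' @export
study_like_spec <- function(n_taxa = 30, seed = 1L, n_sites = 3000,
                            gc_range = c(0.33, 0.51), alpha = 0.4,
                            missing_rate = 0.03, tree_scale = 3.5) {
  stopifnot(n_taxa >= 4)
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = TRUE,
                     tip.label = sprintf("t%02d", seq_len(n_taxa)))
  depth <- node_depths(tree)
  paths <- path_lengths_to_tips(tree)
  tree$edge.length <- tree$edge.length * tree_scale / mean(paths)
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  # GC random walk from the root, then affine rescale so leaves span gc_range
  gc <- numeric(n_nodes)
  gc[ape::Ntip(tree) + 1L] <- mean(gc_range)
  pre <- order(depth[tree$edge[, 2]])
  for (ei in pre) {
    par <- tree$edge[ei, 1]
    ch <- tree$edge[ei, 2]
    gc[ch] <- gc[par] + stats::rnorm(1, 0, 0.08 * sqrt(max(tree$edge.length[ei], 1e-8) / 0.1))
  }
  leaf_gc <- gc[seq_len(n_taxa)]
  span <- range(leaf_gc)
  if (diff(span) < 1e-6) span <- span + c(-0.01, 0.01)
  gc <- gc_range[1] + (gc - span[1]) / diff(span) * diff(gc_range)
  gc <- pmin(pmax(gc, 0.05), 0.95)
  node_comp <- cbind(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  exch <- matrix(c(0, 1, 4, 1,
                   1, 0, 1, 4,
                   4, 1, 0, 1,
                   1, 4, 1, 0), 4, 4)  # transition-biased GTR skeleton
  simulation_spec(tree, node_comp, exch, discrete_gamma(alpha),
                  n_sites = n_sites, seed = seed, missing_rate = missing_rate)
}

# Root-to-tip path lengths.
path_lengths_to_tips <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  acc <- numeric(n)
  pre <- order(node_depths(tree)[tree$edge[, 2]])
  for (ei in pre) {
    acc[tree$edge[ei, 2]] <- acc[tree$edge[ei, 1]] + tree$edge.length[ei]
  }
  acc[seq_len(ape::Ntip(tree))]
}
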