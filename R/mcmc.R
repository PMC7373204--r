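#' MCMC run configuration
#'
#' @param n_generations total generations.
#' @param sample_interval record one sample every this many generations.
#' @param burnin_fraction fraction of samples discarded by consumers
#'   (default 0.25, i.e. the first quarter).
#' @param n_chains number of Metropolis-coupled chains (1 cold + heated;
#'   default 4).
#' @param heating_lambda chain i runs at temperature 1/(1 + lambda * i).
#' @param swap_interval generations between swap attempts (coupled runs).
#' @param proposal_weights named vector of relative weights for the proposal
#'   kinds `blen`, `alpha`, `comp`, `exch`, `nni`, `spr`, `reassign`
#'   (`reassign` only used by NDCH).
#' @param prior list: `blen_mean` (exponential prior mean on branch lengths),
#'   `comp_conc` / `exch_conc` (flat Dirichlet concentrations),
#'   `log_alpha_bounds` (uniform prior bounds on log alpha).
#' @param tuning list: `blen_mult`, `alpha_sd`, `comp_conc`, `exch_conc`
#'   proposal tuning constants (composition proposals are Dirichlet
#'   perturbations centred on the current vector; raise the concentration for
#'   smaller steps).
#' @param seed integer RNG seed; fixed-seed runs are bit-reproducible.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_generations = 10000, sample_interval = 10,
                        burnin_fraction = 0.25, n_chains = 4,
                        heating_lambda = 0.1, swap_interval = 10,
                        proposal_weights = c(blen = 3, alpha = 1, comp = 2,
                                             exch = 1, nni = 2, spr = 1,
                                             reassign = 0),
                        prior = list(blen_mean = 0.1, comp_conc = 1,
                                     exch_conc = 1,
                                     log_alpha_bounds = c(-3, 3)),
                        tuning = list(blen_mult = 1.0, alpha_sd = 0.3,
                                      comp_conc = 300, exch_conc = 300),
                        seed = 1L) {
  stopifnot(burnin_fraction >= 0, burnin_fraction < 1, n_chains >= 1,
            sample_interval >= 1, all(proposal_weights >= 0),
            prior$blen_mean > 0, prior$comp_conc > 0, prior$exch_conc > 0)
  structure(list(n_generations = as.integer(n_generations),
                 sample_interval = as.integer(sample_interval),
                 burnin_fraction = burnin_fraction,
                 n_chains = as.integer(n_chains),
                 heating_lambda = heating_lambda,
                 swap_interval = as.integer(swap_interval),
                 proposal_weights = proposal_weights,
                 prior = prior, tuning = tuning, seed = as.integer(seed)),
            class = "mcmc_config")
}

# ---- tree surgery on the ape edge matrix (node ids stay stable, so per-node
# ---- composition vectors keep their meaning across topology moves) ----

row_of_child <- function(tree) {
  r <- integer(ape::Ntip(tree) + tree$Nnode)
  r[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  r
}

tree_parent <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

tree_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

subtree_nodes <- function(tree, node) {
  out <- node
  frontier <- node
  while (length(frontier)) {
    kids <- tree$edge[tree$edge[, 1] %in% frontier, 2]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# NNI: swap a random child of an internal non-root node with its sibling.
# Symmetric proposal.  Returns NULL when no internal edge exists.
propose_nni <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  cand <- tree$edge[tree$edge[, 2] > ntip, 2]   # internal, non-root children
  if (!length(cand)) return(NULL)
  cnode <- cand[sample.int(length(cand), 1)]
  p <- tree_parent(tree)[cnode]
  z <- setdiff(tree_children(tree, p), cnode)
  x <- tree_children(tree, cnode)
  x <- x[sample.int(length(x), 1)]
  z <- z[sample.int(length(z), 1)]
  rc <- row_of_child(tree)
  tree$edge[rc[x], 1] <- p
  tree$edge[rc[z], 1] <- cnode
  list(tree = tree, log_hastings = 0)
}

# Subtree pruning and regrafting with the pruned node's parent travelling
# with it; uniform choice of prunable node and target edge, uniform split of
# the target branch.  log_hastings includes the count ratio and the
# merge/split Jacobian.
propose_spr <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  par <- tree_parent(tree)
  prunable <- which(par != 0 & par != root)      # nodes with a grandparent
  if (!length(prunable)) return(NULL)
  cnode <- prunable[sample.int(length(prunable), 1)]
  p <- par[cnode]
  g <- par[p]
  z <- setdiff(tree_children(tree, p), cnode)
  rc <- row_of_child(tree)
  sub <- subtree_nodes(tree, cnode)
  targets <- setdiff(which(par != 0), c(sub, p, z))
  if (!length(targets)) return(NULL)
  b <- targets[sample.int(length(targets), 1)]
  len_zp <- tree$edge.length[rc[z]] + tree$edge.length[rc[p]]
  len_b <- tree$edge.length[rc[b]]
  u <- stats::runif(1)
  a <- par[b]
  # merge z upward, insert p into the edge above b
  tree$edge[rc[z], 1] <- g
  tree$edge.length[rc[z]] <- len_zp
  tree$edge[rc[p], 1] <- a
  tree$edge.length[rc[p]] <- u * len_b
  tree$edge[rc[b], 1] <- p
  tree$edge.length[rc[b]] <- (1 - u) * len_b
  # reverse-move counts on the new state
  par2 <- tree_parent(tree)
  prunable2 <- sum(par2 != 0 & par2 != root)
  sub2 <- subtree_nodes(tree, cnode)
  targets2 <- length(setdiff(which(par2 != 0), c(sub2, p, b)))
  log_h <- log(length(prunable)) + log(length(targets)) -
    log(prunable2) - log(targets2) + log(len_b) - log(len_zp)
  list(tree = tree, log_hastings = log_h)
}

# ---- Dirichlet helpers ----

rdirichlet1 <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc)
  g / sum(g)
}

ddirichlet_log <- function(x, conc) {
  sum((conc - 1) * log(x)) + lgamma(sum(conc)) - sum(lgamma(conc))
}

# ---- chain state ----

mcmc_state <- function(tree, node_comp, assignment, exch_free, alpha,
                       comp_mode) {
  list(tree = tree, node_comp = node_comp, assignment = assignment,
       exch_free = exch_free, alpha = alpha, comp_mode = comp_mode)
}

exch_matrix_from_free <- function(free, m) {
  ex <- matrix(0, m, m)
  ex[upper.tri(ex)] <- free
  ex + t(ex)
}

state_model <- function(st, m) {
  phylo_model(st$tree, exch_matrix_from_free(st$exch_free, m), st$node_comp,
              comp_mode = st$comp_mode, rates = discrete_gamma(st$alpha),
              assignment = if (st$comp_mode == "NDCH") st$assignment else NULL)
}

state_log_prior <- function(st, prior) {
  lp <- sum(stats::dexp(st$tree$edge.length, rate = 1 / prior$blen_mean,
                        log = TRUE))
  la <- log(st$alpha)
  b <- prior$log_alpha_bounds
  if (la < b[1] || la > b[2]) return(-Inf)
  lp <- lp - log(diff(b))   # uniform on log alpha
  m <- ncol(st$node_comp)
  for (k in seq_len(nrow(st$node_comp)))
    lp <- lp + ddirichlet_log(st$node_comp[k, ], rep(prior$comp_conc, m))
  lp + ddirichlet_log(st$exch_free, rep(prior$exch_conc,
                                        length(st$exch_free)))
}

#' Bayesian MCMC under tree-heterogeneous composition models
#'
#' Metropolis-Hastings sampling of topology, branch lengths, composition
#' vector(s), exchangeabilities and the gamma shape, with optional Metropolis
#' coupling (heated chains with periodic state swaps; only the cold chain is
#' recorded).  Proposals: branch-length multiplier, log-alpha random walk
#' (reflected at its prior bounds), centred Dirichlet perturbations of one
#' composition vector and of the exchangeabilities, NNI and SPR topology
#' moves, and (NDCH only) node-to-vector reassignment.
#'
#' @param a an [alignment()].
#' @param comp_mode `"CV1"`, `"NDCH"` or `"NDCH2"`.
#' @param cfg an [mcmc_config()].
#' @param K number of composition vectors (NDCH only).
#' @param start_tree optional rooted `phylo` starting tree (default: random
#'   topology with all branch lengths 0.1).
#' @return Object of class `mcmc_trace`: list with `samples` (each holding
#'   `generation`, `logL`, `log_prior`, `tree`, `alpha`, `node_comp` expanded
#'   to one row per node, `exch_free`), `acceptance` (per-proposal counts),
#'   `swap` (attempted/accepted), `cfg`, `comp_mode`, `taxa`, `n_sites`.
#' @export
run_mcmc <- function(a, comp_mode = c("CV1", "NDCH", "NDCH2"),
                     cfg = mcmc_config(), K = 2, start_tree = NULL) {
  comp_mode <- match.arg(comp_mode)
  m <- length(a$alphabet$canonical)
  set.seed(cfg$seed)
  ntax <- n_taxa(a)
  if (is.null(start_tree)) {
    tree <- ape::rtree(ntax, rooted = TRUE, tip.label = sample(a$taxa))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  } else {
    tree <- start_tree
    if (!setequal(tree$tip.label, a$taxa)) stop("start tree taxa mismatch")
  }
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  emp <- empirical_composition(a)
  nK <- switch(comp_mode, CV1 = 1L, NDCH = as.integer(K), NDCH2 = n_nodes)
  node_comp <- matrix(rep(emp, each = nK), nK, m)
  assignment <- if (comp_mode == "NDCH")
    sample.int(nK, n_nodes, replace = TRUE) else NULL
  nfree <- m * (m - 1) / 2
  st <- mcmc_state(tree, node_comp, assignment,
                   rep(1 / nfree, nfree), 1.0, comp_mode)

  w <- cfg$proposal_weights
  if (comp_mode != "NDCH") w["reassign"] <- 0
  if (ntax < 3) w[c("nni", "spr")] <- 0   # no alternative rooted topologies
  w <- w[w > 0]
  betas <- 1 / (1 + cfg$heating_lambda * (seq_len(cfg$n_chains) - 1))

  chains <- lapply(seq_len(cfg$n_chains), function(i) {
    ch <- st
    ch$logL <- log_likelihood(a, state_model(ch, m))
    ch$logP <- state_log_prior(ch, cfg$prior)
    ch
  })
  if (!is.finite(chains[[1]]$logL))
    stop("non-finite likelihood at starting state")

  acc <- matrix(0L, length(w), 2, dimnames = list(names(w),
                                                  c("proposed", "accepted")))
  swap <- c(attempted = 0L, accepted = 0L)
  samples <- vector("list", cfg$n_generations %/% cfg$sample_interval)
  si <- 0L
  zero_acc_warned <- FALSE
  for (gen in seq_len(cfg$n_generations)) {
    for (ci in seq_along(chains)) {
      kind <- sample(names(w), 1, prob = w)
      res <- propose(chains[[ci]], kind, a, m, cfg)
      if (ci == 1L) acc[kind, "proposed"] <- acc[kind, "proposed"] + 1L
      if (!is.null(res)) {
        new <- res$state
        new$logP <- state_log_prior(new, cfg$prior)
        if (is.finite(new$logP)) {
          new$logL <- log_likelihood(a, state_model(new, m))
          lr <- betas[ci] * (new$logL - chains[[ci]]$logL) +
            (new$logP - chains[[ci]]$logP) + res$log_hastings
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            chains[[ci]] <- new
            if (ci == 1L) acc[kind, "accepted"] <- acc[kind, "accepted"] + 1L
          }
        }
      }
    }
    if (cfg$n_chains > 1 && gen %% cfg$swap_interval == 0) {
      i <- sample.int(cfg$n_chains - 1, 1)
      j <- i + 1L
      swap["attempted"] <- swap["attempted"] + 1L
      lr <- (betas[i] - betas[j]) * (chains[[j]]$logL - chains[[i]]$logL)
      if (log(stats::runif(1)) < lr) {
        tmp <- chains[[i]]
        chains[[i]] <- chains[[j]]
        chains[[j]] <- tmp
        swap["accepted"] <- swap["accepted"] + 1L
      }
    }
    if (gen %% cfg$sample_interval == 0) {
      si <- si + 1L
      cold <- chains[[1]]
      full_comp <- if (cold$comp_mode == "NDCH")
        cold$node_comp[cold$assignment, , drop = FALSE]
      else if (cold$comp_mode == "CV1")
        cold$node_comp[rep(1L, n_nodes), , drop = FALSE]
      else cold$node_comp
      samples[[si]] <- list(generation = gen, logL = cold$logL,
                            log_prior = cold$logP, tree = cold$tree,
                            alpha = cold$alpha, node_comp = full_comp,
                            exch_free = cold$exch_free)
    }
    if (!zero_acc_warned && gen == max(200L, cfg$sample_interval) &&
        sum(acc[, "accepted"]) == 0L && sum(acc[, "proposed"]) > 50L) {
      warning("MCMC stall: no proposal accepted in the first ", gen,
              " generations")
      zero_acc_warned <- TRUE
    }
  }
  structure(list(samples = samples[seq_len(si)],
                 acceptance = as.data.frame(acc),
                 swap = swap, cfg = cfg, comp_mode = comp_mode,
                 taxa = a$taxa, n_sites = n_sites(a), m = m),
            class = "mcmc_trace")
}

empirical_composition <- function(a) {
  canon <- a$alphabet$canonical
  s <- a$matrix[a$matrix %in% canon]
  p <- tabulate(factor(s, levels = canon), nbins = length(canon))
  p <- p + 1   # keep strictly positive
  p / sum(p)
}

# One proposal of the given kind; returns list(state, log_hastings) or NULL
# when the move is unavailable / hits the simplex boundary.
propose <- function(st, kind, a, m, cfg) {
  tun <- cfg$tuning
  switch(kind,
    blen = {
      ei <- sample.int(nrow(st$tree$edge), 1)
      f <- exp(tun$blen_mult * (stats::runif(1) - 0.5))
      st$tree$edge.length[ei] <- st$tree$edge.length[ei] * f
      list(state = st, log_hastings = log(f))
    },
    alpha = {
      b <- cfg$prior$log_alpha_bounds
      la <- log(st$alpha) + stats::rnorm(1, 0, tun$alpha_sd)
      while (la < b[1] || la > b[2]) {          # reflect into the prior box
        if (la < b[1]) la <- 2 * b[1] - la
        if (la > b[2]) la <- 2 * b[2] - la
      }
      st$alpha <- exp(la)
      list(state = st, log_hastings = 0)
    },
    comp = {
      k <- sample.int(nrow(st$node_comp), 1)
      cur <- st$node_comp[k, ]
      new <- rdirichlet1(cur * tun$comp_conc)
      if (any(new < 1e-8)) return(NULL)
      lh <- ddirichlet_log(cur, new * tun$comp_conc) -
        ddirichlet_log(new, cur * tun$comp_conc)
      st$node_comp[k, ] <- new
      list(state = st, log_hastings = lh)
    },
    exch = {
      cur <- st$exch_free
      new <- rdirichlet1(cur * tun$exch_conc)
      if (any(new < 1e-8)) return(NULL)
      lh <- ddirichlet_log(cur, new * tun$exch_conc) -
        ddirichlet_log(new, cur * tun$exch_conc)
      st$exch_free <- new
      list(state = st, log_hastings = lh)
    },
    nni = {
      res <- propose_nni(st$tree)
      if (is.null(res)) return(NULL)
      st$tree <- res$tree
      list(state = st, log_hastings = res$log_hastings)
    },
    spr = {
      res <- propose_spr(st$tree)
      if (is.null(res)) return(NULL)
      st$tree <- res$tree
      list(state = st, log_hastings = res$log_hastings)
    },
    reassign = {
      nd <- sample.int(length(st$assignment), 1)
      st$assignment[nd] <- sample.int(nrow(st$node_comp), 1)
      list(state = st, log_hastings = 0)
    })
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat("mcmc_trace:", length(x$samples), "samples,", x$comp_mode, "model,",
      length(x$taxa), "taxa\n")
  if (length(x$samples))
    cat("final logL:", round(x$samples[[length(x$samples)]]$logL, 3), "\n")
  invisible(x)
}

#' Post-burnin samples of a trace
#'
#' @param trace an `mcmc_trace`.
#' @param burnin_fraction override of the config's burnin fraction.
#' @return List of samples.
#' @export
trace_samples <- function(trace, burnin_fraction = NULL) {
  bf <- if (is.null(burnin_fraction)) trace$cfg$burnin_fraction
        else burnin_fraction
  n <- length(trace$samples)
  if (n == 0L) return(list())
  drop <- floor(bf * n)
  trace$samples[seq.int(drop + 1L, n)]
}

#' Serialize a trace to disk
#'
#' Writes `<stem>.params.tsv` (generation, logL, log_prior, alpha, tree
#' length) and `<stem>.trees.nwk` (one Newick string per sample).
#'
#' @param trace an `mcmc_trace`.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_trace <- function(trace, stem) {
  df <- do.call(rbind, lapply(trace$samples, function(s)
    data.frame(generation = s$generation, logL = s$logL,
               log_prior = s$log_prior, alpha = s$alpha,
               tree_length = sum(s$tree$edge.length))))
  utils::write.table(df, paste0(stem, ".params.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  nwk <- vapply(trace$samples, function(s) ape::write.tree(s$tree), "")
  writeLines(nwk, paste0(stem, ".trees.nwk"))
  invisible(stem)
}
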