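test_that("zero-generation runs return an empty trace without error", {
  a <- random_alignment(4, 20, seed = 1)
  trc <- run_mcmc(a, "CV1", mcmc_config(n_generations = 0, n_chains = 1))
  expect_length(trc$samples, 0)
  expect_length(trace_samples(trc), 0)
})

test_that("fixed seeds give bit-identical traces", {
  a <- random_alignment(4, 60, seed = 2)
  cfg <- mcmc_config(n_generations = 200, sample_interval = 10,
                     n_chains = 1, seed = 99)
  t1 <- run_mcmc(a, "CV1", cfg)
  t2 <- run_mcmc(a, "CV1", cfg)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$acceptance, t2$acceptance)
})

test_that("sampled composition vectors stay on the simplex", {
  a <- random_alignment(4, 60, seed = 3)
  trc <- run_mcmc(a, "NDCH2",
                  mcmc_config(n_generations = 400, sample_interval = 10,
                              n_chains = 1, seed = 5))
  for (s in trc$samples) {
    expect_true(all(s$node_comp > 0))
    expect_equal(unname(rowSums(s$node_comp)),
                 rep(1, nrow(s$node_comp)), tolerance = 1e-9)
  }
})

test_that("NDCH runs with K shared vectors and node reassignment", {
  a <- random_alignment(4, 60, seed = 13)
  trc <- run_mcmc(a, "NDCH",
                  mcmc_config(n_generations = 300, sample_interval = 10,
                              n_chains = 1, seed = 4,
                              proposal_weights = c(blen = 2, alpha = 1,
                                                   comp = 2, exch = 1,
                                                   nni = 1, spr = 1,
                                                   reassign = 2)),
                  K = 2)
  expect_equal(trc$comp_mode, "NDCH")
  expect_true("reassign" %in% rownames(trc$acceptance))
  for (s in trc$samples) {
    # expanded per-node compositions drawn from at most K distinct vectors
    expect_equal(nrow(s$node_comp), 7)
    expect_lte(nrow(unique(s$node_comp)), 2)
    expect_equal(unname(rowSums(s$node_comp)), rep(1, 7), tolerance = 1e-9)
  }
})

test_that("Metropolis coupling swaps states between hot and cold chains", {
  a <- random_alignment(4, 60, seed = 4)
  trc <- run_mcmc(a, "CV1",
                  mcmc_config(n_generations = 400, sample_interval = 20,
                              n_chains = 2, swap_interval = 5, seed = 6))
  expect_gt(trc$swap["attempted"], 0)
  expect_gte(trc$swap["accepted"], 0)
  expect_lte(trc$swap["accepted"], trc$swap["attempted"])
})

test_that("NNI sampling matches the brute-force topology posterior", {
  a <- alignment(c(A = "ACGTACGTACGTAAGGCTTA", B = "ACGTACGAACGTAAGGCTAA",
                   C = "AAGTACGTACCTAAGGTTTA"), "nucleotide")
  tr0 <- ape::read.tree(text = "((A:0.1,B:0.12):0.08,C:0.2);")
  cfg <- mcmc_config(n_generations = 20000, sample_interval = 3,
                     n_chains = 1, burnin_fraction = 0.1,
                     proposal_weights = c(blen = 0, alpha = 0, comp = 0,
                                          exch = 0, nni = 1, spr = 0,
                                          reassign = 0),
                     seed = 2)
  trc <- run_mcmc(a, "CV1", cfg, start_tree = tr0)
  # enumerate the three rooted topologies with the same node-attached lengths
  emp <- ndch:::empirical_composition(a)
  exch <- ndch:::exch_matrix_from_free(rep(1 / 6, 6), 4)
  lens <- c(A = 0.1, B = 0.12, C = 0.2, int = 0.08)
  lik <- c()
  for (o in c("A", "B", "C")) {
    ing <- setdiff(c("A", "B", "C"), o)
    txt <- sprintf("((%s:%f,%s:%f):%f,%s:%f);", ing[1], lens[ing[1]],
                   ing[2], lens[ing[2]], lens["int"], o, lens[o])
    m <- phylo_model(ape::read.tree(text = txt), exch, emp, "CV1",
                     rates = discrete_gamma(1))
    lik[paste(sort(ing), collapse = "|")] <- exp(log_likelihood(a, m))
  }
  post <- lik / sum(lik)
  keys <- vapply(trace_samples(trc), function(s)
    paste(sort(s$tree$tip.label[
      ndch:::phangorn_free_descendants(s$tree, 5L)]), collapse = "|"), "")
  freq <- table(factor(keys, levels = names(post))) / length(keys)
  expect_lt(max(abs(post - as.numeric(freq))), 0.04)
})

test_that("SPR leaves the uniform topology distribution invariant", {
  a <- alignment(stats::setNames(rep(strrep("A", 30), 4), c("A", "B", "C", "D")),
                 "nucleotide")
  tr0 <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  cfg <- mcmc_config(n_generations = 24000, sample_interval = 4,
                     n_chains = 1, burnin_fraction = 0.1,
                     proposal_weights = c(blen = 1, alpha = 0, comp = 0,
                                          exch = 0, nni = 0, spr = 1,
                                          reassign = 0),
                     seed = 3)
  trc <- run_mcmc(a, "CV1", cfg, start_tree = tr0)
  sup <- split_supports(trc, rooted = FALSE)
  expect_length(sup, 3)            # all three unrooted splits visited
  expect_lt(max(abs(sup - 1 / 3)), 0.06)
})

test_that("consensus supports equal hand-tallied split frequencies", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  trc <- toy_trace(c(rep(list(t1), 7), rep(list(t2), 3)))
  cons <- consensus_tree(trc)
  expect_equal(unname(cons$supports[["A|B"]]), 0.7)
  expect_equal(unname(cons$supports[["C|D"]]), 0.7)
  expect_equal(unname(cons$supports[["A|C"]]), 0.3)
  expect_equal(unname(cons$supports[["A|B|C|D"]]), 1)
  expect_equal(cons$mean_tree_length, 6)
  # majority-rule tree contains the 70% clade, not the 30% one
  keys <- ndch:::clade_keys(cons$tree)
  expect_true("A|B" %in% keys)
  expect_false("A|C" %in% keys)
  # all samples identical: every support is 1
  trc1 <- toy_trace(rep(list(t1), 5))
  expect_true(all(consensus_tree(trc1)$supports == 1))
  # two samples differing by one NNI: conflicting splits at 0.5 drop out
  trc2 <- toy_trace(list(t1, t2))
  half <- consensus_tree(trc2)
  expect_equal(unname(half$supports[["A|B"]]), 0.5)
  expect_false("A|B" %in% ndch:::clade_keys(half$tree))
})

test_that("asdoss follows the sample-sd formula and its edge cases", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  r1 <- toy_trace(c(rep(list(t1), 9), list(t2)))   # A|B support 0.9
  r2 <- toy_trace(rep(list(t1), 10))               # A|B support 1.0
  expect_equal(asdoss(list(r1, r1)), 0)
  # splits: A|B {0.9, 1}, C|D {0.9, 1}, A|C {0.1, 0}, B|D {0.1, 0}, root {1,1}
  sd1 <- stats::sd(c(0.9, 1))
  sd2 <- stats::sd(c(0.1, 0))
  expect_equal(asdoss(list(r1, r2)), (2 * sd1 + 2 * sd2 + 0) / 5,
               tolerance = 1e-12)
  expect_equal(round(sd1, 4), 0.0707)
  expect_error(asdoss(list(r1)), "at least 2")
})

test_that("composition chi-squared matches hand evaluation", {
  expect_equal(composition_chi2(
    alignment(c(t1 = "AAAA", t2 = "CCCC"), "nucleotide")), 8)
  expect_equal(composition_chi2(
    alignment(c(t1 = "ACGT", t2 = "ACGT", t3 = "TGCA"), "nucleotide")), 0)
  # ambiguity and gaps are excluded from the counts
  expect_equal(composition_chi2(
    alignment(c(t1 = "AAAN-", t2 = "CCCC?"), "nucleotide")),
    composition_chi2(alignment(c(t1 = "AAA?", t2 = "CCCC"), "nucleotide")))
})

test_that("posterior predictive machinery respects its contracts", {
  a <- random_alignment(4, 60, seed = 8)
  trc <- run_mcmc(a, "CV1",
                  mcmc_config(n_generations = 300, sample_interval = 10,
                              n_chains = 1, seed = 7))
  expect_error(posterior_predictive_chi2(trc, a, n_reps = 10000), "exceeds")
  one <- posterior_predictive_chi2(trc, a, n_reps = 1, seed = 4)
  expect_length(one$simulated_statistics, 1)
  expect_true(one$tail_p %in% c(0, 1))
  pp <- posterior_predictive_chi2(trc, a, n_reps = 5, seed = 4)
  expect_lte(pp$sample_min, pp$sample_max)
  expect_gte(pp$tail_p, 0)
  expect_lte(pp$tail_p, 1)
})

test_that("harmonic-mean log marginal likelihood is computed stably", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  trc <- toy_trace(rep(list(t1), 4))
  for (i in seq_along(trc$samples)) trc$samples[[i]]$logL <- -5
  expect_equal(harmonic_mean_logml(trc)$value, -5)
  lls <- c(-10, -12)
  for (i in 1:2) trc$samples[[i]]$logL <- lls[i]
  trc$samples <- trc$samples[1:2]
  expect_equal(harmonic_mean_logml(trc)$value,
               -log(0.5 * (exp(10) + exp(12))), tolerance = 1e-10)
  # bounded above by the max sampled log-likelihood
  expect_lte(harmonic_mean_logml(trc)$value, max(lls))
  # stable far outside double range
  for (i in 1:2) trc$samples[[i]]$logL <- c(-100000, -100010)[i]
  expect_true(is.finite(harmonic_mean_logml(trc)$value))
})

test_that("trace files serialize parameters and trees", {
  a <- random_alignment(4, 40, seed = 9)
  trc <- run_mcmc(a, "CV1",
                  mcmc_config(n_generations = 100, sample_interval = 20,
                              n_chains = 1, seed = 3))
  stem <- withr::local_tempfile()
  write_trace(trc, stem)
  par <- utils::read.delim(paste0(stem, ".params.tsv"))
  expect_equal(nrow(par), 5)
  expect_true(all(c("generation", "logL", "alpha", "tree_length") %in%
                  names(par)))
  nwk <- ape::read.tree(paste0(stem, ".trees.nwk"))
  expect_equal(length(nwk), 5)
})
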