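test_that("build_q produces normalized reversible rate matrices", {
  q <- build_q(jc_exch(), rep(0.25, 4))
  expect_equal(unname(q[1, 2]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(diag(q)), rep(-1, 4), tolerance = 1e-12)
  set.seed(3)
  pi <- random_simplex(4)
  q2 <- build_q(random_exch(4), pi)
  expect_equal(max(abs(pi %*% q2)), 0, tolerance = 1e-12)  # stationarity
  expect_equal(-sum(pi * diag(q2)), 1, tolerance = 1e-12)  # unit rate
  expect_error(build_q(jc_exch(), c(0.5, 0.5, 0, 0)), "zero")
})

test_that("transition matrices hit the JC closed form and its limits", {
  q <- build_q(jc_exch(), rep(0.25, 4))
  expect_equal(transition_matrix(q, 0), diag(4))
  p <- transition_matrix(q, 0.1)
  expect_equal(unname(p[1, 1]), 1 / 4 + 3 / 4 * exp(-0.4 / 3),
               tolerance = 1e-12)
  expect_equal(max(abs(transition_matrix(q, 400) - 0.25)), 0,
               tolerance = 1e-9)
  expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-12)
  expect_error(transition_matrix(q, -1), "negative")
})

test_that("transition matrices match an independent matrix exponential", {
  set.seed(12)
  for (rep in 1:5) {
    pi <- random_simplex(4)
    q <- build_q(random_exch(4), pi)
    t <- runif(1, 0.01, 3)
    expect_equal(transition_matrix(q, t, pi = pi),
                 as.matrix(Matrix::expm(q * t)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("discrete gamma categories average to one and order correctly", {
  for (shape in c(0.2, 0.5, 1, 5)) {
    r <- discrete_gamma(shape)
    expect_equal(mean(r$rates), 1, tolerance = 1e-12)
    expect_equal(r$rates, sort(r$rates))
    expect_length(r$rates, 4)
  }
  # single category degenerates to rate 1
  expect_equal(discrete_gamma(0.7, n_categories = 1)$rates, 1)
})

test_that("phylo_model enforces its composition-mode contracts", {
  tr <- tree4()
  expect_error(phylo_model(tr, jc_exch(), matrix(0.25, 2, 4), "CV1"),
               "exactly one")
  expect_error(phylo_model(tr, jc_exch(), matrix(0.25, 3, 4), "NDCH2"),
               "one composition vector per node")
  expect_error(phylo_model(tr, jc_exch(), c(0.3, 0.3, 0.4), "CV1"),
               "dimension")
  expect_error(phylo_model(tr, matrix(1:16, 4), rep(0.25, 4), "CV1"),
               "symmetric")
  m <- phylo_model(tr, jc_exch(), rep(0.25, 4), "CV1")
  expect_equal(length(unique(m$assignment)), 1)
  m2 <- phylo_model(tr, jc_exch(), matrix(1 / 4, 7, 4), "NDCH2")
  expect_equal(m2$assignment, 1:7)
})

test_that("two-taxon single-site likelihood equals the JC closed form", {
  tr <- ape::read.tree(text = "(t1:0.05,t2:0.05);")
  m <- phylo_model(tr, jc_exch(), rep(0.25, 4), "CV1",
                   rates = discrete_gamma(1, n_categories = 1))
  ll <- log_likelihood(alignment(c(t1 = "A", t2 = "A"), "nucleotide"), m)
  expect_equal(ll, log(0.25 * (0.25 + 0.75 * exp(-0.4 / 3))),
               tolerance = 1e-8)
})

test_that("pruning equals brute-force enumeration on a 4-taxon NDCH2 model", {
  set.seed(42)
  tr <- tree4()
  exch <- random_exch(4)
  comp <- t(apply(matrix(rgamma(7 * 4, 2), 7), 1, function(x) x / sum(x)))
  mat <- matrix(sample(c("A", "C", "G", "T", "R", "-"), 80, TRUE,
                       prob = c(.24, .24, .24, .24, .02, .02)),
                4, 20, dimnames = list(c("A", "B", "C", "D"), NULL))
  a <- alignment(mat, "nucleotide")
  rates <- discrete_gamma(0.6, 4)
  mod <- phylo_model(tr, exch, comp, "NDCH2", rates = rates)
  expect_equal(log_likelihood(a, mod),
               brute_force_loglik(a, tr, exch, comp, rates$rates),
               tolerance = 1e-8)
})

test_that("CV1 equals an independent stationary GTR+G4 implementation", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  tr <- ape::rtree(6, rooted = TRUE)
  tr$tip.label <- paste0("t", 1:6)
  bf <- random_simplex(4, 3)
  rates6 <- runif(6, 0.5, 3)
  exch <- matrix(0, 4, 4)
  exch[lower.tri(exch)] <- rates6
  exch <- exch + t(exch)
  spec <- simulation_spec(tr, matrix(bf, 11, 4, byrow = TRUE), exch,
                          discrete_gamma(0.7), n_sites = 300, seed = 5)
  a <- simulate_alignment(spec)
  mod <- phylo_model(tr, exch, bf, "CV1", rates = discrete_gamma(0.7))
  fit <- phangorn::pml(tr, phangorn::phyDat(a$matrix, type = "DNA"),
                       bf = bf, Q = rates6, k = 4, shape = 0.7)
  expect_equal(log_likelihood(a, mod), fit$logLik, tolerance = 1e-6)
})

test_that("CV1 likelihood is invariant to re-rooting; NDCH2 is not", {
  set.seed(11)
  tr <- tree4()
  exch <- random_exch(4)
  bf <- c(.1, .2, .3, .4)
  spec <- simulation_spec(tr, matrix(bf, 7, 4, byrow = TRUE), exch,
                          discrete_gamma(1, 1), 60, seed = 2)
  a <- simulate_alignment(spec)
  tr2 <- ape::root(ape::unroot(tr), outgroup = "C", resolve.root = TRUE)
  tr2$edge.length[is.na(tr2$edge.length)] <- 0
  m1 <- phylo_model(tr, exch, bf, "CV1", rates = discrete_gamma(0.8))
  m2 <- phylo_model(tr2, exch, bf, "CV1", rates = discrete_gamma(0.8))
  expect_equal(log_likelihood(a, m1), log_likelihood(a, m2),
               tolerance = 1e-8)
  nc <- t(apply(matrix(rgamma(28, 2), 7), 1, function(x) x / sum(x)))
  m3 <- phylo_model(tr, exch, nc, "NDCH2", rates = discrete_gamma(0.8))
  m4 <- phylo_model(tr2, exch, nc, "NDCH2", rates = discrete_gamma(0.8))
  expect_gt(abs(log_likelihood(a, m3) - log_likelihood(a, m4)), 0.1)
})

test_that("likelihood decreases when a branch length leaves its optimum", {
  set.seed(19)
  tr <- tree4()
  spec <- simulation_spec(tr, matrix(0.25, 7, 4, byrow = TRUE), jc_exch(),
                          discrete_gamma(1, 1), 400, seed = 6)
  a <- simulate_alignment(spec)
  model_at <- function(x) {
    t2 <- tr
    t2$edge.length[1] <- x
    phylo_model(t2, jc_exch(), rep(0.25, 4), "CV1",
                rates = discrete_gamma(1, 1))
  }
  grid <- seq(0.01, 1.2, length.out = 25)
  ll <- vapply(grid, function(x) log_likelihood(a, model_at(x)), 1)
  opt <- grid[which.max(ll)]
  # unimodal around the optimum: monotone on each side
  expect_true(all(diff(ll[grid <= opt]) >= 0))
  expect_true(all(diff(ll[grid >= opt]) <= 0))
})

test_that("likelihood is independent of site order", {
  set.seed(23)
  a <- random_alignment(4, 50, amb_rate = 0.1)
  rownames(a$matrix) <- c("A", "B", "C", "D")
  a <- alignment(a$matrix, "nucleotide")
  m <- phylo_model(tree4(), random_exch(4), random_simplex(4), "CV1",
                   rates = discrete_gamma(0.5))
  perm <- sample(n_sites(a))
  b <- alignment(a$matrix[, perm, drop = FALSE], "nucleotide")
  expect_equal(log_likelihood(a, m), log_likelihood(b, m), tolerance = 1e-10)
})

test_that("PAML-format empirical matrix files round-trip", {
  set.seed(29)
  lower <- round(runif(190, 0.01, 5), 6)
  freq <- round(random_simplex(20, 5), 6)
  freq[20] <- 1 - sum(freq[1:19])
  f <- withr::local_tempfile()
  lines <- character(0)
  k <- 0
  for (i in 2:20) {
    lines <- c(lines, paste(lower[(k + 1):(k + i - 1)], collapse = " "))
    k <- k + i - 1
  }
  writeLines(c(lines, "", paste(freq, collapse = " ")), f)
  got <- read_paml_matrix(f)
  expect_equal(got$exch[2, 1], lower[1])
  expect_equal(got$exch, t(got$exch))
  expect_equal(unname(got$freq), freq, tolerance = 1e-9)
  expect_equal(sum(got$freq), 1, tolerance = 1e-9)
  # usable end-to-end in a 20-state likelihood
  tr <- tree4()
  m <- phylo_model(tr, got$exch, got$freq, "CV1",
                   rates = discrete_gamma(1, 1))
  aa <- random_alignment(4, 10, kind = "amino-acid", seed = 1)
  rownames(aa$matrix) <- c("A", "B", "C", "D")
  aa <- alignment(aa$matrix, "amino-acid")
  expect_true(is.finite(log_likelihood(aa, m)))
})
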