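---
title: "Modelling among-lineage compositional heterogeneity with ndch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling among-lineage compositional heterogeneity with ndch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Standard phylogenetic substitution models assume a *stationary* process: one
state-frequency vector shared by every lineage for all time.  Deeply divergent
data — plastid protein-coding genes across green algae and land plants are the
motivating case — routinely violate this assumption: lineages differ in GC
content by ten percentage points or more, and synonymous codon positions are
substitutionally saturated.  Both effects create non-historical signal that a
stationary model converts into confident, wrong topology.

`ndch` packages the three responses to this problem as reusable, tested
components:

1. **Diagnosis.** Matched-pairs tests on the pairwise divergence matrix:
   Bowker's test of symmetry (omnibus), Stuart's test of marginal homogeneity
   (stationarity), and Ababneh's internal test (their difference, signalling
   rate-homogeneity violation).
2. **Data surgery.** Codon-degenerate recoding, which replaces each codon by
   an IUPAC-ambiguity triplet covering its synonymous family, so that only
   non-synonymous differences remain.
3. **Modelling.** Tree-heterogeneous composition models: CV1 (one composition
   vector — the stationary special case), NDCH (K shared vectors assigned to
   nodes), and NDCH2 (one vector per node), fitted by Bayesian MCMC with
   posterior-predictive checking of compositional fit.

A synthetic-data generator with the statistical structure of a 30-taxon
chloroplast supermatrix ties the pieces together and underlies the test
suite.

## The model

On a rooted tree, the branch above node $v$ evolves under the reversible rate
matrix $Q^{(v)}_{ab} = R_{ab}\,\pi^{(v)}_b$ ($a \ne b$), where $R$ is a
symmetric exchangeability matrix (GTR for nucleotides; empirical matrices
such as gcpREV, loaded from PAML-format files, for amino acids) and
$\pi^{(v)}$ is the composition vector of the *child* node $v$.  Each $Q^{(v)}$
is rescaled so that $-\sum_a \pi^{(v)}_a Q^{(v)}_{aa} = 1$, keeping branch
lengths in expected substitutions per site under every composition regime.
The root's own vector is the prior over states at the root.  Site-rate
variation is the usual discrete gamma with 4 equal-probability categories
(category rate = bin mean, so the rates average exactly 1).

With all node vectors equal this collapses to stationary GTR+$\Gamma_4$ (the
test suite verifies equality against an independent implementation); with
unequal vectors the process is non-reversible in the aggregate and the root
placement becomes a real modelling choice.  `ndch` therefore treats every
tree as rooted, carries one composition vector per node including the root,
and leaves rooting to the caller (e.g. by outgroup).  This is stated
prominently because NDCH2 results depend on it.

## Priors, proposals, and tuning parameters

The MCMC samples topology, branch lengths, composition vector(s),
exchangeabilities and the gamma shape $\alpha$.  Defaults (all logged in the
run configuration object):

* flat Dirichlet(1, ..., 1) priors on compositions and exchangeabilities;
* exponential prior with mean 0.1 substitutions/site on branch lengths;
* uniform prior on $\log\alpha \in [-3, 3]$;
* proposals: branch-length multiplier, reflected random walk on
  $\log\alpha$, centred Dirichlet perturbations of a single composition
  vector (concentration 300 by default — raise it for smaller steps; NDCH2
  mixing is the known bottleneck and the reason this is tunable), NNI and
  SPR topology moves that keep node identities stable so per-node vectors
  travel with their nodes, and node reassignment for NDCH;
* optional Metropolis coupling: 1 cold + 3 heated chains by default, chain
  $i$ at temperature $1/(1 + 0.1\,i)$, swaps attempted every 10 generations;
* burnin fraction 0.25 of recorded samples.

Convergence is assessed, as is standard for split-based diagnostics, with
the average standard deviation of split support (asdoss) between independent
runs (inclusion threshold 0.1, sample sd with the $n-1$ denominator).  No
fixed asdoss threshold is imposed; the value is reported and the decision
left to the user.

Model adequacy uses posterior-predictive simulation of the composition
chi-squared statistic $X^2 = \sum_t \sum_s (c_{ts} - E_{ts})^2 / E_{ts}$
(per-taxon canonical-state counts against expectations under the pooled
composition).  Replicate alignments are simulated gap-free at the original
dimensions from evenly thinned posterior samples; the tail probability is
one-sided (fraction of simulated statistics at least as large as the
observed), so an observed statistic above the whole simulated distribution
yields a small p.  Masking the original gap pattern onto replicates is
deliberately not done by default; it is the simpler choice and is stated
here so results are interpreted accordingly.  The harmonic-mean log marginal
likelihood is reported for run comparison only and is labelled the crude
estimator it is.

## The synthetic-data generator

`study_like_spec()` emulates the structure of the motivating 30-taxon
chloroplast supermatrix: a random rooted tree whose node compositions follow
a GC random walk affinely rescaled so leaf GC targets span 0.33–0.51 (the
published ingroup spread), gamma shape 0.4, a transition-biased GTR
skeleton, a uniform missing-data mask of 3% (the ingroup's per-taxon missing
fractions average 4.38%, median 2.36%), and a default root-to-tip path of
3.5 expected substitutions/site.  The long paths are deliberate: plastid
coding data are strongly saturated (the motivating data's raw-nucleotide
tree length is an order of magnitude above its non-synonymous tree length),
and realized leaf GC only approaches the node targets when lineages have
time to equilibrate.  With the default scale the realized leaf GC spread is
about 0.10 — matching the published spread — while matched-pairs rejection
fractions sit far above the 5% nominal level and grow monotonically with
the width of the GC target range.

`simulate_coding()` adds the synonymous layer without a full codon model:
an amino-acid alignment is evolved on the tree, then each leaf's residues
are back-translated by sampling codons from leaf-specific codon-usage
vectors that drift along branches (Dirichlet perturbation per unit branch
length).  Each amino acid is encoded from exactly one degeneracy group
(serine from its TCN family only), which makes "degenerate recoding removes
exactly the synonymous layer" a provable, tested property rather than an
approximation, and guarantees stop-free, in-frame output.  What this
generator does **not** emulate: indels and structured (gene-wise)
missingness, selection on codon usage correlated with topology, among-site
compositional heterogeneity, and among-lineage rate variation.  Passing
tests on this generator therefore demonstrate correctness of the machinery
under lineage-compositional violation only, not robustness to every failure
mode of real plastid data.

## Numerical choices

* Transition probabilities come from the symmetrized eigendecomposition of
  each reversible $Q$ (verified against an independent dense matrix
  exponential to ~1e-15); rows are clipped at zero and renormalized to guard
  rounding.
* The pruning likelihood compresses site patterns, rescales partials per
  node, and averages gamma categories in log space; the value is exact and
  independent of site order.
* Stuart's statistic uses an SVD generalized inverse with singular values
  below 1e-10 (relative) treated as zero and df = rank, which keeps sparse
  amino-acid divergence matrices well-defined.
* Bowker's df counts only state pairs with $n_{ab} + n_{ba} > 0$; the fixed
  $m(m-1)/2$ convention is available via `fixed_df = TRUE`.  Sites with any
  ambiguity code in either sequence are excluded from divergence matrices
  (fractional allocation would break integer count semantics).
* Composition proposals that would leave the open simplex (any entry below
  1e-8) are rejected; the sampler thus targets the posterior restricted to
  the simplex interior, a region of negligible prior mass under the flat
  Dirichlet.
* Codons containing gap or missing characters pass through degenerate
  recoding unchanged (part-recoding would invent frame content); input
  IUPAC ambiguities are recoded to the positionwise union cover of their
  compatible codons' degenerate triplets, which makes recoding idempotent.
* Internally all site coordinates are 0-based half-open; the NEXUS
  reader/writer converts from/to 1-based inclusive `charset` ranges at the
  file boundary.

## Problem sizes used in the tests

The published analyses that motivate this package ran for months per chain;
the test suite and the acceptance script instead exercise every code path on
scaled-down problems chosen to keep the full suite in the minutes range:
4–8 taxa and 600–1200 sites for chain-based checks (topology recovery,
NDCH2 parameter recovery with long terminal branches so leaf compositions
are identifiable, posterior-predictive power and calibration), 30 taxa and
200–3000 sites for the diagnostic and generator checks, and enumeration
oracles (3-taxon topology posteriors, 4-taxon internal-state sums) wherever
an exact reference exists.

## Worked example

```{r example, eval = FALSE}
library(ndch)

## generate a study-like data set and diagnose it
sp <- study_like_spec(n_taxa = 12, seed = 1, n_sites = 1500)
aln <- simulate_alignment(sp)
all_pairs_tests(aln)$summary

## fit the homogeneous and per-node models, check compositional fit
cfg <- mcmc_config(n_generations = 3000, sample_interval = 10,
                   n_chains = 1, seed = 1)
fit_cv1 <- run_mcmc(aln, "CV1", cfg)
posterior_predictive_chi2(fit_cv1, aln, n_reps = 50, seed = 2)$tail_p
```

## Known limitations

* NDCH2 mixing degrades with tree size; independent runs on hard data may
  converge to the same clades but different node-composition values, the
  regime the tunable composition-proposal concentration exists for.  asdoss
  across independent runs is the diagnostic to watch.
* The harmonic-mean marginal-likelihood estimator has infinite variance in
  theory; treat it as a coarse run-comparison number.
* SPR moves resample branch lengths only through their merge/split Jacobian;
  very long chains may prefer a dedicated branch-length-aware topology move
  on large trees.
* Likelihoods are pure R (pattern-compressed and vectorized); the package is
  sized for diagnostic work and simulation studies, not for 10^4-site
  production runs with many taxa.
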