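#' Configure an end-to-end compositional-heterogeneity analysis
#'
#' @param input either a named list of alignments (names in
#'   `"nucleotide"`, `"degen"`, `"amino-acid"`) or a [simulation_spec()]
#'   (a coding spec, from which the nucleotide, codon-degenerate and
#'   amino-acid layers are generated).
#' @param layers which data layers to analyse (subset of
#'   `c("nucleotide", "degen", "amino-acid")`).
#' @param outgroup taxon used to root reported consensus trees (optional;
#'   required thinking for tree-heterogeneous likelihoods is carried by the
#'   MCMC's rooted trees themselves).
#' @param mcmc an [mcmc_config()] applied to every layer.
#' @param comp_modes composition modes fitted per layer (default CV1 and
#'   NDCH2).
#' @param n_runs independent MCMC runs per layer/model (>= 2 enables asdoss).
#' @param n_ppred_reps posterior predictive replicates.
#' @param out_dir optional directory for trace/report files.
#' @param seed master seed; run r of a layer uses `seed + r`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, layers = c("nucleotide", "degen",
                                              "amino-acid"),
                            outgroup = NULL, mcmc = mcmc_config(),
                            comp_modes = c("CV1", "NDCH2"),
                            n_runs = 2, n_ppred_reps = 50,
                            out_dir = NULL, seed = 1L) {
  layers <- match.arg(layers, several.ok = TRUE)
  stopifnot(n_runs >= 1)
  structure(list(input = input, layers = layers, outgroup = outgroup,
                 mcmc = mcmc, comp_modes = comp_modes, n_runs = n_runs,
                 n_ppred_reps = n_ppred_reps, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full compositional-heterogeneity workflow
#'
#' Per enabled layer: taxon composition/missing-data summary, matched-pairs
#' homogeneity tests, then for each composition mode `n_runs` independent
#' MCMC runs, a pooled majority-rule consensus with split supports, asdoss
#' across runs (when `n_runs >= 2`), the posterior predictive chi-squared
#' composition test, and the harmonic-mean log marginal likelihood.  Nodes
#' with posterior support below 0.95 are flagged as weakly supported.
#'
#' @param cfg a [pipeline_config()].
#' @return Object of class `pipeline_report`: nested list, one entry per
#'   layer, with `taxon_summary`, `matched_pairs`, and per-mode `runs`
#'   (traces), `consensus`, `low_support_nodes`, `asdoss`, `ppred`, `logml`.
#'   Written as JSON (plus traces) under `out_dir` when given.
#' @export
run_pipeline <- function(cfg) {
  layers <- pipeline_layers(cfg)
  report <- list(seed = cfg$seed, layers = list())
  for (ly in names(layers)) {
    a <- layers[[ly]]
    entry <- list()
    entry$taxon_summary <- summarize_taxa(a, group = a$taxa)
    entry$matched_pairs <- all_pairs_tests(a)
    entry$modes <- list()
    for (mode in cfg$comp_modes) {
      runs <- lapply(seq_len(cfg$n_runs), function(r) {
        rc <- cfg$mcmc
        rc$seed <- cfg$seed + 1000L * match(ly, names(layers)) +
          100L * match(mode, cfg$comp_modes) + r
        run_mcmc(a, comp_mode = mode, cfg = rc)
      })
      cons <- consensus_tree(runs)
      low <- names(cons$supports)[cons$supports < 0.95]
      asd <- if (cfg$n_runs >= 2) asdoss(runs) else {
        warning("asdoss needs >= 2 independent runs; skipped for ", ly,
                "/", mode)
        NA_real_
      }
      pp <- posterior_predictive_chi2(runs[[1]], a,
                                      n_reps = min(cfg$n_ppred_reps,
                                                   length(trace_samples(runs[[1]]))),
                                      seed = cfg$seed)
      entry$modes[[mode]] <- list(runs = runs, consensus = cons,
                                  low_support_nodes = low, asdoss = asd,
                                  ppred = pp,
                                  logml = harmonic_mean_logml(runs[[1]]))
      if (!is.null(cfg$out_dir)) {
        dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
        for (r in seq_along(runs))
          write_trace(runs[[r]], file.path(cfg$out_dir,
                                           paste0(ly, "_", mode, "_run", r)))
        ape::write.tree(cons$tree,
                        file.path(cfg$out_dir,
                                  paste0(ly, "_", mode, "_consensus.nwk")))
      }
    }
    report$layers[[ly]] <- entry
  }
  class(report) <- "pipeline_report"
  if (!is.null(cfg$out_dir))
    jsonlite::write_json(report_json(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  report
}

# Materialize the requested data layers from alignments or a coding spec.
pipeline_layers <- function(cfg) {
  input <- cfg$input
  if (inherits(input, "simulation_spec")) {
    sim <- simulate_coding(input)
    all <- list("nucleotide" = sim$nucleotide,
                "degen" = degen_recode(sim$nucleotide)$alignment,
                "amino-acid" = sim$amino_acid)
  } else {
    all <- input
    if (!is.null(all[["nucleotide"]]) && is.null(all[["degen"]]) &&
        "degen" %in% cfg$layers)
      all[["degen"]] <- degen_recode(all[["nucleotide"]])$alignment
    if (!is.null(all[["nucleotide"]]) && is.null(all[["amino-acid"]]) &&
        "amino-acid" %in% cfg$layers)
      all[["amino-acid"]] <- translate_alignment(all[["nucleotide"]])
  }
  out <- all[cfg$layers]
  if (any(vapply(out, is.null, TRUE)))
    stop("requested layer(s) unavailable: ",
         paste(cfg$layers[vapply(out, is.null, TRUE)], collapse = ", "))
  out
}

# JSON-friendly digest of a pipeline report (drops bulky trace objects).
report_json <- function(report) {
  lapply(report$layers, function(entry) {
    list(
      taxon_summary = entry$taxon_summary$table,
      matched_pairs_summary = entry$matched_pairs$summary,
      modes = lapply(entry$modes, function(md) list(
        consensus_newick = ape::write.tree(md$consensus$tree),
        mean_tree_length = md$consensus$mean_tree_length,
        low_support_nodes = md$low_support_nodes,
        asdoss = md$asdoss,
        ppred = md$ppred[c("original_statistic", "sample_min", "sample_max",
                           "tail_p")],
        logml = md$logml$value)))
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report over layers:", paste(names(x$layers), collapse = ", "),
      "\n")
  for (ly in names(x$layers)) {
    e <- x$layers[[ly]]
    cat("  ", ly, ": ", sep = "")
    cat(e$matched_pairs$summary$n_rejected[1], "/",
        e$matched_pairs$summary$n_pairs[1],
        " Bowker rejections; modes: ", paste(names(e$modes), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
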