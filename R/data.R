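#' Taxon table of the 30-taxon chloroplast coding dataset
#'
#' Published per-taxon summary of the 30-taxon, 83-gene chloroplast
#' protein-coding supermatrix that motivates this package's diagnostics:
#' taxon name, major lineage (Chlorophyta outgroups vs Streptophyta ingroup),
#' finer classification, GenBank accession, number of sampled genes, percent
#' missing characters, and percent G+C.  The Streptophyta ingroup's missing
#' fractions average 4.38% (median 2.36%), and its GC content spans 33.21% to
#' 50.77% -- the lineage-specific composition spread the synthetic generator
#' [study_like_spec()] emulates.
#'
#' @param streptophyta_only keep only the 26 Streptophyta (ingroup) rows.
#' @return data.frame with columns `taxon`, `lineage`, `classification`,
#'   `accession`, `n_genes`, `pct_missing`, `pct_gc`.
#' @examples
#' mean(plastid30_taxa(streptophyta_only = TRUE)$pct_missing)
#' @export
plastid30_taxa <- function(streptophyta_only = FALSE) {
  path <- system.file("extdata", "plastid30_taxa.tsv", package = "ndch",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (streptophyta_only) tab <- tab[tab$lineage == "Streptophyta", ]
  rownames(tab) <- NULL
  tab
}

#' Group mean and median of percent missing data
#'
#' Convenience wrapper mirroring [summarize_taxa()]'s group statistics for a
#' precomputed per-taxon table such as [plastid30_taxa()].
#'
#' @param pct_missing numeric vector of per-taxon percent-missing values.
#' @return List with `mean` and `median` (both rounded to 2 decimals, the
#'   reporting precision of such tables).
#' @export
missing_data_stats <- function(pct_missing) {
  list(mean = round(mean(pct_missing), 2),
       median = round(stats::median(pct_missing), 2))
}
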