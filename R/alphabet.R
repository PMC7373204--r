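#' State alphabets for molecular sequence data
#'
#' A `state_alphabet` describes the canonical character states of a data type
#' (4 nucleotides or 20 amino acids), the ambiguity codes that denote subsets
#' of those states (IUPAC for nucleotides; X/B/Z/J for amino acids), and the
#' gap/missing codes.  Canonical states map to singleton sets; gap and missing
#' codes map to the full state set for likelihood purposes but are flagged
#' separately for counting statistics such as percent missing data.
#'
#' @param kind `"nucleotide"` or `"amino-acid"`.
#' @return An object of class `state_alphabet` with components `kind`,
#'   `canonical` (ordered state vector), `ambiguity_map` (named list:
#'   code -> character vector of canonical states), `gap_codes`,
#'   `missing_codes`.
#' @examples
#' nt <- state_alphabet("nucleotide")
#' nt$ambiguity_map[["R"]]  # A or G
#' @export
state_alphabet <- function(kind = c("nucleotide", "amino-acid")) {
  kind <- match.arg(kind)
  if (kind == "nucleotide") {
    canonical <- c("A", "C", "G", "T")
    amb <- list(
      R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
      K = c("G", "T"), M = c("A", "C"),
      B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
      V = c("A", "C", "G"), N = canonical
    )
    missing <- c("?", "N")
  } else {
    canonical <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    amb <- list(
      B = c("N", "D"), Z = c("Q", "E"), J = c("I", "L"), X = canonical
    )
    missing <- c("?", "X")
  }
  # canonical codes are also legal "ambiguity" singletons for uniform lookup
  for (s in canonical) amb[[s]] <- s
  structure(list(kind = kind, canonical = canonical, ambiguity_map = amb,
                 gap_codes = "-", missing_codes = missing),
            class = "state_alphabet")
}

#' @export
print.state_alphabet <- function(x, ...) {
  cat("state_alphabet:", x$kind, "(", length(x$canonical), "states )\n")
  invisible(x)
}

legal_codes <- function(alphabet) {
  unique(c(names(alphabet$ambiguity_map), alphabet$gap_codes,
           alphabet$missing_codes))
}

#' Expand a character code to the canonical states it may represent
#'
#' Gap and missing codes expand to the full canonical set (the uninformative
#' indicator used in likelihood computations).
#'
#' @param code single character code.
#' @param alphabet a [state_alphabet()].
#' @return Character vector of canonical states.
#' @export
expand_code <- function(code, alphabet) {
  if (code %in% c(alphabet$gap_codes, alphabet$missing_codes))
    return(alphabet$canonical)
  states <- alphabet$ambiguity_map[[code]]
  if (is.null(states))
    stop("illegal character code '", code, "' for ", alphabet$kind,
         " alphabet", call. = FALSE)
  states
}

# Map a set of canonical nucleotide states back to its IUPAC code.
iupac_code_for <- function(states) {
  key <- paste(sort(unique(states)), collapse = "")
  code <- cached("iupac_rev", .iupac_rev_build)[[key]]
  if (is.null(code)) stop("no IUPAC code for state set {", key, "}")
  code
}

.ndch_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.ndch_cache[[key]])) .ndch_cache[[key]] <- builder()
  .ndch_cache[[key]]
}

.iupac_rev_build <- function() {
  m <- state_alphabet("nucleotide")$ambiguity_map
  rev <- list()
  for (code in names(m)) rev[[paste(sort(m[[code]]), collapse = "")]] <- code
  rev
}

# 0/1 indicator matrix (states x codes) used to translate sequence codes into
# partial-likelihood leaf indicators; gap/missing rows are all-ones.
code_indicator_matrix <- function(alphabet) {
  codes <- legal_codes(alphabet)
  m <- matrix(0, nrow = length(alphabet$canonical), ncol = length(codes),
              dimnames = list(alphabet$canonical, codes))
  for (code in codes) m[expand_code(code, alphabet), code] <- 1
  m
}
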