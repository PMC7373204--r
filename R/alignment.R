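#' Construct an alignment object
#'
#' An `alignment` is a taxa-by-sites character matrix over one
#' [state_alphabet()], together with named character sets (charsets) marking
#' genes and codon positions.  Charsets use 0-based half-open site indices
#' internally; the NEXUS reader/writer converts from/to the 1-based inclusive
#' convention at the file boundary.
#'
#' @param matrix character matrix (rows = taxa, columns = sites); rownames are
#'   taxon names.  A named character vector of equal-length sequence strings is
#'   also accepted.
#' @param kind `"nucleotide"` or `"amino-acid"`.
#' @param charsets named list of integer site-index vectors (0-based).
#' @return Object of class `alignment`: list with `taxa`, `matrix`,
#'   `alphabet`, `charsets`, and `frame_ok` (every gene charset length
#'   divisible by 3; nucleotide data only).
#' @examples
#' a <- alignment(c(t1 = "ACGT", t2 = "ACGA"), kind = "nucleotide")
#' n_sites(a)
#' @export
alignment <- function(matrix, kind = c("nucleotide", "amino-acid"),
                      charsets = list()) {
  kind <- match.arg(kind)
  alphabet <- state_alphabet(kind)
  if (is.character(matrix) && is.null(dim(matrix))) {
    if (is.null(names(matrix))) stop("sequence vector must be named by taxon")
    lens <- nchar(matrix)
    if (length(unique(lens)) > 1)
      stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
    mat <- do.call(rbind, lapply(matrix, function(s)
      strsplit(toupper(s), "")[[1]]))
    if (length(matrix) == 1L) mat <- base::matrix(mat, nrow = 1)
    rownames(mat) <- names(matrix)
    matrix <- mat
  }
  if (is.null(rownames(matrix))) stop("alignment matrix must have taxon rownames")
  taxa <- rownames(matrix)
  if (anyDuplicated(taxa)) stop("duplicate taxon names: ",
                                paste(taxa[duplicated(taxa)], collapse = ", "))
  matrix[] <- toupper(matrix)
  bad <- base::matrix(!(matrix %in% legal_codes(alphabet)), nrow(matrix))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("illegal character '", matrix[idx[1], idx[2]], "' at taxon '",
         taxa[idx[1]], "', site ", idx[2], " (", kind, " alphabet)")
  }
  ns <- ncol(matrix)
  for (nm in names(charsets)) {
    cs <- charsets[[nm]]
    if (any(cs < 0L | cs >= ns))
      stop("charset '", nm, "' has site indices outside [0, ", ns, ")")
    charsets[[nm]] <- as.integer(sort(cs))
  }
  frame_ok <- kind == "nucleotide" &&
    all(vapply(charsets, length, 1L) %% 3 == 0) && ns %% 3 == 0
  structure(list(taxa = taxa, matrix = matrix, alphabet = alphabet,
                 charsets = charsets, frame_ok = frame_ok),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", length(x$taxa), "taxa x", ncol(x$matrix), "sites (",
      x$alphabet$kind, ")\n")
  if (length(x$charsets))
    cat("charsets:", paste(names(x$charsets), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname alignment
#' @param a an `alignment`.
#' @export
n_sites <- function(a) ncol(a$matrix)

#' @rdname alignment
#' @export
n_taxa <- function(a) length(a$taxa)

#' Subset an alignment by taxa and/or sites
#'
#' @param a an [alignment()].
#' @param taxa character vector of taxon names to keep (default all).
#' @param sites 0-based site indices to keep (default all); charsets are
#'   remapped and emptied charsets dropped.
#' @return An `alignment`.
#' @export
subset_alignment <- function(a, taxa = a$taxa, sites = NULL) {
  stopifnot(all(taxa %in% a$taxa))
  if (is.null(sites)) sites <- seq_len(ncol(a$matrix)) - 1L
  keep <- as.integer(sites)
  m <- a$matrix[taxa, keep + 1L, drop = FALSE]
  rownames(m) <- taxa
  remap <- integer(ncol(a$matrix))  # old 0-based -> new 0-based + 1 (0 = drop)
  remap[keep + 1L] <- seq_along(keep)
  cs <- lapply(a$charsets, function(ix) remap[ix + 1L][remap[ix + 1L] > 0] - 1L)
  cs <- cs[vapply(cs, length, 1L) > 0]
  alignment(m, kind = a$alphabet$kind, charsets = cs)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Taxa present in only some input alignments are padded with the missing code
#' over the spans of the genes they lack.  The returned alignment carries one
#' charset per input recording its site span.
#'
#' @param alignments named list of [alignment()] objects sharing one alphabet
#'   kind (names become gene charset names; unnamed inputs are named
#'   `gene1, gene2, ...`).
#' @param fill_missing single character used for absent taxon-by-gene blocks
#'   (default `"?"`).
#' @return An `alignment` whose taxa are the union of input taxa.
#' @export
concatenate <- function(alignments, fill_missing = "?") {
  stopifnot(length(alignments) >= 1)
  kinds <- unique(vapply(alignments, function(a) a$alphabet$kind, ""))
  if (length(kinds) > 1) stop("alphabet mismatch: ", paste(kinds, collapse = " vs "))
  nms <- names(alignments)
  if (is.null(nms)) nms <- rep("", length(alignments))
  nms[nms == ""] <- paste0("gene", which(nms == ""))
  taxa <- unique(unlist(lapply(alignments, function(a) a$taxa)))
  widths <- vapply(alignments, n_sites, 1L)
  total <- sum(widths)
  m <- matrix(fill_missing, nrow = length(taxa), ncol = total,
              dimnames = list(taxa, NULL))
  offs <- cumsum(c(0L, widths[-length(widths)]))
  charsets <- list()
  for (k in seq_along(alignments)) {
    a <- alignments[[k]]
    cols <- offs[k] + seq_len(widths[k])
    m[a$taxa, cols] <- a$matrix
    charsets[[nms[k]]] <- offs[k] + seq_len(widths[k]) - 1L
  }
  alignment(m, kind = kinds, charsets = charsets)
}

#' Per-taxon composition and missing-data summary
#'
#' For each taxon reports the percentage of sites that are gap or missing
#' (gap `-`, `?`, and the fully ambiguous `N`/`X`; partial ambiguities such as
#' R or Y are not counted as missing), the percent G+C among unambiguous
#' A/C/G/T (nucleotide data), and the composition over canonical states among
#' unambiguous sites.
#'
#' @param a an [alignment()].
#' @param group optional character vector of taxon names over which to report
#'   the group mean and median of percent missing.
#' @return A list with `table` (data.frame: taxon, n_sites, pct_missing,
#'   pct_gc, one column per canonical state) and, when `group` is given,
#'   `group_mean_pct_missing` / `group_median_pct_missing`.
#' @examples
#' a <- alignment(c(t1 = "AC-?", t2 = "ACGT"), kind = "nucleotide")
#' summarize_taxa(a)$table
#' @export
summarize_taxa <- function(a, group = NULL) {
  al <- a$alphabet
  miss_codes <- c(al$gap_codes, al$missing_codes)
  rows <- lapply(a$taxa, function(tx) {
    s <- a$matrix[tx, ]
    n <- length(s)
    n_miss <- sum(s %in% miss_codes)
    canon <- s[s %in% al$canonical]
    comp <- if (length(canon)) {
      tabulate(factor(canon, levels = al$canonical),
               nbins = length(al$canonical)) / length(canon)
    } else rep(NA_real_, length(al$canonical))
    pct_gc <- if (al$kind == "nucleotide" && length(canon))
      100 * mean(canon %in% c("G", "C")) else NA_real_
    out <- data.frame(taxon = tx, n_sites = n,
                      pct_missing = 100 * n_miss / n, pct_gc = pct_gc,
                      stringsAsFactors = FALSE)
    comp <- as.list(stats::setNames(comp, al$canonical))
    cbind(out, as.data.frame(comp, check.names = FALSE))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  res <- list(table = tab)
  if (!is.null(group)) {
    stopifnot(all(group %in% a$taxa))
    pm <- tab$pct_missing[match(group, tab$taxon)]
    res$group_mean_pct_missing <- mean(pm)
    res$group_median_pct_missing <- stats::median(pm)
  }
  res
}

#' Translate an in-frame nucleotide alignment to amino acids
#'
#' Codons containing a gap, a missing code, or an ambiguity that does not
#' resolve to a unique amino acid become the missing amino acid `X`; an
#' ambiguity whose compatible codons all encode one amino acid is translated
#' (e.g. `GCN` -> `A`).  Stop codons become `X` (internal coding regions are
#' assumed).
#'
#' @param a nucleotide [alignment()] with `frame_ok` and sites divisible by 3.
#' @return An amino-acid `alignment` with `n_sites(a)/3` columns; gene
#'   charsets are carried over with indices divided by 3.
#' @examples
#' translate_alignment(alignment(c(t = "ATGGCT"), kind = "nucleotide"))
#' @export
translate_alignment <- function(a) {
  if (a$alphabet$kind != "nucleotide") stop("translation needs nucleotide data")
  if (!a$frame_ok || n_sites(a) %% 3 != 0)
    stop("frame violation: sites not divisible by 3 in alignment or a charset")
  nc <- n_sites(a) %/% 3
  out <- matrix("X", nrow = n_taxa(a), ncol = nc, dimnames = list(a$taxa, NULL))
  for (tx in a$taxa) {
    s <- a$matrix[tx, ]
    for (k in seq_len(nc)) {
      out[tx, k] <- translate_codon(s[3 * k - 2], s[3 * k - 1], s[3 * k])
    }
  }
  cs <- lapply(a$charsets, function(ix) unique(ix %/% 3L))
  alignment(out, kind = "amino-acid", charsets = cs)
}

# Translate one codon given as three single-character codes.
translate_codon <- function(c1, c2, c3) {
  nt <- cached("nt_alpha", function() state_alphabet("nucleotide"))
  tab <- codon_table()
  codes <- c(c1, c2, c3)
  if (any(codes %in% c(nt$gap_codes, "?"))) return("X")
  sets <- lapply(codes, expand_code, alphabet = nt)
  if (prod(lengths(sets)) > 64) return("X")
  aas <- unique(unlist(lapply(sets[[1]], function(x1)
    lapply(sets[[2]], function(x2)
      lapply(sets[[3]], function(x3) tab[[paste0(x1, x2, x3)]])))))
  if (length(aas) == 1 && aas != "*") aas else "X"
}

# Standard sense-codon table (identical to plastid/bacterial table 11 on
# sense codons); stops marked "*".  Codon order: positions cycle T,C,A,G with
# the third position fastest.
codon_table <- function() cached("codon_table", function() {
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0("FFLLSSSSYY**CC*W",
                        "LLLLPPPPHHQQRRRR",
                        "IIIMTTTTNNKKSSRR",
                        "VVVVAAAADDEEGGGG"), "")[[1]]
  tab <- list()
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    tab[[paste0(b1, b2, b3)]] <- aa[k]
  }
  tab
})
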