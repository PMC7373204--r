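#' Build a codon-degeneracy recoding table
#'
#' Maps every codon to a degenerate triplet of IUPAC codes covering its
#' synonymous family, so that after recoding only non-synonymous differences
#' remain between sequences.  The degen-1 convention is used: all six leucine
#' codons map to `YTN` and all six arginine codons to `MGN`; serine's two
#' families stay distinct (`TCN`, `AGY`) because they are not connected by
#' single-position synonymous change; stop codons map to `TAR` / `TGA`.
#'
#' @param code_table_id genetic code identifier; `"standard"` (sense codons
#'   identical to plastid/bacterial table 11) is supported.
#' @return Object of class `degen_table`: list with `code_table_id`,
#'   `mapping` (named character vector: codon -> degenerate triplet) and
#'   `family_index` (named integer vector: codon -> degeneracy group id).
#' @examples
#' t <- build_degen_table()
#' t$mapping[["GGA"]]  # "GGN"
#' @export
build_degen_table <- function(code_table_id = "standard") {
  if (!identical(code_table_id, "standard"))
    stop("unknown code table: ", code_table_id)
  codons <- names(codon_table())
  aa <- unlist(codon_table())
  # degeneracy groups: amino acid identity, except serine split into its two
  # families (TCN vs AGY) which are not reachable by synonymous single-position
  # change; leucine and arginine are each one six-codon group (degen-1).
  group <- aa
  ser2 <- codons %in% c("AGT", "AGC")
  group[ser2] <- "S2"
  group[codons == "TGA"] <- "*2"   # stops recode as TAR + TGA, not one group
  fam <- as.integer(factor(group, levels = unique(group)))
  names(fam) <- codons
  mapping <- character(length(codons))
  names(mapping) <- codons
  for (g in unique(fam)) {
    members <- codons[fam == g]
    tri <- vapply(1:3, function(p)
      iupac_code_for(unique(substr(members, p, p))), "")
    mapping[members] <- paste(tri, collapse = "")
  }
  structure(list(code_table_id = code_table_id, mapping = mapping,
                 family_index = fam),
            class = "degen_table")
}

#' @export
print.degen_table <- function(x, ...) {
  cat("degen_table (", x$code_table_id, "):", length(unique(x$family_index)),
      "degeneracy groups over 64 codons\n")
  invisible(x)
}

#' Codon-degenerate recoding of an in-frame nucleotide alignment
#'
#' Every complete unambiguous codon is replaced by its degenerate triplet.
#' Codons containing a gap or missing code (`-`, `?`, `N`) are copied through
#' unchanged.  Codons containing partial IUPAC ambiguities are recoded
#' positionwise to the union cover of the degenerate triplets of all
#' compatible codons, which makes the recoding idempotent.
#'
#' @param a nucleotide [alignment()] with `frame_ok`.
#' @param table a [build_degen_table()] result (built on the fly if omitted).
#' @return A list with `alignment` (the recoded [alignment()], same dimensions
#'   and charsets) and `stats` (codons recoded / passed through / ambiguous,
#'   per the degen module's logging contract).
#' @examples
#' a <- alignment(c(t1 = "ATGTTAGGA"), kind = "nucleotide")
#' degen_recode(a)$alignment$matrix[1, ]
#' @export
degen_recode <- function(a, table = build_degen_table()) {
  if (a$alphabet$kind != "nucleotide") stop("degen recoding needs nucleotide data")
  if (!a$frame_ok || n_sites(a) %% 3 != 0)
    stop("frame violation: sites not divisible by 3 in alignment or a charset")
  nc <- n_sites(a) %/% 3
  out <- a$matrix
  n_recoded <- n_passed <- n_amb <- 0L
  passthrough <- c(a$alphabet$gap_codes, "?", "N")
  for (tx in a$taxa) {
    s <- a$matrix[tx, ]
    for (k in seq_len(nc)) {
      ix <- (3 * k - 2):(3 * k)
      codon <- s[ix]
      if (any(codon %in% passthrough)) {
        n_passed <- n_passed + 1L
        next
      }
      cod <- paste(codon, collapse = "")
      deg <- table$mapping[cod]
      if (is.na(deg)) {  # partial ambiguity: union cover over compatible codons
        n_amb <- n_amb + 1L
        sets <- lapply(codon, expand_code, alphabet = a$alphabet)
        compat <- as.vector(outer(outer(sets[[1]], sets[[2]], paste0),
                                  sets[[3]], paste0))
        covers <- table$mapping[compat]
        deg <- paste(vapply(1:3, function(p) {
          states <- unlist(lapply(substr(covers, p, p), expand_code,
                                  alphabet = a$alphabet))
          iupac_code_for(unique(states))
        }, ""), collapse = "")
      } else n_recoded <- n_recoded + 1L
      out[tx, ix] <- strsplit(deg, "")[[1]]
    }
  }
  list(alignment = alignment(out, kind = "nucleotide", charsets = a$charsets),
       stats = c(codons_recoded = n_recoded, codons_passed_through = n_passed,
                 codons_ambiguous = n_amb))
}
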