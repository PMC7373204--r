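#' Read a sequence alignment
#'
#' Supported formats: FASTA, relaxed sequential PHYLIP, and NEXUS (DATA or
#' CHARACTERS block, plus SETS-block `charset` lines).  NEXUS charsets written
#' as 1-based inclusive ranges (optionally with a `\\3` step) are converted to
#' the package's internal 0-based half-open convention.
#'
#' @param path file path.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @param kind `"nucleotide"` or `"amino-acid"`.
#' @return An [alignment()].
#' @seealso [write_alignment()]
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "nexus"),
                           kind = c("nucleotide", "amino-acid")) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  switch(format,
         fasta = parse_fasta(lines, kind),
         phylip = parse_phylip(lines, kind),
         nexus = parse_nexus(lines, kind))
}

#' Write a sequence alignment
#'
#' @param a an [alignment()].
#' @param path output file path.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.  NEXUS output includes a
#'   SETS block with the alignment's charsets (1-based inclusive ranges).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  seqs <- apply(a$matrix, 1, paste, collapse = "")
  lines <- switch(format,
    fasta = as.vector(rbind(paste0(">", a$taxa), seqs)),
    phylip = c(paste(n_taxa(a), n_sites(a)), paste(a$taxa, seqs)),
    nexus = nexus_lines(a, seqs))
  writeLines(lines, path)
  invisible(path)
}

parse_fasta <- function(lines, kind) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: no '>' header first")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  names(seqs) <- ids
  alignment(seqs, kind = kind)
}

parse_phylip <- function(lines, kind) {
  lines <- lines[nzchar(trimws(lines))]
  hd <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hd) != 2 || anyNA(hd)) stop("bad PHYLIP header: ", lines[1])
  body <- lines[-1]
  if (length(body) != hd[1]) stop("expected ", hd[1], " sequence lines, got ",
                                  length(body))
  seqs <- character(hd[1])
  nms <- character(hd[1])
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    nms[i] <- parts[1]
    seqs[i] <- paste(parts[-1], collapse = "")
  }
  if (any(nchar(seqs) != hd[2]))
    stop("ragged alignment: sequence length differs from header at taxon '",
         nms[which(nchar(seqs) != hd[2])[1]], "'")
  names(seqs) <- nms
  alignment(seqs, kind = kind)
}

parse_nexus <- function(lines, kind) {
  txt <- tolower(paste(lines, collapse = "\n"))
  if (!grepl("#nexus", txt)) stop("not a NEXUS file")
  # matrix block: lines between 'matrix' and ';'
  low <- tolower(trimws(lines))
  mstart <- which(low == "matrix")
  if (!length(mstart)) stop("NEXUS: no matrix found")
  mend <- which(grepl("^;", trimws(lines)) & seq_along(lines) > mstart[1])[1]
  body <- trimws(lines[(mstart[1] + 1):(mend - 1)])
  body <- body[nzchar(body)]
  seqs <- list()
  for (ln in body) {
    ln <- sub(";\\s*$", "", ln)
    parts <- strsplit(ln, "\\s+")[[1]]
    nm <- gsub("^'|'$", "", parts[1])
    seq <- paste(parts[-1], collapse = "")
    seqs[[nm]] <- paste0(if (is.null(seqs[[nm]])) "" else seqs[[nm]], seq)
  }
  a <- alignment(unlist(seqs), kind = kind)
  # charset lines anywhere (SETS or assumptions block)
  cs_lines <- lines[grepl("^\\s*charset\\s", lines, ignore.case = TRUE)]
  charsets <- list()
  for (ln in cs_lines) {
    ln <- sub(";\\s*$", "", trimws(ln))
    eq <- regmatches(ln, regexec("charset\\s+(\\S+)\\s*=\\s*(.+)$", ln,
                                 ignore.case = TRUE))[[1]]
    if (length(eq) != 3) stop("unparseable charset line: ", ln)
    charsets[[eq[2]]] <- parse_nexus_sites(eq[3], n_sites(a))
  }
  a$charsets <- charsets
  a$frame_ok <- a$alphabet$kind == "nucleotide" &&
    all(vapply(charsets, length, 1L) %% 3 == 0) && n_sites(a) %% 3 == 0
  a
}

# "1-6 9 12-20\3" (1-based inclusive, optional step) -> 0-based indices
parse_nexus_sites <- function(txt, ns) {
  out <- integer(0)
  for (tok in strsplit(trimws(txt), "\\s+")[[1]]) {
    step <- 1L
    if (grepl("\\\\", tok)) {
      bits <- strsplit(tok, "\\\\")[[1]]
      tok <- bits[1]
      step <- as.integer(bits[2])
    }
    if (grepl("-", tok)) {
      r <- strsplit(tok, "-")[[1]]
      hi <- if (r[2] == ".") ns else as.integer(r[2])
      out <- c(out, seq(as.integer(r[1]), hi, by = step))
    } else out <- c(out, as.integer(tok))
  }
  if (any(out < 1L | out > ns)) stop("charset sites outside [1, ", ns, "]")
  sort(unique(out)) - 1L
}

nexus_lines <- function(a, seqs) {
  datatype <- if (a$alphabet$kind == "nucleotide") "dna" else "protein"
  out <- c("#NEXUS", "",
           "begin data;",
           paste0("  dimensions ntax=", n_taxa(a), " nchar=", n_sites(a), ";"),
           paste0("  format datatype=", datatype,
                  " gap=- missing=? interleave=no;"),
           "  matrix",
           paste0("    ", format(a$taxa, width = max(nchar(a$taxa))), "  ", seqs),
           "  ;", "end;")
  if (length(a$charsets)) {
    cs <- vapply(names(a$charsets), function(nm)
      paste0("  charset ", nm, " = ",
             ranges_1based(a$charsets[[nm]]), ";"), "")
    out <- c(out, "", "begin sets;", cs, "end;")
  }
  out
}

# 0-based indices -> compact 1-based inclusive range text
ranges_1based <- function(ix) {
  ix <- sort(ix) + 1L
  breaks <- c(0, which(diff(ix) != 1), length(ix))
  parts <- vapply(seq_len(length(breaks) - 1), function(k) {
    lo <- ix[breaks[k] + 1]
    hi <- ix[breaks[k + 1]]
    if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  }, "")
  paste(parts, collapse = " ")
}
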