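#' Read / write FASTA sequence files
#'
#' Uses Biostrings when installed, otherwise a minimal plain-text parser.
#' Comment lines starting with `#` are tolerated.
#'
#' @param path File path.
#' @param sequences Named character vector of sequences (for writing).
#' @return `read_fasta`: a named character vector.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(toupper(out))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k)
    paste(lines[seqed(starts[k] - 1L, ends[k])], collapse = ""), character(1))
  names(seqs) <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  toupper(gsub("\\s", "", seqs))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[k]), con)
    s <- sequences[[k]]
    writeLines(substring(s, seq(1L, nchar(s), 70L),
                         pmin(seq(1L, nchar(s), 70L) + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' Read / write Stockholm alignments with a consensus structure
#'
#' Minimal single-block Stockholm 1.0 support sufficient for
#' structure-annotated RNA alignments: sequence rows plus the
#' `#=GC SS_cons` consensus-structure line (WUSS brackets are collapsed to
#' plain dot-bracket on reading). Multi-block (interleaved) files are
#' concatenated by row name.
#'
#' @param path File path.
#' @param alignment A list with `sequences` (named character vector of
#'   equal-length gapped rows) and optional `ss_cons` (dot-bracket string of
#'   the same length).
#' @return `read_stockholm`: a list with `sequences` and `ss_cons`
#'   (`NULL` when absent).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1L]))
    stop("not a Stockholm file: ", path)
  seqs <- list(); ss <- ""
  for (l in lines[-1L]) {
    if (grepl("^//", l) || !nzchar(trimws(l))) next
    if (grepl("^#=GC\\s+SS_cons\\s", l)) {
      ss <- paste0(ss, sub("^#=GC\\s+SS_cons\\s+", "", l))
    } else if (!grepl("^#", l)) {
      f <- strsplit(trimws(l), "\\s+")[[1L]]
      if (length(f) >= 2L)
        seqs[[f[1L]]] <- paste0(seqs[[f[1L]]] %||% "", f[2L])
    }
  }
  if (!length(seqs)) stop("no sequence rows in ", path)
  sq <- toupper(unlist(seqs))
  sq <- gsub("\\.", "-", sq)
  if (length(unique(nchar(sq))) != 1L) stop("ragged alignment in ", path)
  ss_cons <- if (nzchar(ss)) {
    s <- chartr("<>{}Aa", "()()..", ss)
    s <- gsub("[^()\\[\\]]", ".", s)
    s
  } else NULL
  list(sequences = sq, ss_cons = ss_cons)
}

#' @rdname read_stockholm
#' @export
write_stockholm <- function(alignment, path) {
  sq <- alignment$sequences
  stopifnot(!is.null(names(sq)), length(unique(nchar(sq))) == 1L)
  w <- max(nchar(names(sq)), nchar("#=GC SS_cons"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  for (k in seq_along(sq))
    writeLines(sprintf("%-*s %s", w, names(sq)[k], sq[[k]]), con)
  if (!is.null(alignment$ss_cons))
    writeLines(sprintf("%-*s %s", w, "#=GC SS_cons", alignment$ss_cons), con)
  writeLines("//", con)
  invisible(path)
}
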