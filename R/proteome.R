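#' Read a proteome from a FASTA file
#'
#' Sequences are returned as a named character vector, uppercased. The id of
#' each record is the first whitespace-delimited token of its header line.
#' Letters outside the 20 standard one-letter amino-acid codes (e.g. U, X, B)
#' are retained in the sequence but flagged via the `nonstandard` attribute.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of protein sequences, with attribute
#'   `nonstandard`: a named integer vector counting non-standard letters per
#'   protein that contains any.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("not readable as FASTA: ",
                                           conditionMessage(e)))
  if (length(aas) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate protein id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aas))
  names(seqs) <- ids
  ns <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(!ch %in% AA_STANDARD)
  }, integer(1))
  attr(seqs, "nonstandard") <- ns[ns > 0]
  seqs
}

#' Write a proteome to FASTA
#'
#' @param proteome Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path, width = 60L) {
  stopifnot(length(proteome) >= 1, !is.null(names(proteome)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(proteome)) {
    writeLines(paste0(">", names(proteome)[i]), con)
    s <- proteome[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Background amino-acid frequencies of a proteome
#'
#' Computes the position-independent residue frequencies q_r of the supplied
#' proteome over the 20 standard amino acids; non-standard letters are
#' excluded from both numerator and denominator. Residues absent from the
#' proteome would give q = 0 and break binomial testing, so all frequencies
#' are floored at a pseudocount of 0.5 / (total standard residues) and
#' renormalized.
#'
#' @param proteome Named character vector of sequences (as from
#'   [read_proteome()]), or a single string.
#' @return Object of class `background_model`: list with `residue_freq`
#'   (named numeric, sums to 1), `residue_counts` (named integer) and
#'   `source = "proteome_global"`.
#' @export
background_from_proteome <- function(proteome) {
  stopifnot(length(proteome) >= 1)
  all_chars <- unlist(strsplit(paste(proteome, collapse = ""), ""))
  counts <- table(factor(all_chars, levels = AA_STANDARD))
  total <- sum(counts)
  if (total == 0) stop("proteome contains no standard amino-acid residues")
  q <- as.numeric(counts) / total
  names(q) <- AA_STANDARD
  floor_q <- 0.5 / total
  q <- pmax(q, floor_q)
  q <- q / sum(q)
  structure(list(residue_freq = q,
                 residue_counts = stats::setNames(as.integer(counts),
                                                  AA_STANDARD),
                 source = "proteome_global"),
            class = "background_model")
}

#' Background frequencies from modification-site windows
#'
#' Alternative background: residue frequencies pooled over all non-pad
#' flanking positions of a set of windows (useful when the sampled windows,
#' not the whole proteome, define the comparison population). The same
#' pseudocount floor as [background_from_proteome()] applies.
#'
#' @param windows A `site_windows` object from [extract_windows()].
#' @return A `background_model` with `source = "window_empirical"`.
#' @export
background_from_windows <- function(windows) {
  stopifnot(inherits(windows, "site_windows"))
  res <- as.vector(windows$residues)
  res <- res[res %in% AA_STANDARD]
  if (length(res) == 0) stop("windows contain no standard residues")
  counts <- table(factor(res, levels = AA_STANDARD))
  total <- sum(counts)
  q <- pmax(as.numeric(counts) / total, 0.5 / total)
  names(q) <- AA_STANDARD
  q <- q / sum(q)
  structure(list(residue_freq = q,
                 residue_counts = stats::setNames(as.integer(counts),
                                                  AA_STANDARD),
            source = "window_empirical"),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("Background model (", x$source, "), ",
      sum(x$residue_counts), " residues\n", sep = "")
  print(round(x$residue_freq, 4))
  invisible(x)
}
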