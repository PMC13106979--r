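#' Exact size of the combinatorial peptide library
#'
#' The number of unique peptides a position-weight spec generates is the
#' product of the residue-set sizes over its offsets (the central
#' modification token is fixed). Computed in double precision, which is
#' exact for products below 2^53.
#'
#' @param spec A `position_weight_spec`.
#' @return Numeric scalar (integer-valued); 1 for an empty spec (the bare
#'   central token).
#' @export
library_size <- function(spec) {
  stopifnot(inherits(spec, "position_weight_spec"))
  sizes <- vapply(spec$residues_at, nrow, integer(1))
  prod(as.numeric(sizes))
}

# Map 0-based library indices to peptide strings under the canonical
# offset-major order: the first offset is the most significant digit, and
# residues count in spec-listed order. Central token rendered as CIT_CHAR.
peptides_from_indices <- function(spec, idx0) {
  if (length(idx0) == 0) return(character(0))
  sets <- lapply(spec$residues_at, function(df) df$residue)
  sizes <- vapply(sets, length, integer(1))
  n_off <- length(sets)
  place <- rev(cumprod(rev(c(sizes[-1], 1))))  # place value of each offset
  mat <- matrix("", nrow = length(idx0), ncol = n_off + 1L)
  central_col <- sum(spec$offsets < 0) + 1L
  flank_cols <- setdiff(seq_len(n_off + 1L), central_col)
  for (j in seq_len(n_off)) {
    digit <- (idx0 %/% place[j]) %% sizes[j]
    mat[, flank_cols[j]] <- sets[[j]][digit + 1L]
  }
  mat[, central_col] <- CIT_CHAR
  apply(mat, 1L, paste0, collapse = "")
}

#' Enumerate the combinatorial library deterministically
#'
#' Materializes peptides in lexicographic, offset-major order: the first
#' offset varies slowest, and residues at each offset follow their
#' spec-listed order. The central modification is embedded at its position
#' as the lowercase token `"r"` (see [render_peptides()]).
#'
#' @param spec A `position_weight_spec`.
#' @param limit Optional maximum number of peptides to return (from the
#'   start of the enumeration). `limit = 0` returns an empty library.
#' @return A `peptide_library`: data.frame with columns `peptide_id` and
#'   `peptide`, with attributes `spec`, `origin = "enumerated"`, `seed = NA`.
#' @export
enumerate_library <- function(spec, limit = NULL) {
  total <- library_size(spec)
  n <- if (is.null(limit)) total else min(total, max(0, limit))
  idx0 <- if (n > 0) seq_len(n) - 1 else numeric(0)
  peps <- peptides_from_indices(spec, idx0)
  new_peptide_library(spec, peps, origin = "enumerated", seed = NA)
}

#' Sample a weighted peptide pool from a spec
#'
#' Draws residues independently at each offset with probability
#' percent / 100, emulating a synthesis pool in which positions are coupled
#' as weighted mixtures. Sampling is with replacement by default (a pool is
#' a mixture, not a set); `distinct = TRUE` switches to rejection-based
#' sampling of unique peptides.
#'
#' @param spec A `position_weight_spec`.
#' @param n Number of peptides to draw, >= 1.
#' @param seed Integer seed; required for reproducibility and recorded in
#'   the result.
#' @param distinct If TRUE, keep drawing until `n` unique peptides are
#'   obtained (errors if `n` exceeds the library size).
#' @return A `peptide_library` with `origin = "sampled"`.
#' @export
sample_library <- function(spec, n, seed, distinct = FALSE) {
  stopifnot(n >= 1)
  if (distinct && n > library_size(spec))
    stop("n exceeds the number of unique peptides in the library")
  sets <- lapply(spec$residues_at, function(df) df$residue)
  probs <- lapply(spec$residues_at, function(df) df$percent / 100)
  draw <- function(m) {
    cols <- mapply(function(s, p) sample(s, m, replace = TRUE, prob = p),
                   sets, probs, SIMPLIFY = FALSE)
    mat <- do.call(cbind, cols)
    central_col <- sum(spec$offsets < 0) + 1L
    after <- if (central_col <= length(sets))
      central_col:length(sets) else integer(0)
    full <- cbind(mat[, seq_len(central_col - 1L), drop = FALSE],
                  rep(CIT_CHAR, m),
                  mat[, after, drop = FALSE])
    apply(full, 1L, paste0, collapse = "")
  }
  peps <- with_seed(seed, {
    if (!distinct) draw(n)
    else {
      acc <- character(0)
      while (length(acc) < n)
        acc <- unique(c(acc, draw(max(n - length(acc), 16L))))
      acc[seq_len(n)]
    }
  })
  new_peptide_library(spec, peps, origin = "sampled", seed = seed)
}

new_peptide_library <- function(spec, peptides, origin, seed) {
  df <- data.frame(peptide_id = sprintf("pep%06d", seq_along(peptides)),
                   peptide = peptides, stringsAsFactors = FALSE)
  structure(df, spec = spec, origin = origin, seed = seed,
            class = c("peptide_library", "data.frame"))
}

#' Render peptide strings for plain-text export
#'
#' The internal citrulline token (lowercase `"r"`) is rendered either as
#' `"R"` plus a parallel modification annotation (`"cit@0"`-style, dialect
#' `"annot"`), or inline as `"R[cit]"` (dialect `"inline"`) for
#' single-column formats. Both round-trip through [parse_peptides()].
#'
#' @param peptides Character vector of internal peptide strings.
#' @param dialect `"annot"` or `"inline"`.
#' @return For `"annot"`, a data.frame with columns `sequence` and
#'   `modifications`; for `"inline"`, a character vector.
#' @export
render_peptides <- function(peptides, dialect = c("annot", "inline")) {
  dialect <- match.arg(dialect)
  pos <- regexpr(CIT_CHAR, peptides, fixed = TRUE)
  if (any(pos < 0)) stop("peptide without a central citrulline token")
  if (dialect == "inline")
    return(sub(CIT_CHAR, "R[cit]", peptides, fixed = TRUE))
  data.frame(sequence = toupper(peptides),
             modifications = sprintf("%dR(cit)", as.integer(pos)),
             stringsAsFactors = FALSE)
}

#' Parse rendered peptides back to internal form
#'
#' @param x Character vector (inline dialect) or data.frame with columns
#'   `sequence` and `modifications` (annot dialect).
#' @return Character vector of internal peptide strings (lowercase `"r"`
#'   citrulline token).
#' @export
parse_peptides <- function(x) {
  if (is.character(x))
    return(sub("R[cit]", CIT_CHAR, x, fixed = TRUE))
  stopifnot(is.data.frame(x), all(c("sequence", "modifications") %in% names(x)))
  pos <- as.integer(sub("^(\\d+)R\\(cit\\).*$", "\\1", x$modifications))
  if (any(is.na(pos))) stop("unparseable modification annotation")
  out <- x$sequence
  substr(out, pos, pos) <- CIT_CHAR
  out
}

#' Export a peptide library to TSV or FASTA
#'
#' TSV carries columns peptide_id, sequence, modifications (the citrulline
#' as "R" with a `cit` annotation, never a bare unannotated R). FASTA
#' headers carry the library index, origin and the modification tag.
#'
#' @param library A `peptide_library`.
#' @param path Output path.
#' @param dialect `"tsv"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
export_library <- function(library, path, dialect = c("tsv", "fasta")) {
  dialect <- match.arg(dialect)
  stopifnot(nrow(library) >= 1)
  rend <- render_peptides(library$peptide, "annot")
  if (dialect == "tsv") {
    out <- cbind(data.frame(peptide_id = library$peptide_id,
                            stringsAsFactors = FALSE), rend)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    hdr <- sprintf(">%s origin=%s mod=%s", library$peptide_id,
                   attr(library, "origin"), rend$modifications)
    writeLines(as.vector(rbind(hdr, rend$sequence)), path)
  }
  invisible(path)
}

#' Read a peptide library written by [export_library()]
#'
#' @param path Input path.
#' @param dialect `"tsv"` or `"fasta"`.
#' @return A `peptide_library` (spec attribute absent).
#' @export
read_library <- function(path, dialect = c("tsv", "fasta")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    peps <- parse_peptides(df[, c("sequence", "modifications")])
    ids <- df$peptide_id
    origin <- "imported"
  } else {
    aas <- Biostrings::readAAStringSet(path)
    meta <- strsplit(names(aas), "\\s+")
    ids <- vapply(meta, `[[`, character(1), 1L)
    mods <- sub("^mod=", "", vapply(meta, function(m)
      grep("^mod=", m, value = TRUE)[1], character(1)))
    peps <- parse_peptides(data.frame(sequence = as.character(aas),
                                      modifications = mods,
                                      stringsAsFactors = FALSE))
    origin <- "imported"
  }
  df <- data.frame(peptide_id = ids, peptide = peps,
                   stringsAsFactors = FALSE)
  structure(df, spec = NULL, origin = origin, seed = NA,
            class = c("peptide_library", "data.frame"))
}
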