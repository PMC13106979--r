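#' Read a modification-site table
#'
#' Sites are given as a TSV with columns `protein_id`, `position` (1-based)
#' and `residue` (the expected residue at that position, e.g. R for
#' citrullination or K for homocitrullination).
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns protein_id, position, residue.
#' @export
read_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  df$position <- as.integer(df$position)
  df$residue <- toupper(df$residue)
  df[need]
}

#' Extract flanking-residue windows around modification sites
#'
#' For each site, the residues at offsets -W..-1 and +1..+W relative to the
#' modified position are collected (the central residue is stored separately,
#' never as a flanking residue). Offsets that fall beyond a protein terminus
#' carry the pad token `"-"`, which is never counted in enrichment. Sites
#' whose residue does not match `expected` residue are excluded (reported,
#' not fatal), as are sites on unknown proteins when `strict = FALSE`.
#'
#' @param proteome Named character vector of sequences.
#' @param sites data.frame with columns protein_id, position, residue.
#' @param W Flank width (number of residues on each side), >= 1. Default 5.
#' @param strict If TRUE (default), an unknown protein_id is an error; if
#'   FALSE it is excluded and counted like a residue mismatch.
#' @return Object of class `site_windows`: list with
#'   \describe{
#'     \item{residues}{character matrix, one row per retained site, one
#'       column per offset (colnames are signed offsets).}
#'     \item{offsets}{integer vector -W..-1, 1..W.}
#'     \item{sites}{data.frame of retained sites (protein_id, position,
#'       residue).}
#'     \item{n_excluded}{number of excluded sites.}
#'     \item{exclusions}{data.frame describing each exclusion.}
#'   }
#' @export
extract_windows <- function(proteome, sites, W = 5L, strict = TRUE) {
  stopifnot(W >= 1)
  W <- as.integer(W)
  offsets <- c(-W:-1, 1:W)
  keep <- logical(nrow(sites))
  reason <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    pid <- sites$protein_id[i]
    if (!pid %in% names(proteome)) {
      if (strict) stop("unknown protein id: ", pid)
      reason[i] <- "unknown_protein"
      next
    }
    pos <- sites$position[i]
    len <- nchar(proteome[[pid]])
    if (is.na(pos) || pos < 1 || pos > len) {
      reason[i] <- "position_out_of_range"
      next
    }
    actual <- substr(proteome[[pid]], pos, pos)
    if (actual != sites$residue[i]) {
      reason[i] <- sprintf("residue_mismatch(expected %s, found %s)",
                           sites$residue[i], actual)
      next
    }
    keep[i] <- TRUE
  }
  kept <- sites[keep, , drop = FALSE]
  mat <- matrix(PAD_TOKEN, nrow = nrow(kept), ncol = 2L * W,
                dimnames = list(NULL, format_offset(offsets)))
  if (nrow(kept) > 0) {
    for (j in seq_along(offsets)) {
      p <- kept$position + offsets[j]
      seqs <- proteome[kept$protein_id]
      lens <- nchar(seqs)
      inside <- p >= 1 & p <= lens
      mat[inside, j] <- substr(seqs[inside], p[inside], p[inside])
    }
  }
  excl <- sites[!keep, , drop = FALSE]
  if (nrow(excl) > 0) excl$reason <- reason[!keep]
  structure(list(residues = mat, offsets = offsets, sites = kept,
                 n_excluded = sum(!keep), exclusions = excl),
            class = "site_windows")
}

#' @export
print.site_windows <- function(x, ...) {
  cat("site_windows: ", nrow(x$residues), " windows, W = ",
      max(x$offsets), ", ", x$n_excluded, " excluded\n", sep = "")
  invisible(x)
}
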