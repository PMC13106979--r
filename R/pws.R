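#' Position-weight specification for a modification motif
#'
#' A position-weight spec lists, for each flanking offset around a central
#' modified residue (offset 0, represented by a modification token such as
#' CIT), an ordered set of amino acids with integer percent weights summing
#' to exactly 100. It is the machine form of a "frequency at each position"
#' design table for a weighted combinatorial peptide pool.
#'
#' @param residues_at Named list: names are offsets (integers or signed
#'   strings like "-1", "+1"; never 0), values are data.frames with columns
#'   `residue` and `percent` (or named numeric vectors residue -> percent).
#' @param central_token Modification symbol at offset 0, default "CIT".
#' @return Object of class `position_weight_spec` with fields `offsets`
#'   (sorted integer vector), `residues_at` (list of data.frames keyed by
#'   signed offset string, in offset order) and `central_token`.
#' @examples
#' spec <- position_weight_spec(list(`-1` = c(D = 60, S = 40),
#'                                   `1` = c(G = 100)))
#' library_size(spec)
#' @export
position_weight_spec <- function(residues_at, central_token = "CIT") {
  offs <- as.integer(names(residues_at))
  if (any(is.na(offs))) stop("offset names must be integers")
  if (any(offs == 0)) stop("offset 0 is the central token, not a weighted position")
  if (anyDuplicated(offs)) stop("duplicate offsets")
  ord <- order(offs)
  offs <- offs[ord]
  residues_at <- residues_at[ord]
  residues_at <- lapply(residues_at, function(x) {
    if (!is.data.frame(x))
      x <- data.frame(residue = names(x), percent = as.numeric(x),
                      stringsAsFactors = FALSE)
    stopifnot(all(c("residue", "percent") %in% names(x)))
    x$residue <- toupper(as.character(x$residue))
    x$percent <- as.integer(x$percent)
    x[, c("residue", "percent")]
  })
  names(residues_at) <- format_offset(offs)
  spec <- structure(list(offsets = offs, residues_at = residues_at,
                         central_token = central_token),
                    class = "position_weight_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  for (off in names(spec$residues_at)) {
    df <- spec$residues_at[[off]]
    if (nrow(df) == 0) stop("empty residue list at offset ", off)
    if (anyDuplicated(df$residue))
      stop("duplicate residue at offset ", off)
    bad <- setdiff(df$residue, AA_STANDARD)
    if (length(bad) > 0)
      stop("non-standard residue(s) at offset ", off, ": ",
           paste(bad, collapse = ", "))
    if (sum(df$percent) != 100L)
      stop("percents at offset ", off, " sum to ", sum(df$percent),
           ", not 100")
  }
  invisible(spec)
}

#' Load a position-weight spec from TSV
#'
#' The file must have columns `offset`, `residue`, `percent`; rows sharing
#' an offset define that position's residue set in file order. Percents at
#' each offset must sum to exactly 100.
#'
#' @param path Path to the TSV file.
#' @param central_token Modification symbol, default "CIT".
#' @return A `position_weight_spec`.
#' @export
load_spec <- function(path, central_token = "CIT") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("offset", "residue", "percent")
  if (!all(need %in% names(df)))
    stop("spec file must have columns: ", paste(need, collapse = ", "))
  by_off <- split(df, factor(df$offset, levels = unique(df$offset)))
  residues_at <- lapply(by_off, function(x)
    data.frame(residue = x$residue, percent = x$percent,
               stringsAsFactors = FALSE))
  position_weight_spec(residues_at, central_token = central_token)
}

#' Write a position-weight spec as TSV
#'
#' @param spec A `position_weight_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  rows <- do.call(rbind, lapply(names(spec$residues_at), function(off) {
    df <- spec$residues_at[[off]]
    data.frame(offset = as.integer(off), residue = df$residue,
               percent = df$percent, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged immunization-pool position-weight spec
#'
#' Loads the design table of the 10-mer citrullinated immunogen pool that
#' ships with the package: offsets -4..-1 and +1..+5 around a central
#' citrulline, with 4-6 weighted residues per position (residue-set sizes
#' 4,4,4,4 upstream and 4,4,4,5,6 downstream).
#'
#' @return A `position_weight_spec`.
#' @export
immunogen_pool_spec <- function() {
  load_spec(system.file("extdata", "immunogen_pool_spec.tsv",
                        package = "citmotif", mustWork = TRUE))
}

#' Residue set at an offset of a spec
#'
#' @param spec A `position_weight_spec`.
#' @param offset Integer offset.
#' @return Character vector of residues in spec order.
#' @export
spec_residues <- function(spec, offset) {
  key <- format_offset(as.integer(offset))
  if (!key %in% names(spec$residues_at))
    stop("offset ", key, " not present in spec")
  spec$residues_at[[key]]$residue
}

#' @export
print.position_weight_spec <- function(x, ...) {
  cat("position_weight_spec: central ", x$central_token, ", offsets ",
      paste(format_offset(x$offsets), collapse = " "), "\n", sep = "")
  for (off in names(x$residues_at)) {
    df <- x$residues_at[[off]]
    cat(sprintf("  %3s: %s\n", off,
                paste0(df$residue, "(", df$percent, "%)", collapse = " ")))
  }
  invisible(x)
}
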