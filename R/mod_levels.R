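# Monoisotopic atomic masses (Da), CODATA/IUPAC values.
MONO_MASS <- c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
               O = 15.9949146221)

# Elemental composition changes of the supported modifications.
MOD_COMPOSITION <- list(
  citrullination = c(O = 1, N = -1, H = -1),  # Arg -> citrulline
  deamidation    = c(O = 1, N = -1, H = -1),  # Asn/Gln, same delta
  carbamylation  = c(H = 1, C = 1, N = 1, O = 1)  # Lys -> homocitrulline
)

# Residue each modification is chemically restricted to (NA = unrestricted).
MOD_TARGET <- c(citrullination = "R", carbamylation = "K",
                deamidation = NA, other = NA)

#' Monoisotopic mass shift of a modification
#'
#' Computed from the modification's elemental composition change using
#' standard monoisotopic atomic masses: citrullination (and deamidation,
#' the same composition change) is +O -N -H = +0.9840 Da; carbamylation is
#' +H +C +N +O = +43.0058 Da.
#'
#' @param mod_type One of `"citrullination"`, `"deamidation"`,
#'   `"carbamylation"`.
#' @return Monoisotopic mass delta in Da (double precision).
#' @export
mod_delta <- function(mod_type) {
  if (!mod_type %in% names(MOD_COMPOSITION))
    stop("unknown modification type: ", mod_type)
  comp <- MOD_COMPOSITION[[mod_type]]
  sum(MONO_MASS[names(comp)] * comp)
}

# Mini-grammar for modification strings: semicolon-separated terms
# "<offset><residue>(<type>)", e.g. "3R(cit);7K(carbamyl)". Type aliases:
# cit -> citrullination, carbamyl -> carbamylation, deam -> deamidation.
MOD_ALIASES <- c(cit = "citrullination", citrullination = "citrullination",
                 deam = "deamidation", deamidation = "deamidation",
                 carbamyl = "carbamylation", carbamylation = "carbamylation")

parse_mod_string <- function(s) {
  if (is.na(s) || !nzchar(trimws(s)))
    return(data.frame(offset = integer(0), residue = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  terms <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  m <- regmatches(terms, regexec("^(\\d+)([A-Z])\\(([A-Za-z]+)\\)$", terms))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("malformed modification term(s): ",
         paste(terms[bad], collapse = ", "))
  data.frame(
    offset = as.integer(vapply(m, `[[`, character(1), 2L)),
    residue = vapply(m, `[[`, character(1), 3L),
    type = unname(MOD_ALIASES[tolower(vapply(m, `[[`, character(1), 4L))]),
    stringsAsFactors = FALSE)
}

#' Read a peptide-level MS search summary table
#'
#' Consumes a TSV with columns `sequence`, `intensity` and `modifications`
#' (search-engine-agnostic). Modification strings follow the mini-grammar
#' `"<offset><residue>(<type>)"` joined by semicolons, offsets 1-based in
#' the peptide; e.g. `"3R(cit);7K(carbamyl)"`. Terms whose offset is out of
#' range, whose residue disagrees with the sequence, or whose type is
#' chemically impossible on the residue (citrullination off R, carbamylation
#' off K) are kept but flagged invalid. Rows with unparseable strings are
#' collected as row-level errors, not a failure.
#'
#' @param path Path to the TSV file.
#' @return Object of class `peptide_records`: list with `peptides`
#'   (data.frame record, sequence, intensity), `mods` (data.frame record,
#'   offset, residue, type, valid) and `errors` (data.frame record,
#'   message).
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("sequence", "intensity", "modifications")
  if (!all(need %in% names(df)))
    stop("peptide table must have columns: ", paste(need, collapse = ", "))
  peptide_records(df$sequence, df$intensity, df$modifications)
}

#' Build peptide records from vectors
#'
#' @param sequence Character vector of peptide sequences.
#' @param intensity Non-negative numeric intensities (a.u.).
#' @param modifications Modification strings (see [read_peptide_table()]);
#'   NA or empty means unmodified.
#' @return A `peptide_records` object.
#' @export
peptide_records <- function(sequence, intensity,
                            modifications = rep(NA_character_,
                                                length(sequence))) {
  stopifnot(length(sequence) == length(intensity),
            length(sequence) == length(modifications))
  intensity <- as.numeric(intensity)
  if (any(!is.na(intensity) & intensity < 0))
    stop("negative intensity")
  mods_list <- vector("list", length(sequence))
  errors <- list()
  for (i in seq_along(sequence)) {
    parsed <- tryCatch(parse_mod_string(modifications[i]),
                       error = function(e)
                         simpleError(conditionMessage(e)))
    if (inherits(parsed, "error")) {
      errors[[length(errors) + 1L]] <-
        data.frame(record = i, message = conditionMessage(parsed),
                   stringsAsFactors = FALSE)
      parsed <- parse_mod_string(NA)
    }
    if (nrow(parsed) > 0) {
      parsed$record <- i
      len <- nchar(sequence[i])
      in_range <- parsed$offset >= 1 & parsed$offset <= len
      seq_res <- ifelse(in_range,
                        substr(rep(sequence[i], nrow(parsed)),
                               parsed$offset, parsed$offset), "")
      target <- MOD_TARGET[parsed$type]
      parsed$valid <- in_range & seq_res == parsed$residue &
        (is.na(target) | parsed$residue == target)
      mods_list[[i]] <- parsed[, c("record", "offset", "residue", "type",
                                   "valid")]
    }
  }
  mods <- if (length(mods_list[!vapply(mods_list, is.null, logical(1))]))
    do.call(rbind, mods_list)
  else data.frame(record = integer(0), offset = integer(0),
                  residue = character(0), type = character(0),
                  valid = logical(0))
  rownames(mods) <- NULL
  structure(list(
    peptides = data.frame(record = seq_along(sequence),
                          sequence = toupper(sequence),
                          intensity = ifelse(is.na(intensity), 0,
                                             intensity),
                          stringsAsFactors = FALSE),
    mods = mods,
    errors = if (length(errors)) do.call(rbind, errors)
    else data.frame(record = integer(0), message = character(0))),
    class = "peptide_records")
}

#' Modification-level summary over a peptide table
#'
#' The fraction of modified peptides, both relative to peptides containing
#' the target residue and relative to all peptides, by unique-entry count
#' and by summed intensity. A peptide counts as modified if it carries at
#' least one valid modification of the queried type (multiple sites count
#' once). Zero-intensity peptides are counted but contribute 0 to the
#' intensity ratios. When no peptide contains the target residue, the
#' target-based percentages are NA, not 0.
#'
#' @param records A `peptide_records` object.
#' @param mod_type Modification type to summarize.
#' @param target_residue Residue defining the eligible denominator (e.g.
#'   "R" for citrullination, "K" for carbamylation).
#' @return Object of class `modification_summary`: list of the four
#'   percentages and their underlying counts / intensity sums.
#' @export
percent_modified <- function(records, mod_type, target_residue) {
  stopifnot(inherits(records, "peptide_records"))
  if (!mod_type %in% names(MOD_COMPOSITION))
    stop("unknown modification type: ", mod_type)
  pep <- records$peptides
  if (nrow(pep) < 1) stop("no peptide records")
  modded_records <- unique(records$mods$record[
    records$mods$type == mod_type & records$mods$valid])
  is_mod <- pep$record %in% modded_records
  has_target <- grepl(target_residue, pep$sequence, fixed = TRUE)
  n_all <- nrow(pep)
  n_target <- sum(has_target)
  i_all <- sum(pep$intensity)
  i_target <- sum(pep$intensity[has_target])
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    mod_type = mod_type, target_residue = target_residue,
    pct_target_residue_peptides_modified =
      pct(sum(is_mod & has_target), n_target),
    pct_all_peptides_modified = pct(sum(is_mod), n_all),
    pct_target_intensity_modified =
      pct(sum(pep$intensity[is_mod & has_target]), i_target),
    pct_all_intensity_modified = pct(sum(pep$intensity[is_mod]), i_all),
    n_modified = sum(is_mod), n_target = n_target, n_all = n_all,
    intensity_modified = sum(pep$intensity[is_mod]),
    intensity_target = i_target, intensity_all = i_all),
    class = "modification_summary")
}

#' @export
print.modification_summary <- function(x, ...) {
  cat(sprintf(
    "%s: %.1f%% of %s-containing peptides (%d/%d), %.1f%% of all (%d/%d);\n",
    x$mod_type, x$pct_target_residue_peptides_modified, x$target_residue,
    x$n_modified, x$n_target, x$pct_all_peptides_modified, x$n_modified,
    x$n_all))
  cat(sprintf("  intensity: %.1f%% of %s-containing, %.1f%% of total\n",
              x$pct_target_intensity_modified, x$target_residue,
              x$pct_all_intensity_modified))
  invisible(x)
}

#' Write a modification summary as TSV
#'
#' @param summary A `modification_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mod_summary <- function(summary, path) {
  flat <- summary[vapply(summary, function(v)
    is.numeric(v) || is.character(v), logical(1))]
  df <- data.frame(field = names(flat),
                   value = vapply(flat, as.character, character(1)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
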