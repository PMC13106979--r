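#' Read a per-spot fluorescence table
#'
#' Two dialects are supported. `"tsv"` expects named columns `spot_index`,
#' `f635_mean` and optionally `flag`, `peptide_id`, `kind`. `"gpr"` parses
#' the GenePix/Mapix tab-delimited results format by locating the header row
#' containing the quoted or unquoted column name `F635 Mean` (optional
#' `Flags`, `ID`); rows are taken in file order as spot indices 1..n. In
#' both dialects spots are joined to peptide identities through the design
#' (an `array_design` or a design mapping read by [read_design_table()]).
#'
#' @param path Path to the signal table.
#' @param design An `array_design`, a design-mapping data.frame, or NULL
#'   (then the table itself must carry `kind`/`peptide_id`).
#' @param dialect `"tsv"` or `"gpr"`.
#' @return data.frame of spot records: spot_index, peptide_id, kind, group,
#'   core, f635_mean, flag; attribute `n_unmatched` counts spots that could
#'   not be joined to the design.
#' @export
read_spot_table <- function(path, design = NULL,
                            dialect = c("tsv", "gpr")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    if (!"f635_mean" %in% names(df))
      stop("spot table lacks an intensity column 'f635_mean'")
    if (!"spot_index" %in% names(df)) df$spot_index <- seq_len(nrow(df))
    if (!"flag" %in% names(df)) df$flag <- 0L
  } else {
    lines <- readLines(path)
    hdr <- grep("F635 Mean", lines)[1]
    if (is.na(hdr)) stop("no header row containing 'F635 Mean' found")
    df <- utils::read.delim(path, skip = hdr - 1L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    names(df) <- gsub('^"|"$', "", names(df))
    if (!"F635 Mean" %in% names(df))
      stop("GPR table lacks the 'F635 Mean' column")
    out <- data.frame(spot_index = seq_len(nrow(df)),
                      f635_mean = as.numeric(df[["F635 Mean"]]),
                      flag = if ("Flags" %in% names(df))
                        as.integer(df[["Flags"]]) else 0L,
                      stringsAsFactors = FALSE)
    if ("ID" %in% names(df)) out$peptide_id <- as.character(df[["ID"]])
    df <- out
  }
  join_design(df, design)
}

# Attach kind/group/core from the design; spots whose peptide_id does not
# match any design peptide are retained but counted as unmatched.
join_design <- function(spots, design) {
  if (inherits(design, "array_design")) {
    lay <- design$layout
    peps <- design$peptides
  } else if (is.data.frame(design)) {
    lay <- design
    peps <- unique(design[design$kind == "peptide",
                          intersect(c("peptide_id", "core", "group"),
                                    names(design))])
  } else {
    lay <- NULL
    peps <- NULL
  }
  if (!is.null(lay)) {
    m <- match(spots$spot_index, lay$spot_index)
    spots$kind <- lay$kind[m]
    spots$peptide_id <- lay$peptide_id[m]
    n_unmatched <- sum(is.na(m))
  } else {
    if (!"kind" %in% names(spots))
      spots$kind <- ifelse(is.na(spots$peptide_id), "blank", "peptide")
    n_unmatched <- 0L
  }
  if (!is.null(peps) && "core" %in% names(peps)) {
    mp <- match(spots$peptide_id, peps$peptide_id)
    spots$core <- peps$core[mp]
    spots$group <- peps$group[mp]
  } else {
    spots$core <- NA_character_
    spots$group <- NA_character_
  }
  spots$group[spots$kind == "control"] <- "control"
  spots$group[spots$kind == "blank"] <- "blank"
  n_unmatched <- n_unmatched +
    sum(spots$kind == "peptide" & is.na(spots$group), na.rm = TRUE)
  spots$flag[is.na(spots$flag)] <- 0L
  cols <- c("spot_index", "peptide_id", "kind", "group", "core",
            "f635_mean", "flag")
  out <- spots[, intersect(cols, names(spots))]
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Write a spot table (TSV dialect, lossless round trip)
#'
#' @param spots Spot-record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a spot table in the GPR dialect
#'
#' Emits a minimal GenePix-style results file: an ATF preamble, quoted
#' header row with `Block`, `Column`, `Row`, `ID`, `F635 Mean`, `Flags`,
#' then one row per spot in spot-index order.
#'
#' @param spots Spot-record data.frame.
#' @param path Output path.
#' @param ncol Grid columns for the index -> (row, col) mapping.
#' @return `path`, invisibly.
#' @export
write_gpr <- function(spots, path, ncol = NULL) {
  if (is.null(ncol)) ncol <- ceiling(sqrt(nrow(spots)))
  idx0 <- spots$spot_index - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ATF\t1.0", "2\t6",
               '"Type=GenePix Results 3"',
               '"Wavelengths=635"'), con)
  hdr <- c("Block", "Column", "Row", "ID", "F635 Mean", "Flags")
  writeLines(paste0('"', hdr, '"', collapse = "\t"), con)
  id <- ifelse(is.na(spots$peptide_id), spots$kind, spots$peptide_id)
  tab <- data.frame(1L, idx0 %% ncol + 1L, idx0 %/% ncol + 1L, id,
                    spots$f635_mean, spots$flag)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Normalize spot intensities to the synthesis controls
#'
#' Optional per-array normalization: intensities are scaled so the mean of
#' the valid control spots equals `target`. OFF by default throughout the
#' package — raw F635 means are the standard readout — but useful when
#' comparing arrays hybridized at different overall intensity.
#'
#' @param spots Spot-record data.frame.
#' @param target Post-normalization control mean (default 1).
#' @return The spot table with scaled `f635_mean` and a `scale_factor`
#'   attribute.
#' @export
normalize_to_controls <- function(spots, target = 1) {
  ctrl <- spots$f635_mean[spots$kind == "control" & spots$flag == 0 &
                            !is.na(spots$f635_mean)]
  if (length(ctrl) == 0) stop("no valid control spots to normalize to")
  fac <- target / mean(ctrl)
  spots$f635_mean <- spots$f635_mean * fac
  attr(spots, "scale_factor") <- fac
  spots
}

#' Summarize replicate spots per unique peptide
#'
#' The binding strength of each peptide is the arithmetic mean of its valid
#' replicate F635 intensities. A replicate is valid if its QC flag is zero
#' and its intensity is a non-negative number; peptides with no valid
#' replicate are excluded (and counted in the `n_excluded` attribute).
#'
#' @param spots Spot-record data.frame (peptide spots are used; controls
#'   and blanks are ignored here).
#' @return data.frame of peptide summaries: peptide_id, core, group,
#'   mean_signal, n_valid, cv; attribute `n_excluded`.
#' @export
summarize_replicates <- function(spots) {
  pep <- spots[spots$kind == "peptide" & !is.na(spots$peptide_id), ,
               drop = FALSE]
  valid <- pep$flag == 0 & !is.na(pep$f635_mean) & pep$f635_mean >= 0
  all_ids <- unique(pep$peptide_id)
  pv <- pep[valid, , drop = FALSE]
  if (nrow(pv) == 0) {
    out <- data.frame(peptide_id = character(0), core = character(0),
                      group = character(0), mean_signal = numeric(0),
                      n_valid = integer(0), cv = numeric(0))
    attr(out, "n_excluded") <- length(all_ids)
    return(out)
  }
  sp <- split(pv$f635_mean, pv$peptide_id)
  ids <- names(sp)
  means <- vapply(sp, mean, numeric(1))
  nv <- vapply(sp, length, integer(1))
  sds <- vapply(sp, stats::sd, numeric(1))
  meta <- pv[match(ids, pv$peptide_id), c("core", "group")]
  out <- data.frame(peptide_id = ids, core = meta$core, group = meta$group,
                    mean_signal = unname(means), n_valid = unname(nv),
                    cv = unname(ifelse(means > 0, sds / means, NA_real_)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$peptide_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- length(setdiff(all_ids, ids))
  out
}

#' Per-group signal distributions
#'
#' Summarizes peptide mean signals per design group, and blank (and
#' control) spots from their raw per-spot values — the numbers behind the
#' binding-strength histograms and their median markers.
#'
#' @param summaries Peptide summaries from [summarize_replicates()].
#' @param spots Optional spot-record data.frame supplying blank/control
#'   spot values.
#' @return data.frame: group, n, median, q1, q3, mean.
#' @export
group_distributions <- function(summaries, spots = NULL) {
  grp_stats <- function(v, g) {
    if (length(v) == 0)
      return(data.frame(group = g, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, mean = NA_real_))
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), median = qs[2], q1 = qs[1],
               q3 = qs[3], mean = mean(v), stringsAsFactors = FALSE)
  }
  proto <- data.frame(group = character(0), n = integer(0),
                      median = numeric(0), q1 = numeric(0),
                      q3 = numeric(0), mean = numeric(0))
  groups <- unique(summaries$group)
  out <- do.call(rbind, c(list(proto),
                          lapply(groups, function(g)
                            grp_stats(summaries$mean_signal[summaries$group == g],
                                      g))))
  if (!is.null(spots)) {
    for (k in c("blank", "control")) {
      v <- spots$f635_mean[spots$kind == k & !is.na(spots$f635_mean)]
      if (length(v) > 0 || k == "blank")
        out <- rbind(out, grp_stats(v, k))
    }
  }
  rownames(out) <- NULL
  out
}

#' Select top-quantile strong binders
#'
#' Ranks all tested peptides by mean signal, irrespective of design group,
#' and selects the top fraction `q` (default the top quartile). The number
#' selected is floor(q * n); ties at the threshold are broken
#' deterministically by ascending peptide_id.
#'
#' @param summaries Peptide summaries from [summarize_replicates()].
#' @param q Selection fraction in (0, 1), default 0.25.
#' @return Object of class `binder_selection`: list with `q`, `threshold`
#'   (smallest selected mean signal), `selected` (peptide ids), `n_selected`
#'   and `n_included`.
#' @export
select_strong_binders <- function(summaries, q = 0.25) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  n <- nrow(summaries)
  if (n < ceiling(1 / q)) stop("too few peptides for quantile ", q)
  n_sel <- floor(q * n)
  ord <- order(-summaries$mean_signal, summaries$peptide_id)
  sel <- summaries[ord[seq_len(n_sel)], , drop = FALSE]
  structure(list(q = q, threshold = min(sel$mean_signal),
                 selected = sel$peptide_id, n_selected = n_sel,
                 n_included = n),
            class = "binder_selection")
}

#' @export
print.binder_selection <- function(x, ...) {
  cat("binder_selection: top ", 100 * x$q, "% -> ", x$n_selected, " of ",
      x$n_included, " peptides (threshold ", signif(x$threshold, 4),
      ")\n", sep = "")
  invisible(x)
}

# Per-offset residue count matrix of a set of 7-mer cores (center dropped).
core_counts <- function(cores) {
  stopifnot(all(nchar(cores) == 7L))
  offs <- c(-3L, -2L, -1L, 1L, 2L, 3L)
  cols <- c(1:3, 5:7)
  k <- matrix(0L, nrow = 6L, ncol = 20L,
              dimnames = list(format_offset(offs), AA_STANDARD))
  for (i in seq_along(cols)) {
    tab <- table(factor(substr(cores, cols[i], cols[i]),
                        levels = AA_STANDARD))
    k[i, ] <- as.integer(tab)
  }
  k
}

#' Motif enrichment of selected binders against all tested peptides
#'
#' Reconstructs the binding motif: foreground = the strong-binder cores,
#' background = the per-offset residue composition of ALL tested cores (the
#' tested library is deliberately non-uniform, so the proteome would be the
#' wrong reference). Offsets -3..+3, center excluded; the same exact
#' binomial tails, Bonferroni correction and signed scores as
#' [compute_enrichment()].
#'
#' @param selection A `binder_selection`.
#' @param summaries The full peptide-summary table the selection was drawn
#'   from (provides the cores).
#' @param alpha Significance level (default 0.05).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return An `enrichment_table`.
#' @export
binder_enrichment <- function(selection, summaries, alpha = 0.05,
                              correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(selection, "binder_selection"),
            selection$n_selected >= 1)
  fg_cores <- summaries$core[match(selection$selected,
                                   summaries$peptide_id)]
  if (anyNA(fg_cores)) stop("selected peptides missing core sequences")
  k_fg <- core_counts(fg_cores)
  k_all <- core_counts(summaries$core)
  n_all <- nrow(summaries)
  q_mat <- k_all / n_all
  # background probabilities floored so untested residues stay testable
  q_mat <- pmax(q_mat, 0.5 / n_all)
  q_mat <- q_mat / rowSums(q_mat)
  n_p <- rep(length(fg_cores), nrow(k_fg))
  enrich_counts(k_fg, n_p, q_mat, alpha, correction)
}
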