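#' Exact binomial tail probability
#'
#' Upper tail P(X >= k) or lower tail P(X <= k) for X ~ Binomial(n, q),
#' computed exactly via [stats::pbinom()] (log-space internally, so very
#' small tails do not underflow to zero prematurely).
#'
#' @param k Observed count, 0 <= k <= n.
#' @param n Number of trials.
#' @param q Success probability, 0 < q < 1.
#' @param tail `"over"` for P(X >= k), `"under"` for P(X <= k).
#' @return Numeric p-value (vectorized over k and n).
#' @export
binomial_tail <- function(k, n, q, tail = c("over", "under")) {
  tail <- match.arg(tail)
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly in (0, 1)")
  if (tail == "over")
    stats::pbinom(k - 1, n, q, lower.tail = FALSE)
  else
    stats::pbinom(k, n, q, lower.tail = TRUE)
}

# log10 of the binomial tails, exact via pbinom(log.p = TRUE); used for the
# signed score so extreme enrichments keep finite magnitudes.
binomial_tail_log10 <- function(k, n, q, tail) {
  if (tail == "over")
    stats::pbinom(k - 1, n, q, lower.tail = FALSE, log.p = TRUE) / log(10)
  else
    stats::pbinom(k, n, q, lower.tail = TRUE, log.p = TRUE) / log(10)
}

# Core of the pLogo-style statistic: given foreground counts k (offset x
# residue), per-offset totals n_p and background probabilities q (either a
# single named vector or an offset x residue matrix), compute both tails,
# the signed score and significance flags. Returns the long-format table.
enrich_counts <- function(k_mat, n_p, q, alpha, correction) {
  offsets <- rownames(k_mat)
  residues <- colnames(k_mat)
  scored <- sum(n_p > 0)
  n_tests <- if (correction == "bonferroni") 20L * scored else 1L
  thr <- if (correction == "bonferroni") alpha / n_tests else alpha
  q_mat <- if (is.matrix(q)) q else
    matrix(q[residues], nrow = length(offsets), ncol = length(residues),
           byrow = TRUE, dimnames = dimnames(k_mat))
  rows <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    n_i <- n_p[i]
    k_i <- k_mat[i, ]
    q_i <- q_mat[i, ]
    if (n_i == 0) {
      rows[[i]] <- data.frame(offset = offsets[i], residue = residues,
                              k = 0L, n = 0L, q = q_i,
                              p_over = NA_real_, p_under = NA_real_,
                              score = NA_real_, significant = FALSE,
                              stringsAsFactors = FALSE)
      next
    }
    p_over <- binomial_tail(k_i, n_i, q_i, "over")
    p_under <- binomial_tail(k_i, n_i, q_i, "under")
    l_over <- binomial_tail_log10(k_i, n_i, q_i, "over")
    l_under <- binomial_tail_log10(k_i, n_i, q_i, "under")
    # positive score = over-represented (-log10 p_over); negative =
    # under-represented; 0 when the two tails tie.
    score <- ifelse(p_over < p_under, -l_over,
                    ifelse(p_under < p_over, l_under, 0))
    rows[[i]] <- data.frame(offset = offsets[i], residue = residues,
                            k = as.integer(k_i), n = as.integer(n_i),
                            q = q_i,
                            p_over = p_over, p_under = p_under,
                            score = score,
                            significant = pmin(p_over, p_under) < thr,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, alpha = alpha, n_tests = n_tests, correction = correction,
            class = c("enrichment_table", "data.frame"))
}

#' Position-specific residue enrichment of modification-site windows
#'
#' For every offset and every standard amino acid, counts the residue's
#' occurrences among the (non-pad) windows at that offset and tests the
#' count against the background probability with exact one-sided binomial
#' tests, both tails. With Bonferroni correction the significance threshold
#' is alpha / n_tests with n_tests = 20 residues x number of scored offsets
#' (offsets where at least one window is not padded). The signed score is
#' -log10(p_over) for over-represented cells and +log10(p_under) (i.e.
#' negative) for under-represented ones.
#'
#' @param windows A `site_windows` object.
#' @param background A `background_model`.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return An `enrichment_table`: data.frame with columns offset, residue,
#'   k, n, q, p_over, p_under, score, significant, plus attributes `alpha`,
#'   `n_tests`, `correction`. Pad tokens never contribute to k or n.
#' @export
compute_enrichment <- function(windows, background, alpha = 0.05,
                               correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(windows, "site_windows"),
            inherits(background, "background_model"),
            alpha > 0, alpha < 1)
  if (nrow(windows$residues) < 1) stop("at least one window is required")
  offs <- colnames(windows$residues)
  k_mat <- matrix(0L, nrow = length(offs), ncol = 20L,
                  dimnames = list(offs, AA_STANDARD))
  n_p <- integer(length(offs))
  for (i in seq_along(offs)) {
    col <- windows$residues[, i]
    std <- col[col %in% AA_STANDARD]
    n_p[i] <- length(std)
    tab <- table(factor(std, levels = AA_STANDARD))
    k_mat[i, ] <- as.integer(tab)
  }
  enrich_counts(k_mat, n_p, background$residue_freq, alpha, correction)
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("enrichment_table: ", length(unique(x$offset)), " offsets, alpha = ",
      attr(x, "alpha"), ", n_tests = ", attr(x, "n_tests"), " (",
      attr(x, "correction"), "), ", sum(x$significant, na.rm = TRUE),
      " significant cells\n", sep = "")
  NextMethod()
}

#' Write / read an enrichment table as TSV
#'
#' @param table An `enrichment_table`.
#' @param path Output path.
#' @return `path` invisibly (writer); an `enrichment_table` (reader).
#' @export
write_enrichment <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment
#' @param alpha,n_tests,correction Metadata to restore when reading.
#' @export
read_enrichment <- function(path, alpha = 0.05, n_tests = NA_integer_,
                            correction = "bonferroni") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df, alpha = alpha, n_tests = n_tests, correction = correction,
            class = c("enrichment_table", "data.frame"))
}

#' Select significantly over-represented residues into a position-weight spec
#'
#' Per offset, keeps residues whose over-representation is significant at
#' the table's corrected threshold (positive score and `significant`), and
#' converts their observed foreground frequencies, renormalized over the
#' selected residues, to integer percents summing to 100 by
#' largest-remainder rounding. Offsets with no significant residue are
#' omitted. Residues are ordered by decreasing percent (ties by decreasing
#' k, then alphabetically).
#'
#' @param table An `enrichment_table`.
#' @param central_token Modification symbol for the spec center, default
#'   `"CIT"`.
#' @return A `position_weight_spec` (possibly with no offsets).
#' @export
select_motif_residues <- function(table, central_token = "CIT") {
  stopifnot(inherits(table, "enrichment_table"))
  sel <- table[!is.na(table$p_over) & table$significant &
                 table$p_over < table$p_under, , drop = FALSE]
  residues_at <- list()
  for (off in unique(table$offset)) {
    s <- sel[sel$offset == off, , drop = FALSE]
    if (nrow(s) == 0) next
    pct <- largest_remainder_percents(s$k)
    ord <- order(-pct, -s$k, s$residue)
    residues_at[[off]] <- data.frame(residue = s$residue[ord],
                                     percent = pct[ord],
                                     stringsAsFactors = FALSE)
  }
  position_weight_spec(residues_at, central_token = central_token)
}
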