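#' Enumerate the motif-group 7-mer cores for the microarray
#'
#' Builds every combination of the spec's residue sets at offsets -3..-1 and
#' +1..+3 around a central citrulline, optionally replacing the +1 set by
#' all 20 standard amino acids (the array design choice that probes the +1
#' position exhaustively). Enumeration order is deterministic: offset-major,
#' residues in spec-listed order, the all-20 set alphabetical.
#'
#' @param spec A `position_weight_spec` providing residue sets at
#'   -3..-1 and +1..+3 (weights are ignored here).
#' @param plus1_all20 Replace the +1 residue set with all 20 standard amino
#'   acids (default TRUE).
#' @return Character vector of unique 7-character cores, central citrulline
#'   as lowercase `"r"` at position 4.
#' @export
build_motif_set <- function(spec, plus1_all20 = TRUE) {
  offs <- c(-3L, -2L, -1L, 1L, 2L, 3L)
  sets <- lapply(offs, function(o) spec_residues(spec, o))
  names(sets) <- format_offset(offs)
  if (plus1_all20) sets[["+1"]] <- AA_STANDARD
  sub <- position_weight_spec(
    lapply(sets, function(r)
      data.frame(residue = r,
                 percent = largest_remainder_percents(rep(1, length(r))),
                 stringsAsFactors = FALSE)))
  enumerate_library(sub)$peptide
}

#' Complement residue set at an offset
#'
#' For the non-motif control group: the residues NOT used by the motif set
#' at an offset. At a normal offset this is the 20 standard amino acids
#' minus the spec's residue set; at an all-20 offset (the array's +1) the
#' complement is taken against an explicit exclusion set (the residues
#' enriched there). Optional global exclusions (e.g. C and V) are removed on
#' top.
#'
#' @param spec A `position_weight_spec`.
#' @param offset Integer offset.
#' @param exclusions Residues to exclude when the offset's design set is all
#'   20 (set `all20 = TRUE`); also accepted for normal offsets, where they
#'   are unioned with the spec residues.
#' @param all20 Is this offset an all-20 design position (complement =
#'   20 - exclusions)?
#' @param global_exclude Residues removed from every complement (default
#'   none).
#' @return Character vector (alphabetical) of complement residues.
#' @export
complement_residues <- function(spec, offset, exclusions = character(0),
                                all20 = FALSE,
                                global_exclude = character(0)) {
  drop <- if (all20) exclusions
  else union(spec_residues(spec, offset), exclusions)
  out <- setdiff(AA_STANDARD, union(drop, global_exclude))
  if (length(out) == 0)
    stop("empty complement at offset ", format_offset(offset))
  sort(out)
}

#' Complement sets for the standard array geometry
#'
#' Convenience wrapper applying [complement_residues()] at offsets -3..+3,
#' treating +1 as the all-20 design position whose complement excludes the
#' residues enriched there (G, S, A, D by default).
#'
#' @param spec A `position_weight_spec`.
#' @param plus1_exclusions Residues excluded from the +1 complement.
#' @param global_exclude Residues removed from every complement.
#' @return Named list of per-offset residue vectors.
#' @export
array_complements <- function(spec, plus1_exclusions = c("G", "S", "A", "D"),
                              global_exclude = character(0)) {
  offs <- c(-3L, -2L, -1L, 1L, 2L, 3L)
  sets <- lapply(offs, function(o)
    complement_residues(spec, o,
                        exclusions = if (o == 1L) plus1_exclusions
                        else character(0),
                        all20 = (o == 1L),
                        global_exclude = global_exclude))
  names(sets) <- format_offset(offs)
  sets
}

#' Randomly generate the non-motif 7-mer core set
#'
#' Samples cores by combining residues drawn uniformly and independently
#' from the per-offset complement sets, rejecting duplicates until `n`
#' unique sequences are collected. By construction every core is disjoint
#' from any motif core (the residue sets differ at every offset).
#'
#' @param complements Named list of per-offset residue vectors (e.g. from
#'   [array_complements()]), in offset order; the center is implicit.
#' @param n Number of unique cores to generate.
#' @param seed Integer seed (sampling is deterministic given the seed).
#' @return Character vector of `n` unique 7-character cores (central
#'   lowercase `"r"`).
#' @export
build_non_motif_set <- function(complements, n, seed) {
  sizes <- vapply(complements, length, integer(1))
  if (any(sizes == 0)) stop("empty complement set")
  space <- prod(as.numeric(sizes))
  if (n > space)
    stop("n = ", n, " exceeds the complement space size ", space)
  n_neg <- sum(as.integer(names(complements)) < 0)
  with_seed(seed, {
    acc <- character(0)
    while (length(acc) < n) {
      m <- max(n - length(acc), 64L)
      cols <- lapply(complements, function(s) sample(s, m, replace = TRUE))
      mat <- do.call(cbind, cols)
      full <- cbind(mat[, seq_len(n_neg), drop = FALSE],
                    rep(CIT_CHAR, m),
                    mat[, (n_neg + 1L):length(complements), drop = FALSE])
      acc <- unique(c(acc, apply(full, 1L, paste0, collapse = "")))
    }
    acc[seq_len(n)]
  })
}

#' Flank a 7-mer core with synthesis linkers
#'
#' Array peptides are synthesized with an SG linker at the N-terminus and an
#' SGS linker at the C-terminus to improve epitope accessibility, giving a
#' 12-residue synthesis sequence.
#'
#' @param core Character vector of 7-character cores with the central
#'   citrulline token at position 4.
#' @return Character vector of 12-character synthesis sequences.
#' @export
add_linkers <- function(core) {
  if (any(nchar(core) != 7L))
    stop("cores must be exactly 7 residues long")
  if (any(substr(core, 4L, 4L) != CIT_CHAR))
    stop("core must carry the central citrulline token at position 4")
  paste0("SG", core, "SGS")
}

#' Lay out the full microarray
#'
#' Combines the motif and non-motif core sets into a spot plan: every
#' peptide in `replicates` spots, plus synthesis-control spots and blank
#' (empty) spots, in a seeded random permutation (randomized placement to
#' minimize spatial bias). Defaults mirror a triplicate design with the
#' EDKFVRYVD synthesis control.
#'
#' @param motif_set,non_motif_set Character vectors of unique cores.
#' @param replicates Spots per peptide (default 3).
#' @param control_seq Synthesis-control peptide sequence (default
#'   "EDKFVRYVD").
#' @param n_controls Number of control spots (default 2495).
#' @param n_blanks Number of empty spots (default 2500).
#' @param seed Integer seed for the placement permutation.
#' @return Object of class `array_design`: list with `peptides` (data.frame
#'   peptide_id, core, group), `layout` (data.frame spot_index, kind,
#'   peptide_id), the design parameters and the seed.
#' @export
layout_array <- function(motif_set, non_motif_set = character(0),
                         replicates = 3L, control_seq = "EDKFVRYVD",
                         n_controls = 2495L, n_blanks = 2500L, seed = 1L) {
  stopifnot(replicates >= 1, n_controls >= 0, n_blanks >= 0)
  if (anyDuplicated(motif_set)) stop("duplicate cores in motif_set")
  if (anyDuplicated(non_motif_set)) stop("duplicate cores in non_motif_set")
  if (length(intersect(motif_set, non_motif_set)) > 0)
    stop("motif and non-motif sets overlap")
  peptides <- data.frame(
    peptide_id = c(sprintf("M%05d", seq_along(motif_set)),
                   sprintf("N%05d", seq_along(non_motif_set))),
    core = c(motif_set, non_motif_set),
    group = rep(c("cit_motif", "cit_non_motif"),
                c(length(motif_set), length(non_motif_set))),
    stringsAsFactors = FALSE)
  plan <- data.frame(
    kind = c(rep("peptide", replicates * nrow(peptides)),
             rep("control", n_controls),
             rep("blank", n_blanks)),
    peptide_id = c(rep(peptides$peptide_id, each = replicates),
                   rep(NA_character_, n_controls + n_blanks)),
    stringsAsFactors = FALSE)
  perm <- with_seed(seed, sample.int(nrow(plan)))
  layout <- plan[perm, , drop = FALSE]
  layout <- cbind(spot_index = seq_len(nrow(layout)), layout)
  rownames(layout) <- NULL
  structure(list(peptides = peptides, layout = layout,
                 replicates = as.integer(replicates),
                 control_seq = control_seq,
                 n_controls = as.integer(n_controls),
                 n_blanks = as.integer(n_blanks), seed = seed),
            class = "array_design")
}

#' @export
print.array_design <- function(x, ...) {
  cat("array_design: ", nrow(x$peptides), " unique peptides (",
      sum(x$peptides$group == "cit_motif"), " motif + ",
      sum(x$peptides$group == "cit_non_motif"), " non-motif), ",
      x$replicates, " replicates, ", x$n_controls, " controls, ",
      x$n_blanks, " blanks; ", nrow(x$layout), " spots\n", sep = "")
  invisible(x)
}

#' Export an array design as a GAL-like TSV (and optionally FASTA)
#'
#' Spots are mapped onto an abstract grid (single block by default, row-major
#' with `ncol` columns); the table carries spot_index, block, row, col,
#' kind, peptide_id, group, core and the linker-flanked synthesis sequence.
#'
#' @param design An `array_design`.
#' @param path Output TSV path.
#' @param ncol Grid columns for the index -> (row, col) mapping (default:
#'   ceiling of the square root of the spot count).
#' @return The exported data.frame, invisibly.
#' @export
export_design <- function(design, path, ncol = NULL) {
  lay <- design$layout
  if (is.null(ncol)) ncol <- ceiling(sqrt(nrow(lay)))
  idx0 <- lay$spot_index - 1L
  pep <- design$peptides[match(lay$peptide_id, design$peptides$peptide_id), ]
  synth <- rep(NA_character_, nrow(lay))
  synth[lay$kind == "peptide"] <- add_linkers(pep$core[lay$kind == "peptide"])
  synth[lay$kind == "control"] <- design$control_seq
  out <- data.frame(spot_index = lay$spot_index, block = 1L,
                    row = idx0 %/% ncol + 1L, col = idx0 %% ncol + 1L,
                    kind = lay$kind,
                    peptide_id = ifelse(is.na(lay$peptide_id), "",
                                        lay$peptide_id),
                    group = ifelse(is.na(pep$group),
                                   ifelse(lay$kind == "control", "control",
                                          "blank"),
                                   pep$group),
                    core = ifelse(is.na(pep$core), "", pep$core),
                    synthesis_sequence = ifelse(is.na(synth), "", synth),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Read a design mapping exported by [export_design()]
#'
#' @param path Path to the design TSV.
#' @return data.frame with at least spot_index, kind, peptide_id, group,
#'   core (empty strings restored to NA for non-peptide spots).
#' @export
read_design_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("spot_index", "kind", "peptide_id")
  if (!all(need %in% names(df)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  df
}
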