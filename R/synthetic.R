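# Average amino-acid frequencies of well-annotated protein databases
# (UniProtKB/Swiss-Prot composition statistics), used as the default
# residue distribution for synthetic proteomes.
SWISSPROT_FREQS <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0138,
  Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
  L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
  S = 0.0656, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687)

#' Generate a synthetic background proteome
#'
#' Draws protein lengths from a log-normal distribution (the canonical
#' shape of protein-length distributions; defaults give a median around
#' 350 residues) and residues i.i.d. from the given frequency vector
#' (default: average database composition). Fully deterministic given the
#' seed.
#'
#' @param n_proteins Number of proteins, >= 1.
#' @param meanlog,sdlog Log-normal parameters of the length distribution.
#' @param min_length Minimum protein length (lengths are clamped up).
#' @param residue_freqs Named numeric over the 20 standard residues
#'   (normalized internally).
#' @param seed Integer seed.
#' @return Named character vector of sequences (ids `SYN0001`, ...).
#' @export
generate_proteome <- function(n_proteins, meanlog = log(350), sdlog = 0.45,
                              min_length = 30L,
                              residue_freqs = SWISSPROT_FREQS,
                              seed = 1L) {
  stopifnot(n_proteins >= 1)
  freqs <- residue_freqs[AA_STANDARD]
  stopifnot(!anyNA(freqs), all(freqs >= 0), sum(freqs) > 0)
  freqs <- freqs / sum(freqs)
  with_seed(seed, {
    lens <- pmax(min_length,
                 round(stats::rlnorm(n_proteins, meanlog, sdlog)))
    seqs <- vapply(lens, function(L)
      paste0(sample(AA_STANDARD, L, replace = TRUE, prob = freqs),
             collapse = ""),
      character(1))
    stats::setNames(seqs, sprintf("SYN%04d", seq_len(n_proteins)))
  })
}

#' Plant motif-conforming modification sites into a proteome
#'
#' Chooses non-overlapping window positions across the proteome, sets the
#' central residue to R, and overwrites the flanking residues at the spec's
#' offsets with independent draws from the spec's percent weights — ground
#' truth for motif-recovery experiments. Positions are taken from a
#' disjoint-window grid so no two planted windows interfere.
#'
#' @param proteome Named character vector of sequences.
#' @param spec A `position_weight_spec` (weights used as sampling
#'   probabilities).
#' @param n_sites Number of sites to plant (0 returns the proteome
#'   unchanged with an empty site list).
#' @param seed Integer seed.
#' @param W Window half-width reserved per site (default: max |offset| of
#'   the spec, at least 5).
#' @return List with `proteome` (edited sequences), `sites` (data.frame
#'   protein_id, position, residue = "R") and `spec`.
#' @export
plant_sites <- function(proteome, spec, n_sites, seed, W = NULL) {
  if (is.null(W)) W <- max(5L, max(abs(spec$offsets)))
  span <- 2L * W + 1L
  # disjoint candidate centers: each protein partitioned into span-wide bins
  cand <- do.call(rbind, lapply(names(proteome), function(pid) {
    len <- nchar(proteome[[pid]])
    n_bins <- len %/% span
    if (n_bins < 1) return(NULL)
    data.frame(protein_id = pid,
               position = W + 1L + span * (seq_len(n_bins) - 1L),
               stringsAsFactors = FALSE)
  }))
  if (n_sites == 0)
    return(list(proteome = proteome,
                sites = data.frame(protein_id = character(0),
                                   position = integer(0),
                                   residue = character(0)),
                spec = spec))
  if (is.null(cand) || nrow(cand) < n_sites)
    stop("proteome capacity (", if (is.null(cand)) 0 else nrow(cand),
         " disjoint windows) below n_sites = ", n_sites)
  with_seed(seed, {
    pick <- cand[sample.int(nrow(cand), n_sites), , drop = FALSE]
    for (off in names(spec$residues_at)) {
      df <- spec$residues_at[[off]]
      draws <- sample(df$residue, n_sites, replace = TRUE,
                      prob = df$percent / 100)
      pos <- pick$position + as.integer(off)
      for (i in seq_len(n_sites)) {
        pid <- pick$protein_id[i]
        substr(proteome[[pid]], pos[i], pos[i]) <- draws[i]
      }
    }
    for (i in seq_len(n_sites)) {
      pid <- pick$protein_id[i]
      substr(proteome[[pid]], pick$position[i], pick$position[i]) <- "R"
    }
    sites <- data.frame(protein_id = pick$protein_id,
                        position = pick$position, residue = "R",
                        stringsAsFactors = FALSE)
    rownames(sites) <- NULL
    list(proteome = proteome, sites = sites, spec = spec)
  })
}

#' Position-additive antibody-affinity model
#'
#' The simulated binding signal of a peptide is
#' `base_signal * exp(sum of per-(offset, residue) log-affinity weights)`
#' times multiplicative log-normal replicate noise. Blank spots draw from
#' `LogNormal(blank_mu, blank_sigma)`; control spots sit at a fixed level.
#'
#' @param weights Named list offset -> named numeric (residue ->
#'   log-affinity weight); missing entries mean weight 0.
#' @param base_signal Baseline peptide signal (a.u.), > 0.
#' @param noise_sigma Log-normal sigma of replicate noise, >= 0.
#' @param blank_mu,blank_sigma Log-scale parameters of blank spots.
#' @param control_signal Fixed control-spot level (a.u.).
#' @return Object of class `antibody_model`.
#' @export
antibody_model <- function(weights = list(), base_signal = 500,
                           noise_sigma = 0.3, blank_mu = log(50),
                           blank_sigma = 0.4, control_signal = 5000) {
  stopifnot(base_signal > 0, noise_sigma >= 0, blank_sigma >= 0)
  structure(list(weights = weights, base_signal = base_signal,
                 noise_sigma = noise_sigma, blank_mu = blank_mu,
                 blank_sigma = blank_sigma,
                 control_signal = control_signal),
            class = "antibody_model")
}

#' Motif-aligned antibody model from a position-weight spec
#'
#' Builds log-affinity weights proportional to the spec's percent weights
#' at offsets -3..+3 (scaled so the best residue at each position gains
#' `scale` log units), emulating a clone whose binding preference mirrors
#' the immunization motif.
#'
#' @param spec A `position_weight_spec`.
#' @param scale Log-affinity of the top-weighted residue per offset.
#' @param ... Passed to [antibody_model()].
#' @return An `antibody_model`.
#' @export
motif_antibody_from_spec <- function(spec, scale = 2, ...) {
  offs <- intersect(format_offset(c(-3L, -2L, -1L, 1L, 2L, 3L)),
                    names(spec$residues_at))
  weights <- lapply(spec$residues_at[offs], function(df)
    stats::setNames(scale * df$percent / max(df$percent), df$residue))
  antibody_model(weights = weights, ...)
}

# Deterministic summed log-affinity of a set of cores (0 for a peptide the
# model is indifferent to).
core_log_affinity <- function(cores, model) {
  ls <- rep(0, length(cores))
  cols <- stats::setNames(c(1:3, 5:7), format_offset(c(-3:-1, 1:3)))
  for (off in names(model$weights)) {
    if (!off %in% names(cols)) next
    w <- model$weights[[off]]
    res <- substr(cores, cols[[off]], cols[[off]])
    hit <- res %in% names(w)
    ls[hit] <- ls[hit] + w[res[hit]]
  }
  ls
}

#' Simulate per-spot array fluorescence
#'
#' Every spot of the design receives an F635-style intensity from the
#' antibody model: peptide spots get the model's expected signal with
#' independent multiplicative log-normal noise per replicate, blanks draw
#' from the blank distribution, controls sit at the fixed control level
#' (with the same replicate noise). Deterministic given the seed.
#'
#' @param design An `array_design`.
#' @param model An `antibody_model`.
#' @param seed Integer seed.
#' @return Spot-record data.frame (spot_index, peptide_id, kind, group,
#'   core, f635_mean, flag = 0), one row per design spot.
#' @export
simulate_array <- function(design, model, seed = 1L) {
  lay <- design$layout
  pep <- design$peptides[match(lay$peptide_id, design$peptides$peptide_id), ]
  expected <- rep(NA_real_, nrow(lay))
  is_pep <- lay$kind == "peptide"
  expected[is_pep] <- model$base_signal *
    exp(core_log_affinity(pep$core[is_pep], model))
  expected[lay$kind == "control"] <- model$control_signal
  with_seed(seed, {
    noise <- exp(stats::rnorm(nrow(lay), 0, model$noise_sigma))
    f635 <- expected * noise
    is_blank <- lay$kind == "blank"
    f635[is_blank] <- stats::rlnorm(sum(is_blank), model$blank_mu,
                                    model$blank_sigma)
    data.frame(spot_index = lay$spot_index, peptide_id = lay$peptide_id,
               kind = lay$kind,
               group = ifelse(is.na(pep$group),
                              ifelse(lay$kind == "control", "control",
                                     "blank"),
                              pep$group),
               core = pep$core, f635_mean = f635, flag = 0L,
               stringsAsFactors = FALSE)
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Generates and writes every input the pipeline consumes, with known
#' ground truth: a background proteome (FASTA), motif-planted citrullination
#' sites (TSV), an array design (TSV), simulated spot signals (TSV and GPR
#' dialects) and a JSON truth manifest recording the spec, the antibody
#' model and every seed. Scale `"tiny"` finishes in seconds; `"full"`
#' reproduces the study's design cardinalities (20,480 motif + 44,000
#' non-motif peptides in triplicate, 2,495 controls, 2,500 blanks =
#' 198,435 spots).
#'
#' @param out_dir Output directory (created if needed).
#' @param scale `"tiny"` or `"full"`.
#' @param seed Master seed; per-stage seeds are derived from it and recorded
#'   in the manifest.
#' @return Named list of written file paths, invisibly.
#' @export
make_fixture_bundle <- function(out_dir, scale = c("tiny", "full"),
                                seed = 1L) {
  scale <- match.arg(scale)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- immunogen_pool_spec()
  seeds <- list(proteome = seed, sites = seed + 1L, non_motif = seed + 2L,
                layout = seed + 3L, signals = seed + 4L)
  if (scale == "tiny") {
    prot <- generate_proteome(40, seed = seeds$proteome)
    planted <- plant_sites(prot, spec, n_sites = 60, seed = seeds$sites)
    motif <- build_motif_set(spec, plus1_all20 = FALSE)[1:200]
    nm <- build_non_motif_set(array_complements(spec), 200,
                              seed = seeds$non_motif)
    design <- layout_array(motif, nm, replicates = 3, n_controls = 25,
                           n_blanks = 25, seed = seeds$layout)
  } else {
    prot <- generate_proteome(400, seed = seeds$proteome)
    planted <- plant_sites(prot, spec, n_sites = 5000, seed = seeds$sites)
    motif <- build_motif_set(spec, plus1_all20 = TRUE)
    nm <- build_non_motif_set(array_complements(spec), 44000,
                              seed = seeds$non_motif)
    design <- layout_array(motif, nm, replicates = 3, n_controls = 2495,
                           n_blanks = 2500, seed = seeds$layout)
  }
  model <- motif_antibody_from_spec(spec)
  spots <- simulate_array(design, model, seed = seeds$signals)
  paths <- list(
    proteome = file.path(out_dir, "proteome.fasta"),
    sites = file.path(out_dir, "sites.tsv"),
    design = file.path(out_dir, "design.tsv"),
    signals_tsv = file.path(out_dir, "signals.tsv"),
    signals_gpr = file.path(out_dir, "signals.gpr"),
    manifest = file.path(out_dir, "truth.json"))
  write_proteome_fasta(planted$proteome, paths$proteome)
  utils::write.table(planted$sites, paths$sites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  export_design(design, paths$design)
  write_spot_table(spots, paths$signals_tsv)
  write_gpr(spots, paths$signals_gpr)
  manifest <- list(
    scale = scale, master_seed = seed, seeds = seeds,
    n_proteins = length(prot), n_sites = nrow(planted$sites),
    n_motif = length(motif), n_non_motif = length(nm),
    replicates = design$replicates, n_controls = design$n_controls,
    n_blanks = design$n_blanks, n_spots = nrow(design$layout),
    spec = lapply(spec$residues_at, function(df)
      stats::setNames(as.list(df$percent), df$residue)),
    antibody_model = list(base_signal = model$base_signal,
                          noise_sigma = model$noise_sigma,
                          blank_mu = model$blank_mu,
                          blank_sigma = model$blank_sigma,
                          control_signal = model$control_signal,
                          weights = lapply(model$weights, as.list)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
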