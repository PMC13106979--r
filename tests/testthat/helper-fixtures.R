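# Shared fixture builders: everything is generated in code at test time.

# A minimal two-position spec (sizes 2 x 3).
toy_spec <- function() {
  position_weight_spec(list(
    `-1` = data.frame(residue = c("D", "S"), percent = c(60L, 40L)),
    `1` = data.frame(residue = c("G", "A", "Y"),
                     percent = c(50L, 30L, 20L))))
}

# Write a FASTA file from named sequences; returns the path.
write_tmp_fasta <- function(seqs) {
  path <- tempfile("prot", fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), path)
  path
}

# Brute-force binomial tail oracle by explicit pmf summation, independent
# of pbinom: pmf from choose() and powers.
pmf_tail_oracle <- function(k, n, q, tail) {
  j <- 0:n
  pmf <- choose(n, j) * q^j * (1 - q)^(n - j)
  if (tail == "over") sum(pmf[j >= k]) else sum(pmf[j <= k])
}

# Site windows built directly from residue strings (bypasses a proteome):
# each string covers offsets -W..-1,+1..+W left to right.
windows_from_strings <- function(flanks, W) {
  mat <- do.call(rbind, strsplit(flanks, ""))
  colnames(mat) <- citmotif:::format_offset(c(-W:-1, 1:W))
  structure(list(residues = mat, offsets = c(-W:-1, 1:W),
                 sites = data.frame(protein_id = paste0("P", seq_along(flanks)),
                                    position = W + 1L, residue = "R"),
                 n_excluded = 0L,
                 exclusions = data.frame()),
            class = "site_windows")
}

# A uniform background over the 20 standard residues.
uniform_background <- function() {
  structure(list(residue_freq = stats::setNames(rep(0.05, 20), AA_STANDARD),
                 residue_counts = stats::setNames(rep(1L, 20), AA_STANDARD),
                 source = "proteome_global"),
            class = "background_model")
}
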