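test_that("read_proteome parses ids, rejects duplicates and empty files", {
  path <- write_tmp_fasta(list("P1 some description" = "ACDEF",
                               P2 = "GHIKLMNPQR"))
  prot <- read_proteome(path)
  expect_length(prot, 2)
  expect_named(prot, c("P1", "P2"))
  expect_equal(unname(prot["P1"]), "ACDEF")

  dup <- write_tmp_fasta(list(P1 = "ACDEF", "P1 again" = "GHIKL"))
  expect_error(read_proteome(dup), "duplicate")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_proteome(empty), "empty|FASTA")
})

test_that("read_proteome flags non-standard letters but keeps them", {
  path <- write_tmp_fasta(list(P1 = "ACDXU", P2 = "GHIKL"))
  prot <- read_proteome(path)
  expect_equal(unname(prot["P1"]), "ACDXU")
  expect_equal(attr(prot, "nonstandard"), c(P1 = 2L))
})

test_that("extract_windows pads termini and excludes mismatching sites", {
  prot <- c(P1 = "GSRYE", P2 = "RAAAA")
  sites <- data.frame(protein_id = c("P1", "P2", "P1"),
                      position = c(3L, 1L, 2L),
                      residue = c("R", "R", "R"))
  w <- extract_windows(prot, sites, W = 2)
  expect_equal(colnames(w$residues), c("-2", "-1", "+1", "+2"))
  # interior site: plain flanks
  expect_equal(unname(w$residues[1, ]), c("G", "S", "Y", "E"))
  # N-terminal site: upstream offsets padded
  expect_equal(unname(w$residues[2, ]), c("-", "-", "A", "A"))
  # position 2 of P1 holds S, not R -> excluded, counted
  expect_equal(nrow(w$residues), 2)
  expect_equal(w$n_excluded, 1)
  expect_match(w$exclusions$reason, "mismatch")
})

test_that("extract_windows rejects unknown proteins unless strict = FALSE", {
  prot <- c(P1 = "GSRYE")
  sites <- data.frame(protein_id = "nope", position = 1L, residue = "R")
  expect_error(extract_windows(prot, sites, W = 2), "unknown protein")
  w <- extract_windows(prot, sites, W = 2, strict = FALSE)
  expect_equal(nrow(w$residues), 0)
  expect_equal(w$n_excluded, 1)
})

test_that("background frequencies equal hand counts, with pseudocount floor", {
  # 2-protein toy: A x 5, C x 2, D x 2, E x 1 over 10 residues
  bg <- background_from_proteome(c(P1 = "AACDA", P2 = "ACDEA"))
  expect_s3_class(bg, "background_model")
  expect_equal(sum(bg$residue_freq), 1, tolerance = 1e-12)
  expect_equal(bg$residue_counts[["A"]], 5L)
  expect_equal(bg$residue_counts[["C"]], 2L)
  expect_equal(bg$residue_counts[["E"]], 1L)
  # absent residues floored at 0.5/total, never zero
  expect_true(all(bg$residue_freq > 0))
  expect_equal(unname(bg$residue_freq["W"] / bg$residue_freq["C"]),
               0.5 / 2, tolerance = 1e-9)
  # equal-composition proteome: q = 0.05 everywhere
  bg2 <- background_from_proteome(paste(AA_STANDARD, collapse = ""))
  expect_equal(unname(bg2$residue_freq), rep(0.05, 20), tolerance = 1e-12)
  # non-standard letters excluded from numerator and denominator
  bg3 <- background_from_proteome(c(P1 = "AAXXBA"))
  expect_equal(bg3$residue_counts[["A"]], 3L)
  expect_error(background_from_proteome("XXX"), "no standard")
})

test_that("binomial_tail matches closed forms and rejects bad input", {
  expect_equal(binomial_tail(0, 5, 0.3, "over"), 1.0)
  expect_equal(binomial_tail(5, 5, 0.5, "over"), 0.5^5)
  expect_equal(binomial_tail(5, 5, 0.5, "under"), 1.0)
  expect_error(binomial_tail(6, 5, 0.5, "over"), "k must")
  expect_error(binomial_tail(1, 5, 0, "over"), "q must")
  expect_error(binomial_tail(1, 5, 1, "over"), "q must")
})

test_that("binomial_tail agrees with brute-force pmf summation on a grid", {
  for (n in c(1, 2, 5, 10, 25, 50)) {
    for (q in c(0.01, 0.05, 0.3, 0.5, 0.9)) {
      ks <- unique(round(seq(0, n, length.out = 7)))
      for (k in ks) {
        for (tail in c("over", "under")) {
          expected <- pmf_tail_oracle(k, n, q, tail)
          got <- binomial_tail(k, n, q, tail)
          expect_equal(got, expected, tolerance = 1e-9,
                       label = sprintf("tail(%d,%d,%g,%s)", k, n, q, tail))
        }
      }
    }
  }
})

test_that("binomial tails are monotone in k and share the point mass", {
  p_over <- binomial_tail(0:20, 20, 0.3, "over")
  p_under <- binomial_tail(0:20, 20, 0.3, "under")
  expect_true(all(diff(p_over) <= 1e-15))
  expect_true(all(diff(p_under) >= -1e-15))
  expect_true(all(p_over + p_under >= 1 - 1e-12))
})

test_that("compute_enrichment reproduces a hand-computed cell", {
  # 8 windows; G at offset -1 in 6 of them, rest distinct residues
  flanks <- c("GA", "GC", "GD", "GE", "GF", "GH", "IA", "KC")
  w <- windows_from_strings(flanks, W = 1)
  bg <- uniform_background()
  bg$residue_freq[] <- 0.05
  bg$residue_freq["G"] <- 0.07
  bg$residue_freq <- bg$residue_freq / sum(bg$residue_freq)
  tab <- compute_enrichment(w, bg, alpha = 0.05)
  cell <- tab[tab$offset == "-1" & tab$residue == "G", ]
  q_g <- unname(bg$residue_freq["G"])
  expect_equal(cell$k, 6L)
  expect_equal(cell$n, 8L)
  expect_equal(cell$p_over, pmf_tail_oracle(6, 8, q_g, "over"),
               tolerance = 1e-12)
  expect_equal(attr(tab, "n_tests"), 40L)  # 20 residues x 2 offsets
  expect_equal(cell$significant,
               cell$p_over < 0.05 / 40)
  expect_gt(cell$score, 0)
})

test_that("counts are conserved per offset and pads never counted", {
  w <- windows_from_strings(c("-A", "GA", "GC"), W = 1)
  tab <- compute_enrichment(w, uniform_background())
  for (off in unique(tab$offset)) {
    sub <- tab[tab$offset == off, ]
    expect_equal(sum(sub$k), sub$n[1])
  }
  expect_equal(tab$n[tab$offset == "-1"][1], 2L)  # pad excluded
  expect_equal(tab$n[tab$offset == "+1"][1], 3L)
})

test_that("a single window gives k in {0,1} and sums to 1 per offset", {
  w <- windows_from_strings("GD", W = 1)
  tab <- compute_enrichment(w, uniform_background())
  expect_true(all(tab$k %in% 0:1))
  sums <- tapply(tab$k, tab$offset, sum)
  expect_equal(as.integer(sums[c("-1", "+1")]), c(1L, 1L))
})

test_that("fully padded offsets are reported with n = 0 and no tests", {
  w <- windows_from_strings(c("-A", "-C"), W = 1)
  tab <- compute_enrichment(w, uniform_background())
  sub <- tab[tab$offset == "-1", ]
  expect_true(all(sub$n == 0))
  expect_true(all(is.na(sub$p_over)))
  expect_false(any(sub$significant))
  # n_tests counts only scored offsets
  expect_equal(attr(tab, "n_tests"), 20L)
})

test_that("select_motif_residues renormalizes foreground frequencies", {
  # make G and S overwhelmingly frequent at -1 so both are significant
  flanks <- c(rep("GA", 9), rep("SC", 3))
  w <- windows_from_strings(flanks, W = 1)
  bg <- uniform_background()
  bg$residue_freq[] <- c(0.01)
  bg$residue_freq[c("A", "C")] <- 0.455
  bg$residue_freq <- bg$residue_freq / sum(bg$residue_freq)
  tab <- compute_enrichment(w, bg, alpha = 0.05)
  spec <- select_motif_residues(tab)
  expect_true("-1" %in% names(spec$residues_at))
  sel <- spec$residues_at[["-1"]]
  expect_setequal(sel$residue, c("G", "S"))
  expect_equal(sel$percent[sel$residue == "G"], 75L)  # 9 of 12 selected
  expect_equal(sel$percent[sel$residue == "S"], 25L)  # 3 of 12 selected
  expect_equal(sum(sel$percent), 100L)
})

test_that("no significant residues anywhere yields an empty spec", {
  w <- windows_from_strings(c("GA", "SC"), W = 1)
  tab <- compute_enrichment(w, uniform_background())
  spec <- select_motif_residues(tab)
  expect_length(spec$offsets, 0)
  expect_equal(library_size(spec), 1)
})

test_that("window-empirical background reflects window composition", {
  w <- windows_from_strings(c("GG", "GA"), W = 1)
  bg <- background_from_windows(w)
  expect_equal(bg$source, "window_empirical")
  expect_equal(bg$residue_counts[["G"]], 3L)
  expect_equal(bg$residue_counts[["A"]], 1L)
  expect_equal(sum(bg$residue_freq), 1, tolerance = 1e-12)
})

test_that("enrichment tables round-trip through TSV", {
  w <- windows_from_strings(c("GA", "GC", "GD"), W = 1)
  tab <- compute_enrichment(w, uniform_background())
  path <- tempfile(fileext = ".tsv")
  write_enrichment(tab, path)
  back <- read_enrichment(path)
  expect_equal(back$k, tab$k)
  expect_equal(back$p_over, tab$p_over, tolerance = 1e-12)
  expect_equal(back$significant, tab$significant)
})

test_that("largest-remainder percents sum exactly to 100", {
  expect_equal(largest_remainder_percents(c(1, 1, 1)), c(34L, 33L, 33L))
  expect_equal(sum(largest_remainder_percents(c(6, 2))), 100L)
  expect_equal(largest_remainder_percents(c(6, 2)), c(75L, 25L))
  for (i in 1:20) {
    w <- runif(sample(2:8, 1))
    expect_equal(sum(largest_remainder_percents(w)), 100L)
  }
})
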