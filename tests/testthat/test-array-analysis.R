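# Small simulated design + signals shared across blocks.
tiny_array <- function(seed = 21) {
  spec <- immunogen_pool_spec()
  motif <- build_motif_set(spec, plus1_all20 = FALSE)[1:120]
  nm <- build_non_motif_set(array_complements(spec), 80, seed = seed)
  design <- layout_array(motif, nm, replicates = 3, n_controls = 5,
                         n_blanks = 10, seed = seed)
  model <- motif_antibody_from_spec(spec, scale = 2)
  spots <- simulate_array(design, model, seed = seed + 1)
  list(spec = spec, design = design, model = model, spots = spots)
}

test_that("a minimal GPR file parses via its F635 Mean header", {
  path <- tempfile(fileext = ".gpr")
  writeLines(c("ATF\t1.0", "2\t4",
               '"Type=GenePix Results 3"', '"Wavelengths=635"',
               paste0('"Block"\t"Column"\t"Row"\t"ID"\t"F635 Mean"\t"Flags"'),
               "1\t1\t1\tpepA\t100.5\t0",
               "1\t2\t1\tpepB\t250\t0",
               "1\t3\t1\tblank\t12\t-100"), path)
  spots <- read_spot_table(path, design = NULL, dialect = "gpr")
  expect_equal(nrow(spots), 3)
  expect_equal(spots$f635_mean, c(100.5, 250, 12))
  expect_equal(spots$flag, c(0L, 0L, -100L))
  expect_equal(spots$spot_index, 1:3)
})

test_that("a TSV without the intensity column is rejected", {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(spot_index = 1:2, value = c(1, 2)),
                     path, sep = "\t", row.names = FALSE)
  expect_error(read_spot_table(path, dialect = "tsv"), "f635_mean")
})

test_that("simulated signals join the design with full coverage", {
  ta <- tiny_array()
  tsv <- tempfile(fileext = ".tsv")
  write_spot_table(ta$spots, tsv)
  spots <- read_spot_table(tsv, design = ta$design, dialect = "tsv")
  expect_equal(attr(spots, "n_unmatched"), 0L)
  expect_equal(nrow(spots), nrow(ta$design$layout))
  expect_equal(sum(spots$kind == "peptide"), 3 * 200)
  # GPR dialect round trip against the same design
  gpr <- tempfile(fileext = ".gpr")
  write_gpr(ta$spots, gpr)
  spots2 <- read_spot_table(gpr, design = ta$design, dialect = "gpr")
  expect_equal(attr(spots2, "n_unmatched"), 0L)
  expect_equal(spots2$f635_mean, spots$f635_mean, tolerance = 1e-8)
})

test_that("spot tables round-trip losslessly through the TSV dialect", {
  ta <- tiny_array()
  tsv <- tempfile(fileext = ".tsv")
  write_spot_table(ta$spots, tsv)
  back <- read_spot_table(tsv, design = NULL, dialect = "tsv")
  expect_equal(back$f635_mean, ta$spots$f635_mean, tolerance = 1e-10)
  expect_equal(back$peptide_id, ta$spots$peptide_id)
})

test_that("replicate summaries average valid spots and drop flagged ones", {
  spots <- data.frame(
    spot_index = 1:7,
    peptide_id = c("p1", "p1", "p1", "p2", "p2", "p2", "p3"),
    kind = "peptide", group = "cit_motif", core = "AAArAAA",
    f635_mean = c(100, 110, 120, 100, 110, 999, 50),
    flag = c(0L, 0L, 0L, 0L, 0L, -50L, -100L))
  s <- summarize_replicates(spots)
  expect_equal(s$mean_signal[s$peptide_id == "p1"], 110)
  expect_equal(s$n_valid[s$peptide_id == "p1"], 3L)
  expect_equal(s$mean_signal[s$peptide_id == "p2"], 105)
  expect_equal(s$n_valid[s$peptide_id == "p2"], 2L)
  # p3's only replicate is flagged: excluded and counted
  expect_false("p3" %in% s$peptide_id)
  expect_equal(attr(s, "n_excluded"), 1L)
})

test_that("group distributions order as motif > non-motif > blank", {
  ta <- tiny_array()
  summ <- summarize_replicates(ta$spots)
  gd <- group_distributions(summ, ta$spots)
  med <- stats::setNames(gd$median, gd$group)
  expect_gt(med["cit_motif"], med["cit_non_motif"])
  expect_gt(med["cit_non_motif"], med["blank"])
  expect_equal(gd$n[gd$group == "cit_motif"], 120L)
  expect_equal(gd$n[gd$group == "blank"], 10L)
})

test_that("median conventions match stats::median", {
  summ <- data.frame(peptide_id = paste0("p", 1:5), core = "AAArAAA",
                     group = "g", mean_signal = c(1, 2, 3, 4, 5),
                     n_valid = 3L, cv = 0.1)
  gd <- group_distributions(summ)
  expect_equal(gd$median, 3)
  gd1 <- group_distributions(summ[3, ])
  expect_equal(gd1$median, 3)
  empty <- group_distributions(summ[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("strong-binder selection takes floor(q*n) with deterministic ties", {
  summ <- data.frame(peptide_id = sprintf("p%03d", 1:100),
                     core = "AAArAAA", group = "g",
                     mean_signal = sample(1:100), n_valid = 3L, cv = 0.1)
  sel <- select_strong_binders(summ, q = 0.25)
  expect_equal(sel$n_selected, 25L)
  top25 <- summ$peptide_id[order(-summ$mean_signal)][1:25]
  expect_setequal(sel$selected, top25)
  expect_true(all(summ$mean_signal[match(sel$selected, summ$peptide_id)] >=
                    sel$threshold))
  # all-tied signals: lowest peptide ids win at the boundary
  tied <- data.frame(peptide_id = sprintf("p%d", 1:8), core = "AAArAAA",
                     group = "g", mean_signal = 7, n_valid = 3L, cv = 0)
  sel2 <- select_strong_binders(tied, q = 0.25)
  expect_equal(sel2$n_selected, 2L)
  expect_equal(sort(sel2$selected), c("p1", "p2"))
  expect_error(select_strong_binders(summ, q = 0), "0, 1")
  expect_error(select_strong_binders(summ, q = 1.2), "0, 1")
  expect_error(select_strong_binders(tied[1:3, ], q = 0.25), "too few")
})

test_that("selected fraction stays within [q - 1/n, q]", {
  for (n in c(10, 33, 64, 101)) {
    summ <- data.frame(peptide_id = sprintf("p%04d", 1:n),
                       core = "AAArAAA", group = "g",
                       mean_signal = seq_len(n), n_valid = 3L, cv = 0)
    sel <- select_strong_binders(summ, q = 0.25)
    frac <- sel$n_selected / n
    expect_lte(frac, 0.25)
    expect_gte(frac, 0.25 - 1 / n)
  }
})

test_that("selection of every peptide yields no significant enrichment", {
  ta <- tiny_array()
  summ <- summarize_replicates(ta$spots)
  sel <- select_strong_binders(summ, q = 0.25)
  sel$selected <- summ$peptide_id
  sel$n_selected <- nrow(summ)
  tab <- binder_enrichment(sel, summ)
  expect_false(any(tab$significant))
})

test_that("a single-peptide selection computes but cannot reach significance", {
  ta <- tiny_array()
  summ <- summarize_replicates(ta$spots)
  sel <- select_strong_binders(summ, q = 0.25)
  sel$selected <- sel$selected[1]
  sel$n_selected <- 1L
  tab <- binder_enrichment(sel, summ)
  expect_true(all(tab$n == 1))
  expect_false(any(tab$significant))
})

test_that("control normalization rescales without reordering", {
  ta <- tiny_array()
  norm <- normalize_to_controls(ta$spots, target = 1000)
  ctrl <- norm$f635_mean[norm$kind == "control"]
  expect_equal(mean(ctrl), 1000, tolerance = 1e-9)
  expect_equal(order(norm$f635_mean), order(ta$spots$f635_mean))
  expect_error(normalize_to_controls(ta$spots[ta$spots$kind == "blank", ]),
               "no valid control")
})

test_that("binder enrichment flags a planted +1 preference as top cell", {
  spec <- immunogen_pool_spec()
  motif <- build_motif_set(spec, plus1_all20 = TRUE)
  set.seed(31)
  motif <- sample(motif, 4000)
  model <- antibody_model(weights = list(`+1` = c(D = 2)),
                          noise_sigma = 0.2)
  design <- layout_array(motif, character(0), replicates = 3,
                         n_controls = 0, n_blanks = 0, seed = 31)
  spots <- simulate_array(design, model, seed = 32)
  summ <- summarize_replicates(spots)
  sel <- select_strong_binders(summ, q = 0.25)
  tab <- binder_enrichment(sel, summ)
  top <- tab[which.max(tab$score), ]
  expect_equal(top$offset, "+1")
  expect_equal(top$residue, "D")
  expect_true(top$significant)
})
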