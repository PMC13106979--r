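---
title: "Motif-guided design and analysis of anti-citrulline antibody experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-guided design and analysis of anti-citrulline antibody experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citmotif)
```

## Scope

Citrullination converts peptidyl-arginine to peptidyl-citrulline
(monoisotopic shift +0.9840 Da), and peptidylarginine deiminases (PADs) do
so with sequence preferences around the modified arginine. `citmotif`
implements the computational pipeline that supports motif-guided
development of anti-pan-citrulline antibodies:

1. **Motif enrichment** — position-specific residue enrichment around
   modification sites by exact binomial tail tests against a proteome
   background, with Bonferroni correction (the pLogo-style statistic).
2. **Immunogen design** — a position-weight specification (ordered residue
   sets with integer percent weights per flanking offset) and the weighted
   combinatorial peptide pool it induces.
3. **Array design** — exhaustive motif-group 7-mer cores, randomized
   complement ("non-motif") cores, linkers, replicates, controls, blanks
   and a seeded placement permutation.
4. **Array analysis** — replicate summarization of F635-style per-spot
   intensities, group distributions, top-quantile strong-binder selection
   and motif reconstruction by enrichment against all tested peptides.
5. **Modification levels** — count- and intensity-weighted fractions of
   modified peptides from peptide-level search outputs, and modification
   mass deltas from elemental composition.
6. **Synthetic data** — seeded generators for proteomes, motif-planted
   sites and simulated array fluorescence with known ground truth.

## The enrichment model

For windows of `W` residues on each side of a modified site (default
`W = 5`; terminus overhangs carry a pad token and are never counted), each
(offset, residue) cell holds a count `k` out of `n_p` non-pad windows. With
background probability `q_r`, both one-sided exact binomial tails are
computed:

- over-representation: `P(X >= k)`, `X ~ Binomial(n_p, q_r)`
- under-representation: `P(X <= k)`

via `stats::pbinom` (exact; log-space for the reported scores, so extreme
cells keep finite magnitudes). The signed score is `-log10 p_over` when the
over tail is smaller, and `log10 p_under` (negative) when the under tail
is smaller; a tie scores 0. Significance uses Bonferroni with
`n_tests = 20 residues x (number of scored offsets)`; each one-sided tail
is compared to `alpha / n_tests`. The denominator is a design choice: it
matches per-residue-per-position testing, and offsets where every window is
padded are reported with `n_p = 0` and not counted as tests.

Two backgrounds are supported. The default, `proteome_global`, uses the
position-independent residue frequencies of the supplied proteome, which is
the natural reading of testing "against the proteome"; `window_empirical`
(frequencies pooled over the windows themselves) is available when the
sampled windows are the more honest comparison population. Absent residues
are floored at a pseudocount of `0.5 / total residues` and renormalized so
every `q` lies strictly in (0, 1) — degenerate toy proteomes must not
produce zero-probability tests.

`select_motif_residues` keeps, per offset, the significantly
over-represented residues and converts their foreground frequencies
(renormalized over the selected set) to integer percents by
largest-remainder rounding, which is the only rounding rule that guarantees
the printed percents sum to exactly 100.

## The immunogen pool and its combinatorics

The packaged design table (`immunogen_pool_spec()`) has offsets -4..-1 and
+1..+5 around a central citrulline with residue-set sizes
(4,4,4,4 | 4,4,4,5,6), so the unique-peptide count is

```{r}
library_size(immunogen_pool_spec())
```

`enumerate_library` materializes the pool deterministically (offset-major,
residues in listed order); `sample_library` draws positions independently
with probability `percent / 100`, with replacement by default because a
synthesis pool is a weighted mixture, not a set (`distinct = TRUE` switches
to rejection-based unique sampling). Internally a central citrulline is the
lowercase token `"r"`; plain-text exports always render it as `"R"` plus a
modification annotation (or the inline dialect `"R[cit]"`), never a bare
arginine.

## Array design

The motif core set is the Cartesian product of the spec's residue sets at
-3..+3 with the +1 position opened to all 20 amino acids (20,480 cores for
the packaged spec). The non-motif set samples uniformly from the per-offset
complements — 20 standard residues minus the motif set at that offset, and
at +1 the complement of the enriched residues {G, S, A, D} — so disjointness
from the motif set holds at every position by construction; rejection
sampling enforces uniqueness and a seed makes the set reproducible. Cores
are flanked `SG` + core + `SGS` for synthesis. `layout_array` plans
`replicates x peptides + controls + blanks` spots and permutes them with a
seeded shuffle; geometry is abstract (a 1-D spot index), with a grid writer
mapping index to (block, row, col) because no physical grid is assumed.
Complements include cysteine by default; `global_exclude = c("C", "V")`
reproduces the more conservative ELISA-pool alphabet.

## Array analysis

Per-spot tables are read either as plain TSV or in the GPR dialect
(header-keyed on the `F635 Mean` column; `Flags` and `ID` honoured when
present). A peptide's binding strength is the arithmetic mean of its valid
replicates (flag 0, non-negative intensity); peptides with no valid
replicate are excluded and counted. No normalization is applied by default
— raw means are the readout. Strong binders are the top quantile
(`q = 0.25`) of all tested peptides irrespective of group:
`n_selected = floor(q * n)`, ranked by mean signal with boundary ties
broken by ascending peptide id, a deterministic rule chosen because the
quartile alone does not define tie handling.

Motif reconstruction (`binder_enrichment`) reuses the binomial machinery
with the selected cores as foreground and, as background, the per-offset
residue composition of *all* tested cores — the tested library is
deliberately non-uniform, so a proteome background would mis-state
enrichment.

## Modification levels and mass deltas

`percent_modified` reports four numbers: the modified fraction of
target-residue-containing peptides and of all peptides, by unique-peptide
count and by summed intensity. A peptide is "modified" if it carries at
least one valid modification of the queried type (multiple sites count
once); when no peptide contains the target residue the target-based
fractions are `NA`, not 0. Unique peptide entries are the counting unit
(rather than PSMs); callers aggregating PSM tables should collapse first.
Mass deltas are recomputed from elemental composition with standard
monoisotopic masses — citrullination (and deamidation, the identical
composition change) `+O -N -H = +0.9840 Da`, carbamylation
`+H +C +N +O = +43.0058 Da`.

## The synthetic-data generator

Synthetic proteomes draw protein lengths from a log-normal (median ≈ 350
residues) and residues i.i.d. from average database composition.
`plant_sites` overwrites flanks at the spec's offsets with weighted draws
and sets the center to R, on a disjoint-window grid so planted windows
never overlap. Array signals follow a multiplicative model — the standard
shape for fluorescence — with position-additive log-affinities:
`signal = base * exp(sum of weights) * LogNormal(0, sigma)`; blanks are
log-normal, controls a fixed level. Every stochastic step takes an explicit
seed, and fixture bundles record all seeds in a JSON manifest.

What the simulation does *not* emulate: spatial gradients and scanner
saturation, inter-array scale differences, antibody avidity effects and
sequence-context interactions beyond position additivity. Passing
recovery tests therefore demonstrates correctness of the statistics and
the pipeline plumbing under a position-independent binding model, not
robustness to real-array artifacts.

## Verification choices and problem sizes

- **Binomial tails** are checked against explicit probability-mass
  summation on a grid up to `n = 50` (relative error < 1e-9).
- **Null calibration**: 200 simulated null datasets (50 windows, `W = 2`);
  the fraction of Bonferroni-significant cells stays at or below alpha.
- **Motif recovery**: 5,000 planted sites in a 5,500-protein synthetic
  proteome (~1.9M residues), seeds 1–5. The proteome is sized so the
  planted residues (~45k) shift the global background by only a few
  percent; recovery of the packaged design table is then exact at every
  offset. Smaller proteomes visibly distort the background — a useful
  reminder that the enrichment statistic compares against whatever
  proteome you hand it.
- **Binder recovery** is asserted for an antibody with strictly ranked
  (distinct) per-residue weights: a full preference *ranking* is only
  defined when preferences differ, and tied weights cap the achievable
  rank correlation below 1 by rank arithmetic alone. With distinct weights
  the reconstructed scores match the planted ranking (Spearman >= 0.9 per
  offset, and across all 20 residues at the exhaustive +1 position), and
  the top-scoring residue per offset equals the planted argmax.
- **Full-scale selection**: at the design's cardinality (64,480 peptides in
  triplicate, 2,495 controls, 2,500 blanks = 198,435 spots) the selection
  rule yields `floor(0.25 x 64,480) = 16,120` strong binders. Published
  strong-binder counts from real arrays can differ when additional QC
  filtering changes the denominator; this package reports the stated rule's
  count together with the denominator it used.

## Known limitations

- Enrichment assumes positional independence; no interaction terms.
- Logo rendering (visual scaling of residue heights) is out of scope; the
  exported signed scores are the statistic a logo would draw.
- `library_size` is exact up to 2^53 (double precision), far beyond any
  synthesizable pool.
- The GPR reader handles header-keyed text tables only, not binary ATF
  variants.
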