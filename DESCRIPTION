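Package: citmotif
Title: Citrullination Motif Analysis, Combinatorial Immunogen Design and
    Peptide-Microarray Epitope Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the computational side of motif-guided anti-citrulline
    antibody development: position-specific residue enrichment around
    post-translational modification sites by exact binomial tail tests with
    Bonferroni correction, design of weighted combinatorial immunogen peptide
    libraries from position-weight specifications, construction of
    motif/non-motif peptide-microarray content with replicate, control and
    blank spots, analysis of per-spot fluorescence tables with top-quantile
    strong-binder selection and motif reconstruction, modification-level
    summaries over peptide-level mass-spectrometry search results, and a
    fully seeded synthetic-data generator providing ground-truth inputs for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
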