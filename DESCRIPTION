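Package: corneoquant
Title: Reference-Protein Normalised Quantification and Differential
    Analysis of Stratum Corneum Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Label-free quantification and paired differential analysis of
    tape-strip stratum corneum proteomes from a two-arm contralateral
    (left/right leg) clinical design. Peptide intensities are rolled up to
    per-protein peptide peak intensities (PPI), normalised by per-sample
    weights derived from the most abundant (standard) protein, and
    log10-transformed into a protein amount index (PAI). Proteins discordant
    between arms at baseline are removed by a count-based 95 percent
    concordance filter; per-arm baseline-to-day-14 fold changes are tested
    with exact paired Wilcoxon signed-rank tests and Storey q-values, and
    summarised by fold-change quadrant, between-arm fold-change ratio and
    functional group. Includes a synthetic study generator with planted
    ground truth, clinical endpoint statistics (observer dryness score,
    conductance, immunofluorescence), and a deterministic end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Normalization,
    DifferentialExpression, Software
RoxygenNote: 7.3.3
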