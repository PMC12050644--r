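# Shared fixtures and independent oracles.

# Two-sided signed-rank p by full enumeration of all 2^n sign assignments
# of the (ranked) absolute differences; independent of the package's
# signed-rank code path. Zeros must already be removed; valid for any
# rank pattern (ties included).
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# A noise-free two-subject, two-protein study built by hand: protein STD is
# the constant standard, protein TGT carries an optional per-arm day14
# effect. Returns the peptide and design tables.
handStudy <- function(tgtEffect = c(lotion = 0, lotion_ff = 0),
                      nSubjects = 2L, stdPPI = 1000, tgtPPI = 100) {
  subs <- sprintf("S%02d", seq_len(nSubjects))
  design <- expand.grid(timepoint = c("baseline", "day14"),
                        arm = c("lotion", "lotion_ff"), subject_id = subs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample_id <- paste(design$subject_id, design$arm, design$timepoint,
                            sep = "_")
  design$leg <- "left"
  design <- design[, c("sample_id", "subject_id", "arm", "timepoint", "leg")]
  pep <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    fc <- if (design$timepoint[i] == "day14")
      10^tgtEffect[[design$arm[i]]] else 1
    data.frame(
      peptide_id = paste0(c("STD_p1", "STD_p2", "TGT_p1"), "_", i),
      protein_id = c("STD", "STD", "TGT"),
      sample_id = design$sample_id[i],
      intensity = c(stdPPI * 0.6, stdPPI * 0.4, tgtPPI * fc),
      stringsAsFactors = FALSE)
  }))
  # peptide ids must be stable across samples for round-trips; rebuild
  pep$peptide_id <- sub("_[0-9]+$", "", pep$peptide_id)
  pep$peptide_id <- paste(pep$peptide_id, pep$sample_id, sep = ".")
  list(peptides = pep, design = design)
}

# Small clean generator config: no noise sources unless asked for.
cleanConfig <- function(..., noiseSd = 0, sampleScaleSd = 0, missingRate = 0,
                        nProteins = 15L, nSubjects = 4L, seed = 101L) {
  generatorConfig(nProteins = nProteins, nSubjects = nSubjects,
                  noiseSd = noiseSd, sampleScaleSd = sampleScaleSd,
                  missingRate = missingRate, seed = seed, ...)
}
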