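# Synthetic two-arm contralateral tape-strip studies with planted ground
# truth. Everything downstream of the MS search engine is emulated: a
# long-form peptide intensity table, the sample design, clinical endpoint
# records, and a truth table of planted effects.

#' Configuration of a synthetic stratum corneum study
#'
#' Describes a two-arm (lotion vs lotion + fine-fiber film), two-timepoint
#' (baseline, day 14) contralateral study on the log10 intensity scale.
#' Per-protein per-sample signal is
#' \code{10^(abundance + sampleScale + effect + armOffset + noise)},
#' partitioned across the protein's peptides by fixed per-peptide
#' proportions, so the PPI rollup reconstructs the signal exactly.
#'
#' Defaults emulate the study design this package targets: 8 subjects,
#' 172 proteins, a dominant keratin-10-like standard protein, nine
#' baseline-discordant proteins (folds 3.8x down to 1.9x), and planted
#' per-arm log10 fold changes whose quadrant structure mirrors a
#' 76/50/33/4 split with roughly 49 real between-arm differences
#' (markers: SBSN 0.5x/1.9x, VIM 1.2x/2.3x, ASPRV1 1.3x/2.0x, ANXA2
#' decreasing under the film).
#'
#' @param nSubjects number of subjects (each contributes 2 arms x 2
#'   timepoints = 4 samples).
#' @param nProteins number of proteins.
#' @param peptidesPerProtein list(min=, max=, law="uniform"): per-protein
#'   peptide count distribution.
#' @param baseAbundance list(mean=, sd=): log10-scale protein baseline
#'   abundance distribution.
#' @param standardProteinBoost log10 offset added to the designated
#'   standard protein; must be > 0 (it should dominate every sample).
#' @param standardPeptides peptide count of the standard protein. The most
#'   abundant protein of a tape-strip run yields many identified peptides,
#'   which keeps the normalisation weights stable under peptide-level
#'   missingness; the default (20) reflects that.
#' @param sampleScaleSd sd of the per-sample global log10 loading factor
#'   (applied to every peptide of the sample, standard protein included).
#' @param noiseSd sd of per-protein per-sample log10 measurement noise.
#' @param effects data.frame(protein_id, arm, delta_pai): planted log10
#'   changes baseline -> day14. \code{NULL} = default effect set (see
#'   [defaultEffects()]); use \code{data.frame()} for none.
#' @param baselineOutliers data.frame(protein_id, delta_pai): persistent
#'   log10 offsets applied to the lotion_ff arm at both timepoints,
#'   emulating leg-level baseline discordance. \code{NULL} = defaults.
#' @param missingRate probability in [0, 1) that a peptide observation is
#'   dropped.
#' @param seed integer RNG seed; the whole study is a deterministic
#'   function of the config including the seed.
#' @return a \code{generatorConfig} list, validated.
#' @examples
#' cfg <- generatorConfig(nProteins = 20, nSubjects = 4, seed = 42)
#' cfg$proteins[1:3]
#' @export
generatorConfig <- function(nSubjects = 8L,
                            nProteins = 172L,
                            peptidesPerProtein = list(min = 2L, max = 8L, law = "uniform"),
                            baseAbundance = list(mean = 3.0, sd = 0.8),
                            standardProteinBoost = 3.0,
                            standardPeptides = 20L,
                            sampleScaleSd = 0.15,
                            noiseSd = 0.05,
                            effects = NULL,
                            baselineOutliers = NULL,
                            missingRate = 0.05,
                            seed = 1L) {
  if (!is.numeric(nSubjects) || nSubjects < 2)
    stop("invalid config field 'nSubjects': need >= 2")
  if (!is.numeric(nProteins) || nProteins < 2)
    stop("invalid config field 'nProteins': need >= 2")
  for (f in c("sampleScaleSd", "noiseSd"))
    if (get(f) < 0) stop("invalid config field '", f, "': sd must be >= 0")
  if (missingRate < 0 || missingRate >= 1)
    stop("invalid config field 'missingRate': need [0, 1)")
  if (standardProteinBoost <= 0)
    stop("invalid config field 'standardProteinBoost': must be > 0")
  if (peptidesPerProtein$min < 1 || peptidesPerProtein$max < peptidesPerProtein$min)
    stop("invalid config field 'peptidesPerProtein'")
  if (standardPeptides < 1)
    stop("invalid config field 'standardPeptides': need >= 1")
  if (!identical(peptidesPerProtein$law, "uniform"))
    stop("invalid config field 'peptidesPerProtein': only law='uniform' supported")

  proteins <- .proteinIds(as.integer(nProteins))
  if (is.null(baselineOutliers)) baselineOutliers <- defaultBaselineOutliers(proteins)
  if (is.null(effects)) effects <- defaultEffects(proteins)
  if (nrow(effects)) {
    stopifnot(all(c("protein_id", "arm", "delta_pai") %in% colnames(effects)))
    bad <- setdiff(effects$protein_id, proteins)
    if (length(bad)) stop("invalid config field 'effects': unknown protein ",
                          paste(bad, collapse = ", "))
    if (!all(effects$arm %in% c("lotion", "lotion_ff")))
      stop("invalid config field 'effects': unknown arm")
  }
  if (nrow(baselineOutliers)) {
    stopifnot(all(c("protein_id", "delta_pai") %in% colnames(baselineOutliers)))
    bad <- setdiff(baselineOutliers$protein_id, proteins)
    if (length(bad)) stop("invalid config field 'baselineOutliers': unknown protein ",
                          paste(bad, collapse = ", "))
  }
  structure(list(
    nSubjects = as.integer(nSubjects), nProteins = as.integer(nProteins),
    proteins = proteins, standard = proteins[[1L]],
    peptidesPerProtein = peptidesPerProtein,
    standardPeptides = as.integer(standardPeptides),
    baseAbundance = baseAbundance,
    standardProteinBoost = standardProteinBoost,
    sampleScaleSd = sampleScaleSd, noiseSd = noiseSd,
    effects = effects, baselineOutliers = baselineOutliers,
    missingRate = missingRate, seed = as.integer(seed)),
    class = "generatorConfig")
}

# Accession layout: the standard protein first, then named markers /
# baseline-discordant proteins when there is room, then numbered fillers.
.markerIds <- c("P_SBSN", "P_VIM", "P_ASPRV1", "P_ANXA2")
.outlierIds <- c("P_HBB", "P_S100A7", "P_S100A9", "P_HSPA8", "P_TUFT1",
                 "P_CALML5", "P_IL37", "P_SERPINB2", "P_PGK1")

.proteinIds <- function(n) {
  named <- c("P_K1C10", .markerIds, .outlierIds)
  if (n <= length(named)) return(named[seq_len(n)])
  c(named, sprintf("PROT%04d", seq_len(n - length(named))))
}

#' Default planted baseline-discordant proteins
#'
#' Nine proteins carrying persistent lotion_ff-arm log10 offsets whose
#' folds are 3.8, 3.2, 3.1, 2.8, 2.5, 2.4, 2.1, 1.9 and 1.9 — the scale of
#' discordance a baseline concordance filter is meant to remove. Only
#' planted when the study has room for them beyond the standard protein
#' and markers.
#'
#' @param proteins character vector of the study's accessions.
#' @return data.frame(protein_id, delta_pai).
#' @export
defaultBaselineOutliers <- function(proteins) {
  ids <- intersect(.outlierIds, proteins)
  folds <- c(3.8, 3.2, 3.1, 2.8, 2.5, 2.4, 2.1, 1.9, 1.9)[seq_along(ids)]
  sign <- rep_len(c(1, -1), length(ids))   # discordant in either direction
  data.frame(protein_id = ids, delta_pai = sign * log10(folds),
             stringsAsFactors = FALSE)
}

#' Default planted per-arm effect set
#'
#' A deterministic effect table emulating the quadrant structure of a
#' two-week emollient study: marker proteins with literature-scale folds
#' (SBSN 0.5x lotion / 1.9x film, VIM 1.2x/2.3x, ASPRV1 1.3x/2.0x, ANXA2
#' 0.95x/0.7x) plus, for studies of ~172 proteins, a spread of concordant
#' and discordant changes across the remaining proteins: ~76 up in both
#' arms (29 with a strong extra film response), ~50 down in both (9
#' strong), ~33 film-up/lotion-down (10 strong) and ~4 lotion-up/film-down
#' (1 strong). Magnitudes ramp deterministically so fold-change histograms
#' have spread. For small studies only the markers present are planted.
#'
#' @inheritParams defaultBaselineOutliers
#' @return data.frame(protein_id, arm, delta_pai).
#' @export
defaultEffects <- function(proteins) {
  eff <- list()
  add <- function(p, l, f) if (p %in% proteins)
    data.frame(protein_id = p, arm = c("lotion", "lotion_ff"),
               delta_pai = log10(c(l, f)), stringsAsFactors = FALSE)
  eff$sbsn   <- add("P_SBSN",   0.5,  1.9)
  eff$vim    <- add("P_VIM",    1.2,  2.3)
  eff$asprv1 <- add("P_ASPRV1", 1.3,  2.0)
  eff$anxa2  <- add("P_ANXA2",  0.95, 0.7)
  filler <- grep("^PROT", proteins, value = TRUE)
  # quadrant blocks scaled to the filler count (full size at 158 fillers)
  nf <- length(filler)
  if (nf >= 40L) {
    take <- function(n) {
      n <- min(n, length(filler))
      out <- filler[seq_len(n)]; filler <<- filler[-seq_len(n)]; out
    }
    ramp <- function(ids, lo, hi) seq(lo, hi, length.out = length(ids))
    blocks <- list(
      # up in both arms: 28 strong film responders, 45 mild concordant
      list(ids = take(round(28 * nf / 158)), l = c(0.04, 0.20), f = c(0.48, 0.70)),
      list(ids = take(round(45 * nf / 158)), l = c(0.03, 0.30), f = c(0.05, 0.34)),
      # down in both arms: 8 strong, 40 mild
      list(ids = take(round(8  * nf / 158)), l = c(-0.04, -0.20), f = c(-0.48, -0.65)),
      list(ids = take(round(40 * nf / 158)), l = c(-0.03, -0.30), f = c(-0.05, -0.34)),
      # film up / lotion down: 9 strong, 22 mild
      list(ids = take(round(9  * nf / 158)), l = c(-0.10, -0.20), f = c(0.35, 0.45)),
      list(ids = take(round(22 * nf / 158)), l = c(-0.03, -0.12), f = c(0.04, 0.14)),
      # lotion up / film down: 1 strong, 3 mild
      list(ids = take(round(1  * nf / 158)), l = c(0.15, 0.15), f = c(-0.35, -0.35)),
      list(ids = take(round(3  * nf / 158)), l = c(0.04, 0.08), f = c(-0.04, -0.10)))
    for (b in blocks) {
      if (!length(b$ids)) next
      l <- ramp(b$ids, b$l[1], b$l[2])
      f <- ramp(b$ids, b$f[1], b$f[2])
      eff[[length(eff) + 1L]] <- data.frame(
        protein_id = rep(b$ids, 2L),
        arm = rep(c("lotion", "lotion_ff"), each = length(b$ids)),
        delta_pai = c(l, f), stringsAsFactors = FALSE)
    }
  }
  eff <- eff[!vapply(eff, is.null, logical(1))]
  if (!length(eff))
    return(data.frame(protein_id = character(), arm = character(),
                      delta_pai = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, eff)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic study
#'
#' Produces the four tables a real study would yield downstream of the MS
#' search engine: \code{peptides} (long-form peptide x sample intensities),
#' \code{design} (sample -> subject/arm/timepoint/leg), \code{clinical}
#' (observer dryness score at days 0/7/14, conductance at days 0/7/14,
#' immunofluorescence intensity at day 5) and \code{truth} (every planted
#' effect and baseline offset). Deterministic given the config.
#'
#' @param config a [generatorConfig()].
#' @return named list of data.frames: peptides, design, clinical, truth.
#' @examples
#' study <- generateStudy(generatorConfig(nProteins = 10, nSubjects = 3, seed = 2))
#' head(study$peptides); study$truth
#' @export
generateStudy <- function(config) {
  if (!inherits(config, "generatorConfig"))
    stop("config must come from generatorConfig()")
  set.seed(config$seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, 3L)

  subjects <- sprintf("SUBJ%02d", seq_len(config$nSubjects))
  design <- expand.grid(timepoint = c("baseline", "day14"),
                        arm = c("lotion", "lotion_ff"),
                        subject_id = subjects,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("subject_id", "arm", "timepoint")]
  set.seed(subSeeds[[1L]])
  ffLeft <- runif(config$nSubjects) < 0.5
  names(ffLeft) <- subjects
  design$leg <- ifelse(xor(design$arm == "lotion_ff", ffLeft[design$subject_id]),
                       "right", "left")
  design$sample_id <- paste(design$subject_id, design$arm,
                            design$timepoint, sep = "_")
  design <- design[, c("sample_id", "subject_id", "arm", "timepoint", "leg")]
  rownames(design) <- NULL

  prots <- config$proteins
  P <- length(prots); S <- nrow(design)

  set.seed(subSeeds[[2L]])
  abund <- rnorm(P, config$baseAbundance$mean, config$baseAbundance$sd)
  names(abund) <- prots
  abund[[config$standard]] <- config$baseAbundance$mean + config$standardProteinBoost
  sampScale <- rnorm(S, 0, config$sampleScaleSd)
  noise <- matrix(rnorm(P * S, 0, config$noiseSd), P, S,
                  dimnames = list(prots, design$sample_id))

  logsig <- outer(abund, sampScale, "+") + noise
  if (nrow(config$effects)) {
    d14 <- design$timepoint == "day14"
    for (r in seq_len(nrow(config$effects))) {
      e <- config$effects[r, ]
      cols <- d14 & design$arm == e$arm
      logsig[e$protein_id, cols] <- logsig[e$protein_id, cols] + e$delta_pai
    }
  }
  if (nrow(config$baselineOutliers)) {
    ff <- design$arm == "lotion_ff"
    for (r in seq_len(nrow(config$baselineOutliers))) {
      o <- config$baselineOutliers[r, ]
      logsig[o$protein_id, ff] <- logsig[o$protein_id, ff] + o$delta_pai
    }
  }

  # split each protein signal over its peptides by fixed proportions
  npep <- sample(seq(config$peptidesPerProtein$min, config$peptidesPerProtein$max),
                 P, replace = TRUE)
  npep[match(config$standard, prots)] <- config$standardPeptides
  props <- lapply(npep, function(k) { w <- rgamma(k, 2, 1); w / sum(w) })
  pepProt <- rep(seq_len(P), npep)
  pepNames <- unlist(lapply(seq_len(P), function(i)
    sprintf("%s_pep%02d", prots[i], seq_len(npep[i]))))
  pepProp <- unlist(props)

  inten <- (10^logsig)[pepProt, , drop = FALSE] * pepProp
  keep <- matrix(runif(length(inten)) >= config$missingRate,
                 nrow(inten), ncol(inten))
  obs <- which(keep, arr.ind = TRUE)
  peptides <- data.frame(
    peptide_id = pepNames[obs[, 1L]],
    protein_id = prots[pepProt[obs[, 1L]]],
    sample_id = design$sample_id[obs[, 2L]],
    intensity = inten[obs],
    stringsAsFactors = FALSE)
  peptides <- peptides[order(peptides$sample_id, peptides$peptide_id), ]
  rownames(peptides) <- NULL

  set.seed(subSeeds[[3L]])
  clinical <- .generateClinical(subjects)

  truth <- rbind(
    if (nrow(config$effects))
      data.frame(kind = "effect", config$effects, stringsAsFactors = FALSE),
    if (nrow(config$baselineOutliers))
      data.frame(kind = "baseline_outlier",
                 protein_id = config$baselineOutliers$protein_id,
                 arm = "lotion_ff",
                 delta_pai = config$baselineOutliers$delta_pai,
                 stringsAsFactors = FALSE))
  if (is.null(truth))
    truth <- data.frame(kind = character(), protein_id = character(),
                        arm = character(), delta_pai = numeric(),
                        stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(peptides = peptides, design = design, clinical = clinical,
       truth = truth, config = config)
}

# Simple linear-improvement clinical model with subject random intercepts:
# dryness score falls and conductance rises over two weeks, both steeper in
# the film arm; immunofluorescence measured once (day 5), higher under film.
.generateClinical <- function(subjects) {
  n <- length(subjects)
  days <- c(0L, 7L, 14L)
  scoreInt <- pmin(4, pmax(2.5, round(rnorm(n, 3.1, 0.2) * 2) / 2))
  condInt <- rnorm(n, 22, 3)
  rows <- list()
  for (arm in c("lotion", "lotion_ff")) {
    scoreSlope <- if (arm == "lotion_ff") -0.60 else -0.30   # per week
    condSlope <- if (arm == "lotion_ff") 10 else 5
    for (d in days) {
      sc <- scoreInt + scoreSlope * d / 7 + rnorm(n, 0, 0.15)
      sc <- pmin(4, pmax(0, round(sc * 2) / 2))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects, arm = arm, day = d,
        endpoint = "observer_score", value = sc, stringsAsFactors = FALSE)
      cv <- condInt + condSlope * d / 7 + rnorm(n, 0, 1.5)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects, arm = arm, day = d,
        endpoint = "conductance", value = cv, stringsAsFactors = FALSE)
    }
    ifv <- rnorm(n, if (arm == "lotion_ff") 14 else 10, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = subjects, arm = arm, day = 5L,
      endpoint = "if_intensity", value = ifv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$endpoint, out$day, out$arm, out$subject_id), ]
  rownames(out) <- NULL
  out
}

#' Generate a null study (no planted effects)
#'
#' Same machinery as [generateStudy()] with the effect and baseline-offset
#' tables forced empty — the truth table is empty and every protein is a
#' true null, which is what FDR calibration runs need.
#'
#' @inheritParams generateStudy
#' @return as [generateStudy()]; \code{truth} has zero rows.
#' @export
generateNullStudy <- function(config) {
  if (!inherits(config, "generatorConfig"))
    stop("config must come from generatorConfig()")
  empty <- data.frame(protein_id = character(), arm = character(),
                      delta_pai = numeric(), stringsAsFactors = FALSE)
  config$effects <- empty
  config$baselineOutliers <- empty[, c("protein_id", "delta_pai")]
  generateStudy(config)
}

#' Write a generated study to disk as the pipeline's input TSV files
#'
#' Emits \code{peptides.tsv}, \code{design.tsv}, \code{clinical.tsv} and
#' \code{truth.tsv} into \code{directory}; these round-trip losslessly
#' through [readPeptideTable()] and friends.
#'
#' @param study list from [generateStudy()].
#' @param directory existing writable directory.
#' @return invisibly, the paths written.
#' @export
writeFixture <- function(study, directory) {
  if (!dir.exists(directory))
    stop("directory does not exist: ", directory)
  paths <- file.path(directory,
                     c("peptides.tsv", "design.tsv", "clinical.tsv", "truth.tsv"))
  .writeTsv(study$peptides, paths[[1L]])
  .writeTsv(study$design, paths[[2L]])
  .writeTsv(study$clinical, paths[[3L]])
  .writeTsv(study$truth, paths[[4L]])
  invisible(paths)
}
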