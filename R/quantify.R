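# Peptide -> protein quantification chain:
#   PPI  = per-protein, per-sample sum of peptide peak intensities
#   wt_i = PPI_i(standard) / PPI_k(standard), k = sample with the max
#   PAI  = log10(PPI / wt)

.checkPeptideTable <- function(peptides) {
  need <- c("peptide_id", "protein_id", "sample_id", "intensity")
  miss <- setdiff(need, colnames(peptides))
  if (length(miss))
    stop("peptide table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(peptides$intensity) | peptides$intensity < 0)
  if (length(bad))
    stop("non-finite or negative intensity in peptide record(s): ",
         paste(head(peptides$peptide_id[bad], 5L), collapse = ", "),
         " (row ", paste(head(bad, 5L), collapse = ", "), ")")
  key <- paste(peptides$peptide_id, peptides$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate (peptide_id, sample_id) record: ",
         peptides$peptide_id[d], " / ", peptides$sample_id[d])
  }
  invisible(peptides)
}

#' Roll peptide intensities up to protein peak-intensity sums (PPI)
#'
#' For every protein and sample, PPI is the sum of the intensities of all
#' observed peptides assigned to that protein. A protein with no observed
#' peptide in a sample gets \code{NA} (not observed), never zero.
#'
#' @param peptides long-form data.frame with columns \code{peptide_id},
#'   \code{protein_id}, \code{sample_id}, \code{intensity} (finite,
#'   non-negative). One row per observed peptide per sample.
#' @param samples optional character vector fixing the column order of the
#'   result (defaults to sorted unique sample ids).
#' @return numeric matrix proteins x samples, \code{NA} where unobserved.
#' @examples
#' pep <- data.frame(peptide_id = c("a", "b", "c"),
#'                   protein_id = c("P1", "P1", "P2"),
#'                   sample_id  = "S1", intensity = c(100, 50, 30))
#' computePPI(pep)
#' @export
computePPI <- function(peptides, samples = NULL) {
  .checkPeptideTable(peptides)
  if (is.null(samples)) samples <- sort(unique(peptides$sample_id))
  prots <- sort(unique(peptides$protein_id))
  pi <- factor(peptides$protein_id, levels = prots)
  si <- factor(peptides$sample_id, levels = samples)
  ok <- !is.na(si)
  m <- matrix(NA_real_, length(prots), length(samples),
              dimnames = list(prots, samples))
  idx <- cbind(as.integer(pi[ok]), as.integer(si[ok]))
  sums <- rowsum(peptides$intensity[ok], group = (idx[, 1L] - 1L) * length(samples) + idx[, 2L])
  cells <- as.integer(rownames(sums))
  m[cbind((cells - 1L) %/% length(samples) + 1L,
          (cells - 1L) %% length(samples) + 1L)] <- sums[, 1L]
  m
}

#' Choose the standard (normalisation reference) protein
#'
#' The standard protein is the highest-abundance protein — the one with the
#' largest total PPI summed over samples — restricted to proteins observed
#' (PPI > 0) in every sample, so that normalisation weights are defined
#' everywhere. Exact ties are broken by lexicographically smallest
#' accession. In the skin tape-strip setting this is typically keratin 10
#' (K1C10); use the \code{standardProtein} argument of
#' [quantifyProteins()] to force a named accession instead.
#'
#' @param ppi protein x sample PPI matrix from [computePPI()].
#' @return the accession (rowname) of the selected protein.
#' @export
selectStandardProtein <- function(ppi) {
  everywhere <- apply(ppi, 1L, function(r) all(is.finite(r) & r > 0))
  if (!any(everywhere))
    stop("no protein observed in every sample; cannot select a standard protein")
  tot <- rowSums(ppi[everywhere, , drop = FALSE])
  cand <- names(tot)[tot == max(tot)]
  sort(cand)[1L]
}

#' Per-sample normalisation weights from the standard protein
#'
#' The weight of sample i is the ratio of the standard protein's PPI in
#' sample i to its PPI in the reference sample. By default the reference is
#' the sample attaining the maximum standard-protein PPI, so weights lie in
#' (0, 1] with the maximum exactly 1. A fixed \code{referenceSample} may be
#' supplied instead (e.g. to keep PAI values comparable across reanalyses
#' of overlapping batches); weights may then exceed 1.
#'
#' @param ppi protein x sample PPI matrix.
#' @param standard accession of the standard protein; must have finite
#'   positive PPI in every sample.
#' @param referenceSample optional sample id anchoring the weights.
#' @return list with \code{wt} (named numeric vector) and
#'   \code{referenceSample}.
#' @export
computeWeights <- function(ppi, standard, referenceSample = NULL) {
  if (!standard %in% rownames(ppi))
    stop("standard protein '", standard, "' not present in the PPI matrix")
  s <- ppi[standard, ]
  if (any(!is.finite(s) | s <= 0))
    stop("standard protein '", standard,
         "' is missing or zero in sample(s): ",
         paste(colnames(ppi)[!is.finite(s) | s <= 0], collapse = ", "))
  if (is.null(referenceSample)) {
    referenceSample <- colnames(ppi)[which.max(s)]
  } else if (!referenceSample %in% colnames(ppi)) {
    stop("referenceSample '", referenceSample, "' is not a sample")
  }
  list(wt = s / s[[referenceSample]], referenceSample = referenceSample)
}

#' Protein amount index (PAI)
#'
#' PAI is the log10 of the weight-normalised PPI: \code{log10(PPI / wt)}.
#' Missing PPI propagates to missing PAI.
#'
#' @param ppi protein x sample PPI matrix.
#' @param wt named weight vector (or the list from [computeWeights()]).
#' @return protein x sample PAI matrix.
#' @export
computePAI <- function(ppi, wt) {
  if (is.list(wt)) wt <- wt$wt
  wt <- wt[colnames(ppi)]
  if (any(is.na(wt))) stop("weights missing for some samples")
  log10(sweep(ppi, 2L, wt, "/"))
}

#' Quantify a peptide table into a PaiExperiment
#'
#' Runs the full quantification chain (PPI rollup, standard-protein
#' selection, weights, PAI) for one analysis batch and packages the result
#' with the study design.
#'
#' @param peptides peptide intensity table (see [computePPI()]).
#' @param design data.frame with columns \code{sample_id}, \code{subject_id},
#'   \code{arm} (\code{"lotion"} or \code{"lotion_ff"}), \code{timepoint}
#'   (\code{"baseline"} or \code{"day14"}) and optionally \code{leg}.
#' @param standardProtein optional accession forcing the standard protein
#'   (it must be observed in every sample).
#' @param referenceSample optional fixed reference sample for the weights;
#'   default is the sample with the maximum standard-protein PPI.
#' @return a [PaiExperiment-class] object.
#' @examples
#' study <- generateStudy(generatorConfig(nProteins = 15, nSubjects = 3, seed = 7))
#' pe <- quantifyProteins(study$peptides, study$design)
#' pe
#' @export
quantifyProteins <- function(peptides, design, standardProtein = NULL,
                             referenceSample = NULL) {
  design <- .checkDesign(design)
  extra <- setdiff(unique(peptides$sample_id), design$sample_id)
  if (length(extra))
    stop("peptide table contains sample(s) absent from the design: ",
         paste(head(extra, 5L), collapse = ", "))
  ppi <- computePPI(peptides, samples = design$sample_id)
  std <- if (is.null(standardProtein)) selectStandardProtein(ppi) else {
    s <- ppi[standardProtein, ]
    if (any(!is.finite(s) | s <= 0))
      stop("forced standard protein '", standardProtein,
           "' is not observed in every sample")
    standardProtein
  }
  w <- computeWeights(ppi, std, referenceSample = referenceSample)
  pai <- computePAI(ppi, w$wt)
  cd <- S4Vectors::DataFrame(
    subject = design$subject_id, arm = design$arm,
    timepoint = design$timepoint,
    leg = if ("leg" %in% colnames(design)) design$leg else NA_character_,
    wt = as.numeric(w$wt), row.names = design$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ppi = ppi, pai = pai), colData = cd)
  S4Vectors::metadata(se)$standardProtein <- std
  S4Vectors::metadata(se)$referenceSample <- w$referenceSample
  methods::new("PaiExperiment", se)
}

.checkDesign <- function(design) {
  need <- c("sample_id", "subject_id", "arm", "timepoint")
  miss <- setdiff(need, colnames(design))
  if (length(miss))
    stop("design lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  badArm <- setdiff(unique(design$arm), c("lotion", "lotion_ff"))
  if (length(badArm))
    stop("unknown arm label(s): ", paste(badArm, collapse = ", "))
  badTp <- setdiff(unique(design$timepoint), c("baseline", "day14"))
  if (length(badTp))
    stop("unknown timepoint label(s): ", paste(badTp, collapse = ", "))
  key <- paste(design$subject_id, design$arm, design$timepoint)
  if (anyDuplicated(key))
    stop("more than one sample for a subject x arm x timepoint cell")
  design
}
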