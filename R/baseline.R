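# Baseline between-arm concordance filter: proteins whose arms already
# differed before treatment cannot support a clean between-arm fold-change
# comparison and are removed before differential analysis.

#' Between-arm baseline PAI differences
#'
#' For every protein, the arm-mean PAI difference at baseline
#' (lotion_ff minus lotion), computed pairwise-complete over subjects, plus
#' the absolute difference and its fold equivalent \code{10^|diff|}.
#' Proteins observed at baseline in fewer than \code{minSubjects} subjects
#' in either arm are flagged insufficient and get a missing difference.
#'
#' @param pe a [PaiExperiment-class].
#' @param minSubjects minimum subjects per arm with an observed baseline
#'   PAI (default 2).
#' @return data.frame(protein_id, diff_pai, abs_diff, fold, n_lotion,
#'   n_ff, insufficient), one row per protein, accession-sorted.
#' @export
baselineDifferences <- function(pe, minSubjects = 2L) {
  cd <- SummarizedExperiment::colData(pe)
  base <- cd$timepoint == "baseline"
  if (!any(base & cd$arm == "lotion") || !any(base & cd$arm == "lotion_ff"))
    stop("both arms must have baseline samples")
  pai <- paiMatrix(pe)
  mLot <- pai[, base & cd$arm == "lotion", drop = FALSE]
  mFF <- pai[, base & cd$arm == "lotion_ff", drop = FALSE]
  nLot <- rowSums(!is.na(mLot))
  nFF <- rowSums(!is.na(mFF))
  diff <- rowMeans(mFF, na.rm = TRUE) - rowMeans(mLot, na.rm = TRUE)
  insufficient <- nLot < minSubjects | nFF < minSubjects
  diff[insufficient] <- NA_real_
  out <- data.frame(protein_id = rownames(pai), diff_pai = diff,
                    abs_diff = abs(diff), fold = 10^abs(diff),
                    n_lotion = nLot, n_ff = nFF,
                    insufficient = insufficient,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$protein_id), ]
}

#' Count-based 95% baseline concordance filter
#'
#' Retains the \code{floor(retention * P)} proteins with the smallest
#' absolute baseline between-arm difference, where P is the number of
#' proteins with a defined difference; the remainder are excluded and
#' reported with their folds, largest first. With 172 proteins and the
#' default retention of 0.95 this keeps exactly 163 and excludes 9. Ties
#' at the boundary are broken by smaller \code{abs_diff} first, then
#' lexicographic accession, so the split is deterministic. A
#' percentile-threshold alternative (exclude proteins whose
#' \code{abs_diff} exceeds the retention quantile) is available via
#' \code{method = "percentile"}.
#'
#' @param diffs data.frame from [baselineDifferences()].
#' @param retention fraction in (0, 1] of proteins to keep.
#' @param method \code{"count"} (default) or \code{"percentile"}.
#' @return list(retained = accessions, excluded = data.frame(protein_id,
#'   diff_pai, fold) sorted by descending fold, insufficient = accessions
#'   with undefined differences).
#' @export
applyConcordanceFilter <- function(diffs, retention = 0.95,
                                   method = c("count", "percentile")) {
  method <- match.arg(method)
  if (!is.numeric(retention) || retention <= 0 || retention > 1)
    stop("retention must lie in (0, 1]")
  def <- diffs[!is.na(diffs$diff_pai), ]
  ord <- def[order(def$abs_diff, def$protein_id), ]
  P <- nrow(ord)
  nKeep <- if (method == "count") {
    min(P, floor(retention * P))
  } else {
    thr <- quantile(ord$abs_diff, retention, type = 7, names = FALSE)
    sum(ord$abs_diff <= thr)
  }
  retained <- ord$protein_id[seq_len(nKeep)]
  exc <- ord[seq_len(P) > nKeep, c("protein_id", "diff_pai", "fold")]
  exc <- exc[order(-exc$fold, exc$protein_id), ]
  rownames(exc) <- NULL
  list(retained = sort(retained), excluded = exc,
       insufficient = sort(diffs$protein_id[is.na(diffs$diff_pai)]))
}
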