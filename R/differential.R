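# Per-arm baseline -> day14 fold changes, the between-arm paired Wilcoxon
# family with Storey q-values, quadrant classification, between-arm
# fold-change ratios, and the scatter/histogram summary.

#' Per-subject log10 fold changes within one arm
#'
#' For each protein and subject in the given arm,
#' \code{PAI(day14) - PAI(baseline)}; missing whenever either endpoint is
#' unobserved. Because PAI is log10-scale this difference is the
#' subject-level log10 fold change.
#'
#' @param pe a [PaiExperiment-class].
#' @param arm \code{"lotion"} or \code{"lotion_ff"}.
#' @return protein x subject matrix of log10 fold changes.
#' @export
subjectLogFoldChanges <- function(pe, arm) {
  if (!arm %in% c("lotion", "lotion_ff"))
    stop("unknown arm label: ", arm)
  cd <- SummarizedExperiment::colData(pe)
  pai <- paiMatrix(pe)
  subjects <- sort(unique(cd$subject))
  pick <- function(tp) {
    sel <- cd$arm == arm & cd$timepoint == tp
    m <- matrix(NA_real_, nrow(pai), length(subjects),
                dimnames = list(rownames(pai), subjects))
    m[, cd$subject[sel]] <- pai[, sel, drop = FALSE]
    m
  }
  pick("day14") - pick("baseline")
}

#' Arm-level fold change from subject log fold changes
#'
#' The arm log10 fold change of a protein is the mean of its per-subject
#' log10 fold changes over non-missing subjects (a geometric-mean-style
#' fold on the raw scale); \code{fc = 10^lfc}. Proteins with no usable
#' subject are dropped with a warning.
#'
#' @param delta protein x subject matrix from [subjectLogFoldChanges()].
#' @return data.frame(protein_id, lfc, fc, n).
#' @export
armFoldChange <- function(delta) {
  n <- as.integer(rowSums(!is.na(delta)))
  if (any(n == 0L))
    warning("dropping ", sum(n == 0L),
            " protein(s) with no subject-level fold change")
  keep <- n > 0L
  lfc <- rowMeans(delta[keep, , drop = FALSE], na.rm = TRUE)
  data.frame(protein_id = rownames(delta)[keep], lfc = lfc, fc = 10^lfc,
             n = n[keep], row.names = NULL, stringsAsFactors = FALSE)
}

#' Between-arm paired tests of treatment response
#'
#' For each protein, the per-subject difference of log fold changes
#' (film arm minus lotion arm) is tested against zero with the paired
#' Wilcoxon signed-rank test; p-values are converted to Storey q-values
#' within the supplied protein family. Proteins with fewer than 2 complete
#' subject pairs are flagged untestable (p = NA, excluded from the
#' q-value family).
#'
#' @param deltaLotion,deltaFF protein x subject matrices from
#'   [subjectLogFoldChanges()] (shared subject columns).
#' @param exactLimit passed to [wilcoxonSignedRank()].
#' @return list(table = data.frame(protein_id, n_pairs, p_value, q_value,
#'   untestable), pi0).
#' @export
testBetweenArmChanges <- function(deltaLotion, deltaFF, exactLimit = 25L) {
  subjects <- intersect(colnames(deltaLotion), colnames(deltaFF))
  if (!length(subjects)) stop("no shared subjects between arms")
  prots <- intersect(rownames(deltaLotion), rownames(deltaFF))
  d <- deltaFF[prots, subjects, drop = FALSE] -
    deltaLotion[prots, subjects, drop = FALSE]
  res <- apply(d, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L)
      return(c(n = length(x), p = NA_real_, untestable = 1))
    w <- wilcoxonSignedRank(x, exactLimit = exactLimit)
    c(n = w$n, p = w$p, untestable = as.numeric(w$untestable))
  })
  tab <- data.frame(protein_id = prots, n_pairs = as.integer(res["n", ]),
                    p_value = res["p", ],
                    untestable = res["untestable", ] > 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  st <- storeyQvalues(ifelse(tab$untestable, NA, tab$p_value))
  tab$q_value <- st$q
  list(table = tab, pi0 = st$pi0)
}

#' Fold-change quadrant of a protein
#'
#' Sign-based classification of the two per-arm log fold changes:
#' both positive \code{up_up}, both negative \code{down_down}, film up /
#' lotion down \code{up_ff_down_lotion}, lotion up / film down
#' \code{up_lotion_down_ff}; an exact zero in either arm is
#' \code{boundary}. Vectorised.
#'
#' @param lfcLotion,lfcFF numeric log10 fold changes.
#' @return character vector of quadrant labels.
#' @examples
#' classifyQuadrant(c(0.3, -0.1, 0), c(0.2, 0.4, 0.5))
#' @export
classifyQuadrant <- function(lfcLotion, lfcFF) {
  out <- rep(NA_character_, length(lfcLotion))
  both <- !is.na(lfcLotion) & !is.na(lfcFF)
  sl <- sign(lfcLotion); sf <- sign(lfcFF)
  out[both & sl > 0 & sf > 0] <- "up_up"
  out[both & sl < 0 & sf < 0] <- "down_down"
  out[both & sl < 0 & sf > 0] <- "up_ff_down_lotion"
  out[both & sl > 0 & sf < 0] <- "up_lotion_down_ff"
  out[both & (sl == 0 | sf == 0)] <- "boundary"
  out
}

#' Between-arm fold-change ratio
#'
#' \code{fc_ff / fc_lotion}: how much larger (or smaller) a protein's
#' baseline-to-day-14 fold change is under the film than under lotion
#' alone.
#'
#' @param fcFF,fcLotion positive fold changes.
#' @return numeric ratio(s).
#' @export
foldChangeRatio <- function(fcFF, fcLotion) {
  if (any(!is.na(fcLotion) & fcLotion <= 0))
    stop("fc_lotion must be > 0")
  fcFF / fcLotion
}

#' Full differential table for one study
#'
#' Combines per-arm fold changes, between-arm Wilcoxon/Storey tests,
#' quadrant labels and fold-change ratios into one record per protein.
#' Within-arm change tests (each arm's subject fold changes against zero)
#' are computed as two additional, separate q-value families and attached
#' as columns \code{p_lotion}/\code{q_lotion} and \code{p_ff}/\code{q_ff}.
#'
#' @param pe a [PaiExperiment-class].
#' @param proteins accessions to analyse (typically the retained set from
#'   [applyConcordanceFilter()]); default all.
#' @param qThreshold significance threshold on the between-arm q-value.
#' @param exactLimit passed to [wilcoxonSignedRank()].
#' @return data.frame with one row per analysed protein and attribute
#'   \code{pi0} (named vector for the three families).
#' @export
differentialAnalysis <- function(pe, proteins = NULL, qThreshold = 0.05,
                                 exactLimit = 25L) {
  dl <- subjectLogFoldChanges(pe, "lotion")
  df <- subjectLogFoldChanges(pe, "lotion_ff")
  if (!is.null(proteins)) {
    missing <- setdiff(proteins, rownames(dl))
    if (length(missing))
      stop("unknown protein(s): ", paste(head(missing, 5L), collapse = ", "))
    dl <- dl[proteins, , drop = FALSE]
    df <- df[proteins, , drop = FALSE]
  }
  fcL <- armFoldChange(dl)
  fcF <- armFoldChange(df)
  rec <- merge(setNames(fcL, c("protein_id", "lfc_lotion", "fc_lotion", "n_lotion")),
               setNames(fcF, c("protein_id", "lfc_ff", "fc_ff", "n_ff")),
               by = "protein_id", all = TRUE)
  btw <- testBetweenArmChanges(dl, df, exactLimit = exactLimit)
  rec <- merge(rec, btw$table, by = "protein_id", all.x = TRUE)
  withinArm <- function(delta) {
    r <- apply(delta, 1L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L) return(NA_real_)
      wilcoxonSignedRank(x, exactLimit = exactLimit)$p
    })
    st <- storeyQvalues(r)
    list(p = r, q = st$q, pi0 = st$pi0)
  }
  wl <- withinArm(dl); wf <- withinArm(df)
  il <- match(rec$protein_id, rownames(dl))
  rec$p_lotion <- unname(wl$p[il]); rec$q_lotion <- wl$q[il]
  jf <- match(rec$protein_id, rownames(df))
  rec$p_ff <- unname(wf$p[jf]); rec$q_ff <- wf$q[jf]
  rec$fc_ratio <- foldChangeRatio(rec$fc_ff, rec$fc_lotion)
  rec$quadrant <- classifyQuadrant(rec$lfc_lotion, rec$lfc_ff)
  rec$significant <- !is.na(rec$q_value) & rec$q_value < qThreshold
  rec <- rec[order(rec$protein_id), ]
  rownames(rec) <- NULL
  attr(rec, "pi0") <- c(between_arm = btw$pi0, lotion = wl$pi0, ff = wf$pi0)
  rec
}

#' Scatter/histogram summary of per-arm fold changes
#'
#' Pearson correlation between the two arms' log2 fold changes over
#' proteins with both defined, plus marginal histograms on shared bin
#' edges (the usual side-panels of a fold-change scatter plot).
#' log2 values are \code{lfc / log10(2)}.
#'
#' @param records data.frame from [differentialAnalysis()] (needs
#'   \code{lfc_lotion}, \code{lfc_ff}).
#' @param nBins number of shared histogram bins.
#' @return list(pearson_r, n, breaks, counts_lotion, counts_ff,
#'   degenerate). \code{pearson_r} is NA with \code{degenerate = TRUE}
#'   when either axis has zero variance.
#' @export
scatterSummary <- function(records, nBins = 30L) {
  both <- !is.na(records$lfc_lotion) & !is.na(records$lfc_ff)
  if (sum(both) < 2L) stop("need at least 2 proteins with both fold changes")
  l2l <- records$lfc_lotion[both] / log10(2)
  l2f <- records$lfc_ff[both] / log10(2)
  degen <- sd(l2l) == 0 || sd(l2f) == 0
  r <- if (degen) NA_real_ else cor(l2l, l2f)
  rng <- range(c(l2l, l2f))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  cl <- tabulate(findInterval(l2l, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nBins)
  cf <- tabulate(findInterval(l2f, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nBins)
  list(pearson_r = r, n = sum(both), breaks = breaks,
       counts_lotion = cl, counts_ff = cf, degenerate = degen)
}
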