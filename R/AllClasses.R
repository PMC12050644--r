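#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats median na.omit pnorm psignrank pt quantile rbinom rgamma
#'   rnorm runif sd setNames smooth.spline predict cor p.adjust t.test complete.cases
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' PaiExperiment: normalised stratum corneum quantification container
#'
#' A \linkS4class{SummarizedExperiment} subclass holding the full
#' quantification chain for one analysis batch: the raw per-protein peptide
#' peak intensity rollup (assay \code{"ppi"}), the weight-normalised
#' log10 protein amount index (assay \code{"pai"}), the per-sample
#' normalisation weights (colData column \code{wt}), and the study design
#' (colData columns \code{subject}, \code{arm}, \code{timepoint},
#' \code{leg}). The identity of the standard (reference) protein and of the
#' reference sample used to anchor the weights are kept in
#' \code{metadata()}.
#'
#' Rows are proteins (rownames = accessions), columns are samples. Missing
#' values in either assay mean "protein not observed in that sample", never
#' zero abundance.
#'
#' Objects are normally created by [quantifyProteins()], not directly.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#'
#' @seealso [quantifyProteins()], [paiMatrix()], [sampleWeights()]
#' @export
setClass("PaiExperiment", contains = "SummarizedExperiment")

setValidity("PaiExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("ppi", "pai") %in% an))
    msg <- c(msg, "assays must include 'ppi' and 'pai'")
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject", "arm", "timepoint", "wt")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if ("wt" %in% colnames(cd)) {
    wt <- cd$wt
    if (any(!is.finite(wt)) || any(wt <= 0))
      msg <- c(msg, "all weights must be finite and > 0")
  }
  md <- S4Vectors::metadata(object)
  if (is.null(md$standardProtein) || !md$standardProtein %in% rownames(object))
    msg <- c(msg, "metadata()$standardProtein must name a row")
  if (is.null(md$referenceSample) || !md$referenceSample %in% colnames(object))
    msg <- c(msg, "metadata()$referenceSample must name a column")
  if (length(msg)) msg else TRUE
})

#' @describeIn PaiExperiment compact description of the batch
#' @param object a \code{PaiExperiment}
#' @export
setMethod("show", "PaiExperiment", function(object) {
  callNextMethod()
  md <- S4Vectors::metadata(object)
  cat("standard protein:", md$standardProtein,
      "| reference sample:", md$referenceSample, "\n")
  wt <- SummarizedExperiment::colData(object)$wt
  cat(sprintf("weights: [%.4g, %.4g]\n", min(wt), max(wt)))
})

#' Accessors for PaiExperiment components
#'
#' \code{ppiMatrix} returns the protein x sample matrix of peptide peak
#' intensity sums; \code{paiMatrix} the protein amount index
#' (log10 of weight-normalised PPI); \code{sampleWeights} the named
#' per-sample weight vector; \code{standardProtein} and
#' \code{referenceSample} the normalisation anchors; \code{studyDesign} the
#' design columns of \code{colData} as a plain data.frame.
#'
#' @param x a \code{PaiExperiment}
#' @return matrix, named numeric vector, character scalar or data.frame as
#'   described above.
#' @name pai-accessors
#' @examples
#' study <- generateStudy(generatorConfig(nProteins = 12, nSubjects = 3, seed = 1))
#' pe <- quantifyProteins(study$peptides, study$design)
#' dim(paiMatrix(pe)); standardProtein(pe)
NULL

#' @rdname pai-accessors
#' @export
setGeneric("ppiMatrix", function(x) standardGeneric("ppiMatrix"))
#' @rdname pai-accessors
#' @export
setMethod("ppiMatrix", "PaiExperiment", function(x)
  SummarizedExperiment::assay(x, "ppi"))

#' @rdname pai-accessors
#' @export
setGeneric("paiMatrix", function(x) standardGeneric("paiMatrix"))
#' @rdname pai-accessors
#' @export
setMethod("paiMatrix", "PaiExperiment", function(x)
  SummarizedExperiment::assay(x, "pai"))

#' @rdname pai-accessors
#' @export
setGeneric("sampleWeights", function(x) standardGeneric("sampleWeights"))
#' @rdname pai-accessors
#' @export
setMethod("sampleWeights", "PaiExperiment", function(x)
  setNames(SummarizedExperiment::colData(x)$wt, colnames(x)))

#' @rdname pai-accessors
#' @export
setGeneric("standardProtein", function(x) standardGeneric("standardProtein"))
#' @rdname pai-accessors
#' @export
setMethod("standardProtein", "PaiExperiment", function(x)
  S4Vectors::metadata(x)$standardProtein)

#' @rdname pai-accessors
#' @export
setGeneric("referenceSample", function(x) standardGeneric("referenceSample"))
#' @rdname pai-accessors
#' @export
setMethod("referenceSample", "PaiExperiment", function(x)
  S4Vectors::metadata(x)$referenceSample)

#' @rdname pai-accessors
#' @export
setGeneric("studyDesign", function(x) standardGeneric("studyDesign"))
#' @rdname pai-accessors
#' @export
setMethod("studyDesign", "PaiExperiment", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  keep <- intersect(c("subject", "arm", "timepoint", "leg"), colnames(cd))
  data.frame(sample_id = colnames(x), cd[, keep, drop = FALSE],
             row.names = NULL, stringsAsFactors = FALSE)
})
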