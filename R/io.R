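# TSV input/output and pipeline orchestration. All outputs use '.'
# decimals, 'NA' as the missing token, LF line endings and full numeric
# precision, so reruns are byte-comparable.

.writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE,
                     nsmall = 0),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

.readTsv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  read.delim(path, header = TRUE, sep = "\t", quote = "",
             na.strings = "NA", stringsAsFactors = FALSE)
}

#' Read and validate a peptide intensity table
#'
#' Expects columns \code{peptide_id}, \code{protein_id}, \code{sample_id},
#' \code{intensity}. The literal token \code{NA} is treated as a missing
#' observation and the row is dropped (with a message of the count);
#' negative, non-finite or duplicated (peptide, sample) records are
#' errors naming the offending record.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readPeptideTable <- function(path) {
  tab <- .readTsv(path, "peptide")
  need <- c("peptide_id", "protein_id", "sample_id", "intensity")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("peptides file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!is.numeric(tab$intensity))
    stop("peptides file ", path, ": non-numeric intensity column")
  nNA <- sum(is.na(tab$intensity))
  if (nNA) {
    message("dropping ", nNA, " peptide record(s) with missing intensity")
    tab <- tab[!is.na(tab$intensity), ]
  }
  .checkPeptideTable(tab)
  tab
}

#' Read and validate a study design table
#'
#' Expects columns \code{sample_id}, \code{subject_id}, \code{arm},
#' \code{timepoint} (and optionally \code{leg}). Subjects missing any of
#' the four arm x timepoint samples are reported with a warning (they
#' cannot contribute to all paired analyses).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readStudyDesign <- function(path) {
  tab <- .readTsv(path, "design")
  tab <- .checkDesign(tab)
  cnt <- table(tab$subject_id)
  unpaired <- names(cnt)[cnt < 4L]
  if (length(unpaired))
    warning("subject(s) without all 4 arm x timepoint samples: ",
            paste(unpaired, collapse = ", "))
  tab
}

#' Read and validate a clinical endpoint table
#'
#' Expects columns \code{subject_id}, \code{arm}, \code{day},
#' \code{endpoint}, \code{value}; observer scores must be multiples of
#' 0.5 in [0, 4].
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readClinicalTable <- function(path) {
  tab <- .readTsv(path, "clinical")
  .checkClinical(tab)
  tab
}

#' Pipeline configuration
#'
#' Bundles the file paths and tunable parameters of a full run. Defaults:
#' retention fraction 0.95 (the 95% baseline concordance rule),
#' q threshold 0.05 (5% FDR), automatic standard-protein selection, exact
#' Wilcoxon up to n = 25.
#'
#' @param peptides,design paths to the required input TSVs.
#' @param clinical,functionMap optional input TSV paths (functionMap
#'   defaults to the packaged curated map).
#' @param outputDir directory for all artifacts.
#' @param retentionFraction baseline filter retention in (0, 1].
#' @param qThreshold between-arm significance threshold in (0, 1).
#' @param standardProtein optional forced standard accession.
#' @param referenceSample optional fixed weight reference sample.
#' @param exactLimit exact-Wilcoxon n cutoff.
#' @param lambda Storey pi0 lambda grid.
#' @param seed integer recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters only when the config is reused to
#'   generate inputs).
#' @return a \code{pipelineConfig} list.
#' @export
pipelineConfig <- function(peptides, design, clinical = NULL,
                           functionMap = NULL, outputDir = "corneoquant_out",
                           retentionFraction = 0.95, qThreshold = 0.05,
                           standardProtein = NULL, referenceSample = NULL,
                           exactLimit = 25L,
                           lambda = seq(0.05, 0.95, by = 0.05),
                           seed = 1L) {
  if (retentionFraction <= 0 || retentionFraction > 1)
    stop("retentionFraction must lie in (0, 1]")
  if (qThreshold <= 0 || qThreshold >= 1)
    stop("qThreshold must lie in (0, 1)")
  if (is.null(functionMap))
    functionMap <- system.file("extdata", "function_map.tsv",
                               package = "corneoquant")
  structure(list(peptides = peptides, design = design, clinical = clinical,
                 functionMap = functionMap, outputDir = outputDir,
                 retentionFraction = retentionFraction,
                 qThreshold = qThreshold, standardProtein = standardProtein,
                 referenceSample = referenceSample,
                 exactLimit = as.integer(exactLimit), lambda = lambda,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Quantify -> baseline filter -> differential -> annotate -> clinical,
#' writing every artifact table plus a run manifest (package version,
#' parameters, input checksums) into the output directory. Outputs are
#' bit-for-bit reproducible given identical inputs and configuration.
#'
#' Artifacts: \code{ppi.tsv}, \code{weights.tsv}, \code{pai.tsv},
#' \code{baseline_diffs.tsv}, \code{retained.txt}, \code{differential.tsv},
#' \code{qc_summary.tsv}, \code{scatter.tsv}, \code{groups.tsv},
#' \code{group_summary.tsv}, \code{clinical_tests.tsv} (when clinical data
#' are given), \code{manifest.txt}.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the in-memory results
#'   (\code{pe}, \code{diffs}, \code{filter}, \code{records},
#'   \code{scatter}, \code{groups}, \code{clinical}) and \code{paths}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  peptides <- stage("read", readPeptideTable(config$peptides))
  design <- stage("read", readStudyDesign(config$design))
  clinical <- if (!is.null(config$clinical))
    stage("read", readClinicalTable(config$clinical)) else NULL

  pe <- stage("quantify", quantifyProteins(
    peptides, design, standardProtein = config$standardProtein,
    referenceSample = config$referenceSample))
  diffs <- stage("filter", baselineDifferences(pe))
  filt <- stage("filter", applyConcordanceFilter(
    diffs, retention = config$retentionFraction))
  records <- stage("difftest", differentialAnalysis(
    pe, proteins = filt$retained, qThreshold = config$qThreshold,
    exactLimit = config$exactLimit))
  scat <- stage("difftest", scatterSummary(records))
  map <- stage("annotate", loadFunctionMap(config$functionMap))
  groups <- stage("annotate", groupFoldChangeTable(records, map))
  clin <- if (!is.null(clinical)) stage("clinical", {
    do.call(rbind, lapply(intersect(c("observer_score", "conductance"),
                                    unique(clinical$endpoint)),
                          function(ep) pairedEndpointTests(clinical, ep)))
  }) else NULL

  paths <- stage("report", writeOutputs(
    list(pe = pe, diffs = diffs, filter = filt, records = records,
         scatter = scat, groups = groups, clinical = clin, config = config),
    config$outputDir))
  invisible(list(pe = pe, diffs = diffs, filter = filt, records = records,
                 scatter = scat, groups = groups, clinical = clin,
                 paths = paths))
}

#' Write all pipeline artifacts
#'
#' @param results list as assembled by [runPipeline()].
#' @param dir output directory, created if absent.
#' @return invisibly, named vector of paths.
#' @export
writeOutputs <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pe <- results$pe
  paths <- c()
  mat2df <- function(m) data.frame(protein_id = rownames(m), m,
                                   row.names = NULL, check.names = FALSE,
                                   stringsAsFactors = FALSE)
  put <- function(df, name) {
    p <- file.path(dir, name)
    .writeTsv(df, p)
    paths[[name]] <<- p
  }
  put(mat2df(ppiMatrix(pe)), "ppi.tsv")
  put(data.frame(sample_id = colnames(pe), wt = unname(sampleWeights(pe)),
                 stringsAsFactors = FALSE), "weights.tsv")
  put(mat2df(paiMatrix(pe)), "pai.tsv")
  diffs <- results$diffs
  diffs$excluded <- diffs$protein_id %in% results$filter$excluded$protein_id
  put(diffs, "baseline_diffs.tsv")
  rp <- file.path(dir, "retained.txt")
  writeLines(results$filter$retained, rp)
  paths[["retained.txt"]] <- rp
  put(results$records, "differential.tsv")
  pi0 <- attr(results$records, "pi0")
  qc <- data.frame(
    metric = c("pi0_between_arm", "pi0_lotion", "pi0_ff", "pearson_r",
               "n_proteins", "n_retained",
               paste0("quadrant_", c("up_up", "down_down",
                                     "up_ff_down_lotion",
                                     "up_lotion_down_ff", "boundary"))),
    value = c(pi0[["between_arm"]], pi0[["lotion"]], pi0[["ff"]],
              results$scatter$pearson_r, nrow(results$diffs),
              length(results$filter$retained),
              vapply(c("up_up", "down_down", "up_ff_down_lotion",
                       "up_lotion_down_ff", "boundary"),
                     function(qd) sum(results$records$quadrant == qd,
                                      na.rm = TRUE), numeric(1))),
    stringsAsFactors = FALSE)
  put(qc, "qc_summary.tsv")
  sc <- results$scatter
  put(data.frame(bin_lo = sc$breaks[-length(sc$breaks)],
                 bin_hi = sc$breaks[-1L],
                 count_lotion = sc$counts_lotion,
                 count_ff = sc$counts_ff, stringsAsFactors = FALSE),
      "scatter.tsv")
  put(results$groups$members, "groups.tsv")
  put(results$groups$summary, "group_summary.tsv")
  if (!is.null(results$clinical))
    put(results$clinical, "clinical_tests.tsv")

  cfg <- results$config
  inputs <- Filter(Negate(is.null),
                   list(peptides = cfg$peptides, design = cfg$design,
                        clinical = cfg$clinical,
                        function_map = cfg$functionMap))
  manifest <- c(
    paste0("package: corneoquant ", as.character(packageVersion("corneoquant"))),
    paste0("r_version: ", R.version.string),
    paste0("retention_fraction: ", cfg$retentionFraction),
    paste0("q_threshold: ", cfg$qThreshold),
    paste0("standard_protein: ",
           if (is.null(cfg$standardProtein)) "auto" else cfg$standardProtein),
    paste0("reference_sample: ",
           if (is.null(cfg$referenceSample)) "auto" else cfg$referenceSample),
    paste0("exact_limit: ", cfg$exactLimit),
    paste0("seed: ", cfg$seed),
    vapply(names(inputs), function(n)
      paste0("input_md5 ", n, ": ", unname(tools::md5sum(inputs[[n]]))),
      character(1)))
  mp <- file.path(dir, "manifest.txt")
  writeLines(manifest, mp)
  paths[["manifest.txt"]] <- mp
  invisible(unlist(paths))
}
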