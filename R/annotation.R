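# Functional-group assignment from a local mapping table and the grouped
# fold-change summaries (dot-plot / box-plot data) per group.

#' Load a protein -> functional group mapping
#'
#' Reads a two-column TSV (\code{protein_id}, \code{group_label}). The
#' packaged default (\code{system.file("extdata", "function_map.tsv",
#' package = "corneoquant")}) is a curated map covering the stratum
#' corneum proteins commonly discussed in emollient studies (keratins,
#' proteasome subunits, filaggrin- and cornified-envelope-processing
#' enzymes, cytoskeleton, redox, ...) plus the accessions used by the
#' synthetic generator. Proteins absent from the map are later reported
#' as \code{"unassigned"}.
#'
#' @param path TSV file path.
#' @return named character vector (names = protein ids, values = groups).
#' @export
loadFunctionMap <- function(path) {
  if (!file.exists(path)) stop("function map not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character")
  if (!all(c("protein_id", "group_label") %in% colnames(tab)))
    stop("function map must have columns protein_id and group_label")
  bad <- which(tab$protein_id == "" | tab$group_label == "")
  if (length(bad))
    stop("malformed function map row at line ", bad[1L] + 1L)
  if (anyDuplicated(tab$protein_id)) {
    d <- tab$protein_id[duplicated(tab$protein_id)][1L]
    stop("duplicate accession in function map: ", d)
  }
  setNames(tab$group_label, tab$protein_id)
}

#' Look up functional groups
#'
#' @param proteins accessions.
#' @param map named vector from [loadFunctionMap()].
#' @return character vector of group labels, \code{"unassigned"} where
#'   unmapped.
#' @export
assignGroups <- function(proteins, map) {
  g <- unname(map[proteins])
  g[is.na(g)] <- "unassigned"
  g
}

#' Grouped fold-change summary tables
#'
#' Produces the data behind a per-group report: for every functional
#' group, the member proteins with their log2 between-arm fold-change
#' ratios (dot-plot values), per-arm log2 fold-change five-number
#' summaries (box-plot values) and the count of significant members.
#'
#' @param records data.frame from [differentialAnalysis()].
#' @param map named vector from [loadFunctionMap()].
#' @return list(members = per-protein data.frame with \code{group} and
#'   \code{log2_fc_ratio}, summary = per-group data.frame with counts and
#'   five-number summaries per arm). Groups sort lexicographically.
#' @export
groupFoldChangeTable <- function(records, map) {
  if (!nrow(records)) stop("records must be non-empty")
  g <- assignGroups(records$protein_id, map)
  members <- data.frame(
    group = g, protein_id = records$protein_id,
    log2_fc_ratio = log2(records$fc_ratio),
    log2_fc_lotion = records$lfc_lotion / log10(2),
    log2_fc_ff = records$lfc_ff / log10(2),
    significant = records$significant,
    stringsAsFactors = FALSE)
  members <- members[order(members$group, members$protein_id), ]
  rownames(members) <- NULL
  five <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(rep(NA_real_, 5L))
    unname(quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  }
  summ <- do.call(rbind, lapply(split(members, members$group), function(m) {
    fl <- five(m$log2_fc_lotion); ff <- five(m$log2_fc_ff)
    data.frame(group = m$group[1L], n = nrow(m),
               n_significant = sum(m$significant, na.rm = TRUE),
               median_log2_ratio = median(m$log2_fc_ratio, na.rm = TRUE),
               lotion_min = fl[1L], lotion_q1 = fl[2L], lotion_med = fl[3L],
               lotion_q3 = fl[4L], lotion_max = fl[5L],
               ff_min = ff[1L], ff_q1 = ff[2L], ff_med = ff[3L],
               ff_q3 = ff[4L], ff_max = ff[5L],
               stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$group), ]
  rownames(summ) <- NULL
  list(members = members, summary = summ)
}

#' Write the grouped report tables
#'
#' Writes \code{groups.tsv} (per-protein membership and dot-plot values)
#' and \code{group_summary.tsv} (per-group box-plot summaries) into
#' \code{dir}. Idempotent: running twice produces identical files.
#'
#' @param tables list from [groupFoldChangeTable()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
renderReport <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "groups.tsv")
  p2 <- file.path(dir, "group_summary.tsv")
  .writeTsv(tables$members, p1)
  .writeTsv(tables$summary, p2)
  invisible(c(p1, p2))
}
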