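# Clinical endpoint statistics: observer dryness score (0-4 in 0.5
# steps), conductance (skin hydration), immunofluorescence intensity.

.checkClinical <- function(tab) {
  need <- c("subject_id", "arm", "day", "endpoint", "value")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  key <- paste(tab$subject_id, tab$arm, tab$day, tab$endpoint)
  if (anyDuplicated(key))
    stop("duplicate subject x arm x day x endpoint record")
  os <- tab$value[tab$endpoint == "observer_score"]
  if (length(os) && any(os < 0 | os > 4 | (os * 2) %% 1 != 0))
    stop("observer_score values must be multiples of 0.5 within [0, 4]")
  invisible(tab)
}

#' Changes of a clinical endpoint from the reference day
#'
#' Per subject and arm, \code{value(day) - value(referenceDay)} for every
#' recorded day. Subjects lacking the reference-day record in an arm are
#' excluded with a warning.
#'
#' @param table clinical endpoint table (columns \code{subject_id},
#'   \code{arm}, \code{day}, \code{endpoint}, \code{value}).
#' @param endpoint endpoint name, e.g. \code{"observer_score"}.
#' @param referenceDay baseline day (default 0).
#' @return data.frame(subject_id, arm, day, change).
#' @export
endpointChanges <- function(table, endpoint, referenceDay = 0L) {
  .checkClinical(table)
  tab <- table[table$endpoint == endpoint, ]
  if (!nrow(tab)) stop("no records for endpoint '", endpoint, "'")
  ref <- tab[tab$day == referenceDay, ]
  key <- function(d) paste(d$subject_id, d$arm, sep = "\r")
  refVal <- setNames(ref$value, key(ref))
  out <- tab
  out$change <- out$value - refVal[key(out)]
  dropped <- unique(out$subject_id[is.na(out$change)])
  if (length(dropped))
    warning("excluding subject(s) without day-", referenceDay, " record: ",
            paste(dropped, collapse = ", "))
  out <- out[!is.na(out$change), c("subject_id", "arm", "day", "change")]
  rownames(out) <- NULL
  out
}

#' Paired endpoint comparisons with BH adjustment
#'
#' Two comparison families per endpoint, both using the paired Wilcoxon
#' signed-rank test across subjects: (a) between-arm at each recorded day
#' (film minus lotion) and (b) within-arm change from the reference day at
#' each later day. Benjamini-Hochberg adjustment is applied within each
#' endpoint x comparison family (mirroring figure-panel-wise correction);
#' set \code{family = "endpoint"} to pool both comparisons of an endpoint
#' into one family.
#'
#' @param table clinical endpoint table.
#' @param endpoint endpoint name.
#' @param referenceDay baseline day for within-arm changes.
#' @param alpha significance threshold on adjusted p.
#' @param family \code{"comparison"} (default) or \code{"endpoint"}.
#' @return data.frame(endpoint, comparison, arm, day, n, p, p_adj,
#'   significant); \code{arm} is NA for between-arm rows.
#' @export
pairedEndpointTests <- function(table, endpoint, referenceDay = 0L,
                                alpha = 0.05,
                                family = c("comparison", "endpoint")) {
  family <- match.arg(family)
  .checkClinical(table)
  tab <- table[table$endpoint == endpoint, ]
  if (!nrow(tab)) stop("no records for endpoint '", endpoint, "'")
  rows <- list()
  # (a) between-arm at each day
  for (d in sort(unique(tab$day))) {
    td <- tab[tab$day == d, ]
    wide <- merge(td[td$arm == "lotion", c("subject_id", "value")],
                  td[td$arm == "lotion_ff", c("subject_id", "value")],
                  by = "subject_id")
    if (nrow(wide) < 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = endpoint, comparison = "between_arm", arm = NA_character_,
        day = d, n = nrow(wide), p = NA_real_, untestable = TRUE)
      next
    }
    w <- wilcoxonSignedRank(wide$value.y - wide$value.x)
    rows[[length(rows) + 1L]] <- data.frame(
      endpoint = endpoint, comparison = "between_arm", arm = NA_character_,
      day = d, n = nrow(wide), p = w$p, untestable = w$untestable)
  }
  # (b) within-arm change vs reference day
  ch <- suppressWarnings(endpointChanges(table, endpoint, referenceDay))
  for (arm in c("lotion", "lotion_ff")) {
    for (d in setdiff(sort(unique(ch$day)), referenceDay)) {
      x <- ch$change[ch$arm == arm & ch$day == d]
      if (length(x) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          endpoint = endpoint, comparison = "within_arm", arm = arm,
          day = d, n = length(x), p = NA_real_, untestable = TRUE)
        next
      }
      w <- wilcoxonSignedRank(x)
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = endpoint, comparison = "within_arm", arm = arm,
        day = d, n = length(x), p = w$p, untestable = w$untestable)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  fam <- if (family == "endpoint") rep("all", nrow(out)) else out$comparison
  for (f in unique(fam)) {
    i <- fam == f & !is.na(out$p)
    out$p_adj[i] <- p.adjust(out$p[i], method = "BH")
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out
}
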