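# Copy-number census: cluster genome hits into loci and classify each locus
# as full-length / MITE / partial / non-autonomous / unclassified using the
# inclusive identity-coverage thresholds.

#' Census thresholds
#'
#' Defaults: full-length 95% identity over 95% of the element; partial 80%
#' over 50%; non-autonomous 50% over 25%; MITE 95% identity over both TIRs.
#' Identities are percents, coverages fractions of the element length.
#' @export
census_thresholds <- function(full_min_id = 95, full_min_cov = 0.95,
                              partial_min_id = 80, partial_min_cov = 0.5,
                              nonaut_min_id = 50, nonaut_min_cov = 0.25,
                              mite_tir_min_id = 95) {
  stopifnot(full_min_id >= partial_min_id, partial_min_id >= nonaut_min_id,
            full_min_cov >= partial_min_cov, partial_min_cov >= nonaut_min_cov)
  structure(list(full_min_id = full_min_id, full_min_cov = full_min_cov,
                 partial_min_id = partial_min_id,
                 partial_min_cov = partial_min_cov,
                 nonaut_min_id = nonaut_min_id, nonaut_min_cov = nonaut_min_cov,
                 mite_tir_min_id = mite_tir_min_id),
            class = "census_thresholds")
}

COPY_CLASSES <- c("full_length", "mite", "partial", "non_autonomous",
                  "unclassified")

#' Cluster hits into candidate insertion loci
#'
#' Hits on the same subject and strand whose subject intervals lie within
#' `max_gap` of each other (single linkage) form one locus.
#'
#' @param hits hit table; all rows must share one query (the element).
#' @param element_length length of the element in nt.
#' @param max_gap clustering gap on the subject; default twice the element
#'   length.
#' @return list of data.frames (the member hits per locus), ordered by
#'   subject id, strand, then leftmost subject coordinate.
#' @export
cluster_loci <- function(hits, element_length,
                         max_gap = 2L * element_length) {
  if (nrow(hits) == 0L) return(list())
  if (length(unique(hits$qseqid)) != 1L)
    stop("cluster_loci: hits must all share one query")
  sr <- hit_subject_range(hits)
  hits$.smin <- sr$smin; hits$.smax <- sr$smax; hits$.strand <- sr$strand
  out <- list()
  for (key in sort(unique(paste(hits$sseqid, hits$.strand, sep = "\r")))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- hits[hits$sseqid == parts[1L] & hits$.strand == parts[2L], ,
                drop = FALSE]
    sub <- sub[order(sub$.smin, sub$.smax), , drop = FALSE]
    cur_max <- sub$.smax[1L]
    grp <- integer(nrow(sub)); grp[1L] <- 1L
    g <- 1L
    if (nrow(sub) > 1L) for (k in 2L:nrow(sub)) {
      if (sub$.smin[k] - cur_max > max_gap) g <- g + 1L
      grp[k] <- g
      cur_max <- max(cur_max, sub$.smax[k])
    }
    for (gg in seq_len(g)) {
      loc <- sub[grp == gg, , drop = FALSE]
      loc$.smin <- NULL; loc$.smax <- NULL
      strand <- loc$.strand[1L]; loc$.strand <- NULL
      rownames(loc) <- NULL
      attr(loc, "subject") <- parts[1L]
      attr(loc, "strand") <- strand
      out[[length(out) + 1L]] <- loc
    }
  }
  out
}

#' Classify one locus
#'
#' Precedence: full-length, then MITE, then partial, then non-autonomous,
#' else unclassified. Full/partial/non-autonomous use the single best hit's
#' span ("a scaffold hit"); the MITE rule uses the union of query intervals
#' of hits at or above the MITE identity, which must cover both TIR
#' intervals (one spanning hit or two separate TIR hits both qualify).
#'
#' @param locus one element of [cluster_loci()]'s result.
#' @param element_length element length in nt.
#' @param tir TIR pair from [find_tirs()], or NULL (MITE never assigned).
#' @param t a [census_thresholds()].
#' @return one of `COPY_CLASSES`.
#' @export
classify_locus <- function(locus, element_length, tir = NULL,
                           t = census_thresholds()) {
  if (element_length <= 0L) stop("element_length must be positive")
  cov <- (locus$qend - locus$qstart + 1) / element_length
  if (any(locus$pident >= t$full_min_id & cov >= t$full_min_cov))
    return("full_length")
  if (!is.null(tir)) {
    hi <- locus[locus$pident >= t$mite_tir_min_id, , drop = FALSE]
    if (nrow(hi)) {
      iv <- cbind(hi$qstart, hi$qend)
      if (intervals_cover(iv, tir$tir5[["start"]], tir$tir5[["end"]]) &&
          intervals_cover(iv, tir$tir3[["start"]], tir$tir3[["end"]]))
        return("mite")
    }
  }
  if (any(locus$pident >= t$partial_min_id & cov >= t$partial_min_cov))
    return("partial")
  if (any(locus$pident >= t$nonaut_min_id & cov >= t$nonaut_min_cov))
    return("non_autonomous")
  "unclassified"
}

#' Copy-number census for one element
#'
#' Clusters the hit table into loci and classifies each; counts sum to the
#' number of loci.
#'
#' @param hits element-vs-genome hit table (one query).
#' @param element_length element length in nt.
#' @param tir TIR pair or NULL.
#' @param t a [census_thresholds()].
#' @param max_gap see [cluster_loci()].
#' @return named integer vector over `COPY_CLASSES`.
#' @export
census <- function(hits, element_length, tir = NULL,
                   t = census_thresholds(), max_gap = 2L * element_length) {
  counts <- stats::setNames(integer(length(COPY_CLASSES)), COPY_CLASSES)
  loci <- cluster_loci(hits, element_length, max_gap)
  for (loc in loci) {
    cls <- classify_locus(loc, element_length, tir, t)
    counts[cls] <- counts[cls] + 1L
  }
  counts
}
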