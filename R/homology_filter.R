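# The mining stage: the hit-retention rule (50% identity over at least 50%
# of the query length) and the iterative query-expansion loop with a
# pluggable search engine.

#' Retention thresholds for homology hits
#' @param min_identity_pct minimum percent identity (default 50).
#' @param min_query_coverage minimum fraction of the query length spanned by
#'   the hit (default 0.5).
#' @export
retention_thresholds <- function(min_identity_pct = 50,
                                 min_query_coverage = 0.5) {
  stopifnot(min_identity_pct >= 0, min_identity_pct <= 100,
            min_query_coverage >= 0, min_query_coverage <= 1)
  structure(list(min_identity_pct = min_identity_pct,
                 min_query_coverage = min_query_coverage),
            class = "retention_thresholds")
}

#' Filter hits by identity and query coverage
#'
#' A hit is retained iff `pident >= min_identity_pct` and
#' `(qend - qstart + 1) / query_length >= min_query_coverage` (both
#' boundaries inclusive). Coverage uses the alignment span on the query, not
#' the gapped alignment length, so gapped alignments are handled robustly.
#'
#' @param hits hit table data.frame (see [parse_hit_table()]).
#' @param query_lengths named numeric vector, query id -> length.
#' @param t a [retention_thresholds()].
#' @return the retained rows, order preserved.
#' @export
filter_hits <- function(hits, query_lengths, t = retention_thresholds()) {
  missing <- setdiff(unique(hits$qseqid), names(query_lengths))
  if (length(missing))
    stop("no query length for: ", paste(missing, collapse = ", "))
  if (nrow(hits) == 0L) return(hits)
  qlen <- query_lengths[hits$qseqid]
  cov <- (hits$qend - hits$qstart + 1) / qlen
  keep <- hits$pident >= t$min_identity_pct & cov >= t$min_query_coverage
  hits[keep, , drop = FALSE]
}

# Global protein identity between two sequences (alignment-module convention).
global_identity <- function(a, b) {
  global_align(a, b, type = "protein")$pct_identity
}

# Single-linkage clusters of sequences at >= link_identity_pct; returns a
# list of character vectors of ids.
single_linkage_clusters <- function(seqs, link_identity_pct) {
  ids <- names(seqs)
  n <- length(ids)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1L:(n - 1L)) for (j in (i + 1L):n) {
    if (global_identity(seqs[[i]], seqs[[j]]) >= link_identity_pct) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(ids, roots))
}

# Deterministic cluster representative: longest sequence, ties broken
# lexicographically by id.
cluster_representative <- function(seqs, member_ids) {
  sub <- seqs[member_ids]
  o <- order(-nchar(sub), names(sub))
  names(sub)[o[1L]]
}

#' Iterative mining with query expansion
#'
#' Round 1 searches every seed. Retained sequences that show less than
#' `novelty_identity_pct` global identity to every query used so far are
#' taken as newly identified groups; they are single-linkage clustered at
#' the same identity threshold and one representative per cluster (longest,
#' ties by id) becomes a next-round query. Terminates when no new
#' representative arises or after `max_rounds`.
#'
#' @param search function(query sequence, query id) returning a list with
#'   `hits` (hit table rows for that query) and `sequences` (named character
#'   vector of the subject sequences). Must be deterministic.
#' @param seeds named character vector of seed protein sequences.
#' @param t a [retention_thresholds()].
#' @param novelty_identity_pct identity below which a retained sequence
#'   counts as novel (default 50).
#' @param max_rounds hard cap on rounds (>= 1).
#' @return list: `sequences` (deduplicated union of retained sequences,
#'   seeds included), `queries_used`, `rounds`, `aborted` (TRUE when the
#'   search callable failed; partial results are returned).
#' @export
iterate_mining <- function(search, seeds, t = retention_thresholds(),
                           novelty_identity_pct = 50, max_rounds = 10L) {
  stopifnot(max_rounds >= 1L)
  collected <- seeds
  queries <- seeds
  queued <- seeds
  rounds <- 0L
  aborted <- FALSE
  while (length(queued) > 0L && rounds < max_rounds) {
    rounds <- rounds + 1L
    retained <- character(0)
    for (qi in names(queued)) {
      res <- tryCatch(search(queued[[qi]], qi), error = function(e) e)
      if (inherits(res, "error")) { aborted <- TRUE; break }
      kept <- filter_hits(res$hits,
                          stats::setNames(nchar(queued[[qi]]), qi), t)
      got <- res$sequences[intersect(unique(kept$sseqid),
                                     names(res$sequences))]
      retained <- c(retained, got[!names(got) %in% names(retained)])
    }
    new_seqs <- retained[!names(retained) %in% names(collected)]
    collected <- c(collected, new_seqs)
    if (aborted) break
    # novel = below the novelty threshold against every query used so far
    novel <- new_seqs[vapply(new_seqs, function(s) {
      all(vapply(queries, function(q) global_identity(s, q), numeric(1)) <
            novelty_identity_pct)
    }, logical(1))]
    queued <- character(0)
    if (length(novel)) {
      reps <- vapply(single_linkage_clusters(novel, novelty_identity_pct),
                     function(m) cluster_representative(novel, m),
                     character(1))
      queued <- novel[sort(reps)]
      queries <- c(queries, queued)
    }
  }
  list(sequences = collected, queries_used = names(queries),
       rounds = rounds, aborted = aborted)
}
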