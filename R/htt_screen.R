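# Horizontal transposon transfer (HTT) candidate screen: pairwise identities
# between elements of distantly related hosts, genome copy checks, and the
# contamination heuristics (single-hit rule; >95%/<95% identity asymmetry;
# <92% per-copy or <80% full-element identity => too divergent to pursue).

#' HTT screen thresholds
#'
#' @param min_host_divergence_rank hosts must differ at or above this
#'   taxonomy rank to be evaluated (default "phylum").
#' @param copy_identity_high_pct per-copy identity above which copies count
#'   as recent (95).
#' @param full_element_low_pct full-element identity below which a pair is
#'   rejected as divergent (80).
#' @param copy_identity_low_pct per-copy identity below which genome copies
#'   are too divergent (92).
#' @param min_copies_for_confidence minimum loci per genome (2; a single
#'   locus triggers the contamination flag).
#' @export
htt_thresholds <- function(min_host_divergence_rank = "phylum",
                           copy_identity_high_pct = 95,
                           full_element_low_pct = 80,
                           copy_identity_low_pct = 92,
                           min_copies_for_confidence = 2L) {
  stopifnot(min_host_divergence_rank %in% TAXONOMY_RANKS)
  structure(list(min_host_divergence_rank = min_host_divergence_rank,
                 copy_identity_high_pct = copy_identity_high_pct,
                 full_element_low_pct = full_element_low_pct,
                 copy_identity_low_pct = copy_identity_low_pct,
                 min_copies_for_confidence = min_copies_for_confidence),
            class = "htt_thresholds")
}

# Longest ORF of an element, or NULL.
longest_orf <- function(bases, min_len_aa = 50L) {
  orfs <- find_orfs(bases, min_len_aa = min_len_aa)
  if (nrow(orfs) == 0L) return(NULL)
  orfs[1L, , drop = FALSE]
}

#' Pairwise identities between two elements
#'
#' Computes (i) the amino-acid identity of the DDE domains (the catalytic
#' span from the first to the third triad residue of each transposase),
#' (ii) the nucleotide identity of the transposase ORFs, and (iii) the
#' nucleotide identity of the full elements when both carry TIR-to-TIR
#' sequence. All three are global-alignment identities with gaps counted in
#' the denominator.
#'
#' @param a,b element records: lists with at least `bases`; `tir` (from
#'   [find_tirs()] or NULL) marks whether the element is full-length.
#' @param spacing_range triad spacing window for the DDE scan.
#' @return list (aa_identity_dde, nt_identity_transposase,
#'   nt_identity_full_element (NA unless both full-length), unverifiable,
#'   reason).
#' @export
pair_identities <- function(a, b, spacing_range = c(25L, 70L)) {
  get_parts <- function(el) {
    orfs <- find_orfs(el$bases, min_len_aa = 50L)
    # the transposase is taken as the longest ORF with a locatable triad
    for (k in seq_len(nrow(orfs))) {
      cds <- orf_sequence(el$bases, orfs[k, , drop = FALSE])
      prot <- translate_cds(cds)
      calls <- detect_motif_denovo(prot, spacing_range)
      if (length(calls)) {
        call <- calls[[1L]]
        return(list(cds = cds, prot = prot,
                    dde = substr(prot, call$pos1, call$pos3)))
      }
    }
    NULL
  }
  pa <- get_parts(a); pb <- get_parts(b)
  full_id <- NA_real_
  if (!is.null(a$tir) && !is.null(b$tir)) {
    full_id <- global_align(a$bases, b$bases, type = "dna")$pct_identity
  }
  if (is.null(pa) || is.null(pb)) {
    return(list(aa_identity_dde = NA_real_,
                nt_identity_transposase = NA_real_,
                nt_identity_full_element = full_id,
                unverifiable = TRUE,
                reason = "DDE domain not locatable"))
  }
  list(
    aa_identity_dde = global_align(pa$dde, pb$dde, type = "protein")$pct_identity,
    nt_identity_transposase = global_align(pa$cds, pb$cds, type = "dna")$pct_identity,
    nt_identity_full_element = full_id,
    unverifiable = FALSE, reason = ""
  )
}

#' Genome copy check for one element
#'
#' Clusters the element-vs-genome hits into loci; a single locus raises the
#' contamination suspicion flag (the element may not be a resident,
#' multi-copy transposon of that genome).
#'
#' @param element_length element length in nt.
#' @param genome_hits hit table (element as query) or NULL when no genome is
#'   available.
#' @param t an [htt_thresholds()].
#' @return list (available, copy_count, copy_identities,
#'   single_copy_contamination_suspect).
#' @export
genome_copy_check <- function(element_length, genome_hits,
                              t = htt_thresholds()) {
  if (is.null(genome_hits)) {
    return(list(available = FALSE, copy_count = NA_integer_,
                copy_identities = numeric(0),
                single_copy_contamination_suspect = NA))
  }
  loci <- cluster_loci(genome_hits, element_length)
  ids <- vapply(loci, function(l) max(l$pident), numeric(1))
  list(available = TRUE, copy_count = length(loci), copy_identities = ids,
       single_copy_contamination_suspect =
         length(loci) < t$min_copies_for_confidence)
}

# Broadest rank at which two lineages differ ("" ranks compare equal only to
# ""); returns the rank name or NA when identical at all ranks.
host_divergence_rank <- function(tax, id_a, id_b) {
  ra <- tax[tax$lineage_id == id_a, , drop = FALSE]
  rb <- tax[tax$lineage_id == id_b, , drop = FALSE]
  if (nrow(ra) != 1L || nrow(rb) != 1L) stop("unknown lineage id")
  for (r in TAXONOMY_RANKS) {
    if (!identical(ra[[r]], rb[[r]])) return(r)
  }
  NA_character_
}

rank_depth <- function(r) match(r, TAXONOMY_RANKS)

#' Screen element pairs for horizontal-transfer candidacy
#'
#' A pair is evaluated only when its hosts differ at or above
#' `min_host_divergence_rank`. The decision table, in order: genome
#' unavailable for either side -> `unverifiable`; any genome single-copy ->
#' `rejected_contamination_suspect`; per-copy identity below
#' `copy_identity_low_pct` in both genomes, or full-element identity below
#' `full_element_low_pct` -> `rejected_divergent`; copies >= 95% identical
#' in one genome but < 95% in the other (asymmetric) ->
#' `rejected_contamination_suspect`; otherwise `candidate`.
#'
#' @param elements named list of element records: each a list with `bases`,
#'   `lineage_id`, optional `tir` (see [pair_identities()]).
#' @param taxonomy data.frame from [read_taxonomy()].
#' @param hit_tables named list (by element id) of element-vs-host-genome
#'   hit tables; NULL / missing entry = genome unavailable.
#' @param t an [htt_thresholds()].
#' @param pairs optional 2-column data.frame of element id pairs; default
#'   all unordered pairs.
#' @return data.frame, one row per evaluated pair: ids, identities, copy
#'   counts, flags (comma-joined) and verdict.
#' @export
screen_pairs <- function(elements, taxonomy, hit_tables = list(),
                         t = htt_thresholds(), pairs = NULL) {
  ids <- names(elements)
  if (is.null(pairs)) {
    if (length(ids) < 2L) return(empty_verdicts())
    cmb <- utils::combn(ids, 2L)
    pairs <- data.frame(a = cmb[1L, ], b = cmb[2L, ],
                        stringsAsFactors = FALSE)
  }
  rows <- list()
  gate <- rank_depth(t$min_host_divergence_rank)
  for (k in seq_len(nrow(pairs))) {
    ia <- pairs[[1L]][k]; ib <- pairs[[2L]][k]
    ea <- elements[[ia]]; eb <- elements[[ib]]
    dr <- host_divergence_rank(taxonomy, ea$lineage_id, eb$lineage_id)
    if (is.na(dr) || rank_depth(dr) > gate) next  # plausibly vertical
    pid <- pair_identities(ea, eb)
    ca <- genome_copy_check(nchar(ea$bases), hit_tables[[ia]], t)
    cb <- genome_copy_check(nchar(eb$bases), hit_tables[[ib]], t)
    flags <- character(0)
    if (pid$unverifiable || !ca$available || !cb$available) {
      verdict <- "unverifiable"
    } else {
      if (isTRUE(ca$single_copy_contamination_suspect) ||
          isTRUE(cb$single_copy_contamination_suspect))
        flags <- c(flags, "single_copy_contamination_suspect")
      hi_a <- length(ca$copy_identities) > 0L &&
        all(ca$copy_identities >= t$copy_identity_high_pct)
      hi_b <- length(cb$copy_identities) > 0L &&
        all(cb$copy_identities >= t$copy_identity_high_pct)
      if (xor(hi_a, hi_b)) flags <- c(flags, "asymmetric_identity")
      low_copies <- length(ca$copy_identities) > 0L &&
        length(cb$copy_identities) > 0L &&
        max(ca$copy_identities) < t$copy_identity_low_pct &&
        max(cb$copy_identities) < t$copy_identity_low_pct
      div_full <- !is.na(pid$nt_identity_full_element) &&
        pid$nt_identity_full_element < t$full_element_low_pct
      if (low_copies || div_full) flags <- c(flags, "divergent_pair")
      verdict <- if ("single_copy_contamination_suspect" %in% flags) {
        "rejected_contamination_suspect"
      } else if ("divergent_pair" %in% flags) {
        "rejected_divergent"
      } else if ("asymmetric_identity" %in% flags) {
        "rejected_contamination_suspect"
      } else "candidate"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = ia, id_b = ib, host_divergence_rank = dr,
      aa_identity_dde = pid$aa_identity_dde,
      nt_identity_transposase = pid$nt_identity_transposase,
      nt_identity_full_element = pid$nt_identity_full_element,
      copies_a = ca$copy_count, copies_b = cb$copy_count,
      flags = paste(flags, collapse = ","), verdict = verdict,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_verdicts())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_verdicts <- function() {
  data.frame(id_a = character(0), id_b = character(0),
             host_divergence_rank = character(0),
             aa_identity_dde = numeric(0),
             nt_identity_transposase = numeric(0),
             nt_identity_full_element = numeric(0),
             copies_a = integer(0), copies_b = integer(0),
             flags = character(0), verdict = character(0),
             stringsAsFactors = FALSE)
}
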