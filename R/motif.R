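# Locating the DDD/E catalytic triad, spacing arithmetic, signature strings
# and the family lookup. Family naming follows the ITm signature convention:
# res1 + res2 + (residue count strictly between positions 2 and 3) + res3,
# e.g. DD34E. Only the second interval is used for classification.

#' Construct a motif call
#'
#' @param pos1,pos2,pos3 1-based positions in the ungapped query sequence.
#' @param res1,res2,res3 the residues observed at those positions.
#' @return object of class `motif_call` with `spacing = pos3 - pos2 - 1`
#'   (residues strictly between positions 2 and 3) and `spacing12` (between
#'   positions 1 and 2; reported, never used for classification).
#' @export
motif_call <- function(pos1, pos2, pos3, res1, res2, res3) {
  stopifnot(pos1 < pos2, pos2 < pos3)
  structure(list(found = TRUE,
                 pos1 = as.integer(pos1), pos2 = as.integer(pos2),
                 pos3 = as.integer(pos3),
                 res1 = res1, res2 = res2, res3 = res3,
                 spacing = as.integer(pos3 - pos2 - 1L),
                 spacing12 = as.integer(pos2 - pos1 - 1L)),
            class = "motif_call")
}

motif_not_found <- function(reason) {
  structure(list(found = FALSE, reason = reason), class = "motif_call")
}

#' Signature string of a motif call
#' @param call a `motif_call`.
#' @return e.g. `"DD34E"`, or NA for a no-call.
#' @export
motif_signature <- function(call) {
  if (!isTRUE(call$found)) return(NA_character_)
  paste0(call$res1, call$res2, call$spacing, call$res3)
}

#' Parse a signature string back into its components
#' @param sig e.g. `"DD34E"`.
#' @return list(res1, res2, spacing, res3).
#' @export
parse_signature <- function(sig) {
  m <- regmatches(sig, regexec("^([A-Z])([A-Z])([0-9]+)([A-Z])$", sig))[[1]]
  if (length(m) != 5L) stop("malformed signature: ", sig)
  list(res1 = m[2L], res2 = m[3L], spacing = as.integer(m[4L]), res3 = m[5L])
}

#' Read the catalytic triad off a profile alignment
#'
#' Residues are read at the profile's three catalytic columns and mapped back
#' to ungapped query coordinates; insertions between columns therefore count
#' towards the spacing. A gap at any catalytic column yields a no-call.
#'
#' @param pa a `profile_alignment` from [align_to_profile()].
#' @param profile the [seed_profile()] it was aligned against.
#' @return a `motif_call` (check `$found`).
#' @export
detect_motif <- function(pa, profile) {
  stopifnot(inherits(pa, "profile_alignment"), inherits(profile, "seed_profile"))
  cc <- profile$catalytic_cols
  pos <- pa$col_to_pos[cc]
  if (anyNA(pos)) return(motif_not_found("deleted catalytic position"))
  ch <- strsplit(pa$query, "")[[1]]
  motif_call(pos[1L], pos[2L], pos[3L], ch[pos[1L]], ch[pos[2L]], ch[pos[3L]])
}

#' De novo triad scan
#'
#' Enumerates all position triples (p1 < p2 < p3) whose residues fall in the
#' three allowed sets and whose second interval length lies in
#' `spacing_range`. Fallback for sequences without a profile alignment.
#'
#' @param seq ungapped protein string.
#' @param spacing_range length-2 integer vector, inclusive bounds on
#'   `p3 - p2 - 1`.
#' @param residue_sets list of three character vectors of allowed residues,
#'   default `list("D", "D", c("D", "E"))`.
#' @return list of `motif_call`s ordered by (p1, p2, p3); possibly empty.
#' @export
detect_motif_denovo <- function(seq, spacing_range = c(25L, 70L),
                                residue_sets = list("D", "D", c("D", "E"))) {
  stopifnot(length(spacing_range) == 2L, spacing_range[1L] >= 0L)
  ch <- strsplit(seq, "")[[1]]
  i1 <- which(ch %in% residue_sets[[1L]])
  i2 <- which(ch %in% residue_sets[[2L]])
  i3 <- which(ch %in% residue_sets[[3L]])
  out <- list()
  for (p1 in i1) {
    for (p2 in i2[i2 > p1]) {
      lo <- p2 + 1L + spacing_range[1L]
      hi <- p2 + 1L + spacing_range[2L]
      for (p3 in i3[i3 >= lo & i3 <= hi]) {
        out[[length(out) + 1L]] <-
          motif_call(p1, p2, p3, ch[p1], ch[p2], ch[p3])
      }
    }
  }
  out
}

# The family lookup. Exact signatures first; then the pogo spacing-range
# rule; ambiguous signatures return the full candidate set (resolution is
# deferred to clade membership in the phylogeny).
SIGNATURE_FAMILIES <- list(
  DD34D = "mariner",
  DD34E = c("Tc1", "Tec", "TBE", "HvSm"),
  DD39D = "PlantMar",
  DD37D = "maT",
  DD41D = "rosa",
  DD37E = c("TRT", "impala", "DD37E(L31)")
)

#' Map a triad signature to candidate families
#'
#' Lookup: DD34D -> mariner; DD34E -> Tc1/Tec/TBE/HvSm (ambiguous, resolved
#' only phylogenetically); DD39D -> PlantMar; DD37D -> maT; DD41D -> rosa;
#' DD37E -> TRT/impala/DD37E(L31); other DD(30-35)D -> pogo; anything else ->
#' unknown. Degenerate catalytic residues (domesticated-gene patterns such as
#' DA30P or DD34S) are kept verbatim in the signature and flagged.
#'
#' @param sig signature string, e.g. `"DD34E"`.
#' @return list with `signature`, `spacing`, `candidate_families`,
#'   `degenerate` (logical) and `note`.
#' @export
assign_family <- function(sig) {
  p <- parse_signature(sig)
  degenerate <- !(p$res1 == "D" && p$res2 == "D" && p$res3 %in% c("D", "E"))
  note <- if (degenerate)
    "degenerate catalytic residue(s): domesticated-gene-like motif" else ""
  fams <- "unknown"
  if (!degenerate) {
    if (!is.null(SIGNATURE_FAMILIES[[sig]])) {
      fams <- SIGNATURE_FAMILIES[[sig]]
    } else if (p$res3 == "D" && p$spacing >= 30L && p$spacing <= 35L) {
      fams <- "pogo"
    }
  }
  list(signature = sig, spacing = p$spacing, candidate_families = fams,
       degenerate = degenerate, note = note)
}

#' Motif-classify a set of transposase sequences
#'
#' Convenience wrapper: profile alignment when a profile is given, otherwise
#' the de novo scan (first triad in spacing range); then the family lookup.
#'
#' @param seqs named character vector of protein sequences.
#' @param profile optional [seed_profile()].
#' @param spacing_range passed to [detect_motif_denovo()] when no profile.
#' @return data.frame: id, signature, spacing, candidates (comma-joined),
#'   degenerate, found.
#' @export
classify_motifs <- function(seqs, profile = NULL, spacing_range = c(25L, 70L)) {
  rows <- lapply(names(seqs), function(id) {
    call <- if (!is.null(profile)) {
      detect_motif(align_to_profile(seqs[[id]], profile), profile)
    } else {
      hits <- detect_motif_denovo(seqs[[id]], spacing_range)
      if (length(hits)) hits[[1L]] else motif_not_found("no triad in range")
    }
    if (!isTRUE(call$found)) {
      return(data.frame(id = id, signature = NA_character_,
                        spacing = NA_integer_, candidates = NA_character_,
                        degenerate = NA, found = FALSE,
                        stringsAsFactors = FALSE))
    }
    fam <- assign_family(motif_signature(call))
    data.frame(id = id, signature = fam$signature, spacing = fam$spacing,
               candidates = paste(fam$candidate_families, collapse = ","),
               degenerate = fam$degenerate, found = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
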