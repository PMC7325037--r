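# Structure annotation of nucleotide elements: transposase ORFs, terminal
# inverted repeats (TIRs) and the TA target-site duplication (TSD).
# Coordinates are 1-based closed intervals on the forward strand.

#' Find ATG-to-stop ORFs in all six frames
#'
#' Every ATG opens an ORF running to the next in-frame stop codon; ORFs
#' without a downstream stop are not reported. The reported nucleotide span
#' includes the stop codon.
#'
#' @param bases DNA string over A, C, G, T, N.
#' @param min_len_aa minimum number of codons excluding the stop.
#' @return data.frame (start, end, strand, frame, length_nt) sorted by
#'   length descending, then start, then strand.
#' @export
find_orfs <- function(bases, min_len_aa = 1L) {
  stopifnot(min_len_aa >= 1L)
  n <- nchar(bases)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") bases else revcomp(bases)
    for (f in 0:2) {
      starts_nt <- seq.int(f + 1L, n, by = 3L)
      starts_nt <- starts_nt[starts_nt + 2L <= n]
      if (!length(starts_nt)) next
      codons <- substring(s, starts_nt, starts_nt + 2L)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% STOP_CODONS)
      if (!length(atg) || !length(stp)) next
      # next in-frame stop strictly after each ATG
      nxt <- stp[findInterval(atg, stp) + 1L]
      ok <- !is.na(nxt)
      atg <- atg[ok]; nxt <- nxt[ok]
      len_aa <- nxt - atg  # codons excluding the stop
      keep <- len_aa >= min_len_aa
      if (!any(keep)) next
      a <- starts_nt[atg[keep]]
      b <- starts_nt[nxt[keep]] + 2L  # include stop codon
      if (strand == "+") {
        st <- a; en <- b
      } else {
        st <- n - b + 1L; en <- n - a + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        start = st, end = en, strand = strand, frame = f,
        length_nt = b - a + 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length_nt = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$length_nt, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find the terminal inverted repeat pair
#'
#' Terminal-anchored search: the 5' arm must start within `slack` nt of the
#' first base and the 3' arm must end within `slack` nt of the last base.
#' The two arms are compared ungapped (the 3' arm reverse-complemented);
#' identity is match count over the compared length. Scored as
#' matches - mismatches; ties go to the longer TIR, then the 5'-most.
#'
#' @param bases DNA string.
#' @param window maximum arm length examined (must be <= floor(n/2) - slack).
#' @param min_len,min_identity_pct acceptance thresholds.
#' @param slack permitted offset of each arm from its terminus.
#' @return list (tir5 = c(start, end), tir3 = c(start, end), length,
#'   identity_pct) or NULL when no pair passes.
#' @export
find_tirs <- function(bases, window = 100L, min_len = 10L,
                      min_identity_pct = 80, slack = 5L) {
  n <- nchar(bases)
  if (window > n %/% 2L) stop("window exceeds half the element length")
  ch <- strsplit(bases, "")[[1]]
  comp <- chartr("ACGTN", "TGCAN", ch)
  best <- NULL
  for (a in 0:slack) {
    if (a + window > n) break
    x <- ch[(a + 1L):(a + window)]
    for (b in 0:slack) {
      # y[k] = complement of base at n - b - k + 1 (3' arm read inwards)
      idx <- (n - b):(n - b - window + 1L)
      if (idx[length(idx)] <= a + window) next  # arms may not overlap
      y <- comp[idx]
      cm <- cumsum(x == y)
      Ls <- min_len:window
      ident <- 100 * cm[Ls] / Ls
      score <- 2L * cm[Ls] - Ls
      ok <- which(ident >= min_identity_pct)
      if (!length(ok)) next
      k <- ok[order(-score[ok], -Ls[ok])][1L]
      cand <- list(L = Ls[k], a = a, b = b,
                   score = score[k], identity = ident[k])
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score && cand$L > best$L) ||
          (cand$score == best$score && cand$L == best$L &&
           (cand$a < best$a || (cand$a == best$a && cand$b < best$b)))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(tir5 = c(start = best$a + 1L, end = best$a + best$L),
       tir3 = c(start = n - best$b - best$L + 1L, end = n - best$b),
       length = best$L, identity_pct = best$identity)
}

#' Check for a target-site duplication in the flanks
#'
#' The TSD is the dinucleotide duplicated on both sides of the insertion:
#' the last two nt of the 5' flank must equal the first two nt of the
#' 3' flank. ITm elements duplicate "TA".
#'
#' @param flank5,flank3 flanking sequences (may be empty).
#' @return list (tsd, is_ta) or list (tsd = NULL, reason).
#' @export
check_tsd <- function(flank5 = "", flank3 = "") {
  if (is.null(flank5) || is.null(flank3) ||
      nchar(flank5) < 2L || nchar(flank3) < 2L) {
    return(list(tsd = NULL, reason = "no flanks"))
  }
  t5 <- substr(flank5, nchar(flank5) - 1L, nchar(flank5))
  t3 <- substr(flank3, 1L, 2L)
  if (t5 != t3) return(list(tsd = NULL, reason = "flank dinucleotides differ"))
  list(tsd = t5, is_ta = identical(t5, "TA"))
}

#' Annotate an element: ORFs, TIR pair and TSD
#'
#' @param bases element sequence (TIR to TIR).
#' @param id element identifier.
#' @param flank5,flank3 host flanking sequence (for the TSD check).
#' @param min_len_aa minimum ORF length in codons.
#' @param tir_window,tir_min_len,tir_min_identity_pct,tir_slack TIR search
#'   parameters, see [find_tirs()].
#' @return object of class `element_annotation`: element_id, total_length,
#'   orfs (data.frame), tir (list or NULL), tsd (list).
#' @export
annotate_element <- function(bases, id = "element", flank5 = "", flank3 = "",
                             min_len_aa = 50L, tir_window = 100L,
                             tir_min_len = 10L, tir_min_identity_pct = 80,
                             tir_slack = 5L) {
  tir_window <- min(tir_window, nchar(bases) %/% 2L)
  structure(list(
    element_id = id,
    total_length = nchar(bases),
    orfs = find_orfs(bases, min_len_aa = min_len_aa),
    tir = find_tirs(bases, window = tir_window, min_len = tir_min_len,
                    min_identity_pct = tir_min_identity_pct,
                    slack = tir_slack),
    tsd = check_tsd(flank5, flank3)
  ), class = "element_annotation")
}

#' Extract the nucleotide sequence of an ORF record
#' @param bases element sequence.
#' @param orf one row of the data.frame from [find_orfs()].
#' @return the coding sequence 5'->3' (reverse-complemented for "-" strand).
#' @export
orf_sequence <- function(bases, orf) {
  s <- substr(bases, orf$start, orf$end)
  if (orf$strand == "-") s <- revcomp(s)
  s
}

#' Translate a coding sequence
#' @param cds in-frame DNA string (length divisible by 3).
#' @param strip_stop drop a trailing stop residue.
#' @return protein string.
#' @export
translate_cds <- function(cds, strip_stop = TRUE) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  if (strip_stop) aa <- sub("\\*$", "", aa)
  aa
}
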