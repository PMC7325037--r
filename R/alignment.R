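# Pairwise global alignment (EMBOSS-stretcher-style identity convention) and
# sequence-to-profile alignment against the seed DDE-domain profile.
#
# Identity convention used repo-wide: 100 * identical columns / total
# alignment columns, gaps included in the denominator.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

dna_submat <- function(match = 5, mismatch = -4) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Global pairwise alignment with percent identity
#'
#' Needleman-Wunsch global alignment with affine gaps (a gap of length L
#' costs `gap_open + L * gap_extend`). Percent identity is computed over all
#' alignment columns, gaps included, matching the EMBOSS convention the
#' downstream horizontal-transfer thresholds assume.
#'
#' @param a,b sequences (single strings, same alphabet).
#' @param type "auto" guesses DNA vs protein from the alphabet.
#' @param submat substitution matrix; defaults to BLOSUM62 for protein and
#'   +5/-4 for DNA.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return list with `aligned_a`, `aligned_b` (equal-length gapped strings),
#'   `score` and `pct_identity`.
#' @export
global_align <- function(a, b, type = c("auto", "protein", "dna"),
                         submat = NULL, gap_open = NULL, gap_extend = NULL) {
  type <- match.arg(type)
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (type == "auto") {
    da <- looks_like_dna(a); db <- looks_like_dna(b)
    if (da != db) stop("mixed alphabets: one sequence looks like DNA, the other does not")
    type <- if (da) "dna" else "protein"
  }
  if (type == "protein") {
    submat <- submat %||% blosum62()
    gap_open <- gap_open %||% 10
    gap_extend <- gap_extend %||% 0.5
    pa <- Biostrings::AAString(a); pb <- Biostrings::AAString(b)
  } else {
    submat <- submat %||% dna_submat()
    gap_open <- gap_open %||% 16
    gap_extend <- gap_extend %||% 4
    pa <- Biostrings::BString(a); pb <- Biostrings::BString(b)
  }
  aln <- Biostrings::pairwiseAlignment(
    pa, pb, type = "global", substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  sa <- as.character(Biostrings::alignedPattern(aln))
  sb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(sa, "")[[1]]; cb <- strsplit(sb, "")[[1]]
  out <- list(
    aligned_a = sa, aligned_b = sb,
    score = Biostrings::score(aln),
    pct_identity = 100 * sum(ca == cb & ca != "-") / length(ca)
  )
  class(out) <- "pairwise_alignment"
  out
}

#' Percent identity of two equal-length gapped strings
#'
#' Gap columns count in the denominator; gap/gap columns are forbidden.
#' @param sa,sb aligned strings.
#' @export
alignment_identity <- function(sa, sb) {
  ca <- strsplit(sa, "")[[1]]; cb <- strsplit(sb, "")[[1]]
  stopifnot(length(ca) == length(cb), !any(ca == "-" & cb == "-"))
  100 * sum(ca == cb & ca != "-") / length(ca)
}

#' Construct a seed profile
#'
#' A seed profile is a fixed gapped alignment (the DDE-domain seed) plus the
#' three column indices holding the catalytic D, D and D/E residues.
#'
#' @param rows named character vector of equal-length gapped sequences.
#' @param catalytic_cols three increasing 1-based column indices.
#' @return object of class `seed_profile`.
#' @export
seed_profile <- function(rows, catalytic_cols) {
  stopifnot(length(rows) >= 1L, length(catalytic_cols) == 3L)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("profile rows must have equal aligned length")
  catalytic_cols <- as.integer(catalytic_cols)
  stopifnot(all(diff(catalytic_cols) > 0L), catalytic_cols[1L] >= 1L,
            catalytic_cols[3L] <= w)
  structure(list(rows = rows, width = w, catalytic_cols = catalytic_cols),
            class = "seed_profile")
}

#' Read a seed profile from gapped FASTA plus a YAML sidecar
#'
#' The sidecar must define `catalytic_cols: [i, j, k]` (1-based columns).
#' @param fasta path to the gapped FASTA.
#' @param sidecar path to the YAML file; defaults to `<fasta>.yaml`.
#' @export
read_seed_profile <- function(fasta, sidecar = paste0(fasta, ".yaml")) {
  rows <- read_fasta(fasta)
  cfg <- yaml::read_yaml(sidecar)
  seed_profile(rows, cfg$catalytic_cols)
}

# Per-column match scores: matrix alphabet x width, entry = mean substitution
# score of the residue against the (non-gap) residues observed in the column.
profile_column_scores <- function(profile, submat) {
  ab <- rownames(submat)
  chm <- do.call(rbind, strsplit(profile$rows, ""))
  sc <- matrix(0, nrow = length(ab), ncol = profile$width,
               dimnames = list(ab, NULL))
  for (j in seq_len(profile$width)) {
    res <- chm[, j]
    res <- res[res != "-"]
    if (length(res) == 0L) next
    res[!res %in% ab] <- "X"
    f <- table(res) / length(res)
    sc[, j] <- as.vector(submat[, names(f), drop = FALSE] %*% as.numeric(f))
  }
  sc
}

#' Align a query sequence to a seed profile
#'
#' Dynamic programming of the query against per-column residue frequencies of
#' the profile, with affine gaps. Profile columns are immutable: the result
#' is a gapped query row in profile coordinates plus explicit insertion
#' records for query residues that fall between columns.
#'
#' @param seq query sequence (ungapped protein string).
#' @param profile a [seed_profile()].
#' @param submat substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap costs (gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @return object of class `profile_alignment`: `aligned_row` (gapped string,
#'   one character per profile column), `col_to_pos` (1-based ungapped query
#'   position per column, NA where the column is gapped), `insertions`
#'   (data.frame after_col / length / seq), `score`.
#' @export
align_to_profile <- function(seq, profile, submat = NULL,
                             gap_open = 10, gap_extend = 0.5) {
  stopifnot(inherits(profile, "seed_profile"))
  if (!nzchar(seq)) stop("empty query sequence")
  submat <- submat %||% blosum62()
  q <- strsplit(toupper(seq), "")[[1]]
  q[!q %in% rownames(submat)] <- "X"
  n <- length(q); W <- profile$width
  SC <- profile_column_scores(profile, submat)
  qs <- SC[q, , drop = FALSE]  # n x W match scores

  NEG <- -1e18
  M <- matrix(NEG, n + 1L, W + 1L)   # query i aligned to column j
  X <- matrix(NEG, n + 1L, W + 1L)   # query i is an insertion (consumes i)
  Y <- matrix(NEG, n + 1L, W + 1L)   # column j gapped in query (consumes j)
  M[1L, 1L] <- 0
  if (n >= 1L) X[2L:(n + 1L), 1L] <- -gap_open - gap_extend * (1L:n)
  if (W >= 1L) Y[1L, 2L:(W + 1L)] <- -gap_open - gap_extend * (1L:W)
  # pointers: 1 = from M, 2 = from X, 3 = from Y
  pM <- matrix(0L, n + 1L, W + 1L)
  pX <- matrix(0L, n + 1L, W + 1L)
  pY <- matrix(0L, n + 1L, W + 1L)
  jj <- seq_len(W)
  for (i in 2L:(n + 1L)) {
    prevM <- M[i - 1L, ]; prevX <- X[i - 1L, ]; prevY <- Y[i - 1L, ]
    # match state: best of the three states at (i-1, j-1)
    dM <- prevM[jj]; dX <- prevX[jj]; dY <- prevY[jj]
    best <- pmax(dM, dX, dY)
    M[i, jj + 1L] <- best + qs[i - 1L, ]
    pM[i, jj + 1L] <- ifelse(dM >= best, 1L, ifelse(dX >= best, 2L, 3L))
    # insertion state (consumes query residue i): from row i-1, same column
    xo <- prevM - gap_open - gap_extend
    xe <- prevX - gap_extend
    X[i, ] <- pmax(xo, xe)
    pX[i, ] <- ifelse(xo >= xe, 1L, 2L)
    # deletion state (gaps column j): within-row chain from M via cummax
    acm <- cummax(M[i, jj] + gap_extend * jj)
    Y[i, jj + 1L] <- acm - gap_open - gap_extend * (jj + 1L)
    pY[i, jj + 1L] <- ifelse(M[i, jj] - gap_open - gap_extend >=
                               Y[i, jj] - gap_extend, 1L, 3L)
  }
  ends <- c(M[n + 1L, W + 1L], X[n + 1L, W + 1L], Y[n + 1L, W + 1L])
  state <- which.max(ends)
  score <- ends[state]

  # Traceback.
  col_to_pos <- rep(NA_integer_, W)
  ins_after <- integer(0)   # one entry per inserted query residue
  ins_pos <- integer(0)
  i <- n + 1L; j <- W + 1L
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      col_to_pos[j - 1L] <- i - 1L
      state <- pM[i, j]
      if (state == 0L) state <- 1L
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ins_after <- c(ins_after, j - 1L)
      ins_pos <- c(ins_pos, i - 1L)
      ns <- pX[i, j]
      i <- i - 1L
      state <- if (ns == 0L) 2L else ns
    } else {
      ns <- pY[i, j]
      j <- j - 1L
      state <- if (ns == 0L) 3L else ns
    }
  }
  aligned_row <- rep("-", W)
  filled <- which(!is.na(col_to_pos))
  aligned_row[filled] <- q[col_to_pos[filled]]
  ins <- data.frame(after_col = integer(0), length = integer(0),
                    seq = character(0), stringsAsFactors = FALSE)
  if (length(ins_after)) {
    o <- order(ins_pos)
    ins_after <- ins_after[o]; ins_pos <- ins_pos[o]
    for (ac in unique(ins_after)) {
      p <- ins_pos[ins_after == ac]
      ins <- rbind(ins, data.frame(
        after_col = ac, length = length(p),
        seq = paste(q[p], collapse = ""), stringsAsFactors = FALSE))
    }
    ins <- ins[order(ins$after_col), , drop = FALSE]
    rownames(ins) <- NULL
  }
  structure(list(aligned_row = paste(aligned_row, collapse = ""),
                 col_to_pos = col_to_pos, insertions = ins, score = score,
                 query = paste(q, collapse = "")),
            class = "profile_alignment")
}
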