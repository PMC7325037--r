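# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The 20 standard amino acids
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA4 <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a DNA string
#'
#' @param x a single character string over A, C, G, T, N.
#' @return the reverse complement, same alphabet.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x), "")[[1]]), collapse = "")
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are reproducible without
#' disturbing the caller's random stream.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Random sequence of given length over an alphabet.
random_seq <- function(n, alphabet = DNA4) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Mutate each position independently with probability `rate` to a uniformly
# chosen different letter; positions in `keep` (1-based) are left untouched.
mutate_seq <- function(x, rate, alphabet, keep = integer(0)) {
  ch <- strsplit(x, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  hit <- setdiff(hit, keep)
  for (i in hit) {
    alt <- setdiff(alphabet, ch[i])
    ch[i] <- alt[sample.int(length(alt), 1L)]
  }
  paste(ch, collapse = "")
}

# Does every character of x belong to the DNA alphabet (incl. N and gap)?
looks_like_dna <- function(x) {
  !grepl("[^ACGTNacgtn-]", x)
}

# Merge 1-based closed intervals given as a 2-column matrix; returns a matrix
# of disjoint intervals sorted by start.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (k in 2L:nrow(iv)) {
    last <- nrow(out)
    if (iv[k, 1L] <= out[last, 2L] + 1L) {
      out[last, 2L] <- max(out[last, 2L], iv[k, 2L])
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  out
}

# TRUE iff the union of intervals `iv` fully covers [s, e].
intervals_cover <- function(iv, s, e) {
  if (nrow(iv) == 0L) return(FALSE)
  m <- merge_intervals(iv)
  any(m[, 1L] <= s & m[, 2L] >= e)
}
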