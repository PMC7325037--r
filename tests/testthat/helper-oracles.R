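# Independent brute-force oracles used to validate the implementations.
# These deliberately use the simplest possible algorithm, not the package's
# code paths.

# Exhaustive global alignment score with linear gap penalty (recursive DP
# over plain base R), for tiny sequences.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (ca[i] == cb[j]) match else mismatch,
      S[i, j + 1] + gap,
      S[i + 1, j] + gap
    )
  }
  S[n + 1, m + 1]
}

# Triple-nested enumeration of catalytic triads.
oracle_triads <- function(seq, spacing_range, sets = list("D", "D", c("D", "E"))) {
  ch <- strsplit(seq, "")[[1]]
  out <- list()
  n <- length(ch)
  for (p1 in seq_len(n)) for (p2 in seq_len(n)) for (p3 in seq_len(n)) {
    if (p1 < p2 && p2 < p3 &&
        ch[p1] %in% sets[[1]] && ch[p2] %in% sets[[2]] &&
        ch[p3] %in% sets[[3]] &&
        (p3 - p2 - 1) >= spacing_range[1] && (p3 - p2 - 1) <= spacing_range[2]) {
      out[[length(out) + 1]] <- c(p1, p2, p3)
    }
  }
  out
}

# Brute-force 6-frame ORF scan: check every position for ATG, walk codons
# to the first stop.
oracle_orfs <- function(bases, min_len_aa) {
  n <- nchar(bases)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") bases else tcmariner::revcomp(bases)
    for (st in seq_len(n - 2)) {
      if (substr(s, st, st + 2) != "ATG") next
      p <- st + 3
      repeat {
        if (p + 2 > n) break
        cod <- substr(s, p, p + 2)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          len_aa <- (p - st) / 3
          if (len_aa >= min_len_aa) {
            a <- st; b <- p + 2
            if (strand == "+") res[[length(res) + 1]] <- c(a, b)
            else res[[length(res) + 1]] <- c(n - b + 1, n - a + 1)
          }
          break
        }
        p <- p + 3
      }
    }
  }
  res
}

# Brute-force single-linkage locus partition: hits are linked when on the
# same subject+strand and their subject intervals are within max_gap.
oracle_loci <- function(hits, max_gap) {
  sr <- tcmariner::hit_subject_range(hits)
  n <- nrow(hits)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same <- hits$sseqid[i] == hits$sseqid[j] && sr$strand[i] == sr$strand[j]
    if (!same) next
    gap <- max(sr$smin[i], sr$smin[j]) - min(sr$smax[i], sr$smax[j])
    if (gap <= max_gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), comp))
}

# O(n^2) crossing count.
oracle_crossings <- function(left_order, right_order, links) {
  lp <- match(links$left, left_order)
  rp <- match(links$right, right_order)
  n <- nrow(links)
  cnt <- 0
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if ((lp[i] - lp[j]) * (rp[i] - rp[j]) < 0) cnt <- cnt + 1
  }
  cnt
}

# Exhaustive minimum crossings over all rotation combinations of both trees
# (small trees only).
oracle_min_crossings <- function(te_tree, host_tree, links) {
  orders_of <- function(tree) {
    cl <- tcmariner:::tree_to_clade(tree)
    rec <- function(node) {
      if (is.character(node)) return(list(node))
      kid_orders <- lapply(node, rec)
      out <- list()
      perms <- function(v) {
        if (length(v) == 1) return(list(v))
        res <- list()
        for (k in seq_along(v)) {
          for (rest in perms(v[-k])) res[[length(res) + 1]] <- c(v[k], rest)
        }
        res
      }
      for (pm in perms(seq_along(node))) {
        combos <- list(character(0))
        for (ix in pm) {
          combos <- unlist(lapply(combos, function(pre) {
            lapply(kid_orders[[ix]], function(o) c(pre, o))
          }), recursive = FALSE)
        }
        out <- c(out, combos)
      }
      unique(out)
    }
    rec(cl)
  }
  lo <- orders_of(te_tree); ro <- orders_of(host_tree)
  best <- Inf
  for (l in lo) for (r in ro) {
    best <- min(best, oracle_crossings(l, r, links))
  }
  best
}

# Random gapless alignment whose two halves differ at a fraction of sites.
random_alignment <- function(n_seq, n_col, alphabet = c("A", "C", "G", "T")) {
  sapply(seq_len(n_seq), function(i)
    paste(sample(alphabet, n_col, replace = TRUE), collapse = "")) |>
    stats::setNames(paste0("s", seq_len(n_seq)))
}

# Random additive distance matrix from a random binary tree; returns both.
random_additive <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.3, 2)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
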