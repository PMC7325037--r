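# Tanglegram machinery: a host tree built from the taxonomy table as a rank
# hierarchy, link crossing counts (inversion counting), and an alternating
# barycenter heuristic that minimises crossings by rotating internal nodes.
# The congruence statistic is the normalised crossing count after
# minimisation: low for codiverging TE/host histories, high when horizontal
# transfer scrambles the links.

#' Build a host tree from a taxonomy table
#'
#' The hierarchy kingdom -> phylum -> ... -> species becomes tree structure;
#' leaves are lineage ids. Single-child levels are collapsed; all branch
#' lengths are 1.
#'
#' @param tax data.frame from [read_taxonomy()].
#' @return rooted `ape::phylo` with `tip.label = lineage_id`.
#' @export
host_tree_from_taxonomy <- function(tax) {
  build <- function(rows, depth) {
    if (nrow(rows) == 1L) return(rows$lineage_id[1L])
    if (depth > length(TAXONOMY_RANKS)) {
      return(paste0("(",
                    paste0(rows$lineage_id, ":1", collapse = ","), ")"))
    }
    vals <- rows[[TAXONOMY_RANKS[depth]]]
    groups <- split(seq_len(nrow(rows)), factor(vals, levels = unique(vals)))
    if (length(groups) == 1L) return(build(rows, depth + 1L))
    kids <- vapply(groups, function(ix) {
      paste0(build(rows[ix, , drop = FALSE], depth + 1L), ":1")
    }, character(1))
    paste0("(", paste0(kids, collapse = ","), ")")
  }
  if (nrow(tax) < 2L) stop("need at least two lineages")
  nwk <- paste0(build(tax, 1L), ";")
  ape::read.tree(text = nwk)
}

#' Count link crossings between two leaf orders
#'
#' A pair of links {(a, b), (c, d)} crosses iff
#' (pos(a) - pos(c)) * (pos(b) - pos(d)) < 0. Counted as strict inversions
#' of the link permutation via mergesort.
#'
#' @param left_order,right_order leaf label permutations of the two trees.
#' @param links data.frame with columns `left` and `right`.
#' @return non-negative integer.
#' @export
count_crossings <- function(left_order, right_order, links) {
  if (any(!links$left %in% left_order))
    stop("link to unknown left leaf")
  if (any(!links$right %in% right_order))
    stop("link to unknown right leaf")
  lp <- match(links$left, left_order)
  rp <- match(links$right, right_order)
  o <- order(lp, rp)
  count_inversions(rp[o])
}

# Strict inversion count (pairs i < j with x[i] > x[j]) by mergesort.
count_inversions <- function(x) {
  n <- length(x)
  if (n < 2L) return(0L)
  count <- 0
  width <- 1L
  while (width < n) {
    lo <- 1L
    while (lo + width <= n) {
      mid <- lo + width - 1L
      hi <- min(lo + 2L * width - 1L, n)
      a <- x[lo:mid]; b <- x[(mid + 1L):hi]
      merged <- numeric(hi - lo + 1L)
      i <- 1L; j <- 1L; k <- 1L
      while (i <= length(a) && j <= length(b)) {
        if (a[i] <= b[j]) { merged[k] <- a[i]; i <- i + 1L }
        else { merged[k] <- b[j]; count <- count + (length(a) - i + 1L); j <- j + 1L }
        k <- k + 1L
      }
      if (i <= length(a)) merged[k:length(merged)] <- a[i:length(a)]
      if (j <= length(b)) merged[k:length(merged)] <- b[j:length(b)]
      x[lo:hi] <- merged
      lo <- hi + 1L
    }
    width <- 2L * width
  }
  as.integer(count)
}

# phylo -> nested list of children; a leaf is its label.
tree_to_clade <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  rec <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    lapply(kids[[as.character(node)]], rec)
  }
  rec(n + 1L)
}

clade_leaves <- function(cl) {
  if (is.character(cl)) return(cl)
  unlist(lapply(cl, clade_leaves))
}

# One barycenter pass: reorder children of every internal node of `cl` by
# the mean position (in `partner_pos`) of the leaves their subtrees link to.
# Children without links keep their relative position.
barycenter_sort <- function(cl, link_pos) {
  rec <- function(node) {
    if (is.character(node)) return(node)
    node <- lapply(node, rec)
    key <- vapply(seq_along(node), function(i) {
      p <- unlist(link_pos[clade_leaves(node[[i]])], use.names = FALSE)
      if (length(p)) mean(p) else NA_real_
    }, numeric(1))
    key[is.na(key)] <- seq_along(node)[is.na(key)]  # stable fallback
    node[order(key)]
  }
  rec(cl)
}

# Hill-climbing refinement over internal-node rotations. The neighbourhood
# is every child permutation of every internal node (full permutations for
# nodes with <= 4 children, adjacent swaps for wider nodes), first singly,
# then in pairs to step across plateaus that single rotations cannot leave.
# Only strict improvements are accepted, so crossings never increase.
refine_rotations <- function(cl_l, cl_r, links, cross, max_iter = 500L) {
  perms_of <- function(k) {
    if (k == 1L) return(list())
    if (k <= 4L) {
      out <- list()
      rec <- function(pre, rest) {
        if (!length(rest)) { out[[length(out) + 1L]] <<- pre; return() }
        for (r in seq_along(rest)) rec(c(pre, rest[r]), rest[-r])
      }
      rec(integer(0), seq_len(k))
      Filter(function(p) !identical(p, seq_len(k)), out)
    } else {
      lapply(seq_len(k - 1L), function(i) {
        ix <- seq_len(k); ix[c(i, i + 1L)] <- ix[c(i + 1L, i)]; ix
      })
    }
  }
  apply_at <- function(node, path, perm) {
    if (!length(path)) return(node[perm])
    node[[path[1L]]] <- apply_at(node[[path[1L]]], path[-1L], perm)
    node
  }
  moves_of <- function(cl) {
    paths <- list()
    walk <- function(node, path) {
      if (is.character(node)) return()
      paths[[length(paths) + 1L]] <<- path
      for (i in seq_along(node)) walk(node[[i]], c(path, i))
    }
    walk(cl, integer(0))
    out <- list()
    for (path in paths) {
      sub <- cl
      for (p in path) sub <- sub[[p]]
      for (perm in perms_of(length(sub))) {
        out[[length(out) + 1L]] <- list(path = path, perm = perm)
      }
    }
    out
  }
  eval_pair <- function(l, r) {
    count_crossings(clade_leaves(l), clade_leaves(r), links)
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    improved <- FALSE
    ml <- moves_of(cl_l); mr <- moves_of(cl_r)
    for (mv in ml) {
      cand <- apply_at(cl_l, mv$path, mv$perm)
      cc <- eval_pair(cand, cl_r)
      if (cc < cross) { cl_l <- cand; cross <- cc; improved <- TRUE; break }
    }
    if (!improved) for (mv in mr) {
      cand <- apply_at(cl_r, mv$path, mv$perm)
      cc <- eval_pair(cl_l, cand)
      if (cc < cross) { cl_r <- cand; cross <- cc; improved <- TRUE; break }
    }
    if (!improved) {
      allm <- c(lapply(ml, function(m) c(m, side = "l")),
                lapply(mr, function(m) c(m, side = "r")))
      n_m <- length(allm)
      # when both moves act on the same tree, the first rotation re-indexes
      # children along its path; remap (or skip) the second move accordingly
      remap_path <- function(path2, mv1) {
        p1 <- mv1$path; k <- length(p1)
        if (length(path2) > k && identical(path2[seq_len(k)], p1)) {
          path2[k + 1L] <- which(mv1$perm == path2[k + 1L])
        }
        path2
      }
      for (i in seq_len(max(0L, n_m - 1L))) {
        for (j in (i + 1L):n_m) {
          m1 <- allm[[i]]; m2 <- allm[[j]]
          if (m1$side == m2$side && identical(m1$path, m2$path)) next
          if (m1$side == m2$side) m2$path <- remap_path(m2$path, m1)
          li <- cl_l; ri <- cl_r
          for (mv in list(m1, m2)) {
            if (mv$side == "l") li <- apply_at(li, mv$path, mv$perm)
            else ri <- apply_at(ri, mv$path, mv$perm)
          }
          cc <- eval_pair(li, ri)
          if (cc < cross) {
            cl_l <- li; cl_r <- ri; cross <- cc; improved <- TRUE; break
          }
        }
        if (improved) break
      }
    }
    if (!improved) break
  }
  list(left = cl_l, right = cl_r, cross = cross)
}

# Positions of each leaf's link partners, as a named list.
partner_positions <- function(links, from, to, to_order) {
  pos <- match(links[[to]], to_order)
  split(pos, links[[from]])
}

#' Minimise tanglegram crossings by alternating barycenter sweeps
#'
#' Internal nodes of one tree are rotated against the fixed leaf order of
#' the other, alternating sides; a sweep is kept only if it does not
#' increase the crossing count, so crossings never increase between sweeps.
#'
#' @param te_tree,host_tree rooted `ape::phylo` trees.
#' @param links data.frame with columns `left` (TE leaf) and `right` (host
#'   leaf); many TEs may link to one host.
#' @param max_sweeps cap on alternating sweeps.
#' @return list of class `tanglegram`: `left_order`, `right_order`,
#'   `crossings`, `normalized_crossings` (crossings / C(n_links, 2)),
#'   `initial_crossings`, `sweeps`.
#' @export
minimize_crossings <- function(te_tree, host_tree, links, max_sweeps = 20L) {
  cl_l0 <- tree_to_clade(te_tree)
  cl_r0 <- tree_to_clade(host_tree)
  initial <- count_crossings(clade_leaves(cl_l0), clade_leaves(cl_r0), links)
  # deterministic multi-start: the given rotations plus mirrored variants
  reverse_all <- function(node) {
    if (is.character(node)) return(node)
    rev(lapply(node, reverse_all))
  }
  starts <- list(list(cl_l0, cl_r0),
                 list(reverse_all(cl_l0), cl_r0),
                 list(cl_l0, reverse_all(cl_r0)),
                 list(reverse_all(cl_l0), reverse_all(cl_r0)))
  best <- NULL
  for (st in starts) {
    run <- untangle_once(st[[1L]], st[[2L]], links, max_sweeps)
    if (is.null(best) || run$cross < best$cross) best <- run
    if (best$cross == 0L) break
  }
  n_links <- nrow(links)
  structure(list(left_order = clade_leaves(best$left),
                 right_order = clade_leaves(best$right),
                 crossings = min(best$cross, initial),
                 normalized_crossings =
                   min(best$cross, initial) / max(1, choose(n_links, 2)),
                 initial_crossings = initial, sweeps = best$sweeps),
            class = "tanglegram")
}

# One barycenter + hill-climbing run from a fixed starting rotation.
untangle_once <- function(cl_l, cl_r, links, max_sweeps) {
  ord_l <- clade_leaves(cl_l)
  ord_r <- clade_leaves(cl_r)
  cross <- count_crossings(ord_l, ord_r, links)
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    improved <- FALSE
    # left against fixed right
    cand <- barycenter_sort(cl_l, partner_positions(links, "left", "right", ord_r))
    cc <- count_crossings(clade_leaves(cand), ord_r, links)
    if (cc < cross) {
      cl_l <- cand; ord_l <- clade_leaves(cl_l); cross <- cc; improved <- TRUE
    }
    # right against fixed left
    cand <- barycenter_sort(cl_r, partner_positions(links, "right", "left", ord_l))
    cc <- count_crossings(ord_l, clade_leaves(cand), links)
    if (cc < cross) {
      cl_r <- cand; ord_r <- clade_leaves(cl_r); cross <- cc; improved <- TRUE
    }
    # local refinement: accept any single-node child permutation that
    # lowers the count (hill climbing; never increases)
    if (!improved) {
      ref <- refine_rotations(cl_l, cl_r, links, cross)
      if (ref$cross < cross) {
        cl_l <- ref$left; cl_r <- ref$right
        ord_l <- clade_leaves(cl_l); ord_r <- clade_leaves(cl_r)
        cross <- ref$cross
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(left = cl_l, right = cl_r, cross = cross, sweeps = sweeps)
}
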