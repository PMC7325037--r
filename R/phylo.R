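# Desk-scale tree inference: p-distances, canonical neighbor-joining with
# deterministic tie-breaking, column-resampling bootstrap, outgroup rooting
# and support-thresholded clade extraction. Trees are ape "phylo" objects
# throughout; externally computed Newick trees are first-class inputs.

#' Pairwise p-distance matrix from a gapped alignment
#'
#' d(i, j) = mismatches / compared columns, with pairwise deletion of
#' columns where either sequence is gapped.
#'
#' @param aln named character vector of equal-length (gapped) sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  stopifnot(length(aln) >= 2L)
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(aln, ""))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in 1L:(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop("no comparable columns between ", names(aln)[i], " and ",
           names(aln)[j])
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

fmt_bl <- function(x) sprintf("%.15g", max(x, 0))

#' Neighbor-joining tree
#'
#' Canonical NJ (Q criterion). Ties in Q are broken by the smallest index
#' pair in the current agglomeration order (original taxa first, joined
#' nodes appended), so the result is deterministic. Negative branch lengths
#' are clamped to zero with the deficit moved to the sister branch, which
#' preserves the joined pair's path length.
#'
#' @param d symmetric non-negative distance matrix, >= 3 taxa, with
#'   dimnames. Taxon labels may not contain Newick metacharacters.
#' @return unrooted `ape::phylo` tree (root trifurcation).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  if (any(grepl("[():,;\\s]", labels))) stop("taxon labels contain Newick metacharacters")
  frag <- labels
  D <- unname(d)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    i <- best[[1L]]; j <- best[[2L]]
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt_bl(li),
                       frag[j], fmt_bl(lj))
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
  }
  # three-point closed form for the final join
  la <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
  lb <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
  lc <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1L], fmt_bl(la),
                 frag[2L], fmt_bl(lb), frag[3L], fmt_bl(lc))
  ape::read.tree(text = nwk)
}

#' NJ tree with bootstrap supports
#'
#' Alignment columns are resampled with replacement per replicate from one
#' seeded generator; the support of an internal edge is the percentage of
#' replicate trees containing the same bipartition, stored in `node.label`.
#'
#' @param aln named character vector of equal-length sequences.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; fixed seed gives identical supports.
#' @return unrooted `ape::phylo` with `node.label` supports in \[0, 100\].
#' @export
bootstrap_supports <- function(aln, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  L <- unique(nchar(aln))
  if (length(L) != 1L || L < 2L) stop("alignment must have >= 2 columns")
  main <- nj_tree(p_distance_matrix(aln))
  m <- do.call(rbind, strsplit(aln, ""))
  boots <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
      nj_tree(p_distance_matrix(stats::setNames(res, names(aln))))
    })
  })
  cnt <- ape::prop.clades(main, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  main$node.label <- as.character(round(100 * cnt / n_reps, 1))
  main
}

# Tip index sets descending from each node (1..Ntip+Nnode).
node_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  sets <- vector("list", n + nn)
  for (i in seq_len(n)) sets[[i]] <- i
  # postorder so children are done before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    p <- eo[k, 1L]; c <- eo[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

#' Root a tree with an outgroup
#'
#' The root is placed on the edge separating the smallest clade containing
#' all outgroup leaves from the rest, with the rooting edge's length split
#' evenly between the two root children. If the outgroup is not
#' monophyletic in the unrooted tree, the edge maximising the product of
#' outgroup purity and completeness on the outgroup side is used and the
#' result carries `attr(,"outgroup_monophyletic") = FALSE`.
#'
#' @param tree unrooted (or arbitrarily rooted) `ape::phylo`.
#' @param outgroup_ids leaf labels of the outgroup.
#' @return rooted `ape::phylo`; supports are carried as edge labels.
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  unknown <- setdiff(outgroup_ids, tree$tip.label)
  if (length(unknown)) stop("unknown outgroup id(s): ",
                            paste(unknown, collapse = ", "))
  n <- length(tree$tip.label)
  og <- match(outgroup_ids, tree$tip.label)
  sets <- node_tip_sets(tree)
  all_tips <- seq_len(n)
  is_split <- any(vapply(sets, function(s) {
    setequal(s, og) || setequal(setdiff(all_tips, s), og)
  }, logical(1)))
  if (is_split || length(og) == 1L) {
    rooted <- ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE,
                        edgelabel = TRUE)
    attr(rooted, "outgroup_monophyletic") <- TRUE
  } else {
    score <- vapply(seq_along(sets), function(k) {
      s <- sets[[k]]
      inside <- length(intersect(s, og))
      f1 <- (inside / length(s)) * (inside / length(og))
      comp <- setdiff(all_tips, s)
      inside2 <- length(intersect(comp, og))
      f2 <- if (length(comp)) (inside2 / length(comp)) * (inside2 / length(og)) else 0
      max(f1, f2)
    }, numeric(1))
    score[seq_len(n + tree$Nnode) > n & lengths(sets) == n] <- -1  # skip root
    k <- which.max(score)
    rooted <- if (k <= n) {
      ape::root(tree, outgroup = tree$tip.label[k], resolve.root = TRUE,
                edgelabel = TRUE)
    } else {
      ape::root(tree, node = k, resolve.root = TRUE, edgelabel = TRUE)
    }
    attr(rooted, "outgroup_monophyletic") <- FALSE
  }
  # split the rooting edge length evenly between the two root children
  rn <- length(rooted$tip.label) + 1L
  kids <- which(rooted$edge[, 1L] == rn)
  if (length(kids) == 2L && !is.null(rooted$edge.length)) {
    tot <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- tot / 2
  }
  rooted
}

#' Extract maximal supported clades
#'
#' Returns the maximal clades whose support is at least `min_support` and
#' whose parent node is not itself such a clade; every leaf belongs to at
#' most one group. Leaves covered by no group are reported as isolated.
#'
#' @param tree rooted `ape::phylo` with supports in `node.label`.
#' @param min_support support threshold in percent (default 70).
#' @return list with `groups` (each: members, support, node) and
#'   `isolated` (leaf labels).
#' @export
extract_supported_clades <- function(tree, min_support = 70) {
  n <- length(tree$tip.label)
  supp <- node_supports(tree)
  cand <- !is.na(supp) & supp >= min_support     # per internal node
  sets <- node_tip_sets(tree)
  parent_of <- integer(n + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  groups <- list()
  for (k in seq_len(tree$Nnode)) {
    node <- n + k
    if (!cand[k]) next
    par <- parent_of[node]
    par_cand <- par > n && cand[par - n]
    if (!par_cand) {
      groups[[length(groups) + 1L]] <- list(
        members = tree$tip.label[sets[[node]]],
        support = supp[k], node = node)
    }
  }
  covered <- unlist(lapply(groups, `[[`, "members"))
  list(groups = groups,
       isolated = setdiff(tree$tip.label, covered))
}
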