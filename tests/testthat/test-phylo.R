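test_that("p-distances match hand counts and the column oracle", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAA"))[1, 2], 0)
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))[1, 2], 0.25)
  # pairwise deletion of gap columns
  expect_equal(p_distance_matrix(c(a = "A-AA", b = "ATAT"))[1, 2], 1 / 3)
  expect_error(p_distance_matrix(c(a = "--A", b = "A--")), "no comparable")
  set.seed(101)
  for (k in 1:50) {
    n <- sample(3:8, 1); L <- sample(10:60, 1)
    aln <- stats::setNames(vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T", "-"), L, TRUE,
                   prob = c(rep(0.23, 4), 0.08)), collapse = "")
    }, character(1)), paste0("s", seq_len(n)))
    d <- tryCatch(p_distance_matrix(aln), error = function(e) NULL)
    if (is.null(d)) next
    i <- sample(n, 1); j <- sample(setdiff(seq_len(n), i), 1)
    ci <- strsplit(aln[[i]], "")[[1]]; cj <- strsplit(aln[[j]], "")[[1]]
    ok <- ci != "-" & cj != "-"
    expect_equal(d[i, j], sum(ci[ok] != cj[ok]) / sum(ok))
    expect_true(isSymmetric(d))
  }
})

test_that("three taxa solve the closed form exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  got <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(got, d, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "at least 3")
  bad <- d; bad[1, 2] <- 9
  expect_error(nj_tree(bad), "not symmetric")
})

test_that("NJ recovers generating trees from additive matrices", {
  set.seed(102)
  # 4-taxon planted tree, exact lengths
  q <- random_additive(4)
  t4 <- nj_tree(q$d)
  expect_equal(ape::cophenetic.phylo(t4)[rownames(q$d), colnames(q$d)],
               q$d, tolerance = 1e-9, ignore_attr = TRUE)
  # 50 random 6-taxon trees: topology and path lengths recovered
  recovered <- 0L
  for (k in 1:50) {
    r <- random_additive(6)
    tr <- nj_tree(r$d)
    rf <- ape::dist.topo(ape::unroot(r$tree), tr)
    len_ok <- max(abs(ape::cophenetic.phylo(tr)[rownames(r$d), colnames(r$d)]
                      - r$d)) < 1e-8
    if (rf == 0 && len_ok) recovered <- recovered + 1L
  }
  expect_identical(recovered, 50L)
})

test_that("NJ agrees with ape's implementation on random additive input", {
  set.seed(103)
  skip_if_not_installed("phangorn")
  for (k in 1:10) {
    r <- random_additive(sample(5:10, 1))
    expect_equal(phangorn::RF.dist(nj_tree(r$d), ape::nj(r$d)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are deterministic, bounded and signal-responsive", {
  fam <- sim_family(n = 6, length = 120, flank1 = 20, gap12 = 20,
                    divergence = 0.2, seed = 104)
  aln <- fam$seqs
  b1 <- bootstrap_supports(aln, n_reps = 50, seed = 7)
  b2 <- bootstrap_supports(aln, n_reps = 50, seed = 7)
  expect_identical(write_newick(b1), write_newick(b2))
  expect_identical(b1$node.label, b2$node.label)
  s <- node_supports(b1)
  expect_true(all(s >= 0 & s <= 100, na.rm = TRUE))
  one <- bootstrap_supports(aln, n_reps = 1, seed = 8)
  expect_true(all(node_supports(one) %in% c(0, 100)))
  # two strongly differentiated clades: the focal bipartition is near-certain
  set.seed(105)
  core <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  grp2 <- tcmariner:::mutate_seq(core, 0.5, c("A", "C", "G", "T"))
  aln2 <- c(
    stats::setNames(vapply(1:4, function(i)
      tcmariner:::mutate_seq(core, 0.02, c("A", "C", "G", "T")),
      character(1)), paste0("x", 1:4)),
    stats::setNames(vapply(1:4, function(i)
      tcmariner:::mutate_seq(grp2, 0.02, c("A", "C", "G", "T")),
      character(1)), paste0("y", 1:4)))
  bt <- bootstrap_supports(aln2, n_reps = 100, seed = 9)
  rooted <- root_with_outgroup(bt, paste0("y", 1:4))
  cl <- extract_supported_clades(rooted, min_support = 99)
  big <- Filter(function(g) setequal(g$members, paste0("x", 1:4)) ||
                  setequal(g$members, paste0("y", 1:4)), cl$groups)
  expect_true(length(big) >= 1)
})

test_that("outgroup rooting splits the pendant edge and keeps bipartitions", {
  tr <- parse_newick("(a:1,b:1,(c:1,d:2):1);")
  r <- root_with_outgroup(tr, "d")
  expect_true(ape::is.rooted(r))
  kids <- which(r$edge[, 1] == length(r$tip.label) + 1L)
  expect_equal(r$edge.length[kids], c(1, 1))  # d's pendant edge bisected
  expect_error(root_with_outgroup(tr, "zz"), "unknown")
  # monophyletic two-leaf outgroup -> ingroup is a clade
  tr2 <- parse_newick("((a:1,b:1):1,(c:1,d:1):1,e:1);")
  r2 <- root_with_outgroup(tr2, c("a", "b"))
  sets <- tcmariner:::node_tip_sets(r2)
  ing <- match(c("c", "d", "e"), r2$tip.label)
  expect_true(any(vapply(sets, function(s) setequal(s, ing), logical(1))))
  # rerooting preserves the unrooted bipartition set
  set.seed(106)
  for (k in 1:10) {
    rt <- ape::rtree(20)
    og <- sample(rt$tip.label, 1)
    rr <- root_with_outgroup(ape::unroot(rt), og)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(rr), ape::unroot(rt))), 0)
  }
})

test_that("non-monophyletic outgroups are flagged but still rooted", {
  tr <- parse_newick("((a:1,x:1):1,(b:1,y:1):1,c:1);")
  r <- root_with_outgroup(tr, c("x", "y"))
  expect_false(attr(r, "outgroup_monophyletic"))
  expect_true(ape::is.rooted(r))
})

test_that("supported-clade extraction honours maximality and isolation", {
  tr <- parse_newick("(((a:1,b:1)100:1,(c:1,d:1)100:1)100:1,(e:1,f:1)0:1)100;")
  all_high <- extract_supported_clades(tr, min_support = 70)
  # the root itself is supported: one group holding every leaf
  expect_length(all_high$groups, 1)
  expect_setequal(all_high$groups[[1]]$members, letters[1:6])
  expect_length(all_high$isolated, 0)
  none <- parse_newick("(((a:1,b:1)0:1,(c:1,d:1)0:1)0:1,(e:1,f:1)0:1)0;")
  res0 <- extract_supported_clades(none, min_support = 70)
  expect_length(res0$groups, 0)
  expect_setequal(res0$isolated, letters[1:6])
  mid <- parse_newick("(((a:1,b:1)95:1,(c:1,d:1)40:1)30:1,(e:1,f:1)80:1)10;")
  resm <- extract_supported_clades(mid, min_support = 70)
  expect_length(resm$groups, 2)
  expect_setequal(unlist(lapply(resm$groups, `[[`, "members")),
                  c("a", "b", "e", "f"))
  expect_setequal(resm$isolated, c("c", "d"))
})

test_that("two planted families emerge as two supported clades", {
  famA <- sim_family(n = 5, length = 150, flank1 = 30, gap12 = 30,
                     divergence = 0.05, seed = 107, prefix = "A")
  famB <- sim_family(n = 5, length = 150, flank1 = 30, gap12 = 30,
                     divergence = 0.05, seed = 108, prefix = "B")
  out <- sim_family(n = 1, length = 150, flank1 = 30, gap12 = 30,
                    divergence = 0, seed = 109, prefix = "OG")
  aln <- c(famA$seqs, famB$seqs, out$seqs)
  bt <- bootstrap_supports(aln, n_reps = 100, seed = 10)
  rooted <- root_with_outgroup(bt, names(out$seqs))
  cl <- extract_supported_clades(rooted, min_support = 70)
  fams <- Filter(function(g) setequal(g$members, names(famA$seqs)) ||
                   setequal(g$members, names(famB$seqs)), cl$groups)
  expect_length(fams, 2)
})
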