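test_that("minimal ORFs are found with the stop codon included", {
  orfs <- find_orfs("ATGAAATAA", min_len_aa = 2)
  expect_identical(nrow(orfs), 1L)
  expect_identical(orfs$length_nt, 9L)
  expect_identical(translate_cds(substr("ATGAAATAA", orfs$start, orfs$end)),
                   "MK")
  expect_identical(nrow(find_orfs("CCCCCCCCC", min_len_aa = 1)), 0L)
})

test_that("ORF scan equals the brute-force 6-frame oracle on random sequences", {
  set.seed(71)
  for (k in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    got <- find_orfs(s, min_len_aa = 5)
    want <- oracle_orfs(s, min_len_aa = 5)
    expect_identical(nrow(got), length(want))
    if (nrow(got)) {
      gm <- as.matrix(got[order(got$start, got$end), c("start", "end")])
      wm <- do.call(rbind, want)
      wm <- wm[order(wm[, 1], wm[, 2]), , drop = FALSE]
      expect_equal(unname(gm), unname(wm))
    }
  }
})

test_that("ORFs are invariant under appending non-coding 3' sequence", {
  el <- sim_element(seed = 72, plant_triad = TRUE)
  base <- find_orfs(el$bases, min_len_aa = 50)
  # a tail of stop-free non-ATG junk cannot create or destroy reported ORFs
  ext <- find_orfs(paste0(el$bases, strrep("TTACTTTGATAG", 1)), min_len_aa = 50)
  expect_true(all(paste(base$start, base$end, base$strand) %in%
                  paste(ext$start, ext$end, ext$strand)))
})

test_that("planted perfect TIRs are recovered exactly", {
  set.seed(73)
  tir <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  el <- paste0(tir, paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                          collapse = ""), revcomp(tir))
  got <- find_tirs(el, window = 100, min_len = 10, min_identity_pct = 90)
  expect_identical(got$length, 20L)
  expect_equal(got$identity_pct, 100)
  expect_equal(unname(got$tir5), c(1, 20))
  expect_equal(unname(got$tir3), c(nchar(el) - 19, nchar(el)))
})

test_that("TIR mismatches lower identity and gate acceptance", {
  el <- sim_element(seed = 74, tir_len = 20, tir_identity = 90)
  got90 <- find_tirs(el$bases, window = 100, min_len = 15,
                     min_identity_pct = 90)
  expect_false(is.null(got90))
  expect_true(got90$identity_pct >= 90)
  got99 <- find_tirs(el$bases, window = 100, min_len = 15,
                     min_identity_pct = 99)
  expect_true(is.null(got99) || got99$identity_pct >= 99)
})

test_that("random sequences rarely produce spurious TIR calls", {
  set.seed(75)
  fp <- 0L
  for (k in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
    if (!is.null(find_tirs(s, window = 100, min_len = 15,
                           min_identity_pct = 90))) fp <- fp + 1L
  }
  expect_lte(fp, 1L)
})

test_that("TIR detection mirrors under reverse complement", {
  for (seed in 76:80) {
    el <- sim_element(seed = seed, tir_len = 25)
    a <- find_tirs(el$bases, window = 100, min_len = 10,
                   min_identity_pct = 90)
    b <- find_tirs(revcomp(el$bases), window = 100, min_len = 10,
                   min_identity_pct = 90)
    n <- nchar(el$bases)
    expect_identical(a$length, b$length)
    expect_equal(a$identity_pct, b$identity_pct)
    expect_equal(unname(b$tir5),
                 unname(n - a$tir3[c("end", "start")] + 1))
  }
})

test_that("planted TIR lengths are recovered across the printed range", {
  hits <- 0L; total <- 0L
  for (tl in c(15L, 20L, 56L)) {
    for (seed in 1:20) {
      el <- sim_element(seed = 800 + 100 * tl + seed, tir_len = tl)
      got <- find_tirs(el$bases, window = 100, min_len = 10,
                       min_identity_pct = 95)
      total <- total + 1L
      if (!is.null(got) && got$length == tl) hits <- hits + 1L
    }
  }
  expect_identical(hits, total)
})

test_that("TSD checks compare flank dinucleotides", {
  expect_identical(check_tsd("GGGTA", "TAGCC"), list(tsd = "TA", is_ta = TRUE))
  expect_identical(check_tsd("GGGCA", "TAGCC")$tsd, NULL)
  expect_identical(check_tsd("A", "TAGC")$reason, "no flanks")
  expect_identical(check_tsd("", "")$reason, "no flanks")
  gg <- check_tsd("AAGG", "GGTT")
  expect_identical(gg$tsd, "GG")
  expect_false(gg$is_ta)
})

test_that("composite annotation mirrors the planted element architecture", {
  el <- sim_element(seed = 81, tir_len = 56, orf_len_nt = 3321,
                    plant_triad = TRUE)
  ann <- annotate_element(el$bases, el$id, el$flank5, el$flank3)
  expect_identical(ann$total_length, nchar(el$bases))
  expect_identical(ann$tir$length, 56L)
  expect_identical(ann$tsd$tsd, "TA")
  expect_true(ann$tsd$is_ta)
  planted <- el$truth$orf
  expect_true(any(ann$orfs$start == planted[["start"]] &
                  ann$orfs$end == planted[["end"]] &
                  ann$orfs$strand == "+"))
  # no flanks -> no TSD, with a reason
  bare <- annotate_element(el$bases, el$id)
  expect_null(bare$tsd$tsd)
  expect_identical(bare$tsd$reason, "no flanks")
})
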