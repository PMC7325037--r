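mk_census_hit <- function(pident, qstart, qend, sseqid = "scf1",
                          sstart = 1000L, minus = FALSE) {
  span <- qend - qstart + 1L
  data.frame(qseqid = "el", sseqid = sseqid, pident = pident,
             length = span, mismatch = 0L, gapopen = 0L,
             qstart = as.integer(qstart), qend = as.integer(qend),
             sstart = if (minus) sstart + span - 1L else sstart,
             send = if (minus) sstart else sstart + span - 1L,
             evalue = 0, bitscore = 2 * span, stringsAsFactors = FALSE)
}

test_that("locus clustering groups nearby same-strand hits", {
  h <- rbind(mk_census_hit(90, 1, 100, sstart = 1000L),
             mk_census_hit(90, 200, 300, sstart = 1150L))  # 50 nt apart
  expect_length(cluster_loci(h, element_length = 1000), 1L)
  h2 <- rbind(mk_census_hit(90, 1, 100, sseqid = "scf1"),
              mk_census_hit(90, 1, 100, sseqid = "scf2"))
  expect_length(cluster_loci(h2, element_length = 1000), 2L)
  h3 <- rbind(mk_census_hit(90, 1, 100, sstart = 1000L),
              mk_census_hit(90, 1, 100, sstart = 1000L, minus = TRUE))
  expect_length(cluster_loci(h3, element_length = 1000), 2L)
  mixed <- rbind(mk_census_hit(90, 1, 100),
                 within(mk_census_hit(90, 1, 100), qseqid <- "other"))
  expect_error(cluster_loci(mixed, 1000), "one query")
})

test_that("locus partition equals brute-force single linkage on random layouts", {
  set.seed(91)
  for (k in 1:100) {
    n <- sample(2:12, 1)
    h <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_census_hit(90, 1, 100,
                    sseqid = sample(c("s1", "s2"), 1),
                    sstart = sample.int(8000L, 1),
                    minus = runif(1) < 0.3)
    }))
    max_gap <- sample(c(100L, 500L, 2000L), 1)
    got <- cluster_loci(h, element_length = 100, max_gap = max_gap)
    want <- oracle_loci(h, max_gap)
    expect_identical(length(got), length(want))
    # same multiset of locus sizes and members
    sig <- function(rows) paste(sort(paste(rows$sstart, rows$send)), collapse = "|")
    expect_setequal(vapply(got, sig, character(1)),
                    vapply(want, function(ix) sig(h[ix, ]), character(1)))
  }
})

test_that("classification respects the inclusive class boundaries", {
  L <- 1000L
  t0 <- census_thresholds()
  full <- cluster_loci(mk_census_hit(95.0, 1, 950), L)[[1]]
  expect_identical(classify_locus(full, L, NULL, t0), "full_length")
  near <- cluster_loci(mk_census_hit(94.9, 1, 950), L)[[1]]
  expect_identical(classify_locus(near, L, NULL, t0), "partial")
  part <- cluster_loci(mk_census_hit(80.0, 1, 500), L)[[1]]
  expect_identical(classify_locus(part, L, NULL, t0), "partial")
  nonaut <- cluster_loci(mk_census_hit(60, 1, 300), L)[[1]]
  expect_identical(classify_locus(nonaut, L, NULL, t0), "non_autonomous")
  weak <- cluster_loci(mk_census_hit(40, 1, 1000), L)[[1]]
  expect_identical(classify_locus(weak, L, NULL, t0), "unclassified")
})

test_that("MITE evidence takes precedence below full-length", {
  L <- 1000L
  tir <- list(tir5 = c(start = 1L, end = 20L),
              tir3 = c(start = 981L, end = 1000L))
  two <- rbind(mk_census_hit(96, 1, 20, sstart = 5000L),
               mk_census_hit(96, 981, 1000, sstart = 5100L))
  locus <- cluster_loci(two, L)[[1]]
  expect_identical(classify_locus(locus, L, tir), "mite")
  # without TIR coordinates MITE is never assigned
  expect_identical(classify_locus(locus, L, NULL), "unclassified")
  # a hit spanning the whole element outranks the MITE rule
  span <- cluster_loci(mk_census_hit(97, 1, 1000, sstart = 5000L), L)[[1]]
  expect_identical(classify_locus(span, L, tir), "full_length")
  # TIR hits plus a mid-identity internal fragment: MITE outranks partial
  mixed <- cluster_loci(rbind(mk_census_hit(96, 1, 20, sstart = 5000L),
                              mk_census_hit(96, 981, 1000, sstart = 5060L),
                              mk_census_hit(85, 100, 700, sstart = 5120L)),
                        L)[[1]]
  expect_identical(classify_locus(mixed, L, tir), "mite")
  # sub-threshold identity over the TIRs is not MITE evidence
  dim_ <- cluster_loci(rbind(mk_census_hit(94, 1, 20),
                             mk_census_hit(94, 981, 1000, sstart = 1100L)),
                       L)[[1]]
  expect_identical(classify_locus(dim_, L, tir), "unclassified")
})

test_that("census recovers planted copy counts and handles empty tables", {
  expect_identical(sum(census(tcmariner:::empty_hit_table(), 1000)), 0L)
  el <- sim_element(seed = 92, plant_triad = TRUE)
  tir <- list(tir5 = el$truth$tir5, tir3 = el$truth$tir3)
  set.seed(93)
  for (k in 1:20) {
    counts <- c(full = sample(0:4, 1), partial = sample(0:4, 1),
                mite = sample(0:4, 1), nonaut = sample(0:4, 1))
    sim <- sim_hit_table(nchar(el$bases), tir, counts, seed = 900 + k,
                         query_id = "el", at_boundary = k <= 5)
    got <- census(sim$hits, nchar(el$bases), tir)
    expect_identical(got, sim$truth)
  }
})

test_that("a duplicated assembly doubles every census count", {
  el <- sim_element(seed = 94, plant_triad = TRUE)
  tir <- list(tir5 = el$truth$tir5, tir3 = el$truth$tir3)
  sim <- sim_hit_table(nchar(el$bases), tir,
                       c(full = 2, partial = 3, mite = 1, nonaut = 2),
                       seed = 95, query_id = "el")
  dup <- sim$hits
  dup$sseqid <- paste0(dup$sseqid, "_copy2")
  both <- rbind(sim$hits, dup)
  expect_identical(census(both, nchar(el$bases), tir),
                   census(sim$hits, nchar(el$bases), tir) * 2L)
})
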