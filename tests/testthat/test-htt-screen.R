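test_that("identical elements score 100 on all three identities", {
  el <- sim_element(seed = 131, plant_triad = TRUE)
  rec <- list(id = "a", bases = el$bases,
              tir = list(tir5 = el$truth$tir5, tir3 = el$truth$tir3))
  ids <- pair_identities(rec, rec)
  expect_equal(ids$aa_identity_dde, 100)
  expect_equal(ids$nt_identity_transposase, 100)
  expect_equal(ids$nt_identity_full_element, 100)
  expect_false(ids$unverifiable)
})

test_that("planted nucleotide divergence is reflected in the identities", {
  el <- sim_element(seed = 132, plant_triad = TRUE)
  set.seed(133)
  other_bases <- mutate_element_bases(el$bases, 0.10, el$truth$orf,
                                      keep_aa = el$truth$triad[c("pos1",
                                                                 "pos2",
                                                                 "pos3")])
  a <- list(id = "a", bases = el$bases,
            tir = list(tir5 = el$truth$tir5, tir3 = el$truth$tir3))
  b <- list(id = "b", bases = other_bases,
            tir = list(tir5 = el$truth$tir5, tir3 = el$truth$tir3))
  ids <- pair_identities(a, b)
  expect_true(abs(ids$nt_identity_full_element - 90) < 2.5)
})

test_that("a partial element (no TIRs) yields no full-element identity", {
  el <- sim_element(seed = 134, plant_triad = TRUE)
  a <- list(id = "a", bases = el$bases,
            tir = list(tir5 = el$truth$tir5, tir3 = el$truth$tir3))
  b <- list(id = "b", bases = el$bases, tir = NULL)
  ids <- pair_identities(a, b)
  expect_true(is.na(ids$nt_identity_full_element))
  expect_equal(ids$nt_identity_transposase, 100)
})

test_that("elements without a locatable DDE domain are unverifiable", {
  a <- list(id = "a", bases = strrep("C", 300), tir = NULL)
  b <- list(id = "b", bases = strrep("C", 300), tir = NULL)
  ids <- pair_identities(a, b)
  expect_true(ids$unverifiable)
  expect_match(ids$reason, "DDE")
})

test_that("the genome copy check flags single-locus elements", {
  bench <- sim_htt_pairs(1, 1, 0, seed = 135)
  contam_id <- bench$pairs$a[bench$pairs$scenario == "contamination"]
  rep1 <- genome_copy_check(nchar(bench$elements[[contam_id]]$bases),
                            bench$hit_tables[[contam_id]])
  expect_identical(rep1$copy_count, 1L)
  expect_true(rep1$single_copy_contamination_suspect)
  multi_id <- bench$pairs$a[bench$pairs$scenario == "transfer"]
  rep3 <- genome_copy_check(nchar(bench$elements[[multi_id]]$bases),
                            bench$hit_tables[[multi_id]])
  expect_identical(rep3$copy_count, 3L)
  expect_false(rep3$single_copy_contamination_suspect)
  expect_true(all(rep3$copy_identities >= 95))
  none <- genome_copy_check(1000, NULL)
  expect_false(none$available)
})

test_that("the decision table follows the published heuristics", {
  bench <- sim_htt_pairs(2, 2, 2, seed = 136)
  verdicts <- screen_pairs(bench$elements, bench$taxonomy,
                           bench$hit_tables, pairs = bench$pairs[1:2])
  key <- paste(verdicts$id_a, verdicts$id_b)
  truth <- bench$truth
  # vertical (same-phylum) pairs are never evaluated
  vert <- truth[truth$scenario == "vertical", ]
  expect_false(any(paste(vert$a, vert$b) %in% key))
  # planted transfers are candidates, planted contaminations rejected
  for (k in which(truth$scenario != "vertical")) {
    row <- verdicts[key == paste(truth$a[k], truth$b[k]), ]
    expect_identical(row$verdict, truth$expected[k])
  }
})

test_that("divergent full-length elements are rejected as divergent", {
  el <- sim_element(seed = 137, plant_triad = TRUE)
  set.seed(138)
  far <- mutate_element_bases(el$bases, 0.30, el$truth$orf,
                              keep_aa = el$truth$triad[c("pos1", "pos2",
                                                         "pos3")])
  mkhits <- function(id, L) {
    do.call(rbind, lapply(1:3, function(k) data.frame(
      qseqid = id, sseqid = paste0("s", k), pident = 90.5, length = L,
      mismatch = 0L, gapopen = 0L, qstart = 1L, qend = L, sstart = 1L,
      send = L, evalue = 0, bitscore = 2 * L, stringsAsFactors = FALSE)))
  }
  elements <- list(
    a = list(id = "a", bases = el$bases, lineage_id = "HA",
             tir = list(tir5 = el$truth$tir5, tir3 = el$truth$tir3)),
    b = list(id = "b", bases = far, lineage_id = "HB",
             tir = list(tir5 = el$truth$tir5, tir3 = el$truth$tir3)))
  tax <- data.frame(lineage_id = c("HA", "HB"), kingdom = c("K1", "K2"),
                    phylum = c("PA", "PB"), class = "", order = "",
                    family = "", genus = "", species = c("sa", "sb"),
                    stringsAsFactors = FALSE)
  hits <- list(a = mkhits("a", nchar(el$bases)),
               b = mkhits("b", nchar(far)))
  v <- screen_pairs(elements, tax, hits)
  expect_identical(v$verdict, "rejected_divergent")
  expect_match(v$flags, "divergent_pair")
  # and with one genome missing the pair is unverifiable
  v2 <- screen_pairs(elements, tax, hits["a"])
  expect_identical(v2$verdict, "unverifiable")
})

test_that("asymmetric copy identities raise the contamination flag", {
  el <- sim_element(seed = 139, plant_triad = TRUE)
  set.seed(140)
  near <- mutate_element_bases(el$bases, 0.02, el$truth$orf,
                               keep_aa = el$truth$triad[c("pos1", "pos2",
                                                          "pos3")])
  mkhits <- function(id, L, pid) {
    do.call(rbind, lapply(1:3, function(k) data.frame(
      qseqid = id, sseqid = paste0("s", k), pident = pid, length = L,
      mismatch = 0L, gapopen = 0L, qstart = 1L, qend = L, sstart = 1L,
      send = L, evalue = 0, bitscore = 2 * L, stringsAsFactors = FALSE)))
  }
  elements <- list(
    a = list(id = "a", bases = el$bases, lineage_id = "HA",
             tir = list(tir5 = el$truth$tir5, tir3 = el$truth$tir3)),
    b = list(id = "b", bases = near, lineage_id = "HB",
             tir = list(tir5 = el$truth$tir5, tir3 = el$truth$tir3)))
  tax <- data.frame(lineage_id = c("HA", "HB"), kingdom = c("K1", "K2"),
                    phylum = c("PA", "PB"), class = "", order = "",
                    family = "", genus = "", species = c("sa", "sb"),
                    stringsAsFactors = FALSE)
  hits <- list(a = mkhits("a", nchar(el$bases), 98.5),
               b = mkhits("b", nchar(near), 93.0))
  v <- screen_pairs(elements, tax, hits)
  expect_identical(v$verdict, "rejected_contamination_suspect")
  expect_match(v$flags, "asymmetric_identity")
})

test_that("tightening thresholds never converts rejections into candidates", {
  bench <- sim_htt_pairs(4, 2, 0, seed = 141)
  loose <- screen_pairs(bench$elements, bench$taxonomy, bench$hit_tables,
                        t = htt_thresholds(), pairs = bench$pairs[1:2])
  tight <- screen_pairs(bench$elements, bench$taxonomy, bench$hit_tables,
                        t = htt_thresholds(copy_identity_low_pct = 97,
                                           full_element_low_pct = 97,
                                           min_copies_for_confidence = 4L),
                        pairs = bench$pairs[1:2])
  key <- paste(loose$id_a, loose$id_b)
  for (k in seq_along(key)) {
    if (loose$verdict[k] != "candidate") {
      expect_false(tight$verdict[tight$id_a == loose$id_a[k] &
                                 tight$id_b == loose$id_b[k]] == "candidate")
    }
  }
})
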