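# Synthetic-data generators. Every generator is seeded, byte-reproducible,
# and returns a machine-readable truth table alongside the data, so that
# recovery tests read truth rather than re-deriving it. Catalytic triad
# sites are immutable under simulated divergence: motif ground truth is a
# construction guarantee, with biological realism secondary to testability.

# One fixed sense codon per amino acid, for reverse translation.
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

reverse_translate <- function(prot) {
  paste(CODON_OF[strsplit(prot, "")[[1]]], collapse = "")
}

#' Simulate a transposase family with a planted catalytic triad
#'
#' An ancestor is drawn with a D, D, D/E triad at the configured geometry;
#' descendants accumulate i.i.d. substitutions at non-catalytic sites only.
#'
#' @param n number of descendant sequences.
#' @param length sequence length in residues.
#' @param flank1 residues before the first catalytic position.
#' @param gap12 residues strictly between positions 1 and 2 (reported, not
#'   classified on).
#' @param spacing residues strictly between positions 2 and 3 (the family
#'   signature interval, e.g. 34 for DD34E).
#' @param third the third catalytic residue, "D" or "E" (degenerate residues
#'   allowed for domesticated-motif simulations).
#' @param divergence per-site substitution probability per descendant.
#' @param seed RNG seed.
#' @param prefix id prefix.
#' @return list: `seqs` (named character, ancestor excluded), `ancestor`,
#'   `truth` (data.frame id / pos1 / pos2 / pos3 / spacing / signature).
#' @export
sim_family <- function(n = 20L, length = 340L, flank1 = 120L, gap12 = 70L,
                       spacing = 34L, third = "E", divergence = 0.1,
                       seed = 1L, prefix = "fam") {
  n <- as.integer(n); length <- as.integer(length)
  flank1 <- as.integer(flank1); gap12 <- as.integer(gap12)
  spacing <- as.integer(spacing)
  pos1 <- flank1 + 1L
  pos2 <- pos1 + gap12 + 1L
  pos3 <- pos2 + spacing + 1L
  if (pos3 > length) stop("infeasible geometry: triad exceeds sequence length")
  with_seed(seed, {
    anc <- strsplit(random_seq(length, AA20), "")[[1]]
    anc[pos1] <- "D"; anc[pos2] <- "D"; anc[pos3] <- third
    ancestor <- paste(anc, collapse = "")
    keep <- c(pos1, pos2, pos3)
    ids <- sprintf("%s_%03d", prefix, seq_len(n))
    seqs <- stats::setNames(vapply(ids, function(i) {
      mutate_seq(ancestor, divergence, AA20, keep = keep)
    }, character(1)), ids)
    sig <- paste0("DD", spacing, third)
    truth <- data.frame(id = ids, pos1 = pos1, pos2 = pos2, pos3 = pos3,
                        spacing = spacing, signature = sig,
                        stringsAsFactors = FALSE)
    list(seqs = seqs, ancestor = ancestor, truth = truth)
  })
}

#' Build a seed profile from a simulated family
#'
#' Ungapped equal-length family sequences are already a trivial alignment;
#' the catalytic columns are the planted triad positions.
#'
#' @param fam result of [sim_family()].
#' @param n_rows number of rows to keep (ancestor first).
#' @return a [seed_profile()].
#' @export
sim_seed_profile <- function(fam, n_rows = 6L) {
  rows <- c(stats::setNames(fam$ancestor, "seed_ancestor"),
            fam$seqs[seq_len(min(n_rows - 1L, length(fam$seqs)))])
  seed_profile(rows, unlist(fam$truth[1L, c("pos1", "pos2", "pos3")]))
}

#' Simulate a full-length element
#'
#' Architecture (element body, 5' to 3'): TIR, 5' spacer, transposase ORF,
#' 3' spacer, reverse complement of the TIR (mutated down to
#' `tir_identity`). Host flanks carry the TA target-site duplication. The
#' defaults mirror a compact ITm element (20 bp TIRs, 756 bp ORF, 1841 bp
#' total, TA TSDs).
#'
#' @param seed RNG seed.
#' @param id element id.
#' @param tir_len TIR length in nt (>= 1).
#' @param tir_identity percent identity of the 3' TIR arm to the reverse
#'   complement of the 5' arm.
#' @param tsd target-site duplication (default "TA").
#' @param orf_len_nt transposase ORF length including the stop codon
#'   (divisible by 3).
#' @param utr5,utr3 spacer lengths between TIRs and ORF.
#' @param flank_len host flank length on each side.
#' @param plant_triad plant a D, D, third triad in the transposase protein
#'   (required for motif/HTT simulations).
#' @param triad_flank1,triad_gap12,triad_spacing,triad_third triad geometry
#'   within the ORF protein.
#' @param orf_protein optional explicit transposase protein (first residue
#'   forced to M); overrides `orf_len_nt` and the triad parameters.
#' @return list: `id`, `bases`, `flank5`, `flank3`, `truth` (coordinates of
#'   all planted features, 1-based closed).
#' @export
sim_element <- function(seed = 1L, id = "element", tir_len = 20L,
                        tir_identity = 100, tsd = "TA", orf_len_nt = 756L,
                        utr5 = 520L, utr3 = 525L, flank_len = 50L,
                        plant_triad = FALSE, triad_flank1 = 60L,
                        triad_gap12 = 40L, triad_spacing = 34L,
                        triad_third = "E", orf_protein = NULL) {
  if (tir_len < 1L) stop("tir_len must be >= 1")
  if (!is.null(orf_protein)) orf_len_nt <- 3L * (nchar(orf_protein) + 1L)
  stopifnot(orf_len_nt %% 3L == 0L, orf_len_nt >= 9L)
  with_seed(seed, {
    n_aa <- orf_len_nt %/% 3L - 1L   # residues excluding the stop codon
    if (!is.null(orf_protein)) {
      pr <- strsplit(orf_protein, "")[[1]]
      pr[1L] <- "M"   # the scan needs an ATG start
      prot <- paste(pr, collapse = "")
    } else if (plant_triad) {
      pos1 <- triad_flank1 + 1L
      pos2 <- pos1 + triad_gap12 + 1L
      pos3 <- pos2 + triad_spacing + 1L
      if (pos3 > n_aa) stop("infeasible triad geometry for ORF length")
      pr <- strsplit(random_seq(n_aa, AA20), "")[[1]]
      pr[1L] <- "M"; pr[pos1] <- "D"; pr[pos2] <- "D"; pr[pos3] <- triad_third
      prot <- paste(pr, collapse = "")
    } else {
      prot <- paste0("M", random_seq(n_aa - 1L, setdiff(AA20, "M")))
    }
    orf <- paste0(reverse_translate(prot), "TAA")
    tir <- random_seq(tir_len)
    arm3 <- revcomp(tir)
    n_mm <- round((1 - tir_identity / 100) * tir_len)
    if (n_mm > 0L) {
      ch <- strsplit(arm3, "")[[1]]
      at <- sample.int(tir_len, n_mm)
      for (i in at) ch[i] <- sample(setdiff(DNA4, ch[i]), 1L)
      arm3 <- paste(ch, collapse = "")
    }
    bases <- paste0(tir, random_seq(utr5), orf, random_seq(utr3), arm3)
    # pin the TIR boundary: the two bases just inside each spacer must not
    # extend the inverted repeat, so the planted length is the detector's
    # unique optimum
    if (utr5 >= 2L && utr3 >= 2L) {
      ch <- strsplit(bases, "")[[1]]
      nb <- length(ch)
      for (k in seq_len(min(20L, utr5, utr3))) {
        partner <- chartr("ACGT", "TGCA", ch[nb - tir_len - k + 1L])
        if (ch[tir_len + k] == partner)
          ch[tir_len + k] <- sample(setdiff(DNA4, partner), 1L)
      }
      bases <- paste(ch, collapse = "")
    }
    flank5 <- paste0(random_seq(max(0L, flank_len - nchar(tsd))), tsd)
    flank3 <- paste0(tsd, random_seq(max(0L, flank_len - nchar(tsd))))
    total <- nchar(bases)
    orf_start <- tir_len + utr5 + 1L
    truth <- list(
      tir_len = tir_len, tir_identity = tir_identity, tsd = tsd,
      tir5 = c(start = 1L, end = tir_len),
      tir3 = c(start = total - tir_len + 1L, end = total),
      orf = c(start = orf_start, end = orf_start + orf_len_nt - 1L),
      orf_strand = "+", orf_protein = prot,
      triad = if (plant_triad) c(pos1 = pos1, pos2 = pos2, pos3 = pos3,
                                 spacing = triad_spacing) else NULL,
      total_length = total
    )
    list(id = id, bases = bases, flank5 = flank5, flank3 = flank3,
         truth = truth)
  })
}

#' Mutate an element while keeping its transposase ORF readable
#'
#' Applies i.i.d. substitutions and then repairs the planted ORF: the start
#' and stop codons are restored and any premature in-frame stop created by
#' the mutations has its third base set to C. Codons of the catalytic triad
#' can be held immutable, mirroring the purifying selection acting on an
#' active transposase.
#'
#' @param bases element sequence.
#' @param rate per-site substitution probability.
#' @param orf planted ORF interval, `c(start = , end = )` (plus strand).
#' @param keep_aa optional protein positions (1-based within the ORF) whose
#'   codons are left untouched.
#' @return mutated sequence, same length.
#' @export
mutate_element_bases <- function(bases, rate, orf, keep_aa = integer(0)) {
  keep_nt <- integer(0)
  if (length(keep_aa)) {
    keep_nt <- as.integer(outer(0:2, orf[["start"]] + 3L * (keep_aa - 1L),
                                "+"))
  }
  out <- mutate_seq(bases, rate, DNA4, keep = keep_nt)
  ch <- strsplit(out, "")[[1]]
  # restore start and terminal stop
  ch[orf[["start"]]:(orf[["start"]] + 2L)] <- c("A", "T", "G")
  ch[(orf[["end"]] - 2L):orf[["end"]]] <- c("T", "A", "A")
  # disarm premature in-frame stops
  for (s in seq.int(orf[["start"]] + 3L, orf[["end"]] - 6L, by = 3L)) {
    if (paste(ch[s:(s + 2L)], collapse = "") %in% STOP_CODONS)
      ch[s + 2L] <- "C"
  }
  paste(ch, collapse = "")
}

#' Simulate an element-vs-genome hit table with planted copy classes
#'
#' Per planted copy, one (or for MITEs two) hit rows are drawn with identity
#' and coverage inside the class band: full-length id >= 95 and cov >= 0.95;
#' partial id in \[80, 95) and cov in \[0.5, 0.95); MITE id >= 95 over
#' exactly the two TIR intervals; non-autonomous id in \[50, 80) and cov in
#' \[0.25, 0.5). Each copy lands on its own scaffold.
#'
#' @param element_length element length in nt.
#' @param tir TIR pair (truth coordinates); required when MITE copies are
#'   requested.
#' @param counts named vector: full, partial, mite, nonaut.
#' @param seed RNG seed.
#' @param query_id query id for the hit rows.
#' @param at_boundary make the first copy of each class sit exactly on the
#'   class thresholds (for boundary-inclusivity checks).
#' @return list: `hits` (hit table data.frame), `truth` (named counts as
#'   used by [census()]).
#' @export
sim_hit_table <- function(element_length, tir = NULL,
                          counts = c(full = 3L, partial = 2L, mite = 4L,
                                     nonaut = 0L),
                          seed = 1L, query_id = "element",
                          at_boundary = FALSE) {
  for (nm in c("full", "partial", "mite", "nonaut"))
    if (is.na(counts[nm])) counts[nm] <- 0L
  if (counts[["mite"]] > 0L && is.null(tir))
    stop("MITE copies need TIR coordinates")
  with_seed(seed, {
    rows <- list()
    scaf <- 0L
    mk <- function(pident, qstart, qend, scaffold, minus = NULL, s0 = NULL) {
      span <- qend - qstart + 1L
      minus <- minus %||% (stats::runif(1) < 0.5)
      s0 <- s0 %||% sample.int(50000L, 1L)
      data.frame(qseqid = query_id, sseqid = scaffold,
                 pident = round(pident, 1), length = span,
                 mismatch = as.integer(round(span * (1 - pident / 100))),
                 gapopen = 0L, qstart = qstart, qend = qend,
                 sstart = if (minus) s0 + span - 1L else s0,
                 send = if (minus) s0 else s0 + span - 1L,
                 evalue = 0, bitscore = round(2 * span, 1),
                 stringsAsFactors = FALSE)
    }
    for (k in seq_len(counts[["full"]])) {
      scaf <- scaf + 1L
      pid <- if (at_boundary && k == 1L) 95 else stats::runif(1, 95, 99.9)
      cov <- if (at_boundary && k == 1L) 0.95 else stats::runif(1, 0.95, 1)
      span <- max(1L, ceiling(cov * element_length))
      rows[[length(rows) + 1L]] <-
        mk(pid, 1L, span, sprintf("scaffold_%03d", scaf))
    }
    for (k in seq_len(counts[["partial"]])) {
      scaf <- scaf + 1L
      pid <- if (at_boundary && k == 1L) 80 else stats::runif(1, 80, 94.9)
      cov <- if (at_boundary && k == 1L) 0.5 else stats::runif(1, 0.5, 0.949)
      span <- max(1L, ceiling(cov * element_length))
      qs <- sample.int(element_length - span + 1L, 1L)
      rows[[length(rows) + 1L]] <-
        mk(pid, qs, qs + span - 1L, sprintf("scaffold_%03d", scaf))
    }
    for (k in seq_len(counts[["mite"]])) {
      scaf <- scaf + 1L
      pid <- if (at_boundary && k == 1L) 95 else stats::runif(1, 95, 99.9)
      sc <- sprintf("scaffold_%03d", scaf)
      # one insertion: both TIR hits share a strand and sit within the
      # locus-clustering gap on the scaffold
      minus <- stats::runif(1) < 0.5
      s0 <- sample.int(50000L, 1L)
      gap <- sample.int(element_length, 1L)
      rows[[length(rows) + 1L]] <-
        mk(pid, tir[["tir5"]][["start"]], tir[["tir5"]][["end"]], sc, minus,
           s0 = s0)
      rows[[length(rows) + 1L]] <-
        mk(pid, tir[["tir3"]][["start"]], tir[["tir3"]][["end"]], sc, minus,
           s0 = s0 + gap)
    }
    for (k in seq_len(counts[["nonaut"]])) {
      scaf <- scaf + 1L
      pid <- if (at_boundary && k == 1L) 50 else stats::runif(1, 50, 79.9)
      cov <- if (at_boundary && k == 1L) 0.25 else stats::runif(1, 0.25, 0.499)
      span <- max(1L, ceiling(cov * element_length))
      qs <- sample.int(element_length - span + 1L, 1L)
      rows[[length(rows) + 1L]] <-
        mk(pid, qs, qs + span - 1L, sprintf("scaffold_%03d", scaf))
    }
    hits <- if (length(rows)) do.call(rbind, rows) else empty_hit_table()
    # MITE pairs must cluster into one locus: force both hits of a pair onto
    # nearby subject coordinates (already same scaffold; gap is immaterial
    # because each scaffold holds one copy).
    truth <- stats::setNames(integer(length(COPY_CLASSES)), COPY_CLASSES)
    truth["full_length"] <- as.integer(counts[["full"]])
    truth["partial"] <- as.integer(counts[["partial"]])
    truth["mite"] <- as.integer(counts[["mite"]])
    truth["non_autonomous"] <- as.integer(counts[["nonaut"]])
    list(hits = hits, truth = truth)
  })
}

# Binary address of host i (1-based): the leading bits split the hosts as
# evenly as possible, so every rank level varies even for small host counts;
# padded to 4 levels (kingdom, phylum, class, order).
host_address <- function(i, n_hosts) {
  d <- max(2L, ceiling(log2(n_hosts)))
  bits <- as.integer(intToBits(i - 1L))[d:1L]
  c(bits, rep(0L, 4L - d))[1:4]
}

#' Simulate a codiverging TE/host system with planted horizontal transfers
#'
#' Hosts sit on a binary rank hierarchy (kingdom, phylum, class, order);
#' one TE per host evolves along that hierarchy (vertical transmission),
#' except for `n_htt_events` TEs whose sequence is replaced by a recent
#' copy of a TE from a different kingdom (horizontal transfer), which
#' scrambles the tanglegram.
#'
#' @param n_hosts number of hosts (4..16).
#' @param n_htt_events number of planted transfers.
#' @param seq_len TE sequence length in residues.
#' @param rate_per_level per-site substitution probability per hierarchy
#'   level.
#' @param seed RNG seed.
#' @return list: `aln` (named TE sequences, equal length), `taxonomy`,
#'   `links` (data.frame left = TE, right = host), `truth` (events
#'   data.frame recipient / donor).
#' @export
sim_cophylo <- function(n_hosts = 16L, n_htt_events = 0L, seq_len = 200L,
                        rate_per_level = 0.06, seed = 1L) {
  stopifnot(n_hosts >= 4L, n_hosts <= 16L)
  with_seed(seed, {
    hosts <- sprintf("H%02d", seq_len(n_hosts))
    addr <- t(vapply(seq_len(n_hosts), host_address, integer(4),
                     n_hosts = n_hosts))
    tax <- data.frame(
      lineage_id = hosts,
      kingdom = paste0("K", addr[, 1L]),
      phylum = paste0("P", addr[, 1L], addr[, 2L]),
      class = paste0("C", addr[, 1L], addr[, 2L], addr[, 3L]),
      order = paste0("O", addr[, 1L], addr[, 2L], addr[, 3L], addr[, 4L]),
      family = "", genus = "", species = hosts,
      stringsAsFactors = FALSE
    )
    # evolve one sequence per address prefix, level by level
    root <- random_seq(seq_len, AA20)
    level_seqs <- list(stats::setNames(root, ""))
    for (lv in 1:4) {
      prefixes <- unique(apply(addr[, 1:lv, drop = FALSE], 1L, paste,
                               collapse = ""))
      prev <- level_seqs[[lv]]
      cur <- stats::setNames(vapply(prefixes, function(p) {
        parent_seq <- if (lv == 1L) prev[[1L]]
                      else prev[[substr(p, 1L, lv - 1L)]]
        mutate_seq(parent_seq, rate_per_level, AA20)
      }, character(1)), prefixes)
      level_seqs[[lv + 1L]] <- cur
    }
    leaf_prefix <- apply(addr, 1L, paste, collapse = "")
    aln <- stats::setNames(
      vapply(leaf_prefix, function(p) level_seqs[[5L]][[p]], character(1)),
      paste0("te_", hosts))
    events <- data.frame(recipient = character(0), donor = character(0),
                         stringsAsFactors = FALSE)
    if (n_htt_events > 0L) {
      recips <- sample(seq_len(n_hosts), n_htt_events,
                       replace = n_htt_events > n_hosts)
      for (r in recips) {
        donors <- which(addr[, 1L] != addr[r, 1L])  # other kingdom
        d <- donors[sample.int(length(donors), 1L)]
        aln[[r]] <- mutate_seq(aln[[d]], 0.02, AA20)
        events <- rbind(events, data.frame(
          recipient = paste0("te_", hosts[r]),
          donor = paste0("te_", hosts[d]), stringsAsFactors = FALSE))
      }
    }
    links <- data.frame(left = paste0("te_", hosts), right = hosts,
                        stringsAsFactors = FALSE)
    list(aln = aln, taxonomy = tax, links = links,
         truth = list(n_htt_events = n_htt_events, events = events))
  })
}

#' Simulate a benchmark of element pairs for the HTT screen
#'
#' Three planted scenarios: `transfer` (hosts in different kingdoms,
#' recently diverged elements, several high-identity copies in both
#' genomes), `contamination` (as transfer, but one genome holds a single
#' copy), and `vertical` (hosts in the same phylum; gated out of the
#' screen).
#'
#' @param n_transfer,n_contam,n_vertical scenario counts.
#' @param seed RNG seed.
#' @return list: `elements`, `taxonomy`, `hit_tables`, `pairs` (data.frame
#'   a / b / scenario), `truth` (expected verdict per pair).
#' @export
sim_htt_pairs <- function(n_transfer = 10L, n_contam = 10L,
                          n_vertical = 10L, seed = 1L) {
  with_seed(seed, {
    elements <- list(); hit_tables <- list(); tax_rows <- list()
    pairs <- data.frame(a = character(0), b = character(0),
                        scenario = character(0), stringsAsFactors = FALSE)
    scen <- c(rep("transfer", n_transfer), rep("contamination", n_contam),
              rep("vertical", n_vertical))
    mk_hits <- function(el_id, L, n_copies, id_lo, id_hi) {
      rows <- lapply(seq_len(n_copies), function(k) {
        pid <- round(stats::runif(1, id_lo, id_hi), 1)
        data.frame(qseqid = el_id, sseqid = sprintf("scf_%s_%02d", el_id, k),
                   pident = pid, length = L, mismatch = 0L, gapopen = 0L,
                   qstart = 1L, qend = L, sstart = 1000L,
                   send = 1000L + L - 1L, evalue = 0, bitscore = 2 * L,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    for (k in seq_along(scen)) {
      sc <- scen[k]
      ida <- sprintf("el_%03d_a", k); idb <- sprintf("el_%03d_b", k)
      ha <- sprintf("host_%03d_a", k); hb <- sprintf("host_%03d_b", k)
      base <- sim_element(seed = sample.int(1e6, 1L), id = ida,
                          plant_triad = TRUE)
      rate <- switch(sc, transfer = 0.02, contamination = 0.01,
                     vertical = 0.03)
      triad <- base$truth$triad
      eb_bases <- mutate_element_bases(base$bases, rate, base$truth$orf,
                                       keep_aa = triad[c("pos1", "pos2",
                                                         "pos3")])
      ea <- list(id = ida, bases = base$bases, lineage_id = ha,
                 tir = list(tir5 = base$truth$tir5, tir3 = base$truth$tir3))
      eb <- list(id = idb, bases = eb_bases, lineage_id = hb,
                 tir = list(tir5 = base$truth$tir5, tir3 = base$truth$tir3))
      elements[[ida]] <- ea; elements[[idb]] <- eb
      L <- nchar(base$bases)
      if (sc == "contamination") {
        hit_tables[[ida]] <- mk_hits(ida, L, 1L, 98, 99.5)
        hit_tables[[idb]] <- mk_hits(idb, L, 3L, 96, 99.5)
      } else {
        hit_tables[[ida]] <- mk_hits(ida, L, 3L, 96, 99.5)
        hit_tables[[idb]] <- mk_hits(idb, L, 3L, 96, 99.5)
      }
      if (sc == "vertical") {
        kng <- "K_v"; phy <- sprintf("P_v%03d", k)
        tax_rows[[length(tax_rows) + 1L]] <- data.frame(
          lineage_id = c(ha, hb), kingdom = kng, phylum = phy,
          class = c("Ca", "Cb"), order = "", family = "", genus = "",
          species = c(ha, hb), stringsAsFactors = FALSE)
      } else {
        tax_rows[[length(tax_rows) + 1L]] <- data.frame(
          lineage_id = c(ha, hb), kingdom = c("K_x", "K_y"),
          phylum = c(sprintf("P_x%03d", k), sprintf("P_y%03d", k)),
          class = "", order = "", family = "", genus = "",
          species = c(ha, hb), stringsAsFactors = FALSE)
      }
      pairs <- rbind(pairs, data.frame(a = ida, b = idb, scenario = sc,
                                       stringsAsFactors = FALSE))
    }
    truth <- ifelse(scen == "transfer", "candidate",
                    ifelse(scen == "contamination",
                           "rejected_contamination_suspect", "not_evaluated"))
    list(elements = elements, taxonomy = do.call(rbind, tax_rows),
         hit_tables = hit_tables, pairs = pairs,
         truth = data.frame(a = pairs$a, b = pairs$b, scenario = scen,
                            expected = truth, stringsAsFactors = FALSE))
  })
}

#' Synthetic reference transposases with printed triad geometries
#'
#' Stand-in sequences (not database records) that are homologues of one
#' synthetic seed family, differing by background substitutions and by
#' planted indels between the second and third catalytic positions. Their
#' geometries mirror well-described reference motifs: an HvSm-style DD34E,
#' a PlantMar-style DD39D, a rosa-style DD41D and a TIGD1-style DD32D.
#' Because they are homologues of the seed rows, aligning them to the seed
#' profile and reading the catalytic columns recovers each spacing — the
#' same procedure used on real transposases.
#'
#' @param seed RNG seed for the shared background.
#' @param divergence background substitution probability per reference.
#' @return list: `seqs` (named proteins), `truth` (id, spacing, signature),
#'   `profile` (the matching [seed_profile()]).
#' @export
reference_transposases <- function(seed = 100L, divergence = 0.08) {
  fam <- sim_family(n = 5L, spacing = 34L, third = "E",
                    divergence = 0.05, seed = seed, prefix = "seedrow")
  profile <- sim_seed_profile(fam)
  p1 <- fam$truth$pos1[1L]; p2 <- fam$truth$pos2[1L]
  p3 <- fam$truth$pos3[1L]
  specs <- list(
    hvsm_like = list(delta = 0L, third = "E", seed_off = 1L),
    plantmar_like = list(delta = 5L, third = "D", seed_off = 2L),
    rosa_like = list(delta = 7L, third = "D", seed_off = 3L),
    tigd1_like = list(delta = -2L, third = "D", seed_off = 4L)
  )
  seqs <- character(0); truth <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    seqs[nm] <- with_seed(seed + sp$seed_off, {
      base <- mutate_seq(fam$ancestor, divergence, AA20,
                         keep = c(p1, p2, p3))
      ch <- strsplit(base, "")[[1]]
      ch[p3] <- sp$third
      at <- p2 + 15L  # indel site strictly between positions 2 and 3
      if (sp$delta > 0L) {
        ch <- append(ch, sample(AA20, sp$delta, replace = TRUE), after = at)
      } else if (sp$delta < 0L) {
        ch <- ch[-((at + 1L):(at - sp$delta))]
      }
      paste(ch, collapse = "")
    })
    spacing <- 34L + sp$delta
    truth[[nm]] <- data.frame(id = nm, spacing = spacing,
                              signature = paste0("DD", spacing, sp$third),
                              stringsAsFactors = FALSE)
  }
  list(seqs = seqs, truth = do.call(rbind, truth), profile = profile)
}
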