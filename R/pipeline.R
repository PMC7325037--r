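# End-to-end orchestration: simulate (or load) inputs, filter, classify
# motifs, build the tree, extract clades, tanglegram, census and HTT
# screen. Stage boundaries are file-level: every stage writes a TSV that
# the next stage (or a rerun) can consume, and reruns with the same config
# are byte-identical.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @return nested list understood by [run_analysis()].
#' @export
default_config <- function(out_dir, seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, motif = TRUE, phylo = TRUE,
                  tangle = TRUE, census = TRUE, htt = TRUE),
    families = list(
      list(prefix = "tc1like", n = 10L, spacing = 34L, third = "E",
           divergence = 0.08),
      list(prefix = "marinerlike", n = 10L, spacing = 34L, third = "D",
           divergence = 0.08),
      list(prefix = "plantmarlike", n = 8L, spacing = 39L, third = "D",
           divergence = 0.08),
      list(prefix = "IS630out", n = 3L, spacing = 34L, third = "E",
           divergence = 0.25)
    ),
    bootstrap_reps = 100L,
    min_support = 70,
    outgroup_prefix = "IS630out",
    tangle = list(n_hosts = 16L, n_htt_events = 5L),
    census = list(counts = c(full = 3L, partial = 2L, mite = 4L,
                             nonaut = 2L)),
    htt = list(n_transfer = 3L, n_contam = 3L, n_vertical = 3L)
  )
}

read_run_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  stopifnot(is.list(cfg), !is.null(cfg$out_dir))
  base <- default_config(cfg$out_dir, cfg$seed %||% 1L)
  utils::modifyList(base, cfg)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis
#'
#' Executes the enabled stages in order and writes per-stage tables plus a
#' JSON summary under `cfg$out_dir`. With all stage toggles off only the
#' configuration echo (`config.json`) is written. Reruns with an identical
#' configuration produce byte-identical outputs.
#'
#' @param cfg a config list (see [default_config()]) or path to a YAML file.
#' @return invisibly, a list with the per-stage results and `summary`.
#' @export
run_analysis <- function(cfg) {
  cfg <- read_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res <- list(config = cfg)
  summary <- list(seed = cfg$seed)

  if (isTRUE(cfg$stages$simulate)) {
    fams <- lapply(seq_along(cfg$families), function(i) {
      f <- cfg$families[[i]]
      do.call(sim_family, c(f, list(seed = cfg$seed + i)))
    })
    seqs <- do.call(c, lapply(fams, `[[`, "seqs"))
    truth <- do.call(rbind, lapply(fams, `[[`, "truth"))
    write_fasta(seqs, file.path(cfg$out_dir, "transposases.faa"))
    write_tsv(truth, file.path(cfg$out_dir, "truth_families.tsv"))
    res$fams <- fams
    res$proteins <- seqs
    res$family_truth <- truth
    message("simulate: ", length(seqs), " transposases from ",
            length(fams), " families")
  }

  if (isTRUE(cfg$stages$motif)) {
    # each family is classified against its own seed profile (the seed
    # alignment is a given input of the motif-reading procedure)
    tab <- do.call(rbind, lapply(res$fams, function(f) {
      classify_motifs(f$seqs, profile = sim_seed_profile(f))
    }))
    write_tsv(tab, file.path(cfg$out_dir, "motif_table.tsv"))
    counts <- as.data.frame(table(signature = tab$signature),
                            stringsAsFactors = FALSE)
    names(counts) <- c("signature", "n")
    write_tsv(counts, file.path(cfg$out_dir, "family_counts.tsv"))
    res$motifs <- tab
    summary$signature_counts <- stats::setNames(as.list(counts$n),
                                                counts$signature)
    message("motif: ", sum(tab$found), "/", nrow(tab), " triads located")
  }

  if (isTRUE(cfg$stages$phylo)) {
    tree <- bootstrap_supports(res$proteins, n_reps = cfg$bootstrap_reps,
                               seed = cfg$seed + 100L)
    og <- grep(paste0("^", cfg$outgroup_prefix), names(res$proteins),
               value = TRUE)
    rooted <- root_with_outgroup(tree, og)
    writeLines(write_newick(rooted), file.path(cfg$out_dir, "tree.nwk"))
    cl <- extract_supported_clades(rooted, cfg$min_support)
    cl_tab <- do.call(rbind, lapply(seq_along(cl$groups), function(i) {
      g <- cl$groups[[i]]
      data.frame(group = i, support = g$support,
                 members = paste(sort(g$members), collapse = ","),
                 stringsAsFactors = FALSE)
    })) %||% data.frame(group = integer(0), support = numeric(0),
                        members = character(0))
    write_tsv(cl_tab, file.path(cfg$out_dir, "clades.tsv"))
    res$tree <- rooted
    res$clades <- cl
    summary$n_supported_clades <- length(cl$groups)
    summary$n_isolated <- length(cl$isolated)
    message("phylo: ", length(cl$groups), " supported clades, ",
            length(cl$isolated), " isolated leaves")
  }

  if (isTRUE(cfg$stages$tangle)) {
    sim <- sim_cophylo(n_hosts = cfg$tangle$n_hosts,
                       n_htt_events = cfg$tangle$n_htt_events,
                       seed = cfg$seed + 200L)
    te_tree <- root_with_outgroup(
      nj_tree(p_distance_matrix(sim$aln)), names(sim$aln)[1L])
    host_tree <- host_tree_from_taxonomy(sim$taxonomy)
    tg <- minimize_crossings(te_tree, host_tree, sim$links)
    write_tsv(data.frame(crossings = tg$crossings,
                         normalized_crossings = tg$normalized_crossings,
                         initial_crossings = tg$initial_crossings,
                         n_links = nrow(sim$links),
                         planted_htt_events = sim$truth$n_htt_events),
              file.path(cfg$out_dir, "tanglegram.tsv"))
    res$tanglegram <- tg
    summary$normalized_crossings <- tg$normalized_crossings
    message("tangle: ", tg$crossings, " crossings after minimisation (",
            tg$initial_crossings, " before)")
  }

  if (isTRUE(cfg$stages$census)) {
    el <- sim_element(seed = cfg$seed + 300L, plant_triad = TRUE)
    sim <- sim_hit_table(nchar(el$bases),
                         tir = list(tir5 = el$truth$tir5,
                                    tir3 = el$truth$tir3),
                         counts = cfg$census$counts,
                         seed = cfg$seed + 301L, query_id = el$id)
    ann <- annotate_element(el$bases, el$id, el$flank5, el$flank3)
    cc <- census(sim$hits, nchar(el$bases), tir = ann$tir)
    write_tsv(data.frame(class = names(cc), count = as.integer(cc),
                         truth = as.integer(sim$truth[names(cc)])),
              file.path(cfg$out_dir, "census.tsv"))
    res$census <- cc
    res$census_truth <- sim$truth
    summary$census <- as.list(cc)
    message("census: ", sum(cc), " loci classified")
  }

  if (isTRUE(cfg$stages$htt)) {
    bench <- sim_htt_pairs(cfg$htt$n_transfer, cfg$htt$n_contam,
                           cfg$htt$n_vertical, seed = cfg$seed + 400L)
    verdicts <- screen_pairs(bench$elements, bench$taxonomy,
                             bench$hit_tables, pairs = bench$pairs[1:2])
    write_tsv(verdicts, file.path(cfg$out_dir, "htt_verdicts.tsv"))
    res$htt <- verdicts
    summary$htt_candidates <- sum(verdicts$verdict == "candidate")
    message("htt: ", nrow(verdicts), " pairs evaluated, ",
            sum(verdicts$verdict == "candidate"), " candidates")
  }

  if (any(unlist(cfg$stages))) {
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res$summary <- summary
  invisible(res)
}
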