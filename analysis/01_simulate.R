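#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Generates the synthetic transposase families (three ingroup families with
# distinct DDD/E signatures plus an IS630-style outgroup), one full-length
# element with the compact ITm architecture, its genome hit table with
# planted copy classes, and writes everything (with truth tables) under
# results/.

suppressPackageStartupMessages(library(tcmariner))
dir.create("results", showWarnings = FALSE)

seed <- 1L
cfg <- default_config("results", seed = seed)

fams <- lapply(seq_along(cfg$families), function(i) {
  do.call(sim_family, c(cfg$families[[i]], list(seed = seed + i)))
})
seqs <- do.call(c, lapply(fams, `[[`, "seqs"))
truth <- do.call(rbind, lapply(fams, `[[`, "truth"))
write_fasta(seqs, "results/transposases.faa")
write.table(truth, "results/truth_families.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("simulated %d transposases from %d families -> results/transposases.faa\n",
            length(seqs), length(fams)))

el <- sim_element(seed = seed + 300L, plant_triad = TRUE)
write_fasta(c(element = el$bases), "results/element.fna")
sim <- sim_hit_table(nchar(el$bases),
                     tir = list(tir5 = el$truth$tir5, tir3 = el$truth$tir3),
                     counts = cfg$census$counts, seed = seed + 301L,
                     query_id = "element")
write_hit_table(sim$hits, "results/element_genome_hits.tsv")
cat(sprintf("simulated element (%d nt, %d bp TIRs) and %d genome hits\n",
            nchar(el$bases), el$truth$tir_len, nrow(sim$hits)))

co <- sim_cophylo(n_hosts = cfg$tangle$n_hosts,
                  n_htt_events = cfg$tangle$n_htt_events,
                  seed = seed + 200L)
write_fasta(co$aln, "results/te_alignment.afa")
write_taxonomy(co$taxonomy, "results/host_taxonomy.tsv")
write.table(co$links, "results/links.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("simulated %d hosts with %d planted horizontal transfers\n",
            cfg$tangle$n_hosts, cfg$tangle$n_htt_events))
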