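#!/usr/bin/env Rscript
# Generate the synthetic study inputs: two 454-style flower EST libraries
# (sexual and apomictic) with planted hairpin precursors, truncated
# precursors and tRNA/rRNA contaminants; a multi-species mature-miRNA
# reference set with planted cross-species duplication; tag counts across
# four ovule stages with one up-regulated tag at stage two in the apomictic
# mode; and qPCR Ct triplicates with a planted 4-fold effect.

suppressPackageStartupMessages(library(mirseeker))

outdir <- "results/simulated"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_reads = 500, n_planted = 25, seed = 7)
write_sim_config(cfg, file.path(outdir, "sim_config.yaml"))

refset <- gen_reference_set(n_species = 4, n_families = 30,
                            duplicate_rate = 0.4, seed = 7)
cat(sprintf("reference set: %d entries, %d unique matures\n",
            nrow(refset$refs), refset$n_unique))

sim <- gen_est_library(cfg, refs = refset$refs, outdir = outdir)
cat(sprintf("libraries: %d reads (%d sexual, %d apomictic)\n",
            nrow(sim$reads), sum(sim$reads$library == "sexual"),
            sum(sim$reads$library == "apomictic")))
cat(sprintf("planted: %d precursors, %d truncated, %d contaminant reads\n",
            nrow(sim$truth$planted), nrow(sim$truth$truncated),
            length(sim$truth$contaminant_ids)))

tags <- gen_tag_counts(1000, planted = list(list(tag = 1, stage = 2,
                                                 mode = "apomictic",
                                                 fold = 10)),
                       depth = 1e5, seed = 7)
write.table(data.frame(tag = rownames(tags$counts), tags$counts),
            file.path(outdir, "tag_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tags$meta, file.path(outdir, "tag_libraries.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

qp <- gen_qpcr(10, effect_log2 = 2, noise_sd = 0.2, seed = 7)
write.table(qp$records, file.path(outdir, "qpcr_ct.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

saveRDS(list(sim = sim, refset = refset, tags = tags, qpcr = qp),
        file.path("results", "sim_objects.rds"))
cat("inputs written under", outdir, "\n")
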