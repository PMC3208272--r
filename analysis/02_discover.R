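#!/usr/bin/env Rscript
# Homology search and hairpin evaluation over the simulated libraries:
# dedup the reference set, exclude contaminants, scan for 20-24 nt gapless
# matches with <= 3 mismatches, fold candidates, apply the five stem-loop
# acceptance criteria, and compare the accepted set with the planted truth.

suppressPackageStartupMessages(library(mirseeker))

objects <- readRDS("results/sim_objects.rds")
sim <- objects$sim

cfg <- default_config(refs = objects$refset$refs, ests = sim$reads,
                      contaminants = sim$contaminant_db, seed = 7,
                      outdir = "results/discovery")
res <- run_discovery(cfg)

cat(sprintf("reference: %d entries -> %d unique queries\n",
            res$manifest$n_refs_in, res$manifest$n_refs_unique))
cat(sprintf("reads: %d in, %d removed as contaminants\n",
            res$manifest$n_reads, res$manifest$n_removed_contaminant))
cat(sprintf("candidates: %d, accepted stem-loops: %d\n",
            res$manifest$n_candidates, res$manifest$n_accepted))

planted <- sim$truth$planted
recovered <- res$accepted[res$accepted$est_id %in% planted$read_id, ]
cat(sprintf("planted recovery: %d / %d precursors\n",
            length(unique(recovered$est_id)), nrow(planted)))

trunc_ids <- sim$truth$truncated$read_id
trunc_rec <- res$records[res$records$est_id %in% trunc_ids, ]
cat(sprintf("truncated reads evaluated: %d, rejected: %d (reasons: %s)\n",
            nrow(trunc_rec), sum(!trunc_rec$accepted),
            paste(unique(trunc_rec$failure_reasons[!trunc_rec$accepted]),
                  collapse = " | ")))

per_lib <- table(res$accepted$library)
cat("accepted per library:",
    paste(names(per_lib), per_lib, sep = "=", collapse = ", "), "\n")
cat("reports written under results/discovery\n")
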