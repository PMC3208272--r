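#!/usr/bin/env Rscript
# Downstream expression analyses: miRNA target prediction on simulated
# transcripts, microarray detection calls, the family-set comparison between
# detection methods, per-stage tag-count differential expression, and ddCt
# relative quantification.

suppressPackageStartupMessages(library(mirseeker))
objects <- readRDS("results/sim_objects.rds")
dir.create("results", showWarnings = FALSE)

# -- target prediction -------------------------------------------------------
set.seed(7)
refs <- objects$refset$refs
mirnas <- refs[!duplicated(refs$family), ][1:5, c("id", "mature_seq")]
transcripts <- do.call(rbind, lapply(1:20, function(i) {
  seq <- paste(sample(c("A", "C", "G", "U"), 400, replace = TRUE),
               collapse = "")
  if (i <= 5) { # plant a near-perfect site for one miRNA
    site <- revcomp(mirnas$mature_seq[i])
    substr(seq, 100, 99 + nchar(site)) <- site
  }
  data.frame(id = sprintf("transcript%02d", i), seq = seq)
}))
hits <- predict_targets(mirnas, transcripts)
cat(sprintf("target prediction: %d sites on %d transcripts (planted: 5)\n",
            nrow(hits), length(unique(hits$transcript_id))))
write.table(hits, "results/target_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# -- family sets: homology vs array -----------------------------------------
pm <- published_precursor_metrics()
bioinf <- unique(pm$family)
array_set <- c(sort(bioinf)[1:15], sprintf("array-only-%d", 1:7))
venn <- compare_family_sets(bioinf, array_set)
cat(sprintf("family sets: %d homology, %d array, %d shared, union %d\n",
            length(bioinf), length(array_set), venn$both$n, venn$union$n))
jsonlite::write_json(venn, "results/family_venn.json", auto_unbox = TRUE,
                     pretty = TRUE)

# -- differential expression across stages ----------------------------------
tags <- objects$tags
de1 <- diff_expression(tags$counts, tags$meta, "tag00001")
cat("planted tag per-stage comparison:\n")
print(de1)
write.table(de1, "results/de_planted_tag.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# -- ddCt --------------------------------------------------------------------
rel <- ddct(objects$qpcr$records, "cal")
cat(sprintf("ddCt: mean fold %.2f (planted %.1f) over %d samples\n",
            mean(rel$fold[rel$sample != "cal"]),
            objects$qpcr$truth$expected_fold, sum(rel$sample != "cal")))
write.table(rel, "results/qpcr_relative_expression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
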