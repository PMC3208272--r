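test_that("hairpin construction places the mature on the requested arm", {
  m <- "UGACAGAAGAGAGAGAGCAC"
  hp5 <- make_hairpin_precursor(m, "5p", loop_len = 6, seed = 1)
  expect_equal(substr(hp5$seq, hp5$mature_start, hp5$mature_end), m)
  expect_equal(hp5$mature_start, 1)
  f5 <- fold_mfe(hp5$seq)
  # perfect complement: all mature bases paired, before the loop
  partner <- mirseeker:::.db_partner(f5$dot_bracket)
  expect_true(all(!is.na(partner[hp5$mature_start:hp5$mature_end])))
  expect_equal(parse_hairpin(f5, c(hp5$mature_start, hp5$mature_end))$arm, "5p")

  hp3 <- make_hairpin_precursor(m, "3p", loop_len = 6, seed = 1)
  expect_equal(substr(hp3$seq, hp3$mature_start, hp3$mature_end), m)
  expect_gt(hp3$mature_start, nchar(m))  # after star arm and loop
  f3 <- fold_mfe(hp3$seq)
  expect_equal(parse_hairpin(f3, c(hp3$mature_start, hp3$mature_end))$arm, "3p")
})

test_that("arm mismatches leave most mature positions paired", {
  m <- "UGACAGAAGAGAGAGAGCAC"
  hp <- make_hairpin_precursor(m, "5p", loop_len = 6, n_arm_mismatches = 3,
                               target_len = 80, seed = 2)
  f <- fold_mfe(hp$seq)
  partner <- mirseeker:::.db_partner(f$dot_bracket)
  paired <- sum(!is.na(partner[hp$mature_start:hp$mature_end]))
  expect_gte(paired, nchar(m) - 3 - 2)  # tolerance for local rearrangement
})

test_that("invalid hairpin requests are rejected", {
  expect_error(make_hairpin_precursor("UGACAGAAGAGAGAGAGCAX", "5p"), "non-RNA")
  expect_error(make_hairpin_precursor("UGACAGAAGAGAGAGAGCAC", "5p",
                                      loop_len = 2), "loop")
  expect_error(make_hairpin_precursor("ACGU", "5p"), "20-24")
})

test_that("the generator is deterministic under a fixed config", {
  cfg <- sim_config(n_reads = 60, n_planted = 6, seed = 42,
                    homopolymer_indel_rate = 0.002)
  a <- gen_est_library(cfg)
  b <- gen_est_library(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  # and differs under another seed
  c <- gen_est_library(sim_config(n_reads = 60, n_planted = 6, seed = 43,
                                  homopolymer_indel_rate = 0.002))
  expect_false(identical(a$reads$seq, c$reads$seq))
})

test_that("read and precursor lengths respect the stated bounds", {
  sim <- gen_est_library(sim_config(n_reads = 150, n_planted = 20, seed = 3))
  lens <- nchar(sim$reads$seq)
  expect_true(all(lens >= 51 - 2 & lens <= 478 + 2))  # +/- homopolymer indels
  pl <- sim$truth$planted
  expect_true(all(pl$precursor_end - pl$precursor_start + 1 >= 66))
  expect_true(all(pl$precursor_end - pl$precursor_start + 1 <= 233))
  # spans lie within read bounds and every truth id exists
  expect_true(all(pl$read_id %in% sim$reads$id))
  read_len <- setNames(lens, sim$reads$id)
  expect_true(all(pl$precursor_end <= read_len[pl$read_id]))
  expect_true(all(pl$precursor_start >= 1))
})

test_that("planted precursors extracted by their spans pass the criteria", {
  sim <- gen_est_library(sim_config(n_reads = 40, n_planted = 10,
                                    contaminant_fraction = 0,
                                    truncation_fraction = 0,
                                    homopolymer_indel_rate = 0, seed = 17))
  pl <- sim$truth$planted
  for (i in seq_len(nrow(pl))) {
    read <- sim$reads$seq[sim$reads$id == pl$read_id[i]]
    prec <- substr(read, pl$precursor_start[i], pl$precursor_end[i])
    f <- fold_mfe(prec)
    span <- c(pl$mature_start[i], pl$mature_end[i]) - pl$precursor_start[i] + 1
    hp <- parse_hairpin(f, span)
    expect_true(f$delta_g <= -10, info = pl$read_id[i])
    expect_equal(hp$arm, pl$arm[i], info = pl$read_id[i])
    expect_lte(hp$unpaired_in_span, 6)
    au <- mirseeker:::.au_percent(pl$mature_seq[i])
    expect_true(au >= 40 && au <= 70)
  }
})

test_that("homopolymer noise updates or flags planted spans", {
  cfg <- sim_config(n_reads = 80, n_planted = 20, contaminant_fraction = 0,
                    truncation_fraction = 0, homopolymer_indel_rate = 0.01,
                    seed = 19)
  sim <- gen_est_library(cfg)
  pl <- sim$truth$planted
  read_len <- setNames(nchar(sim$reads$seq), sim$reads$id)
  # shifted spans still lie within their reads
  expect_true(all(pl$precursor_start >= 1))
  expect_true(all(pl$precursor_end <= read_len[pl$read_id]))
  # intact spans still fold to an acceptable hairpin
  intact <- pl[pl$span_intact, ]
  ok <- vapply(seq_len(nrow(intact)), function(i) {
    read <- sim$reads$seq[sim$reads$id == intact$read_id[i]]
    prec <- substr(read, intact$precursor_start[i], intact$precursor_end[i])
    fold_mfe(prec)$delta_g <= -10
  }, logical(1))
  expect_true(all(ok))
})

test_that("reference sets without duplication are fully unique", {
  rs <- gen_reference_set(n_species = 3, n_families = 8, duplicate_rate = 0,
                          seed = 7)
  expect_equal(rs$n_unique, nrow(rs$refs))
  expect_equal(length(unique(rs$refs$mature_seq)), nrow(rs$refs))
})

test_that("tag-count truth is empty without planted effects", {
  sim <- gen_tag_counts(50, planted = list(), depth = 1e4, seed = 5)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(dim(sim$counts), c(50, 8))
  expect_true(all(colSums(sim$counts) == 1e4))
  expect_error(gen_tag_counts(10, depth = 0), "depth")
})

test_that("a strongly planted tag is flagged in its stage and mode", {
  sim <- gen_tag_counts(200, planted = list(list(tag = 1, stage = 2,
                                                 mode = "apomictic",
                                                 fold = 10)),
                        depth = 1e5, seed = 9)
  de <- diff_expression(sim$counts, sim$meta, "tag00001")
  row <- de[de$stage == 2, ]
  expect_lt(row$p_value, 0.05)
  expect_equal(row$direction, "apomictic")
})

test_that("noise-free qPCR reproduces planted folds exactly", {
  sim0 <- gen_qpcr(4, effect_log2 = 0, noise_sd = 0, seed = 1)
  rel0 <- ddct(sim0$records, "cal")
  expect_equal(rel0$fold, rep(1, nrow(rel0)))
  sim1 <- gen_qpcr(4, effect_log2 = 1, noise_sd = 0, seed = 1)
  rel1 <- ddct(sim1$records, "cal")
  expect_equal(rel1$fold[rel1$sample != "cal"], rep(2, 4))
  expect_error(gen_qpcr(4, noise_sd = -1), "noise_sd")
  expect_error(gen_qpcr(4, replicates = 1), "replicates")
})
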