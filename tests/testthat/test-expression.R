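test_that("an exact reverse-complement site is a perfect target hit", {
  mirna <- data.frame(id = "m1", mature_seq = "UGACAGAAGAGAGUGAGCAC")
  site <- revcomp(mirna$mature_seq)
  tr <- data.frame(id = "t1", seq = paste0("CCCCC", site, "GGGGG"))
  hits <- predict_targets(mirna, tr)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site_start, 6)
  expect_equal(hits$weighted_mm, 0)
})

test_that("four hard mismatches disqualify a site", {
  mirna <- data.frame(id = "m1", mature_seq = strrep("G", 20))
  # site of C's pairs perfectly; replace 4 site positions with G (G:G no pair)
  site <- paste0(strrep("C", 16), strrep("G", 4))
  tr <- data.frame(id = "t1", seq = site)
  hits <- predict_targets(mirna, tr)
  expect_equal(nrow(hits), 0)
})

test_that("target scanning equals the naive windowed oracle", {
  set.seed(44)
  for (i in 1:15) {
    mirna <- rand_rna(21)
    tr <- paste0(rand_rna(40), revcomp(mirna), rand_rna(40))
    for (gw in c(0.5, 1)) {
      got <- predict_targets(data.frame(id = "m", mature_seq = mirna),
                             data.frame(id = "t", seq = tr),
                             max_weighted_mm = 3, gu_weight = gw)
      want <- naive_target_oracle(mirna, tr, 3, gw)
      expect_equal(got$site_start, want$site_start)
      expect_equal(got$weighted_mm, want$wmm)
    }
  }
})

test_that("full-weight G:U hits are a subset of half-weight hits", {
  set.seed(45)
  for (i in 1:10) {
    mirna <- data.frame(id = "m", mature_seq = rand_rna(21))
    tr <- data.frame(id = "t", seq = rand_rna(300))
    strict <- predict_targets(mirna, tr, gu_weight = 1)
    loose <- predict_targets(mirna, tr, gu_weight = 0.5)
    expect_true(all(strict$site_start %in% loose$site_start))
  }
})

test_that("microarray detection applies all three clauses", {
  spots <- data.frame(
    probe_id = c("ok", "dim", "noisy", "flat"),
    signal = c(100, 20, 100, 100), background_sd = c(10, 10, 10, 10),
    cv = c(0.1, 0.1, 0.6, 0.1), p_value = c(0.001, 0.001, 0.001, 0.5))
  res <- microarray_detect(spots)
  expect_equal(res$detected, c(TRUE, FALSE, FALSE, FALSE))
  expect_false(res$pass_signal[2])
  expect_false(res$pass_cv[3])
  expect_false(res$pass_p[4])
})

test_that("synthetic spot sets with planted calls are exactly recovered", {
  set.seed(46)
  n <- 60
  truth <- runif(n) < 0.5
  spots <- data.frame(
    probe_id = sprintf("p%02d", 1:n),
    signal = ifelse(truth, runif(n, 50, 200), runif(n, 0, 25)),
    background_sd = 10,
    cv = ifelse(truth, runif(n, 0, 0.4), runif(n, 0, 1)),
    p_value = ifelse(truth, runif(n, 0, 0.009), runif(n, 0, 1)))
  # force failing probes to fail at least one clause
  fail_clause <- sample(1:3, n, replace = TRUE)
  spots$signal[!truth & fail_clause == 1] <- 5
  spots$cv[!truth & fail_clause == 2] <- 0.8
  spots$p_value[!truth & fail_clause == 3] <- 0.5
  res <- microarray_detect(spots)
  expect_equal(res$detected, truth)
})

test_that("family-set algebra reproduces partition arithmetic", {
  a <- sprintf("famA%02d", 1:44)
  b <- c(a[1:15], sprintf("famB%02d", 1:7))
  cmp <- compare_family_sets(a, b)
  expect_equal(cmp$both$n, 15)
  expect_equal(cmp$a_only$n, 29)
  expect_equal(cmp$b_only$n, 7)
  expect_equal(cmp$union$n, 51)
  eq <- compare_family_sets(a, a)
  expect_equal(eq$a_only$n, 0)
  expect_equal(eq$b_only$n, 0)
  dis <- compare_family_sets(a[1:5], b[16:22])
  expect_equal(dis$union$n, 12)
})

test_that("identical proportions give p = 1 and no direction", {
  counts <- matrix(c(10, 990, 10, 990, 10, 990, 10, 990), nrow = 2,
                   dimnames = list(c("t1", "rest"),
                                   c("sex_st1", "apo_st1", "sex_st2", "apo_st2")))
  meta <- data.frame(library = colnames(counts), stage = c(1, 1, 2, 2),
                     mode = c("sexual", "apomictic", "sexual", "apomictic"))
  de <- diff_expression(counts, meta, "t1")
  expect_equal(de$p_value, c(1, 1))
  expect_true(all(is.na(de$direction)))
})

test_that("a strong count excess is significant toward the right mode", {
  counts <- matrix(c(5, 99995, 50, 99950), nrow = 2,
                   dimnames = list(c("t1", "rest"), c("sex_st1", "apo_st1")))
  meta <- data.frame(library = colnames(counts), stage = 1,
                     mode = c("sexual", "apomictic"))
  de <- diff_expression(counts, meta, "t1", stages = 1)
  expect_lt(de$p_value, 0.05)
  expect_equal(de$direction, "apomictic")
  # matches the direct hypergeometric enumeration
  expect_equal(de$p_value, hypergeom_fisher_p(5, 1e5 - 5, 50, 1e5 - 50),
               tolerance = 1e-9)
})

test_that("Fisher p-values equal hypergeometric enumeration on small margins", {
  set.seed(47)
  for (i in 1:20) {
    a <- sample(0:30, 1); c <- sample(0:30, 1)
    b <- sample(50:150, 1); d <- sample(50:150, 1)
    counts <- matrix(c(a, b, c, d), nrow = 2,
                     dimnames = list(c("t1", "rest"), c("s", "a")))
    meta <- data.frame(library = c("s", "a"), stage = 1,
                       mode = c("sexual", "apomictic"))
    de <- diff_expression(counts, meta, "t1", stages = 1)
    expect_equal(de$p_value, hypergeom_fisher_p(a, b, c, d), tolerance = 1e-7)
  }
})

test_that("ddCt is exact on constructed records and shift-invariant", {
  rec <- rbind(
    data.frame(sample = "cal", gene = "target", ct = c(25, 25, 25)),
    data.frame(sample = "cal", gene = "reference", ct = c(20, 20, 20)),
    data.frame(sample = "s1", gene = "target", ct = c(24, 24, 24)),
    data.frame(sample = "s1", gene = "reference", ct = c(20, 20, 20)))
  rel <- ddct(rec, "cal")
  expect_equal(rel$fold[rel$sample == "cal"], 1)
  expect_equal(rel$fold[rel$sample == "s1"], 2)  # ddCt = -1
  # shifting one sample's target and reference together changes nothing
  rec2 <- rec
  shift <- rec2$sample == "s1"
  rec2$ct[shift] <- rec2$ct[shift] + 3.7
  expect_equal(ddct(rec2, "cal")$fold, rel$fold)
  expect_error(ddct(rec[rec$gene == "target", ], "cal"), "lacks")
  expect_error(ddct(rec, "nope"), "calibrator")
})
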