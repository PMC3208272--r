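test_that("substitution detection is a character-wise comparison", {
  expect_equal(nrow(detect_ns("UGACAG", "UGACAG") |> suppressWarnings()), 0)
  subs <- detect_ns("UGACAGAAGAGAGA", "UGACAGAAGAGAGU")
  expect_equal(subs$position, 14)
  expect_equal(subs$ref_nt, "U")
  expect_equal(subs$obs_nt, "A")
  expect_error(detect_ns("ACGU", "ACGUA"), "length")
  set.seed(33)
  for (i in 1:25) {
    a <- rand_rna(21); b <- rand_rna(21)
    subs <- detect_ns(a, b)
    expect_equal(subs$position,
                 which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
  }
})

test_that("the substitution spectrum counts reference nucleotides per mode", {
  rec <- data.frame(ref_nt = c("U", "U", "G", "A"),
                    obs_nt = c("A", "C", "A", "G"),
                    mode = c("sexual", "apomictic", "apomictic", "apomictic"))
  sp <- ns_spectrum(rec)
  sx <- sp[sp$mode == "sexual", ]
  expect_equal(sx$frequency[sx$ref_nt == "U"], 1)
  ap <- sp[sp$mode == "apomictic", ]
  expect_equal(sum(ap$frequency), 1)
  expect_equal(ap$count[ap$ref_nt == "U"], 1)
  expect_equal(nrow(ns_spectrum(rec[0, ])), 0)
})

test_that("correcting a precursor is an involution touching only the span", {
  hp <- make_hairpin_precursor("UGACAGAAGAGAGAGAGCAC", "5p", loop_len = 8,
                               target_len = 80, seed = 4)
  span <- c(hp$mature_start, hp$mature_end)
  subs <- data.frame(position = c(3, 14), ref_nt = c("U", "U"),
                     obs_nt = c("A", "A"))
  # make the observed nucleotides consistent with the precursor
  obs <- hp$seq
  corrected <- correct_precursor(obs, span, subs, "to_reference")
  diff_pos <- which(strsplit(obs, "")[[1]] != strsplit(corrected, "")[[1]])
  expect_true(length(diff_pos) <= nrow(subs))
  expect_true(all(diff_pos >= span[1] & diff_pos <= span[2]))
  back <- correct_precursor(corrected, span, subs, "to_observed")
  # reverse direction restores the observed nucleotides at the sub positions
  expect_equal(substr(back, span[1] + 2, span[1] + 2),
               subs$obs_nt[1])
  expect_equal(correct_precursor(obs, span, subs[0, ], "to_reference"), obs)
  expect_error(correct_precursor(obs, span,
                                 data.frame(position = 50, ref_nt = "A",
                                            obs_nt = "U")),
               "outside")
})

test_that("a substitution-free experiment is neutral with zero delta", {
  hp <- make_hairpin_precursor("UGACAGAAGAGAGAGAGCAC", "5p", loop_len = 8,
                               target_len = 80, seed = 9)
  res <- correction_experiment(hp$seq, c(hp$mature_start, hp$mature_end),
                               data.frame(position = integer(0),
                                          ref_nt = character(0),
                                          obs_nt = character(0)))
  expect_equal(res$delta, 0)
  expect_equal(res$call, "neutral")
})

test_that("published free-energy pairs classify as reported: 8/9 and 5/9", {
  dg <- published_hairpin_dg()
  t3 <- dg[dg$direction == "to_reference", ]
  t3$call <- classify_correction(t3$dg_natural, t3$dg_corrected)
  expect_equal(sum(t3$call[t3$mode == "apomictic"] == "stabilizing"), 8)
  expect_equal(length(t3$call[t3$mode == "apomictic"]), 9)
  expect_equal(sum(t3$call[t3$mode == "sexual"] == "stabilizing"), 5)
  expect_equal(length(t3$call[t3$mode == "sexual"]), 9)
})

test_that("the classification matches stated example pairs", {
  expect_equal(classify_correction(-21.6, -19.3), "stabilizing")
  expect_equal(classify_correction(-55.9, -56.8), "destabilizing")
  expect_equal(classify_correction(-30, -30.02), "neutral")
})

test_that("exact signed-rank p equals full 2^n enumeration for small n", {
  set.seed(55)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, mean = -0.5), 1)
    d <- d[d != 0]
    if (length(d) < 2) next
    got <- paired_stability_test(d)
    expect_equal(got$p_value, enumerate_signed_rank_p(d), tolerance = 1e-12,
                 info = paste(d, collapse = ","))
  }
})

test_that("exact signed-rank p matches wilcox.test in tie-free cases", {
  set.seed(66)
  for (i in 1:8) {
    d <- rnorm(12)  # continuous: no ties, no zeros
    got <- paired_stability_test(d)
    ref <- wilcox.test(d, alternative = "less", exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the test is invariant under permutation of input order", {
  d <- c(-2.3, -2.3, 0.9, -0.3, -3.2, -1.6, 4.2, 2.1, 0.6)
  p1 <- paired_stability_test(d)$p_value
  set.seed(77)
  p2 <- paired_stability_test(sample(d))$p_value
  expect_equal(p1, p2)
})

test_that("degenerate all-zero differences give p = 1", {
  res <- paired_stability_test(c(0, 0, 0))
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  expect_equal(res$n_dropped_zero, 3)
})

test_that("large-n p-values use a sane normal approximation", {
  set.seed(88)
  d <- rnorm(40, mean = -0.4)
  res <- paired_stability_test(d)
  ref <- wilcox.test(d, alternative = "less", exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("the pooled published pairs are significant at 0.05", {
  dg <- published_hairpin_dg()
  t3 <- dg[dg$direction == "to_reference", ]
  res <- paired_stability_test(t3$dg_natural - t3$dg_corrected)
  expect_equal(res$n_pairs, 18)
  expect_lte(res$p_value, 0.05)
})
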