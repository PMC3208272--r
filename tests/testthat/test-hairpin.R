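test_that("AMFE normalizes |MFE| per 100 nt", {
  expect_equal(round(compute_amfe(-21.6, 75), 2), 28.80)
  expect_equal(round(compute_amfe(-18.7, 75), 2), 24.93)
  expect_equal(compute_amfe(-10, 100), 10)
  expect_error(compute_amfe(-10, 0))
  expect_error(compute_amfe(5, 100))
})

test_that("MFEI is AMFE over G+C percentage", {
  expect_equal(round(compute_mfei(28.80, 54.67), 3), 0.635)
  expect_equal(round(compute_mfei(48.20, 60.00), 3), 1.205)
  expect_equal(compute_mfei(40, 50), 0.8)
  expect_error(compute_mfei(40, 100), "G\\+C")
})

test_that("arm assignment follows the mature span relative to the loop", {
  f <- structure(list(seq = strrep("A", 16),
                      dot_bracket = "((((((....))))))", delta_g = -1),
                 class = "fold_result")
  expect_equal(parse_hairpin(f, c(1, 6))$arm, "5p")
  expect_equal(parse_hairpin(f, c(11, 16))$arm, "3p")
  res <- parse_hairpin(f, c(5, 12))
  expect_true(res$loop_overlap)
  expect_true(is.na(res$arm))
  expect_false(res$ok)
})

test_that("mature spans overlapping a multiloop are flagged", {
  db <- "((..((((....))))..((((....))))..))"
  f <- structure(list(seq = strrep("G", nchar(db)), dot_bracket = db,
                      delta_g = -1), class = "fold_result")
  res <- parse_hairpin(f, c(15, 20))  # crosses first stem into multiloop
  expect_true(res$multiloop_overlap)
  expect_false(res$ok)
})

test_that("a planted precursor is accepted with the true arm", {
  for (arm in c("5p", "3p")) {
    hp <- make_hairpin_precursor("UGACAGAAGAGAGUGAGCAC", arm, loop_len = 8,
                                 target_len = 90, seed = 5)
    est <- data.frame(id = "e1", seq = hp$seq)
    hit <- data.frame(query_id = "q", family = "miR900", est_id = "e1",
                      est_start = hp$mature_start, est_end = hp$mature_end,
                      strand = "+", aln_len = 20, mismatches = 0,
                      mismatch_positions = "",
                      aligned_est_subseq = "UGACAGAAGAGAGUGAGCAC")
    rec <- evaluate_candidate(est, hit)
    expect_true(rec$accepted)
    expect_equal(rec$arm, arm)
    expect_true(rec$mfe <= -10)
  }
})

test_that("high A+U matures fail the composition criterion", {
  # A+U = 80% mature: outside the 40-70% window
  mature <- "AAUUAAUUAAUUAAUUGCGC"
  expect_equal(mirseeker:::.au_percent(mature), 80)
  hp <- make_hairpin_precursor(mature, "5p", loop_len = 8,
                               target_len = 80, seed = 6)
  est <- data.frame(id = "e1", seq = hp$seq)
  hit <- data.frame(query_id = "q", family = "miR901", est_id = "e1",
                    est_start = hp$mature_start, est_end = hp$mature_end,
                    strand = "+", aln_len = 20, mismatches = 0,
                    mismatch_positions = "", aligned_est_subseq = mature)
  rec <- evaluate_candidate(est, hit)
  expect_false(rec$accepted)
  expect_false(rec$c4)
  expect_match(rec$failure_reasons, "A\\+U")
  # the same candidate passes when the criterion is evaluated on the
  # precursor (whose flanks dilute the A+U content)
  cfg <- default_config(au_criterion_on = "precursor")
  rec2 <- evaluate_candidate(est, hit, cfg)
  expect_true(rec2$c4 || rec2$au_percent > 70)
})

test_that("minus-strand candidates are evaluated in mature orientation", {
  mature <- "UGACAGAAGAGAGUGAGCAC"
  hp <- make_hairpin_precursor(mature, "5p", loop_len = 8,
                               target_len = 90, seed = 7)
  flipped <- revcomp(hp$seq)
  n <- nchar(flipped)
  est <- data.frame(id = "e1", seq = flipped)
  hit <- data.frame(query_id = "q", family = "miR900", est_id = "e1",
                    est_start = n - hp$mature_end + 1,
                    est_end = n - hp$mature_start + 1,
                    strand = "-", aln_len = 20, mismatches = 0,
                    mismatch_positions = "",
                    aligned_est_subseq = revcomp(mature))
  rec <- evaluate_candidate(est, hit)
  expect_true(rec$accepted)
  expect_equal(rec$mature_seq, mature)
  expect_equal(rec$arm, "5p")
})

test_that("records carry a full, internally consistent metric set", {
  hp <- make_hairpin_precursor("UGACAGAAGAGAGUGAGCAC", "5p", loop_len = 8,
                               target_len = 100, seed = 8)
  est <- data.frame(id = "e1", seq = hp$seq)
  hit <- data.frame(query_id = "q", family = "miR900", est_id = "e1",
                    est_start = hp$mature_start, est_end = hp$mature_end,
                    strand = "+", aln_len = 20, mismatches = 0,
                    mismatch_positions = "",
                    aligned_est_subseq = "UGACAGAAGAGAGUGAGCAC")
  rec <- evaluate_candidate(est, hit)
  expect_equal(rec$nn, rec$window_end - rec$window_start + 1)
  expect_equal(rec$amfe, abs(rec$mfe) / rec$nn * 100)
  expect_equal(rec$mfei, rec$amfe / (100 - rec$au_percent))
  expect_true(all(c(rec$c1, rec$c2, rec$c3, rec$c4, rec$c5) == rec$accepted |
                    rec$accepted))
})
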