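#' Adjusted minimal folding energy (AMFE)
#'
#' AMFE normalizes a precursor's minimum free energy to a 100-nt basis:
#' `|MFE| / NN * 100`, where `NN` is the precursor length. Reported as a
#' positive magnitude (kcal/mol per 100 nt), following the convention of
#' printing positive AMFE against negative folding energies.
#'
#' @param mfe minimum free energy, kcal/mol (`<= 0`).
#' @param nn precursor length in nucleotides (`>= 1`).
#' @return AMFE in kcal/mol per 100 nt (unrounded; tables print 2 decimals).
#' @export
compute_amfe <- function(mfe, nn) {
  stopifnot(all(nn >= 1), all(mfe <= 0))
  abs(mfe) / nn * 100
}

#' Minimal folding energy index (MFEI)
#'
#' `MFEI = AMFE / (G+C%)` with `G+C% = 100 - A+U%`; a dimensionless index
#' used to distinguish miRNA precursors (typically MFEI > 0.85) from tRNA,
#' rRNA and mRNA. Here MFEI is reported, not filtered on: conserved
#' precursors with substitutions can fall well below 0.85.
#'
#' @param amfe AMFE, kcal/mol per 100 nt.
#' @param au_percent A+U content of the precursor, percent, in `[0, 100)`.
#' @return MFEI (unrounded; tables print 3 decimals).
#' @export
compute_mfei <- function(amfe, au_percent) {
  stopifnot(all(au_percent >= 0))
  if (any(au_percent >= 100)) {
    stop("A+U content of 100% leaves no G+C to normalize by", call. = FALSE)
  }
  amfe / (100 - au_percent)
}

#' Locate the mature miRNA on a hairpin arm
#'
#' Given a folded structure and the mature miRNA span, determines which arm
#' of the enclosing stem-loop carries the mature sequence: `5p` if every
#' paired mature base pairs downstream of the span (the mature lies before
#' the terminal loop), `3p` if every partner lies upstream. A span that
#' overlaps the terminal (hairpin) loop or a multiloop, pairs in both
#' directions, or contains no paired base, has no defined arm and is
#' flagged.
#'
#' @param fold a `fold_result` from [fold_mfe()].
#' @param mature_span integer vector `c(start, end)`, 1-based inclusive.
#' @return list with `arm` (`"5p"`, `"3p"` or `NA`), `unpaired_in_span`,
#'   `loop_overlap`, `multiloop_overlap`, and `ok` (TRUE when an arm is
#'   defined).
#' @export
parse_hairpin <- function(fold, mature_span) {
  stopifnot(inherits(fold, "fold_result"), length(mature_span) == 2)
  n <- nchar(fold$seq)
  s <- mature_span[1]; e <- mature_span[2]
  if (s < 1 || e > n || s > e) stop("mature span outside sequence")
  partner <- .db_partner(fold$dot_bracket)
  cls <- .db_loop_classes(fold$dot_bracket)
  span <- s:e
  loop_overlap <- any(cls[span] == "hairpin")
  multiloop_overlap <- any(cls[span] == "multi")
  paired <- span[!is.na(partner[span])]
  unpaired_in_span <- length(span) - length(paired)
  arm <- NA_character_
  if (!loop_overlap && !multiloop_overlap && length(paired) > 0) {
    partners <- partner[paired]
    if (all(partners > e)) arm <- "5p"
    else if (all(partners < s)) arm <- "3p"
  }
  list(arm = arm, unpaired_in_span = unpaired_in_span,
       loop_overlap = loop_overlap, multiloop_overlap = multiloop_overlap,
       ok = !is.na(arm))
}

# candidate precursor windows around a homology hit: the full read first,
# then symmetric extensions of the hit by w nt on each side
.candidate_windows <- function(n, hit_start, hit_end, extents = c(100, 60, 20)) {
  wins <- list(c(1L, n))
  for (w in extents) {
    win <- c(max(1L, hit_start - w), min(n, hit_end + w))
    if (!any(vapply(wins, function(x) all(x == win), logical(1)))) {
      wins[[length(wins) + 1]] <- win
    }
  }
  wins
}

#' Evaluate a homology hit as a candidate miRNA precursor
#'
#' Extracts candidate precursor windows around a homology hit (the full read,
#' then symmetric windows of +/- 100, 60 and 20 nt around the hit), folds
#' each with [fold_mfe()], and applies the five hairpin acceptance criteria:
#' (1) at most `max_mm` mismatches to the reference mature (inherited from
#' the hit); (2) the mature lies wholly on one arm of a stem-loop; (3)
#' MFE <= `mfe_max` kcal/mol; (4) A+U content within `au_range` percent; (5)
#' the mature overlaps neither the terminal loop nor a multiloop and contains
#' at most `gap_tolerance` unpaired bases. Among windows passing all
#' criteria the one with the most negative MFE is kept; if none passes, the
#' record reports the full-read fold with explicit failure reasons. The
#' criteria failures are data, not errors.
#'
#' By default criterion (4) is evaluated on the mature sequence (the stated
#' acceptance rule); `au_criterion_on = "precursor"` applies it to the
#' precursor window instead. The precursor A+U% is always reported, since
#' MFEI is defined from it.
#'
#' On the minus strand the precursor is the reverse complement of the read
#' window, so that the mature sequence appears in sense orientation.
#'
#' @param est one read as a list or one-row data.frame (`id`, `seq`).
#' @param hit one hit row from [scan_library()] / [collapse_redundant()].
#' @param config pipeline configuration from [default_config()] (thresholds
#'   `max_mm`, `mfe_max`, `au_range`, `gap_tolerance`, `window_extents`,
#'   `au_criterion_on`, `backend`).
#' @return one-row data.frame: `family`, `mature_seq`, `est_id`, `nn`,
#'   `arm`, `au_percent` (precursor), `mature_au_percent`, `mfe`, `amfe`,
#'   `mfei`, `window_start`, `window_end`, criteria flags `c1`..`c5`,
#'   `accepted`, `failure_reasons`, `dot_bracket`.
#' @export
evaluate_candidate <- function(est, hit, config = default_config()) {
  seq <- .normalize_rna(est$seq[[1]])
  n <- nchar(seq)
  hs <- hit$est_start[[1]]; he <- hit$est_end[[1]]
  stopifnot(hs >= 1, he <= n)
  mature <- hit$aligned_est_subseq[[1]]
  minus <- identical(hit$strand[[1]], "-")
  if (minus) mature <- revcomp(mature)
  mature_au <- .au_percent(mature)
  family <- if (!is.null(hit$families)) hit$families[[1]] else hit$family[[1]]

  wins <- .candidate_windows(n, hs, he, config$window_extents)
  evaluated <- lapply(wins, function(win) {
    wseq <- substr(seq, win[1], win[2])
    span <- c(hs - win[1] + 1L, he - win[1] + 1L)
    if (minus) {
      wlen <- win[2] - win[1] + 1L
      wseq <- revcomp(wseq)
      span <- c(wlen - span[2] + 1L, wlen - span[1] + 1L)
    }
    fold <- fold_mfe(wseq, backend = config$backend)
    hp <- parse_hairpin(fold, span)
    au_pre <- .au_percent(wseq)
    au_checked <- if (config$au_criterion_on == "mature") mature_au else au_pre
    crit <- c(
      c1 = hit$mismatches[[1]] <= config$max_mm,
      c2 = hp$ok,
      c3 = fold$delta_g <= config$mfe_max,
      c4 = au_checked >= config$au_range[1] && au_checked <= config$au_range[2],
      c5 = !hp$loop_overlap && !hp$multiloop_overlap &&
           hp$unpaired_in_span <= config$gap_tolerance
    )
    list(win = win, fold = fold, hp = hp, au_pre = au_pre, crit = crit,
         pass = all(crit))
  })
  passing <- Filter(function(x) x$pass, evaluated)
  best <- if (length(passing) > 0) {
    passing[[which.min(vapply(passing, function(x) x$fold$delta_g, numeric(1)))]]
  } else {
    evaluated[[1]]
  }

  reasons <- character(0)
  if (!best$pass) {
    crit <- best$crit
    if (!crit["c1"]) reasons <- c(reasons, "more than max mismatches")
    if (!crit["c2"] || !crit["c3"]) reasons <- c(reasons, "no stable stem-loop")
    if (!crit["c4"]) reasons <- c(reasons, "A+U content outside range")
    if (crit["c2"] && crit["c3"] && !crit["c5"]) {
      reasons <- c(reasons, "loop or gap in mature miRNA")
    }
  }
  nn <- best$win[2] - best$win[1] + 1L
  mfe <- best$fold$delta_g
  amfe <- if (mfe <= 0) compute_amfe(mfe, nn) else NA_real_
  mfei <- if (!is.na(amfe) && best$au_pre < 100) {
    compute_mfei(amfe, best$au_pre)
  } else NA_real_
  data.frame(
    family = family, mature_seq = mature, est_id = hit$est_id[[1]],
    strand = hit$strand[[1]], nn = nn, arm = best$hp$arm,
    au_percent = best$au_pre, mature_au_percent = mature_au,
    mfe = mfe, amfe = amfe, mfei = mfei,
    window_start = best$win[1], window_end = best$win[2],
    mismatches = hit$mismatches[[1]],
    c1 = unname(best$crit["c1"]), c2 = unname(best$crit["c2"]),
    c3 = unname(best$crit["c3"]), c4 = unname(best$crit["c4"]),
    c5 = unname(best$crit["c5"]),
    accepted = best$pass,
    failure_reasons = paste(reasons, collapse = "; "),
    dot_bracket = best$fold$dot_bracket,
    stringsAsFactors = FALSE
  )
}
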