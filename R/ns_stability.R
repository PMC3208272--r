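#' Detect nucleotide substitutions between an observed and a reference mature
#'
#' Position-by-position comparison of two equal-length, gapless mature miRNA
#' sequences. The notation follows the convention `ref/obs`: a record means
#' the reference carries `ref_nt` where the observed mature carries `obs_nt`.
#'
#' @param obs_mature observed mature sequence.
#' @param ref_mature reference (conserved) mature sequence of equal length.
#' @return data.frame with columns `position` (1-based), `ref_nt`, `obs_nt`;
#'   zero rows when the sequences are identical.
#' @export
detect_ns <- function(obs_mature, ref_mature) {
  obs_mature <- .normalize_rna(obs_mature)
  ref_mature <- .normalize_rna(ref_mature)
  if (nchar(obs_mature) != nchar(ref_mature)) {
    stop("sequences differ in length; gapped comparison is not supported",
         call. = FALSE)
  }
  o <- strsplit(obs_mature, "", fixed = TRUE)[[1]]
  r <- strsplit(ref_mature, "", fixed = TRUE)[[1]]
  pos <- which(o != r)
  data.frame(position = pos, ref_nt = r[pos], obs_nt = o[pos],
             stringsAsFactors = FALSE)
}

#' Substitution frequency spectrum by reference nucleotide
#'
#' Tabulates how often each reference nucleotide (A/C/G/U) is substituted
#' away, per library mode. Frequencies sum to 1 within each mode.
#'
#' @param records data.frame of substitution records with columns `ref_nt`
#'   and `mode` (e.g. `"sexual"`/`"apomictic"`).
#' @return data.frame with `mode`, `ref_nt`, `count`, `frequency`; zero rows
#'   for empty input.
#' @export
ns_spectrum <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    return(data.frame(mode = character(0), ref_nt = character(0),
                      count = integer(0), frequency = numeric(0),
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("ref_nt", "mode") %in% names(records)))
  out <- do.call(rbind, lapply(split(records, records$mode), function(sub) {
    counts <- table(factor(sub$ref_nt, levels = c("A", "C", "G", "U")))
    data.frame(mode = sub$mode[1], ref_nt = names(counts),
               count = as.integer(counts),
               frequency = as.numeric(counts) / sum(counts),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Apply (or revert) nucleotide substitutions within a precursor
#'
#' Rewrites the mature-miRNA region of a precursor according to a set of
#' substitution records, producing the "corrected" hairpin of the stability
#' experiment. `direction = "to_reference"` replaces observed nucleotides
#' with the reference ones (correcting the species-specific substitutions);
#' `direction = "to_observed"` does the reverse (giving a reference precursor
#' the observed nucleotides). Length is preserved; applying one direction
#' then the other returns the original sequence.
#'
#' @param precursor precursor sequence.
#' @param mature_span `c(start, end)` of the mature within the precursor,
#'   1-based inclusive.
#' @param subs data.frame from [detect_ns()] (`position` 1-based along the
#'   mature, `ref_nt`, `obs_nt`).
#' @param direction `"to_reference"` or `"to_observed"`.
#' @return the corrected precursor sequence.
#' @export
correct_precursor <- function(precursor, mature_span, subs,
                              direction = c("to_reference", "to_observed")) {
  direction <- match.arg(direction)
  precursor <- .normalize_rna(precursor)
  if (nrow(subs) == 0) return(precursor)
  pos <- mature_span[1] + subs$position - 1L
  if (any(subs$position < 1) || any(pos > mature_span[2])) {
    stop("substitution position outside the mature span", call. = FALSE)
  }
  ch <- strsplit(precursor, "", fixed = TRUE)[[1]]
  new_nt <- if (direction == "to_reference") subs$ref_nt else subs$obs_nt
  ch[pos] <- new_nt
  paste(ch, collapse = "")
}

#' Classify a natural-vs-corrected free-energy pair
#'
#' A substitution set is called `stabilizing` when the natural hairpin is
#' more stable than the corrected one beyond a tolerance
#' (`delta = dg_natural - dg_corrected < -tol`), `destabilizing` when it is
#' less stable (`delta > tol`), and `neutral` otherwise. The default
#' tolerance of 0.05 kcal/mol is half the precision at which hairpin free
#' energies are conventionally printed (one decimal).
#'
#' @param dg_natural,dg_corrected free energies, kcal/mol.
#' @param tol neutrality tolerance, kcal/mol.
#' @return character vector of calls.
#' @export
classify_correction <- function(dg_natural, dg_corrected, tol = 0.05) {
  delta <- dg_natural - dg_corrected
  ifelse(delta < -tol, "stabilizing",
         ifelse(delta > tol, "destabilizing", "neutral"))
}

#' Natural-vs-corrected hairpin stability experiment
#'
#' Folds a precursor both with its natural mature sequence and with the
#' substitutions corrected, using the same folding backend for both members
#' of the pair, and classifies the effect of the substitutions on stem-loop
#' stability.
#'
#' @inheritParams correct_precursor
#' @param precursor_id identifier for the output record.
#' @param backend folding backend passed to [fold_mfe()].
#' @param tol neutrality tolerance, kcal/mol (see [classify_correction()]).
#' @return one-row data.frame: `precursor_id`, `n_subs`, `dg_natural`,
#'   `dg_corrected`, `delta` (`dg_natural - dg_corrected`), `call`.
#' @export
correction_experiment <- function(precursor, mature_span, subs,
                                  precursor_id = "precursor",
                                  direction = "to_reference",
                                  backend = "builtin", tol = 0.05) {
  corrected <- correct_precursor(precursor, mature_span, subs, direction)
  dg_nat <- fold_mfe(precursor, backend = backend)$delta_g
  dg_cor <- fold_mfe(corrected, backend = backend)$delta_g
  data.frame(precursor_id = precursor_id, n_subs = nrow(subs),
             dg_natural = dg_nat, dg_corrected = dg_cor,
             delta = dg_nat - dg_cor,
             call = classify_correction(dg_nat, dg_cor, tol),
             stringsAsFactors = FALSE)
}

# exact null distribution of the doubled signed-rank statistic by a
# generating-function convolution over doubled mid-ranks
.signed_rank_exact_p <- function(r2, w2_obs) {
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in r2) {
    g <- numeric(total + 1)
    g[(r + 1):(total + 1)] <- f[1:(total + 1 - r)]
    f <- (f + g) / 2
  }
  sum(f[seq_len(min(w2_obs, total) + 1)])
}

#' One-sided paired signed-rank test of hairpin stabilization
#'
#' Tests whether natural hairpins are systematically more stable than their
#' corrected counterparts, i.e. whether the paired differences
#' `delta = dg_natural - dg_corrected` are shifted below zero. The statistic
#' is the Wilcoxon signed-rank sum of the positive differences; small values
#' support stabilization. Zero differences are dropped; absolute differences
#' are mid-ranked under ties. For up to `exact_max` non-zero pairs the
#' p-value is computed from the exact null distribution (a convolution over
#' doubled mid-ranks, exact also under ties); beyond that, a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. A paired one-sided t-test is available as a sensitivity check via
#' `method = "t"`.
#'
#' @param deltas numeric vector of paired differences, or a data.frame from
#'   [correction_experiment()] rows (column `delta` is used).
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @param exact_max largest n for the exact null (default 25).
#' @return list with `n_pairs` (non-zero differences), `n_dropped_zero`,
#'   `statistic` (signed-rank W+ for wilcoxon, t for t-test), `p_value`
#'   (one-sided, direction natural-more-stable), `direction`, `method`,
#'   `degenerate` (TRUE when all differences were zero).
#' @export
paired_stability_test <- function(deltas, method = c("wilcoxon", "t"),
                                  exact_max = 25) {
  method <- match.arg(method)
  if (is.data.frame(deltas)) deltas <- deltas$delta
  stopifnot(is.numeric(deltas))
  nz <- deltas[deltas != 0]
  n_dropped <- length(deltas) - length(nz)
  if (length(nz) == 0) {
    return(list(n_pairs = 0L, n_dropped_zero = n_dropped, statistic = NA_real_,
                p_value = 1, direction = "natural-more-stable",
                method = method, degenerate = TRUE))
  }
  if (length(nz) < 2) {
    stop("need at least 2 non-zero differences", call. = FALSE)
  }
  if (method == "t") {
    tt <- stats::t.test(nz, alternative = "less")
    return(list(n_pairs = length(nz), n_dropped_zero = n_dropped,
                statistic = unname(tt$statistic), p_value = tt$p.value,
                direction = "natural-more-stable", method = "t",
                degenerate = FALSE))
  }
  n <- length(nz)
  rk <- rank(abs(nz))           # mid-ranks under ties
  w_plus <- sum(rk[nz > 0])
  r2 <- as.integer(round(2 * rk))
  w2_obs <- as.integer(round(2 * w_plus))
  if (n <= exact_max) {
    p <- .signed_rank_exact_p(r2, w2_obs)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- pnorm((w_plus - mu + 0.5) / sqrt(sigma2))
  }
  list(n_pairs = n, n_dropped_zero = n_dropped, statistic = w_plus,
       p_value = min(1, p), direction = "natural-more-stable",
       method = "wilcoxon", degenerate = FALSE)
}
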