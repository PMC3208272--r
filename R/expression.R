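#' Predict miRNA target sites by complementarity
#'
#' Scans each transcript for gap-free windows whose antiparallel pairing with
#' the miRNA stays within a weighted mismatch budget: a Watson-Crick pair
#' costs 0, a G:U wobble costs `gu_weight` (default 0.5, following common
#' plant target-scoring practice), and any other column costs 1. The plain
#' "three mismatches, no gaps" rule is recovered with `gu_weight = 1`.
#'
#' @param mirna data.frame (`id`, `mature_seq`) or a single named sequence.
#' @param transcripts data.frame (`id`, `seq`).
#' @param max_weighted_mm weighted mismatch budget (default 3).
#' @param gu_weight cost of a G:U column (default 0.5).
#' @return data.frame with `mirna_id`, `transcript_id`, `site_start`,
#'   `site_end` (1-based inclusive on the transcript), `weighted_mm`,
#'   `gu_pairs`.
#' @export
predict_targets <- function(mirna, transcripts, max_weighted_mm = 3,
                            gu_weight = 0.5) {
  if (!is.data.frame(mirna)) {
    mirna <- data.frame(id = names(mirna) %||% "mirna",
                        mature_seq = unname(mirna), stringsAsFactors = FALSE)
  }
  out <- list()
  for (q in seq_len(nrow(mirna))) {
    mseq <- .normalize_rna(mirna$mature_seq[q])
    m <- nchar(mseq)
    qch <- strsplit(mseq, "", fixed = TRUE)[[1]]
    for (t in seq_len(nrow(transcripts))) {
      tseq <- .normalize_rna(transcripts$seq[t])
      n <- nchar(tseq)
      if (n < m) next
      tch <- strsplit(tseq, "", fixed = TRUE)[[1]]
      for (s in 1:(n - m + 1)) {
        # antiparallel duplex: miRNA 5'->3' against site 3'->5'
        site <- tch[(s + m - 1):s]
        wc <- (qch == "A" & site == "U") | (qch == "U" & site == "A") |
              (qch == "G" & site == "C") | (qch == "C" & site == "G")
        gu <- (qch == "G" & site == "U") | (qch == "U" & site == "G")
        cost <- sum(!wc & !gu) + gu_weight * sum(gu)
        if (cost <= max_weighted_mm) {
          out[[length(out) + 1]] <- data.frame(
            mirna_id = mirna$id[q], transcript_id = transcripts$id[t],
            site_start = s, site_end = s + m - 1L,
            weighted_mm = cost, gu_pairs = sum(gu),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      weighted_mm = numeric(0), gu_pairs = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Microarray detection calls
#'
#' A probe is called detected when its mean signal exceeds three times the
#' background standard deviation, its spot coefficient of variation is below
#' 0.5, and the two-channel (Cy3 vs Cy5) p-value is below 0.01. Each failed
#' clause is reported. Probes with missing background are skipped with a
#' warning.
#'
#' @param spots data.frame with columns `probe_id`, `signal` (mean spot
#'   signal), `background_sd`, `cv`, `p_value`.
#' @param signal_factor background multiplier (default 3).
#' @param cv_max CV threshold (default 0.5).
#' @param p_max channel p-value threshold (default 0.01).
#' @return the input with logical columns `pass_signal`, `pass_cv`,
#'   `pass_p`, `detected`.
#' @export
microarray_detect <- function(spots, signal_factor = 3, cv_max = 0.5,
                              p_max = 0.01) {
  stopifnot(all(c("probe_id", "signal", "background_sd", "cv", "p_value")
                %in% names(spots)))
  missing_bg <- is.na(spots$background_sd)
  if (any(missing_bg)) {
    warning(sprintf("skipping %d probe(s) with missing background",
                    sum(missing_bg)))
    spots <- spots[!missing_bg, , drop = FALSE]
  }
  spots$pass_signal <- spots$signal > signal_factor * spots$background_sd
  spots$pass_cv <- spots$cv < cv_max
  spots$pass_p <- spots$p_value < p_max
  spots$detected <- spots$pass_signal & spots$pass_cv & spots$pass_p
  rownames(spots) <- NULL
  spots
}

#' Set algebra on two miRNA family sets
#'
#' Compares the families found by two detection methods (e.g. sequence
#' homology and a microarray assay), returning the shared families, those
#' unique to each method, and the union. Family labels should be normalized
#' consistently (e.g. a miR156/157 merge policy applied to both sets) before
#' comparison.
#'
#' @param set_a,set_b character vectors of family labels.
#' @return list with `both`, `a_only`, `b_only`, `union` (each a list with
#'   `n` and `families`).
#' @export
compare_family_sets <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  piece <- function(x) list(n = length(x), families = sort(x))
  list(both = piece(intersect(a, b)),
       a_only = piece(setdiff(a, b)),
       b_only = piece(setdiff(b, a)),
       union = piece(union(a, b)))
}

#' Per-stage differential expression of a tag between modes
#'
#' For each developmental stage, pools tag counts per reproductive mode and
#' tests the 2x2 table (tag count vs library remainder, sexual vs apomictic)
#' with Fisher's exact test, two-sided. The direction is the mode with the
#' higher normalized count.
#'
#' @param counts integer matrix, tags x libraries, with rownames (tag ids)
#'   and colnames (library ids).
#' @param meta data.frame describing libraries: `library`, `stage` (1-4),
#'   `mode` (`"sexual"`/`"apomictic"`).
#' @param tag tag id (rowname of `counts`).
#' @param stages stages to test (default all present).
#' @return data.frame with `tag`, `stage`, `count_sexual`, `count_apomictic`,
#'   `depth_sexual`, `depth_apomictic`, `p_value`, `direction` (`NA` when the
#'   normalized counts are equal).
#' @export
diff_expression <- function(counts, meta, tag, stages = sort(unique(meta$stage))) {
  stopifnot(tag %in% rownames(counts),
            all(c("library", "stage", "mode") %in% names(meta)))
  depth <- colSums(counts)
  if (any(depth == 0)) stop("zero library size", call. = FALSE)
  rows <- lapply(stages, function(st) {
    libs_s <- meta$library[meta$stage == st & meta$mode == "sexual"]
    libs_a <- meta$library[meta$stage == st & meta$mode == "apomictic"]
    if (length(libs_s) == 0 || length(libs_a) == 0) {
      stop("both modes must be represented at stage ", st, call. = FALSE)
    }
    cs <- sum(counts[tag, libs_s]); ca <- sum(counts[tag, libs_a])
    ds <- sum(depth[libs_s]); da <- sum(depth[libs_a])
    tab <- matrix(c(cs, ds - cs, ca, da - ca), nrow = 2)
    p <- fisher.test(tab)$p.value
    rs <- cs / ds; ra <- ca / da
    dir <- if (rs == ra) NA_character_
           else if (ra > rs) "apomictic" else "sexual"
    data.frame(tag = tag, stage = st, count_sexual = cs,
               count_apomictic = ca, depth_sexual = ds, depth_apomictic = da,
               p_value = p, direction = dir, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Comparative delta-delta-Ct relative quantification
#'
#' Implements the comparative ddCt method against a housekeeping reference
#' gene and a calibrator sample: `dCt = mean(Ct_target) - mean(Ct_reference)`
#' per sample, `ddCt = dCt_sample - dCt_calibrator`, relative expression
#' `fold = 2^-ddCt`. Replicate means and standard deviations are reported.
#' Samples lacking either gene are rejected.
#'
#' @param records long data.frame with columns `sample`, `gene` (`"target"`
#'   or `"reference"`), `ct` (one row per technical replicate; at least 2
#'   replicates per sample and gene).
#' @param calibrator name of the calibrator sample.
#' @return data.frame per sample: `sample`, `ct_target_mean`, `ct_target_sd`,
#'   `ct_reference_mean`, `ct_reference_sd`, `dct`, `ddct`, `fold`.
#' @export
ddct <- function(records, calibrator) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(records)))
  samples <- unique(records$sample)
  if (!calibrator %in% samples) stop("calibrator sample not found", call. = FALSE)
  per_sample <- lapply(samples, function(sm) {
    sub <- records[records$sample == sm, , drop = FALSE]
    tg <- sub$ct[sub$gene == "target"]
    rf <- sub$ct[sub$gene == "reference"]
    if (length(tg) < 2 || length(rf) < 2) {
      stop("sample ", sm, " lacks replicate target or reference Ct values",
           call. = FALSE)
    }
    data.frame(sample = sm, ct_target_mean = mean(tg), ct_target_sd = sd(tg),
               ct_reference_mean = mean(rf), ct_reference_sd = sd(rf),
               dct = mean(tg) - mean(rf), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_sample)
  dct_cal <- out$dct[out$sample == calibrator]
  out$ddct <- out$dct - dct_cal
  out$fold <- 2^(-out$ddct)
  rownames(out) <- NULL
  out
}
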