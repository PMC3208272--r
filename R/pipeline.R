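#' Pipeline configuration
#'
#' Assembles and validates the thresholds, paths and options driving the
#' discovery pipeline. Threshold defaults implement the hairpin acceptance
#' criteria: at most 3 mismatches to the reference mature, MFE at most -10
#' kcal/mol, A+U content within 40-70% (checked on the mature; see
#' [evaluate_candidate()]), mature length 20-24 nt, and at most 6 unpaired
#' bases within the mature span. MFEI is reported, never filtered on.
#'
#' @param refs,ests,contaminants input paths (FASTA) or data.frames; `ests`
#'   may be a named list/vector with one entry per library.
#' @param max_mm maximum mismatches in the homology alignment.
#' @param mfe_max maximum (least negative) acceptable MFE, kcal/mol.
#' @param au_range acceptable A+U percentage range.
#' @param mature_len acceptable mature length range, nt.
#' @param gap_tolerance maximum unpaired bases within the mature span.
#' @param au_criterion_on `"mature"` or `"precursor"`.
#' @param window_extents symmetric window extensions tried around a hit, nt.
#' @param contaminant_k minimum exact contaminant match length, nt.
#' @param mfei_report_only MFEI is reported, not used as a filter.
#' @param alpha significance threshold for downstream tests.
#' @param backend folding backend.
#' @param seed integer seed.
#' @param outdir optional output directory for report TSVs.
#' @return a validated `pipeline_config` list that round-trips losslessly
#'   through [write_pipeline_config()] / [read_pipeline_config()].
#' @export
default_config <- function(refs = NULL, ests = NULL, contaminants = NULL,
                           max_mm = 3, mfe_max = -10, au_range = c(40, 70),
                           mature_len = c(20, 24), gap_tolerance = 6,
                           au_criterion_on = c("mature", "precursor"),
                           window_extents = c(100, 60, 20),
                           contaminant_k = 20, mfei_report_only = TRUE,
                           alpha = 0.05, backend = "builtin", seed = 1,
                           outdir = NULL) {
  au_criterion_on <- match.arg(au_criterion_on)
  stopifnot(max_mm >= 0, max_mm <= 3, mfe_max <= 0,
            length(au_range) == 2, au_range[1] >= 0, au_range[2] <= 100,
            au_range[1] < au_range[2],
            length(mature_len) == 2, mature_len[1] >= 20, mature_len[2] <= 24,
            gap_tolerance >= 0, alpha > 0, alpha <= 1)
  cfg <- list(refs = refs, ests = ests, contaminants = contaminants,
              max_mm = as.integer(max_mm), mfe_max = mfe_max,
              au_range = au_range, mature_len = as.integer(mature_len),
              gap_tolerance = as.integer(gap_tolerance),
              au_criterion_on = au_criterion_on,
              window_extents = as.integer(window_extents),
              contaminant_k = as.integer(contaminant_k),
              mfei_report_only = isTRUE(mfei_report_only),
              alpha = alpha, backend = backend, seed = as.integer(seed),
              outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname default_config
#' @param cfg a `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

.as_records <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("missing ", what, " file: ", x, call. = FALSE)
    return(read_fasta(x))
  }
  stop("cannot interpret ", what, " input", call. = FALSE)
}

#' Run the candidate-discovery pipeline
#'
#' Chains the discovery stages: reference deduplication, contaminant
#' exclusion, gapless homology scan, redundancy collapse, and hairpin
#' evaluation, producing a per-candidate report mirroring the conserved
#' stem-loop tables (family, mature, NN, arm, A+U%, AMFE, MFEI), a
#' failure-reason audit, and a run manifest recording seed and thresholds.
#' An empty EST input yields an empty report (with a warning), not an error.
#'
#' @param config a [default_config()]; `refs` and `ests` must be set
#'   (`contaminants` optional). `refs` needs columns `id`, `family`,
#'   `mature_seq` when given as a data.frame; a FASTA path is parsed with
#'   the family taken from the id's `miR...` token.
#' @return list with `records` (all evaluated candidates), `accepted`
#'   (passing records), `hits`, `removed` (contaminant audit), `manifest`.
#'   Written as TSVs under `config$outdir` when set.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  refs <- .as_records(config$refs, "reference")
  ests <- .as_records(config$ests, "EST library")
  contam <- .as_records(config$contaminants, "contaminant")
  if (is.null(refs) || is.null(ests)) {
    stop("config must provide refs and ests", call. = FALSE)
  }
  if (is.null(refs$family)) {
    tok <- regmatches(refs$id, regexpr("miR[0-9A-Za-z]+", refs$id))
    refs$family <- ifelse(lengths(regmatches(refs$id, gregexpr("miR[0-9A-Za-z]+", refs$id))) > 0, tok, refs$id)
  }
  if (is.null(refs$species)) refs$species <- "unk"
  if (is.null(refs$mature_seq)) refs$mature_seq <- refs$seq
  if (is.null(ests$library)) ests$library <- rep("library1", nrow(ests))

  dd <- dedup_mirnas(refs)
  keep_len <- nchar(dd$kept$mature_seq) >= config$mature_len[1] &
              nchar(dd$kept$mature_seq) <= config$mature_len[2]
  queries <- dd$kept[keep_len, , drop = FALSE]

  if (!is.null(contam)) {
    fc <- filter_contaminants(ests, contam, k = config$contaminant_k)
  } else {
    fc <- list(kept = ests,
               removed = data.frame(id = character(0), reason = character(0),
                                    contaminant_id = character(0),
                                    position = integer(0)))
  }
  kept <- fc$kept

  records <- list()
  hits_all <- list()
  if (nrow(kept) > 0 && nrow(queries) > 0) {
    hits <- scan_library(queries, kept, max_mm = config$max_mm)
    cands <- collapse_redundant(hits)
    hits_all <- cands
    for (i in seq_len(nrow(cands))) {
      est <- kept[kept$id == cands$est_id[i], , drop = FALSE]
      rec <- evaluate_candidate(est, cands[i, , drop = FALSE], config)
      rec$library <- est$library[[1]]
      records[[length(records) + 1]] <- rec
    }
  } else {
    if (nrow(kept) == 0) warning("no reads to scan after filtering")
    hits_all <- data.frame()
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(family = character(0), mature_seq = character(0),
               est_id = character(0), nn = integer(0), arm = character(0),
               au_percent = numeric(0), mfe = numeric(0), amfe = numeric(0),
               mfei = numeric(0), accepted = logical(0),
               failure_reasons = character(0), library = character(0),
               stringsAsFactors = FALSE)
  manifest <- list(
    n_refs_in = nrow(refs), n_refs_unique = nrow(dd$kept),
    n_queries = nrow(queries), n_reads = nrow(ests),
    n_removed_contaminant = nrow(fc$removed), n_candidates =
      if (is.data.frame(hits_all)) nrow(hits_all) else 0,
    n_accepted = sum(records$accepted),
    thresholds = list(max_mm = config$max_mm, mfe_max = config$mfe_max,
                      au_range = config$au_range,
                      mature_len = config$mature_len,
                      gap_tolerance = config$gap_tolerance,
                      au_criterion_on = config$au_criterion_on,
                      window_extents = config$window_extents,
                      contaminant_k = config$contaminant_k,
                      mfei_report_only = config$mfei_report_only,
                      alpha = config$alpha),
    backend = config$backend, seed = config$seed)

  out <- list(records = records, accepted = records[records$accepted, ,
                                                    drop = FALSE],
              hits = hits_all, removed = fc$removed, manifest = manifest)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    .write_report <- function(df, name) {
      write.table(df, file.path(config$outdir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    for (l in unique(records$library)) {
      .write_report(.format_precursor_report(records[records$library == l &
                                                       records$accepted, ,
                                                     drop = FALSE]),
                    paste0("candidates_", l, ".tsv"))
    }
    .write_report(records[!records$accepted,
                          c("family", "est_id", "failure_reasons")],
                  "failure_audit.tsv")
    .write_report(fc$removed, "contaminant_audit.tsv")
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

# table-style rounding: A+U% and AMFE to 2 decimals, MFEI to 3
.format_precursor_report <- function(records) {
  if (nrow(records) == 0) return(records)
  records$au_percent <- round(records$au_percent, 2)
  records$amfe <- round(records$amfe, 2)
  records$mfei <- round(records$mfei, 3)
  records[, c("family", "mature_seq", "est_id", "nn", "arm", "au_percent",
              "amfe", "mfei", "mfe", "accepted")]
}

#' Run discovery plus the substitution-stability and expression analyses
#'
#' Executes [run_discovery()], then, for every accepted candidate whose
#' mature differs from its reference query, runs the natural-vs-corrected
#' hairpin experiment ([correction_experiment()]) on the candidate's
#' precursor window and pools the differences per library into the one-sided
#' signed-rank stabilization test. When tag counts and/or qPCR records are
#' supplied, per-stage differential expression and ddCt quantification are
#' appended.
#'
#' @param config a [default_config()].
#' @param tag_counts optional list as from [gen_tag_counts()] (`counts`,
#'   `meta`); all tags are tested at every stage.
#' @param qpcr optional list as from [gen_qpcr()] (`records`), calibrated on
#'   sample `"cal"`.
#' @return list with `discovery`, `ns` (per-candidate correction results and
#'   per-mode + pooled test summaries), `expression` (optional), `summary`.
#' @export
run_full <- function(config, tag_counts = NULL, qpcr = NULL) {
  disc <- run_discovery(config)
  refs <- .as_records(config$refs, "reference")
  if (is.null(refs$mature_seq)) refs$mature_seq <- refs$seq

  ns_results <- list()
  acc <- disc$accepted
  for (i in seq_len(nrow(acc))) {
    fam <- strsplit(acc$family[i], ",", fixed = TRUE)[[1]][1]
    hit_hits <- disc$hits[disc$hits$est_id == acc$est_id[i], , drop = FALSE]
    if (nrow(hit_hits) == 0) next
    ref_row <- refs[refs$id == hit_hits$query_id[1], , drop = FALSE]
    if (nrow(ref_row) == 0) next
    subs <- tryCatch(detect_ns(acc$mature_seq[i], ref_row$mature_seq[1]),
                     error = function(e) NULL)
    if (is.null(subs) || nrow(subs) == 0) next
    # precursor window in mature-sense orientation, as evaluated
    est <- .as_records(config$ests, "EST library")
    eseq <- est$seq[est$id == acc$est_id[i]][1]
    wseq <- substr(eseq, acc$window_start[i], acc$window_end[i])
    span <- c(hit_hits$est_start[1] - acc$window_start[i] + 1L,
              hit_hits$est_end[1] - acc$window_start[i] + 1L)
    if (identical(acc$strand[i], "-")) {
      wlen <- nchar(wseq)
      wseq <- revcomp(wseq)
      span <- c(wlen - span[2] + 1L, wlen - span[1] + 1L)
    }
    res <- correction_experiment(wseq, span, subs,
                                 precursor_id = paste0(fam, "|", acc$est_id[i]),
                                 backend = config$backend)
    res$library <- acc$library[i]
    res$n_subs <- nrow(subs)
    ns_results[[length(ns_results) + 1]] <- res
  }
  ns_df <- if (length(ns_results)) do.call(rbind, ns_results) else NULL
  ns_tests <- list()
  if (!is.null(ns_df) && nrow(ns_df) >= 2) {
    ns_tests$pooled <- paired_stability_test(ns_df$delta)
    for (l in unique(ns_df$library)) {
      sub <- ns_df$delta[ns_df$library == l]
      if (length(sub[sub != 0]) >= 2) {
        ns_tests[[l]] <- paired_stability_test(sub)
      }
    }
  }

  expr <- NULL
  if (!is.null(tag_counts)) {
    rows <- lapply(rownames(tag_counts$counts), function(tg)
      diff_expression(tag_counts$counts, tag_counts$meta, tg))
    de <- do.call(rbind, rows)
    de$significant <- de$p_value <= config$alpha
    expr <- list(tags = de)
  }
  if (!is.null(qpcr)) {
    rel <- ddct(qpcr$records, calibrator = "cal")
    expr <- c(expr %||% list(), list(qpcr = rel))
  }

  summary <- list(
    n_accepted = nrow(acc),
    families_accepted = sort(unique(unlist(strsplit(acc$family, ",")))),
    n_ns_pairs = if (is.null(ns_df)) 0L else nrow(ns_df),
    stability_p = if (!is.null(ns_tests$pooled)) ns_tests$pooled$p_value else NA_real_,
    n_de_significant = if (!is.null(expr$tags)) sum(expr$tags$significant) else NA_integer_)

  out <- list(discovery = disc, ns = list(results = ns_df, tests = ns_tests),
              expression = expr, summary = summary)
  if (!is.null(config$outdir)) {
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
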