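#' Configuration for the synthetic 454-style library generator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the flower EST libraries the pipeline is designed for:
#' read lengths between 51 and 478 nt with about 80% near 200 nt, planted
#' hairpin precursors of 66-233 nt carrying 20-24 nt mature miRNAs, a
#' background base composition with a mild A+U bias (0.55, matching the
#' 42-63% A+U range of plant precursors), and 454-like homopolymer
#' insertion/deletion noise.
#'
#' @param n_reads total reads across the two libraries.
#' @param n_planted reads carrying a planted hairpin precursor.
#' @param mature_len_range mature miRNA length range, nt.
#' @param precursor_len_range planted precursor length range, nt.
#' @param arm_mismatches non-complementary positions per planted arm (0-3).
#' @param loop_len terminal loop length of planted hairpins, nt.
#' @param contaminant_fraction fraction of reads copied verbatim from
#'   tRNA/rRNA-like contaminant records.
#' @param truncation_fraction fraction of reads carrying only one precursor
#'   arm (truncated precursors: homology hits that cannot fold).
#' @param homopolymer_indel_rate per-base insertion/deletion probability
#'   within homopolymer runs of length >= 2.
#' @param au_bias background A+U fraction.
#' @param seed integer seed fixing all randomness end-to-end.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_reads = 500, n_planted = 25,
                       mature_len_range = c(20, 24),
                       precursor_len_range = c(66, 233),
                       arm_mismatches = 0, loop_len = 8,
                       contaminant_fraction = 0.05,
                       truncation_fraction = 0.05,
                       homopolymer_indel_rate = 0.001,
                       au_bias = 0.55, seed = 1) {
  cfg <- list(n_reads = as.integer(n_reads), n_planted = as.integer(n_planted),
              mature_len_range = as.integer(mature_len_range),
              precursor_len_range = as.integer(precursor_len_range),
              arm_mismatches = as.integer(arm_mismatches),
              loop_len = as.integer(loop_len),
              contaminant_fraction = contaminant_fraction,
              truncation_fraction = truncation_fraction,
              homopolymer_indel_rate = homopolymer_indel_rate,
              au_bias = au_bias, seed = as.integer(seed))
  fr <- c(cfg$contaminant_fraction, cfg$truncation_fraction,
          cfg$homopolymer_indel_rate, cfg$au_bias)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$n_planted > cfg$n_reads) stop("n_planted exceeds n_reads")
  if (cfg$loop_len < 3) stop("loop_len must be >= 3")
  if (cfg$arm_mismatches < 0 || cfg$arm_mismatches > 3) {
    stop("arm_mismatches must be 0-3")
  }
  stopifnot(diff(cfg$mature_len_range) >= 0, diff(cfg$precursor_len_range) >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param path YAML file path.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

# random RNA of length n with A+U bias
.rand_seq <- function(n, au_bias = 0.55) {
  p <- c(A = au_bias / 2, C = (1 - au_bias) / 2,
         G = (1 - au_bias) / 2, U = au_bias / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random mature with A+U content inside [40, 70]%
.rand_mature <- function(len_range, au_bias = 0.55) {
  for (i in 1:100) {
    m <- .rand_seq(sample(len_range[1]:len_range[2], 1), au_bias)
    au <- .au_percent(m)
    if (au >= 40 && au <= 70) return(m)
  }
  m
}

# a base that cannot pair (neither Watson-Crick nor G:U) with `nt`
.nonpairing_base <- function(nt) {
  choices <- switch(nt, A = c("A", "C", "G"), C = c("A", "C", "U"),
                    G = c("A", "G"), U = c("C", "U"))
  sample(choices, 1)
}

#' Construct a hairpin precursor around a mature miRNA
#'
#' Builds a synthetic pre-miRNA: a lower stem (random flank paired with its
#' reverse complement), the mature miRNA on the requested arm, a terminal
#' loop, and the mature's reverse complement (the star arm) with exactly
#' `n_arm_mismatches` non-pairing positions. The mature span within the
#' returned precursor is exact; folding the construct at zero mismatches
#' yields a clean stem-loop with the mature fully paired on the chosen arm.
#'
#' @param mature mature miRNA sequence, 20-24 nt, strict ACGU.
#' @param arm `"5p"` (mature before the terminal loop) or `"3p"` (after).
#' @param loop_len terminal loop length, `>= 3`.
#' @param n_arm_mismatches star-arm positions made non-complementary (0-3).
#' @param target_len desired precursor length (achieved via the lower stem
#'   and loop); `NULL` for no lower stem.
#' @param au_bias base composition of random segments.
#' @param seed optional seed for reproducibility of this call.
#' @return list with `seq`, `mature_start`, `mature_end` (1-based inclusive),
#'   `arm`.
#' @export
make_hairpin_precursor <- function(mature, arm = c("5p", "3p"), loop_len = 8,
                                   n_arm_mismatches = 0, target_len = NULL,
                                   au_bias = 0.55, seed = NULL) {
  arm <- match.arg(arm)
  if (!is.null(seed)) set.seed(seed)
  mature <- .normalize_rna(mature)
  .check_rna(mature, allow_n = FALSE, what = "mature")
  m <- nchar(mature)
  if (m < 20 || m > 24) stop("mature length must be 20-24 nt", call. = FALSE)
  if (loop_len < 3) stop("loop_len must be >= 3", call. = FALSE)
  if (n_arm_mismatches > 3) stop("at most 3 arm mismatches", call. = FALSE)

  star <- revcomp(mature)
  if (n_arm_mismatches > 0) {
    mpos <- sample(m, n_arm_mismatches)
    sch <- strsplit(star, "", fixed = TRUE)[[1]]
    mch <- strsplit(mature, "", fixed = TRUE)[[1]]
    for (p in mpos) {
      sch[m - p + 1] <- .nonpairing_base(mch[p])
    }
    star <- paste(sch, collapse = "")
  }
  flank_len <- 0L
  if (!is.null(target_len)) {
    extra <- target_len - 2L * m - loop_len
    if (extra < 0) stop("target_len too short for mature and loop", call. = FALSE)
    flank_len <- extra %/% 2L
    loop_len <- loop_len + extra %% 2L
  }
  lower <- if (flank_len > 0) .rand_seq(flank_len, au_bias) else ""
  loop <- .rand_seq(loop_len, au_bias)
  if (arm == "5p") {
    seq <- paste0(lower, mature, loop, star, revcomp(lower))
    start <- flank_len + 1L
  } else {
    seq <- paste0(lower, star, loop, mature, revcomp(lower))
    start <- flank_len + m + loop_len + 1L
  }
  list(seq = seq, mature_start = start, mature_end = start + m - 1L, arm = arm)
}

#' Generate a multi-species mature miRNA reference set
#'
#' Emits species-annotated mature miRNAs in which a `duplicate_rate` fraction
#' of the non-canonical entries are exact sequence copies attributed to a
#' different species (the redundancy that reference-set deduplication must
#' remove). The truth records the unique-sequence count.
#'
#' @param n_species,n_families counts (`>= 1`).
#' @param duplicate_rate fraction of cross-species entries that are exact
#'   copies of the family's canonical sequence.
#' @param seed integer seed.
#' @param mature_len_range mature length range.
#' @param au_bias base composition.
#' @return list with `refs` (data.frame `id`, `species`, `family`,
#'   `mature_seq`) and `n_unique` (truth).
#' @export
gen_reference_set <- function(n_species, n_families, duplicate_rate = 0,
                              seed = 1, mature_len_range = c(20, 24),
                              au_bias = 0.55) {
  stopifnot(n_species >= 1, n_families >= 1,
            duplicate_rate >= 0, duplicate_rate <= 1)
  set.seed(seed)
  species <- sprintf("sp%02d", seq_len(n_species))
  families <- sprintf("miR%d", 900 + seq_len(n_families))
  seen <- character(0)
  rows <- list()
  for (f in seq_len(n_families)) {
    canonical <- .rand_mature(mature_len_range, au_bias)
    while (canonical %in% seen) canonical <- .rand_mature(mature_len_range, au_bias)
    seen <- c(seen, canonical)
    for (s in seq_len(n_species)) {
      seq_fs <- if (s == 1) {
        canonical
      } else if (runif(1) < duplicate_rate) {
        canonical
      } else {
        v <- .mutate_mature(canonical)
        while (v %in% seen) v <- .mutate_mature(canonical)
        seen <- c(seen, v)
        v
      }
      rows[[length(rows) + 1]] <- data.frame(
        id = paste0(species[s], "-", families[f]), species = species[s],
        family = families[f], mature_seq = seq_fs, stringsAsFactors = FALSE)
    }
  }
  refs <- do.call(rbind, rows)
  list(refs = refs, n_unique = length(unique(refs$mature_seq)))
}

# 1-2 random substitutions
.mutate_mature <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- sample(1:2, 1)
  for (p in sample(length(ch), k)) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# 454-like homopolymer noise: insert/delete within runs >= 2 nt
.homopolymer_noise <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, events = integer(0)))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  events <- integer(0)  # positions (original coords); +pos = insertion, -pos = deletion
  for (i in seq_along(r$lengths)) {
    if (r$lengths[i] < 2) next
    for (p in starts[i]:ends[i]) {
      if (runif(1) < rate) {
        events <- c(events, if (runif(1) < 0.5) p else -p)
      }
    }
  }
  if (length(events) == 0) return(list(seq = seq, events = events))
  out <- character(0)
  del <- abs(events[events < 0]); ins <- events[events > 0]
  for (p in seq_along(ch)) {
    if (!(p %in% del)) out <- c(out, ch[p])
    if (p %in% ins) out <- c(out, ch[p])
  }
  list(seq = paste(out, collapse = ""), events = events)
}

#' Generate synthetic sexual/apomictic EST libraries with ground truth
#'
#' Builds two 454-style flower EST libraries (one per reproductive mode) of
#' random-background reads in which hairpin precursors, truncated (one-arm)
#' precursors and verbatim tRNA/rRNA contaminant copies are planted at known
#' positions. The returned truth bookkeeping drives recovery tests: every
#' planted id exists in the emitted reads, spans lie within read bounds, and
#' at zero noise each planted precursor extracted by its span folds into a
#' hairpin passing the acceptance criteria.
#'
#' @param config a [sim_config()].
#' @param refs optional reference set (data.frame `id`, `species`, `family`,
#'   `mature_seq`); planted matures are drawn from it so that an end-to-end
#'   homology search can recover them. When `NULL`, de-novo matures are
#'   generated and returned as a matching reference set.
#' @param contaminant_db optional contaminant records (`id`, `seq`); a small
#'   tRNA/rRNA-like database is generated when absent.
#' @param outdir optional directory to write `sexual.fasta`,
#'   `apomictic.fasta`, `contaminants.fasta` and `truth_planted.tsv`.
#' @return list with `reads` (data.frame `id`, `seq`, `library`), `truth`
#'   (list: `planted` data.frame with spans and arms, `contaminant_ids`,
#'   `truncated` data.frame), `refs`, `contaminant_db`.
#' @export
gen_est_library <- function(config = sim_config(), refs = NULL,
                            contaminant_db = NULL, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reads
  n_contam <- round(config$contaminant_fraction * n)
  n_trunc <- round(config$truncation_fraction * n)
  if (config$n_planted + n_contam + n_trunc > n) {
    stop("planted + contaminant + truncated reads exceed n_reads", call. = FALSE)
  }
  if (is.null(contaminant_db) && n_contam > 0) {
    contaminant_db <- data.frame(
      id = sprintf("contam%02d", 1:5),
      seq = vapply(1:5, function(i) .rand_seq(sample(300:800, 1), 0.5),
                   character(1)),
      stringsAsFactors = FALSE)
  }
  if (is.null(refs)) {
    need <- config$n_planted + n_trunc
    fam_seqs <- vapply(seq_len(max(need, 1)), function(i)
      .rand_mature(config$mature_len_range, config$au_bias), character(1))
    refs <- data.frame(id = sprintf("sim-miR%03d", seq_along(fam_seqs)),
                       species = "sim", family = sprintf("miR%03d", seq_along(fam_seqs)),
                       mature_seq = fam_seqs, stringsAsFactors = FALSE)
  }

  roles <- rep("background", n)
  idx <- sample(n)
  roles[idx[seq_len(config$n_planted)]] <- "planted"
  if (n_trunc > 0) roles[idx[config$n_planted + seq_len(n_trunc)]] <- "truncated"
  if (n_contam > 0) {
    roles[idx[config$n_planted + n_trunc + seq_len(n_contam)]] <- "contaminant"
  }
  lib <- rep(c("sexual", "apomictic"), length.out = n)
  ids <- sprintf("read%04d", seq_len(n))

  ref_pick <- function() refs[sample(nrow(refs), 1), , drop = FALSE]
  planted_rows <- list(); trunc_rows <- list(); contam_ids <- character(0)
  seqs <- character(n)

  sample_len <- function(min_len = 51) {
    for (i in 1:100) {
      len <- if (runif(1) < 0.8) round(rnorm(1, 200, 30)) else sample(51:478, 1)
      len <- max(51, min(478, len))
      if (len >= min_len) return(as.integer(len))
    }
    as.integer(min_len)
  }

  for (i in seq_len(n)) {
    role <- roles[i]
    if (role == "planted") {
      ref <- ref_pick()
      m <- nchar(ref$mature_seq)
      min_prec <- max(config$precursor_len_range[1], 2 * m + config$loop_len)
      rlen <- sample_len(min_len = min_prec + 10)
      prec_len <- sample(min_prec:min(config$precursor_len_range[2], rlen - 4), 1)
      hp <- make_hairpin_precursor(ref$mature_seq, sample(c("5p", "3p"), 1),
                                   config$loop_len, config$arm_mismatches,
                                   target_len = prec_len,
                                   au_bias = config$au_bias)
      nn <- nchar(hp$seq)
      offset <- sample(0:(rlen - nn), 1)
      left <- if (offset > 0) .rand_seq(offset, config$au_bias) else ""
      right_len <- rlen - nn - offset
      right <- if (right_len > 0) .rand_seq(right_len, config$au_bias) else ""
      seqs[i] <- paste0(left, hp$seq, right)
      planted_rows[[length(planted_rows) + 1]] <- data.frame(
        read_id = ids[i], library = lib[i], family = ref$family,
        mature_seq = ref$mature_seq,
        precursor_start = offset + 1L, precursor_end = offset + nn,
        mature_start = offset + hp$mature_start,
        mature_end = offset + hp$mature_end,
        arm = hp$arm, span_intact = TRUE, stringsAsFactors = FALSE)
    } else if (role == "truncated") {
      # one-arm fragments are short reads: the arm plus a little context
      ref <- ref_pick()
      m <- nchar(ref$mature_seq)
      rlen <- sample(max(51, m + 20):100, 1)
      stem <- paste0(.rand_seq(10, config$au_bias), ref$mature_seq)
      offset <- sample(0:(rlen - nchar(stem)), 1)
      left <- if (offset > 0) .rand_seq(offset, config$au_bias) else ""
      right_len <- rlen - nchar(stem) - offset
      right <- if (right_len > 0) .rand_seq(right_len, config$au_bias) else ""
      seqs[i] <- paste0(left, stem, right)
      trunc_rows[[length(trunc_rows) + 1]] <- data.frame(
        read_id = ids[i], library = lib[i], family = ref$family,
        mature_seq = ref$mature_seq, stringsAsFactors = FALSE)
    } else if (role == "contaminant") {
      rec <- contaminant_db[sample(nrow(contaminant_db), 1), , drop = FALSE]
      clen <- nchar(rec$seq)
      rlen <- min(sample_len(), clen)
      s0 <- sample(0:(clen - rlen), 1)
      seqs[i] <- substr(rec$seq, s0 + 1, s0 + rlen)
      contam_ids <- c(contam_ids, ids[i])
    } else {
      seqs[i] <- .rand_seq(sample_len(), config$au_bias)
    }
  }

  # homopolymer indel noise after planting; spans shifted or flagged
  if (config$homopolymer_indel_rate > 0) {
    planted_df <- if (length(planted_rows)) do.call(rbind, planted_rows) else NULL
    for (i in seq_len(n)) {
      noised <- .homopolymer_noise(seqs[i], config$homopolymer_indel_rate)
      if (length(noised$events) == 0) next
      seqs[i] <- noised$seq
      if (!is.null(planted_df)) {
        j <- which(planted_df$read_id == ids[i])
        if (length(j) == 1) {
          ev_pos <- abs(noised$events)
          shift <- function(p) sum(sign(noised$events)[ev_pos < p])
          inside <- ev_pos >= planted_df$precursor_start[j] &
                    ev_pos <= planted_df$precursor_end[j]
          if (any(inside)) {
            planted_df$span_intact[j] <- FALSE
          }
          planted_df$precursor_start[j] <- planted_df$precursor_start[j] +
            shift(planted_df$precursor_start[j])
          planted_df$precursor_end[j] <- planted_df$precursor_end[j] +
            shift(planted_df$precursor_end[j]) +
            sum(inside & noised$events > 0) - sum(inside & noised$events < 0)
          planted_df$mature_start[j] <- planted_df$mature_start[j] +
            shift(planted_df$mature_start[j])
          planted_df$mature_end[j] <- planted_df$mature_end[j] +
            shift(planted_df$mature_end[j])
        }
      }
    }
    planted <- planted_df
  } else {
    planted <- if (length(planted_rows)) do.call(rbind, planted_rows) else NULL
  }
  if (is.null(planted)) {
    planted <- data.frame(read_id = character(0), library = character(0),
                          family = character(0), mature_seq = character(0),
                          precursor_start = integer(0), precursor_end = integer(0),
                          mature_start = integer(0), mature_end = integer(0),
                          arm = character(0), span_intact = logical(0),
                          stringsAsFactors = FALSE)
  }
  truncated <- if (length(trunc_rows)) do.call(rbind, trunc_rows) else
    data.frame(read_id = character(0), library = character(0),
               family = character(0), mature_seq = character(0),
               stringsAsFactors = FALSE)
  reads <- data.frame(id = ids, seq = seqs, library = lib,
                      stringsAsFactors = FALSE)
  out <- list(reads = reads,
              truth = list(planted = planted, contaminant_ids = contam_ids,
                           truncated = truncated),
              refs = refs, contaminant_db = contaminant_db)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (l in c("sexual", "apomictic")) {
      write_fasta(reads[reads$library == l, ], file.path(outdir, paste0(l, ".fasta")))
    }
    if (!is.null(contaminant_db)) {
      write_fasta(contaminant_db, file.path(outdir, "contaminants.fasta"))
    }
    write_fasta(data.frame(id = refs$id, seq = refs$mature_seq),
                file.path(outdir, "reference.fasta"))
    write.table(planted, file.path(outdir, "truth_planted.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate a tag-count table across ovule stages and modes
#'
#' Counts are drawn per library from a multinomial over per-tag abundance
#' weights (exponentially distributed), with one library per (stage, mode)
#' combination. A planted tag has its weight multiplied by the stated fold
#' change in its (stage, mode) library only.
#'
#' @param n_tags number of tags.
#' @param n_stages developmental stages (default 4).
#' @param planted list of lists with elements `tag` (index), `stage`,
#'   `mode`, `fold` (`> 0`).
#' @param depth sequencing depth per library (`> 0`).
#' @param seed integer seed.
#' @return list with `counts` (matrix tags x libraries), `meta` (library
#'   data.frame), `truth` (planted data.frame).
#' @export
gen_tag_counts <- function(n_tags, n_stages = 4, planted = list(),
                           depth = 1e5, seed = 1) {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  set.seed(seed)
  modes <- c("sexual", "apomictic")
  meta <- expand.grid(stage = seq_len(n_stages), mode = modes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$library <- sprintf("%s_st%d", substr(meta$mode, 1, 3), meta$stage)
  w <- rgamma(n_tags, shape = 1, rate = 1) + 1e-6
  tags <- sprintf("tag%05d", seq_len(n_tags))
  counts <- matrix(0L, n_tags, nrow(meta), dimnames = list(tags, meta$library))
  truth_rows <- list()
  for (p in planted) {
    stopifnot(p$stage %in% seq_len(n_stages), p$mode %in% modes, p$fold > 0)
    truth_rows[[length(truth_rows) + 1]] <- data.frame(
      tag = tags[p$tag], stage = p$stage, mode = p$mode,
      direction = if (p$fold > 1) "up" else "down", fold = p$fold,
      stringsAsFactors = FALSE)
  }
  for (l in seq_len(nrow(meta))) {
    wl <- w
    for (p in planted) {
      if (p$stage == meta$stage[l] && p$mode == meta$mode[l]) {
        wl[p$tag] <- wl[p$tag] * p$fold
      }
    }
    counts[, l] <- rmultinom(1, size = depth, prob = wl)[, 1]
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(tag = character(0), stage = integer(0), mode = character(0),
               direction = character(0), fold = numeric(0),
               stringsAsFactors = FALSE)
  list(counts = counts, meta = meta[, c("library", "stage", "mode")],
       truth = truth)
}

#' Generate qPCR Ct triplicates with a planted expression effect
#'
#' Emits target and housekeeping-reference (ubiquitin-like) Ct replicates for
#' a calibrator sample and `n_samples` treated samples. The treated samples'
#' target Ct is lowered by `effect_log2` cycles relative to the calibrator,
#' so the planted log2 fold change equals `-ddCt` in expectation and the
#' recovered relative expression is `2^effect_log2`. Gaussian noise of
#' `noise_sd` cycles is added independently to every Ct value.
#'
#' @param n_samples treated samples (a calibrator `"cal"` is added).
#' @param effect_log2 planted log2 fold change.
#' @param replicates technical replicates per Ct (`>= 2`).
#' @param noise_sd Ct noise standard deviation (`>= 0`).
#' @param seed integer seed.
#' @return list with `records` (long data.frame `sample`, `gene`,
#'   `replicate`, `ct`) and `truth` (`expected_fold`).
#' @export
gen_qpcr <- function(n_samples, effect_log2 = 0, replicates = 3,
                     noise_sd = 0.2, seed = 1) {
  if (replicates < 2) stop("replicates must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  samples <- c("cal", sprintf("s%02d", seq_len(n_samples)))
  base_ref <- 20; base_dct <- 3
  rows <- list()
  for (sm in samples) {
    eff <- if (sm == "cal") 0 else effect_log2
    for (g in c("reference", "target")) {
      mu <- if (g == "reference") base_ref else base_ref + base_dct - eff
      rows[[length(rows) + 1]] <- data.frame(
        sample = sm, gene = g, replicate = seq_len(replicates),
        ct = mu + rnorm(replicates, 0, noise_sd), stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, rows),
       truth = list(expected_fold = 2^effect_log2))
}
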