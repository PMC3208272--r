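#' Gapless scan of a mature miRNA against a read
#'
#' Exhaustively scans a subject sequence (both strands) for full-length,
#' gap-free alignments of a mature miRNA query with Hamming distance at most
#' `max_mm`. This replaces a heuristic word-seeded search: because every
#' window is examined, any hit a word-size-7 seeded search could produce is
#' guaranteed to be found. `N` matches nothing (always counts as a
#' mismatch). Coordinates are reported on the forward strand of the subject,
#' 1-based inclusive; mismatch positions are 1-based along the query.
#'
#' @param query mature miRNA sequence, 20-24 nt.
#' @param subject read sequence.
#' @param max_mm maximum mismatches (default 3; must be `<= 3`).
#' @return data.frame with columns `est_start`, `est_end`, `strand`,
#'   `aln_len`, `mismatches`, `mismatch_positions` (comma-separated, 1-based
#'   on the query), `aligned_est_subseq`.
#' @export
gapless_scan <- function(query, subject, max_mm = 3) {
  query <- .normalize_rna(query)
  subject <- .normalize_rna(subject)
  m <- nchar(query)
  if (m < 20 || m > 24) {
    stop("query length must be 20-24 nt, got ", m, call. = FALSE)
  }
  stopifnot(max_mm <= 3, max_mm >= 0)
  res <- gapless_scan_cpp(query, subject, as.integer(max_mm))
  k <- length(res$est_start)
  data.frame(
    est_start = res$est_start + 1L,
    est_end = res$est_start + m,
    strand = as.character(res$strand),
    aln_len = rep(m, k),
    mismatches = res$mismatches,
    mismatch_positions = as.character(res$mismatch_positions),
    aligned_est_subseq = as.character(res$aligned_est_subseq),
    stringsAsFactors = FALSE
  )
}

#' Scan an EST library with a non-redundant miRNA reference set
#'
#' Applies [gapless_scan()] to every (query, read) pair and retains, for each
#' (family, read) combination, only the best hit: fewest mismatches, then
#' longest alignment, then leftmost start, then strand `+`. Output order is
#' deterministic (family, est id, start).
#'
#' @param refs data.frame of reference miRNAs (`id`, `family`, `mature_seq`;
#'   optionally `species`).
#' @param ests data.frame of reads (`id`, `seq`).
#' @param max_mm maximum mismatches per alignment (default 3).
#' @return data.frame of retained hits with columns `query_id`, `family`,
#'   `est_id` plus the [gapless_scan()] columns.
#' @export
scan_library <- function(refs, ests, max_mm = 3) {
  empty <- data.frame(query_id = character(0), family = character(0),
                      est_id = character(0), est_start = integer(0),
                      est_end = integer(0), strand = character(0),
                      aln_len = integer(0), mismatches = integer(0),
                      mismatch_positions = character(0),
                      aligned_est_subseq = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(refs) || nrow(refs) == 0) {
    warning("empty reference set; no hits")
    return(empty)
  }
  out <- vector("list", nrow(refs) * nrow(ests))
  idx <- 0
  for (q in seq_len(nrow(refs))) {
    for (e in seq_len(nrow(ests))) {
      hits <- gapless_scan(refs$mature_seq[q], ests$seq[e], max_mm)
      if (nrow(hits) == 0) next
      idx <- idx + 1
      hits$query_id <- refs$id[q]
      hits$family <- refs$family[q]
      hits$est_id <- ests$id[e]
      out[[idx]] <- hits
    }
  }
  if (idx == 0) return(empty)
  all_hits <- do.call(rbind, out[seq_len(idx)])
  # best hit per (family, est): fewest mm, longest, leftmost, strand +
  ord <- order(all_hits$family, all_hits$est_id, all_hits$mismatches,
               -all_hits$aln_len, all_hits$est_start,
               all_hits$strand, method = "radix")
  all_hits <- all_hits[ord, , drop = FALSE]
  keep <- !duplicated(paste(all_hits$family, all_hits$est_id, sep = "\r"))
  res <- all_hits[keep, c("query_id", "family", "est_id", "est_start",
                          "est_end", "strand", "aln_len", "mismatches",
                          "mismatch_positions", "aligned_est_subseq")]
  rownames(res) <- NULL
  res
}

#' Collapse hits sharing the same read window into unique candidates
#'
#' Candidates with identical `(est_id, est_start, est_end, strand)` are
#' merged into one record carrying the union of matching families (the
#' situation where two closely related families, e.g. miR156 and miR157,
#' match the same window of one read). Merging is idempotent.
#'
#' @param hits data.frame as returned by [scan_library()].
#' @return data.frame of unique candidates; `families` is a comma-separated,
#'   sorted union of family labels, `query_id` the id of the best hit kept
#'   (fewest mismatches, ties by family order).
#' @export
collapse_redundant <- function(hits) {
  if (nrow(hits) == 0) {
    out <- hits
    out$families <- character(0)
    return(out)
  }
  if (is.null(hits$families)) hits$families <- hits$family
  key <- paste(hits$est_id, hits$est_start, hits$est_end, hits$strand,
               sep = "\r")
  parts <- split(seq_len(nrow(hits)), key)
  rows <- lapply(parts, function(ix) {
    sub <- hits[ix, , drop = FALSE]
    fams <- sort(unique(unlist(strsplit(sub$families, ","))))
    best <- order(sub$mismatches, sub$family, method = "radix")[1]
    rec <- sub[best, , drop = FALSE]
    rec$families <- paste(fams, collapse = ",")
    rec
  })
  out <- do.call(rbind, rows)
  ord <- order(out$est_id, out$est_start, out$strand, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
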