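#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Reads a FASTA file via Biostrings and normalizes sequences to the internal
#' RNA alphabet: case folded to upper, `T` mapped to `U`. Record ids (the
#' first whitespace-delimited token of each header) and input order are
#' preserved. Duplicate ids are disambiguated with a numeric suffix
#' (`_2`, `_3`, ...) and a warning; records with empty sequences are dropped
#' with a warning.
#'
#' @param path FASTA file path.
#' @return a data.frame with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- .normalize_rna(as.character(set))
  empty <- nchar(seqs) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d empty record(s): %s", sum(empty),
                    paste(head(ids[empty], 3), collapse = ", ")))
    ids <- ids[!empty]
    seqs <- seqs[!empty]
  }
  if (anyDuplicated(ids)) {
    warning("duplicate ids in FASTA; suffixing duplicates")
    occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    ids[occ > 1] <- paste0(ids[occ > 1], "_", occ[occ > 1])
  }
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param records data.frame with columns `id` and `seq`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Remove duplicated mature miRNAs shared between species
#'
#' Collapses a multi-species mature-miRNA reference set to one record per
#' distinct mature sequence, emulating the removal of duplicated miRNAs
#' shared between species in homology-search reference sets. The record kept
#' for each sequence is the first after a deterministic sort by
#' `(species, id)`, so the result does not depend on input order.
#'
#' @param refs data.frame with columns `id`, `species`, `family`,
#'   `mature_seq`.
#' @return a list with `kept` (non-redundant data.frame, sorted by
#'   `(species, id)`) and `map` (data.frame mapping `removed_id` to
#'   `kept_id`).
#' @export
dedup_mirnas <- function(refs) {
  stopifnot(all(c("id", "species", "mature_seq") %in% names(refs)))
  ord <- order(refs$species, refs$id, method = "radix")
  refs <- refs[ord, , drop = FALSE]
  keep <- !duplicated(refs$mature_seq)
  kept <- refs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  removed <- refs[!keep, , drop = FALSE]
  kept_for <- setNames(kept$id, kept$mature_seq)
  map <- data.frame(removed_id = removed$id,
                    kept_id = unname(kept_for[removed$mature_seq]),
                    stringsAsFactors = FALSE)
  list(kept = kept, map = map)
}

# all k-mers of a character vector of sequences (forward strand only)
.kmers <- function(seqs, k) {
  out <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  })
  out
}

#' Exclude reads matching tRNA/rRNA contaminant records
#'
#' Removes every read that shares an exact substring of at least `k`
#' nucleotides (on either strand) with any record of a contaminant database,
#' emulating the exclusion of ESTs with exact matches to tRNA or rRNA
#' sequences before homology search.
#'
#' @param ests data.frame of reads (`id`, `seq`).
#' @param contaminant_db data.frame of contaminant records (`id`, `seq`).
#' @param k minimum exact shared substring length (default 20).
#' @return a list with `kept` (data.frame), and `removed` (data.frame with
#'   `id`, `reason`, `contaminant_id`, `position` of the first shared k-mer,
#'   1-based).
#' @export
filter_contaminants <- function(ests, contaminant_db, k = 20) {
  empty_removed <- data.frame(id = character(0), reason = character(0),
                              contaminant_id = character(0),
                              position = integer(0), stringsAsFactors = FALSE)
  if (is.null(contaminant_db) || nrow(contaminant_db) == 0) {
    warning("empty contaminant database; no reads removed")
    return(list(kept = ests, removed = empty_removed))
  }
  db_seqs <- c(contaminant_db$seq, revcomp(contaminant_db$seq))
  db_ids <- rep(contaminant_db$id, 2)
  km <- .kmers(db_seqs, k)
  kmer_owner <- setNames(rep(db_ids, lengths(km)), unlist(km))

  removed_idx <- integer(0)
  removed <- empty_removed
  for (i in seq_len(nrow(ests))) {
    s <- ests$seq[i]
    n <- nchar(s)
    if (n < k) next
    read_kmers <- substring(s, 1:(n - k + 1), k:n)
    hit <- match(read_kmers, names(kmer_owner))
    first <- which(!is.na(hit))[1]
    if (!is.na(first)) {
      removed_idx <- c(removed_idx, i)
      removed <- rbind(removed, data.frame(
        id = ests$id[i], reason = sprintf("shared %d-mer with contaminant", k),
        contaminant_id = unname(kmer_owner[hit[first]]), position = first,
        stringsAsFactors = FALSE))
    }
  }
  kept <- if (length(removed_idx)) ests[-removed_idx, , drop = FALSE] else ests
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}
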