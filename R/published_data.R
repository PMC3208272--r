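#' Published conserved-precursor metrics for Boechera flower libraries
#'
#' Loads the bundled reference table of previously reported conserved miRNA
#' families identified in sexual and apomictic *Boechera* flower EST
#' libraries: one row per matched EST, with the mature sequence, the
#' reference species and its nucleotide substitutions (`ref/obs` notation),
#' and — for the reads that fold into stable stem-loops — the precursor
#' length (`nn`), arm, A+U%, AMFE and MFEI. Rows that did not fold carry
#' `NA` metrics. Two merged multi-precursor rows have an ambiguous printed
#' mature sequence and carry `NA` there.
#'
#' @return data.frame with columns `mode`, `family`, `est_id`, `mature_seq`,
#'   `ref_species`, `ns`, `nn`, `arm`, `au_percent`, `amfe`, `mfei`.
#' @export
published_precursor_metrics <- function() {
  path <- system.file("extdata", "published_precursor_metrics.tsv",
                      package = "mirseeker", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Published natural-vs-corrected hairpin free energies
#'
#' Loads the bundled free-energy pairs of the nucleotide-substitution
#' stability experiment: for each precursor whose mature miRNA carries
#' species-specific substitutions, the folding free energy of the natural
#' hairpin and of the hairpin with the substitutions corrected.
#' `direction == "to_reference"` rows correct *Boechera* matures to the
#' reference species' nucleotides; `direction == "to_observed"` rows give
#' reference-species precursors the *Boechera* nucleotides.
#'
#' @return data.frame with columns `direction`, `mode`, `precursor_id`,
#'   `ns`, `nn`, `dg_natural`, `dg_corrected` (kcal/mol).
#' @export
published_hairpin_dg <- function() {
  path <- system.file("extdata", "published_hairpin_dg.tsv",
                      package = "mirseeker", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Parse `ref/obs` substitution annotations
#'
#' Converts comma-separated substitution strings such as `"U/A,A/G"` into a
#' long data.frame of (`ref_nt`, `obs_nt`) records.
#'
#' @param ns character vector of annotations (`NA` for none).
#' @param mode optional vector of the same length carried through.
#' @return data.frame with `ref_nt`, `obs_nt` and optionally `mode`.
#' @export
parse_ns_annotation <- function(ns, mode = NULL) {
  rows <- list()
  for (i in seq_along(ns)) {
    if (is.na(ns[i]) || ns[i] == "") next
    for (piece in strsplit(ns[i], ",", fixed = TRUE)[[1]]) {
      nts <- strsplit(trimws(piece), "/", fixed = TRUE)[[1]]
      if (length(nts) != 2) next
      rows[[length(rows) + 1]] <- data.frame(
        ref_nt = nts[1], obs_nt = nts[2],
        mode = if (is.null(mode)) NA_character_ else mode[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(ref_nt = character(0), obs_nt = character(0),
                      mode = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
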