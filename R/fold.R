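#' Fold an RNA sequence into its minimum-free-energy structure
#'
#' Predicts the minimum-free-energy (MFE) nested secondary structure of an
#' RNA sequence. The built-in backend is an exact dynamic program over a
#' nearest-neighbour energy model: stacking energies for adjacent base pairs
#' (AU, UA, GC, CG, GU, UG), tabulated hairpin, bulge and internal-loop
#' penalties (interior loops capped at 30 nt), and an affine multiloop cost.
#' Energies are maintained internally in exact tenths of kcal/mol, so results
#' are fully deterministic. The `"vienna"` backend shells out to `RNAfold`
#' when available and is intended for cross-checking, not as the default.
#'
#' Sequences shorter than 8 nt cannot form a hairpin under the model's
#' minimum-loop constraint and are returned unstructured with free energy 0.
#'
#' @param seq a single RNA string (A/C/G/U, optionally N; N never pairs).
#' @param backend `"builtin"` (default) or `"vienna"`.
#' @return an object of class `fold_result`: a list with elements `seq`,
#'   `dot_bracket` (balanced `(` `.` `)` string) and `delta_g` (kcal/mol,
#'   `<= 0`, `0` for an unstructured sequence).
#' @examples
#' fold_mfe("GGGGAAAACCCC")
#' @export
fold_mfe <- function(seq, backend = c("builtin", "vienna")) {
  backend <- match.arg(backend)
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- .normalize_rna(seq)
  .check_rna(seq, allow_n = TRUE)
  if (nchar(seq) < 8) {
    return(.fold_result(seq, strrep(".", nchar(seq)), 0))
  }
  if (backend == "vienna") {
    return(.fold_vienna(seq))
  }
  res <- fold_mfe_cpp(seq)
  .fold_result(seq, res$db, res$dg10 / 10)
}

.fold_result <- function(seq, db, dg) {
  structure(list(seq = seq, dot_bracket = db, delta_g = dg),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$dot_bracket, "  (", sprintf("%.1f", x$delta_g),
      " kcal/mol)\n", sep = "")
  invisible(x)
}

.fold_vienna <- function(seq) {
  rnafold <- Sys.which("RNAfold")
  if (rnafold == "") stop("RNAfold not found on PATH", call. = FALSE)
  out <- system2(rnafold, c("--noPS"), input = seq, stdout = TRUE)
  line <- out[2]
  db <- sub("^(\\S+).*$", "\\1", line)
  dg <- as.numeric(gsub("[() ]", "", sub("^\\S+\\s+", "", line)))
  .fold_result(seq, db, dg)
}

#' Score an explicit secondary structure under the built-in energy model
#'
#' Computes the free energy of a given dot-bracket structure by loop
#' decomposition, using the same parameter table as [fold_mfe()]. Useful for
#' evaluating alternative structures against the MFE.
#'
#' @param seq RNA string.
#' @param dot_bracket structure string of equal length.
#' @return free energy in kcal/mol, or `NA` if the structure is invalid under
#'   the model (non-complementary pair, hairpin loop < 3 nt, or an interior
#'   loop larger than 30 nt).
#' @export
score_structure <- function(seq, dot_bracket) {
  seq <- .normalize_rna(seq)
  score_structure_cpp(seq, dot_bracket)
}

#' Exhaustive-enumeration minimum free energy (reference implementation)
#'
#' Enumerates every nested secondary structure of a short sequence and
#' returns the minimum free energy under the built-in parameter table. This
#' brute-force reference is algorithmically independent of the dynamic
#' program in [fold_mfe()] and is used to verify it exactly; it is only
#' practical for sequences of a few dozen nucleotides.
#'
#' @param seq RNA string (at most 40 nt).
#' @return minimum free energy in kcal/mol (0 if no structure is favourable).
#' @export
fold_enumerate <- function(seq) {
  seq <- .normalize_rna(seq)
  .check_rna(seq, allow_n = TRUE)
  enumerate_mfe_cpp(seq)
}

# partner vector from a dot-bracket string: partner[i] is the paired index
# (1-based) or NA
.db_partner <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
      partner[i] <- j
    } else if (ch[i] != ".") {
      stop("invalid dot-bracket character: ", ch[i])
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string")
  partner
}

# classify each position of a structure: "paired", "hairpin", "bulge",
# "internal", "multi", "exterior" (unpaired classes by enclosing loop)
.db_loop_classes <- function(db) {
  partner <- .db_partner(db)
  n <- length(partner)
  cls <- rep("exterior", n)
  cls[!is.na(partner)] <- "paired"
  # for every closing pair, classify the unpaired positions directly inside
  for (i in seq_len(n)) {
    j <- partner[i]
    if (is.na(j) || j <= i) next
    inside <- integer(0)
    child_start <- integer(0)
    child_end <- integer(0)
    k <- i + 1
    while (k < j) {
      if (is.na(partner[k])) {
        inside <- c(inside, k)
        k <- k + 1
      } else {
        child_start <- c(child_start, k)
        child_end <- c(child_end, partner[k])
        k <- partner[k] + 1
      }
    }
    nchild <- length(child_start)
    type <- if (nchild == 0) {
      "hairpin"
    } else if (nchild == 1) {
      n5 <- sum(inside < child_start[1])
      n3 <- sum(inside > child_end[1])
      if (n5 > 0 && n3 > 0) "internal" else "bulge"
    } else {
      "multi"
    }
    cls[inside] <- type
  }
  cls
}
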