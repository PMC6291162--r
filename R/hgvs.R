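# HGVS-lite protein-change notation, in the dialect used by clinical variant
# tables for single-residue events: missense "p.(V25M)", single-residue
# in-frame deletion "p.(A158del)", and premature stops written either in the
# standard form "p.(Arg176Ter)" / "p.(R176*)" or in the common shorthand
# "R176X" (a literal "X" after a position is read as a stop, not as the
# unknown-residue code). One- and three-letter residue codes are both
# accepted; the surrounding "p.(...)" is optional.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

.aa3_to_1 <- c(stats::setNames(names(AA3), AA3), Ter = "*")

.aa_token_to_1 <- function(tok, role, text) {
  if (nchar(tok) == 3L) {
    out <- unname(.aa3_to_1[tok])
    if (is.na(out)) {
      stop(sprintf("unrecognised %s residue code '%s' in '%s'",
                   role, tok, text), call. = FALSE)
    }
    return(out)
  }
  if (!tok %in% AA1) {
    stop(sprintf("unrecognised %s residue code '%s' in '%s'",
                 role, tok, text), call. = FALSE)
  }
  tok
}

#' Parse a protein change in HGVS-lite notation
#'
#' Parses single-residue protein changes as printed in clinical variant
#' tables: missense substitutions (`"p.(V25M)"`), single-residue in-frame
#' deletions (`"p.(A158del)"`), and premature stop codons in either standard
#' (`"p.(Arg176Ter)"`, `"p.(R176*)"`) or shorthand (`"R176X"`) form. The
#' `"p.("` wrapper is optional and one- and three-letter amino-acid codes are
#' both understood.
#'
#' @param text A single character string with the protein change.
#'
#' @return A list with components `ref_residue` (one-letter code),
#'   `codon_index` (1-based integer residue position), `alt_residue`
#'   (one-letter code, `"*"` for a stop, `"del"` for a deletion),
#'   `consequence` (`"missense"`, `"nonsense"` or `"inframe_deletion"`) and
#'   `synonymous` (`TRUE` when reference and alternate residues are
#'   identical; such calls also raise a warning).
#'
#' @details A literal `"X"` following the position is interpreted as a stop
#'   codon, matching common clinical shorthand, so `"R176X"` parses as a
#'   nonsense change. Multi-residue deletions (`"p.(X1_Y5del)"`) are outside
#'   the dialect and rejected. Position 0 is rejected: residue numbering is
#'   1-based.
#'
#' @examples
#' parse_protein_change("p.(V25M)")
#' parse_protein_change("A158del")
#' parse_protein_change("p.(Arg176Ter)")
#'
#' @seealso [format_protein_change()] for the inverse operation.
#' @export
parse_protein_change <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("'text' must be a single character string", call. = FALSE)
  }
  s <- trimws(text)
  s <- sub("^p\\.", "", s)
  s <- sub("^\\(", "", s)
  s <- sub("\\)$", "", s)
  if (grepl("_", s, fixed = TRUE)) {
    stop(sprintf("multi-residue change '%s' is outside the single-residue dialect",
                 text), call. = FALSE)
  }
  m <- regmatches(s, regexec("^([A-Z][a-z]{2}|[A-Z])([0-9]+)(.*)$", s))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("cannot parse protein change '%s'", text), call. = FALSE)
  }
  ref <- .aa_token_to_1(m[2], "reference", text)
  codon <- suppressWarnings(as.integer(m[3]))
  if (is.na(codon)) {
    stop(sprintf("cannot parse residue position in '%s'", text), call. = FALSE)
  }
  if (codon < 1L) {
    stop(sprintf("residue position must be >= 1 (got %d in '%s')", codon, text),
         call. = FALSE)
  }
  alt_tok <- m[4]
  if (alt_tok == "") {
    stop(sprintf("missing alternate residue in '%s'", text), call. = FALSE)
  }
  if (alt_tok == "del") {
    alt <- "del"
    consequence <- "inframe_deletion"
  } else if (alt_tok %in% c("*", "X", "Ter")) {
    alt <- "*"
    consequence <- "nonsense"
  } else if (grepl("^([A-Z][a-z]{2}|[A-Z])$", alt_tok)) {
    alt <- .aa_token_to_1(alt_tok, "alternate", text)
    consequence <- "missense"
  } else {
    stop(sprintf("unrecognised alternate token '%s' in '%s'", alt_tok, text),
         call. = FALSE)
  }
  synonymous <- consequence == "missense" && identical(ref, alt)
  if (synonymous) {
    warning(sprintf("'%s' is a synonymous (identity) substitution", text),
            call. = FALSE)
  }
  list(ref_residue = ref, codon_index = codon, alt_residue = alt,
       consequence = consequence, synonymous = synonymous)
}

#' Format a parsed protein change back to HGVS-lite
#'
#' Inverse of [parse_protein_change()]: renders the one-letter dialect used in
#' the packaged variant tables, e.g. `"p.(V25M)"`, `"p.(A158del)"`,
#' `"p.(R176X)"` (stops are written with the shorthand `X`).
#'
#' @param ref_residue One-letter reference residue.
#' @param codon_index 1-based residue position.
#' @param alt_residue One-letter alternate residue, `"*"` for a stop or
#'   `"del"` for a single-residue deletion.
#' @return A character string.
#' @export
format_protein_change <- function(ref_residue, codon_index, alt_residue) {
  stopifnot(ref_residue %in% AA1, codon_index >= 1)
  alt <- if (identical(alt_residue, "*")) "X" else alt_residue
  if (!identical(alt, "del") && !identical(alt, "X") && !alt %in% AA1) {
    stop(sprintf("invalid alternate residue '%s'", alt_residue), call. = FALSE)
  }
  sprintf("p.(%s%d%s)", ref_residue, as.integer(codon_index), alt)
}

#' Extent of the C-terminal truncation caused by a premature stop
#'
#' For a stop gained at `codon_index` on a protein of `protein_length`
#' residues, reports both common ways of counting the lost C-terminus: the
#' number of residues at and after the stop position (the stop codon replaces
#' the residue there) and the number strictly after it. Published reports
#' sometimes use yet other conventions, so both counts are returned rather
#' than a single number.
#'
#' @param codon_index 1-based position of the gained stop.
#' @param protein_length Length of the wild-type protein in residues.
#' @return A list with `lost_at_and_after`, `lost_after` and
#'   `last_retained_residue`.
#' @examples
#' truncation_extent(176, 206) # 31 at-and-after, 30 strictly after
#' @export
truncation_extent <- function(codon_index, protein_length) {
  codon_index <- as.integer(codon_index)
  protein_length <- as.integer(protein_length)
  stopifnot(codon_index >= 1, codon_index <= protein_length)
  list(lost_at_and_after = protein_length - codon_index + 1L,
       lost_after = protein_length - codon_index,
       last_retained_residue = codon_index - 1L)
}
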