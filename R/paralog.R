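# Residue-position mapping between homologous proteins by global pairwise
# alignment. The alignment itself is a standard Needleman-Wunsch/affine-gap
# problem and is delegated to Biostrings::pairwiseAlignment (BLOSUM62,
# gap open 11, gap extend 1 by default — the ubiquitous protein defaults);
# this module owns the position-map bookkeeping built on top of it.

.valid_aa <- paste0(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                      "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                    collapse = "")

.check_protein_seq <- function(seq, label) {
  if (!nzchar(seq)) stop(sprintf("empty sequence '%s'", label), call. = FALSE)
  bad <- setdiff(strsplit(toupper(seq), "")[[1]],
                 strsplit(.valid_aa, "")[[1]])
  if (length(bad)) {
    stop(sprintf("invalid residue character(s) in '%s': %s", label,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  toupper(seq)
}

#' Globally align two protein sequences and build a position map
#'
#' Optimal global (Needleman-Wunsch) alignment under an affine gap penalty,
#' returning a column-by-column map between 1-based residue positions of the
#' two sequences. Tie-breaking among co-optimal alignments follows the
#' deterministic traceback of the underlying aligner, so results are
#' reproducible.
#'
#' @param seq_a,seq_b Protein sequences: character strings, or named
#'   length-one character vectors / `AAStringSet` elements whose names become
#'   the sequence ids.
#' @param id_a,id_b Sequence identifiers (default: names of the inputs, else
#'   `"A"`/`"B"`).
#' @param substitution_matrix Name of the substitution matrix (a data set of
#'   \pkg{Biostrings}, e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An object of class `alignment_map`: list with `id_a`, `id_b`,
#'   `seq_a`, `seq_b`, `columns` (data frame `a_pos`/`b_pos`, `NA` at gaps),
#'   `score`, `percent_identity` and `scoring`.
#' @examples
#' m <- global_align("ACDEFG", "ACEFG")
#' map_position(m, 5) # F maps 5 -> 4
#' @export
global_align <- function(seq_a, seq_b, id_a = NULL, id_b = NULL,
                         substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  if (is.null(id_a)) id_a <- if (!is.null(names(seq_a))) names(seq_a)[1] else "A"
  if (is.null(id_b)) id_b <- if (!is.null(names(seq_b))) names(seq_b)[1] else "B"
  sa <- .check_protein_seq(as.character(seq_a)[1], id_a)
  sb <- .check_protein_seq(as.character(seq_b)[1], id_b)
  mat <- .get_subst_matrix(substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  ca <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  cb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  columns <- data.frame(a_pos = ifelse(ca == "-", NA_integer_, ia),
                        b_pos = ifelse(cb == "-", NA_integer_, ib))
  both <- !is.na(columns$a_pos) & !is.na(columns$b_pos)
  pid <- 100 * sum(ca[both] == cb[both]) / sum(both)
  structure(list(id_a = id_a, id_b = id_b, seq_a = sa, seq_b = sb,
                 columns = columns, score = Biostrings::score(aln),
                 percent_identity = pid,
                 scoring = list(matrix = substitution_matrix,
                                gap_open = gap_open,
                                gap_extend = gap_extend)),
            class = "alignment_map")
}

.get_subst_matrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e)) {
    stop(sprintf("unknown substitution matrix '%s'", name), call. = FALSE)
  }
  get(name, envir = e)
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("Global alignment %s (%d aa) vs %s (%d aa): score %.1f, %.1f%% identity\n",
              x$id_a, nchar(x$seq_a), x$id_b, nchar(x$seq_b),
              x$score, x$percent_identity))
  invisible(x)
}

#' Map a residue position through an alignment
#'
#' @param map An `alignment_map`.
#' @param a_pos 1-based residue position in the first sequence.
#' @return The aligned 1-based position in the second sequence, or
#'   `NA_integer_` when `a_pos` aligns to a gap.
#' @export
map_position <- function(map, a_pos) {
  stopifnot(inherits(map, "alignment_map"))
  a_pos <- as.integer(a_pos)
  if (length(a_pos) != 1L || is.na(a_pos) || a_pos < 1L ||
      a_pos > nchar(map$seq_a)) {
    stop(sprintf("position out of range 1..%d", nchar(map$seq_a)),
         call. = FALSE)
  }
  col <- which(!is.na(map$columns$a_pos) & map$columns$a_pos == a_pos)
  map$columns$b_pos[col]
}

#' Reverse an alignment map
#'
#' Swaps the roles of the two sequences; composing a map with its reverse is
#' the identity on all mapped (non-gap) positions.
#'
#' @param map An `alignment_map`.
#' @return An `alignment_map` from sequence B to sequence A.
#' @export
reverse_alignment_map <- function(map) {
  stopifnot(inherits(map, "alignment_map"))
  out <- map
  out$id_a <- map$id_b; out$id_b <- map$id_a
  out$seq_a <- map$seq_b; out$seq_b <- map$seq_a
  out$columns <- data.frame(a_pos = map$columns$b_pos,
                            b_pos = map$columns$a_pos)
  out
}

#' Report homologous positions of cohort variants in paralogs
#'
#' For each cohort variant and each alignment (query gene as sequence A),
#' reports the homologous residue in the paralog and any matching entry in a
#' table of known disease-associated positions.
#'
#' @param cohort_variants Data frame with at least `protein_change` and
#'   `codon_index` columns (e.g. `collapse_families()` output or
#'   `cohort$variants`).
#' @param maps List of `alignment_map` objects sharing the cohort gene as
#'   sequence A.
#' @param known_positions Data frame with columns `gene`, `residue`,
#'   `phenotype`, `citation` (see [read_known_positions()]); may have zero
#'   rows, in which case no matches are reported.
#' @return A data frame with one row per (variant, paralog): columns
#'   `protein_change`, `query_residue`, `paralog`, `paralog_residue` (`"gap"`
#'   for unmapped positions), `known_phenotype`, `known_citation`.
#' @export
homolog_report <- function(cohort_variants, maps, known_positions = NULL) {
  cohort_variants <- as.data.frame(cohort_variants)
  stopifnot(all(c("protein_change", "codon_index") %in%
                  names(cohort_variants)))
  if (inherits(maps, "alignment_map")) maps <- list(maps)
  if (is.null(known_positions)) {
    known_positions <- data.frame(gene = character(0), residue = integer(0),
                                  phenotype = character(0),
                                  citation = character(0))
  }
  rows <- list()
  for (i in seq_len(nrow(cohort_variants))) {
    v <- cohort_variants[i, ]
    for (m in maps) {
      bp <- map_position(m, v$codon_index)
      hit <- known_positions[known_positions$gene == m$id_b &
                               !is.na(bp) &
                               known_positions$residue == bp, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_change = v$protein_change,
        query_residue = v$codon_index,
        paralog = m$id_b,
        paralog_residue = if (is.na(bp)) "gap" else as.character(bp),
        known_phenotype = if (nrow(hit)) paste(hit$phenotype, collapse = "; ")
                          else NA_character_,
        known_citation = if (nrow(hit)) paste(hit$citation, collapse = "; ")
                         else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a table of known disease-associated GTPase positions
#'
#' Tab-separated with columns `gene`, `residue`, `phenotype`, `citation`.
#' A small editable table covering the classic RAS-family positions ships
#' with the package; see
#' `system.file("extdata", "gtpase_disease_positions.tsv", package = "ralascope")`.
#'
#' @param path Path to the TSV (defaults to the packaged table).
#' @return A data frame.
#' @export
read_known_positions <- function(path = system.file(
    "extdata", "gtpase_disease_positions.tsv", package = "ralascope")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "residue", "phenotype", "citation")
  if (!all(need %in% names(tab))) {
    stop("known-positions table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tab$residue <- as.integer(tab$residue)
  tab
}

#' Read protein sequences from FASTA
#'
#' @param path Path to a protein FASTA file.
#' @return A named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(s), sub("\\s.*", "", names(s)))
}

#' Fetch canonical paralog sequences from UniProt (requires network)
#'
#' Convenience helper downloading canonical sequences by UniProt accession.
#' The package also ships reconstructed RALA/HRAS/KRAS sequences
#' (`inst/extdata/gtpase_paralogs_reconstructed.fa`, clearly labelled as
#' reconstructions) for fully offline use; prefer freshly fetched canonical
#' records when network is available.
#'
#' @param accessions Named character vector, names are gene symbols and
#'   values UniProt accessions.
#' @param dest Output FASTA path.
#' @return `dest` invisibly; errors when the download fails.
#' @export
fetch_paralog_sequences <- function(accessions = c(RALA = "P11233",
                                                   HRAS = "P01112",
                                                   KRAS = "P01116"),
                                    dest = tempfile(fileext = ".fa")) {
  lines <- character(0)
  for (i in seq_along(accessions)) {
    url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta",
                   accessions[[i]])
    rec <- tryCatch(readLines(url, warn = FALSE),
                    error = function(e) stop("cannot fetch ", url, ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
    rec[1] <- paste0(">", names(accessions)[i], " ", sub("^>", "", rec[1]))
    lines <- c(lines, rec)
  }
  writeLines(lines, dest)
  invisible(dest)
}
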