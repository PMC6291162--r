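# Ligand-contact annotation of a binding region from a 3D structure.
# The rule: a residue belongs to the region iff any of its atoms (side chain
# or backbone) lies within a distance threshold of any ligand atom. Heavy
# atoms only by default, since deposited crystal structures usually lack
# hydrogens; 1.5 angstroms is the conventional default threshold here but is
# deliberately configurable — over heavy atoms it is physically very tight
# (hydrogen-bond heavy-atom distances run 2.5-3.5 angstroms), and annotation
# sets published from hydrogen-added models are not generally reproducible
# from the heavy-atom structure at the same cutoff.

.water_codes <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein structure with bound ligand(s) from a PDB file
#'
#' Parses ATOM and HETATM records (via \pkg{bio3d}), drops waters, and keeps
#' the highest-occupancy alternate location for each atom (first on ties).
#' HETATM residues whose 3-letter code is in `ligand_codes` are the ligand
#' atoms; the function errors when none of the requested codes is present,
#' since downstream contact annotation would be meaningless.
#'
#' @param path Path to a PDB file.
#' @param ligand_codes Character vector of 3-letter heteroatom codes to treat
#'   as ligand (default GDP/GTP and their common analogues GNP/GSP).
#' @return An object of class `structure_model`: a list with `atoms` (a data
#'   frame with `chain`, `resno`, `resid`, `elety`, `elesy`, `x`, `y`, `z`,
#'   `het`) and `ligand_codes` (the codes actually present).
#' @export
read_structure <- function(path, ligand_codes = c("GDP", "GTP", "GNP", "GSP")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("no atom records in '", path, "'", call. = FALSE)
  }
  at <- at[!(at$resid %in% .water_codes), , drop = FALSE]
  if (nrow(at) == 0L) stop("only water records in '", path, "'", call. = FALSE)
  # altloc resolution: keep the highest-occupancy copy of each atom
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  ord <- order(key, -occ)
  at <- at[ord[!duplicated(key[ord])], , drop = FALSE]
  if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z))) {
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, elesy = at$elesy,
                      x = at$x, y = at$y, z = at$z,
                      het = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  atoms <- atoms[order(atoms$het, atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  present <- intersect(ligand_codes, atoms$resid[atoms$het])
  if (length(present) == 0L) {
    stop("ligand absent: no HETATM residue matching ",
         paste(ligand_codes, collapse = "/"), " in '", path, "'",
         call. = FALSE)
  }
  structure(list(atoms = atoms, ligand_codes = present),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure: %d protein atoms in %d residues; ligand(s) %s (%d atoms)\n",
              sum(!a$het), length(unique(a$resno[!a$het])),
              paste(x$ligand_codes, collapse = ","), sum(a$het)))
  invisible(x)
}

#' Construct a binding-region annotation
#'
#' @param residues Integer vector of 1-based residue indices (duplicates are
#'   removed; the stored set is sorted).
#' @param protein_length Protein length in residues.
#' @param source Optional named list recording provenance (structure id,
#'   ligand code, threshold, atom policy).
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(residues, protein_length, source = list()) {
  residues <- sort(unique(as.integer(residues)))
  protein_length <- as.integer(protein_length)
  stopifnot(length(protein_length) == 1L, protein_length > 0L)
  if (length(residues) && (min(residues) < 1L || max(residues) > protein_length)) {
    stop("region residues outside [1, ", protein_length, "]", call. = FALSE)
  }
  structure(list(residues = residues, protein_length = protein_length,
                 source = source),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("Region: %d of %d residues (%.1f%%)\n",
              length(x$residues), x$protein_length, region_fraction(x)))
  if (length(x$residues)) {
    cat("  ", paste(x$residues, collapse = " "), "\n", sep = "")
  }
  if (length(x$source)) {
    cat("  source:", paste(names(x$source), unlist(x$source), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Annotate ligand-contact residues by the distance rule
#'
#' A residue is annotated iff the minimum Euclidean distance between any of
#' its atoms (backbone or side chain) and any atom of the ligand is less than
#' or equal to `threshold` (boundary inclusive). When several copies of the
#' ligand are present, the union of contacts over all copies is returned.
#'
#' @param structure A `structure_model` from [read_structure()].
#' @param ligand 3-letter heteroatom code of the ligand.
#' @param threshold Distance threshold in angstroms; must be positive.
#' @param offset Integer added to structure residue numbers to obtain
#'   protein-sequence numbering (0 when the structure is numbered on the
#'   mature sequence).
#' @param protein_length Protein length for the resulting annotation;
#'   defaults to the highest (offset) protein residue number seen.
#' @param include_hydrogens Include hydrogen atoms if present (default FALSE:
#'   heavy atoms only).
#' @return A `region_annotation` whose `source` records the rule parameters.
#' @export
contact_residues <- function(structure, ligand = "GDP", threshold = 1.5,
                             offset = 0L, protein_length = NULL,
                             include_hydrogens = FALSE) {
  stopifnot(inherits(structure, "structure_model"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("'threshold' must be a positive distance in angstroms",
         call. = FALSE)
  }
  a <- structure$atoms
  prot <- a[!a$het, , drop = FALSE]
  lig <- a[a$het & a$resid == ligand, , drop = FALSE]
  if (nrow(lig) == 0L) {
    stop("ligand absent: no HETATM residue '", ligand, "' in structure",
         call. = FALSE)
  }
  is_h <- function(d) !is.na(d$elesy) & toupper(d$elesy) == "H"
  if (!include_hydrogens) {
    prot <- prot[!is_h(prot), , drop = FALSE]
    lig <- lig[!is_h(lig), , drop = FALSE]
  }
  px <- as.matrix(prot[, c("x", "y", "z")])
  lx <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(px^2), rep(1, nrow(lx))) +
    outer(rep(1, nrow(px)), rowSums(lx^2)) - 2 * px %*% t(lx)
  min_d <- sqrt(pmax(apply(d2, 1, min), 0))
  hits <- sort(unique(prot$resno[min_d <= threshold])) + as.integer(offset)
  if (is.null(protein_length)) {
    protein_length <- max(prot$resno) + as.integer(offset)
  }
  region_annotation(hits, protein_length,
                    source = list(ligand = ligand, threshold = threshold,
                                  offset = as.integer(offset),
                                  atoms = if (include_hydrogens) "all"
                                          else "heavy"))
}

#' Fraction of the protein covered by a region
#'
#' @param region A `region_annotation`.
#' @return Percentage of residues in the region, rounded to one decimal.
#' @examples
#' region_fraction(region_annotation(1:24, 206)) # 11.7
#' @export
region_fraction <- function(region) {
  stopifnot(inherits(region, "region_annotation"))
  round(100 * length(region$residues) / region$protein_length, 1)
}

#' Read a region from a residue-list file
#'
#' One 1-based residue index per line; blank lines and `#` comments ignored.
#'
#' @param path Path to the residue-list file.
#' @param protein_length Protein length for the annotation.
#' @return A `region_annotation`.
#' @export
read_region <- function(path, protein_length) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  res <- suppressWarnings(as.integer(lines))
  if (anyNA(res)) stop("non-integer entries in region file '", path, "'",
                       call. = FALSE)
  region_annotation(res, protein_length, source = list(file = basename(path)))
}

#' Export a region as a residue list or BED intervals
#'
#' The residue-list format writes 1-based indices, one per line. The BED
#' format converts each maximal run of consecutive residues to a 0-based
#' half-open interval on a pseudo-chromosome named after the gene (residue 25
#' becomes `start=24, end=25`).
#'
#' @param region A `region_annotation`.
#' @param path Output path.
#' @param format `"residues"` or `"bed"`.
#' @param name Pseudo-chromosome name for BED output.
#' @return Invisibly, `path`.
#' @export
write_region <- function(region, path, format = c("residues", "bed"),
                         name = "protein") {
  stopifnot(inherits(region, "region_annotation"))
  format <- match.arg(format)
  if (format == "residues") {
    writeLines(as.character(region$residues), path)
  } else {
    iv <- region_intervals(region)
    lines <- sprintf("%s\t%d\t%d", name, iv$start0, iv$end)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Maximal runs of consecutive region residues as 0-based half-open intervals
#'
#' @param region A `region_annotation`.
#' @return A data frame with columns `start0` (0-based) and `end` (exclusive).
#' @export
region_intervals <- function(region) {
  stopifnot(inherits(region, "region_annotation"))
  if (length(region$residues) == 0L) {
    return(data.frame(start0 = integer(0), end = integer(0)))
  }
  runs <- IRanges::reduce(IRanges::IRanges(region$residues, region$residues))
  data.frame(start0 = IRanges::start(runs) - 1L, end = IRanges::end(runs))
}
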