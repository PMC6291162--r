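# Cohort variant and phenotype tables. The on-disk dialect is tab-separated
# UTF-8 with a header row; phenotype flags are coded "+", "-", "NR"
# (not reported). Monozygotic sets are groups of probands carrying the same
# germline mutational event; they share a family_id and collapse to a single
# family-level allele.

.cohort_variant_cols <- c("proband_id", "family_id", "monozygotic_set_id",
                          "gene", "transcript", "cdna_change",
                          "protein_change", "inheritance", "site")

.inheritance_levels <- c("de_novo", "inherited", "unknown")

#' Construct a validated cohort table
#'
#' Combines a variant table (one row per proband allele observation) with an
#' optional phenotype table (one row per proband, one column per flag coded
#' `"+"`, `"-"` or `"NR"`). Protein changes are parsed with
#' [parse_protein_change()] and the parsed fields (`ref_residue`,
#' `codon_index`, `alt_residue`, `consequence`) are appended to the variant
#' table.
#'
#' @param variants A data frame with columns `proband_id`, `family_id`,
#'   `monozygotic_set_id` (empty/`NA` when the proband is not part of a
#'   monozygotic set), `gene`, `transcript`, `cdna_change`, `protein_change`,
#'   `inheritance` (`de_novo`, `inherited` or `unknown`) and `site`.
#' @param phenotypes Optional data frame with a `proband_id` column and one
#'   column per phenotype flag.
#' @param protein_length Optional protein length; when given, parsed codon
#'   indices are validated against it.
#'
#' @return An object of class `rala_cohort`: a list with elements `variants`
#'   and `phenotypes`.
#' @export
cohort_table <- function(variants, phenotypes = NULL, protein_length = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_variant_cols, names(variants))
  if (length(missing_cols)) {
    stop("variant table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(variants) == 0L) {
    stop("variant table contains no records", call. = FALSE)
  }
  if (anyDuplicated(variants$proband_id)) {
    stop("duplicated proband_id in variant table", call. = FALSE)
  }
  bad_inh <- setdiff(unique(variants$inheritance), .inheritance_levels)
  if (length(bad_inh)) {
    stop("invalid inheritance value(s): ", paste(bad_inh, collapse = ", "),
         call. = FALSE)
  }
  parsed <- lapply(variants$protein_change, parse_protein_change)
  variants$ref_residue <- vapply(parsed, `[[`, "", "ref_residue")
  variants$codon_index <- vapply(parsed, `[[`, 1L, "codon_index")
  variants$alt_residue <- vapply(parsed, `[[`, "", "alt_residue")
  variants$consequence <- vapply(parsed, `[[`, "", "consequence")
  if (!is.null(protein_length) &&
      any(variants$codon_index > protein_length)) {
    stop("codon_index beyond protein length ", protein_length, call. = FALSE)
  }
  mz <- variants$monozygotic_set_id
  mz[is.na(mz) | mz == ""] <- NA_character_
  variants$monozygotic_set_id <- mz
  for (set_id in unique(mz[!is.na(mz)])) {
    fams <- unique(variants$family_id[!is.na(mz) & mz == set_id])
    if (length(fams) != 1L) {
      stop(sprintf("monozygotic set '%s' spans multiple families (%s)",
                   set_id, paste(fams, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(phenotypes)) {
    phenotypes <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
    if (!"proband_id" %in% names(phenotypes)) {
      stop("phenotype table needs a proband_id column", call. = FALSE)
    }
    flag_cols <- setdiff(names(phenotypes), "proband_id")
    for (fc in flag_cols) {
      bad <- setdiff(stats::na.omit(unique(phenotypes[[fc]])),
                     c("+", "-", "NR"))
      if (length(bad)) {
        stop(sprintf("phenotype column '%s' has values outside {+, -, NR}: %s",
                     fc, paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
  }
  structure(list(variants = variants, phenotypes = phenotypes,
                 protein_length = protein_length),
            class = "rala_cohort")
}

#' Read a cohort from tab-separated files
#'
#' @param variants_path Path to the variant TSV (see [cohort_table()] for the
#'   required columns).
#' @param phenotypes_path Optional path to the phenotype TSV.
#' @param protein_length Optional protein length for validation.
#' @return An object of class `rala_cohort`.
#' @export
read_cohort <- function(variants_path, phenotypes_path = NULL,
                        protein_length = NULL) {
  variants <- utils::read.delim(variants_path, stringsAsFactors = FALSE,
                                colClasses = "character",
                                fileEncoding = "UTF-8")
  phenotypes <- NULL
  if (!is.null(phenotypes_path)) {
    phenotypes <- utils::read.delim(phenotypes_path, stringsAsFactors = FALSE,
                                    colClasses = "character",
                                    fileEncoding = "UTF-8")
  }
  cohort_table(variants, phenotypes, protein_length = protein_length)
}

#' Write a cohort back to the tab-separated dialect
#'
#' Writes only the dialect columns (parsed fields are derived, not stored),
#' so a write/read round trip reproduces the cohort exactly.
#'
#' @param cohort An `rala_cohort`.
#' @param variants_path Output path for the variant TSV.
#' @param phenotypes_path Optional output path for the phenotype TSV.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, variants_path, phenotypes_path = NULL) {
  stopifnot(inherits(cohort, "rala_cohort"))
  out <- cohort$variants[, .cohort_variant_cols]
  out$monozygotic_set_id[is.na(out$monozygotic_set_id)] <- ""
  utils::write.table(out, variants_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(phenotypes_path) && !is.null(cohort$phenotypes)) {
    utils::write.table(cohort$phenotypes, phenotypes_path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(c(variants_path, phenotypes_path))
}

#' Collapse probands to family-level allele records
#'
#' Monozygotic twins (and higher-order monozygotic sets) carry a single
#' germline mutational event, so burden and recurrence statistics count
#' families, not probands. All probands within a family must carry the same
#' protein change; discordance is an error because it contradicts the
#' single-event assumption.
#'
#' @param cohort An `rala_cohort`.
#' @return A data frame with one row per family: `family_id`, `n_probands`,
#'   `proband_ids`, `gene`, `protein_change`, `codon_index`, `consequence`,
#'   `inheritance`, `site`.
#' @export
collapse_families <- function(cohort) {
  stopifnot(inherits(cohort, "rala_cohort"))
  v <- cohort$variants
  if (nrow(v) == 0L) {
    return(data.frame(family_id = character(0), n_probands = integer(0),
                      proband_ids = character(0), gene = character(0),
                      protein_change = character(0), codon_index = integer(0),
                      consequence = character(0), inheritance = character(0),
                      site = character(0), stringsAsFactors = FALSE))
  }
  fams <- split(v, v$family_id)
  rows <- lapply(fams, function(fv) {
    if (length(unique(fv$protein_change)) != 1L) {
      set_lab <- unique(stats::na.omit(fv$monozygotic_set_id))
      lab <- if (length(set_lab)) {
        sprintf("monozygotic set '%s'", set_lab[1])
      } else {
        sprintf("family '%s'", fv$family_id[1])
      }
      stop(sprintf("discordant variants within %s: %s", lab,
                   paste(unique(fv$protein_change), collapse = " vs ")),
           call. = FALSE)
    }
    data.frame(family_id = fv$family_id[1],
               n_probands = nrow(fv),
               proband_ids = paste(fv$proband_id, collapse = ","),
               gene = fv$gene[1],
               protein_change = fv$protein_change[1],
               codon_index = fv$codon_index[1],
               consequence = fv$consequence[1],
               inheritance = fv$inheritance[1],
               site = fv$site[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$family_id), , drop = FALSE]
}

#' Summarize a phenotype flag as a fraction of informative probands
#'
#' The denominator counts probands with an informative value (`"+"` or
#' `"-"`); `"NR"` and missing entries are excluded. The percentage is rounded
#' to the nearest integer, the convention used in clinical cohort reports.
#'
#' @param cohort An `rala_cohort` with a phenotype table.
#' @param flag_label Name of the phenotype column.
#' @return A list of class `phenotype_fraction` with `numerator`,
#'   `denominator`, `percent` (`NA` with `undefined = TRUE` when no proband
#'   is informative) and `flag_label`.
#' @export
phenotype_fraction <- function(cohort, flag_label) {
  stopifnot(inherits(cohort, "rala_cohort"))
  ph <- cohort$phenotypes
  if (is.null(ph)) stop("cohort has no phenotype table", call. = FALSE)
  if (!flag_label %in% names(ph)) {
    stop(sprintf("unknown phenotype flag '%s'", flag_label), call. = FALSE)
  }
  vals <- ph[[flag_label]]
  informative <- !is.na(vals) & vals %in% c("+", "-")
  num <- sum(vals[informative] == "+")
  den <- sum(informative)
  pct <- if (den > 0) round(100 * num / den) else NA_real_
  structure(list(flag_label = flag_label, numerator = num, denominator = den,
                 percent = pct, undefined = den == 0),
            class = "phenotype_fraction")
}

#' @export
print.phenotype_fraction <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("%s: 0/0 (undefined; no informative probands)\n",
                x$flag_label))
  } else {
    cat(sprintf("%s: %d/%d (%d%%)\n", x$flag_label, x$numerator,
                x$denominator, x$percent))
  }
  invisible(x)
}

#' @export
print.rala_cohort <- function(x, ...) {
  v <- x$variants
  cat(sprintf("Cohort of %d probands in %d families (%s)\n",
              nrow(v), length(unique(v$family_id)),
              paste(unique(v$gene), collapse = ", ")))
  n_mz <- length(unique(stats::na.omit(v$monozygotic_set_id)))
  if (n_mz > 0) cat(sprintf("  %d monozygotic set(s)\n", n_mz))
  cat("  Inheritance:",
      paste(sprintf("%s=%d", names(table(v$inheritance)),
                    as.integer(table(v$inheritance))), collapse = ", "), "\n")
  if (!is.null(x$phenotypes)) {
    cat(sprintf("  Phenotype flags: %d\n", ncol(x$phenotypes) - 1L))
  }
  invisible(x)
}

#' @export
summary.rala_cohort <- function(object, ...) {
  print(object)
  fams <- collapse_families(object)
  dn <- fams[fams$inheritance == "de_novo", , drop = FALSE]
  cat(sprintf("  Family-level alleles: %d (%d de novo)\n",
              nrow(fams), nrow(dn)))
  if (!is.null(object$phenotypes)) {
    for (fc in setdiff(names(object$phenotypes), "proband_id")) {
      print(phenotype_fraction(object, fc))
    }
  }
  invisible(object)
}

#' Count observed de novo family-level alleles
#'
#' Counts qualifying de novo alleles after twin collapsing: inheritance
#' `de_novo` and consequence in `consequences`. When a burden analysis is
#' restricted to probands ascertained within systematically screened trio
#' cohorts, pass the qualifying sites via `sites`.
#'
#' @param cohort An `rala_cohort`.
#' @param consequences Consequence classes that qualify.
#' @param sites Optional character vector of site labels; families from other
#'   sites are excluded.
#' @return Integer count of family-level de novo alleles.
#' @export
observed_denovo <- function(cohort,
                            consequences = c("missense", "nonsense",
                                             "inframe_deletion"),
                            sites = NULL) {
  fams <- collapse_families(cohort)
  keep <- fams$inheritance == "de_novo" & fams$consequence %in% consequences
  if (!is.null(sites)) keep <- keep & fams$site %in% sites
  sum(keep)
}
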