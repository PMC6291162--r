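# Regional missense-depletion testing and codon recurrence.
# Unit of analysis for depletion is the residue: a residue either carries at
# least one qualifying population missense variant or it does not. The 2x2
# table (in/out of the annotated region x variant-bearing or not) is tested
# with Fisher's exact test under the minimum-likelihood two-sided convention:
# sum, over all tables with the observed margins, the hypergeometric point
# probabilities not exceeding that of the observed table.

#' Build the residue-level 2x2 depletion table
#'
#' @param region A `region_annotation` defining the in-region residues.
#' @param variant_residues Integer vector of 1-based residue indices carrying
#'   at least one qualifying population missense variant (duplicates
#'   collapse: a residue with several variants counts once).
#' @return An object of class `depletion_table`: a 2x2 integer matrix with
#'   rows `in_region`/`outside` and columns `variant`/`no_variant`.
#' @examples
#' reg <- region_annotation(1:24, 206)
#' build_depletion_table(reg, 25:58) # [[0,24],[34,148]]
#' @export
build_depletion_table <- function(region, variant_residues) {
  stopifnot(inherits(region, "region_annotation"))
  variant_residues <- unique(as.integer(variant_residues))
  L <- region$protein_length
  if (length(variant_residues) &&
      (min(variant_residues) < 1L || max(variant_residues) > L)) {
    stop("variant residues outside [1, ", L, "]", call. = FALSE)
  }
  R <- length(region$residues)
  in_var <- sum(variant_residues %in% region$residues)
  out_var <- length(variant_residues) - in_var
  tab <- matrix(c(in_var, out_var, R - in_var, (L - R) - out_var),
                nrow = 2, dimnames = list(c("in_region", "outside"),
                                          c("variant", "no_variant")))
  storage.mode(tab) <- "integer"
  class(tab) <- c("depletion_table", class(tab))
  tab
}

#' Read population missense-variant residues
#'
#' Accepts either a residue-index list (one 1-based index per line, `#`
#' comments allowed) or an annotated-variant TSV with columns `residue`,
#' `consequence` and `filter`, from which only records with consequence
#' `missense` and filter `PASS` are kept — mirroring the use of high-quality
#' population-database variants only.
#'
#' @param path Input path.
#' @return Sorted integer vector of unique variant-bearing residue indices.
#' @export
read_population_variants <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first) || grepl("residue", first, ignore.case = TRUE)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("residue", "consequence", "filter")
    if (!all(need %in% names(tab))) {
      stop("variant TSV needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    keep <- tab$consequence == "missense" & tab$filter == "PASS"
    return(sort(unique(as.integer(tab$residue[keep]))))
  }
  lines <- trimws(sub("#.*", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  res <- suppressWarnings(as.integer(lines))
  if (anyNA(res)) stop("non-integer entries in '", path, "'", call. = FALSE)
  sort(unique(res))
}

#' Fisher's exact test for a 2x2 table (minimum-likelihood two-sided)
#'
#' Enumerates every table compatible with the observed margins and sums the
#' hypergeometric point probabilities of those no more likely than the
#' observed table (ties detected with relative tolerance `tie_tol`). Also
#' returns the one-sided lower-tail probability, i.e. the probability of at
#' most the observed count in the top-left cell — the depletion direction
#' when the top-left cell is in-region variant-bearing residues.
#'
#' @param tab A 2x2 matrix of nonnegative counts.
#' @param tie_tol Relative tolerance for probability ties.
#' @return A list of class `fisher_exact` with `p_two_sided`, `p_lower`,
#'   `table` and `degenerate` (TRUE for the all-zero table, for which both
#'   p-values are 1).
#' @examples
#' fisher_exact_two_sided(matrix(c(0, 34, 24, 148), 2))
#' @export
fisher_exact_two_sided <- function(tab, tie_tol = 1e-7) {
  tab <- as.matrix(unclass(tab))
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("table cells must be nonnegative integers", call. = FALSE)
  }
  x <- tab[1, 1]
  m <- sum(tab[1, ])          # size of group 1 (e.g. in-region residues)
  n <- sum(tab[2, ])          # size of group 2
  k <- sum(tab[, 1])          # total "successes" (variant-bearing residues)
  if (m + n == 0) {
    return(structure(list(p_two_sided = 1, p_lower = 1, table = tab,
                          degenerate = TRUE), class = "fisher_exact"))
  }
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  lp_obs <- stats::dhyper(x, m, n, k, log = TRUE)
  p_two <- sum(exp(logp[logp <= lp_obs + log1p(tie_tol)]))
  p_lower <- sum(exp(logp[support <= x]))
  structure(list(p_two_sided = min(p_two, 1), p_lower = min(p_lower, 1),
                 table = tab, degenerate = FALSE),
            class = "fisher_exact")
}

#' @export
print.fisher_exact <- function(x, ...) {
  cat("Fisher's exact test\n")
  print(x$table)
  if (x$degenerate) {
    cat("  degenerate (all-zero) table: p = 1\n")
  } else {
    cat(sprintf("  two-sided p = %.3g (minimum-likelihood convention)\n",
                x$p_two_sided))
    cat(sprintf("  one-sided lower-tail p = %.3g\n", x$p_lower))
  }
  invisible(x)
}

#' Test regional depletion of population missense variation
#'
#' Builds the residue-level 2x2 table with [build_depletion_table()] and
#' applies [fisher_exact_two_sided()].
#'
#' @inheritParams build_depletion_table
#' @return An object of class `depletion_test` combining the table, the
#'   two-sided and lower-tail p-values, and the region provenance.
#' @export
depletion_test <- function(region, variant_residues) {
  tab <- build_depletion_table(region, variant_residues)
  ft <- fisher_exact_two_sided(tab)
  structure(list(table = tab, p_two_sided = ft$p_two_sided,
                 p_lower = ft$p_lower, degenerate = ft$degenerate,
                 region = region),
            class = "depletion_test")
}

#' @export
print.depletion_test <- function(x, ...) {
  cat(sprintf("Regional depletion: %d/%d in-region vs %d/%d outside residues variant-bearing\n",
              x$table[1, 1], sum(x$table[1, ]),
              x$table[2, 1], sum(x$table[2, ])))
  cat(sprintf("  Fisher two-sided p = %.3g; lower-tail p = %.3g\n",
              x$p_two_sided, x$p_lower))
  invisible(x)
}

#' Codon-level recurrence of de novo family alleles
#'
#' Counts twin-collapsed de novo alleles per codon (in-frame deletions count
#' at their first deleted residue) and reports how concentrated the alleles
#' are at the two most recurrent codons. Recurrence is reported
#' descriptively; see [recurrence_permutation_test()] for an optional test.
#'
#' @param cohort An `rala_cohort`.
#' @return An object of class `recurrence_summary` with `per_codon` (a data
#'   frame of codon/count sorted by descending count then ascending codon),
#'   `top_codons` (the first two rows), `concentrated_alleles` (alleles at
#'   the top-2 codons) and `total_denovo_alleles`.
#' @export
recurrence_summary <- function(cohort) {
  fams <- collapse_families(cohort)
  dn <- fams[fams$inheritance == "de_novo", , drop = FALSE]
  if (nrow(dn) == 0L) {
    per <- data.frame(codon_index = integer(0), count = integer(0))
  } else {
    tab <- table(dn$codon_index)
    per <- data.frame(codon_index = as.integer(names(tab)),
                      count = as.integer(tab))
    per <- per[order(-per$count, per$codon_index), , drop = FALSE]
    rownames(per) <- NULL
  }
  top <- utils::head(per, 2L)
  structure(list(per_codon = per, top_codons = top,
                 concentrated_alleles = sum(top$count),
                 total_denovo_alleles = nrow(dn)),
            class = "recurrence_summary")
}

#' @export
print.recurrence_summary <- function(x, ...) {
  cat(sprintf("Recurrence: %d of %d de novo family alleles at the top-2 codons",
              x$concentrated_alleles, x$total_denovo_alleles))
  if (nrow(x$top_codons)) {
    cat(" (", paste(sprintf("%d: %d", x$top_codons$codon_index,
                            x$top_codons$count), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Permutation test for codon recurrence (extension)
#'
#' An optional, seeded permutation test that goes beyond the descriptive
#' recurrence summary: under the null, alleles land on codons independently
#' and uniformly; the statistic is the number of alleles at the two most
#' recurrent codons. The p-value is the fraction of permutations with a
#' statistic at least as concentrated as observed (observed included).
#'
#' @param cohort An `rala_cohort`.
#' @param protein_length Number of codons alleles can land on.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A list with `observed_concentrated`, `total_alleles`, `p_value`.
#' @export
recurrence_permutation_test <- function(cohort, protein_length = 206,
                                        n_perm = 10000, seed = 1) {
  rs <- recurrence_summary(cohort)
  n <- rs$total_denovo_alleles
  if (n == 0L) {
    return(list(observed_concentrated = 0L, total_alleles = 0L, p_value = 1))
  }
  stat <- function(codons) {
    sum(utils::head(sort(table(codons), decreasing = TRUE), 2L))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    stat(sample.int(protein_length, n, replace = TRUE))
  }, 0)
  p <- (1 + sum(null_stats >= rs$concentrated_alleles)) / (n_perm + 1)
  list(observed_concentrated = rs$concentrated_alleles,
       total_alleles = n, p_value = p)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
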