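# Seeded synthetic-data generators for every pipeline input. Each generator
# draws from its own deterministic stream derived from a single root seed
# (root * 16 + a fixed per-generator stream id, reduced mod 2^31 - 1), so
# adding a generator never perturbs the others, and the caller's RNG state is
# saved and restored: generators are pure functions of their arguments.
#
# Defaults encode the study conditions the analysis targets: a screened
# cohort of 16,086 trios, a per-chromosome de novo rate of 6.16e-6 for a
# 206-residue protein, a 24-residue binding region with 34 variant-bearing
# residues outside it and absolute depletion inside (depletion_factor 0).

.stream_ids <- c(cohort = 1L, counts = 2L, population = 3L, structure = 4L,
                 assay = 5L, homolog = 6L)

.with_stream <- function(seed, stream, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  derived <- (abs(as.numeric(seed)) * 16 + .stream_ids[[stream]]) %%
    2147483647
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(derived))
  force(expr)
}

.random_missense <- function(n) {
  ref <- sample(AA1, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(AA1, r), 1L), "")
  list(ref = ref, alt = alt)
}

#' Simulate a trio-cohort variant table under the mutation-rate null
#'
#' The number of de novo alleles is `Binomial(2 * n_probands, denovo_rate)`;
#' each allele lands in a distinct proband. Codons are drawn uniformly over
#' the protein, or concentrated at `hotspot_codons` with probability
#' `hotspot_weight` per allele. Optionally, monozygotic twin probands
#' (sharing family and variant) are appended, and phenotype flags are sampled
#' with the given prevalences (`"NR"` with probability `nr_rate`).
#'
#' @param n_probands Number of screened probands.
#' @param denovo_rate Per-chromosome de novo rate.
#' @param protein_length Number of codons alleles can land on.
#' @param hotspot_codons Optional codon indices forming recurrence hotspots.
#' @param hotspot_weight Probability that an allele lands in a hotspot.
#' @param n_mz_twins Number of variant-carrying probands to duplicate as
#'   monozygotic twins (at most the number of variant carriers).
#' @param phenotype_prevalence Named numeric vector of `P(flag == "+")`.
#' @param nr_rate Probability that a phenotype value is not reported.
#' @param seed Integer root seed.
#' @return An `rala_cohort` (possibly with zero variant rows).
#' @export
simulate_cohort <- function(n_probands = 16086, denovo_rate = 6.16e-6,
                            protein_length = 206, hotspot_codons = NULL,
                            hotspot_weight = 0, n_mz_twins = 0,
                            phenotype_prevalence = NULL, nr_rate = 0.1,
                            seed = 1) {
  stopifnot(n_probands >= 1, denovo_rate >= 0, denovo_rate < 1)
  .with_stream(seed, "cohort", {
    n_var <- stats::rbinom(1L, 2L * n_probands, denovo_rate)
    n_var <- min(n_var, n_probands)
    if (n_var == 0L) {
      variants <- data.frame(proband_id = character(0),
                             family_id = character(0),
                             monozygotic_set_id = character(0),
                             gene = character(0), transcript = character(0),
                             cdna_change = character(0),
                             protein_change = character(0),
                             inheritance = character(0),
                             site = character(0), stringsAsFactors = FALSE)
      return(.cohort_table_internal(variants, NULL, protein_length))
    }
    codons <- integer(n_var)
    for (i in seq_len(n_var)) {
      use_hot <- length(hotspot_codons) > 0 &&
        stats::runif(1) < hotspot_weight
      codons[i] <- if (use_hot) {
        hotspot_codons[sample.int(length(hotspot_codons), 1L)]
      } else {
        sample.int(protein_length, 1L)
      }
    }
    aa <- .random_missense(n_var)
    variants <- data.frame(
      proband_id = sprintf("P%d", seq_len(n_var)),
      family_id = sprintf("F%d", seq_len(n_var)),
      monozygotic_set_id = NA_character_,
      gene = "SIM", transcript = "SIM.1",
      cdna_change = sprintf("c.%d%s>%s", codons * 3L - 2L, "N", "N"),
      protein_change = mapply(format_protein_change, aa$ref, codons, aa$alt),
      inheritance = "de_novo", site = "SimSite",
      stringsAsFactors = FALSE)
    n_tw <- min(n_mz_twins, n_var)
    if (n_tw > 0L) {
      idx <- sample.int(n_var, n_tw)
      twins <- variants[idx, , drop = FALSE]
      twins$proband_id <- paste0(twins$proband_id, "t")
      sets <- sprintf("MZ%d", seq_len(n_tw))
      twins$monozygotic_set_id <- sets
      variants$monozygotic_set_id[idx] <- sets
      variants <- rbind(variants, twins)
    }
    phenotypes <- NULL
    if (!is.null(phenotype_prevalence)) {
      phenotypes <- data.frame(proband_id = variants$proband_id,
                               stringsAsFactors = FALSE)
      for (flag in names(phenotype_prevalence)) {
        u <- stats::runif(nrow(phenotypes))
        v <- ifelse(u < nr_rate, "NR",
                    ifelse(stats::runif(nrow(phenotypes)) <
                             phenotype_prevalence[[flag]], "+", "-"))
        phenotypes[[flag]] <- v
      }
    }
    .cohort_table_internal(variants, phenotypes, protein_length)
  })
}

# cohort_table that tolerates zero rows (simulated null cohorts are often
# empty; file readers still reject empty inputs)
.cohort_table_internal <- function(variants, phenotypes, protein_length) {
  if (nrow(variants) == 0L) {
    variants$ref_residue <- character(0)
    variants$codon_index <- integer(0)
    variants$alt_residue <- character(0)
    variants$consequence <- character(0)
    return(structure(list(variants = variants, phenotypes = phenotypes,
                          protein_length = protein_length),
                     class = "rala_cohort"))
  }
  cohort_table(variants, phenotypes, protein_length = protein_length)
}

#' Simulate null de novo counts for many cohorts at once
#'
#' The count-level marginal of [simulate_cohort()]: draws `n_rep`
#' independent `Binomial(2 * n_probands, rate)` counts. Used for calibration
#' studies where only the per-cohort count matters, at a fraction of the cost
#' of materialising full cohort tables.
#'
#' @param n_rep Number of simulated cohorts.
#' @param n_probands Probands per cohort.
#' @param rate Per-chromosome de novo rate.
#' @param seed Integer root seed.
#' @return Integer vector of length `n_rep`.
#' @export
simulate_denovo_counts <- function(n_rep, n_probands = 16086,
                                   rate = 6.16e-6, seed = 1) {
  .with_stream(seed, "counts", stats::rbinom(n_rep, 2L * n_probands, rate))
}

#' Simulate population variant-bearing residues with regional depletion
#'
#' Each residue independently carries a variant with probability `q` outside
#' the region and `depletion_factor * q` inside, where `q` is chosen so that
#' the expected total count equals `n_variant_residues` (under
#' `depletion_factor = 1` this is uniform placement; under factor 0 the
#' expected outside count equals `n_variant_residues` and the region is
#' empty).
#'
#' @param region A `region_annotation`.
#' @param n_variant_residues Target expected number of variant residues.
#' @param depletion_factor Relative per-residue variant odds inside the
#'   region (0 = absolute depletion; 1 = no depletion).
#' @param seed Integer root seed.
#' @return Sorted integer vector of variant-bearing residue indices.
#' @export
simulate_population_variants <- function(region, n_variant_residues = 34,
                                         depletion_factor = 0, seed = 1) {
  stopifnot(inherits(region, "region_annotation"), depletion_factor >= 0)
  L <- region$protein_length
  R <- length(region$residues)
  q <- n_variant_residues / ((L - R) + depletion_factor * R)
  p <- rep(min(q, 1), L)
  p[region$residues] <- min(depletion_factor * q, 1)
  .with_stream(seed, "population", {
    which(stats::runif(L) < p)
  })
}

#' Simulate a PDB structure with a declared ligand-contact set
#'
#' Writes a syntactically valid PDB file with one pseudo-atom (CA) per
#' residue along a straight backbone at `spacing` angstroms, and one ligand
#' atom per declared contact residue placed at a seeded random distance in
#' `[0.6, 0.9] * threshold` from it. By construction the declared residues —
#' and only those — lie within `threshold` of a ligand atom, with a margin of
#' at least `0.1 * threshold` on both sides of the boundary. An empty contact
#' set places a single ligand atom far from every residue.
#'
#' @param n_residues Number of protein residues.
#' @param contact_set Integer vector of residue indices declared in contact.
#' @param threshold Target distance threshold in angstroms. Must satisfy
#'   `0.6 * threshold >= 0.8` (atomic-overlap limit) and
#'   `threshold < spacing`, otherwise the geometry is infeasible and an error
#'   is raised.
#' @param spacing Backbone spacing in angstroms.
#' @param path Output PDB path.
#' @param ligand_code 3-letter heteroatom code for the ligand.
#' @param seed Integer root seed.
#' @return A list with `path`, `contacts` (the declared set), `threshold`
#'   and `n_residues`.
#' @export
simulate_structure <- function(n_residues = 10, contact_set = c(3, 4, 7),
                               threshold = 2.0, spacing = 3.8,
                               path = tempfile(fileext = ".pdb"),
                               ligand_code = "GDP", seed = 1) {
  contact_set <- sort(unique(as.integer(contact_set)))
  if (length(contact_set) &&
      (min(contact_set) < 1L || max(contact_set) > n_residues)) {
    stop("contact_set outside 1..n_residues", call. = FALSE)
  }
  if (0.6 * threshold < 0.8) {
    stop(sprintf(paste("infeasible geometry: declared contacts at %.2f A",
                       "would violate the 0.8 A atomic-overlap limit"),
                 0.6 * threshold), call. = FALSE)
  }
  if (threshold >= spacing) {
    stop("infeasible geometry: threshold must be smaller than the backbone spacing",
         call. = FALSE)
  }
  .with_stream(seed, "structure", {
    px <- cbind(spacing * seq_len(n_residues), 0, 0)
    if (length(contact_set)) {
      d <- stats::runif(length(contact_set), 0.6, 0.9) * threshold
      ang <- stats::runif(length(contact_set), 0, 2 * pi)
      lx <- cbind(spacing * contact_set,
                  d * cos(ang), d * sin(ang))
    } else {
      lx <- cbind(spacing * (n_residues + 10), 50, 50)
    }
    xyz <- rbind(px, lx)
    n_l <- nrow(lx)
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(xyz)),
      type = c(rep("ATOM", n_residues), rep("HETATM", n_l)),
      resno = c(seq_len(n_residues), rep(n_residues + 1L, n_l)),
      resid = c(rep("ALA", n_residues), rep(ligand_code, n_l)),
      eleno = seq_len(n_residues + n_l),
      elety = c(rep("CA", n_residues), sprintf("O%d", seq_len(n_l))),
      elesy = c(rep("C", n_residues), rep("O", n_l)),
      chain = rep("A", n_residues + n_l),
      o = rep(1, n_residues + n_l), b = rep(0, n_residues + n_l))
    list(path = path, contacts = contact_set, threshold = threshold,
         n_residues = n_residues)
  })
}

#' Simulate replicate plate-assay signals
#'
#' Replicate signals are normal with the given group means and standard
#' deviations, truncated at zero (negative draws are rejected and redrawn).
#' The group table must include an NTC row, which anchors normalization.
#'
#' @param groups Data frame with columns `construct`, `mean`, `sd`, `n`.
#' @param assay_type `"gtpase_luminescence"` or `"glisa_absorbance"`.
#' @param seed Integer root seed.
#' @return A `plate_assay`.
#' @export
simulate_assay <- function(groups,
                           assay_type = c("gtpase_luminescence",
                                          "glisa_absorbance"),
                           seed = 1) {
  assay_type <- match.arg(assay_type)
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  stopifnot(all(c("construct", "mean", "sd", "n") %in% names(groups)))
  if (!"NTC" %in% groups$construct) {
    stop("group table must include an NTC row", call. = FALSE)
  }
  .with_stream(seed, "assay", {
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      x <- numeric(g$n)
      for (j in seq_len(g$n)) {
        repeat {
          v <- stats::rnorm(1, g$mean, g$sd)
          if (v >= 0) break
        }
        x[j] <- v
      }
      data.frame(construct = g$construct, replicate = seq_len(g$n),
                 signal = x, stringsAsFactors = FALSE)
    })
    plate_assay(do.call(rbind, rows), assay_type = assay_type)
  })
}

#' Simulate a homologous sequence pair with a known position map
#'
#' Evolves a random ancestor by point substitutions (probability
#' `divergence` per site) and indels (probability `indel_rate` per site,
#' split evenly between a single-residue deletion and a single-residue
#' insertion), recording the ground-truth correspondence between positions of
#' the two sequences. Used to validate alignment-based position mapping.
#'
#' @param length Ancestor length in residues.
#' @param divergence Per-site substitution probability.
#' @param indel_rate Per-site indel probability.
#' @param seed Integer root seed.
#' @return A list with `seq_a`, `seq_b` and `truth` (data frame `a_pos`,
#'   `b_pos`; `b_pos` is `NA` for deleted positions).
#' @export
simulate_homolog_pair <- function(length = 200, divergence = 0.05,
                                  indel_rate = 0.01, seed = 1) {
  stopifnot(length >= 1, divergence >= 0, divergence <= 1,
            indel_rate >= 0, indel_rate < 1)
  .with_stream(seed, "homolog", {
    a <- sample(AA1, length, replace = TRUE)
    b <- character(0)
    b_pos <- integer(length)
    for (i in seq_len(length)) {
      u <- stats::runif(1)
      if (u < indel_rate / 2) {          # deletion of site i
        b_pos[i] <- NA_integer_
        next
      }
      if (u < indel_rate) {              # insertion before site i
        b <- c(b, sample(AA1, 1L))
      }
      res <- a[i]
      if (stats::runif(1) < divergence) {
        res <- sample(setdiff(AA1, res), 1L)
      }
      b <- c(b, res)
      b_pos[i] <- base::length(b)
    }
    list(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""),
         truth = data.frame(a_pos = seq_len(length), b_pos = b_pos))
  })
}
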