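test_that("the residue-level 2x2 table counts variant-bearing residues in and out of region", {
  reg <- region_annotation(1:24, 206)
  tab <- build_depletion_table(reg, 25:58)
  expect_equal(unclass(tab)[1:4], c(0L, 34L, 24L, 148L), ignore_attr = TRUE)
  # multiple variants at one residue count once
  tab2 <- build_depletion_table(reg, c(30, 30, 30, 5))
  expect_identical(tab2[1, 1], 1L)
  expect_identical(tab2[2, 1], 1L)
  # degenerate fills
  expect_identical(build_depletion_table(reg, integer(0))[, 1],
                   c(in_region = 0L, outside = 0L))
  all_var <- build_depletion_table(reg, 1:206)
  expect_identical(all_var[, 2], c(in_region = 0L, outside = 0L))
  expect_error(build_depletion_table(reg, c(5, 300)), "outside")
})

test_that("Fisher two-sided follows the minimum-likelihood convention with a lower tail", {
  ft <- fisher_exact_two_sided(matrix(c(0, 34, 24, 148), 2))
  expect_equal(signif(ft$p_two_sided, 2), 0.017)
  expect_equal(signif(ft$p_lower, 4), signif(0.00986799, 4))
  # diagonal 2x2 with both tables equally probable
  expect_equal(fisher_exact_two_sided(matrix(c(1, 0, 0, 1), 2))$p_two_sided, 1)
  # all-zero table is degenerate
  z <- fisher_exact_two_sided(matrix(0L, 2, 2))
  expect_true(z$degenerate)
  expect_equal(z$p_two_sided, 1)
  expect_error(fisher_exact_two_sided(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("Fisher p-values equal full enumeration and fisher.test on random tables", {
  set.seed(13)
  for (i in 1:200) {
    tab <- random_2x2(60)
    ours <- fisher_exact_two_sided(tab)
    ref <- oracle_fisher(tab)
    expect_equal(ours$p_two_sided, ref$p_two, tolerance = 1e-10)
    expect_equal(ours$p_lower, ref$p_lower, tolerance = 1e-10)
    # point probabilities over the support are a distribution
    expect_equal(sum(ref$point_probs), 1, tolerance = 1e-10)
    # two-sided at least the smaller one-sided tail, both in (0, 1]
    p_upper <- fisher.test(tab, alternative = "greater")$p.value
    expect_gte(ours$p_two_sided + 1e-9, min(ours$p_lower, p_upper))
    expect_gt(ours$p_lower, 0)
    expect_lte(ours$p_two_sided, 1)
    # independent library route
    expect_equal(ours$p_two_sided, fisher.test(tab)$p.value, tolerance = 1e-7)
    expect_equal(ours$p_lower, fisher.test(tab, alternative = "less")$p.value,
                 tolerance = 1e-7)
  }
})

test_that("uniform variant placement keeps the depletion test at nominal size", {
  reg <- region_annotation(1:24, 206)
  n_sim <- 2000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    pv <- simulate_population_variants(reg, n_variant_residues = 34,
                                       depletion_factor = 1, seed = i)
    if (depletion_test(reg, pv)$p_two_sided <= 0.05) rejections <- rejections + 1L
  }
  # allow 3 binomial standard errors above the nominal rate
  expect_lte(rejections / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("absolute depletion at observed scale is usually detected", {
  reg <- region_annotation(1:24, 206)
  n_sim <- 400
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    pv <- simulate_population_variants(reg, n_variant_residues = 34,
                                       depletion_factor = 0, seed = i)
    if (depletion_test(reg, pv)$p_two_sided <= 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / n_sim, 0.5)
})

test_that("PASS-missense filtering drives the population-variant reader", {
  pv <- read_population_variants(
    rala_fixture("rala_population_variants_synthetic.tsv"))
  expect_identical(length(pv), 34L)
  expect_false(25 %in% pv)   # non-PASS record dropped
  expect_false(10 %in% pv)   # synonymous dropped
  expect_false(176 %in% pv)  # nonsense dropped
  expect_identical(sum(duplicated(pv)), 0L)
})

test_that("codon recurrence concentrates the packaged cohort at two codons", {
  rs <- recurrence_summary(table1_cohort())
  expect_identical(rs$total_denovo_alleles, 9L)
  expect_identical(rs$top_codons$codon_index, c(25L, 128L))
  expect_identical(rs$top_codons$count, c(4L, 2L))
  expect_identical(rs$concentrated_alleles, 6L)
})

test_that("recurrence handles single-allele and all-distinct cohorts", {
  co <- table1_cohort()
  single <- cohort_table(co$variants[1, 1:9])
  rs1 <- recurrence_summary(single)
  expect_identical(rs1$concentrated_alleles, 1L)
  expect_identical(rs1$total_denovo_alleles, 1L)
  distinct <- co$variants[co$variants$proband_id %in%
                            c("P1", "P6", "P8", "P9"), 1:9]
  rs2 <- recurrence_summary(cohort_table(distinct))
  expect_identical(rs2$total_denovo_alleles, 4L)
  expect_identical(rs2$concentrated_alleles, 2L)
  # ties broken by ascending codon index
  expect_identical(rs2$top_codons$codon_index, c(25L, 128L))
})

test_that("the optional recurrence permutation test is seeded and sane", {
  p1 <- recurrence_permutation_test(table1_cohort(), n_perm = 2000, seed = 4)
  p2 <- recurrence_permutation_test(table1_cohort(), n_perm = 2000, seed = 4)
  expect_identical(p1, p2)
  expect_lt(p1$p_value, 0.01)  # 6/9 at two codons of 206 is extreme
  expect_identical(p1$observed_concentrated, 6L)
})
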