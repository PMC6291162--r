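test_that("generators are pure functions of their seed", {
  c1 <- simulate_cohort(n_probands = 2000, denovo_rate = 0.002, seed = 5)
  c2 <- simulate_cohort(n_probands = 2000, denovo_rate = 0.002, seed = 5)
  expect_identical(c1$variants, c2$variants)
  expect_false(identical(
    c1$variants,
    simulate_cohort(n_probands = 2000, denovo_rate = 0.002, seed = 6)$variants))

  p1 <- simulate_population_variants(region_annotation(1:24, 206), seed = 9)
  p2 <- simulate_population_variants(region_annotation(1:24, 206), seed = 9)
  expect_identical(p1, p2)

  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  simulate_structure(8, c(2, 5), path = f1, seed = 3)
  simulate_structure(8, c(2, 5), path = f2, seed = 3)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  unlink(c(f1, f2))

  a1 <- simulate_assay(data.frame(construct = c("NTC", "WT"),
                                  mean = c(100, 50), sd = 3, n = 3), seed = 8)
  a2 <- simulate_assay(data.frame(construct = c("NTC", "WT"),
                                  mean = c(100, 50), sd = 3, n = 3), seed = 8)
  expect_identical(a1$wells, a2$wells)

  h1 <- simulate_homolog_pair(seed = 12)
  h2 <- simulate_homolog_pair(seed = 12)
  expect_identical(h1, h2)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_cohort(n_probands = 100, denovo_rate = 0.01, seed = 1))
  invisible(simulate_structure(5, 2, seed = 1))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("a zero mutation rate yields an empty cohort that still summarizes", {
  co <- simulate_cohort(n_probands = 1000, denovo_rate = 0, seed = 1)
  expect_identical(nrow(co$variants), 0L)
  expect_identical(observed_denovo(co), 0L)
  expect_identical(nrow(collapse_families(co)), 0L)
  rs <- recurrence_summary(co)
  expect_identical(rs$total_denovo_alleles, 0L)
})

test_that("simulated de novo counts follow the binomial null", {
  counts <- simulate_denovo_counts(10000, n_probands = 16086,
                                   rate = 6.16e-6, seed = 23)
  lambda <- 2 * 16086 * 6.16e-6
  # mean within 3 standard errors of the null expectation
  se <- sqrt(lambda / 10000)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # chi-square goodness of fit on binned counts at alpha = 0.01
  probs <- dbinom(0:2, 32172, 6.16e-6)
  probs <- c(probs, 1 - sum(probs))
  obs <- tabulate(pmin(counts, 3) + 1L, nbins = 4L)
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("recurrence hotspots concentrate simulated alleles", {
  co <- simulate_cohort(n_probands = 5000, denovo_rate = 0.01,
                        hotspot_codons = c(25, 128), hotspot_weight = 0.7,
                        seed = 2)
  rs <- recurrence_summary(co)
  expect_gt(rs$concentrated_alleles / rs$total_denovo_alleles, 0.5)
  expect_true(all(rs$top_codons$codon_index %in% c(25L, 128L)))
})

test_that("population-variant placement respects the depletion factor", {
  reg <- region_annotation(1:24, 206)
  # absolute depletion: never inside the region
  for (seed in 1:50) {
    pv <- simulate_population_variants(reg, 34, depletion_factor = 0,
                                       seed = seed)
    expect_identical(sum(pv %in% reg$residues), 0L)
  }
  # saturation: every residue variant
  pv_all <- simulate_population_variants(reg, 206, depletion_factor = 1,
                                         seed = 1)
  expect_identical(pv_all, 1:206)
  # uniform placement hits the region proportionally on average
  hits <- vapply(1:400, function(s) {
    sum(simulate_population_variants(reg, 34, depletion_factor = 1,
                                     seed = s) %in% reg$residues)
  }, 0)
  expect_lt(abs(mean(hits) - 34 * 24 / 206), 3 * sqrt(34 * (24 / 206) / 400))
})

test_that("infeasible structure geometries are refused", {
  expect_error(simulate_structure(10, 3, threshold = 1.0),
               "atomic-overlap")
  expect_error(simulate_structure(10, 3, threshold = 4.0, spacing = 3.8),
               "spacing")
  expect_error(simulate_structure(10, 12, threshold = 2.0),
               "contact_set")
})

test_that("truncated assay signals stay nonnegative and honour sd = 0", {
  exact <- simulate_assay(data.frame(construct = c("NTC", "WT"),
                                     mean = c(100, 50), sd = 0, n = 3),
                          seed = 1)
  expect_equal(exact$wells$signal, c(100, 100, 100, 50, 50, 50))
  noisy <- simulate_assay(data.frame(construct = c("NTC", "WT"),
                                     mean = c(2, 1), sd = 5, n = 50),
                          seed = 4)
  expect_true(all(noisy$wells$signal >= 0))
  expect_error(simulate_assay(data.frame(construct = "WT", mean = 1,
                                         sd = 0, n = 2)), "NTC")
})
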