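make_gtpase <- function(signals) {
  rows <- do.call(rbind, lapply(names(signals), function(g) {
    data.frame(construct = g, replicate = seq_along(signals[[g]]),
               signal = signals[[g]], stringsAsFactors = FALSE)
  }))
  plate_assay(rows, "gtpase_luminescence")
}

make_glisa <- function(signals) {
  pa <- make_gtpase(signals)
  pa$assay_type <- "glisa_absorbance"
  pa
}

test_that("GTPase normalization anchors NTC at zero activity", {
  pa <- make_gtpase(list(NTC = c(900, 1100), WT = c(1000, 0, 250)))
  nz <- normalize_gtpase(pa)
  wt <- nz$value[nz$construct == "WT"]
  expect_equal(wt, c(0, 100, 75))  # = NTC mean, total consumption, 25% of NTC
  expect_equal(mean(nz$value[nz$construct == "NTC"]), 0)
  expect_error(normalize_gtpase(make_gtpase(list(NTC = c(0, 0), WT = 1))),
               "NTC mean")
})

test_that("G-LISA normalization reports fold over NTC with optional protein correction", {
  pa <- make_glisa(list(NTC = c(0.2, 0.2), WT = 0.2, G23D = 0.4))
  nz <- normalize_glisa(pa)
  expect_equal(nz$value[nz$construct == "WT"], 1.0)
  expect_equal(nz$value[nz$construct == "G23D"], 2.0)
  west <- data.frame(construct = "WT", relative_intensity = 0.5)
  nz2 <- normalize_glisa(pa, western = west)
  expect_equal(nz2$value[nz2$construct == "WT"], 2.0)
  expect_equal(nz2$value[nz2$construct == "G23D"], 2.0)  # uncorrected
})

test_that("normalization is invariant to rescaling all raw signals", {
  sig <- list(NTC = c(100, 120, 95), WT = c(40, 38, 45), MUT = c(90, 99, 85))
  for (c_factor in c(0.01, 3, 1000)) {
    a1 <- normalize_gtpase(make_gtpase(sig))
    a2 <- normalize_gtpase(make_gtpase(lapply(sig, `*`, c_factor)))
    expect_equal(a1$value, a2$value)
    g1 <- normalize_glisa(make_glisa(sig))
    g2 <- normalize_glisa(make_glisa(lapply(sig, `*`, c_factor)))
    expect_equal(g1$value, g2$value)
  }
})

test_that("group comparisons are two-sided Welch tests with star tiers", {
  nz <- normalize_gtpase(make_gtpase(list(
    NTC = c(100, 101, 99), WT = c(20, 22, 18), MUT = c(80, 84, 76))))
  res <- compare_groups(nz, reference = "WT")
  mut <- res[res$construct == "MUT", ]
  x <- nz$value[nz$construct == "MUT"]
  y <- nz$value[nz$construct == "WT"]
  expect_equal(mut$p_value, oracle_welch_p(x, y), tolerance = 1e-10)
  expect_equal(mut$p_value, t.test(x, y)$p.value, tolerance = 1e-12)
  expect_equal(mut$mean, mean(x))
  expect_equal(mut$sem, sd(x) / sqrt(3))
  # identical groups compare as equal
  same <- compare_groups(normalize_gtpase(make_gtpase(list(
    NTC = c(100, 100), WT = c(50, 60), EQ = c(50, 60)))), "WT")
  expect_equal(same$p_value[same$construct == "EQ"], 1.0)
  expect_identical(same$tier[same$construct == "EQ"], "ns")
})

test_that("Welch p-values match the closed form across random groups", {
  set.seed(31)
  for (i in 1:40) {
    x <- rnorm(sample(2:8, 1), mean = runif(1, 0, 100), sd = runif(1, 0.5, 20))
    y <- rnorm(sample(2:8, 1), mean = runif(1, 0, 100), sd = runif(1, 0.5, 20))
    d <- data.frame(construct = c(rep("A", length(x)), rep("WT", length(y))),
                    value = c(x, y))
    res <- compare_groups(d, "WT")
    expect_equal(res$p_value[res$construct == "A"], oracle_welch_p(x, y),
                 tolerance = 1e-10)
  }
})

test_that("significance tiers map p-value ranges to the conventional stars", {
  expect_identical(as.character(significance_tier(
    c(5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 0.04, 0.05, 0.5))),
    c("****", "***", "***", "**", "**", "*", "*", "ns", "ns"))
})

test_that("single-replicate groups are skipped with a warning", {
  nz <- normalize_gtpase(make_gtpase(list(
    NTC = c(100, 100), WT = c(50, 52), LONE = 10)))
  expect_warning(res <- compare_groups(nz, "WT"), "LONE.*skipped")
  expect_true(is.na(res$p_value[res$construct == "LONE"]))
  expect_error(compare_groups(
    normalize_gtpase(make_gtpase(list(NTC = c(1, 1), WT = 5))), "WT"),
    ">= 2 replicates")
})

test_that("strongly separated simulated groups are highly significant", {
  # triplicates with sd 5 on an 80-point separation: the Welch statistic is
  # huge but its df is only ~2-4, so the p-value lands around 1e-5..1e-3;
  # assert agreement with the closed form and clear significance
  groups <- data.frame(construct = c("NTC", "WT", "MUT"),
                       mean = c(100, 100, 20), sd = c(5, 5, 5), n = 3)
  pa <- simulate_assay(groups, "gtpase_luminescence", seed = 17)
  nz <- normalize_gtpase(pa)
  res <- compare_groups(nz, "WT")
  mut_p <- res$p_value[res$construct == "MUT"]
  expect_equal(mut_p, oracle_welch_p(nz$value[nz$construct == "MUT"],
                                     nz$value[nz$construct == "WT"]),
               tolerance = 1e-10)
  expect_lt(mut_p, 0.01)
  # at tight replicate noise the comparison reaches the top tier
  tight <- simulate_assay(data.frame(construct = c("NTC", "WT", "MUT"),
                                     mean = c(100, 100, 20), sd = 1, n = 3),
                          "gtpase_luminescence", seed = 17)
  res_t <- compare_groups(normalize_gtpase(tight), "WT")
  expect_identical(res_t$tier[res_t$construct == "MUT"], "****")
})

test_that("assay CSVs round-trip through the long-format reader", {
  pa <- simulate_assay(data.frame(construct = c("NTC", "WT"),
                                  mean = c(100, 40), sd = 2, n = 3),
                       "gtpase_luminescence", seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- cbind(assay = "gtpase_luminescence", pa$wells)
  write.csv(out, path, row.names = FALSE)
  back <- read_assay_csv(path)
  expect_named(back, "gtpase_luminescence")
  expect_equal(back[[1]]$wells$signal, pa$wells$signal)
})
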