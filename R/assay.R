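# Normalization and group comparison for GTPase-activity (luminescence) and
# effector-binding (G-LISA absorbance) plate assays.
#
# GTPase assay: luminescence measures remaining free GTP, so the no-template
# control (NTC, no enzyme) defines 100% remaining GTP. Raw signals are first
# rescaled so the NTC mean is 100, then activity = 100 - rescaled signal:
# the NTC anchors zero activity by construction, and a well consuming all
# GTP scores 100.
#
# G-LISA: absorbance is divided by the NTC mean (baseline binding = 1), with
# an optional division by relative Western band intensity to correct for
# differences in purified protein amount.

.assay_types <- c("gtpase_luminescence", "glisa_absorbance")

#' Construct a plate-assay object
#'
#' @param wells Data frame with columns `construct` (e.g. `"NTC"`, `"WT"`,
#'   `"G23D"`, ...), `replicate` (index), `signal` (nonnegative raw reading)
#'   and optionally `assay`; or pass `assay_type` separately.
#' @param assay_type `"gtpase_luminescence"` or `"glisa_absorbance"`.
#' @return An object of class `plate_assay`.
#' @export
plate_assay <- function(wells, assay_type = c("gtpase_luminescence",
                                              "glisa_absorbance")) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  if ("assay" %in% names(wells) && missing(assay_type)) {
    assay_type <- unique(wells$assay)
  }
  assay_type <- match.arg(assay_type[1], .assay_types)
  need <- c("construct", "replicate", "signal")
  if (!all(need %in% names(wells))) {
    stop("well table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  wells$signal <- as.numeric(wells$signal)
  if (any(!is.finite(wells$signal)) || any(wells$signal < 0)) {
    stop("raw signals must be finite and nonnegative", call. = FALSE)
  }
  if (!"NTC" %in% wells$construct) {
    stop("assay must include an NTC (no template control) group",
         call. = FALSE)
  }
  structure(list(wells = wells[, need], assay_type = assay_type),
            class = "plate_assay")
}

#' Read a long-format assay CSV
#'
#' Columns: `assay`, `construct`, `replicate`, `signal` — the simple export
#' format of a raw plate-data workbook.
#'
#' @param path CSV path.
#' @return A list of `plate_assay` objects, one per assay type present.
#' @export
read_assay_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("assay", "construct", "replicate", "signal")
  if (!all(need %in% names(tab))) {
    stop("assay CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(tab, tab$assay), function(d) {
    plate_assay(d, assay_type = d$assay[1])
  })
}

.ntc_mean <- function(assay) {
  ntc <- assay$wells$signal[assay$wells$construct == "NTC"]
  m <- mean(ntc)
  if (!is.finite(m) || m <= 0) {
    stop("NTC mean signal must be positive for normalization", call. = FALSE)
  }
  m
}

#' Normalize a GTPase-activity luminescence assay
#'
#' Signals are rescaled so that the NTC mean equals 100 (percent remaining
#' GTP), then activity per well is `100 - rescaled signal`. NTC activity is 0
#' on average by construction; a well that consumed all GTP scores 100.
#'
#' @param assay A `plate_assay` of type `gtpase_luminescence`.
#' @return An object of class `plate_norm`: the well table with `scaled` and
#'   `value` (activity) columns; attributes record the NTC mean and value
#'   label.
#' @export
normalize_gtpase <- function(assay) {
  stopifnot(inherits(assay, "plate_assay"))
  if (assay$assay_type != "gtpase_luminescence") {
    stop("normalize_gtpase() expects a gtpase_luminescence assay",
         call. = FALSE)
  }
  ntc <- .ntc_mean(assay)
  w <- assay$wells
  w$scaled <- 100 * w$signal / ntc
  w$value <- 100 - w$scaled
  structure(w, class = c("plate_norm", "data.frame"),
            assay_type = assay$assay_type, ntc_mean = ntc,
            value_label = "activity (% GTP consumed, NTC-anchored)")
}

#' Normalize an effector-binding (G-LISA) absorbance assay
#'
#' Binding per well is the raw absorbance divided by the NTC mean (baseline
#' binding = 1). When `western` is supplied, each construct's binding is
#' additionally divided by its relative band intensity, correcting for
#' differences in purified protein amount; the uncorrected values are what
#' you get by omitting `western`.
#'
#' @param assay A `plate_assay` of type `glisa_absorbance`.
#' @param western Optional data frame with columns `construct` and
#'   `relative_intensity` (relative Western band intensities).
#' @return A `plate_norm` data frame with a `value` (binding) column.
#' @export
normalize_glisa <- function(assay, western = NULL) {
  stopifnot(inherits(assay, "plate_assay"))
  if (assay$assay_type != "glisa_absorbance") {
    stop("normalize_glisa() expects a glisa_absorbance assay", call. = FALSE)
  }
  ntc <- .ntc_mean(assay)
  w <- assay$wells
  w$value <- w$signal / ntc
  corrected <- FALSE
  if (!is.null(western)) {
    western <- as.data.frame(western, stringsAsFactors = FALSE)
    stopifnot(all(c("construct", "relative_intensity") %in% names(western)))
    fac <- stats::setNames(as.numeric(western$relative_intensity),
                           western$construct)
    if (any(!is.finite(fac)) || any(fac <= 0)) {
      stop("relative_intensity values must be positive", call. = FALSE)
    }
    idx <- w$construct %in% names(fac)
    w$value[idx] <- w$value[idx] / fac[w$construct[idx]]
    corrected <- TRUE
  }
  structure(w, class = c("plate_norm", "data.frame"),
            assay_type = assay$assay_type, ntc_mean = ntc,
            western_corrected = corrected,
            value_label = "binding (fold over NTC)")
}

#' Significance tier for a p-value
#'
#' The conventional star tiers: `****` p < 0.0001, `***` p < 0.001,
#' `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE)
}

#' Compare constructs to a reference group (Welch t-tests)
#'
#' Two-sided Welch (unequal-variance) t-test of each construct against the
#' reference group, with the conventional star tiers. Constructs with fewer
#' than two replicates are skipped with a warning (a variance cannot be
#' estimated). Both `sd` and `sem` are reported since published error bars
#' may be either.
#'
#' @param normalized A `plate_norm` data frame (from [normalize_gtpase()] or
#'   [normalize_glisa()]), or any data frame with `construct` and `value`.
#' @param reference Reference construct label (`"WT"` or `"NTC"`).
#' @return A data frame of class `assay_comparison`: `construct`, `n`,
#'   `mean`, `sd`, `sem`, `p_value` (vs reference), `tier`.
#' @export
compare_groups <- function(normalized, reference = "WT") {
  d <- as.data.frame(normalized)
  stopifnot(all(c("construct", "value") %in% names(d)))
  if (!reference %in% d$construct) {
    stop(sprintf("reference group '%s' not present", reference),
         call. = FALSE)
  }
  ref <- d$value[d$construct == reference]
  if (length(ref) < 2L) {
    stop(sprintf("reference group '%s' needs >= 2 replicates", reference),
         call. = FALSE)
  }
  groups <- split(d$value, d$construct)
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    out <- data.frame(construct = g, n = length(v), mean = mean(v),
                      sd = stats::sd(v), sem = stats::sd(v) / sqrt(length(v)),
                      p_value = NA_real_, stringsAsFactors = FALSE)
    if (g == reference) return(out)
    if (length(v) < 2L) {
      warning(sprintf("construct '%s' has < 2 replicates; comparison skipped",
                      g), call. = FALSE)
      return(out)
    }
    if (stats::sd(v) == 0 && stats::sd(ref) == 0) {
      # degenerate Welch statistic; identical constants compare as equal
      out$p_value <- if (isTRUE(all.equal(mean(v), mean(ref)))) 1 else 0
      return(out)
    }
    out$p_value <- stats::t.test(v, ref, alternative = "two.sided",
                                 var.equal = FALSE)$p.value
    out
  })
  res <- do.call(rbind, rows)
  res$tier <- as.character(significance_tier(res$p_value))
  res$tier[is.na(res$p_value)] <- NA_character_
  res <- res[order(res$construct != reference, res$construct), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "reference") <- reference
  class(res) <- c("assay_comparison", "data.frame")
  res
}

#' @export
print.assay_comparison <- function(x, ...) {
  cat(sprintf("Group comparison vs %s (two-sided Welch t-tests)\n",
              attr(x, "reference")))
  y <- as.data.frame(x)
  y$mean <- signif(y$mean, 4); y$sd <- signif(y$sd, 3)
  y$sem <- signif(y$sem, 3); y$p_value <- signif(y$p_value, 3)
  print(y, row.names = FALSE)
  invisible(x)
}
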