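# Independent oracles, kept deliberately naive: direct summation and
# closed-form expressions that do not share code with the package internals.

# binomial upper tail by direct term-by-term summation (small n only)
oracle_binom_tail <- function(k, n, p) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}

# Poisson upper tail by direct summation, far past the mode
oracle_pois_tail <- function(k, lambda, extra = 400) {
  if (k == 0) return(1)
  i <- k:(k + extra)
  sum(exp(i * log(lambda) - lambda - lfactorial(i)))
}

# Fisher 2x2: full enumeration over the hypergeometric support using
# log-binomial coefficients (minimum-likelihood two-sided convention)
oracle_fisher <- function(tab, tie_tol = 1e-7) {
  x <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  lp_obs <- logp[support == x]
  list(p_two = sum(exp(logp[logp <= lp_obs + log1p(tie_tol)])),
       p_lower = sum(exp(logp[support <= x])),
       point_probs = exp(logp))
}

# Welch two-sample t-test from the closed-form statistic
oracle_welch_p <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * pt(-abs(tstat), df)
}

# random 2x2 tables with a bounded total, for exhaustive-style comparisons
random_2x2 <- function(total_max = 60) {
  n <- sample.int(total_max - 3, 1) + 3
  cells <- as.integer(rmultinom(1, n, prob = runif(4, 0.05, 1)))
  matrix(cells, 2, 2)
}

# a minimal structure_model built directly (for geometric edge cases)
make_structure <- function(prot_xyz, lig_xyz, lig_code = "GDP") {
  n <- nrow(prot_xyz); m <- nrow(lig_xyz)
  atoms <- data.frame(
    chain = "A",
    resno = c(seq_len(n), rep(n + 1L, m)),
    resid = c(rep("ALA", n), rep(lig_code, m)),
    elety = c(rep("CA", n), sprintf("O%d", seq_len(m))),
    elesy = c(rep("C", n), rep("O", m)),
    x = c(prot_xyz[, 1], lig_xyz[, 1]),
    y = c(prot_xyz[, 2], lig_xyz[, 2]),
    z = c(prot_xyz[, 3], lig_xyz[, 3]),
    het = c(rep(FALSE, n), rep(TRUE, m)),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, ligand_codes = lig_code),
            class = "structure_model")
}

# hand-written PDB fixture with alternate locations: residue 1 has CA in two
# altlocs (A occ 0.40 at x=10, B occ 0.60 at x=14); residue 2 a single CA;
# one GDP atom. 4 raw atom records -> 3 after altloc resolution.
write_altloc_pdb <- function(path) {
  fmt <- "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- c(
    sprintf(fmt, "ATOM", 1L, " CA ", "A", "ALA", "A", 1L, 10, 0, 0, 0.40, 10, "C"),
    sprintf(fmt, "ATOM", 2L, " CA ", "B", "ALA", "A", 1L, 14, 0, 0, 0.60, 10, "C"),
    sprintf(fmt, "ATOM", 3L, " CA ", "", "GLY", "A", 2L, 20, 0, 0, 1.00, 10, "C"),
    sprintf(fmt, "HETATM", 4L, " PA ", "", "GDP", "A", 9L, 15, 1, 0, 1.00, 10, "P"),
    "END")
  writeLines(lines, path)
  path
}

# rigid motion: random rotation (QR-orthogonalised) + translation
apply_rigid_motion <- function(sm, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, sd = 20)
  xyz <- as.matrix(sm$atoms[, c("x", "y", "z")]) %*% q
  sm$atoms$x <- xyz[, 1] + shift[1]
  sm$atoms$y <- xyz[, 2] + shift[2]
  sm$atoms$z <- xyz[, 3] + shift[3]
  sm
}
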