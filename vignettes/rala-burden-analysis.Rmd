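---
title: "Methods: de novo burden and binding-region analysis for RALA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo burden and binding-region analysis for RALA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ralascope)
```

This vignette documents the models, conventions and design choices behind
the package. It is the place where every "why" lives; function reference
pages document the "how".

## The burden model

A cohort of `N` proband–parent trios screens `2N` transmitted chromosomes.
Under the null hypothesis of no disease association, the number of
qualifying de novo events (missense, nonsense, in-frame deletion) in a gene
is

$$X \sim \mathrm{Binomial}(2N, \mu),$$

where $\mu$ is a published gene-level per-chromosome mutation rate derived
from gene length and trinucleotide context. The package treats $\mu$ as an
input constant: estimating mutation-rate models is a different problem with
different data requirements, and re-deriving a published rate would only
obscure provenance. The test is the exact one-sided upper tail
$P(X \ge k)$ with the observed value included and no mid-p correction — the
conservative convention for discrete counts. A Poisson tail at
$\lambda = 2N\mu$ is always reported beside the binomial one; in the regime
of interest ($N \sim 10^4$, $2N\mu \ll 1$) the two agree to within 2%, and
the comparison is a useful self-check on both code paths.

**Counting the observed events.** The unit is the family, not the proband:
monozygotic twins share one germline mutational event and collapse to a
single allele (`collapse_families()`). Variants of unknown inheritance are
excluded. One subtlety matters in the packaged RALA configuration: the full
cohort table carries nine twin-collapsed de novo family alleles, but only
eight of those families were ascertained within the systematically screened
trio cohorts that define the denominator of 16,086 probands; the ninth was
found outside them. A burden test must keep numerator and denominator on the
same footing, so the packaged configuration tests 8 observed events against
32,172 alleles while the recurrence summary — a statement about the cohort
itself, not about screening — uses all nine alleles. `observed_denovo()`
accepts a site filter for exactly this distinction.

**Numerics.** Tail probabilities are computed by log-space summation of the
point mass (via `dbinom(..., log = TRUE)`/`dpois(..., log = TRUE)` and a
log-sum-exp reduction) from $k$ up to an explicit truncation point beyond
the mode, chosen so that a geometric bound on the omitted mass is below
$10^{-15}$ of the accumulated sum; the bound is re-checked and the window
doubled if necessary. This keeps p-values of order $10^{-11}$ (and far
smaller) exact to double precision without summing tens of thousands of
negligible terms. Tests verify equality with naive term-by-term summation to
$10^{-12}$ relative for $n \le 50$ and with `pbinom`/`ppois` on large
problems.

Because the published rate is printed to three significant figures and
enters an eighth-order tail, the final p-value inherits a relative
uncertainty of roughly 1%; comparisons against previously printed p-values
should allow for that input rounding.

## Binding-region annotation

A residue belongs to the ligand-binding region iff any of its atoms (side
chain or backbone) lies within a distance threshold of any ligand atom,
boundary inclusive. Choices and their reasons:

- **Threshold, default 1.5 Å, configurable.** Over heavy atoms 1.5 Å is
  physically very tight — heavy-atom hydrogen-bond distances run
  2.5–3.5 Å — and annotation sets published from hydrogen-added models are
  generally not reproducible from the deposited heavy-atom structure at the
  same cutoff. The package therefore never hard-codes any published residue
  set; for published-number comparisons the region is a user-supplied
  residue list.
- **Heavy atoms by default** (`include_hydrogens = FALSE`), since crystal
  structures usually lack hydrogens; the flag includes them when present.
- **Alternate locations** resolve to the highest-occupancy copy per atom
  (first on ties). Waters are never ligands.
- **Multiple ligand copies** contribute the union of their contacts —
  conservative and deterministic.
- **Numbering offset** between structure and sequence coordinates is an
  explicit integer (`offset`, default 0); the package shifts but does not
  guess.

The packaged `rala_region24_synthetic.txt` is an illustrative 24-residue set
assembled from the canonical G-box motifs, *not* a published annotation; it
exists so the depletion analysis runs offline at the published table sizes.

## Regional depletion and recurrence

Depletion is tested at residue level: each residue either carries at least
one high-quality (PASS) population missense variant or it does not. This
mirrors how population summaries report "variants observed at x of y
residues" and makes the 2×2 table margins well-defined regardless of allele
counts. The two-sided Fisher p-value follows the minimum-likelihood
convention — sum the hypergeometric point probabilities of all
margin-preserving tables no more likely than the observed one, with a
relative tie tolerance of $10^{-7}$ — which is also R's `fisher.test`
convention; the one-sided lower tail (the depletion direction) is always
reported beside it, because the sidedness convention materially changes the
number (about 0.017 two-sided vs 0.0099 one-sided on the packaged table)
and readers should see both. The all-zero table is degenerate and returns
p = 1 with a flag. Tests verify the implementation against a full
`lchoose`-based enumeration oracle to $10^{-10}$ and against `fisher.test`.

Recurrence — how many family alleles sit at the two most recurrent codons —
is reported descriptively, because the headline claim is descriptive.
A seeded uniform-reassignment permutation test is provided
(`recurrence_permutation_test()`) but labelled an extension.

## Paralog mapping

Positions map between homologs through an explicit global alignment
(BLOSUM62, gap open 11, gap extend 1 — the ubiquitous protein defaults;
configurable), rather than through any published numbering equivalences, so
disagreements are detectable. Alignment is delegated to
`Biostrings::pairwiseAlignment`; tie-breaking among co-optimal alignments is
its deterministic traceback. At RAL/RAS-level identity (~45–50%) the mapped
anchors are robust to reasonable scoring choices.

The packaged `gtpase_paralogs_reconstructed.fa` contains *reconstructed*
RALA/HRAS/KRAS sequences, labelled as such in the file name and headers.
They satisfy every independently checkable anchor (lengths; residue
identities at all cohort positions; the C-terminal CAAX motif), but users
with network access should fetch canonical records
(`fetch_paralog_sequences()`) and verify against UniProt
P11233/P01112/P01116 before any canonical use.

## Assay normalization

The GTPase assay reads remaining free GTP as luminescence, so the
no-template control (no enzyme) defines 100% remaining GTP. Signals are
first rescaled so the NTC mean is 100, then activity = 100 − rescaled
signal. This is the only reading under which "subtract from 100 and
normalize to NTC" makes the NTC the zero-activity anchor; the rescaling is
recorded in the output attributes. G-LISA absorbance divides by the NTC mean
(baseline binding = 1), with optional division by relative Western band
intensity to correct for protein amounts; both corrected and uncorrected
values are obtainable. Both normalizations are invariant to rescaling all
raw signals, which tests assert.

Group comparisons use two-sided Welch t-tests — no test is canonical for
triplicate plate data, and Welch avoids the equal-variance assumption — with
the conventional star tiers (`****` < 1e-4 ≤ `***` < 1e-3 ≤ `**` < 1e-2 ≤
`*` < 0.05 ≤ ns). Both `sd` and `sem` are reported since published error
bars may be either. A caution from the package's own testing: with
triplicates the Welch degrees of freedom are only ~2–4, so even an
enormous mean separation (e.g. 80 units at sd 5) can realize p-values
anywhere from ~1e-5 to ~1e-3; expecting a specific star tier from n = 3 is
unreliable unless replicate noise is very small.

## What the generators emulate — and what they do not

- `simulate_cohort()` draws the de novo count from the binomial null
  (optionally concentrating codons at hotspots and injecting monozygotic
  twins). It emulates count structure, recurrence and twin collapsing — not
  sequence context, variant spectra, or ascertainment bias.
- `simulate_population_variants()` places variant-bearing residues
  independently per residue with in-region odds scaled by a depletion
  factor, calibrated so the expected total equals the configured count under
  uniform placement (and the expected outside count equals it under absolute
  depletion). Real population data have allele-frequency structure and
  mutability heterogeneity that this ignores.
- `simulate_structure()` writes residues along a straight backbone at 3.8 Å
  spacing and plants one ligand atom per declared contact at a seeded
  distance in [0.6, 0.9] × threshold, guaranteeing a ≥ 0.1 × threshold
  margin on both sides of the decision boundary. Geometry is declared
  infeasible (an error) if placements would fall under a 0.8 Å
  atomic-overlap limit or the threshold reaches the backbone spacing. It
  validates the contact rule, not crystallographic realism.
- `simulate_assay()` draws replicates from zero-truncated normals;
  `simulate_homolog_pair()` evolves a random ancestor with tracked
  substitutions and single-residue indels, providing ground-truth position
  maps.

Each generator consumes its own stream derived from one root seed
(root × 16 + a fixed stream id), so adding a generator never perturbs the
others, and the caller's RNG state is restored afterwards. Passing tests on
these generators demonstrates correctness of the statistical machinery under
the stated models — not robustness to the messiness of real cohorts,
population databases or crystal structures.

## Problem sizes used by the test suite

The suite favours exhaustive checks where they are cheap: 200 random 2×2
tables against the enumeration oracle, 60 small-n binomial tails against
naive summation, 100 seeded structures for exact contact recovery, 2,000
uniform-placement proteins for depletion-test size, 10,000 simulated cohorts
at full study scale (16,086 trios) for burden calibration — the count-level
generator makes the last of these effectively free. The whole suite runs in
well under a minute.

## Known limitations

- The HGVS dialect is deliberately minimal: single-residue substitutions,
  single-residue deletions and stops. Frameshifts, splice variants and
  multi-residue events are rejected, loudly.
- The burden model assumes autosomal inheritance (2 chromosomes per
  proband); X-linked genes need a different allele count.
- A premature-stop truncation length is reported under both common counting
  conventions (`truncation_extent()`: residues at-and-after the stop, and
  strictly after), because published reports are inconsistent; for a stop at
  codon 176 of 206 these are 31 and 30.
- The depletion test conditions on the observed number of variant-bearing
  residues (fixed margins); it does not model mutability differences between
  regions.
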