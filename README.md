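# ralascope

Statistical and structural analysis of de novo variation in a candidate
dominant disease gene, built around the small GTPase **RALA**. The package is
aimed at clinical-genomics and rare-disease researchers who assemble trio
sequencing cohorts (e.g. via matchmaking platforms) and need to quantify, for
one gene, whether the observed de novo variants exceed the mutational null,
whether they cluster in a functionally critical region, and how they relate
to known disease alleles in paralogous genes and to in vitro activity.

## What it computes

**De novo burden.** With `N` screened probands, `2N` transmitted chromosomes
are at risk, and under the null the de novo count for a gene is
`X ~ Binomial(2N, mu)` where `mu` is the published per-chromosome mutation
rate for qualifying (missense + loss-of-function) events. The test is the
exact one-sided upper tail `P(X >= k)`, computed by log-space summation with
an explicit truncation bound so p-values of order 1e-11 do not underflow; a
Poisson upper tail at `lambda = 2N*mu` is reported as a cross-check.
Monozygotic twins collapse to a single family-level allele before counting.

**Regional clustering.** A GTP/GDP-binding region is annotated geometrically
from a ligand-bound structure: a residue is in the region iff any of its
atoms lies within a distance threshold (default 1.5 angstroms, configurable;
heavy atoms by default) of any ligand atom. Depletion of population missense
variation from the region is tested at residue level with Fisher's exact
test on the 2x2 table (in/out of region x variant-bearing or not), using the
minimum-likelihood two-sided convention, with the one-sided lower tail also
reported. Codon-level recurrence of cohort alleles is summarized
descriptively, with an optional seeded permutation test.

**Paralog mapping.** Global pairwise alignment (BLOSUM62, affine gaps) maps
residue positions onto RAS-family paralogs and cross-references a table of
known disease-associated positions.

**Assay normalization.** GTPase-activity luminescence is rescaled so the
no-template control (NTC) mean is 100 and activity = 100 − rescaled signal;
G-LISA effector-binding absorbance is divided by the NTC mean, optionally
corrected by relative Western band intensity. Constructs are compared with
two-sided Welch t-tests and the conventional star tiers.

Every input has a seeded synthetic generator (`simulate_cohort()`,
`simulate_population_variants()`, `simulate_structure()`,
`simulate_assay()`, `simulate_homolog_pair()`), so the full pipeline is
testable offline.

## Worked example

The package ships a transcription of the published cohort table (eleven
probands, ten families, probands 4 and 5 monozygotic twins) plus synthetic
region and population-variant fixtures sized to the published analysis.

```r
library(ralascope)

cohort <- table1_cohort()
recurrence_summary(cohort)
#> Recurrence: 6 of 9 de novo family alleles at the top-2 codons (25: 4, 128: 2)

phenotype_fraction(cohort, "weight_lastexam_le10")
#> weight_lastexam_le10: 8/11 (73%)

# 8 of the de novo families were ascertained within screened trio cohorts
# totalling 16,086 probands; the published per-chromosome rate is 6.16e-6
denovo_burden(observed = 8, n_probands = 16086, rate = 6.16e-6)
#> De novo burden test (one-sided, exact)
#>   8 observed de novo alleles in 32172 screened alleles (16086 probands)
#>   expected 0.198 at rate 6.16e-06 per chromosome (fold 40.4)
#>   exact binomial p = 4.95e-11; Poisson p = 4.95e-11

region <- read_region(rala_fixture("rala_region24_synthetic.txt"),
                      protein_length = 206)
region_fraction(region)
#> [1] 11.7

pop <- read_population_variants(
  rala_fixture("rala_population_variants_synthetic.tsv"))
depletion_test(region, pop)
#> Regional depletion: 0/24 in-region vs 34/182 outside residues variant-bearing
#>   Fisher two-sided p = 0.0168; lower-tail p = 0.00987
```

The eight-events-in-32,172-alleles test says the observed de novo count is
about forty-fold above the mutational null and essentially impossible under
it; the depletion test says the absence of population missense variants from
the 24-residue binding region (11.7% of the protein) is unlikely to be
random. `run_ralascope(example_run_config())` runs all stages — including
paralog mapping against packaged *reconstructed* RALA/HRAS/KRAS sequences
(verify against UniProt P11233/P01112/P01116 before canonical use) — and
`write_report()` serializes the full-precision report to JSON.

## Scope notes

The per-chromosome mutation rate is consumed as a published constant, never
re-estimated; variant calling, CADD/pLI/RVIS computation, hydrogen placement
and per-mutant structural modeling are out of scope. See the methods
vignette (`vignettes/rala-burden-analysis.Rmd`) for model assumptions,
parameter choices and limitations.
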