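---
title: "Homoeolog dosage mosaicism: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homoeolog dosage mosaicism: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicHE)
```

`mosaicHE` analyses homoeolog dosage mosaics in nascent segmental
allotetraploids — populations in which meiotic crossovers between the two
parental subgenomes (homoeologous exchanges, HEs) convert an initially
uniform 2:2 genome into individualized mosaics of the five dosage states
4:0, 3:1, 2:2, 1:3, 0:4.  This vignette is the package's account of its
models: what is assumed, which knobs matter, what the simulator does and
does not emulate, and where design decisions were genuinely open.  The
exported functions are the pipeline's interface; each stage (simulation,
calling, landscape, phenotype statistics, cytonuclear scan, expression
concordance, GWAS, epistasis) is a small family of functions documented on
its help page.

## Coordinates and containers

All intervals are 0-based half-open; VCF is the only 1-based surface and is
converted on read.  The genome is carved by `genome_grid()` into analysis
bins (default 5 kb — the resolution at which breakpoints are reported) and
regional bins (default 500 kb) used only to label pericentromeric territory
(the three consecutive regional bins harbouring the centromere) and
subtelomeric territory (four consecutive regional bins from each chromosome
end).  Uncalled dosage is `NA`, never 0, because 0 is a legal state (0:4).

## The read model and the caller

A parental-diagnostic SNP panel assigns each read to a subgenome.  For a bin
with pooled counts K (NPB) of N (total), each dosage state d ∈ {0..4} is
scored as a binomial log-likelihood with success probability

  f_d = (d/4)(1 − 2e) + e,

where e is the per-read misassignment/sequencing error rate (default 0.01
for DNA depths; the caller accepts any 0 ≤ e < 0.5, and e = 0 is handled by
flooring log 0 so impossible configurations score astronomically badly
rather than NaN).  `viterbi_dosage()` smooths the per-bin scores along each
chromosome under a 5-state Markov chain: staying costs log(1 − τ) per
boundary, switching log(τ/4), with τ = 1e-4 by default — roughly the prior
that a chromosome of a few thousand bins carries a handful of true state
changes.  Ties break toward the left neighbour so runs extend rather than
flicker.  Bins with no reads contribute flat emissions and inherit the
smoothed state.  The smoother is exactly the most probable path: the test
suite checks it against brute-force enumeration of all 5^nb paths on
hundreds of small instances.

Two consequences of smoothing are worth stating plainly.  First, an
isolated exchange tract of 1–2 bins must pay the switching cost twice; at
10× coverage and ~10 SNPs per bin the pooled evidence for the weakest
contrast (2:2 vs 3:1, about 12.5 nats per ~100-read bin) is below
2·|log τ| ≈ 18.4 + 18.4 nats, so such tracts are deliberately absorbed.
Breakpoint-recovery guarantees therefore apply to tracts of ≥ 3 bins;
genome-wide dosage accuracy is unaffected (>99.9% in the shipped
experiments).  Second, a state change across a run of uncalled bins is
bridged to a single breakpoint at the gap's midpoint boundary and flagged
`low_resolution` — the alternative (dropping the event) would bias the
cumulative counts that the rate estimator divides by 2g meioses.

`screen_euploidy()` flags whole-chromosome gains/losses from normalized
median bin depth with tolerance 0.15, the midpoint between a euploid ratio
(1.0) and a one-copy gain (1.25).  Flagged individuals should be excluded
before dosage calling, mirroring the euploid-only design of the study
populations this package targets.

## The simulator

`simulate_population()` is first-class, tested code, not a fixture.  The S0
founder of each reciprocal cross is a fixed heterozygote: two NPB homologs
in subgenome A, two 93-11 homologs in subgenome B (dosage 2 everywhere).
Each selfing generation unites two gametes from independent meioses of one
parent; lines are propagated by single-seed descent and expanded to sibs in
the final generation.  Per meiosis and chromosome quartet:

* one obligate homologous crossover per bivalent at a uniform interior
  boundary — homologous crossovers only create variation after an earlier HE
  has made a subgenome internally heterozygous, and this minimal rule
  reproduces 1:2:1 segregation of a d = 3 locus under selfing (tested);
* Poisson(2λ) homoeologous exchanges (λ per chromosome pair; two pairs per
  quartet; default λ = 0.75, i.e. 24 × 0.75 = 18 per meiosis for the
  12-chromosome karyotype), each replacing the distal segment of one
  transmitted chromatid with material from a uniformly chosen haplotype of
  the opposite subgenome, at positions drawn from a weight profile —
  pericentromeric bins at weight 0.5, subtelomeric at 2, others at 1,
  a coarse rendering of the depletion/enrichment pattern of plant meiotic
  recombination (chosen once; any per-bin profile can be supplied).

Haplotypes are tracked at bin resolution (breakpoints snap to bin edges)
because all downstream inference is binned.  The truth set records, per
individual, the dosage matrix, and the cumulative HE events over the 2g
meioses of its pedigree — expectation 2·g·24·λ, the quantity the rate
estimator `he_rate()` divides by 2g.  Dosage-visible breakpoints are a
slightly smaller set: an exchange landing where the two chromatids already
match leaves no step, and homozygous junctions merge into one focus, so the
called-per-meiosis rate sits marginally below the event rate in late
generations.  Viability selection is rejection sampling at gamete union:
offspring lacking every copy of the required parental homoeolog in a listed
segment are redrawn with probability s, which yields 100% retention at
s = 1 and retention monotone in s (tested).

What the simulator does **not** emulate: sequence-level mutation,
aneuploidy (the study screened to euploids), non-reciprocal
gene-conversion-like HEs, base-pair-resolution breakpoints, linkage between
sequencing error and genotype, and any population structure beyond a
biparental selfing family.  Passing tests therefore demonstrate correctness
of the inference machinery under this generative model, not robustness to,
say, mapping bias or segmental duplications in real resequencing data.

Depth sampling is Poisson(coverage) per SNP with binomially split parental
reads at f_d; expression sampling gives dosage-coupled genes a
Binomial(total, d/4) NPB transcript count (optionally beta-binomial) and
uncoupled genes a fixed 1:1 ratio.  Trait values follow the F∞
parameterisation (below) plus Gaussian noise; reference groups use the
fixed codes of the diploid parents (all-4 / all-0) and F1 hybrids (all-2).

## Statistics: conventions and defaults

* Exact binomial tests (state symmetry, transgression sign test) use the
  minimum-likelihood two-sided convention of `binom.test`.
* Permutation tests (chromosome density, regional enrichment) redistribute
  events proportionally to physical length and report two-sided empirical
  p-values with a +1 pseudocount, p = (1 + 2·min(#≤, #≥))/(n_perm + 1),
  never zero; they are calibrated against the exact binomial oracle on a
  two-chromosome construction in the tests.  "cM/Mb" is operationalized as
  100 × events per meiosis per Mb, each HE treated as one
  crossover-equivalent.
* Group comparisons use Welch's t-test — tetraploid and parental variances
  differ grossly; a doubly-degenerate comparison returns p = 1 (equal
  means) or p = 0.
* Transgression is counted against parental group extremes, not means —
  the stricter, population-level reading of "greater than both parents".
* The cytonuclear scan's chi-square null is the cross's genome-wide
  empirical five-state frequencies.  A caveat discovered and kept visible:
  with several sibs per line the per-bin chi-square sees pseudo-replicated
  draws, and genuine positional heterogeneity (the HE weight profile) also
  shifts local state frequencies, so the raw chi-square rejects above
  nominal under neutrality; the *candidate* rule (retention fraction > 0.95
  AND p < 0.01) stays near the α budget.  Calibration experiments in the
  tests use one individual per line.
* Segment classification: bins are first labelled by cross-direction
  agreement (maternal-in-both = Group I, paternal-in-both = Group II,
  paternal-in-exactly-one = Group III, maternal-in-one = unclassified),
  then merged into segments bridging gaps of ≤ 1 bin (tolerating isolated
  uncalled bins).  Labelling before merging makes a direction conflict
  inside one segment impossible by construction.
* Expression concordance calls a gene dosage-dependent only if the dosage
  model is *not* rejected (BH-adjusted Fisher-combined GOF p ≥ 0.05) *and*
  the balanced 1:1 null *is* rejected for at least one individual with
  d ≠ 2 — a bare non-rejection cannot distinguish coupling from low power,
  and at d = 2 the two nulls coincide.  Default min_reads = 20 per cell;
  e = 0.001 in the expectations keeps d ∈ {0,4} away from zero-count
  degeneracy.

## GWAS

The five states are encoded as in the study design: additive 0–4 on the NPB copy
number, and three dominance codings (0,1,1,1,0; 0,2,2,2,1; 1,2,2,2,0)
capturing heterozygote equivalence and the two transgressive-homozygote
patterns.  The scan is FarmCPU-flavoured but deliberately fixed-effect
only: the population is a single biparental selfing family with no
stratification, which is what FarmCPU's random-effect step guards against.
Each iteration (1) tests every marker by OLS with the current pseudo-QTN
codes as covariates, dropping for a given test any pseudo-QTN correlated
with it at |r| > 0.7, and (2) re-selects pseudo-QTNs greedily among
Bonferroni-significant markers under mutual |r| ≤ 0.7.  Iteration stops
when the set repeats — including two-cycles between equivalent taggings of
one long linkage block, which dense bin-markers in a selfing family readily
produce.  With an empty pseudo-QTN set the scan reduces exactly to
single-marker OLS (tested against `lm` to 1e-10).  The Bonferroni M is the
number of polymorphic markers actually tested in the run.  Signal segments
extend from each peak while neighbouring bins correlate with it at
r > 0.9.

## F∞ epistasis

Two-locus fits use w = (d − 2)/2 (homozygote contrast ±1) and
v = [d ∈ {1,2,3}] (any-heterozygote indicator) — the direct five-state
generalization of the diploid F∞ codes — regressing the trait on
[1, w₁, v₁, w₂, v₂, w₁w₂, w₁v₂, v₁w₂, v₁v₂].  Swapping loci swaps ad↔da and
fixes aa, dd (tested).  Collinear terms (a locus segregating only 0/4 has
constant v) are dropped and reported NA.  When the fit is exact (σ = 0) the
t statistics are 0/0; the fit then reports p = 0 for coefficients whose
estimate exceeds 1e-8 and p = 1 otherwise, so noiseless classification is
exact.  Pair-level significance applies BH across all pairs × 4 interaction
terms of a run at α = 0.05; a pair may count toward several interaction
types, as in the population summaries.

## Problem sizes in the shipped experiments

The test suite and `scripts/acceptance.R` run the pipeline end-to-end at
sizes chosen to exercise the study design while remaining desk-scale: the
caller-recovery experiment uses the full genome geometry (12 × 30-Mb
chromosomes, 5-kb bins, ≥ 5 diagnostic SNPs per bin, 10× coverage) with 100
S4 individuals; the no-exchange control uses 20 individuals on 12 × 10-Mb
chromosomes; GWAS calibration/power uses twenty seeded 200-individual
populations on 2 × 5-Mb chromosomes (≈ 2000 bin-markers, planted QTL
explaining ~20% of trait variance); epistasis and cytonuclear experiments
use 120–200 individuals on 1–2 small chromosomes.  Segment-recovery for the
cytonuclear scan is reported as the percentage of planted bins covered by
segments of the expected group, a more informative quantity than a binary
hit.  Under these conditions the shipped runs give >99.9% dosage accuracy,
a per-pair exchange rate within Monte-Carlo error of λ, zero false
breakpoints in the control, 100% null-GWAS cleanliness, ≥95% additive
power with dominance-specific detection of heterozygote advantage, unbiased
interaction estimates with ≤5% false epistasis flags, and full recovery of
planted Group I/III segments.

## Known limitations

Breakpoints are bin-resolution by construction; tracts shorter than three
bins are beneath the smoother's evidence threshold at default coverage; the
per-meiosis rate estimator assumes the 2-meioses-per-generation selfing
pedigree and full euploidy; the cytonuclear chi-square inherits the
baseline choice discussed above; and the GWAS intentionally omits kinship
corrections, so applying it outside a single biparental family would
require a mixed model instead.
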