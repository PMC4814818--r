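---
title: "Likelihood-ratio population assignment from SNP genotype frequencies"
author: "SNPclassify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-ratio population assignment from SNP genotype frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SNPclassify)
```

## The model

A biallelic SNP has three genotype categories: the two homozygotes and the
heterozygote. `SNPclassify` models the genotype of a random individual at
marker $i$ as a single draw from a trinomial distribution,
$(p_i, q_i, r_i)$ in population A and $(u_i, v_i, w_i)$ in population B,
each triple summing to one. Two standing assumptions license everything
else:

* **Linkage equilibrium.** Markers are statistically independent within a
  population, so the likelihood of a multi-marker profile factorizes into
  per-marker genotype probabilities. The packaged example panel was drawn
  from eight different chromosomes precisely so this holds to a good
  approximation.
* **Representative frequencies.** The trinomial parameters are plug-in
  estimates from reference samples; the classifier treats them as known.
  `estimateModel()` quantifies the sampling error of that step and
  `hweExactPvalue()` screens for genotyping artefacts that would distort
  the estimates.

For a profile $S$ with observed genotypes $g_1,\dots,g_n$,

$$L(A) = \prod_{i} \Pr(g_i \mid A), \qquad L(B) = \prod_i \Pr(g_i \mid B),$$

and $S$ is assigned to A exactly when $L(A)/L(B) > 1$; everything else —
including an exact tie — goes to B. This strict inequality is deliberate
and is preserved everywhere (classification, enumeration, simulation), so
two identical models classify *every* profile to B, and the power under A
of such a degenerate comparison is exactly 0 while the power under B is 1.

When the two population sizes are known, the expected-count variant
compares $E(A) = N(A)\,L(A)$ against $E(B) = N(B)\,L(B)$: the expected
number of individuals in each population carrying the observed profile.
With $N(A) = N(B)$ it reduces to the likelihood-ratio rule, a property the
test-suite checks on random models. The reported `logRatio` always remains
the unweighted $\log L(A) - \log L(B)$; the size weighting enters only the
decision.

## Tunable parameters

* **`floor`** (`ClassifierConfig`, default $10^{-6}$, dimensionless
  probability). Reference frequency tables regularly contain sampling
  zeros; an unmodified zero in one population would force an infinite
  likelihood ratio from a single marker and make the decision
  non-robust to a single genotyping error. Probabilities below `floor` are
  therefore clamped to `floor` at decision time. The default is far below
  any frequency resolvable by the reference sample sizes the package is
  aimed at (hundreds to thousands of individuals), so it never affects
  decisions between genuinely observed genotypes. `floor = 0` disables
  clamping: log-likelihoods may then be $-\infty$, and $-\infty$ versus
  $-\infty$ counts as a tie (to B).
* **`pseudocount`** (`estimateModel`, default 0). Additive smoothing
  $(\text{count} + \alpha)/(n + 3\alpha)$. The default is 0 for
  transparency — estimation reports exactly what was observed — because
  zero-handling is a *classification-time* concern already covered by
  `floor`; setting both would double-correct.
* **`missingRate`** (`simulateProfiles`, default 0). Uniform, independent
  per-call missingness. Missing calls are skipped (likelihood factor 1),
  never imputed, and the skip count is surfaced in every result.
* **`tol` in `mafFilter`** (default $5\times10^{-4}$). Published MAF
  selection windows are quoted at three decimals while MAF recomputed from
  genotype frequencies is not rounded; the bounds are widened by half a
  unit in the third decimal so that a window quoted at printed precision
  admits exactly the markers it was meant to. `tol = 0` restores strict
  inclusive bounds.

## Exact power by enumeration

The power of a panel under population A is the probability that a random A
individual is assigned to A. Because the model factorizes, this is a sum
over all $3^n$ genotype vectors of the product-of-marginals mass of the
vectors the rule labels A. `exactAccuracy()` computes the $3^n$ totals by
an odometer-style accumulation in log space (one `outer()` per marker), in
model marker order; the decision uses floored probabilities while the
summed mass uses the raw ones. A guard refuses $3^n > 10^7$ (n > 14),
beyond which the memory cost stops being desk-scale; `monteCarloAccuracy()`
covers larger panels with binomial standard errors instead.

Three structural properties follow from the construction and are verified
by the test suite rather than assumed: probability mass is conserved
(accuracy under A plus mass labelled B equals 1), the result is invariant
to permuting markers within a panel, and the balanced accuracy of nested
panels is non-decreasing — the equal-prior Bayes rule cannot lose power
from an extra independent marker, and the tie-to-B convention contributes
the tied mass to the same side under both panels.

On the packaged eight-marker panel the enumeration yields accuracy under A
of 0.733, 0.813, 0.814 and 0.841 for panels of 2, 4, 6 and 8 markers
(`nestedPanelAccuracies()`, step 2). The accuracies published with the
original study of this panel are one to two percentage points higher for
the larger panels. The published figures were measured on the cohort's own
genotyped individuals, whose empirical joint genotype frequencies need not
factorize into the printed per-marker tables; the model-expected
enumeration from the frequency tables is adopted here as the reference
computation because it is exactly reproducible from the packaged data. The
package documents this gap rather than tuning anything to close it.

## Hardy–Weinberg tests

`hweExactPvalue()` is the conditional exact test: given the observed
allele counts, the heterozygote count indexes all reachable genotype
configurations; the p-value sums the conditional probabilities (under
random union of alleles) of configurations no more probable than the
observed one. Standard probability ordering, no mid-p correction — chosen
because it is reproducible and directly checkable against an enumeration
oracle, which the tests do exhaustively for all count triples with
$n \le 10$. Monomorphic input returns exactly 1. `hweChisqPvalue()` is the
1-df asymptotic companion without continuity correction; it refuses
degenerate inputs (an expected category count of zero) explicitly rather
than returning a misleading number.

## The synthetic-data generator

`simulateProfiles()` draws each marker independently from its trinomial —
exactly the model the classifier assumes — and applies uniform independent
missingness. One integer seed fully determines the output; draws consume
the RNG stream in marker order then sample order, so adding a marker
changes downstream draws (documented, not hidden).
`simulateTwoPopulationStudy()` concatenates labelled draws from both
models under a single seed.

What the generator emulates: genotype sampling noise at realistic
reference sizes (the packaged cohort has 641 individuals; validation uses
$10^4$ draws, where three binomial standard errors resolve frequencies to
about $\pm 0.015$), and uniform missingness. What it does not emulate:
linkage disequilibrium between markers, admixed or related individuals,
genotyping error, or structured (genotype-dependent) missingness. Passing
simulation-based tests therefore shows the implementation is faithful *to
the model*, not that the model is adequate for cohorts where those
features matter; the enumeration/simulation agreement checks would not
detect, say, LD-induced miscalibration on real data.

## Numerical and design choices

* **Log-space throughout.** Likelihoods over thousands of markers
  underflow in linear space; sums of logs do not, and agreement with
  direct products is tested on small cases.
* **Renormalization tolerance 0.005.** Published frequency tables rounded
  to three decimals have column sums of $1 \pm 0.001$; the reader accepts
  a residue up to 0.005 and divides by the sum, and rejects anything
  larger as a data error rather than silently repairing it. The packaged
  fixtures are transcribed exactly as printed, so loading them exercises
  this path.
* **Genotype canonicalization.** Heterozygote labels are written with
  allele characters sorted ("TC" and "CT" are the same category), which is
  what makes frequency tables from different sources joinable.
* **Allele order.** When a frequency table is read without marker
  metadata, the allele pair is inferred from the nonzero genotype rows
  with the first allele alphabetical; a marker summary table (the
  `Allele` column, e.g. `T:C`) can fix a different order. MAF, ObsHET,
  HWE and all classification results are invariant to this order.
* **Monomorphic columns.** A column whose nonzero rows expose only one
  allele character cannot reveal the second allele; the reader raises an
  explicit error instead of guessing, and `estimateModel()` behaves the
  same way unless given marker templates.
* **Reproducible outputs.** CLI outputs carry no timestamps or hostnames;
  identical arguments and seed produce byte-identical files, which the
  tests assert.

## Validation problem sizes

The shipped tests pin the implementation to independent brute-force
oracles at sizes chosen to be exhaustive where feasible and statistically
decisive otherwise: all HWE count triples with $n \le 10$ against a
sequence-enumeration oracle; exact power against an explicit-grid oracle
on the packaged panels and on 100 random 3-marker model pairs; Monte-Carlo
power at $10^5$ simulations against the exact value (4 standard errors);
parameter recovery at $10^4$ simulated profiles (3 binomial standard
errors per genotype frequency); rule-equivalence and monotonicity
properties on 50–1000 random cases under fixed seeds.

## Known limitations

Two populations only; biallelic autosomal SNPs only (no X/Y/mitochondrial
ploidy handling); no LD-aware haplotype likelihoods; no posterior
probabilities beyond the population-size weighting; the exact enumerator
is intentionally capped at $3^n \le 10^7$. The plug-in treatment of
estimated frequencies understates uncertainty when reference samples are
small — inspect `markerSummary()` counts before trusting close calls.
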