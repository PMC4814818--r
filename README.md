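# SNPclassify

Two-population classification of individuals from a small panel of biallelic
SNP markers.

## The problem and who this is for

Forensic screening, disaster-victim triage and biodiversity surveys often
need to decide which of two candidate populations an individual came from,
using only a handful of cheap SNP genotypes rather than the 30–70 markers
needed for individual identification. `SNPclassify` implements the standard
likelihood-ratio assignment rule for that setting, together with the marker
summary statistics used to build such panels (MAF, observed heterozygosity,
Hardy–Weinberg tests), exact power calculations, and a simulator for
end-to-end validation.

## The model

For each biallelic SNP *i* the genotype of a random individual is one draw
from a trinomial distribution over the three genotype categories
(hom-first, het, hom-second): parameters (*p*ᵢ, *q*ᵢ, *r*ᵢ) in population A
and (*u*ᵢ, *v*ᵢ, *w*ᵢ) in population B, with each triple summing to 1.
Markers are assumed to be in linkage equilibrium, so for a sample *S* with
observed genotypes *g₁ … gₙ*,

    L(A) = ∏ᵢ Pr(gᵢ | A),   L(B) = ∏ᵢ Pr(gᵢ | B)

and the decision rule is: assign *S* to population A if L(A)/L(B) > 1,
otherwise to B (ties go to B). When the population sizes N(A) and N(B) are
known, the expected-count variant compares E(A) = N(A)·L(A) with
E(B) = N(B)·L(B) instead.

The power (accuracy) of a marker panel is computed exactly: all 3ⁿ genotype
vectors are enumerated, each is labelled by the rule, and the probability
mass of correctly labelled vectors is summed under each population. A
Monte-Carlo estimator with binomial standard errors covers panels too large
to enumerate.

## Worked example

The package ships an eight-marker example panel: population A is a regional
cohort of 641 genotyped individuals, population B a general reference
population from a public SNP database.

```r
library(SNPclassify)
p <- examplePanel()
markerSummary(p$A)
#>      marker alleles    maf obs_het hwe_pvalue
#> 1 rs2856838     C:T 0.2485   0.379         NA
#> 2 rs8193036     C:T 0.2925   0.407         NA
#> 3 rs2243191     T:C 0.2760   0.406         NA
#> 4   rs20541     C:T 0.3100   0.426         NA
#> 5 rs2227306     C:T 0.3550   0.476         NA
#> 6 rs4739139     C:T 0.2895   0.445         NA
#> 7  rs741344     A:G 0.3405   0.465         NA
#> 8  rs583911     G:A 0.2680   0.412         NA
```

All eight MAFs fall in the panel's selection window [0.249, 0.355]. Classify
one three-marker profile:

```r
s <- SampleProfile("S1", c(rs2856838 = "CC", rs8193036 = "TT", rs20541 = "CT"))
classifyLikelihoodRatio(s, p$A, p$B)
#> LikelihoodResult 'S1': label B (log LR = -1.0715, LR = 0.3425; 3 used, 0 skipped)
```

L(A)/L(B) = 0.34 < 1, so the sample is assigned to population B. The power
of growing panels (2, 4, 6, 8 markers, exact enumeration):

```r
accuracyTable(nestedPanelAccuracies(p$A, p$B, panelOrder(), step = 2))
#>   n_markers acc_under_A acc_under_B balanced method
#> 1         2      0.7327      0.6422   0.6875  exact
#> 2         4      0.8125      0.7440   0.7783  exact
#> 3         6      0.8144      0.7766   0.7955  exact
#> 4         8      0.8413      0.8088   0.8251  exact
```

`acc_under_A` is the probability that a random population-A individual is
assigned back to A; it rises from 73% with two markers to 84% with all
eight — a small SNP panel carries substantial population signal even though
single markers are nearly uninformative.

## Command line

A thin wrapper (`inst/scripts/snpclassify`) exposes the same operations:

```sh
snpclassify evaluate --pop-a popA.tsv --pop-b popB.tsv --nested --step 2
snpclassify classify --pop-a popA.tsv --pop-b popB.tsv --genotypes cohort.tsv
snpclassify simulate --pop popA.tsv --n 1000 --seed 7 --out sim.tsv
```

Outputs are plain TSV without timestamps, so runs are byte-reproducible.

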