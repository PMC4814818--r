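#' @include AllClasses.R
NULL

#' Allele frequencies implied by a genotype distribution
#'
#' For a distribution (p, q, r) over (hom-first, het, hom-second), the first
#' allele has frequency p + q/2 and the second r + q/2; the two sum to 1.
#'
#' @param dist A \code{\linkS4class{GenotypeDistribution}}.
#' @param marker Optional \code{\linkS4class{Marker}}; when supplied the
#'   returned pair is named by its alleles.
#' @return Numeric pair (first-allele frequency, second-allele frequency).
#' @examples
#' d <- GenotypeDistribution("rs2243191", c(0.521, 0.406, 0.073))
#' alleleFrequencies(d)  # 0.724 0.276
#' @export
alleleFrequencies <- function(dist, marker = NULL) {
    p <- probs(dist)
    f <- c(p[1] + p[2] / 2, p[3] + p[2] / 2)
    if (!is.null(marker)) names(f) <- alleles(marker)
    f
}

#' Minor allele frequency
#'
#' The frequency of the rarer allele implied by a genotype distribution;
#' always in [0, 0.5], and 0 exactly when the marker is monomorphic.
#'
#' @inheritParams alleleFrequencies
#' @return Minor allele frequency.
#' @examples
#' minorAlleleFrequency(GenotypeDistribution("rs20541", c(0.477, 0.426, 0.097)))
#' @export
minorAlleleFrequency <- function(dist) {
    min(alleleFrequencies(dist))
}

#' Observed heterozygosity
#'
#' The fraction of individuals heterozygous at the marker, i.e. the middle
#' trinomial parameter q.
#'
#' @inheritParams alleleFrequencies
#' @return Heterozygote frequency.
#' @examples
#' observedHeterozygosity(GenotypeDistribution("rs2227306", c(0.407, 0.476, 0.117)))
#' @export
observedHeterozygosity <- function(dist) {
    probs(dist)[2]
}

#' Hardy-Weinberg expected genotype distribution
#'
#' Projects a genotype distribution onto Hardy-Weinberg proportions: with
#' allele frequencies (f1, f2) it returns (f1^2, 2 f1 f2, f2^2). The map is
#' idempotent.
#'
#' @inheritParams alleleFrequencies
#' @return A \code{\linkS4class{GenotypeDistribution}} at HWE proportions.
#' @examples
#' hweExpected(GenotypeDistribution("rs1", c(0.5, 0, 0.5)))  # (0.25, 0.5, 0.25)
#' @export
hweExpected <- function(dist) {
    f <- alleleFrequencies(dist)
    GenotypeDistribution(markerId(dist),
                         c(f[1]^2, 2 * f[1] * f[2], f[2]^2),
                         tolerance = 1e-9)
}

#' Filter markers by minor allele frequency
#'
#' Returns, in model order, the ids of markers whose MAF lies in
#' \code{[lo, hi]} (bounds inclusive). Published MAF windows are usually
#' quoted at 3-decimal precision while MAFs recomputed from genotype
#' frequencies are not rounded, so the bounds are widened by \code{tol},
#' half a unit in the third decimal by default; set \code{tol = 0} for
#' strict inclusive bounds.
#'
#' @param model A \code{\linkS4class{PopulationModel}}.
#' @param lo,hi MAF window bounds, 0 <= lo <= hi <= 0.5.
#' @param tol Bound tolerance for windows quoted at printed precision.
#' @return Character vector of marker ids.
#' @examples
#' m <- Marker("rs1", c("C", "T"))
#' d <- GenotypeDistribution("rs1", c(0.25, 0.5, 0.25))
#' mafFilter(PopulationModel("toy", list(m), list(d)), 0.4, 0.5)
#' @export
mafFilter <- function(model, lo, hi, tol = 5e-4) {
    stopifnot(lo >= 0, lo <= hi, hi <= 0.5, tol >= 0)
    maf <- vapply(distributions(model), minorAlleleFrequency, numeric(1))
    markerIds(model)[maf >= lo - tol & maf <= hi + tol]
}

#' Per-marker summary table of a population model
#'
#' MAF, observed heterozygosity and, when per-marker sample counts are
#' available, a Hardy-Weinberg exact-test p-value computed from the counts
#' implied by rounding frequency x count to whole genotypes.
#'
#' @param model A \code{\linkS4class{PopulationModel}}.
#' @return A data.frame with columns marker, alleles, maf, obs_het, hwe_pvalue
#'   (NA when no counts are stored).
#' @examples
#' p <- examplePanel()
#' head(markerSummary(p$B))
#' @export
markerSummary <- function(model) {
    ids <- markerIds(model)
    cnt <- markerCounts(model)
    rows <- lapply(seq_along(ids), function(i) {
        d <- distributions(model)[[i]]
        m <- markers(model)[[i]]
        pv <- NA_real_
        if (!is.na(cnt[i])) {
            obs <- round(probs(d) * cnt[i])
            if (sum(obs) >= 1) pv <- hweExactPvalue(obs)
        }
        data.frame(marker = ids[i],
                   alleles = paste(alleles(m), collapse = ":"),
                   maf = minorAlleleFrequency(d),
                   obs_het = observedHeterozygosity(d),
                   hwe_pvalue = pv,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
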