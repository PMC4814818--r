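#' @include AllClasses.R
NULL

.asCountTriple <- function(counts) {
    if (is(counts, "GenotypeCounts")) counts <- counts@counts
    counts <- as.numeric(counts)
    if (length(counts) != 3L || anyNA(counts))
        stop("genotype counts must be a triple (n_hom1, n_het, n_hom2)")
    if (any(counts < 0)) stop("genotype counts must be non-negative")
    if (any(abs(counts - round(counts)) > 1e-8))
        stop("genotype counts must be whole numbers")
    as.integer(round(counts))
}

## log of the conditional probability of nAB heterozygotes given n individuals
## and nA copies of the first allele, under random allele union:
## P(nAB) = n! / (nAA! nAB! nBB!) * 2^nAB * nA! * nB! / (2n)!
.hweLogProb <- function(nAB, n, nA) {
    nB <- 2L * n - nA
    nAA <- (nA - nAB) / 2
    nBB <- (nB - nAB) / 2
    lfactorial(n) - lfactorial(nAA) - lfactorial(nAB) - lfactorial(nBB) +
        nAB * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2L * n)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, heterozygote
#' counts of the same parity index the possible genotype configurations; the
#' p-value is the sum of the conditional probabilities of all configurations
#' no more probable than the observed one. No mid-p correction is applied.
#' A monomorphic sample (one allele absent) returns 1 exactly.
#'
#' @param counts A \code{\linkS4class{GenotypeCounts}} or a numeric triple
#'   (n_hom1, n_het, n_hom2).
#' @return Exact p-value in [0, 1].
#' @references Wigginton JE, Cutler DJ, Abecasis GR (2005) A note on exact
#'   tests of Hardy-Weinberg equilibrium. Am J Hum Genet 76:887-893.
#' @examples
#' hweExactPvalue(c(25, 50, 25))
#' hweExactPvalue(GenotypeCounts(c(10, 0, 0)))  # monomorphic: 1
#' @export
hweExactPvalue <- function(counts) {
    counts <- .asCountTriple(counts)
    n <- sum(counts)
    if (n < 1L) stop("total count must be >= 1")
    nA <- 2L * counts[1] + counts[2]
    nB <- 2L * counts[3] + counts[2]
    if (nA == 0L || nB == 0L) return(1.0)
    ## heterozygote counts sharing the parity of nA (and nB), bounded by both
    ## allele counts
    hets <- seq.int(nA %% 2L, min(nA, nB), by = 2L)
    lp <- .hweLogProb(hets, n, nA)
    pObs <- lp[match(counts[2], hets)]
    ## tolerance absorbs round-off when comparing equal-probability configs
    min(1, sum(exp(lp)[lp <= pObs + 1e-10]))
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test of the observed genotype counts
#' against the counts expected from the sample allele frequencies, without
#' continuity correction. The asymptotic companion to
#' \code{\link{hweExactPvalue}}.
#'
#' @inheritParams hweExactPvalue
#' @return Chi-square p-value.
#' @examples
#' hweChisqPvalue(c(25, 50, 25))  # exactly HWE: p = 1
#' @export
hweChisqPvalue <- function(counts) {
    counts <- .asCountTriple(counts)
    n <- sum(counts)
    if (n < 1L) stop("total count must be >= 1")
    fA <- (2 * counts[1] + counts[2]) / (2 * n)
    expected <- n * c(fA^2, 2 * fA * (1 - fA), (1 - fA)^2)
    if (any(expected <= 0))
        stop("chi-square HWE test inapplicable: an expected genotype count is zero")
    stat <- sum((counts - expected)^2 / expected)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
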