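# Shared fixtures and independent brute-force oracles.

# toy model builder: freqs = named list of probability triples, alleles in
# alphabetical order unless given
makeModel <- function(label, freqs, alleles = NULL, sizeN = NA) {
    ids <- names(freqs)
    mk <- lapply(ids, function(id) {
        al <- if (is.null(alleles)) c("C", "T") else alleles[[id]]
        Marker(id, al)
    })
    ds <- lapply(ids, function(id) GenotypeDistribution(id, freqs[[id]]))
    PopulationModel(label, mk, ds, sizeN = sizeN)
}

# a random strictly-positive trinomial (kept away from 0 so floor clamping
# and Bayes-rule tie subtleties don't kick in)
randomTriple <- function() {
    x <- stats::runif(3, min = 0.05)
    x / sum(x)
}

randomModelPair <- function(nMarkers) {
    ids <- paste0("rs", seq_len(nMarkers))
    fa <- lapply(ids, function(i) randomTriple())
    fb <- lapply(ids, function(i) randomTriple())
    names(fa) <- names(fb) <- ids
    list(A = makeModel("A", fa), B = makeModel("B", fb))
}

# Independent accuracy oracle: explicit grid of genotype vectors, direct
# product arithmetic (no logs), strict > for A with ties to B.
enumAccuracyOracle <- function(A, B, ids, floor = 1e-6) {
    pA <- lapply(ids, function(id) {
        probs(distributions(A)[[match(id, markerIds(A))]])
    })
    pB <- lapply(ids, function(id) {
        probs(distributions(B)[[match(id, markerIds(B))]])
    })
    grid <- as.matrix(expand.grid(rep(list(1:3), length(ids))))
    prodOver <- function(plist, clamp) {
        apply(grid, 1, function(g) {
            v <- mapply(function(p, k) p[k], plist, g)
            if (clamp) v <- pmax(v, floor)
            prod(v)
        })
    }
    decA <- prodOver(pA, clamp = TRUE)
    decB <- prodOver(pB, clamp = TRUE)
    massA <- prodOver(pA, clamp = FALSE)
    massB <- prodOver(pB, clamp = FALSE)
    winA <- decA > decB
    c(underA = sum(massA[winA]), underB = sum(massB[!winA]))
}

# Independent HWE exact-test oracle for all genotype-count triples of total
# n: enumerate every ordered genotype sequence, condition on allele counts,
# weight each sequence by 2^(number of heterozygotes).
hweOracleTable <- function(n) {
    grid <- as.matrix(expand.grid(rep(list(0:2), n)))  # copies of 2nd allele
    nB <- rowSums(grid)
    hets <- rowSums(grid == 1)
    w <- 2^hets
    function(counts) {
        stopifnot(sum(counts) == n)
        target <- 2 * counts[3] + counts[2]
        sel <- nB == target
        if (!any(sel)) return(NA_real_)
        byHet <- tapply(w[sel], hets[sel], sum)
        probs <- byHet / sum(byHet)
        pObs <- probs[as.character(counts[2])]
        sum(probs[probs <= pObs + 1e-12])
    }
}

countTriples <- function(n) {
    out <- list()
    for (a in 0:n) for (b in 0:(n - a)) out[[length(out) + 1L]] <- c(a, b, n - a - b)
    out
}
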