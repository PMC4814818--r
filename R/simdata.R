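#' @include AllClasses.R
NULL

## draws an n x m genotype matrix from the model's trinomials using the
## current RNG state; stream order is marker-major (all n draws for marker 1,
## then marker 2, ...), then one marker-major block of missingness draws
.simulateMatrix <- function(model, n, missingRate, idPrefix) {
    ids <- markerIds(model)
    g <- matrix(NA_character_, nrow = n, ncol = length(ids),
                dimnames = list(sprintf("%s%d", idPrefix, seq_len(n)), ids))
    for (j in seq_along(ids)) {
        cats <- genotypeCategories(markers(model)[[j]])
        p <- probs(distributions(model)[[j]])
        g[, j] <- cats[sample.int(3L, n, replace = TRUE, prob = p)]
    }
    if (missingRate > 0) {
        drop <- matrix(stats::runif(n * length(ids)) < missingRate,
                       nrow = n)
        g[drop] <- NA_character_
    }
    g
}

#' Simulate genotype profiles from a population model
#'
#' Draws each marker's genotype independently from its trinomial
#' distribution; each call is then independently replaced by missing with
#' probability \code{missingRate}. The single seed fully determines the
#' output; draws consume the RNG stream in marker order then sample order, so
#' adding markers changes downstream draws.
#'
#' @param model A \code{\linkS4class{PopulationModel}}.
#' @param n Number of profiles (>= 1).
#' @param seed Integer seed.
#' @param missingRate Per-call missingness probability in [0, 1).
#' @param idPrefix Prefix for generated sample ids.
#' @return A \code{\linkS4class{GenotypeDataset}}.
#' @examples
#' p <- examplePanel()
#' simulateProfiles(p$A, n = 3, seed = 42)
#' @export
simulateProfiles <- function(model, n, seed, missingRate = 0,
                             idPrefix = "S") {
    stopifnot(n >= 1, missingRate >= 0, missingRate < 1)
    set.seed(seed)
    GenotypeDataset(.simulateMatrix(model, n, missingRate, idPrefix))
}

#' Simulate a labelled two-population study
#'
#' Concatenates \code{nA} draws from population A and \code{nB} from
#' population B (in that order) under one seed, with true population labels
#' attached — the end-to-end test harness for the classifier.
#'
#' @param A,B \code{\linkS4class{PopulationModel}}s.
#' @param nA,nB Number of profiles from each population (>= 0, nA + nB >= 1).
#' @inheritParams simulateProfiles
#' @return A labelled \code{\linkS4class{GenotypeDataset}}.
#' @examples
#' p <- examplePanel()
#' ds <- simulateTwoPopulationStudy(p$A, p$B, 3, 3, seed = 7)
#' trueLabels(ds)
#' @export
simulateTwoPopulationStudy <- function(A, B, nA, nB, seed, missingRate = 0) {
    stopifnot(nA >= 0, nB >= 0, nA + nB >= 1, missingRate >= 0,
              missingRate < 1)
    set.seed(seed)
    parts <- list()
    if (nA > 0) parts$A <- .simulateMatrix(A, nA, missingRate, "A")
    if (nB > 0) parts$B <- .simulateMatrix(B, nB, missingRate, "B")
    g <- do.call(rbind, unname(parts))
    labels <- c(rep(populationLabel(A), nA), rep(populationLabel(B), nB))
    GenotypeDataset(g, trueLabels = labels)
}

#' Estimate a population model from genotype data
#'
#' Per-marker genotype probabilities are estimated as
#' (count + alpha) / (n_called + 3 alpha); missing calls are excluded from
#' n_called. Marker allele pairs are taken from \code{markers} when given,
#' otherwise inferred from the distinct allele characters observed at the
#' marker (two distinct characters are required for inference).
#'
#' @param dataset A \code{\linkS4class{GenotypeDataset}}.
#' @param markerIds Markers to estimate; default all in the dataset.
#' @param pseudocount Additive smoothing alpha >= 0 (default 0).
#' @param label Population name of the returned model.
#' @param markers Optional list of \code{\linkS4class{Marker}} templates
#'   fixing allele pairs and category order.
#' @return A \code{\linkS4class{PopulationModel}} whose per-marker counts
#'   record the number of called samples.
#' @examples
#' p <- examplePanel()
#' ds <- simulateProfiles(p$A, n = 200, seed = 5)
#' estimateModel(ds, label = "Ahat", markers = markers(p$A))
#' @export
estimateModel <- function(dataset, markerIds = NULL, pseudocount = 0,
                          label = "estimated", markers = NULL) {
    stopifnot(pseudocount >= 0)
    g <- genotypes(dataset)
    if (is.null(markerIds)) markerIds <- colnames(g)
    if (!is.null(markers)) {
        names(markers) <- vapply(markers, markerId, character(1))
    }
    mk <- vector("list", length(markerIds))
    ds <- vector("list", length(markerIds))
    for (i in seq_along(markerIds)) {
        id <- markerIds[i]
        if (!id %in% colnames(g))
            stop(sprintf("marker %s not in dataset", id))
        obs <- g[, id]
        obs <- obs[!is.na(obs)]
        if (!is.null(markers) && id %in% names(markers)) {
            m <- markers[[id]]
        } else {
            chars <- sort(unique(unlist(strsplit(obs, ""))))
            if (length(chars) != 2L)
                stop(sprintf(
                    "cannot infer the allele pair of %s from %d observed allele(s); supply 'markers'",
                    id, length(chars)))
            m <- Marker(id, chars)
        }
        cats <- genotypeCategories(m)
        bad <- setdiff(unique(obs), cats)
        if (length(bad))
            stop(sprintf("genotype(s) %s at %s inconsistent with alleles %s/%s",
                         paste(bad, collapse = ","), id, alleles(m)[1],
                         alleles(m)[2]))
        cnt <- vapply(cats, function(ct) sum(obs == ct), numeric(1))
        nCalled <- sum(cnt)
        if (nCalled == 0 && pseudocount == 0)
            stop(sprintf("marker %s never observed and pseudocount is 0", id))
        mk[[i]] <- m
        ds[[i]] <- GenotypeDistribution(
            id, (cnt + pseudocount) / (nCalled + 3 * pseudocount),
            tolerance = 1e-9)
    }
    cnts <- vapply(seq_along(markerIds), function(i)
        sum(!is.na(g[, markerIds[i]])), numeric(1))
    PopulationModel(label, mk, ds, markerCounts = cnts)
}
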