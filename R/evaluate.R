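#' @include AllClasses.R
NULL

ENUM_GUARD <- 1e7

## log-probability totals of all 3^n genotype vectors: start from a single
## empty vector and, marker by marker, add each of the 3 genotype log-probs
## to every existing total (odometer order: the last marker varies fastest
## within blocks laid down first, matching base-3 counting in model order)
.enumLogTotals <- function(logp) {
    tot <- 0
    for (j in seq_len(ncol(logp))) tot <- as.vector(outer(logp[, j], tot, "+"))
    tot
}

#' Exact classification accuracy by exhaustive enumeration
#'
#' Enumerates all 3^n genotype vectors over the chosen markers, labels each
#' vector with the likelihood-ratio rule, and sums the product-of-marginals
#' probability mass of correctly labelled vectors under each population.
#' Valid when markers are independent (no linkage disequilibrium), which is
#' the model's standing assumption.
#'
#' @param A,B \code{\linkS4class{PopulationModel}}s sharing the markers used.
#' @param markerIds Marker subset to use; default all of A's markers.
#' @param config A \code{\linkS4class{ClassifierConfig}}; the floor applies
#'   to the decision rule, not to the probability mass being summed.
#' @return An \code{\linkS4class{AccuracyReport}} with method \code{"exact"}.
#' @examples
#' p <- examplePanel()
#' exactAccuracy(p$A, p$B, c("rs2856838", "rs8193036"))
#' @export
exactAccuracy <- function(A, B, markerIds = NULL,
                          config = ClassifierConfig()) {
    if (is.null(markerIds)) markerIds <- markerIds(A)
    n <- length(markerIds)
    if (n < 1L) stop("need at least one marker")
    if (3^n > ENUM_GUARD)
        stop(sprintf("3^%d genotype vectors exceed the enumeration guard (%g)",
                     n, ENUM_GUARD))
    pA <- probMatrix(A, markerIds)
    pB <- probMatrix(B, markerIds)
    ## decision uses floored probabilities; mass uses the true ones
    decA <- .enumLogTotals(.clampLog(pA, config@floor))
    decB <- .enumLogTotals(.clampLog(pB, config@floor))
    massA <- exp(.enumLogTotals(log(pA)))
    massB <- exp(.enumLogTotals(log(pB)))
    d <- decA - decB
    winA <- !is.nan(d) & d > 0   # ties (incl. -Inf vs -Inf) go to B
    AccuracyReport(markerIds, sum(massA[winA]), sum(massB[!winA]),
                   method = "exact")
}

#' Monte-Carlo classification accuracy
#'
#' Simulates \code{nSims} genotype profiles from each population, classifies
#' each by the likelihood-ratio rule, and reports the empirical accuracies
#' with their binomial standard errors. Deterministic given \code{seed}.
#'
#' @inheritParams exactAccuracy
#' @param nSims Number of simulated profiles per population.
#' @param seed Integer seed for the simulation.
#' @return An \code{\linkS4class{AccuracyReport}} with method
#'   \code{"monte_carlo"}.
#' @examples
#' p <- examplePanel()
#' monteCarloAccuracy(p$A, p$B, c("rs2856838", "rs8193036"),
#'                    nSims = 1000, seed = 1)
#' @export
monteCarloAccuracy <- function(A, B, markerIds = NULL, nSims, seed,
                               config = ClassifierConfig()) {
    if (is.null(markerIds)) markerIds <- markerIds(A)
    stopifnot(nSims >= 1)
    pA <- probMatrix(A, markerIds)
    pB <- probMatrix(B, markerIds)
    lA <- .clampLog(pA, config@floor)
    lB <- .clampLog(pB, config@floor)
    set.seed(seed)
    accOne <- function(gen) {
        ## draw genotype indices marker by marker, accumulate both log-liks
        sA <- numeric(nSims); sB <- numeric(nSims)
        for (j in seq_len(ncol(gen))) {
            g <- sample.int(3L, nSims, replace = TRUE, prob = gen[, j])
            sA <- sA + lA[g, j]
            sB <- sB + lB[g, j]
        }
        d <- sA - sB
        d[is.nan(d)] <- 0
        d
    }
    dA <- accOne(pA)   # profiles drawn from A
    dB <- accOne(pB)   # profiles drawn from B
    accA <- mean(dA > 0)
    accB <- mean(dB <= 0)
    se <- sqrt(c(accA * (1 - accA), accB * (1 - accB)) / nSims)
    AccuracyReport(markerIds, accA, accB, method = "monte_carlo",
                   nSims = nSims, stdError = se, seed = seed)
}

#' Accuracy of nested marker panels
#'
#' Exact accuracy reports for growing prefixes of an ordered marker list:
#' the first \code{step} markers, the first \code{2 step}, and so on. With
#' the packaged eight-marker panel order and \code{step = 2} this produces
#' the accuracy curve for panels of 2, 4, 6 and 8 markers.
#'
#' @inheritParams exactAccuracy
#' @param orderedMarkerIds Marker ids in panel-growth order.
#' @param step Number of markers added per panel (>= 1).
#' @return A list of \code{\linkS4class{AccuracyReport}}s.
#' @examples
#' p <- examplePanel()
#' reports <- nestedPanelAccuracies(p$A, p$B, markerIds(p$A), step = 4)
#' sapply(reports, accuracyUnderA)
#' @export
nestedPanelAccuracies <- function(A, B, orderedMarkerIds, step = 2,
                                  config = ClassifierConfig()) {
    stopifnot(step >= 1)
    sizes <- seq(step, length(orderedMarkerIds), by = step)
    lapply(sizes, function(k)
        exactAccuracy(A, B, orderedMarkerIds[seq_len(k)], config))
}

#' Turn accuracy reports into a data.frame
#'
#' @param reports A list of \code{\linkS4class{AccuracyReport}}s (or one).
#' @return A data.frame with columns n_markers, marker_ids, acc_under_A,
#'   acc_under_B, balanced, method, n_sims, seed.
#' @examples
#' p <- examplePanel()
#' accuracyTable(nestedPanelAccuracies(p$A, p$B, markerIds(p$A), step = 4))
#' @export
accuracyTable <- function(reports) {
    if (is(reports, "AccuracyReport")) reports <- list(reports)
    do.call(rbind, lapply(reports, function(r) data.frame(
        n_markers = length(markerIds(r)),
        marker_ids = paste(markerIds(r), collapse = ","),
        acc_under_A = accuracyUnderA(r),
        acc_under_B = accuracyUnderB(r),
        balanced = balancedAccuracy(r),
        method = accuracyMethod(r),
        n_sims = r@nSims,
        seed = r@seed,
        stringsAsFactors = FALSE)))
}
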