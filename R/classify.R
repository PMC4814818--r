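#' @include AllClasses.R
NULL

## clamp a genotype probability at the configured floor; floor = 0 disables
## clamping and lets log(0) = -Inf through
.clampLog <- function(p, floor) {
    if (floor > 0) log(pmax(p, floor)) else log(p)
}

## internal log-likelihood with bookkeeping
.logLik <- function(profile, model, config) {
    cl <- calls(profile)
    ids <- names(cl)
    modeled <- ids %in% markerIds(model)
    used <- 0L
    skipped <- sum(!modeled) + sum(modeled & is.na(cl))
    ll <- 0
    for (id in ids[modeled & !is.na(cl)]) {
        m <- getMarker(model, id)
        cats <- genotypeCategories(m)
        k <- match(cl[[id]], cats)
        if (is.na(k))
            stop(sprintf(
                "genotype '%s' at %s is inconsistent with alleles %s/%s",
                cl[[id]], id, alleles(m)[1], alleles(m)[2]))
        ll <- ll + .clampLog(probs(getDistribution(model, id))[k], config@floor)
        used <- used + 1L
    }
    list(ll = ll, used = used, skipped = skipped)
}

#' Log-likelihood of a sample profile under one population model
#'
#' The likelihood of a profile is the product, over its called and modelled
#' markers, of the population's probability of the observed genotype; the
#' computation is carried out in natural-log space. Missing calls and markers
#' absent from the model contribute a factor of 1. Probabilities below the
#' configured floor are clamped to the floor.
#'
#' @param profile A \code{\linkS4class{SampleProfile}}.
#' @param model A \code{\linkS4class{PopulationModel}}.
#' @param config A \code{\linkS4class{ClassifierConfig}}.
#' @return The log-likelihood (0 for an empty profile).
#' @examples
#' p <- examplePanel()
#' logLikelihood(SampleProfile("S1", c(rs2856838 = "CC")), p$A)  # log(0.562)
#' @export
logLikelihood <- function(profile, model, config = ClassifierConfig()) {
    .logLik(profile, model, config)$ll
}

## error when a profile's markers are modelled in one population only
.checkSymmetric <- function(profile, A, B) {
    ids <- names(calls(profile))
    inA <- ids %in% markerIds(A)
    inB <- ids %in% markerIds(B)
    bad <- ids[xor(inA, inB)]
    if (length(bad))
        stop(sprintf("markers modelled in only one population: %s",
                     paste(bad, collapse = ", ")))
}

.classifyOne <- function(profile, A, B, config, weighted) {
    .checkSymmetric(profile, A, B)
    ra <- .logLik(profile, A, config)
    rb <- .logLik(profile, B, config)
    scoreA <- ra$ll
    scoreB <- rb$ll
    if (weighted) {
        if (is.na(populationSize(A)) || is.na(populationSize(B)))
            stop("the expected-count rule needs sizeN on both population models")
        scoreA <- scoreA + log(populationSize(A))
        scoreB <- scoreB + log(populationSize(B))
    }
    ## strict > for A; ties (including -Inf vs -Inf) go to B
    win <- !is.nan(scoreA - scoreB) && (scoreA - scoreB) > 0
    LikelihoodResult(sampleId(profile), ra$ll, rb$ll, ra$used, ra$skipped,
                     if (win) populationLabel(A) else populationLabel(B))
}

#' Classify a sample by the likelihood-ratio rule
#'
#' Assigns the profile to population A when L(A)/L(B) > 1 and to population B
#' otherwise, so exact ties go to B. The two models must agree on which of
#' the profile's markers they cover.
#'
#' @inheritParams logLikelihood
#' @param A,B \code{\linkS4class{PopulationModel}}s for the two candidate
#'   populations.
#' @return A \code{\linkS4class{LikelihoodResult}}.
#' @examples
#' p <- examplePanel()
#' classifyLikelihoodRatio(SampleProfile("S1", c(rs2856838 = "CC")), p$A, p$B)
#' @export
classifyLikelihoodRatio <- function(profile, A, B,
                                    config = ClassifierConfig()) {
    .classifyOne(profile, A, B, config, weighted = FALSE)
}

#' Classify a sample by the population-size-weighted expected-count rule
#'
#' When the population sizes N(A) and N(B) are known, E(X) = N(X) L(X) is the
#' expected number of individuals of population X carrying the observed
#' genotype profile; the sample is assigned to A when E(A)/E(B) > 1 and to B
#' otherwise. With N(A) = N(B) this reduces exactly to
#' \code{\link{classifyLikelihoodRatio}}.
#'
#' @inheritParams classifyLikelihoodRatio
#' @return A \code{\linkS4class{LikelihoodResult}} (its \code{logRatio} slot
#'   remains the unweighted log L(A) - log L(B)).
#' @examples
#' p <- examplePanel()
#' A <- PopulationModel("A", markers(p$A), distributions(p$A), sizeN = 100)
#' B <- PopulationModel("B", markers(p$B), distributions(p$B), sizeN = 900)
#' classifyExpectedCounts(SampleProfile("S1", c(rs2856838 = "CC")), A, B)
#' @export
classifyExpectedCounts <- function(profile, A, B,
                                   config = ClassifierConfig()) {
    .classifyOne(profile, A, B, config, weighted = TRUE)
}

#' Classify a batch of sample profiles
#'
#' Applies \code{\link{classifyLikelihoodRatio}} (or, when
#' \code{config@usePopulationSizes} is set, \code{\link{classifyExpectedCounts}})
#' to every profile, in input order.
#'
#' @param x A \code{\linkS4class{GenotypeDataset}} or a list of
#'   \code{\linkS4class{SampleProfile}}s.
#' @inheritParams classifyLikelihoodRatio
#' @return A list with \code{results}, a data.frame with one row per sample
#'   (sample_id, log_lik_A, log_lik_B, log_ratio, label, n_used, n_skipped),
#'   and \code{tally}, the named label counts (population A first).
#' @examples
#' p <- examplePanel()
#' ds <- simulateProfiles(p$A, n = 5, seed = 1)
#' classifyBatch(ds, p$A, p$B)$tally
#' @export
classifyBatch <- function(x, A, B, config = ClassifierConfig()) {
    profiles <- if (is(x, "GenotypeDataset")) {
        lapply(seq_along(sampleIds(x)), function(i) profileAt(x, i))
    } else x
    res <- lapply(profiles, function(pr) {
        tryCatch(.classifyOne(pr, A, B, config, config@usePopulationSizes),
                 error = function(e) stop(sprintf("sample '%s': %s",
                                                  sampleId(pr), conditionMessage(e)),
                                          call. = FALSE))
    })
    df <- data.frame(
        sample_id = vapply(res, sampleId, character(1)),
        log_lik_A = vapply(res, logLikA, numeric(1)),
        log_lik_B = vapply(res, logLikB, numeric(1)),
        log_ratio = vapply(res, logRatio, numeric(1)),
        label = vapply(res, assignedLabel, character(1)),
        n_used = vapply(res, nMarkersUsed, integer(1)),
        n_skipped = vapply(res, nMarkersSkipped, integer(1)),
        stringsAsFactors = FALSE)
    tally <- c(sum(df$label == populationLabel(A)),
               sum(df$label == populationLabel(B)))
    names(tally) <- c(populationLabel(A), populationLabel(B))
    list(results = df, tally = tally)
}
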