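#' @include AllGenerics.R
NULL

MISSING_TOKENS <- c(".", "NN", "")

## canonical genotype label: allele characters sorted alphabetically,
## so "TC" and "CT" denote the same heterozygote
canonicalGenotype <- function(g) {
    vapply(g, function(x) {
        if (is.na(x)) return(NA_character_)
        paste(sort(strsplit(x, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# Marker
# ---------------------------------------------------------------------------

#' Marker: a biallelic SNP
#'
#' A biallelic SNP marker with an rsID, an informational cytogenetic band
#' label and an ordered allele pair. The three genotype categories follow
#' from the allele pair: homozygote of the first allele, heterozygote
#' (written with its allele characters sorted alphabetically), homozygote of
#' the second allele.
#'
#' @slot id rsID string.
#' @slot locus Cytogenetic band label (informational, may be empty).
#' @slot alleles Ordered pair of distinct nucleotide characters from
#'   \code{A,C,G,T}.
#'
#' @param id,locus,alleles See slots.
#' @return \code{Marker()} returns a \code{Marker} object.
#'
#' @examples
#' m <- Marker("rs2243191", alleles = c("T", "C"), locus = "01q32")
#' genotypeCategories(m)  # "TT" "CT" "CC"
#' @aliases markerId,Marker-method alleles,Marker-method
#'   genotypeCategories,Marker-method show,Marker-method
#' @export Marker
#' @exportClass Marker
setClass("Marker", representation(
    id = "character",
    locus = "character",
    alleles = "character"
))

setValidity("Marker", function(object) {
    msg <- character(0)
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@alleles) != 2L ||
        !all(object@alleles %in% c("A", "C", "G", "T")))
        msg <- c(msg, "'alleles' must be two nucleotide characters from A,C,G,T")
    else if (object@alleles[1] == object@alleles[2])
        msg <- c(msg, "alleles must be distinct")
    if (length(msg)) msg else TRUE
})

#' @rdname Marker-class
#' @export
Marker <- function(id, alleles, locus = "") {
    new("Marker", id = as.character(id), locus = as.character(locus),
        alleles = toupper(as.character(alleles)))
}

#' @export
setMethod("markerId", "Marker", function(x) x@id)

#' @export
setMethod("alleles", "Marker", function(x) x@alleles)

#' @export
setMethod("genotypeCategories", "Marker", function(x) {
    a <- x@alleles
    c(paste0(a[1], a[1]), paste(sort(a), collapse = ""), paste0(a[2], a[2]))
})

setMethod("show", "Marker", function(object) {
    cat(sprintf("Marker %s [%s] alleles %s:%s (%s)\n", object@id,
        if (nzchar(object@locus)) object@locus else "-",
        object@alleles[1], object@alleles[2],
        paste(genotypeCategories(object), collapse = "/")))
})

# ---------------------------------------------------------------------------
# GenotypeDistribution
# ---------------------------------------------------------------------------

#' GenotypeDistribution: trinomial genotype frequencies of one marker
#'
#' The trinomial parameters (p, q, r) of one marker in one population,
#' ordered (homozygote of the first allele, heterozygote, homozygote of the
#' second allele). Triples whose printed values sum to 1 within
#' \code{tolerance} (default 0.005, covering 3-decimal rounding residue) are
#' renormalized by dividing by their sum at construction; a larger residue is
#' an error.
#'
#' @slot markerId rsID string.
#' @slot probs Numeric triple summing to 1.
#'
#' @param markerId,probs See slots.
#' @param tolerance Maximum tolerated |sum - 1| before renormalization.
#' @return \code{GenotypeDistribution()} returns a
#'   \code{GenotypeDistribution} object.
#'
#' @examples
#' GenotypeDistribution("rs2856838", c(0.562, 0.379, 0.059))
#' @aliases markerId,GenotypeDistribution-method
#'   probs,GenotypeDistribution-method show,GenotypeDistribution-method
#' @export GenotypeDistribution
#' @exportClass GenotypeDistribution
setClass("GenotypeDistribution", representation(
    markerId = "character",
    probs = "numeric"
))

setValidity("GenotypeDistribution", function(object) {
    msg <- character(0)
    if (length(object@markerId) != 1L)
        msg <- c(msg, "'markerId' must be a single string")
    p <- object@probs
    if (length(p) != 3L || anyNA(p))
        msg <- c(msg, "'probs' must be a numeric triple without NA")
    else {
        if (any(p < 0) || any(p > 1))
            msg <- c(msg, "probabilities must lie in [0, 1]")
        if (abs(sum(p) - 1) > 1e-9)
            msg <- c(msg, sprintf("probabilities must sum to 1 (got %.6f)", sum(p)))
    }
    if (length(msg)) msg else TRUE
})

#' @rdname GenotypeDistribution-class
#' @export
GenotypeDistribution <- function(markerId, probs, tolerance = 0.005) {
    probs <- as.numeric(probs)
    if (length(probs) != 3L || anyNA(probs))
        stop("'probs' must be a numeric triple without NA")
    s <- sum(probs)
    if (abs(s - 1) > tolerance)
        stop(sprintf("genotype frequencies of %s sum to %.4f, outside 1 +/- %.3g",
                     markerId, s, tolerance))
    new("GenotypeDistribution", markerId = as.character(markerId),
        probs = probs / s)
}

#' @export
setMethod("markerId", "GenotypeDistribution", function(x) x@markerId)

#' @export
setMethod("probs", "GenotypeDistribution", function(x) x@probs)

setMethod("show", "GenotypeDistribution", function(object) {
    cat(sprintf("GenotypeDistribution %s: (%.4f, %.4f, %.4f)\n",
        object@markerId, object@probs[1], object@probs[2], object@probs[3]))
})

# ---------------------------------------------------------------------------
# GenotypeCounts
# ---------------------------------------------------------------------------

#' GenotypeCounts: observed genotype counts at one marker
#'
#' Non-negative integer counts (n_hom1, n_het, n_hom2) of the three genotype
#' categories of a biallelic marker, as used by the Hardy-Weinberg tests.
#'
#' @slot counts Integer triple of non-negative counts.
#'
#' @param counts Numeric/integer triple of non-negative counts.
#' @return \code{GenotypeCounts()} returns a \code{GenotypeCounts} object.
#'
#' @examples
#' GenotypeCounts(c(25, 50, 25))
#' @aliases show,GenotypeCounts-method
#' @export GenotypeCounts
#' @exportClass GenotypeCounts
setClass("GenotypeCounts", representation(counts = "integer"))

setValidity("GenotypeCounts", function(object) {
    n <- object@counts
    if (length(n) != 3L || anyNA(n)) return("'counts' must be an integer triple")
    if (any(n < 0)) return("counts must be non-negative")
    if (sum(n) < 1) return("total count must be >= 1")
    TRUE
})

#' @rdname GenotypeCounts-class
#' @export
GenotypeCounts <- function(counts) {
    counts <- as.numeric(counts)
    if (any(abs(counts - round(counts)) > 1e-8))
        stop("genotype counts must be whole numbers")
    new("GenotypeCounts", counts = as.integer(round(counts)))
}

setMethod("show", "GenotypeCounts", function(object) {
    cat(sprintf("GenotypeCounts (%d, %d, %d), n = %d\n", object@counts[1],
        object@counts[2], object@counts[3], sum(object@counts)))
})

# ---------------------------------------------------------------------------
# PopulationModel
# ---------------------------------------------------------------------------

#' PopulationModel: a named population's genotype-frequency model
#'
#' A named population: an ordered list of markers, one genotype-frequency
#' distribution per marker, an optional population size N (used by the
#' expected-count classification rule) and optional per-marker sample counts
#' (the number of individuals behind each marker's frequencies, when known).
#'
#' @slot label Population name.
#' @slot markers List of \code{\linkS4class{Marker}}, unique ids.
#' @slot distributions List of \code{\linkS4class{GenotypeDistribution}},
#'   aligned 1:1 with \code{markers}.
#' @slot sizeN Integer population size, \code{NA} when unknown.
#' @slot markerCounts Numeric per-marker sample sizes, \code{NA} when unknown.
#'
#' @param label,markers,distributions,sizeN,markerCounts See slots.
#' @return \code{PopulationModel()} returns a \code{PopulationModel}.
#'
#' @examples
#' m <- Marker("rs1", c("C", "T"))
#' d <- GenotypeDistribution("rs1", c(0.25, 0.5, 0.25))
#' PopulationModel("toy", list(m), list(d))
#' @aliases populationLabel,PopulationModel-method
#'   populationSize,PopulationModel-method markers,PopulationModel-method
#'   distributions,PopulationModel-method markerIds,PopulationModel-method
#'   markerCounts,PopulationModel-method show,PopulationModel-method
#' @export PopulationModel
#' @exportClass PopulationModel
setClass("PopulationModel", representation(
    label = "character",
    markers = "list",
    distributions = "list",
    sizeN = "integer",
    markerCounts = "numeric"
))

setValidity("PopulationModel", function(object) {
    msg <- character(0)
    if (length(object@label) != 1L || !nzchar(object@label))
        msg <- c(msg, "'label' must be a single non-empty string")
    ids <- vapply(object@markers, markerId, character(1))
    if (anyDuplicated(ids))
        msg <- c(msg, "marker ids must be unique")
    if (length(object@distributions) != length(object@markers))
        msg <- c(msg, "need exactly one distribution per marker")
    else {
        dids <- vapply(object@distributions, markerId, character(1))
        if (!identical(ids, dids))
            msg <- c(msg, "distributions must align with markers (same ids, same order)")
    }
    if (length(object@sizeN) != 1L)
        msg <- c(msg, "'sizeN' must be a single integer or NA")
    else if (!is.na(object@sizeN) && object@sizeN < 1L)
        msg <- c(msg, "'sizeN' must be >= 1 when present")
    if (length(object@markerCounts) != length(object@markers))
        msg <- c(msg, "'markerCounts' must align with markers")
    if (length(msg)) msg else TRUE
})

#' @rdname PopulationModel-class
#' @export
PopulationModel <- function(label, markers, distributions, sizeN = NA,
                            markerCounts = NULL) {
    if (is.null(markerCounts)) markerCounts <- rep(NA_real_, length(markers))
    new("PopulationModel", label = as.character(label), markers = markers,
        distributions = distributions, sizeN = as.integer(sizeN),
        markerCounts = as.numeric(markerCounts))
}

#' @export
setMethod("populationLabel", "PopulationModel", function(x) x@label)

#' @export
setMethod("populationSize", "PopulationModel", function(x) x@sizeN)

#' @export
setMethod("markers", "PopulationModel", function(x) x@markers)

#' @export
setMethod("distributions", "PopulationModel", function(x) x@distributions)

#' @export
setMethod("markerCounts", "PopulationModel", function(x) {
    structure(x@markerCounts, names = markerIds(x))
})

#' @export
setMethod("markerIds", "PopulationModel", function(x) {
    vapply(x@markers, markerId, character(1))
})

setMethod("show", "PopulationModel", function(object) {
    cat(sprintf("PopulationModel '%s': %d markers%s\n", object@label,
        length(object@markers),
        if (is.na(object@sizeN)) "" else sprintf(", N = %d", object@sizeN)))
    ids <- markerIds(object)
    for (i in seq_len(min(length(ids), 8L))) {
        p <- probs(object@distributions[[i]])
        cat(sprintf("  %-12s %s  (%.3f, %.3f, %.3f)\n", ids[i],
            paste(genotypeCategories(object@markers[[i]]), collapse = "/"),
            p[1], p[2], p[3]))
    }
    if (length(ids) > 8L) cat(sprintf("  ... and %d more\n", length(ids) - 8L))
})

## internal: fetch marker / distribution by id (error when absent)
getMarker <- function(model, id) {
    i <- match(id, markerIds(model))
    if (is.na(i)) stop(sprintf("marker %s not in model '%s'", id, model@label))
    model@markers[[i]]
}

getDistribution <- function(model, id) {
    i <- match(id, markerIds(model))
    if (is.na(i)) stop(sprintf("marker %s not in model '%s'", id, model@label))
    model@distributions[[i]]
}

## internal: 3 x m matrix of genotype probabilities for a set of marker ids,
## rows aligned to each marker's (hom1, het, hom2) categories
probMatrix <- function(model, ids = markerIds(model)) {
    i <- match(ids, markerIds(model))
    if (anyNA(i))
        stop(sprintf("markers absent from model '%s': %s", model@label,
                     paste(ids[is.na(i)], collapse = ", ")))
    vapply(i, function(j) probs(model@distributions[[j]]), numeric(3))
}

# ---------------------------------------------------------------------------
# SampleProfile
# ---------------------------------------------------------------------------

#' SampleProfile: one individual's genotype calls
#'
#' One individual's genotype calls across markers: a character vector of
#' canonical genotype labels named by marker id, with \code{NA} for missing
#' calls. At most one call per marker. Heterozygote labels are canonicalized
#' (allele characters sorted) at construction.
#'
#' @slot sampleId Sample identifier.
#' @slot calls Named character vector of genotype labels (NA = missing).
#'
#' @param sampleId,calls See slots. Missing tokens \code{"."}, \code{"NN"}
#'   and \code{""} are converted to \code{NA}.
#' @return \code{SampleProfile()} returns a \code{SampleProfile}.
#'
#' @examples
#' SampleProfile("S1", c(rs2856838 = "CC", rs8193036 = "TC"))
#' @aliases sampleId,SampleProfile-method calls,SampleProfile-method
#'   show,SampleProfile-method
#' @export SampleProfile
#' @exportClass SampleProfile
setClass("SampleProfile", representation(
    sampleId = "character",
    calls = "character"
))

setValidity("SampleProfile", function(object) {
    msg <- character(0)
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "'sampleId' must be a single string")
    if (length(object@calls) && is.null(names(object@calls)))
        msg <- c(msg, "'calls' must be named by marker id")
    if (anyDuplicated(names(object@calls)))
        msg <- c(msg, "duplicate marker ids in calls")
    if (length(msg)) msg else TRUE
})

#' @rdname SampleProfile-class
#' @export
SampleProfile <- function(sampleId, calls = character(0)) {
    calls <- vapply(calls, as.character, character(1))
    calls[calls %in% MISSING_TOKENS] <- NA_character_
    cc <- canonicalGenotype(calls)
    names(cc) <- names(calls)
    new("SampleProfile", sampleId = as.character(sampleId), calls = cc)
}

#' @export
setMethod("sampleId", "SampleProfile", function(x) x@sampleId)

#' @export
setMethod("calls", "SampleProfile", function(x) x@calls)

setMethod("show", "SampleProfile", function(object) {
    cat(sprintf("SampleProfile '%s': %d calls (%d missing)\n", object@sampleId,
        length(object@calls), sum(is.na(object@calls))))
})

# ---------------------------------------------------------------------------
# GenotypeDataset
# ---------------------------------------------------------------------------

#' GenotypeDataset: genotype calls for many samples
#'
#' A rectangular genotype dataset: a character matrix of canonical genotype
#' labels with samples as rows and markers as columns (\code{NA} = missing),
#' plus optional per-sample true population labels and free-form metadata
#' (e.g. counts of records skipped during VCF import).
#'
#' @slot genotypes Character matrix, rownames = sample ids, colnames =
#'   marker ids.
#' @slot trueLabels Character vector of population labels aligned with rows,
#'   or length zero when unknown.
#' @slot metadata List of provenance information.
#'
#' @param genotypes,trueLabels,metadata See slots.
#' @return \code{GenotypeDataset()} returns a \code{GenotypeDataset}.
#'
#' @examples
#' g <- matrix(c("CC", "CT"), nrow = 1,
#'             dimnames = list("S1", c("rs1", "rs2")))
#' GenotypeDataset(g)
#' @aliases sampleIds,GenotypeDataset-method markerIds,GenotypeDataset-method
#'   genotypes,GenotypeDataset-method trueLabels,GenotypeDataset-method
#'   show,GenotypeDataset-method
#' @export GenotypeDataset
#' @exportClass GenotypeDataset
setClass("GenotypeDataset", representation(
    genotypes = "matrix",
    trueLabels = "character",
    metadata = "list"
))

setValidity("GenotypeDataset", function(object) {
    msg <- character(0)
    g <- object@genotypes
    if (!is.character(g))
        msg <- c(msg, "'genotypes' must be a character matrix")
    if (is.null(rownames(g)) && nrow(g) > 0)
        msg <- c(msg, "'genotypes' must have sample ids as rownames")
    if (is.null(colnames(g)) && ncol(g) > 0)
        msg <- c(msg, "'genotypes' must have marker ids as colnames")
    if (anyDuplicated(rownames(g)))
        msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(g)))
        msg <- c(msg, "duplicate marker ids")
    if (length(object@trueLabels) && length(object@trueLabels) != nrow(g))
        msg <- c(msg, "'trueLabels' must align 1:1 with samples")
    if (length(msg)) msg else TRUE
})

#' @rdname GenotypeDataset-class
#' @export
GenotypeDataset <- function(genotypes, trueLabels = character(0),
                            metadata = list()) {
    if (length(genotypes)) {
        cg <- canonicalGenotype(genotypes)
        cg[cg %in% MISSING_TOKENS] <- NA_character_
        genotypes[] <- cg
    }
    new("GenotypeDataset", genotypes = genotypes,
        trueLabels = as.character(trueLabels), metadata = metadata)
}

#' @export
setMethod("sampleIds", "GenotypeDataset", function(x) rownames(x@genotypes))

#' @export
setMethod("markerIds", "GenotypeDataset", function(x) colnames(x@genotypes))

#' @export
setMethod("genotypes", "GenotypeDataset", function(x) x@genotypes)

#' @export
setMethod("trueLabels", "GenotypeDataset", function(x) x@trueLabels)

setMethod("show", "GenotypeDataset", function(object) {
    cat(sprintf("GenotypeDataset: %d samples x %d markers (%.1f%% missing)%s\n",
        nrow(object@genotypes), ncol(object@genotypes),
        if (length(object@genotypes)) 100 * mean(is.na(object@genotypes)) else 0,
        if (length(object@trueLabels)) ", labelled" else ""))
})

#' Extract one sample of a GenotypeDataset as a SampleProfile
#'
#' @param dataset A \code{\linkS4class{GenotypeDataset}}.
#' @param i Row index or sample id.
#' @return A \code{\linkS4class{SampleProfile}}.
#' @examples
#' g <- matrix("CC", 1, 1, dimnames = list("S1", "rs1"))
#' profileAt(GenotypeDataset(g), "S1")
#' @export
profileAt <- function(dataset, i) {
    g <- genotypes(dataset)
    if (is.character(i)) i <- match(i, rownames(g))
    SampleProfile(rownames(g)[i], g[i, ])
}

# ---------------------------------------------------------------------------
# ClassifierConfig
# ---------------------------------------------------------------------------

#' ClassifierConfig: tuning knobs of the classification rules
#'
#' Configuration for the likelihood computations. \code{floor} is the small
#' probability substituted for genotype probabilities below it, so that a
#' sampling zero in one population cannot force an infinite likelihood ratio
#' from a single marker; set \code{floor = 0} to disable clamping, in which
#' case a zero probability yields a -Inf log-likelihood (and -Inf vs -Inf
#' counts as a tie, which goes to population B).
#'
#' @slot floor Probability floor in [0, 1).
#' @slot usePopulationSizes Whether classification should weight likelihoods
#'   by population sizes (the expected-count rule).
#'
#' @param floor,usePopulationSizes See slots.
#' @return \code{ClassifierConfig()} returns a \code{ClassifierConfig}.
#'
#' @examples
#' ClassifierConfig()
#' ClassifierConfig(floor = 0)
#' @aliases show,ClassifierConfig-method
#' @export ClassifierConfig
#' @exportClass ClassifierConfig
setClass("ClassifierConfig", representation(
    floor = "numeric",
    usePopulationSizes = "logical"
))

setValidity("ClassifierConfig", function(object) {
    if (length(object@floor) != 1L || is.na(object@floor) ||
        object@floor < 0 || object@floor >= 1)
        return("'floor' must be a single value in [0, 1)")
    if (length(object@usePopulationSizes) != 1L || is.na(object@usePopulationSizes))
        return("'usePopulationSizes' must be TRUE or FALSE")
    TRUE
})

#' @rdname ClassifierConfig-class
#' @export
ClassifierConfig <- function(floor = 1e-6, usePopulationSizes = FALSE) {
    new("ClassifierConfig", floor = as.numeric(floor),
        usePopulationSizes = as.logical(usePopulationSizes))
}

setMethod("show", "ClassifierConfig", function(object) {
    cat(sprintf("ClassifierConfig: floor = %g, usePopulationSizes = %s\n",
        object@floor, object@usePopulationSizes))
})

# ---------------------------------------------------------------------------
# LikelihoodResult
# ---------------------------------------------------------------------------

#' LikelihoodResult: outcome of classifying one sample
#'
#' Log-likelihoods (natural log) of a sample profile under the two population
#' models, their difference, the number of markers used and skipped, and the
#' assigned population label. \code{logRatio} is always the unweighted
#' \code{logLikA - logLikB}; under the expected-count rule the decision also
#' incorporates \code{log N(A) - log N(B)}.
#'
#' @slot sampleId Sample identifier.
#' @slot logLikA,logLikB Log-likelihoods under populations A and B.
#' @slot logRatio \code{logLikA - logLikB}.
#' @slot nUsed,nSkipped Markers used / skipped (missing or unmodelled).
#' @slot label Assigned population name.
#'
#' @param sampleId,logLikA,logLikB,nUsed,nSkipped,label See slots.
#' @return \code{LikelihoodResult()} returns a \code{LikelihoodResult}.
#' @aliases sampleId,LikelihoodResult-method logLikA,LikelihoodResult-method
#'   logLikB,LikelihoodResult-method logRatio,LikelihoodResult-method
#'   assignedLabel,LikelihoodResult-method
#'   nMarkersUsed,LikelihoodResult-method
#'   nMarkersSkipped,LikelihoodResult-method show,LikelihoodResult-method
#' @export LikelihoodResult
#' @exportClass LikelihoodResult
setClass("LikelihoodResult", representation(
    sampleId = "character",
    logLikA = "numeric",
    logLikB = "numeric",
    logRatio = "numeric",
    nUsed = "integer",
    nSkipped = "integer",
    label = "character"
))

setValidity("LikelihoodResult", function(object) {
    d <- object@logLikA - object@logLikB
    if (is.finite(d) && is.finite(object@logRatio) &&
        abs(d - object@logRatio) > 1e-12)
        return("logRatio inconsistent with the two log-likelihoods")
    TRUE
})

#' @rdname LikelihoodResult-class
#' @export
LikelihoodResult <- function(sampleId, logLikA, logLikB, nUsed, nSkipped,
                             label) {
    d <- logLikA - logLikB
    if (is.nan(d)) d <- 0  # -Inf vs -Inf: a tie
    new("LikelihoodResult", sampleId = as.character(sampleId),
        logLikA = logLikA, logLikB = logLikB, logRatio = d,
        nUsed = as.integer(nUsed), nSkipped = as.integer(nSkipped),
        label = as.character(label))
}

#' @export
setMethod("sampleId", "LikelihoodResult", function(x) x@sampleId)

#' @export
setMethod("logLikA", "LikelihoodResult", function(x) x@logLikA)

#' @export
setMethod("logLikB", "LikelihoodResult", function(x) x@logLikB)

#' @export
setMethod("logRatio", "LikelihoodResult", function(x) x@logRatio)

#' @export
setMethod("assignedLabel", "LikelihoodResult", function(x) x@label)

#' @export
setMethod("nMarkersUsed", "LikelihoodResult", function(x) x@nUsed)

#' @export
setMethod("nMarkersSkipped", "LikelihoodResult", function(x) x@nSkipped)

setMethod("show", "LikelihoodResult", function(object) {
    ratio <- exp(object@logRatio)
    cat(sprintf(
        "LikelihoodResult '%s': label %s (log LR = %.4f, LR = %s; %d used, %d skipped)\n",
        object@sampleId, object@label, object@logRatio,
        if (is.finite(ratio)) sprintf("%.4g", ratio) else format(ratio),
        object@nUsed, object@nSkipped))
})

# ---------------------------------------------------------------------------
# AccuracyReport
# ---------------------------------------------------------------------------

#' AccuracyReport: classification power of a marker panel
#'
#' The probability that a random individual of population A (respectively B)
#' is assigned back to its own population by the likelihood-ratio rule, for a
#' given marker subset, computed either exactly (exhaustive enumeration of
#' genotype vectors) or by Monte-Carlo simulation. \code{balancedAccuracy} is
#' the mean of the two per-population accuracies.
#'
#' @slot markerIds Ordered marker subset used.
#' @slot accuracyA,accuracyB Per-population accuracies in [0, 1].
#' @slot balanced Mean of the two.
#' @slot method \code{"exact"} or \code{"monte_carlo"}.
#' @slot nSims,stdError,seed Monte-Carlo metadata (\code{NA} for exact
#'   reports); \code{stdError} holds the two binomial standard errors.
#'
#' @param markerIds,accuracyA,accuracyB,method,nSims,stdError,seed See slots.
#' @return \code{AccuracyReport()} returns an \code{AccuracyReport}.
#' @aliases markerIds,AccuracyReport-method
#'   accuracyUnderA,AccuracyReport-method accuracyUnderB,AccuracyReport-method
#'   balancedAccuracy,AccuracyReport-method
#'   accuracyMethod,AccuracyReport-method show,AccuracyReport-method
#' @export AccuracyReport
#' @exportClass AccuracyReport
setClass("AccuracyReport", representation(
    markerIds = "character",
    accuracyA = "numeric",
    accuracyB = "numeric",
    balanced = "numeric",
    method = "character",
    nSims = "integer",
    stdError = "numeric",
    seed = "integer"
))

setValidity("AccuracyReport", function(object) {
    msg <- character(0)
    acc <- c(object@accuracyA, object@accuracyB, object@balanced)
    if (any(acc < -1e-12 | acc > 1 + 1e-12))
        msg <- c(msg, "accuracies must lie in [0, 1]")
    if (abs(object@balanced - (object@accuracyA + object@accuracyB) / 2) > 1e-12)
        msg <- c(msg, "balanced accuracy must be the mean of the two accuracies")
    if (!object@method %in% c("exact", "monte_carlo"))
        msg <- c(msg, "method must be 'exact' or 'monte_carlo'")
    if (object@method == "monte_carlo" && is.na(object@nSims))
        msg <- c(msg, "monte_carlo reports need nSims")
    if (length(msg)) msg else TRUE
})

#' @rdname AccuracyReport-class
#' @export
AccuracyReport <- function(markerIds, accuracyA, accuracyB, method,
                           nSims = NA, stdError = c(NA_real_, NA_real_),
                           seed = NA) {
    new("AccuracyReport", markerIds = as.character(markerIds),
        accuracyA = accuracyA, accuracyB = accuracyB,
        balanced = (accuracyA + accuracyB) / 2, method = method,
        nSims = as.integer(nSims), stdError = as.numeric(stdError),
        seed = as.integer(seed))
}

#' @export
setMethod("markerIds", "AccuracyReport", function(x) x@markerIds)

#' @export
setMethod("accuracyUnderA", "AccuracyReport", function(x) x@accuracyA)

#' @export
setMethod("accuracyUnderB", "AccuracyReport", function(x) x@accuracyB)

#' @export
setMethod("balancedAccuracy", "AccuracyReport", function(x) x@balanced)

#' @export
setMethod("accuracyMethod", "AccuracyReport", function(x) x@method)

setMethod("show", "AccuracyReport", function(object) {
    cat(sprintf(
        "AccuracyReport (%s, %d markers): under A %.3f, under B %.3f, balanced %.3f\n",
        object@method, length(object@markerIds), object@accuracyA,
        object@accuracyB, object@balanced))
    if (object@method == "monte_carlo")
        cat(sprintf("  nSims = %d, SE = (%.4f, %.4f), seed = %d\n",
            object@nSims, object@stdError[1], object@stdError[2], object@seed))
})
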