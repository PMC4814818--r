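#' Accessor generics
#'
#' Small accessor generics shared by the S4 classes in this package. Each has
#' methods documented on the class it applies to.
#'
#' @param x An object of one of the package's S4 classes.
#' @return The slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markerId", function(x) standardGeneric("markerId"))

#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname accessors
#' @export
setGeneric("genotypeCategories", function(x) standardGeneric("genotypeCategories"))

#' @rdname accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname accessors
#' @export
setGeneric("populationLabel", function(x) standardGeneric("populationLabel"))

#' @rdname accessors
#' @export
setGeneric("populationSize", function(x) standardGeneric("populationSize"))

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname accessors
#' @export
setGeneric("distributions", function(x) standardGeneric("distributions"))

#' @rdname accessors
#' @export
setGeneric("markerCounts", function(x) standardGeneric("markerCounts"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("logLikA", function(x) standardGeneric("logLikA"))

#' @rdname accessors
#' @export
setGeneric("logLikB", function(x) standardGeneric("logLikB"))

#' @rdname accessors
#' @export
setGeneric("logRatio", function(x) standardGeneric("logRatio"))

#' @rdname accessors
#' @export
setGeneric("assignedLabel", function(x) standardGeneric("assignedLabel"))

#' @rdname accessors
#' @export
setGeneric("nMarkersUsed", function(x) standardGeneric("nMarkersUsed"))

#' @rdname accessors
#' @export
setGeneric("nMarkersSkipped", function(x) standardGeneric("nMarkersSkipped"))

#' @rdname accessors
#' @export
setGeneric("accuracyUnderA", function(x) standardGeneric("accuracyUnderA"))

#' @rdname accessors
#' @export
setGeneric("accuracyUnderB", function(x) standardGeneric("accuracyUnderB"))

#' @rdname accessors
#' @export
setGeneric("balancedAccuracy", function(x) standardGeneric("balancedAccuracy"))

#' @rdname accessors
#' @export
setGeneric("accuracyMethod", function(x) standardGeneric("accuracyMethod"))
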