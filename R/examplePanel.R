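#' @include io.R
NULL

#' Packaged eight-marker example panel
#'
#' Loads the genotype-frequency tables of a published eight-SNP panel that
#' ships with the package: population A, a regional cohort of 641 genotyped
#' individuals, and population B, a general reference population whose
#' frequencies come from a public SNP database (with the per-marker sample
#' counts behind them). The marker summary carries each marker's cytogenetic
#' band, observed heterozygosity, Hardy-Weinberg p-value, MAF and allele
#' pair; the panel was assembled by MAF filtering (all MAF in [0.249,
#' 0.355]). The frequency files are transcribed as printed (three decimals),
#' so loading them exercises the reader's renormalization of rounding
#' residue.
#'
#' @param markerOrder Optional character vector giving the marker order of
#'   the returned models; default \code{panelOrder()}.
#' @return A list with \code{A} and \code{B}
#'   (\code{\linkS4class{PopulationModel}}s), \code{markers} (list of
#'   \code{\linkS4class{Marker}}) and \code{info} (the marker summary
#'   data.frame).
#' @examples
#' p <- examplePanel()
#' p$A
#' @export
examplePanel <- function(markerOrder = panelOrder()) {
    mt <- readMarkerTable(system.file("extdata", "panel_markers.tsv",
                                      package = "SNPclassify"))
    A <- readFrequencyTable(system.file("extdata", "popA_genotype_freqs.tsv",
                                        package = "SNPclassify"),
                            layout = "wide", label = "A",
                            markers = mt$markers, sizeN = 641)
    B <- readFrequencyTable(system.file("extdata", "popB_genotype_freqs.tsv",
                                        package = "SNPclassify"),
                            layout = "wide", label = "B",
                            markers = mt$markers)
    list(A = reorderModel(A, markerOrder), B = reorderModel(B, markerOrder),
         markers = mt$markers, info = mt$info)
}

#' Canonical marker order of the packaged panel
#'
#' The panel-growth order used by the packaged accuracy curve: panels of 2,
#' 4, 6 and 8 markers are prefixes of this sequence.
#'
#' @return Character vector of eight rsIDs.
#' @examples
#' panelOrder()[1:2]
#' @export
panelOrder <- function() {
    c("rs2856838", "rs8193036", "rs2243191", "rs20541",
      "rs2227306", "rs4739139", "rs741344", "rs583911")
}

#' Reorder or subset a population model's markers
#'
#' @param model A \code{\linkS4class{PopulationModel}}.
#' @param ids Marker ids in the desired order (must all exist in the model).
#' @return The reordered \code{\linkS4class{PopulationModel}}.
#' @examples
#' p <- examplePanel()
#' markerIds(reorderModel(p$A, c("rs20541", "rs2856838")))
#' @export
reorderModel <- function(model, ids) {
    i <- match(ids, markerIds(model))
    if (anyNA(i))
        stop(sprintf("markers absent from model '%s': %s",
                     populationLabel(model), paste(ids[is.na(i)], collapse = ", ")))
    PopulationModel(populationLabel(model), markers(model)[i],
                    distributions(model)[i], sizeN = populationSize(model),
                    markerCounts = model@markerCounts[i])
}
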