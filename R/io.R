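#' @include AllClasses.R
NULL

.readTsv <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "")
}

.num <- function(x) formatC(x, digits = 15, format = "g")

## resolve the Marker for one column: template when available, otherwise
## alleles inferred (alphabetical order) from the nonzero genotype rows
.resolveMarker <- function(id, nonzeroLabels, templates) {
    if (!is.null(templates) && id %in% names(templates))
        return(templates[[id]])
    chars <- sort(unique(unlist(strsplit(nonzeroLabels, ""))))
    if (length(chars) != 2L)
        stop(sprintf(
            "cannot infer the allele pair of %s: %d distinct allele character(s) in its nonzero genotype rows",
            id, length(chars)))
    Marker(id, chars)
}

.distFromRows <- function(id, labels, values, templates) {
    labels <- canonicalGenotype(labels)
    nz <- labels[values > 0]
    marker <- .resolveMarker(id, nz, templates)
    cats <- genotypeCategories(marker)
    bad <- setdiff(nz, cats)
    if (length(bad))
        stop(sprintf("nonzero genotype row(s) %s inconsistent with alleles %s/%s of %s",
                     paste(bad, collapse = ","), alleles(marker)[1],
                     alleles(marker)[2], id))
    ## structurally-zero rows (wrong alleles) are dropped; rows consistent
    ## with the allele pair are kept even when their value is 0
    keep <- labels %in% cats
    hits <- table(factor(labels[keep], levels = cats))
    if (any(hits != 1L))
        stop(sprintf("marker %s needs exactly one row per genotype category %s",
                     id, paste(cats, collapse = "/")))
    v <- values[keep][match(cats, labels[keep])]
    list(marker = marker, dist = GenotypeDistribution(id, v))
}

#' Read a genotype-frequency table as a population model
#'
#' Two layouts are supported. \code{"wide"} mirrors the printed tables:
#' genotype labels in the first column, one column per marker, and an
#' optional \code{Count} row holding the per-marker sample sizes; each marker
#' column has three rows consistent with its allele pair and structurally
#' zero rows for the other genotypes. \code{"long"} has columns
#' \code{marker_id}, \code{genotype}, \code{frequency}. Heterozygote labels
#' are canonicalized (\code{"TC"} and \code{"CT"} are the same category), and
#' each marker's three frequencies must sum to 1 within 0.005 (3-decimal
#' rounding residue); they are renormalized by their sum.
#'
#' @param path TSV file path.
#' @param layout \code{"wide"} or \code{"long"}.
#' @param label Population name for the returned model.
#' @param markers Optional list of \code{\linkS4class{Marker}} templates
#'   fixing allele pairs (and hence category order); without it allele pairs
#'   are inferred from the nonzero genotype rows, first allele alphabetical.
#' @param sizeN Optional population size to store on the model.
#' @return A \code{\linkS4class{PopulationModel}}.
#' @examples
#' path <- system.file("extdata", "popA_genotype_freqs.tsv",
#'                     package = "SNPclassify")
#' readFrequencyTable(path, label = "A")
#' @export
readFrequencyTable <- function(path, layout = c("wide", "long"),
                               label = "population", markers = NULL,
                               sizeN = NA) {
    layout <- match.arg(layout)
    if (!is.null(markers))
        names(markers) <- vapply(markers, markerId, character(1))
    tab <- .readTsv(path)
    if (layout == "wide") {
        rowLab <- as.character(tab[[1]])
        isCount <- tolower(rowLab) == "count"
        counts <- NULL
        if (any(isCount)) {
            counts <- as.numeric(tab[isCount, -1, drop = FALSE][1, ])
            tab <- tab[!isCount, , drop = FALSE]
            rowLab <- rowLab[!isCount]
        }
        ids <- colnames(tab)[-1]
        parsed <- lapply(ids, function(id)
            .distFromRows(id, rowLab, as.numeric(tab[[id]]), markers))
        mcnt <- if (is.null(counts)) NULL else counts
    } else {
        need <- c("marker_id", "genotype", "frequency")
        if (!all(need %in% colnames(tab)))
            stop("long layout needs columns marker_id, genotype, frequency")
        ids <- unique(tab$marker_id)
        parsed <- lapply(ids, function(id) {
            sub <- tab[tab$marker_id == id, ]
            .distFromRows(id, sub$genotype, as.numeric(sub$frequency), markers)
        })
        mcnt <- NULL
    }
    PopulationModel(label, lapply(parsed, `[[`, "marker"),
                    lapply(parsed, `[[`, "dist"), sizeN = sizeN,
                    markerCounts = mcnt)
}

#' Write a population model as a genotype-frequency table
#'
#' Inverse of \code{\link{readFrequencyTable}}: reading the written file
#' (with the same marker templates) reproduces the model within 1e-9 per
#' probability. Wide output lists every genotype category appearing in the
#' model as a row, with structural zeros for inapplicable markers, and
#' appends a \code{Count} row when per-marker counts are stored.
#'
#' @param model A \code{\linkS4class{PopulationModel}} with >= 1 marker.
#' @param path Output TSV path.
#' @param layout \code{"wide"} or \code{"long"}.
#' @return \code{path}, invisibly.
#' @examples
#' p <- examplePanel()
#' tmp <- tempfile(fileext = ".tsv")
#' writeFrequencyTable(p$A, tmp)
#' @export
writeFrequencyTable <- function(model, path, layout = c("wide", "long")) {
    layout <- match.arg(layout)
    ids <- markerIds(model)
    if (!length(ids)) stop("cannot write a model with no markers")
    if (layout == "wide") {
        catsPer <- lapply(markers(model), genotypeCategories)
        rows <- unique(unlist(catsPer))
        out <- matrix("0", nrow = length(rows), ncol = length(ids),
                      dimnames = list(rows, ids))
        for (j in seq_along(ids)) {
            p <- probs(distributions(model)[[j]])
            out[match(catsPer[[j]], rows), j] <- .num(p)
        }
        lines <- c(paste(c("genotype", ids), collapse = "\t"),
                   vapply(seq_along(rows), function(i)
                       paste(c(rows[i], out[i, ]), collapse = "\t"),
                       character(1)))
        cnt <- markerCounts(model)
        if (any(!is.na(cnt)))
            lines <- c(lines, paste(c("Count", .num(cnt)), collapse = "\t"))
    } else {
        lines <- "marker_id\tgenotype\tfrequency"
        for (j in seq_along(ids)) {
            cats <- genotypeCategories(markers(model)[[j]])
            p <- probs(distributions(model)[[j]])
            lines <- c(lines, sprintf("%s\t%s\t%s", ids[j], cats, .num(p)))
        }
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read a marker summary table
#'
#' Reads a marker description table with columns \code{Marker},
#' \code{Position}, \code{ObsHET}, \code{HWpval}, \code{MAF} and
#' \code{Allele} (alleles as \code{"T:C"}; the first listed allele defines
#' the marker's hom-first category).
#'
#' @param path TSV file path.
#' @return A list with \code{markers} (list of \code{\linkS4class{Marker}})
#'   and \code{info} (the table as a data.frame).
#' @examples
#' path <- system.file("extdata", "panel_markers.tsv", package = "SNPclassify")
#' readMarkerTable(path)$info
#' @export
readMarkerTable <- function(path) {
    tab <- .readTsv(path)
    need <- c("Marker", "Allele")
    if (!all(need %in% colnames(tab)))
        stop("marker table needs at least columns Marker and Allele")
    mk <- lapply(seq_len(nrow(tab)), function(i) {
        al <- strsplit(tab$Allele[i], ":")[[1]]
        Marker(tab$Marker[i], al,
               locus = if ("Position" %in% colnames(tab)) tab$Position[i] else "")
    })
    list(markers = mk, info = tab)
}

#' Read a genotype matrix
#'
#' Reads a rectangular TSV with a \code{sample_id} column followed by one
#' column per marker; cells are two-character genotype strings or a missing
#' token (\code{"."} or \code{"NN"}). Genotypes are canonicalized. When a
#' model is supplied, every call is validated against its marker's allele
#' pair and offending cells are reported by sample and marker.
#'
#' @param path TSV file path.
#' @param model Optional \code{\linkS4class{PopulationModel}} for validation.
#' @return A \code{\linkS4class{GenotypeDataset}}.
#' @examples
#' p <- examplePanel()
#' tmp <- tempfile(fileext = ".tsv")
#' writeGenotypeMatrix(simulateProfiles(p$A, 3, seed = 1), tmp)
#' readGenotypeMatrix(tmp, model = p$A)
#' @export
readGenotypeMatrix <- function(path, model = NULL) {
    tab <- .readTsv(path)
    if (colnames(tab)[1] != "sample_id")
        stop("genotype matrix must start with a sample_id column")
    sids <- as.character(tab$sample_id)
    if (anyDuplicated(sids))
        stop(sprintf("duplicate sample id(s): %s",
                     paste(unique(sids[duplicated(sids)]), collapse = ", ")))
    g <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(g) <- "character"
    rownames(g) <- sids
    bad <- !is.na(g) & !(g %in% MISSING_TOKENS) & nchar(g) != 2L
    if (any(bad)) {
        i <- which(bad, arr.ind = TRUE)[1, ]
        stop(sprintf("invalid genotype string '%s' (sample %s, marker %s)",
                     g[bad][1], sids[i[1]], colnames(g)[i[2]]))
    }
    ds <- GenotypeDataset(g)
    if (!is.null(model)) {
        gg <- genotypes(ds)
        for (id in intersect(colnames(gg), markerIds(model))) {
            cats <- genotypeCategories(getMarker(model, id))
            off <- which(!is.na(gg[, id]) & !(gg[, id] %in% cats))
            if (length(off))
                stop(sprintf(
                    "genotype '%s' of sample %s at %s inconsistent with alleles %s",
                    gg[off[1], id], rownames(gg)[off[1]], id,
                    paste(alleles(getMarker(model, id)), collapse = "/")))
        }
    }
    ds
}

#' Write a genotype matrix (and optional labels file)
#'
#' @param dataset A \code{\linkS4class{GenotypeDataset}}.
#' @param path Output TSV path.
#' @param labelsPath Optional path for a two-column (sample_id, label) TSV of
#'   the true population labels; requires a labelled dataset.
#' @param missingToken Token written for missing calls.
#' @return \code{path}, invisibly.
#' @examples
#' p <- examplePanel()
#' writeGenotypeMatrix(simulateProfiles(p$A, 2, seed = 1),
#'                     tempfile(fileext = ".tsv"))
#' @export
writeGenotypeMatrix <- function(dataset, path, labelsPath = NULL,
                                missingToken = ".") {
    g <- genotypes(dataset)
    out <- g
    out[is.na(out)] <- missingToken
    lines <- c(paste(c("sample_id", colnames(g)), collapse = "\t"),
               vapply(seq_len(nrow(g)), function(i)
                   paste(c(rownames(g)[i], out[i, ]), collapse = "\t"),
                   character(1)))
    writeLines(lines, path)
    if (!is.null(labelsPath)) {
        if (!length(trueLabels(dataset)))
            stop("dataset has no true labels to write")
        writeLines(c("sample_id\tlabel",
                     paste(rownames(g), trueLabels(dataset), sep = "\t")),
                   labelsPath)
    }
    invisible(path)
}
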