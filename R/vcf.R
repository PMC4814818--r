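#' @include AllClasses.R
NULL

#' Read genotype calls from a VCF file
#'
#' Convenience ingestion of diploid genotypes for a set of biallelic SNP
#' markers. Records whose ID is not in \code{markerIds} are ignored;
#' matching records that are multi-allelic or not simple SNPs are skipped
#' with a warning, and the skip count is stored in the dataset's metadata
#' (\code{metadata(ds)$skipped_records}). GT fields are mapped as
#' \code{0/0} to the reference homozygote, \code{0/1}/\code{1/0} (phased
#' \code{|} treated identically) to the heterozygote, \code{1/1} to the
#' alternate homozygote, and \code{./.} to missing. Requires the
#' \pkg{vcfR} package.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param markerIds Marker rsIDs to extract.
#' @return A \code{\linkS4class{GenotypeDataset}} (samples x markers; markers
#'   never seen in the file are absent from the result).
#' @examples
#' \dontrun{
#' readVcfGenotypes("cohort.vcf", panelOrder())
#' }
#' @export
readVcfGenotypes <- function(path, markerIds) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("readVcfGenotypes requires the optional 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))
        fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    hit <- which(fix[, "ID"] %in% markerIds)
    skipped <- 0L
    keep <- integer(0)
    for (i in hit) {
        ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
        if (is.na(alt) || nchar(ref) != 1L || grepl(",", alt) ||
            nchar(alt) != 1L) {
            skipped <- skipped + 1L
        } else keep <- c(keep, i)
    }
    if (skipped > 0L)
        warning(sprintf("skipped %d multi-allelic or non-SNP record(s)", skipped))
    gtRaw <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gtRaw)))
        gtRaw <- matrix(gtRaw, nrow = 1, dimnames = list(NULL, names(gtRaw)))
    samples <- colnames(v@gt)[-1]
    g <- matrix(NA_character_, nrow = length(samples), ncol = length(keep),
                dimnames = list(samples, unname(fix[keep, "ID"])))
    for (k in seq_along(keep)) {
        i <- keep[k]
        ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
        gt <- gsub("|", "/", gtRaw[i, , drop = TRUE], fixed = TRUE)
        g[, k] <- vapply(gt, function(x) {
            if (is.na(x) || x == "./." || x == ".") return(NA_character_)
            a <- strsplit(x, "/", fixed = TRUE)[[1]]
            if (length(a) != 2L || !all(a %in% c("0", "1")))
                stop(sprintf("unsupported GT field '%s' at %s", x,
                             fix[i, "ID"]))
            paste(sort(c(ref, alt)[as.integer(a) + 1L]), collapse = "")
        }, character(1), USE.NAMES = FALSE)
    }
    GenotypeDataset(g, metadata = list(skipped_records = skipped,
                                       source = "vcf"))
}
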