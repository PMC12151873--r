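#' Construct a BetaSet from a beta matrix, sample sheet and annotation
#'
#' @param beta numeric matrix of methylation fractions in \[0, 1\], probes as
#'   rows and samples as columns; `NA` marks missing calls.  Row and column
#'   names are required (probe and sample ids).
#' @param sampleSheet data frame with one row per column of `beta`
#'   (matched by `sample_id` or by row name) providing `age_days`, `sex`
#'   and `environment`, optionally `exposure_group`.
#' @param probeAnnotation optional data frame with one row per probe
#'   (`probe_id` column or row names) providing `chrom` and `probe_class`.
#'
#' @return A \linkS4class{BetaSet}.
#' @examples
#' b <- matrix(runif(6, 0.2, 0.8), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"), age_days = c(30, 200),
#'                     sex = c("F", "M"), environment = c("lab", "field"))
#' BetaSet(b, sheet)
#' @export
BetaSet <- function(beta, sampleSheet, probeAnnotation = NULL) {
    if (is.null(rownames(beta)) || is.null(colnames(beta)))
        stop("beta matrix must have probe row names and sample column names")
    sampleSheet <- as.data.frame(sampleSheet)
    if ("sample_id" %in% colnames(sampleSheet))
        rownames(sampleSheet) <- sampleSheet$sample_id
    missingIds <- setdiff(colnames(beta), rownames(sampleSheet))
    if (length(missingIds))
        stop("sample sheet lacks samples: ", paste(missingIds, collapse = ", "))
    cd <- S4Vectors::DataFrame(sampleSheet[colnames(beta), , drop = FALSE])
    rd <- S4Vectors::DataFrame(row.names = rownames(beta))
    if (!is.null(probeAnnotation)) {
        probeAnnotation <- as.data.frame(probeAnnotation)
        if ("probe_id" %in% colnames(probeAnnotation))
            rownames(probeAnnotation) <- probeAnnotation$probe_id
        missingProbes <- setdiff(rownames(beta), rownames(probeAnnotation))
        if (length(missingProbes))
            stop("probe annotation lacks ", length(missingProbes), " probes")
        rd <- S4Vectors::DataFrame(
            probeAnnotation[rownames(beta), , drop = FALSE])
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = beta), colData = cd, rowData = rd)
    new("BetaSet", se)
}

#' @describeIn BetaSet beta value matrix (probes x samples)
#' @param x,object a `BetaSet`
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @describeIn BetaSet sample ages in days
#' @export
sampleAges <- function(x) {
    a <- SummarizedExperiment::colData(x)$age_days
    names(a) <- colnames(x)
    a
}

#' @describeIn BetaSet sample environment labels ("lab"/"field")
#' @export
sampleEnvironment <- function(x) {
    e <- as.character(SummarizedExperiment::colData(x)$environment)
    names(e) <- colnames(x)
    e
}

#' @describeIn BetaSet sample sexes ("F"/"M")
#' @export
sampleSex <- function(x) {
    s <- as.character(SummarizedExperiment::colData(x)$sex)
    names(s) <- colnames(x)
    s
}

#' @describeIn BetaSet probe chromosome labels (NA when unannotated)
#' @export
probeChromosome <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    chrom <- if ("chrom" %in% colnames(rd)) as.character(rd$chrom)
             else rep(NA_character_, nrow(x))
    names(chrom) <- rownames(x)
    chrom
}

#' @describeIn BetaSet logical: probe maps to an autosome (not X/Y/MT)
#' @export
isAutosomal <- function(x) {
    chrom <- probeChromosome(x)
    !is.na(chrom) & !(chrom %in% NONAUTOSOMES)
}

setMethod("show", "BetaSet", function(object) {
    cat("BetaSet with", nrow(object), "probes and", ncol(object), "samples\n")
    env <- table(sampleEnvironment(object))
    cat("  environments:",
        paste(sprintf("%s=%d", names(env), as.integer(env)), collapse = ", "),
        "\n")
    ages <- sampleAges(object)
    cat(sprintf("  ages: %g-%g days\n", min(ages), max(ages)))
    b <- betaValues(object)
    cat(sprintf("  missing beta calls: %.2f%%\n", 100 * mean(is.na(b))))
})
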