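#' @importFrom utils read.delim read.csv write.table packageVersion
NULL

# Delimiter from extension: .csv(.gz) -> comma, otherwise tab. gzip is
# handled transparently by the reader connections.
.delimFor <- function(path) {
    if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta matrix from TSV/CSV (optionally gzipped)
#'
#' Expects a header row of sample ids and a first column of probe ids;
#' empty cells and `NA` mark missing values.  Values outside \[0, 1\],
#' non-numeric cells and duplicate probe ids are rejected with the
#' offending coordinates in the message.  CRLF line endings and trailing
#' whitespace are tolerated.
#'
#' @param path file path; `.csv`/`.csv.gz` are comma-separated, anything
#'   else tab-separated.
#' @return numeric matrix, probes as rows.
#' @export
readBetaMatrix <- function(path) {
    df <- read.delim(path, sep = .delimFor(path), header = TRUE,
                     check.names = FALSE, strip.white = TRUE,
                     na.strings = c("NA", ""))
    probeIds <- trimws(as.character(df[[1]]))
    dup <- probeIds[duplicated(probeIds)]
    if (length(dup))
        stop("duplicate probe ids: ", paste(unique(dup), collapse = ", "))
    vals <- df[, -1, drop = FALSE]
    nonNum <- !vapply(vals, is.numeric, logical(1))
    if (any(nonNum))
        stop("non-numeric beta values in column(s): ",
             paste(colnames(vals)[nonNum], collapse = ", "))
    m <- as.matrix(vals)
    rownames(m) <- probeIds
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("beta value %g outside [0, 1] at probe '%s', sample '%s'",
                     m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                     colnames(m)[bad[1, 2]]))
    m
}

#' Write a beta matrix as TSV (probe_id first column)
#' @param beta numeric matrix with dimnames.
#' @param path output path; a `.gz` suffix gzips the file.
#' @export
writeBetaMatrix <- function(beta, path) {
    df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample sheet CSV
#'
#' Requires columns `sample_id`, `age_days`, `sex`, `environment`;
#' `exposure_group` is optional.  Validates uniqueness of ids, positive
#' ages and the sex/environment vocabularies.
#' @param path CSV path.
#' @return data.frame keyed by `sample_id`.
#' @export
readSampleSheet <- function(path) {
    df <- read.csv(path, strip.white = TRUE, stringsAsFactors = FALSE)
    need <- c("sample_id", "age_days", "sex", "environment")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
    if (any(df$age_days <= 0)) stop("ages must be positive (days)")
    if (!all(df$sex %in% SEX_LEVELS)) stop("sex must be 'F' or 'M'")
    if (!all(df$environment %in% ENV_LEVELS))
        stop("environment must be 'lab' or 'field'")
    rownames(df) <- df$sample_id
    df
}

#' Read probe annotation TSV (probe_id, chrom, probe_class)
#' @param path TSV path.
#' @return data.frame keyed by `probe_id`.
#' @export
readProbeAnnotation <- function(path) {
    df <- read.delim(path, strip.white = TRUE, stringsAsFactors = FALSE)
    need <- c("probe_id", "chrom", "probe_class")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("probe annotation lacks column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$probe_id)) stop("duplicate probe ids")
    rownames(df) <- df$probe_id
    df
}

#' Read probe-set collections from GMT or two-column TSV
#'
#' GMT lines are `name <tab> description <tab> member...` (parsed with
#' `fgsea::gmtPathways`); the two-column form has a header `set`, `probe`
#' with one membership pair per line.
#'
#' @param path file path; `.gmt` selects the GMT parser.
#' @return named list of unique probe-id vectors.
#' @export
readProbeSets <- function(path) {
    if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
        sets <- fgsea::gmtPathways(path)
    } else {
        df <- read.delim(path, strip.white = TRUE, stringsAsFactors = FALSE)
        if (!all(c("set", "probe") %in% colnames(df)))
            stop("two-column probe-set files need 'set' and 'probe' columns")
        sets <- split(df$probe, df$set)
    }
    lapply(sets, unique)
}

#' Write per-probe fit results as TSV
#' @param fit a \linkS4class{SiteWiseFit} or \linkS4class{InteractionFit}.
#' @param path output path.
#' @export
writeFitTable <- function(fit, path) {
    write.table(as.data.frame(fitResults(fit)), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write the synthetic ground-truth table as TSV
#' @param truth the `truth` element of [simulateCohorts()] output.
#' @param path output path.
#' @export
writeTruthTable <- function(truth, path) {
    write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Serialize a clock model as TSV with a metadata header block
#'
#' Header lines of the form `#key: value` carry the intercept (months),
#' alpha, lambda, fold count, seed and training size; the body has columns
#' `probe_id`, `weight`, `feature_mean`.  The same format is accepted for
#' externally published clocks (missing metadata defaults to `NA`;
#' `feature_mean` may be omitted, in which case 0.5 is assumed for
#' imputation).
#'
#' @param model a \linkS4class{ClockModel}.
#' @param path output path.
#' @export
writeClockModel <- function(model, path) {
    con <- file(path, "w")
    on.exit(close(con))
    meta <- c(intercept = model@intercept, alpha = model@alpha,
              lambda = model@lambda, n_folds = model@nFolds,
              seed = model@seed, n_train = model@nTrain)
    writeLines(sprintf("#%s: %.17g", names(meta), meta), con)
    df <- data.frame(probe_id = model@probes, weight = model@weights,
                     feature_mean = model@featureMeans)
    write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeClockModel
#' @param path path of a serialized clock model.
#' @return `readClockModel`: a \linkS4class{ClockModel}.
#' @export
readClockModel <- function(path) {
    lines <- readLines(path)
    metaLines <- grep("^#", lines, value = TRUE)
    meta <- list()
    for (ln in metaLines) {
        kv <- sub("^#", "", ln)
        key <- trimws(sub(":.*$", "", kv))
        meta[[key]] <- as.numeric(trimws(sub("^[^:]*:", "", kv)))
    }
    getMeta <- function(key, default) {
        if (!is.null(meta[[key]]) && is.finite(meta[[key]])) meta[[key]]
        else default
    }
    body <- read.delim(textConnection(lines[!grepl("^#", lines)]),
                       strip.white = TRUE, stringsAsFactors = FALSE)
    if (!all(c("probe_id", "weight") %in% colnames(body)))
        stop("clock model file needs 'probe_id' and 'weight' columns")
    fm <- if ("feature_mean" %in% colnames(body)) body$feature_mean
          else rep(0.5, nrow(body))
    new("ClockModel",
        probes = as.character(body$probe_id),
        weights = as.numeric(body$weight),
        intercept = getMeta("intercept", 0),
        featureMeans = as.numeric(fm),
        alpha = getMeta("alpha", NA_real_),
        lambda = getMeta("lambda", NA_real_),
        nFolds = as.integer(getMeta("n_folds", NA_real_)),
        seed = as.integer(getMeta("seed", NA_real_)),
        nTrain = as.integer(getMeta("n_train", NA_real_)))
}

#' Assemble a validated pipeline configuration
#'
#' Thresholds default to the study's values: q < 0.01 for joint/at-least-one
#' age association, q < 0.05 for the interaction and for enrichment queries,
#' 0.15 effect magnitude for queries, 0.2 maximum missing fraction, elastic
#' net with alpha 0.5 and 10-fold cross-validation.
#'
#' @param beta_file,sample_file,annotation_file,sets_file,clock_file input
#'   paths (`sets_file` and `clock_file` optional; when all input paths are
#'   `NULL` the pipeline simulates its inputs).
#' @param out_dir output directory.
#' @param q_joint,q_interaction,q_query,effect_thresh,reference_duration,max_missing,alpha,n_folds,seed
#'   analysis settings; see the corresponding stage functions.
#' @param n_probes,n_lab,n_field generator sizes used when simulating.
#' @return named list of validated settings.
#' @export
runConfig <- function(beta_file = NULL, sample_file = NULL,
                      annotation_file = NULL, sets_file = NULL,
                      clock_file = NULL, out_dir = "epiage-out",
                      q_joint = 0.01, q_interaction = 0.05, q_query = 0.05,
                      effect_thresh = 0.15, reference_duration = 1,
                      max_missing = 0.2, alpha = 0.5, n_folds = 10L,
                      seed = 1L, n_probes = 20000L, n_lab = 20L,
                      n_field = 41L) {
    cfg <- list(beta_file = beta_file, sample_file = sample_file,
                annotation_file = annotation_file, sets_file = sets_file,
                clock_file = clock_file, out_dir = out_dir,
                q_joint = q_joint, q_interaction = q_interaction,
                q_query = q_query, effect_thresh = effect_thresh,
                reference_duration = reference_duration,
                max_missing = max_missing, alpha = alpha,
                n_folds = as.integer(n_folds), seed = as.integer(seed),
                n_probes = as.integer(n_probes), n_lab = as.integer(n_lab),
                n_field = as.integer(n_field))
    for (f in c("q_joint", "q_interaction", "q_query"))
        if (cfg[[f]] <= 0 || cfg[[f]] > 1)
            stop(f, " must lie in (0, 1]")
    if (cfg$effect_thresh < 0) stop("effect_thresh must be nonnegative")
    if (cfg$max_missing < 0 || cfg$max_missing >= 1)
        stop("max_missing must lie in [0, 1)")
    if (cfg$alpha < 0 || cfg$alpha > 1) stop("alpha must lie in [0, 1]")
    cfg
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; keys match
#' [runConfig()] arguments and unset keys take the defaults.
#'
#' @param path configuration file path.
#' @return validated configuration list (via [runConfig()]).
#' @export
readRunConfig <- function(path) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    args <- list()
    for (ln in lines) {
        if (!grepl("=", ln)) stop("malformed config line: ", ln)
        key <- trimws(sub("=.*$", "", ln))
        val <- trimws(sub("^[^=]*=", "", ln))
        num <- suppressWarnings(as.numeric(val))
        args[[key]] <- if (!is.na(num)) num else val
    }
    unknown <- setdiff(names(args), names(formals(runConfig)))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    do.call(runConfig, args)
}
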