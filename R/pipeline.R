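#' @importFrom tools md5sum
NULL

.stageLog <- function(stage, ...) {
    message(sprintf("[epiage] stage %-12s %s", stage, paste0(...)))
}

.stage <- function(stage, expr) {
    .stageLog(stage, "start")
    res <- tryCatch(expr, error = function(e)
        stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
    .stageLog(stage, "done")
    res
}

# Per-stage substreams derived from the single configured seed, so each
# stochastic stage is reproducible in isolation.
.stageSeed <- function(seed, stage) {
    offsets <- c(simulate = 101L, clock = 211L)
    (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the comparative epigenetic-aging pipeline end to end
#'
#' Stages, in order: load (or simulate) inputs; per-environment site-wise
#' fits; interaction model; site categorization; octant summary;
#' zero-intercept rate ratios for joint hyper- and hypomethylating sites;
#' Spearman concordance; interaction direction counts; probe-set enrichment
#' of gain/loss queries (when a set collection is supplied); clock training
#' (or import) plus prediction and residual comparison.  Every stage writes
#' a TSV under `out_dir` and a run manifest records package version,
#' thresholds, seed and input checksums.  Given the same configuration and
#' seed, outputs are byte-identical across runs.
#'
#' @param config list from [runConfig()] or [readRunConfig()].
#' @param betas optional in-memory \linkS4class{BetaSet} overriding the
#'   configured input files.
#' @return invisible list of in-memory stage results (`betas`, `labFit`,
#'   `fieldFit`, `interaction`, `categories`, `octants`, `ratios`,
#'   `concordance`, `directions`, `enrichment`, `clock`, `predictions`,
#'   `residualComparison`, `outputs`).
#' @export
runPipeline <- function(config = runConfig(), betas = NULL) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character()
    emit <- function(df, name) {
        path <- file.path(config$out_dir, name)
        write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        outputs[[name]] <<- path
        path
    }

    inputFiles <- c(config$beta_file, config$sample_file,
                    config$annotation_file, config$sets_file,
                    config$clock_file)
    truth <- NULL
    if (is.null(betas)) {
        if (is.null(config$beta_file)) {
            sim <- .stage("simulate", {
                simulateCohorts(SimConfig(
                    nProbes = config$n_probes, nLab = config$n_lab,
                    nField = config$n_field,
                    seed = .stageSeed(config$seed, "simulate")))
            })
            betas <- sim$betas
            truth <- sim$truth
            emit(truth, "truth.tsv")
        } else {
            betas <- .stage("load", {
                m <- readBetaMatrix(config$beta_file)
                sheet <- readSampleSheet(config$sample_file)
                anno <- if (!is.null(config$annotation_file))
                    readProbeAnnotation(config$annotation_file) else NULL
                BetaSet(m, sheet, anno)
            })
        }
    }

    labFit <- .stage("fit_lab",
        fitAgeModel(betas, "lab", maxMissing = config$max_missing))
    fieldFit <- .stage("fit_field",
        fitAgeModel(betas, "field", maxMissing = config$max_missing))
    emit(fitResults(labFit), "sitewise_lab.tsv")
    emit(fitResults(fieldFit), "sitewise_field.tsv")

    inter <- .stage("interaction",
        fitInteractionModel(betas, maxMissing = config$max_missing))
    emit(fitResults(inter), "interaction.tsv")

    categories <- .stage("categorize",
        categorizeSites(labFit, fieldFit, qThresh = config$q_joint))
    emit(categories, "categories.tsv")

    # analysis set: age-associated sites with rates estimated in both
    # environments (a singly-significant probe can lack the other fit)
    assoc <- categories$category != "not_significant" &
        is.finite(categories$slope_lab) & is.finite(categories$slope_field)
    octants <- .stage("octants", {
        if (!any(assoc)) NULL
        else octantSummary(categories$slope_lab, categories$slope_field,
                           mask = assoc)
    })
    if (!is.null(octants)) emit(octants, "octants.tsv")

    ratios <- .stage("rate_ratio", {
        out <- list()
        for (cat in c("joint_hyper", "joint_hypo")) {
            m <- categories$category == cat
            if (sum(m) >= 2L)
                out[[cat]] <- zeroInterceptRatio(
                    categories$slope_lab, categories$slope_field, mask = m)
        }
        out
    })
    if (length(ratios)) {
        tab <- do.call(rbind, lapply(names(ratios), function(nm)
            cbind(category = nm, rateRatioTable(ratios[[nm]]))))
        emit(tab, "rate_ratios.tsv")
    }

    conc <- .stage("concordance", {
        if (sum(assoc) >= 3L)
            rateConcordance(categories$slope_lab, categories$slope_field,
                            mask = assoc)
        else NULL
    })
    if (!is.null(conc))
        emit(data.frame(rho = conc$rho, p = conc$p, n = conc$n),
             "concordance.tsv")

    directions <- .stage("directions",
        countInteractionDirections(categories, inter,
                                   qIntThresh = config$q_interaction))
    emit(directions, "direction_counts.tsv")

    enrich <- NULL
    if (!is.null(config$sets_file)) {
        enrich <- .stage("enrichment", {
            sets <- readProbeSets(config$sets_file)
            universe <- fitResults(labFit)$probe_id
            out <- list()
            for (dir in c("gain", "loss")) {
                qLab <- selectQuery(labFit, dir, qThresh = config$q_query,
                                    effectThresh = config$effect_thresh,
                                    referenceDuration = config$reference_duration)
                qField <- selectQuery(fieldFit, dir,
                                      qThresh = config$q_query,
                                      effectThresh = config$effect_thresh,
                                      referenceDuration = config$reference_duration)
                query <- union(qLab, qField)
                if (length(query))
                    out[[dir]] <- testEnrichment(query, sets, universe)
            }
            out
        })
        for (dir in names(enrich))
            emit(enrich[[dir]], sprintf("enrichment_%s.tsv", dir))
    }

    clock <- .stage("clock", {
        if (!is.null(config$clock_file)) readClockModel(config$clock_file)
        else trainClock(betas[, sampleEnvironment(betas) == "lab"],
                        alpha = config$alpha, nFolds = config$n_folds,
                        seed = .stageSeed(config$seed, "clock"))
    })
    writeClockModel(clock, file.path(config$out_dir, "clock_model.tsv"))
    outputs[["clock_model.tsv"]] <- file.path(config$out_dir,
                                              "clock_model.tsv")
    predictions <- .stage("predict", predictAge(clock, betas))
    emit(predictions, "clock_predictions.tsv")
    residCmp <- .stage("residuals", compareResiduals(predictions))
    emit(data.frame(median_field = residCmp$median_field,
                    median_lab = residCmp$median_lab,
                    median_difference = residCmp$median_difference,
                    p = residCmp$p, n_field = residCmp$n_field,
                    n_lab = residCmp$n_lab, test = residCmp$test),
         "clock_residual_comparison.tsv")

    manifest <- file.path(config$out_dir, "manifest.txt")
    cfgLines <- vapply(names(config), function(k) {
        v <- config[[k]]
        sprintf("%s: %s", k, if (is.null(v)) "" else format(v, digits = 15))
    }, character(1))
    sums <- character()
    for (f in inputFiles)
        if (!is.null(f) && file.exists(f))
            sums <- c(sums, sprintf("md5 %s: %s", basename(f), md5sum(f)))
    writeLines(c(sprintf("epiage version: %s",
                         as.character(packageVersion("epiage"))),
                 cfgLines, sums), manifest)

    invisible(list(betas = betas, truth = truth, labFit = labFit,
                   fieldFit = fieldFit, interaction = inter,
                   categories = categories, octants = octants,
                   ratios = ratios, concordance = conc,
                   directions = directions, enrichment = enrich,
                   clock = clock, predictions = predictions,
                   residualComparison = residCmp, outputs = outputs))
}
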