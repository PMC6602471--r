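#' @include report.R modelIO.R predictionTable.R simulate.R crossValidate.R
NULL

#' Run a complete workflow from a configuration
#'
#' The single programmatic entry point behind the command-line wrapper.
#' \code{config} is a named list with a \code{command} and the fields that
#' command needs; every run echoes its configuration into the report
#' header for provenance.
#'
#' \describe{
#'   \item{train}{\code{upbm} (probe table path), \code{out} (model file);
#'     optional \code{sequenceColumn}, \code{intensityColumn}, \code{tf},
#'     \code{crossValidate} (logical), \code{nFolds}, \code{seed}.}
#'   \item{predict}{\code{variants}, \code{format} (vcf/icgc/tab/seq),
#'     \code{out}, and \code{model} (model file) or \code{table}
#'     (prediction table); optional \code{genome}, \code{escoreTable},
#'     \code{pCutoff}, \code{transition}, \code{escoreBound},
#'     \code{escoreUnbound}, \code{reportFormat} (tsv/csv), \code{adjust}
#'     (logical, Benjamini-Hochberg q-values).}
#'   \item{table}{\code{model}, \code{out}; optional
#'     \code{includeIdentity} (default TRUE) and \code{contextsFile} (TSV
#'     with columns \code{context}, \code{alt}) to generate a partial
#'     table over a key subset instead of the complete one.}
#'   \item{simulate}{\code{outPrefix}; optional \code{nProbes},
#'     \code{noise}, \code{seed}, \code{consensus} --- writes
#'     \code{<prefix>_upbm.tsv}, \code{<prefix>_escores.tsv} and
#'     \code{<prefix>_truth.tsv}.}
#' }
#'
#' @param config named list as above.
#' @return Invisibly, the command's main result (a model, a prediction
#'   record data.frame, a table path, or a list of written paths).
#' @export
runPipeline <- function(config) {
    if (is.null(config$command))
        .dbStop("config must name a command (train/predict/table/simulate)",
                "db_usage_error")
    switch(config$command,
           train = .cmdTrain(config),
           predict = .cmdPredict(config),
           table = .cmdTable(config),
           simulate = .cmdSimulate(config),
           .dbStop(sprintf("unknown command '%s'", config$command),
                   "db_usage_error"))
}

.cfg <- function(config, name, default = NULL) {
    if (!is.null(config[[name]])) config[[name]] else default
}

.cmdTrain <- function(config) {
    if (is.null(config$upbm) || is.null(config$out))
        .dbStop("train needs `upbm` and `out`", "db_usage_error")
    ds <- readUPBMTable(config$upbm,
                        sequenceColumn = .cfg(config, "sequenceColumn",
                                              "sequence"),
                        intensityColumn = .cfg(config, "intensityColumn",
                                               "intensity"),
                        metadata = list(source = config$upbm))
    idx <- buildKmerIndex(6L)
    X <- featureMatrix(idx, ds)
    y <- logIntensities(ds)
    qc <- list()
    if (isTRUE(.cfg(config, "crossValidate", FALSE)))
        qc <- crossValidate(X, y, nFolds = .cfg(config, "nFolds", 5L),
                            seed = .cfg(config, "seed", 1L))
    model <- fitOLS(X, y, idx, qc = qc,
                    metadata = list(tf = .cfg(config, "tf", "TF"),
                                    trainingData = config$upbm))
    saveModel(model, config$out)
    message(sprintf("trained model on %d probes; wrote %s",
                    length(intensities(ds)), config$out))
    invisible(model)
}

.cmdPredict <- function(config) {
    for (need in c("variants", "format", "out"))
        if (is.null(config[[need]]))
            .dbStop(sprintf("predict needs `%s`", need), "db_usage_error")
    if (is.null(config$model) && is.null(config$table))
        .dbStop("predict needs `model` or `table`", "db_usage_error")
    ## open the scoring backend first: a bad model path is reported as a
    ## model-file error even when the variant file is also unusable
    model <- if (!is.null(config$model)) loadModel(config$model) else NULL
    tab <- if (is.null(model)) readPredictionTable(config$table) else NULL
    records <- parseVariants(config$variants, config$format,
                             genome = config$genome,
                             assembly = .cfg(config, "assembly"))
    nSkip <- sum(records$status == "skipped")
    if (nSkip)
        message(sprintf("skipped %d record(s): %s", nSkip,
                        paste(sprintf("%s (%s)",
                                      records$id[records$status == "skipped"],
                                      records$reason[records$status == "skipped"]),
                              collapse = "; ")))
    escores <- if (!is.null(config$escoreTable))
        readEScoreTable(config$escoreTable) else NULL
    thetaB <- .cfg(config, "escoreBound", 0.4)
    thetaU <- .cfg(config, "escoreUnbound", 0.35)
    if (!is.null(model)) {
        tfName <- .cfg(model@metadata, "tf", "model")
        preds <- predictVariants(stats::setNames(list(model), tfName),
                                 records, escores = escores,
                                 thetaBound = thetaB, thetaUnbound = thetaU)
    } else {
        preds <- .predictFromTable(tab, records, escores, thetaB, thetaU)
    }
    if (isTRUE(.cfg(config, "adjust", FALSE)))
        preds <- adjustPvalues(preds, "BH")
    writeReport(preds, config$out,
                format = .cfg(config, "reportFormat", "tsv"),
                pCutoff = config$pCutoff,
                transitionFilter = config$transition, config = config)
    message(sprintf("wrote %d prediction row(s) to %s", nrow(preds),
                    config$out))
    invisible(preds)
}

## Table-backed scoring path; mirrors predictVariants row-for-row.
.predictFromTable <- function(tab, records, escores, thetaBound,
                              thetaUnbound) {
    use <- records$status %in% c("ok", "identity")
    rec <- records[use, , drop = FALSE]
    base <- predictVariants(
        .dummyModelForStatus(), records, escores = escores,
        thetaBound = thetaBound, thetaUnbound = thetaUnbound)
    if (nrow(rec)) {
        lk <- lookupPrediction(tab, substr(rec$context17, 4L, 14L), rec$alt)
        stopifnot(nrow(lk) == nrow(base))
        base$delta <- lk$delta
        base$z <- lk$z
        base$p <- lk$p
    }
    base$tf <- tab@modelId
    base
}

## A zero model used only to shape table-backed reports (status calls and
## record bookkeeping); its delta/z/p are overwritten by table values.
.dummyModelForStatus <- function() {
    idx <- buildKmerIndex(6L)
    p <- length(idx@kmers)
    new("PBMModel", beta = stats::setNames(numeric(p), idx@kmers),
        cholR = diag(p), eigVectors = matrix(0, 0, 0),
        eigValues = numeric(0), rank = as.integer(p), sigma2 = 1,
        df = 1000L, index = idx, qc = list(), metadata = list(),
        cache = new.env(parent = emptyenv()))
}

.cmdTable <- function(config) {
    if (is.null(config$model) || is.null(config$out))
        .dbStop("table needs `model` and `out`", "db_usage_error")
    model <- loadModel(config$model)
    contexts <- alts <- NULL
    if (!is.null(config$contextsFile)) {
        ## partial table over a key subset: TSV with columns context, alt
        tab <- utils::read.table(config$contextsFile, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
        if (!all(c("context", "alt") %in% colnames(tab)))
            .dbStop("contexts file needs columns `context` and `alt`",
                    "db_format_error")
        contexts <- as.character(tab$context)
        alts <- as.character(tab$alt)
    }
    generatePredictionTable(model, config$out, contexts = contexts,
                            alts = alts,
                            includeIdentity = .cfg(config, "includeIdentity",
                                                   TRUE))
    message(sprintf("wrote prediction table %s", config$out))
    invisible(config$out)
}

.cmdSimulate <- function(config) {
    if (is.null(config$outPrefix))
        .dbStop("simulate needs `outPrefix`", "db_usage_error")
    truth <- simulateGroundTruth(
        consensus = .cfg(config, "consensus", "TGACGT"),
        noiseSd = .cfg(config, "noise", 0.5),
        seed = .cfg(config, "seed", 1L))
    ds <- simulateUPBM(truth, nProbes = .cfg(config, "nProbes", 44000L))
    es <- simulateEScores(truth)
    paths <- paste0(config$outPrefix,
                    c("_upbm.tsv", "_escores.tsv", "_truth.tsv"))
    writeUPBMTable(ds, paths[1L])
    writeEScoreTable(es, paths[2L])
    writeGroundTruth(truth, paths[3L])
    message(sprintf("wrote %s, %s, %s", paths[1L], paths[2L], paths[3L]))
    invisible(paths)
}
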