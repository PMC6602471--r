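#' @include variantIO.R variantEffect.R
NULL

#' Score parsed variants against one or more fitted models
#'
#' For every scoreable variant record and every model, computes the
#' predicted binding change (mutant minus wild type), z-score and P-value
#' from the model's coefficient contrast, and, when an E-score table is
#' given, classifies the wild-type and mutant 17-bp sites as bound /
#' unbound / ambiguous and labels the transition.  Identity records (ref
#' equal to alt) score (0, 0, 1).  Skipped records are not scored.
#'
#' @param models a \linkS4class{PBMModel} or a named list of them (names
#'   are used as the TF/model ids).
#' @param records variant record data.frame from \code{\link{parseVariants}}.
#' @param escores optional \linkS4class{EScoreTable} for status calls.
#' @param thetaBound,thetaUnbound E-score thresholds for the status rule
#'   (defaults 0.4 and 0.35).
#' @return A prediction record data.frame with one row per (variant,
#'   model): \code{variantId}, \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{tf}, \code{delta}, \code{z}, \code{p},
#'   \code{statusWild}, \code{statusMut}, \code{transition}.  Rows keep
#'   the input variant order, then model order.
#' @export
predictVariants <- function(models, records, escores = NULL,
                            thetaBound = 0.4, thetaUnbound = 0.35) {
    if (is(models, "PBMModel")) models <- list(model = models)
    if (is.null(names(models)))
        names(models) <- paste0("model", seq_along(models))
    use <- records$status %in% c("ok", "identity")
    rec <- records[use, , drop = FALSE]
    out <- list()
    if (nrow(rec)) {
        context11 <- substr(rec$context17, 4L, 14L)
        statusWild <- statusMut <- transition <- rep(NA_character_, nrow(rec))
        if (!is.null(escores)) {
            mutSite <- rec$context17
            substr(mutSite, 9L, 9L) <- rec$alt
            for (i in seq_len(nrow(rec))) {
                w <- classifySite(escores, rec$context17[i], thetaBound,
                                  thetaUnbound)
                m <- classifySite(escores, mutSite[i], thetaBound,
                                  thetaUnbound)
                statusWild[i] <- status(w)
                statusMut[i] <- status(m)
                transition[i] <- statusTransition(w, m)
            }
        }
        for (mi in seq_along(models)) {
            pred <- predictEffect(models[[mi]], context11, rec$alt)
            out[[mi]] <- data.frame(
                variantId = rec$id, chrom = rec$chrom, pos = rec$pos,
                ref = rec$ref, alt = rec$alt, tf = names(models)[mi],
                delta = pred$delta, z = pred$z, p = pred$p,
                statusWild = statusWild, statusMut = statusMut,
                transition = transition, stringsAsFactors = FALSE,
                row.names = NULL)
        }
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(variantId = character(0), chrom = character(0),
                          pos = integer(0), ref = character(0),
                          alt = character(0), tf = character(0),
                          delta = numeric(0), z = numeric(0), p = numeric(0),
                          statusWild = character(0),
                          statusMut = character(0),
                          transition = character(0), stringsAsFactors = FALSE)
    ## input variant order first, then model id
    res[order(match(res$variantId, records$id), res$tf), , drop = FALSE]
}

#' Write the prediction report
#'
#' Writes prediction records as TSV or CSV, optionally filtered by a
#' P-value cutoff and/or a status-transition label.  Provenance key=value
#' pairs from \code{config} are echoed as comment lines above the header.
#' An empty result after filtering still writes the header and succeeds.
#'
#' @param records prediction record data.frame from
#'   \code{\link{predictVariants}} (optionally with a \code{q} column from
#'   \code{\link{adjustPvalues}}).
#' @param path output file.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @param pCutoff optional filter: keep rows with \code{p <= pCutoff}.
#' @param transitionFilter optional filter: keep rows with this transition
#'   label (e.g. \code{"unbound>bound"}).
#' @param config optional named list echoed into the report header.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(records, path, format = c("tsv", "csv"),
                        pCutoff = NULL, transitionFilter = NULL,
                        config = NULL) {
    format <- match.arg(format)
    if (!is.null(pCutoff))
        records <- records[records$p <= pCutoff, , drop = FALSE]
    if (!is.null(transitionFilter))
        records <- records[!is.na(records$transition) &
                           records$transition == transitionFilter, ,
                           drop = FALSE]
    sep <- if (format == "tsv") "\t" else ","
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(config) && length(config))
        writeLines(sprintf("# %s=%s", names(config),
                           vapply(config, function(v)
                               paste(as.character(v), collapse = ","), "")),
                   con)
    utils::write.table(records, con, sep = sep, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
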