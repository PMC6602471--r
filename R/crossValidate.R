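#' @include olsFit.R
NULL

#' Cross-validation quality control for a uPBM dataset
#'
#' Splits the probes into \code{nFolds} folds by a seeded shuffle, fits the
#' OLS model on each training set and assembles out-of-fold predictions for
#' every probe.  Quality is summarized as the Pearson correlation between
#' predicted and observed log intensity restricted to the 10\% and 20\% of
#' probes with the highest observed intensity (the probes that carry the
#' binding signal); a dataset passes QC when both correlations are at least
#' 0.2.  The top-fraction cutoffs are \code{ceiling(f * n)} probes after
#' sorting by decreasing intensity, ties broken by input order.
#'
#' @param features design matrix (see \code{\link{featureMatrix}}).
#' @param outcomes numeric log-intensity vector.
#' @param nFolds number of folds (default 5).
#' @param seed integer seed for the fold shuffle; folds are a deterministic
#'   function of \code{(n, nFolds, seed)}.
#' @param threshold QC pass threshold on both correlations (default 0.2).
#' @return A list with \code{rTop10}, \code{rTop20}, \code{nFolds},
#'   \code{seed}, \code{threshold} and \code{passes}.
#' @importFrom stats cor
#' @export
crossValidate <- function(features, outcomes, nFolds = 5L, seed = 1L,
                          threshold = 0.2) {
    n <- nrow(features)
    p <- ncol(features)
    outcomes <- as.numeric(outcomes)
    if (length(outcomes) != n)
        .dbStop("outcomes must be parallel to the design rows",
                "db_input_error")
    if (nFolds < 2L)
        .dbStop("nFolds must be at least 2", "db_parameter_error")
    fold <- .withLocalSeed(seed, sample(rep_len(seq_len(nFolds), n)))
    if (any(tabulate(fold, nFolds) > n - p))
        .dbStop("training folds would have fewer observations than features",
                "db_fold_size_error")
    pred <- numeric(n)
    for (f in seq_len(nFolds)) {
        test <- fold == f
        Xtr <- features[!test, , drop = FALSE]
        XtX <- as.matrix(Matrix::crossprod(Xtr))
        Xty <- as.numeric(Matrix::crossprod(Xtr, outcomes[!test]))
        beta <- .olsSolve(XtX, Xty)$beta
        pred[test] <- as.numeric(features[test, , drop = FALSE] %*% beta)
    }
    ord <- order(-outcomes, seq_len(n))
    rTop <- function(frac) {
        idx <- ord[seq_len(ceiling(frac * n))]
        suppressWarnings(stats::cor(pred[idx], outcomes[idx]))
    }
    rTop10 <- rTop(0.10)
    rTop20 <- rTop(0.20)
    list(rTop10 = rTop10, rTop20 = rTop20, nFolds = as.integer(nFolds),
         seed = as.integer(seed), threshold = threshold,
         passes = isTRUE(rTop10 >= threshold) && isTRUE(rTop20 >= threshold))
}
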