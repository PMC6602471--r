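#' @include featureMatrix.R
NULL

## Solve the normal equations for one or more right-hand sides.
## Returns list(beta, method, cholR, eigVectors, eigValues, rank).
## Full-rank, well-conditioned designs use the Cholesky factor of X'X;
## ill-conditioned or singular designs fall back to a symmetric
## eigendecomposition and the minimum-norm (pseudoinverse) solution.
.olsSolve <- function(XtX, Xty, conditionThreshold = 1e10) {
    p <- ncol(XtX)
    U <- tryCatch(chol(XtX), error = function(e) NULL)
    if (!is.null(U)) {
        ## cheap condition estimate from the triangular factor
        rc <- rcond(U, triangular = TRUE)
        if (is.finite(rc) && rc > 0 && (1 / rc)^2 < conditionThreshold) {
            beta <- backsolve(U, backsolve(U, Xty, transpose = TRUE))
            return(list(beta = beta, method = "chol", cholR = U,
                        eigVectors = matrix(0, 0, 0),
                        eigValues = numeric(0), rank = p))
        }
    }
    e <- eigen(XtX, symmetric = TRUE)
    tol <- max(e$values, 0) * p * .Machine$double.eps * 100
    keep <- e$values > tol
    rank <- sum(keep)
    dinv <- ifelse(keep, 1 / e$values, 0)
    beta <- e$vectors %*% (dinv * crossprod(e$vectors, Xty))
    list(beta = beta, method = "eigen", cholR = matrix(0, 0, 0),
         eigVectors = e$vectors, eigValues = e$values, rank = rank)
}

#' Fit the OLS model of TF binding specificity
#'
#' Fits the multiple linear regression \eqn{Y = X\beta + \epsilon} by
#' ordinary least squares, where X holds canonical k-mer counts and Y the
#' log-transformed probe intensities.  No intercept is included: the model
#' formulas carry none, and because every row of X sums to the constant
#' \eqn{L - k + 1} an intercept column would make the design rank
#' deficient.  Stores \eqn{\hat\beta = (X'X)^{-1}X'Y}, a factorization of
#' \eqn{X'X} for contrast variances, \eqn{\hat\sigma^2 = RSS/(n-p)} and the
#' residual degrees of freedom \eqn{n - p}.
#'
#' If \eqn{X'X} is numerically singular the minimum-norm solution is used
#' and the model is flagged rank deficient; contrasts are then checked for
#' estimability before testing.
#'
#' @param features design matrix from \code{\link{featureMatrix}} (sparse
#'   or dense), or a \linkS4class{UPBMExperiment} (counted with
#'   \code{index}).
#' @param outcomes numeric outcome vector (natural-log intensities).  May
#'   be omitted when \code{features} is a \linkS4class{UPBMExperiment}.
#' @param index the \linkS4class{KmerIndex} of the design; reconstructed
#'   from the column names when omitted.
#' @param qc optional cross-validation QC list (see
#'   \code{\link{crossValidate}}).
#' @param metadata named list (TF name, training-data id).
#' @return A \linkS4class{PBMModel}.
#' @examples
#' idx <- buildKmerIndex(2)
#' seqs <- vapply(1:50, function(i)
#'     paste(sample(c("A","C","G","T"), 12, TRUE), collapse = ""), "")
#' X <- featureMatrix(idx, seqs)
#' beta <- stats::rnorm(nFeatures(idx))
#' fit <- fitOLS(X, as.vector(X %*% beta), idx)
#' cor(coef(fit), beta)
#' @importFrom stats coef
#' @export
fitOLS <- function(features, outcomes = NULL, index = NULL, qc = list(),
                   metadata = list()) {
    if (is(features, "UPBMExperiment")) {
        if (is.null(index)) index <- buildKmerIndex(6L)
        if (is.null(outcomes)) outcomes <- logIntensities(features)
        features <- featureMatrix(index, features)
    }
    if (is.null(index)) {
        cn <- colnames(features)
        if (is.null(cn))
            .dbStop("supply `index` or a feature matrix with k-mer column names",
                    "db_input_error")
        index <- buildKmerIndex(nchar(cn[1L]))
    }
    n <- nrow(features)
    p <- ncol(features)
    if (p != length(index@kmers))
        .dbStop("feature matrix does not match the index dimension",
                "db_index_error")
    if (n <= p)
        .dbStop(sprintf("under-determined fit: %d observations for %d features",
                        n, p), "db_underdetermined_error")
    outcomes <- as.numeric(outcomes)
    if (length(outcomes) != n || any(!is.finite(outcomes)))
        .dbStop("outcomes must be finite and parallel to the design rows",
                "db_input_error")
    XtX <- as.matrix(Matrix::crossprod(features))
    Xty <- as.numeric(Matrix::crossprod(features, outcomes))
    sol <- .olsSolve(XtX, Xty)
    beta <- as.numeric(sol$beta)
    resid <- outcomes - as.numeric(features %*% beta)
    rss <- sum(resid^2)
    df <- n - p
    sigma2 <- rss / df
    if (sol$rank < p)
        warning(sprintf("design is rank deficient (rank %d < %d features); minimum-norm solution used",
                        sol$rank, p))
    new("PBMModel", beta = stats::setNames(beta, index@kmers),
        cholR = sol$cholR, eigVectors = sol$eigVectors,
        eigValues = sol$eigValues, rank = as.integer(sol$rank),
        sigma2 = sigma2, df = as.integer(df), index = index, qc = qc,
        metadata = metadata, cache = new.env(parent = emptyenv()))
}

#' @describeIn fitOLS coefficient estimates, named by canonical k-mers.
#' @param object a \linkS4class{PBMModel}.
#' @param ... ignored.
#' @export
setMethod("coef", "PBMModel", function(object, ...) object@beta)

#' @describeIn fitOLS residual variance estimate.
#' @param x a \linkS4class{PBMModel}.
#' @export
setMethod("sigma2", "PBMModel", function(x) x@sigma2)

#' @describeIn fitOLS residual degrees of freedom n - p.
#' @importFrom stats df.residual
#' @export
setMethod("df.residual", "PBMModel", function(object, ...) object@df)

#' @describeIn fitOLS cross-validation QC list.
#' @export
setMethod("modelQC", "PBMModel", function(x) x@qc)

#' @describeIn fitOLS k-mer index accessor.
#' @export
setMethod("kmerIndex", "PBMModel", function(x) x@index)

#' @export
setMethod("nFeatures", "PBMModel", function(x) length(x@beta))

setMethod("show", "PBMModel", function(object) {
    cat(sprintf("PBMModel: %d features (k = %d), df = %d, sigma2 = %.4g%s\n",
                length(object@beta), object@index@k, object@df,
                object@sigma2,
                if (object@rank < length(object@beta))
                    sprintf(" [rank deficient: rank %d]", object@rank) else ""))
    if (length(object@qc))
        cat(sprintf("  QC: rTop10 = %.3f, rTop20 = %.3f, passes = %s\n",
                    object@qc$rTop10, object@qc$rTop20, object@qc$passes))
    if (length(object@metadata))
        cat("  metadata:", paste(names(object@metadata),
                                 unlist(object@metadata),
                                 sep = "=", collapse = ", "), "\n")
})

## Contrast variance c'(X'X)^{-1}c (without the sigma2 factor), plus
## estimability checking under rank deficiency.
.contrastQuad <- function(model, cvec) {
    if (nrow(model@cholR) > 0L) {
        u <- backsolve(model@cholR, cvec, transpose = TRUE)
        sum(u^2)
    } else {
        w <- as.numeric(crossprod(model@eigVectors, cvec))
        tol <- max(model@eigValues, 0) * length(cvec) *
            .Machine$double.eps * 100
        keep <- model@eigValues > tol
        nrm <- sqrt(sum(cvec^2))
        if (nrm > 0 && any(abs(w[!keep]) > 1e-8 * nrm))
            .dbStop("contrast is not estimable under the rank-deficient fit",
                    "db_estimability_error")
        sum(w[keep]^2 / model@eigValues[keep])
    }
}

#' Test a linear contrast of the fitted coefficients
#'
#' Tests \eqn{H_0: c'\beta = 0} with the statistic \eqn{t = c'\hat\beta /
#' \sqrt{c'\hat\Sigma c}}, \eqn{\hat\Sigma = \hat\sigma^2 (X'X)^{-1}}.
#' With tens of thousands of residual degrees of freedom the statistic is
#' effectively standard normal, so the z-score and its two-sided normal
#' P-value are reported; the exact Student-t P-value at \eqn{n - p} degrees
#' of freedom is returned alongside for comparison.
#'
#' @param model a \linkS4class{PBMModel}.
#' @param contrast a \linkS4class{KmerContrast} or a numeric vector of the
#'   model's feature dimension.
#' @return A list with \code{estimate} (\eqn{c'\hat\beta}), \code{se}
#'   (\eqn{\sqrt{c'\hat\Sigma c}}), \code{z}, \code{p} (two-sided normal),
#'   \code{p.t} (two-sided Student-t) and \code{df}.  An all-zero contrast
#'   returns estimate 0, z 0, p 1 by convention.
#' @importFrom stats pnorm pt
#' @export
contrastTest <- function(model, contrast) {
    stopifnot(is(model, "PBMModel"))
    p <- length(model@beta)
    if (is(contrast, "KmerContrast")) {
        if (contrast@nFeatures != p)
            .dbStop("contrast dimension does not match the model",
                    "db_input_error")
        cvec <- numeric(p)
        cvec[contrast@features] <- contrast@values
    } else {
        cvec <- as.numeric(contrast)
        if (length(cvec) != p)
            .dbStop("contrast dimension does not match the model",
                    "db_input_error")
    }
    est <- sum(cvec * model@beta)
    if (all(cvec == 0))
        return(list(estimate = 0, se = 0, z = 0, p = 1, p.t = 1,
                    df = model@df))
    quad <- .contrastQuad(model, cvec)
    se <- sqrt(model@sigma2 * quad)
    if (se == 0) {
        if (est == 0)
            return(list(estimate = 0, se = 0, z = 0, p = 1, p.t = 1,
                        df = model@df))
        .dbStop("degenerate model: zero standard error with non-zero estimate",
                "db_degenerate_error")
    }
    z <- est / se
    list(estimate = est, se = se, z = z,
         p = 2 * stats::pnorm(-abs(z)),
         p.t = 2 * stats::pt(-abs(z), df = model@df),
         df = model@df)
}
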