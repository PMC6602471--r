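#' @include olsFit.R
NULL

## Windows of width k covering the center of a (2k-1)-mer: exactly k of
## them, offsets 1..k.  For the 6-mer models this is the 11-bp scoring
## window with its six 6-mer windows.
.windowMatrix <- function(contexts, k) {
    vapply(seq_len(k), function(o) substr(contexts, o, o + k - 1L),
           character(length(contexts)))
}

## Vectorised contrast construction for m variants.
## Returns list(idx: k x 2m matrix of feature indices (wt | mut columns
## interleaved by variant block), or more usefully a list of per-variant
## sparse entries).  Internally we return flat vectors for speed.
.contrastEntriesMany <- function(index, contexts, alts) {
    k <- index@k
    m <- length(contexts)
    stopifnot(length(alts) == m)
    width <- 2L * k - 1L
    if (any(nchar(contexts) != width))
        .dbStop(sprintf("context must be %d bp with the variant at the center",
                        width), "db_context_error")
    if (!all(.isACGT(contexts)) || !all(alts %in% DNA_BASES4))
        .dbStop("contexts and alternate bases must use the ACGT alphabet",
                "db_alphabet_error")
    mut <- contexts
    substr(mut, k, k) <- alts
    wtWin <- .windowMatrix(contexts, k)    # m x k
    mutWin <- .windowMatrix(mut, k)
    dim(wtWin) <- dim(mutWin) <- c(m, k)
    wtIdx <- matrix(index@lut[.kmerCode(as.vector(wtWin), k) + 1L], m, k)
    mutIdx <- matrix(index@lut[.kmerCode(as.vector(mutWin), k) + 1L], m, k)
    list(wt = wtIdx, mut = mutIdx,
         identity = substr(contexts, k, k) == alts)
}

#' Build the contrast vector for a single-nucleotide variant
#'
#' For a variant at the center of an 11-bp wild-type window, the contrast
#' holds the count difference (mutant minus wild type) of every canonical
#' 6-mer feature: the six windows of the wild-type context are decremented
#' and the six windows of the mutant context incremented.  Entries sum to
#' zero and at most twelve features change.  When the alternate base equals
#' the center base the contrast is all-zero.
#'
#' @param index a \linkS4class{KmerIndex} (k = 6 for the standard models;
#'   any k works, with a (2k-1)-bp context).
#' @param context11 the (2k-1)-bp wild-type window, variant at the center.
#' @param alt the alternate base (A/C/G/T).
#' @return A \linkS4class{KmerContrast}.
#' @export
buildContrast <- function(index, context11, alt) {
    stopifnot(is(index, "KmerIndex"))
    if (length(context11) != 1L || length(alt) != 1L)
        .dbStop("buildContrast takes a single context and alt", "db_input_error")
    ent <- .contrastEntriesMany(index, context11, alt)
    if (ent$identity)
        return(new("KmerContrast", features = integer(0), values = integer(0),
                   context = context11, alt = alt,
                   nFeatures = length(index@kmers)))
    delta <- tabulate(ent$mut[1L, ], nbins = length(index@kmers)) -
        tabulate(ent$wt[1L, ], nbins = length(index@kmers))
    nz <- which(delta != 0L)
    new("KmerContrast", features = nz, values = as.integer(delta[nz]),
        context = context11, alt = alt, nFeatures = length(index@kmers))
}

#' @export
setMethod("nFeatures", "KmerContrast", function(x) x@nFeatures)

setMethod("show", "KmerContrast", function(object) {
    cat(sprintf("KmerContrast: %s > %s at center of %s; %d non-zero features\n",
                substr(object@context, (nchar(object@context) + 1L) %/% 2L,
                       (nchar(object@context) + 1L) %/% 2L),
                object@alt, object@context, length(object@features)))
})

## Estimability of a batch of sparse contrasts under a rank-deficient fit:
## each contrast must be orthogonal to the null space of X'X.
.checkEstimable <- function(model, C) {
    if (nrow(model@cholR) > 0L) return(invisible(TRUE))
    tol <- max(model@eigValues, 0) * length(model@beta) *
        .Machine$double.eps * 100
    null <- model@eigVectors[, model@eigValues <= tol, drop = FALSE]
    if (ncol(null) == 0L) return(invisible(TRUE))
    proj <- abs(as.matrix(Matrix::crossprod(null, C)))
    nrm <- sqrt(Matrix::colSums(C^2))
    bad <- apply(proj, 2L, max) > 1e-8 * pmax(nrm, 1e-300) & nrm > 0
    if (any(bad))
        .dbStop(sprintf("%d contrast(s) not estimable under the rank-deficient fit",
                        sum(bad)), "db_estimability_error")
    invisible(TRUE)
}

## Memoized (X'X)^{-1} (or pseudoinverse) for batched contrast variances.
.xtxInverse <- function(model) {
    if (!is.null(model@cache$xtxInv)) return(model@cache$xtxInv)
    inv <- if (nrow(model@cholR) > 0L) {
        chol2inv(model@cholR)
    } else {
        tol <- max(model@eigValues, 0) * length(model@beta) *
            .Machine$double.eps * 100
        keep <- model@eigValues > tol
        V <- model@eigVectors[, keep, drop = FALSE]
        V %*% (t(V) / model@eigValues[keep])
    }
    model@cache$xtxInv <- inv
    inv
}

#' Predict the binding change of single-nucleotide variants
#'
#' For each (context, alt) pair, computes the predicted change in log
#' binding signal \eqn{\Delta = c'\hat\beta} (mutant minus wild type;
#' positive means gain of binding), the z-score \eqn{\Delta /
#' \sqrt{c'\hat\Sigma c}} and the two-sided normal P-value.  Identity
#' variants (alt equal to the center base) return (0, 0, 1).
#'
#' @param model a \linkS4class{PBMModel}.
#' @param contexts character vector of (2k-1)-bp wild-type windows (11 bp
#'   for the standard 6-mer models), variant at the center.
#' @param alts character vector of alternate bases, recycled against
#'   \code{contexts}.
#' @param statistics if FALSE only \code{delta} is computed (useful for
#'   noise-free models, whose standard errors are degenerate).
#' @return A data.frame with columns \code{context}, \code{alt},
#'   \code{delta} and, when \code{statistics}, \code{se}, \code{z},
#'   \code{p}.
#' @export
predictEffect <- function(model, contexts, alts, statistics = TRUE) {
    stopifnot(is(model, "PBMModel"))
    n <- max(length(contexts), length(alts))
    contexts <- rep_len(as.character(contexts), n)
    alts <- rep_len(as.character(alts), n)
    index <- model@index
    ent <- .contrastEntriesMany(index, contexts, alts)
    net <- .netContrasts(ent, length(index@kmers), n)
    beta <- unname(model@beta)
    ## summation in sorted-feature order: a variant and its reverse
    ## complement produce the identical net contrast, so predictions agree
    ## bitwise across strands
    delta <- as.vector(Matrix::crossprod(net$C, beta))
    .checkEstimable(model, net$C)
    out <- data.frame(context = contexts, alt = alts, delta = delta,
                      stringsAsFactors = FALSE)
    if (!statistics) return(out)
    quad <- .contrastQuadMany(model, net)
    se <- sqrt(model@sigma2 * quad)
    if (any(se == 0 & delta != 0))
        .dbStop("degenerate model: zero standard error with non-zero estimate",
                "db_degenerate_error")
    z <- ifelse(se > 0, delta / se, 0)
    out$se <- se
    out$z <- z
    out$p <- 2 * stats::pnorm(-abs(z))
    out
}

## Net (deduplicated, feature-sorted) contrasts for a batch of variants:
## a p x n sparse matrix C plus fixed-width padded index/value matrices
## for the quadratic form.  At most 12 features change per variant.
.netContrasts <- function(ent, p, n) {
    k <- ncol(ent$wt)
    C <- Matrix::sparseMatrix(
        i = c(as.vector(ent$mut), as.vector(ent$wt)),
        j = rep.int(seq_len(n), 2L * k),
        x = c(rep.int(1, n * k), rep.int(-1, n * k)),
        dims = c(p, n))
    C <- Matrix::drop0(C)
    lens <- diff(C@p)
    if (any(lens > 2L * k))
        stop("internal error: contrast wider than 2k features")
    J <- matrix(1L, 12L, n)
    Vv <- matrix(0, 12L, n)
    if (any(lens > 0)) {
        cols <- rep.int(seq_len(n), lens)
        slots <- sequence(lens)
        J[cbind(slots, cols)] <- C@i + 1L
        Vv[cbind(slots, cols)] <- C@x
    }
    list(C = C, J = J, V = Vv)
}

## Vectorised c'(X'X)^{-1}c for sparse contrasts: only the <=12 x <=12
## submatrix of the inverse is touched.  Accumulation order follows the
## sorted feature slots, so it is strand symmetric.
.contrastQuadMany <- function(model, net) {
    inv <- .xtxInverse(model)
    n <- ncol(net$J)
    q <- numeric(n)
    for (a in 1:12) {
        va <- net$V[a, ]
        if (all(va == 0)) next
        ia <- net$J[a, ]
        for (b in 1:12) {
            vb <- net$V[b, ]
            q <- q + va * vb * inv[cbind(ia, net$J[b, ])]
        }
    }
    pmax(q, 0)
}

#' Benjamini-Hochberg adjustment of prediction P-values
#'
#' Appends step-up q-values to a prediction record table.  With
#' \code{method = "none"} the records are returned untouched.
#'
#' @param records a data.frame with a \code{p} column (e.g. from
#'   \code{\link{predictVariants}}).
#' @param method \code{"BH"} (Benjamini-Hochberg) or \code{"none"}.
#' @return The records, with a \code{q} column appended when adjusting.
#' @importFrom stats p.adjust
#' @export
adjustPvalues <- function(records, method = c("BH", "none")) {
    method <- match.arg(method)
    if (method == "none") return(records)
    if (nrow(records) == 0L) {
        records$q <- numeric(0)
        return(records)
    }
    if (any(is.na(records$p)) || any(records$p < 0 | records$p > 1))
        .dbStop("records must carry valid P-values", "db_input_error")
    records$q <- stats::p.adjust(records$p, method = "BH")
    records
}
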