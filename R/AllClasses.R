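#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Canonical (reverse-complement-collapsed) k-mer index
#'
#' Maps every ACGT k-mer to a stable feature index such that a k-mer and its
#' reverse complement share the same index.  The canonical representative of
#' each pair is the lexicographically smaller of the two; representatives are
#' indexed in lexicographic order, so the mapping is deterministic across
#' runs and safe to serialize.  For k = 6 there are 2080 features.
#'
#' @slot k k-mer width (1..12).
#' @slot kmers character vector of canonical k-mers in feature order.
#' @slot lut integer vector of length 4^k mapping the base-4 code of any
#'   k-mer (A=0, C=1, G=2, T=3, big-endian) to its feature index.
#' @export
setClass("KmerIndex",
    representation(k = "integer", kmers = "character", lut = "integer"))

setValidity("KmerIndex", function(object) {
    msg <- character(0)
    if (length(object@k) != 1L || object@k < 1L || object@k > 12L)
        msg <- c(msg, "k must be a single integer in 1..12")
    if (length(object@lut) != 4^object@k)
        msg <- c(msg, "lut must have length 4^k")
    if (anyNA(object@lut) ||
        !identical(range(object@lut), c(1L, length(object@kmers))))
        msg <- c(msg, "lut must cover feature indices 1..n_features")
    if (length(msg)) msg else TRUE
})

#' Universal PBM experiment: probe sequences and intensities
#'
#' The training observations for a TF binding-specificity model: one row per
#' probe, a fixed-length DNA sequence (canonically 60 bp: a 36-bp variable
#' region followed by a constant 24-bp primer complement) and a strictly
#' positive fluorescence intensity.
#'
#' @slot probes a \link[Biostrings]{DNAStringSet}, all the same width.
#' @slot intensities numeric vector of positive, finite intensities
#'   (arbitrary fluorescence units), parallel to \code{probes}.
#' @slot metadata named list of free-form annotations (TF name, source id).
#' @export
setClass("UPBMExperiment",
    representation(probes = "DNAStringSet", intensities = "numeric",
                   metadata = "list"))

setValidity("UPBMExperiment", function(object) {
    msg <- character(0)
    n <- length(object@probes)
    if (length(object@intensities) != n)
        msg <- c(msg, "intensities must be parallel to probes")
    if (n > 0L) {
        w <- Biostrings::width(object@probes)
        if (length(unique(w)) != 1L)
            msg <- c(msg, "all probe sequences must have the same length")
        else if (w[1L] < 6L)
            msg <- c(msg, "probe length must be at least 6")
        if (any(!is.finite(object@intensities)) || any(object@intensities <= 0))
            msg <- c(msg, "intensities must be strictly positive and finite")
        freq <- Biostrings::alphabetFrequency(object@probes, baseOnly = TRUE)
        if (any(freq[, "other"] > 0))
            msg <- c(msg, "probe sequences must contain only A/C/G/T")
    }
    if (length(msg)) msg else TRUE
})

#' 8-mer E-score table
#'
#' Rank-based enrichment scores in [-0.5, 0.5] summarizing a TF's relative
#' preference for each 8-mer.  Scores are strand symmetric; internally one
#' score is stored per reverse-complement pair (keyed by the canonical
#' 8-mer) and \code{\link{escore}} resolves any queried 8-mer.
#'
#' @slot scores numeric vector named by canonical 8-mers, values in
#'   [-0.5, 0.5].
#' @slot metadata named list of annotations.
#' @export
setClass("EScoreTable",
    representation(scores = "numeric", metadata = "list"))

setValidity("EScoreTable", function(object) {
    msg <- character(0)
    s <- object@scores
    if (length(s)) {
        if (is.null(names(s)) || any(nchar(names(s)) != 8L) ||
            !all(.isACGT(names(s))))
            msg <- c(msg, "scores must be named by ACGT 8-mers")
        if (any(!is.finite(s)) || any(s < -0.5) || any(s > 0.5))
            msg <- c(msg, "E-scores must lie in [-0.5, 0.5]")
    }
    if (length(msg)) msg else TRUE
})

#' Fitted OLS model of TF binding specificity
#'
#' Holds the OLS estimate \eqn{\hat\beta = (X'X)^{-1}X'Y} over canonical
#' k-mer count features, a factorization of \eqn{X'X} sufficient to form the
#' contrast variance \eqn{c'\hat\Sigma c = \hat\sigma^2 c'(X'X)^{-1}c}, the
#' residual variance \eqn{\hat\sigma^2} and the residual degrees of freedom
#' \eqn{n - p}.  Full-rank fits store the Cholesky factor of \eqn{X'X};
#' ill-conditioned or rank-deficient fits store its eigendecomposition and
#' use the minimum-norm (pseudoinverse) solution, in which case contrasts
#' are checked for estimability.
#'
#' @slot beta numeric vector of coefficient estimates, named by canonical
#'   k-mers.
#' @slot cholR upper-triangular Cholesky factor U with X'X = U'U (0 x 0
#'   matrix when the eigen route was used).
#' @slot eigVectors,eigValues eigendecomposition of X'X (empty for the
#'   Cholesky route).
#' @slot rank numerical rank of X'X used by the solver.
#' @slot sigma2 residual variance estimate RSS / (n - p).
#' @slot df residual degrees of freedom n - p (p = number of features).
#' @slot index the \linkS4class{KmerIndex} of the design.
#' @slot qc cross-validation QC list (see \code{\link{crossValidate}}).
#' @slot metadata named list (TF name, training-data id, ...).
#' @slot cache environment memoizing derived matrices such as the inverse
#'   of X'X used for batched contrast variances.
#' @export
setClass("PBMModel",
    representation(beta = "numeric", cholR = "matrix",
                   eigVectors = "matrix", eigValues = "numeric",
                   rank = "integer", sigma2 = "numeric", df = "integer",
                   index = "KmerIndex", qc = "list", metadata = "list",
                   cache = "environment"))

setValidity("PBMModel", function(object) {
    msg <- character(0)
    p <- length(object@beta)
    if (p != length(object@index@kmers))
        msg <- c(msg, "beta length must equal the number of index features")
    if (object@df <= 0L)
        msg <- c(msg, "residual degrees of freedom (n - p) must be positive")
    if (object@sigma2 < 0)
        msg <- c(msg, "sigma2 must be non-negative")
    hasChol <- nrow(object@cholR) == p
    hasEig <- ncol(object@eigVectors) == p && length(object@eigValues) == p
    if (!hasChol && !hasEig)
        msg <- c(msg, "model must carry a Cholesky or eigen factorization of X'X")
    if (length(msg)) msg else TRUE
})

#' Sparse contrast vector for a single-nucleotide variant
#'
#' The per-feature count difference (mutant minus wild type) over the six
#' 6-mer windows that overlap a variant in its 11-bp context.  Entries sum
#' to zero and, after reverse-complement collapsing, at most 12 features are
#' non-zero.  The predicted binding change is \eqn{c'\hat\beta}.
#'
#' @slot features integer vector of feature indices with non-zero entries.
#' @slot values integer count differences, parallel to \code{features}.
#' @slot context the 11-bp wild-type window (variant at the center).
#' @slot alt the alternate base.
#' @slot nFeatures total feature-space dimension.
#' @export
setClass("KmerContrast",
    representation(features = "integer", values = "integer",
                   context = "character", alt = "character",
                   nFeatures = "integer"))

setValidity("KmerContrast", function(object) {
    msg <- character(0)
    if (length(object@features) != length(object@values))
        msg <- c(msg, "features and values must be parallel")
    if (length(object@values) && sum(object@values) != 0L)
        msg <- c(msg, "contrast entries must sum to zero")
    if (length(object@features) > 12L)
        msg <- c(msg, "a single-nucleotide contrast has at most 12 non-zero features")
    if (any(object@values == 0L))
        msg <- c(msg, "stored entries must be non-zero")
    if (length(msg)) msg else TRUE
})

#' Precomputed 12-mer prediction table
#'
#' A table keyed by (11-bp wild-type context, alternate base) holding the
#' predicted binding change, z-score and P-value for one model.  Full tables
#' (all 4^11 contexts) are addressed by offset arithmetic on disk and are
#' not loaded into memory; partial tables keep sorted keys and values in
#' memory.  Values are stored in IEEE single precision, with the P-value
#' stored as -log10(p) to preserve small values.
#'
#' @slot path path of the backing file.
#' @slot modelId model identifier recorded at generation time.
#' @slot kContext context width (11).
#' @slot includeIdentity whether identity rows (alt equal to the center
#'   base; delta 0, p 1) are present.
#' @slot full whether the table covers every context (offset-addressable).
#' @slot n number of rows.
#' @slot keys sorted integer key codes (partial tables only).
#' @slot delta,z,neglog10p in-memory value columns (partial tables only).
#' @export
setClass("PredictionTable",
    representation(path = "character", modelId = "character",
                   kContext = "integer", includeIdentity = "logical",
                   full = "logical", n = "numeric", keys = "numeric",
                   delta = "numeric", z = "numeric", neglog10p = "numeric"))

#' Binding status call for a 17-bp site
#'
#' Classification of a site from its ten overlapping 8-mer E-scores:
#' \emph{bound} if two consecutive overlapping 8-mers (adjacent start
#' offsets) both have E-score > \code{thetaBound}; \emph{unbound} if all ten
#' 8-mers have E-score < \code{thetaUnbound}; otherwise \emph{ambiguous}.
#' Inequalities are strict.
#'
#' @slot status one of "bound", "unbound", "ambiguous".
#' @slot maxEscore the maximum 8-mer E-score observed in the site.
#' @slot thetaBound,thetaUnbound the thresholds used (defaults 0.4, 0.35).
#' @export
setClass("StatusCall",
    representation(status = "character", maxEscore = "numeric",
                   thetaBound = "numeric", thetaUnbound = "numeric"))

setValidity("StatusCall", function(object) {
    msg <- character(0)
    if (!object@status %in% c("bound", "unbound", "ambiguous"))
        msg <- c(msg, "status must be bound, unbound or ambiguous")
    if (object@thetaUnbound > object@thetaBound)
        msg <- c(msg, "thetaUnbound must not exceed thetaBound")
    if (length(msg)) msg else TRUE
})

#' Ground truth for synthetic uPBM data
#'
#' A planted additive 6-mer model: \code{betaTrue} is non-zero only for
#' canonical 6-mers within Hamming distance 1 of a consensus (in either
#' orientation), with magnitude decaying with mismatch count.  Synthetic log
#' intensities are \code{counts \%*\% betaTrue + baselineLog + N(0,
#' noiseSd^2)}.
#'
#' @slot betaTrue numeric vector over canonical 6-mer features.
#' @slot consensus the planted consensus 6-mer.
#' @slot amplitude coefficient of the consensus 6-mer (natural-log units).
#' @slot decay multiplicative decay per mismatch.
#' @slot noiseSd Gaussian noise standard deviation on log intensities.
#' @slot baselineLog baseline log intensity added to every probe.
#' @slot seed integer seed from which all simulation randomness flows.
#' @slot index the \linkS4class{KmerIndex} (k = 6).
#' @export
setClass("GroundTruth",
    representation(betaTrue = "numeric", consensus = "character",
                   amplitude = "numeric", decay = "numeric",
                   noiseSd = "numeric", baselineLog = "numeric",
                   seed = "integer", index = "KmerIndex"))

setValidity("GroundTruth", function(object) {
    msg <- character(0)
    if (length(object@betaTrue) != length(object@index@kmers))
        msg <- c(msg, "betaTrue must be parallel to the index features")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be non-negative")
    if (nchar(object@consensus) != object@index@k || !.isACGT(object@consensus))
        msg <- c(msg, "consensus must be an ACGT k-mer matching the index")
    if (length(msg)) msg else TRUE
})
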