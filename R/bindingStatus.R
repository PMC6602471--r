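#' @include pbmData.R
NULL

#' Classify a 17-bp site as bound / unbound / ambiguous
#'
#' Evaluates the ten overlapping 8-mers of the site against an E-score
#' table: the site is \emph{bound} if two consecutive overlapping 8-mers
#' (adjacent start offsets, overlapping by 7 bp) both have E-score strictly
#' greater than \code{thetaBound}; \emph{unbound} if all ten 8-mers have
#' E-score strictly less than \code{thetaUnbound}; otherwise
#' \emph{ambiguous}.  A score exactly equal to a threshold satisfies
#' neither strict inequality.
#'
#' @param escores an \linkS4class{EScoreTable} covering the site's 8-mers.
#' @param site a 17-bp ACGT string (8 bp of context on each side of the
#'   variant position).
#' @param thetaBound bound threshold (default 0.4).
#' @param thetaUnbound unbound threshold (default 0.35; must not exceed
#'   \code{thetaBound}).
#' @return A \linkS4class{StatusCall}.
#' @export
classifySite <- function(escores, site, thetaBound = 0.4,
                         thetaUnbound = 0.35) {
    stopifnot(is(escores, "EScoreTable"))
    if (length(site) != 1L || nchar(site) != 17L)
        .dbStop("site must be a single 17-bp sequence", "db_input_error")
    if (!.isACGT(site))
        .dbStop("site contains non-ACGT characters (e.g. N); cannot classify",
                "db_classification_error")
    if (thetaUnbound > thetaBound)
        .dbStop("thetaUnbound must not exceed thetaBound",
                "db_parameter_error")
    eightmers <- substring(site, 1:10, 8:17)
    sc <- escore(escores, eightmers)
    if (anyNA(sc))
        .dbStop("site 8-mer(s) missing from the E-score table",
                "db_classification_error")
    above <- sc > thetaBound
    bound <- any(above[-10] & above[-1])
    st <- if (bound) "bound"
          else if (all(sc < thetaUnbound)) "unbound"
          else "ambiguous"
    new("StatusCall", status = st, maxEscore = max(sc),
        thetaBound = thetaBound, thetaUnbound = thetaUnbound)
}

#' @describeIn classifySite status accessor.
#' @param x a \linkS4class{StatusCall}.
#' @export
setMethod("status", "StatusCall", function(x) x@status)

setMethod("show", "StatusCall", function(object) {
    cat(sprintf("StatusCall: %s (max E-score %.3f; thresholds > %.2f bound, < %.2f unbound)\n",
                object@status, object@maxEscore, object@thetaBound,
                object@thetaUnbound))
})

#' Label the binding-status transition of a variant
#'
#' Combines the wild-type and mutant status calls into one of the nine
#' transition labels \code{"X>Y"} with X, Y in bound / unbound / ambiguous
#' (e.g. \code{"unbound>bound"} for a variant that creates a binding
#' site).  Both calls must have been made with identical thresholds.
#'
#' @param wild,mut \linkS4class{StatusCall}s for the wild-type and mutant
#'   site.
#' @return A transition label string.
#' @export
statusTransition <- function(wild, mut) {
    stopifnot(is(wild, "StatusCall"), is(mut, "StatusCall"))
    if (wild@thetaBound != mut@thetaBound ||
        wild@thetaUnbound != mut@thetaUnbound)
        .dbStop("wild-type and mutant calls used different thresholds",
                "db_consistency_error")
    paste0(wild@status, ">", mut@status)
}
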