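#' Number of canonical k-mer features
#'
#' @param x a \linkS4class{KmerIndex}, \linkS4class{PBMModel} or
#'   \linkS4class{KmerContrast}.
#' @return Integer scalar, the number of reverse-complement-collapsed k-mer
#'   features (2080 for k = 6).
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Canonical k-mers in feature order
#' @param x a \linkS4class{KmerIndex} or an object carrying one.
#' @return Character vector of canonical k-mers, one per feature, in stable
#'   (lexicographic) index order.
#' @export
setGeneric("canonicalKmers", function(x) standardGeneric("canonicalKmers"))

#' Extract the k-mer index of an object
#' @param x a model or feature container.
#' @return The \linkS4class{KmerIndex} the object was built with.
#' @export
setGeneric("kmerIndex", function(x) standardGeneric("kmerIndex"))

#' Probe sequences of a uPBM experiment
#' @param x a \linkS4class{UPBMExperiment}.
#' @return A \link[Biostrings]{DNAStringSet} of probe sequences.
#' @export
setGeneric("probeSequences", function(x) standardGeneric("probeSequences"))

#' Probe intensities of a uPBM experiment
#' @param x a \linkS4class{UPBMExperiment}.
#' @return Numeric vector of positive fluorescence intensities.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Natural-log transformed probe intensities
#'
#' The regression outcome vector Y: element i is \code{log(intensity[i])}.
#'
#' @param x a \linkS4class{UPBMExperiment}.
#' @return Numeric vector, same length as the number of probes.
#' @export
setGeneric("logIntensities", function(x) standardGeneric("logIntensities"))

#' Look up E-scores for 8-mers
#'
#' Lookup is strand symmetric: an 8-mer and its reverse complement always
#' return the same score.
#'
#' @param x an \linkS4class{EScoreTable}.
#' @param kmers character vector of 8-mers (ACGT alphabet).
#' @return Numeric vector of E-scores in [-0.5, 0.5]; NA for 8-mers absent
#'   from the table.
#' @export
setGeneric("escore", function(x, kmers) standardGeneric("escore"))

#' Residual variance estimate of a fitted model
#' @param x a \linkS4class{PBMModel}.
#' @return The unbiased estimate \eqn{\hat\sigma^2 = RSS / (n - p)}.
#' @export
setGeneric("sigma2", function(x) standardGeneric("sigma2"))

#' Cross-validation quality metrics of a fitted model
#' @param x a \linkS4class{PBMModel}.
#' @return A list with elements \code{rTop10}, \code{rTop20}, \code{nFolds},
#'   \code{passes}, or an empty list when cross-validation was not run.
#' @export
setGeneric("modelQC", function(x) standardGeneric("modelQC"))

#' Binding status of a site classification
#' @param x a \linkS4class{StatusCall}.
#' @return One of \code{"bound"}, \code{"unbound"}, \code{"ambiguous"}.
#' @export
setGeneric("status", function(x) standardGeneric("status"))
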