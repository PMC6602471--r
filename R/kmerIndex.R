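#' @include AllGenerics.R AllClasses.R
NULL

#' Build the canonical k-mer feature index
#'
#' Enumerates all 4^k ACGT k-mers, collapses each k-mer with its reverse
#' complement into a single feature, and assigns contiguous indices in
#' lexicographic order of the canonical representatives (the smaller member
#' of each pair).  For k = 6 this yields 2080 features: (4^6 + 4^3) / 2,
#' counting the 64 reverse-complement palindromes once.
#'
#' @param k k-mer width, between 1 and 12 (default 6, the model feature
#'   width).
#' @return A \linkS4class{KmerIndex}.
#' @examples
#' idx <- buildKmerIndex(6)
#' nFeatures(idx)   # 2080
#' @export
buildKmerIndex <- function(k = 6L) {
    if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k) ||
        k < 1 || k > 12)
        .dbStop("k must be a single integer between 1 and 12",
                "db_parameter_error")
    k <- as.integer(k)
    all <- .codeToKmer(0:(4^k - 1), k)
    rc <- .revCompChar(all)
    canon <- ifelse(all <= rc, all, rc)
    kmers <- sort(unique(canon))
    lut <- match(canon, kmers)
    new("KmerIndex", k = k, kmers = kmers, lut = lut)
}

#' Canonical form of k-mers
#'
#' Returns, for each input k-mer, the lexicographically smaller of the
#' k-mer and its reverse complement.
#'
#' @param kmers character vector of ACGT k-mers (equal widths).
#' @return Character vector of canonical representatives.
#' @export
canonicalKmer <- function(kmers) {
    if (!length(kmers)) return(character(0))
    if (!all(.isACGT(kmers)))
        .dbStop("k-mers must use the ACGT alphabet", "db_input_error")
    rc <- .revCompChar(kmers)
    ifelse(kmers <= rc, kmers, rc)
}

#' Feature index of k-mers
#'
#' Maps k-mers to their canonical feature indices; a k-mer and its reverse
#' complement always map to the same index.
#'
#' @param index a \linkS4class{KmerIndex}.
#' @param kmers character vector of k-mers of width \code{index@k}.
#' @return Integer vector of 1-based feature indices.
#' @export
kmerFeatureIndex <- function(index, kmers) {
    stopifnot(is(index, "KmerIndex"))
    if (!length(kmers)) return(integer(0))
    if (any(nchar(kmers) != index@k))
        .dbStop(sprintf("k-mers must have width %d", index@k),
                "db_input_error")
    if (!all(.isACGT(kmers)))
        .dbStop("k-mers must use the ACGT alphabet", "db_input_error")
    index@lut[.kmerCode(kmers, index@k) + 1L]
}

#' @describeIn nFeatures number of canonical k-mer features of an index.
#' @export
setMethod("nFeatures", "KmerIndex", function(x) length(x@kmers))

#' @describeIn canonicalKmers canonical k-mers of an index, in feature
#'   order.
#' @export
setMethod("canonicalKmers", "KmerIndex", function(x) x@kmers)

setMethod("show", "KmerIndex", function(object) {
    cat(sprintf("KmerIndex: k = %d, %d canonical features\n",
                object@k, length(object@kmers)))
})

#' Serialize / rebuild a canonical k-mer index
#'
#' The plain-text serialization is the list of canonical k-mers in feature
#' order, one per line; rebuilding from it (or from scratch at the same k)
#' yields an identical mapping.
#'
#' @param index a \linkS4class{KmerIndex}.
#' @param path file to write to.
#' @return \code{writeKmerIndex} returns \code{path} invisibly;
#'   \code{readKmerIndex} returns a \linkS4class{KmerIndex}.
#' @export
writeKmerIndex <- function(index, path) {
    stopifnot(is(index, "KmerIndex"))
    writeLines(index@kmers, path)
    invisible(path)
}

#' @rdname writeKmerIndex
#' @export
readKmerIndex <- function(path) {
    kmers <- readLines(path)
    k <- nchar(kmers[1L])
    idx <- buildKmerIndex(k)
    if (!identical(idx@kmers, kmers))
        .dbStop("serialized index does not match the canonical ordering",
                "db_index_error")
    idx
}
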