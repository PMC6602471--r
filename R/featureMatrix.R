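#' @include kmerIndex.R
NULL

#' Count canonical k-mer occurrences in one sequence
#'
#' Slides a width-k window with step 1 over the whole sequence (including
#' any constant primer region: the TF can bind anywhere on the probe) and
#' counts occurrences per canonical feature.  The counts sum to
#' \code{L - k + 1}.
#'
#' @param index a \linkS4class{KmerIndex}.
#' @param sequence a single ACGT string of length >= k.
#' @return Integer vector of length \code{nFeatures(index)}, named by
#'   canonical k-mers.
#' @export
countKmerFeatures <- function(index, sequence) {
    stopifnot(is(index, "KmerIndex"))
    if (length(sequence) != 1L || !.isACGT(sequence))
        .dbStop("sequence must be a single ACGT string", "db_input_error")
    k <- index@k
    if (nchar(sequence) < k)
        .dbStop("sequence shorter than k", "db_input_error")
    counts <- drop(as.matrix(featureMatrix(index, sequence)))
    storage.mode(counts) <- "integer"
    counts
}

#' Build the design matrix of canonical k-mer counts
#'
#' Row i holds the canonical k-mer counts of probe i; every row sums to
#' \code{L - k + 1}.  This is the X of the regression \eqn{Y = X\beta +
#' \epsilon}.
#'
#' @param index a \linkS4class{KmerIndex}.
#' @param x a \linkS4class{UPBMExperiment}, a
#'   \link[Biostrings]{DNAStringSet}, or a character vector of equal-length
#'   ACGT sequences.
#' @param chunkSize probes per counting chunk (memory control).
#' @return A sparse \link[Matrix]{dgCMatrix-class} matrix, columns named by
#'   canonical k-mers.
#' @examples
#' idx <- buildKmerIndex(6)
#' X <- featureMatrix(idx, c(strrep("A", 60), strrep("ACGT", 15)))
#' Matrix::rowSums(X)   # both 55
#' @importFrom Biostrings oligonucleotideFrequency
#' @export
featureMatrix <- function(index, x, chunkSize = 10000L) {
    stopifnot(is(index, "KmerIndex"))
    if (is(x, "UPBMExperiment")) x <- x@probes
    if (is.character(x)) {
        if (!all(.isACGT(x)))
            .dbStop("sequences must use the ACGT alphabet", "db_input_error")
        x <- Biostrings::DNAStringSet(x)
    }
    k <- index@k
    if (length(x) && any(Biostrings::width(x) < k))
        .dbStop("all sequences must be at least k long", "db_input_error")
    p <- length(index@kmers)
    if (length(x) == 0L)
        return(Matrix::Matrix(0, nrow = 0L, ncol = p, sparse = TRUE,
                              dimnames = list(NULL, index@kmers)))
    canonCode <- .kmerCode(index@kmers, k)
    partnerCode <- .kmerCode(.revCompChar(index@kmers), k)
    nonpal <- partnerCode != canonCode
    chunks <- split(seq_along(x), ceiling(seq_along(x) / chunkSize))
    rows <- lapply(chunks, function(ii) {
        onf <- Biostrings::oligonucleotideFrequency(x[ii], width = k)
        m <- onf[, canonCode + 1L, drop = FALSE]
        m[, nonpal] <- m[, nonpal, drop = FALSE] +
            onf[, partnerCode[nonpal] + 1L, drop = FALSE]
        Matrix::Matrix(m, sparse = TRUE)
    })
    X <- if (length(rows) == 1L) rows[[1L]] else do.call(rbind, rows)
    if (is.null(dim(X))) X <- Matrix::Matrix(X, nrow = length(x), sparse = TRUE)
    dimnames(X) <- list(NULL, index@kmers)
    X
}
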