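#' @include AllClasses.R
NULL

#' Construct a uPBM experiment object
#'
#' @param sequences character vector or \link[Biostrings]{DNAStringSet} of
#'   equal-length ACGT probe sequences.
#' @param intensities numeric vector of positive fluorescence intensities.
#' @param metadata named list of annotations.
#' @return A \linkS4class{UPBMExperiment}.
#' @export
UPBMExperiment <- function(sequences, intensities, metadata = list()) {
    if (is.character(sequences))
        sequences <- Biostrings::DNAStringSet(sequences)
    new("UPBMExperiment", probes = sequences,
        intensities = as.numeric(intensities), metadata = metadata)
}

#' @describeIn UPBMExperiment probe sequences accessor.
#' @param x a \linkS4class{UPBMExperiment}.
#' @export
setMethod("probeSequences", "UPBMExperiment", function(x) x@probes)

#' @describeIn UPBMExperiment intensity accessor.
#' @export
setMethod("intensities", "UPBMExperiment", function(x) x@intensities)

#' @describeIn UPBMExperiment natural-log intensities (the regression
#'   outcome Y).
#' @export
setMethod("logIntensities", "UPBMExperiment", function(x) {
    if (any(x@intensities <= 0))
        .dbStop("intensities must be positive for the log transform",
                "db_domain_error")
    log(x@intensities)
})

setMethod("show", "UPBMExperiment", function(object) {
    cat(sprintf("UPBMExperiment: %d probes x %s bp\n", length(object@probes),
                if (length(object@probes)) Biostrings::width(object@probes)[1L]
                else "?"))
    if (length(object@metadata))
        cat("  metadata:", paste(names(object@metadata),
                                 unlist(object@metadata),
                                 sep = "=", collapse = ", "), "\n")
})

#' Read a uPBM probe table
#'
#' Reads a tab- or comma-separated table with a header row, one probe per
#' line.  Rows whose sequence contains non-ACGT characters or whose
#' intensity is missing, non-finite or not strictly positive are dropped
#' with a message reporting the count.
#'
#' @param path path to the table.
#' @param sequenceColumn,intensityColumn header names of the two columns
#'   (defaults \code{"sequence"}, \code{"intensity"}).
#' @param metadata named list attached to the returned object.
#' @return A \linkS4class{UPBMExperiment}.
#' @export
readUPBMTable <- function(path, sequenceColumn = "sequence",
                          intensityColumn = "intensity",
                          metadata = list()) {
    if (!file.exists(path))
        .dbStop(sprintf("uPBM table not found: %s", path), "db_io_error")
    sep <- .sniffSep(path)
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, comment.char = "",
                             check.names = FALSE, quote = "")
    miss <- setdiff(c(sequenceColumn, intensityColumn), colnames(tab))
    if (length(miss))
        .dbStop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
                "db_format_error")
    seqs <- toupper(as.character(tab[[sequenceColumn]]))
    ints <- suppressWarnings(as.numeric(tab[[intensityColumn]]))
    keep <- .isACGT(seqs) & is.finite(ints) & ints > 0
    dropped <- sum(!keep)
    if (dropped > 0)
        message(sprintf("readUPBMTable: dropped %d of %d rows (non-ACGT sequence or non-positive intensity)",
                        dropped, length(keep)))
    if (!any(keep))
        .dbStop("no usable probes after filtering", "db_empty_dataset_error")
    UPBMExperiment(seqs[keep], ints[keep], metadata = metadata)
}

#' Write a uPBM probe table
#'
#' @param x a \linkS4class{UPBMExperiment}.
#' @param path output path (TSV with header \code{sequence}, \code{intensity}).
#' @return \code{path}, invisibly.
#' @export
writeUPBMTable <- function(x, path) {
    stopifnot(is(x, "UPBMExperiment"))
    utils::write.table(
        data.frame(sequence = as.character(x@probes),
                   intensity = x@intensities),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.sniffSep <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) "\t" else ","
}

#' Construct an E-score table
#'
#' Scores are stored once per reverse-complement pair under the canonical
#' 8-mer; if both members of a pair are supplied they must agree.
#'
#' @param scores numeric vector named by ACGT 8-mers, values in
#'   [-0.5, 0.5].
#' @param metadata named list of annotations.
#' @return An \linkS4class{EScoreTable}.
#' @export
EScoreTable <- function(scores, metadata = list()) {
    kmers <- names(scores)
    if (is.null(kmers) || any(nchar(kmers) != 8L) || !all(.isACGT(kmers)))
        .dbStop("scores must be named by ACGT 8-mers", "db_format_error")
    if (any(!is.finite(scores)) || any(scores < -0.5 | scores > 0.5))
        .dbStop("E-scores must lie in [-0.5, 0.5]", "db_range_error")
    canon <- canonicalKmer(kmers)
    first <- !duplicated(canon)
    ref <- as.numeric(scores[first])[match(canon, canon[first])]
    conflict <- abs(as.numeric(scores) - ref) > 1e-9
    if (any(conflict))
        .dbStop(sprintf("conflicting E-scores for reverse-complement pair(s): %s",
                        paste(utils::head(unique(canon[conflict]), 5),
                              collapse = ", ")),
                "db_symmetry_error")
    vals <- stats::setNames(as.numeric(scores[first]), canon[first])
    new("EScoreTable", scores = vals[order(names(vals))],
        metadata = metadata)
}

#' @describeIn EScoreTable strand-symmetric score lookup; NA for 8-mers not
#'   covered by the table.
#' @param x an \linkS4class{EScoreTable}.
#' @param kmers character vector of ACGT 8-mers.
#' @export
setMethod("escore", "EScoreTable", function(x, kmers) {
    if (!length(kmers)) return(numeric(0))
    if (any(nchar(kmers) != 8L) || !all(.isACGT(kmers)))
        .dbStop("E-score lookup requires ACGT 8-mers", "db_input_error")
    unname(x@scores[canonicalKmer(kmers)])
})

setMethod("show", "EScoreTable", function(object) {
    cat(sprintf("EScoreTable: %d reverse-complement 8-mer pairs (%.1f%% of all pairs)\n",
                length(object@scores), 100 * length(object@scores) / 32896))
})

#' Read an 8-mer E-score table
#'
#' Expects a tab-separated file with a header.  The first column holds the
#' 8-mer and the score is taken from a column named \code{escore} (or
#' \code{E-score}); otherwise the first numeric column is used.  A second
#' 8-mer column holding the reverse complement, as in standard uPBM
#' releases, is tolerated and ignored.  Tables may list all 4^8 8-mers or
#' one per reverse-complement pair; conflicting scores within a pair are an
#' error.
#'
#' @param path path to the table.
#' @param metadata named list attached to the returned object.
#' @return An \linkS4class{EScoreTable}.
#' @export
readEScoreTable <- function(path, metadata = list()) {
    if (!file.exists(path))
        .dbStop(sprintf("E-score table not found: %s", path), "db_io_error")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "",
                             check.names = FALSE, quote = "")
    if (ncol(tab) < 2L)
        .dbStop("E-score table needs an 8-mer column and a score column",
                "db_format_error")
    kmers <- toupper(as.character(tab[[1L]]))
    if (any(nchar(kmers) != 8L) || !all(.isACGT(kmers)))
        .dbStop("first column must contain ACGT 8-mers", "db_format_error")
    scoreCol <- match(tolower(c("escore", "e-score")), tolower(colnames(tab)))
    scoreCol <- scoreCol[!is.na(scoreCol)][1]
    if (is.na(scoreCol)) {
        ## skip a tolerated second 8-mer column, take the next column
        scoreCol <- if (ncol(tab) >= 3L &&
                        all(.isACGT(toupper(as.character(tab[[2L]])))) &&
                        all(nchar(tab[[2L]]) == 8L)) 3L else 2L
    }
    scores <- suppressWarnings(as.numeric(tab[[scoreCol]]))
    if (anyNA(scores))
        .dbStop("score column is not numeric", "db_format_error")
    EScoreTable(stats::setNames(scores, kmers), metadata = metadata)
}

#' Write an 8-mer E-score table
#'
#' Writes one row per stored canonical pair: canonical 8-mer, its reverse
#' complement, and the E-score (the conventional uPBM three-column layout).
#'
#' @param x an \linkS4class{EScoreTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEScoreTable <- function(x, path) {
    stopifnot(is(x, "EScoreTable"))
    kmers <- names(x@scores)
    utils::write.table(
        data.frame(`8mer` = kmers, `8mer_rc` = .revCompChar(kmers),
                   escore = unname(x@scores), check.names = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
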