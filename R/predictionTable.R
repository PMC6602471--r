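#' @include variantEffect.R
NULL

.TABLE_MAGIC <- charToRaw("DB12")
.TABLE_VERSION <- 1L
.RECORD_BYTES <- 12L   # three float32: delta, z, -log10(p)

## Key code of a (context, alt) pair: base-4 code of the (2k-1)-mer context
## times 4 plus the alt base code.  Numeric order == lexicographic order of
## (context, alt), the fixed row order of every table.
.tableKey <- function(contexts, alts, k) {
    ctx <- .kmerCode(contexts, 2L * k - 1L)
    ctx * 4 + (match(alts, DNA_BASES4) - 1)
}

.keyToContextAlt <- function(keys, k) {
    list(context = .codeToKmer(keys %/% 4, 2L * k - 1L),
         alt = DNA_BASES4[keys %% 4 + 1])
}

## Row rank (0-based) of a key in a full table.  Without identity rows each
## context keeps its 3 non-identity alts in alphabetical order.
.fullTableRank <- function(keys, k, includeIdentity) {
    if (includeIdentity) return(keys)
    ctx <- keys %/% 4
    altIdx <- keys %% 4
    center <- (ctx %/% 4^(k - 1L)) %% 4   # code of the center base
    isId <- altIdx == center
    rank <- ctx * 3 + altIdx - (altIdx > center)
    rank[isId] <- NA_real_
    rank
}

#' Row count of a complete 12-mer table
#'
#' @param k model k-mer width (6 for the standard models; contexts are
#'   2k-1 bp).
#' @param includeIdentity whether identity rows (alt equal to the center
#'   base) are counted.
#' @return \code{4^(2k)} rows with identity rows (16,777,216 for k = 6),
#'   \code{3 * 4^(2k-1)} without.
#' @export
fullTableRows <- function(k = 6L, includeIdentity = TRUE) {
    if (includeIdentity) 4^(2L * k) else 3 * 4^(2L * k - 1L)
}

#' Generate a precomputed 12-mer prediction table
#'
#' Writes, for every (11-bp wild-type context, alternate base) key --- or
#' for a supplied subset of keys --- the model's predicted binding change,
#' z-score and P-value.  Rows are generated in lexicographic key order in
#' fixed-size chunks, so a complete table never needs all rows in memory.
#' Values are stored as IEEE single-precision floats (P-values as
#' -log10(p)); a lookup therefore reproduces direct computation exactly at
#' stored (float32) precision.
#'
#' @param model a \linkS4class{PBMModel}.
#' @param path output file.
#' @param contexts,alts optional key subset (parallel vectors); the
#'   default NULL generates the complete table.
#' @param includeIdentity include identity rows (delta 0, z 0, p 1).
#'   Complete tables with identity rows are addressed by offset arithmetic.
#' @param chunkSize keys computed per chunk.
#' @return The path, invisibly.
#' @export
generatePredictionTable <- function(model, path, contexts = NULL,
                                    alts = NULL, includeIdentity = TRUE,
                                    chunkSize = 65536L) {
    stopifnot(is(model, "PBMModel"))
    k <- model@index@k
    modelId <- if (!is.null(model@metadata$id)) as.character(model@metadata$id)
               else if (!is.null(model@metadata$tf)) as.character(model@metadata$tf)
               else "unnamed-model"
    full <- is.null(contexts)
    if (full) {
        nCtx <- 4^(2L * k - 1L)
        n <- fullTableRows(k, includeIdentity)
        keys <- NULL
    } else {
        if (is.null(alts))
            .dbStop("supply alts alongside contexts", "db_input_error")
        keys <- .tableKey(as.character(contexts), as.character(alts), k)
        if (anyNA(keys))
            .dbStop("malformed context/alt keys", "db_input_error")
        o <- order(keys)
        keys <- keys[o]
        dup <- duplicated(keys)
        keys <- keys[!dup]
        if (!includeIdentity) {
            ka <- .keyToContextAlt(keys, k)
            keep <- substr(ka$context, k, k) != ka$alt
            keys <- keys[keep]
        }
        n <- length(keys)
    }
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(.TABLE_MAGIC, con)
    writeBin(c(.TABLE_VERSION, as.integer(2L * k - 1L),
               as.integer(includeIdentity), as.integer(full)), con,
             size = 4L, endian = "little")
    idRaw <- charToRaw(modelId)
    writeBin(length(idRaw), con, size = 4L, endian = "little")
    writeBin(idRaw, con)
    writeBin(as.numeric(n), con, size = 8L, endian = "little")
    if (!full && n > 0)
        writeBin(as.numeric(keys), con, size = 8L, endian = "little")
    writeChunk <- function(chunkKeys) {
        ka <- .keyToContextAlt(chunkKeys, k)
        pred <- predictEffect(model, ka$context, ka$alt)
        neglog <- -log10(pred$p)
        writeBin(as.numeric(rbind(pred$delta, pred$z, neglog)), con,
                 size = 4L, endian = "little")
    }
    if (full) {
        allAlt <- 0:3
        ctxPerChunk <- max(1L, chunkSize %/% 4L)
        starts <- seq(0, nCtx - 1, by = ctxPerChunk)
        for (s in starts) {
            ctxCodes <- s:min(s + ctxPerChunk - 1, nCtx - 1)
            keysChunk <- rep(ctxCodes, each = 4) * 4 + allAlt
            if (!includeIdentity) {
                center <- (keysChunk %/% 4 %/% 4^(k - 1L)) %% 4
                keysChunk <- keysChunk[keysChunk %% 4 != center]
            }
            writeChunk(keysChunk)
        }
    } else if (n > 0) {
        for (s in seq(1L, n, by = chunkSize))
            writeChunk(keys[s:min(s + chunkSize - 1L, n)])
    }
    invisible(path)
}

#' Open a prediction table
#'
#' Reads the header (and, for partial tables, the sorted keys and values).
#' Complete tables stay on disk and are addressed by offset arithmetic at
#' lookup time.
#'
#' @param path path written by \code{\link{generatePredictionTable}}.
#' @return A \linkS4class{PredictionTable}.
#' @export
readPredictionTable <- function(path) {
    if (!file.exists(path))
        .dbStop(sprintf("prediction table not found: %s", path),
                "db_table_file_error")
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", n = 4L)
    if (!identical(magic, .TABLE_MAGIC))
        .dbStop("not a deltaBind prediction table", "db_table_file_error")
    hdr <- readBin(con, "integer", n = 4L, size = 4L, endian = "little")
    if (hdr[1L] != .TABLE_VERSION)
        .dbStop(sprintf("unsupported table version %d", hdr[1L]),
                "db_table_file_error")
    idLen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    modelId <- rawToChar(readBin(con, "raw", n = idLen))
    n <- readBin(con, "numeric", n = 1L, size = 8L, endian = "little")
    full <- hdr[4L] == 1L
    obj <- new("PredictionTable", path = normalizePath(path),
               modelId = modelId, kContext = hdr[2L],
               includeIdentity = hdr[3L] == 1L, full = full, n = n,
               keys = numeric(0), delta = numeric(0), z = numeric(0),
               neglog10p = numeric(0))
    if (!full) {
        obj@keys <- readBin(con, "numeric", n = n, size = 8L,
                            endian = "little")
        vals <- readBin(con, "numeric", n = 3L * n, size = 4L,
                        endian = "little")
        if (length(obj@keys) != n || length(vals) != 3L * n)
            .dbStop("truncated prediction table", "db_table_file_error")
        m <- matrix(vals, nrow = 3L)
        obj@delta <- m[1L, ]
        obj@z <- m[2L, ]
        obj@neglog10p <- m[3L, ]
    } else {
        expect <- .tableDataOffset(idLen, full = TRUE, n = 0) +
            n * .RECORD_BYTES
        if (file.info(path)$size != expect)
            .dbStop("truncated prediction table", "db_table_file_error")
    }
    obj
}

.tableDataOffset <- function(idLen, full, n) {
    4L + 4L * 4L + 4L + idLen + 8L + if (full) 0 else 8 * n
}

#' Look up predictions in a table
#'
#' Returns the stored (delta, z, p) for each (context, alt) key; identical
#' to \code{\link{predictEffect}} at stored float32 precision.  Missing
#' keys error, distinguishing identity rows excluded by the table flag
#' from keys absent from a partial table.
#'
#' @param table a \linkS4class{PredictionTable}.
#' @param contexts,alts key vectors (contexts of width \code{kContext},
#'   variant at the center).
#' @return data.frame with columns \code{context}, \code{alt},
#'   \code{delta}, \code{z}, \code{p}.
#' @export
lookupPrediction <- function(table, contexts, alts) {
    stopifnot(is(table, "PredictionTable"))
    n <- max(length(contexts), length(alts))
    contexts <- rep_len(as.character(contexts), n)
    alts <- rep_len(as.character(alts), n)
    width <- table@kContext
    if (any(nchar(contexts) != width) || !all(.isACGT(contexts)) ||
        !all(alts %in% DNA_BASES4))
        .dbStop(sprintf("lookup keys must be ACGT %d-mers plus an alternate base",
                        width), "db_key_error")
    k <- (width + 1L) %/% 2L
    keys <- .tableKey(contexts, alts, k)
    identity <- substr(contexts, k, k) == alts
    if (!table@includeIdentity && any(identity))
        .dbStop("identity rows were excluded from this table",
                "db_lookup_miss_identity")
    if (table@full) {
        rank <- .fullTableRank(keys, k, table@includeIdentity)
        vals <- .readRecords(table, rank)
    } else {
        pos <- match(keys, table@keys)
        if (anyNA(pos))
            .dbStop(sprintf("%d key(s) absent from this partial table",
                            sum(is.na(pos))), "db_lookup_miss")
        vals <- list(delta = table@delta[pos], z = table@z[pos],
                     neglog10p = table@neglog10p[pos])
    }
    data.frame(context = contexts, alt = alts, delta = vals$delta,
               z = vals$z, p = 10^(-vals$neglog10p),
               stringsAsFactors = FALSE)
}

.readRecords <- function(table, ranks) {
    idLen <- length(charToRaw(table@modelId))
    base <- .tableDataOffset(idLen, full = TRUE, n = 0)
    con <- file(table@path, "rb")
    on.exit(close(con))
    ord <- order(ranks)
    out <- matrix(NA_real_, nrow = 3L, ncol = length(ranks))
    for (i in ord) {
        seek(con, where = base + ranks[i] * .RECORD_BYTES, origin = "start")
        out[, i] <- readBin(con, "numeric", n = 3L, size = 4L,
                            endian = "little")
    }
    list(delta = out[1L, ], z = out[2L, ], neglog10p = out[3L, ])
}

setMethod("show", "PredictionTable", function(object) {
    cat(sprintf("PredictionTable: model '%s', %s-bp contexts, %s rows (%s%s)\n",
                object@modelId, object@kContext,
                format(object@n, big.mark = ","),
                if (object@full) "complete" else "partial",
                if (object@includeIdentity) ", identity rows included" else ""))
})
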