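#' @include olsFit.R
NULL

.MODEL_FORMAT <- "deltaBind-model"
.MODEL_VERSION <- 1L

## Order-insensitive byte checksum of the serialized payload; cheap
## corruption guard, not a cryptographic hash.
.payloadChecksum <- function(payload) {
    r <- serialize(payload, NULL, version = 3L)
    sum(as.double(r)) + length(r)
}

#' Save / load a fitted model
#'
#' The model file is a single self-describing archive (R serialization)
#' holding a format tag, a version number, the canonical k-mer index as
#' plain text lines, the coefficient vector, the stored factorization of
#' X'X, the scalars \eqn{\hat\sigma^2} and \eqn{n - p}, the QC record, the
#' metadata and a checksum.  Loading verifies the tag, version and
#' checksum, so a truncated or corrupted file errors rather than silently
#' degrading.
#'
#' @param model a \linkS4class{PBMModel}.
#' @param path file path.
#' @return \code{saveModel} returns \code{path} invisibly;
#'   \code{loadModel} returns the restored \linkS4class{PBMModel}.
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "PBMModel"))
    payload <- list(k = model@index@k, kmers = model@index@kmers,
                    beta = unname(model@beta), cholR = model@cholR,
                    eigVectors = model@eigVectors,
                    eigValues = model@eigValues, rank = model@rank,
                    sigma2 = model@sigma2, df = model@df, qc = model@qc,
                    metadata = model@metadata)
    obj <- list(format = .MODEL_FORMAT, version = .MODEL_VERSION,
                payload = payload, checksum = .payloadChecksum(payload))
    saveRDS(obj, path)
    invisible(path)
}

#' @rdname saveModel
#' @param k optional expected k-mer width; loading a model fitted at a
#'   different k errors.
#' @export
loadModel <- function(path, k = NULL) {
    if (!file.exists(path))
        .dbStop(sprintf("model file not found: %s", path),
                "db_model_file_error")
    obj <- tryCatch(readRDS(path), error = function(e)
        .dbStop(sprintf("unreadable model file (truncated or corrupt): %s",
                        conditionMessage(e)), "db_model_file_error"))
    if (!is.list(obj) || !identical(obj$format, .MODEL_FORMAT))
        .dbStop("not a deltaBind model file", "db_model_file_error")
    if (!identical(obj$version, .MODEL_VERSION))
        .dbStop(sprintf("unsupported model file version %s", obj$version),
                "db_model_file_error")
    if (!identical(.payloadChecksum(obj$payload), obj$checksum))
        .dbStop("model file checksum mismatch", "db_model_file_error")
    pl <- obj$payload
    if (!is.null(k) && pl$k != k)
        .dbStop(sprintf("model was fitted at k = %d, expected k = %d",
                        pl$k, k), "db_index_error")
    index <- buildKmerIndex(pl$k)
    if (!identical(index@kmers, pl$kmers))
        .dbStop("stored k-mer index does not match the canonical ordering",
                "db_index_error")
    new("PBMModel", beta = stats::setNames(pl$beta, pl$kmers),
        cholR = pl$cholR, eigVectors = pl$eigVectors,
        eigValues = pl$eigValues, rank = pl$rank, sigma2 = pl$sigma2,
        df = pl$df, index = index, qc = pl$qc, metadata = pl$metadata,
        cache = new.env(parent = emptyenv()))
}
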