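#' @include featureMatrix.R pbmData.R
NULL

#' Default constant primer-complement sequence for simulated probes
#'
#' A fixed, synthetic 24-bp sequence standing in for the constant
#' double-stranding primer complement of uPBM probes.  Any fixed ACGT
#' 24-mer works; this one is arbitrary and GC-balanced.
#'
#' @return A 24-character string.
#' @export
defaultPrimer <- function() "CCTGTCGTATGACAACGGAGCCTA"

#' Plant a ground-truth additive 6-mer binding model
#'
#' Builds a motif-like coefficient vector: the canonical feature of the
#' consensus 6-mer (matched in either orientation) gets coefficient
#' \code{amplitude}; features within Hamming distance 1 get
#' \code{amplitude * decay}; all others 0.  Defaults emulate a strong,
#' specific TF on the natural-log intensity scale: the consensus multiplies
#' a probe's intensity by about e^3 (~20-fold) per occurrence, a single
#' mismatch by about e (~2.7-fold), and probe noise has sd 0.5.
#'
#' @param consensus the planted consensus 6-mer.
#' @param amplitude consensus coefficient, natural-log intensity units.
#' @param decay multiplicative decay per mismatch.
#' @param noiseSd Gaussian noise sd on log intensities.
#' @param baselineLog baseline (background) log intensity.
#' @param seed integer seed; all downstream simulation randomness flows
#'   from it.
#' @param index a k = 6 \linkS4class{KmerIndex} (built if omitted).
#' @return A \linkS4class{GroundTruth}.
#' @export
simulateGroundTruth <- function(consensus = "TGACGT", amplitude = 3,
                                decay = 1 / 3, noiseSd = 0.5,
                                baselineLog = 7, seed = 1L, index = NULL) {
    if (is.null(index)) index <- buildKmerIndex(6L)
    if (nchar(consensus) != index@k || !.isACGT(consensus))
        .dbStop("consensus must be an ACGT k-mer matching the index",
                "db_input_error")
    kmers <- index@kmers
    cc <- strsplit(c(consensus, .revCompChar(consensus)), "")
    mm <- vapply(strsplit(kmers, ""), function(s)
        min(sum(s != cc[[1L]]), sum(s != cc[[2L]])), 0L)
    beta <- ifelse(mm <= 1L, amplitude * decay^mm, 0)
    new("GroundTruth", betaTrue = stats::setNames(beta, kmers),
        consensus = consensus, amplitude = amplitude, decay = decay,
        noiseSd = noiseSd, baselineLog = baselineLog,
        seed = as.integer(seed), index = index)
}

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: consensus %s, amplitude %.2f, decay %.2f, noise sd %.2f, seed %d; %d non-zero features\n",
                object@consensus, object@amplitude, object@decay,
                object@noiseSd, object@seed, sum(object@betaTrue != 0)))
})

#' @describeIn simulateGroundTruth k-mer index accessor.
#' @param x a \linkS4class{GroundTruth}.
#' @export
setMethod("kmerIndex", "GroundTruth", function(x) x@index)

#' Simulate a uPBM dataset from a planted model
#'
#' Probe sequences are uniform random variable regions followed by a fixed
#' primer complement (canonically 36 + 24 bp).  Log intensities are the
#' additive 6-mer model plus Gaussian noise:
#' \code{counts \%*\% betaTrue + baselineLog + N(0, noiseSd^2)}, and
#' intensities are exponentiated back to the positive fluorescence scale.
#' The same truth object always yields the identical dataset (the seed is
#' part of the truth).
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param nProbes number of probes; the default matches the scale of a
#'   real uPBM experiment.  Must exceed the feature count for downstream
#'   fitting.
#' @param variableLength width of the random variable region (36).
#' @param primer constant primer-complement sequence appended to every
#'   probe (24 bp by default; any fixed ACGT string is accepted).
#' @return A \linkS4class{UPBMExperiment}.
#' @importFrom stats rnorm
#' @export
simulateUPBM <- function(truth, nProbes = 44000L, variableLength = 36L,
                         primer = defaultPrimer()) {
    stopifnot(is(truth, "GroundTruth"))
    if (!.isACGT(primer))
        .dbStop("primer must be an ACGT string", "db_input_error")
    .withLocalSeed(truth@seed, {
        var <- .randomDNA(nProbes, variableLength)
        seqs <- paste0(var, primer)
        X <- featureMatrix(truth@index, seqs)
        y <- as.vector(X %*% unname(truth@betaTrue)) + truth@baselineLog +
            stats::rnorm(nProbes, 0, truth@noiseSd)
        UPBMExperiment(seqs, exp(y),
                       metadata = list(simulated = "TRUE",
                                       consensus = truth@consensus,
                                       seed = truth@seed))
    })
}

#' Derive a strand-symmetric 8-mer E-score table from the planted model
#'
#' Each canonical 8-mer is scored by the summed ground-truth coefficients
#' of its three constituent 6-mers, then rank-scaled into (-0.5, 0.5):
#' score = (rank - 0.5) / n - 0.5 with average ranks for ties.  The top
#' 8-mers (those containing the consensus) approach +0.5 and the
#' background mass sits near 0 from below, mimicking the shape of real
#' uPBM E-score distributions.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @return An \linkS4class{EScoreTable} covering all 8-mers.
#' @export
simulateEScores <- function(truth) {
    stopifnot(is(truth, "GroundTruth"))
    idx8 <- buildKmerIndex(8L)
    canon8 <- idx8@kmers
    k <- truth@index@k
    nwin <- 8L - k + 1L
    win <- vapply(seq_len(nwin), function(o) substr(canon8, o, o + k - 1L),
                  character(length(canon8)))
    dim(win) <- c(length(canon8), nwin)
    fid <- matrix(truth@index@lut[.kmerCode(as.vector(win), k) + 1L],
                  nrow = length(canon8))
    sums <- rowSums(matrix(unname(truth@betaTrue)[fid], nrow = length(canon8)))
    n <- length(canon8)
    scores <- (rank(sums, ties.method = "average") - 0.5) / n - 0.5
    EScoreTable(stats::setNames(scores, canon8),
                metadata = list(simulated = "TRUE",
                                consensus = truth@consensus))
}

#' Enumerate a single-nucleotide mutagenesis library
#'
#' All possible single-nucleotide variants within a region of a sequence:
#' 3 variants per position, each returned with its full-length mutant
#' sequence (the in-vitro custom-library design).
#'
#' @param sequence wild-type ACGT sequence.
#' @param start,end 1-based inclusive region bounds within the sequence.
#' @return data.frame with columns \code{position}, \code{ref},
#'   \code{alt}, \code{mutant}; \code{3 * (end - start + 1)} rows.
#' @export
mutagenesisLibrary <- function(sequence, start, end) {
    if (length(sequence) != 1L || !.isACGT(sequence))
        .dbStop("sequence must be a single ACGT string", "db_input_error")
    L <- nchar(sequence)
    if (start > end) return(data.frame(position = integer(0),
                                       ref = character(0),
                                       alt = character(0),
                                       mutant = character(0)))
    if (start < 1L || end > L)
        .dbStop("region out of sequence bounds", "db_input_error")
    pos <- rep(start:end, each = 3L)
    ref <- substring(sequence, pos, pos)
    alt <- unlist(lapply(substring(sequence, start:end, start:end),
                         function(b) setdiff(DNA_BASES4, b)))
    mutant <- sequence
    mutant <- vapply(seq_along(pos), function(i) {
        s <- sequence
        substr(s, pos[i], pos[i]) <- alt[i]
        s
    }, "")
    data.frame(position = pos, ref = ref, alt = alt, mutant = mutant,
               stringsAsFactors = FALSE)
}

#' Evaluate predictions against simulated measured binding changes
#'
#' Emulates the custom-PBM evaluation: for each library variant the
#' "measured" change is the ground-truth log-signal difference between
#' mutant and wild-type full sequences plus Gaussian measurement noise,
#' and the prediction is the model's contrast delta for the variant's
#' 11-bp context.  Variants closer than k bp to a sequence end (whose
#' scoring window would be truncated) are excluded.
#'
#' @param model a fitted \linkS4class{PBMModel}.
#' @param truth the \linkS4class{GroundTruth} the training data came from.
#' @param sequence the wild-type sequence carrying the site.
#' @param library mutagenesis library from
#'   \code{\link{mutagenesisLibrary}}; built over the interior of
#'   \code{sequence} when NULL.
#' @param noiseSdMeasure measurement noise sd on the log-ratio scale.
#' @param seed seed for the measurement noise.
#' @return A list with \code{pearson}, \code{spearman}, \code{n},
#'   and the per-variant \code{predicted} and \code{measured} changes.
#'   Degenerate (constant) predictions yield NA correlations with a
#'   warning.
#' @importFrom stats cor rnorm
#' @export
evaluatePredictions <- function(model, truth, sequence, library = NULL,
                                noiseSdMeasure = 0.3, seed = 1L) {
    stopifnot(is(model, "PBMModel"), is(truth, "GroundTruth"))
    k <- model@index@k
    L <- nchar(sequence)
    if (is.null(library))
        library <- mutagenesisLibrary(sequence, k, L - k + 1L)
    interior <- library$position >= k & library$position <= L - k + 1L
    if (any(!interior))
        message(sprintf("evaluatePredictions: excluding %d variant(s) within %d bp of a sequence end",
                        sum(!interior), k - 1L))
    lib <- library[interior, , drop = FALSE]
    n <- nrow(lib)
    contexts <- substring(sequence, lib$position - (k - 1L),
                          lib$position + (k - 1L))
    predicted <- predictEffect(model, contexts, lib$alt,
                               statistics = FALSE)$delta
    betaTrue <- unname(truth@betaTrue)
    wtCounts <- countKmerFeatures(truth@index, sequence)
    trueChange <- vapply(lib$mutant, function(m)
        sum((countKmerFeatures(truth@index, m) - wtCounts) * betaTrue),
        numeric(1), USE.NAMES = FALSE)
    measured <- trueChange +
        .withLocalSeed(seed, stats::rnorm(n, 0, noiseSdMeasure))
    pe <- if (stats::sd(predicted) == 0 || stats::sd(measured) == 0) {
        warning("degenerate (constant) predictions or measurements; correlation undefined")
        NA_real_
    } else stats::cor(predicted, measured)
    sp <- if (is.na(pe)) NA_real_ else
        stats::cor(predicted, measured, method = "spearman")
    list(pearson = pe, spearman = sp, n = n, predicted = predicted,
         measured = measured, trueChange = trueChange)
}

#' Write ground-truth coefficients as a plain-text table
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output TSV (canonical 6-mer, beta).
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
    utils::write.table(
        data.frame(kmer = names(truth@betaTrue),
                   beta = unname(truth@betaTrue)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
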