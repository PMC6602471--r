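test_that("simulation is a deterministic function of the seed", {
    t1 <- simulateGroundTruth(seed = 141)
    t2 <- simulateGroundTruth(seed = 141)
    d1 <- simulateUPBM(t1, nProbes = 200)
    d2 <- simulateUPBM(t2, nProbes = 200)
    expect_identical(as.character(probeSequences(d1)),
                     as.character(probeSequences(d2)))
    expect_identical(intensities(d1), intensities(d2))

    d3 <- simulateUPBM(simulateGroundTruth(seed = 142), nProbes = 200)
    expect_false(identical(intensities(d1), intensities(d3)))

    ## probe anatomy: 36-bp variable region + constant 24-bp primer
    seqs <- as.character(probeSequences(d1))
    expect_true(all(nchar(seqs) == 60))
    expect_identical(unique(substr(seqs, 37, 60)), defaultPrimer())

    expect_error(simulateUPBM(t1, nProbes = 10, primer = "NNN"), "ACGT")
})

test_that("the planted coefficients have motif-like structure", {
    truth <- simulateGroundTruth(consensus = "TGACGT", amplitude = 3,
                                 decay = 1 / 3, seed = 1)
    beta <- truth@betaTrue
    expect_identical(unname(beta[canonicalKmer("TGACGT")]), 3)
    expect_identical(unname(beta["ACACGT"]), 0)   # Hamming 2
    one <- beta[canonicalKmer("TGACGA")]          # Hamming 1
    expect_identical(unname(one), 1)
    ## strand symmetric by construction: defined over canonical features
    expect_identical(unname(beta[canonicalKmer("ACGTCA")]), 3)
    expect_identical(sum(beta != 0) > 10, TRUE)
})

test_that("a noise-free fit recovers the planted model", {
    fx <- simFixture()
    ## rows sum to 55, so the baseline log intensity is absorbed exactly as
    ## a uniform +baseline/55 shift of every coefficient; zero-sum variant
    ## contrasts are unaffected by it
    shift <- fx$truth0@baselineLog / 55
    expect_lt(max(abs(coef(fx$fit0) - fx$truth0@betaTrue - shift)), 1e-6)
    expect_lt(sigma2(fx$fit0), 1e-12)

    ## variants outside any planted 6-mer predict exactly no change
    set.seed(143)
    nullCtx <- character(0)
    while (length(nullCtx) < 20) {
        cand <- randomSeqs(50, 11)
        touch <- vapply(cand, function(ctx) {
            wins <- substring(ctx, 1:6, 6:11)
            any(fx$truth0@betaTrue[kmerFeatureIndex(fx$idx, wins)] != 0)
        }, TRUE)
        nullCtx <- c(nullCtx, cand[!touch])
    }
    nullCtx <- nullCtx[1:20]
    alts <- substr(chartr("ACGT", "CGTA", nullCtx), 6, 6)
    pred <- predictEffect(fx$fit0, nullCtx, alts, statistics = FALSE)
    ## mutant windows may still touch the motif; keep truly null ones
    keep <- vapply(seq_along(nullCtx), function(i) {
        mut <- nullCtx[i]; substr(mut, 6, 6) <- alts[i]
        all(fx$truth0@betaTrue[kmerFeatureIndex(
            fx$idx, substring(mut, 1:6, 6:11))] == 0)
    }, TRUE)
    expect_gt(sum(keep), 5)
    expect_lt(max(abs(pred$delta[keep])), 1e-8)
})

test_that("simulated E-scores are symmetric, bounded and motif-topped", {
    truth <- simulateGroundTruth(seed = 144)
    es <- simulateEScores(truth)
    set.seed(145)
    w <- randomSeqs(300, 8)
    expect_identical(escore(es, w), escore(es, oracleRevComp(w)))
    all8 <- canonicalKmers(buildKmerIndex(8))
    sc <- escore(es, all8)
    expect_true(all(sc > -0.5 & sc < 0.5))
    ## consensus-bearing 8-mers rank at the very top
    top <- escore(es, paste0("A", "TGACGT", "A"))
    expect_gt(top, 0.45)
    ## background mass sits near zero
    expect_lt(abs(median(sc)), 0.05)
})

test_that("mutagenesis libraries enumerate every single-nucleotide variant once", {
    seqn <- paste0(strrep("A", 10), "TGACGTTGAC", strrep("C", 10))
    lib <- mutagenesisLibrary(seqn, 11, 20)
    expect_identical(nrow(lib), 30L)
    expect_identical(anyDuplicated(lib[, c("position", "alt")]), 0L)
    diffs <- mapply(function(m, pos, alt) {
        d <- which(strsplit(m, "")[[1]] != strsplit(seqn, "")[[1]])
        identical(d, as.integer(pos)) &&
            substr(m, pos, pos) == alt
    }, lib$mutant, lib$position, lib$alt)
    expect_true(all(diffs))
    expect_true(all(lib$ref != lib$alt))

    expect_identical(nrow(mutagenesisLibrary(seqn, 5, 4)), 0L)
    expect_error(mutagenesisLibrary(seqn, 0, 5), "bounds")
})

test_that("noise-free training and measurement agree perfectly; shuffling destroys it", {
    fx <- simFixture()
    site <- paste0("ACGTACGTACGTACG", "TGACGT", "TACGTACGTACGTAC")
    ev <- evaluatePredictions(fx$fit0, fx$truth0, site, noiseSdMeasure = 0,
                              seed = 5)
    expect_gt(ev$pearson, 1 - 1e-8)
    expect_identical(ev$n, 78L)   # 3 x 26 interior positions of a 36-mer

    set.seed(146)
    shuffled <- sample(ev$predicted)
    expect_lt(abs(cor(shuffled, ev$measured)), 0.4)
})

test_that("parameter recovery improves with sample size at fixed noise", {
    idx <- buildKmerIndex(3)
    truth <- simulateGroundTruth(consensus = "TGA", amplitude = 2,
                                 seed = 147, index = idx)
    rec <- vapply(c(300, 1000, 6000), function(n) {
        ds <- simulateUPBM(
            simulateGroundTruth(consensus = "TGA", amplitude = 2,
                                seed = 147 + n, index = idx),
            nProbes = n, variableLength = 36)
        X <- featureMatrix(idx, ds)
        fit <- suppressWarnings(fitOLS(X, logIntensities(ds), idx))
        cor(coef(fit), truth@betaTrue)
    }, 0)
    expect_true(all(diff(rec) > 0))
    expect_gt(rec[3], 0.95)
})
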