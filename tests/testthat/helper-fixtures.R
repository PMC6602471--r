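## Shared simulation fixtures, built once per test session.  The main
## fixture reproduces the package's reference evaluation conditions:
## 5000 probes (36-bp variable region + 24-bp primer), planted consensus
## motif, Gaussian log-intensity noise sd 0.5.

.fixtures <- new.env(parent = emptyenv())

simFixture <- function() {
    if (is.null(.fixtures$main)) {
        idx <- buildKmerIndex(6L)
        truth <- simulateGroundTruth(seed = 101L, index = idx)
        ds <- simulateUPBM(truth, nProbes = 5000L)
        X <- featureMatrix(idx, ds)
        y <- logIntensities(ds)
        fit <- fitOLS(X, y, idx, metadata = list(tf = "SIMTF", id = "SIMTF"))
        ## same design, noise-free outcomes: exact-interpolation fit
        truth0 <- simulateGroundTruth(seed = 101L, noiseSd = 0, index = idx)
        y0 <- as.vector(X %*% unname(truth0@betaTrue)) + truth0@baselineLog
        fit0 <- fitOLS(X, y0, idx, metadata = list(tf = "SIMTF0"))
        .fixtures$main <- list(idx = idx, truth = truth, ds = ds, X = X,
                               y = y, fit = fit, truth0 = truth0, y0 = y0,
                               fit0 = fit0)
    }
    .fixtures$main
}

## small full-rank design: random 12-bp probes, k = 2 (10 features)
smallDesign <- function(n = 200L, seed = 11L, k = 2L, width = 12L) {
    idx <- buildKmerIndex(k)
    set.seed(seed)
    seqs <- randomSeqs(n, width)
    X <- featureMatrix(idx, seqs)
    list(idx = idx, seqs = seqs, X = X)
}

## a tiny two-chromosome genome for coordinate-based variant parsing
testGenome <- function(seed = 21L) {
    set.seed(seed)
    Biostrings::DNAStringSet(c(chr1 = randomSeqs(1, 300),
                               chr2 = randomSeqs(1, 120)))
}

## an E-score table that covers the ten 8-mers of `site` with the given
## scores and leaves every other 8-mer at `background`
siteEScoreTable <- function(site, scores, background = 0) {
    eights <- substring(site, 1:10, 8:17)
    canon <- oracleCanonical(eights)
    stopifnot(length(unique(canon)) == 10L)   # no collisions
    if (is.null(.fixtures$all8))
        .fixtures$all8 <- deltaBind::canonicalKmers(buildKmerIndex(8L))
    vals <- stats::setNames(rep(background, length(.fixtures$all8)),
                            .fixtures$all8)
    vals[canon] <- scores
    EScoreTable(vals)
}

## a 17-bp site whose ten 8-mer windows have ten distinct canonical forms
distinctWindowSite <- function(seed = 31L) {
    set.seed(seed)
    repeat {
        site <- randomSeqs(1, 17)
        canon <- oracleCanonical(substring(site, 1:10, 8:17))
        if (length(unique(canon)) == 10L) return(site)
    }
}
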