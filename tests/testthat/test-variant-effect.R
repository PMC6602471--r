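test_that("contrasts are zero-sum, sparse, and match brute-force window diffs", {
    idx <- buildKmerIndex(6)

    ## identity variant: all-zero contrast
    c0 <- buildContrast(idx, "AAAAAAAAAAA", "A")
    expect_identical(length(c0@features), 0L)

    ## worked case: poly-A context mutated at the center
    c1 <- buildContrast(idx, "AAAAAAAAAAA", "C")
    expect_identical(sum(c1@values), 0L)
    oracle <- oracleContrast("AAAAAAAAAAA", "C")
    expect_identical(length(c1@features), length(oracle))
    got <- stats::setNames(c1@values, canonicalKmers(idx)[c1@features])
    expect_identical(as.integer(got[names(oracle)]), unname(oracle))

    ## property sweep against the brute-force oracle
    set.seed(111)
    for (i in 1:200) {
        ctx <- randomSeqs(1, 11)
        alt <- sample(c("A", "C", "G", "T"), 1)
        cc <- buildContrast(idx, ctx, alt)
        orc <- oracleContrast(ctx, alt)
        expect_identical(sum(cc@values), 0L)
        expect_lte(length(cc@features), 12L)
        expect_identical(
            stats::setNames(as.integer(cc@values),
                            canonicalKmers(idx)[cc@features])[names(orc)],
            orc)
    }

    expect_error(buildContrast(idx, "AAAA", "C"), "11 bp")
    expect_error(buildContrast(idx, "AAAAANAAAAA", "C"), "ACGT")
})

test_that("noise-free predictions equal hand-summed coefficient differences", {
    fx <- simFixture()
    betaTrue <- unname(fx$truth0@betaTrue)
    set.seed(112)
    contexts <- randomSeqs(50, 11)
    ## embed the consensus in some contexts so effects are non-trivial
    contexts[1:10] <- paste0(substr(contexts[1:10], 1, 3), "TGACGT",
                             substr(contexts[1:10], 10, 11))
    alts <- sample(c("A", "C", "G", "T"), 50, replace = TRUE)
    pred <- predictEffect(fx$fit0, contexts, alts, statistics = FALSE)
    for (i in seq_along(contexts)) {
        mut <- contexts[i]
        substr(mut, 6, 6) <- alts[i]
        wtScore <- sum(betaTrue[kmerFeatureIndex(fx$idx,
                           substring(contexts[i], 1:6, 6:11))])
        mutScore <- sum(betaTrue[kmerFeatureIndex(fx$idx,
                           substring(mut, 1:6, 6:11))])
        expect_equal(pred$delta[i], mutScore - wtScore, tolerance = 1e-8)
    }
    ## identity variants predict exactly no change
    id <- predictEffect(fx$fit, "ACGTATGACGT", "T")
    expect_identical(c(id$delta, id$z, id$p), c(0, 0, 1))
})

test_that("predictions are exactly strand symmetric", {
    fx <- simFixture()
    set.seed(113)
    contexts <- randomSeqs(300, 11)
    alts <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
    fwd <- predictEffect(fx$fit, contexts, alts)
    rev <- predictEffect(fx$fit, oracleRevComp(contexts),
                         chartr("ACGT", "TGCA", alts))
    expect_identical(fwd$delta, rev$delta)
    expect_identical(fwd$se, rev$se)
    expect_identical(fwd$z, rev$z)
    expect_identical(fwd$p, rev$p)
})

test_that("swapping alleles negates delta and z and preserves p", {
    fx <- simFixture()
    set.seed(114)
    contexts <- randomSeqs(100, 11)
    refs <- substr(contexts, 6, 6)
    alts <- vapply(refs, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    fwd <- predictEffect(fx$fit, contexts, alts)
    swapped <- contexts
    substr(swapped, 6, 6) <- alts
    bwd <- predictEffect(fx$fit, swapped, refs)
    expect_identical(bwd$delta, -fwd$delta)
    expect_identical(bwd$z, -fwd$z)
    expect_identical(bwd$p, fwd$p)
})

test_that("zero-sum contrasts make predictions shift invariant", {
    fx <- simFixture()
    shifted <- fx$fit
    shifted@beta <- fx$fit@beta + 5
    set.seed(115)
    contexts <- randomSeqs(100, 11)
    alts <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
    a <- predictEffect(fx$fit, contexts, alts)
    b <- predictEffect(shifted, contexts, alts)
    expect_equal(a$delta, b$delta, tolerance = 1e-9)
    expect_identical(a$se, b$se)
})

test_that("Benjamini-Hochberg q-values follow the step-up closed form", {
    rec <- data.frame(p = c(0.01, 0.02, 0.03))
    adj <- adjustPvalues(rec, "BH")
    expect_equal(adj$q, c(0.03, 0.03, 0.03), tolerance = 1e-12)
    expect_identical(adj$q, p.adjust(rec$p, "BH"))

    rec1 <- data.frame(p = rep(1, 5))
    expect_identical(adjustPvalues(rec1, "BH")$q, rep(1, 5))

    set.seed(116)
    recr <- data.frame(p = runif(200))
    q <- adjustPvalues(recr, "BH")$q
    ord <- order(recr$p)
    expect_false(is.unsorted(q[ord]))
    expect_true(all(q <= 1))
    expect_true(all(q >= recr$p))

    expect_identical(adjustPvalues(recr, "none"), recr)
    empty <- adjustPvalues(data.frame(p = numeric(0)), "BH")
    expect_identical(nrow(empty), 0L)
})
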