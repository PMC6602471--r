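test_that("noise-free outcomes are interpolated exactly", {
    d <- smallDesign(n = 200, seed = 11)
    set.seed(12)
    betaTrue <- rnorm(nFeatures(d$idx))
    y <- as.vector(d$X %*% betaTrue)
    fit <- fitOLS(d$X, y, d$idx)
    expect_lt(max(abs(coef(fit) - betaTrue)), 1e-8)
    expect_lt(sigma2(fit), 1e-16)
})

test_that("coefficients match an independent normal-equations solve", {
    d <- smallDesign(n = 200, seed = 31)
    set.seed(32)
    y <- rnorm(200, sd = 2)
    fit <- fitOLS(d$X, y, d$idx)
    orc <- oracleOLS(d$X, y)
    expect_lt(max(abs(coef(fit) - orc$beta) / pmax(abs(orc$beta), 1)), 1e-8)
    expect_equal(sigma2(fit), orc$sigma2, tolerance = 1e-10)
    expect_identical(df.residual(fit), orc$df)

    ## residual orthogonality: X'(y - X beta_hat) ~ 0
    resid <- y - as.vector(d$X %*% coef(fit))
    expect_lt(max(abs(as.vector(Matrix::crossprod(d$X, resid)))),
              1e-8 * max(abs(y)) * 200)
})

test_that("contrast tests match the explicit-covariance oracle", {
    d <- smallDesign(n = 200, seed = 41)
    set.seed(42)
    y <- rnorm(200)
    fit <- fitOLS(d$X, y, d$idx)
    orc <- oracleOLS(d$X, y)
    p <- nFeatures(d$idx)
    for (i in 1:25) {
        cvec <- numeric(p)
        nz <- sample(p, 4)
        cvec[nz] <- c(1, 1, -1, -1)
        got <- contrastTest(fit, cvec)
        want <- oracleContrastTest(orc, cvec)
        expect_equal(got$estimate, want$estimate, tolerance = 1e-8)
        expect_equal(got$se, want$se, tolerance = 1e-8)
        expect_equal(got$z, want$z, tolerance = 1e-8)
        expect_equal(got$p, want$p, tolerance = 1e-8)
    }

    ## null contrast convention and the normal quantile identity
    z0 <- contrastTest(fit, numeric(p))
    expect_identical(c(z0$estimate, z0$z, z0$p), c(0, 0, 1))
    anyc <- numeric(p); anyc[1:2] <- c(1, -1)
    ct <- contrastTest(fit, anyc)
    expect_equal(ct$p, 2 * pnorm(-abs(ct$z)), tolerance = 1e-15)
    expect_equal(2 * pnorm(-1.959964), 0.05, tolerance = 1e-6)

    expect_error(contrastTest(fit, numeric(p + 1)), "dimension")
})

test_that("under-determined or non-finite inputs are rejected", {
    d <- smallDesign(n = 8, seed = 51)
    expect_error(fitOLS(d$X, rnorm(8), d$idx), "under-determined")
    d2 <- smallDesign(n = 50, seed = 52)
    y <- rnorm(50); y[3] <- NA
    expect_error(fitOLS(d2$X, y, d2$idx), "finite")
})

test_that("normal and exact-t P-values agree at PBM-scale degrees of freedom", {
    ## n - p >= 10,000 justifies the normal approximation of the t statistic
    idx <- buildKmerIndex(2)
    set.seed(61)
    seqs <- randomSeqs(10050, 12)
    X <- featureMatrix(idx, seqs)
    y <- rnorm(10050)
    fit <- fitOLS(X, y, idx)
    expect_gte(df.residual(fit), 10000L)
    p <- nFeatures(idx)
    worst <- 0
    for (i in 1:50) {
        cvec <- numeric(p)
        cvec[sample(p, 4)] <- c(1, 1, -1, -1)
        ct <- contrastTest(fit, cvec)
        worst <- max(worst, abs(ct$p - ct$p.t))
    }
    expect_lt(worst, 1e-4)
})

test_that("rank-deficient designs use minimum-norm fits with estimability checks", {
    idx <- buildKmerIndex(2)
    set.seed(71)
    ## AC-only sequences never contain G/T-rich 2-mers: zero columns
    seqs <- vapply(1:60, function(i)
        paste(sample(c("A", "C"), 12, TRUE), collapse = ""), "")
    X <- featureMatrix(idx, seqs)
    y <- rnorm(60)
    expect_warning(fit <- fitOLS(X, y, idx), "rank deficient")
    zero <- which(Matrix::colSums(X) == 0)
    expect_gt(length(zero), 0)
    ## minimum-norm: unobserved features get coefficient 0
    expect_true(all(abs(coef(fit)[zero]) < 1e-10))
    ## a contrast touching an unobserved feature is not estimable
    bad <- numeric(nFeatures(idx))
    bad[zero[1]] <- 1; bad[zero[length(zero)]] <- -1
    expect_error(contrastTest(fit, bad), "not estimable")
})

test_that("P-values are calibrated under the model's own assumptions", {
    ## small-scale null simulation: true c' beta = 0 for every contrast
    idx <- buildKmerIndex(3)
    p <- nFeatures(idx)
    set.seed(81)
    seqs <- randomSeqs(2000, 15)
    X <- featureMatrix(idx, seqs)
    betaTrue <- rnorm(p, sd = 0.3)
    y <- as.vector(X %*% betaTrue) + rnorm(2000, sd = 0.5)
    fit <- fitOLS(X, y, idx)
    pvals <- vapply(1:400, function(i) {
        cvec <- numeric(p)
        nz <- sample(p, 4)
        cvec[nz] <- c(1, 1, -1, -1)
        ## adjust one entry so the contrast is exactly null under betaTrue
        delta <- sum(cvec * betaTrue)
        cvec[nz[1]] <- cvec[nz[1]] - delta / betaTrue[nz[1]]
        contrastTest(fit, cvec)$p
    }, 0)
    ks <- suppressWarnings(ks.test(pvals, "punif"))
    expect_lt(unname(ks$statistic), 0.1)
})
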