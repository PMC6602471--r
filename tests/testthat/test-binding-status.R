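test_that("the bound / unbound / ambiguous rule follows the worked cases", {
    site <- distinctWindowSite()

    expect_identical(status(classifySite(siteEScoreTable(site, rep(0.45, 10)),
                                         site)), "bound")
    expect_identical(status(classifySite(siteEScoreTable(site, rep(0.10, 10)),
                                         site)), "unbound")
    ## alternating high/low: no adjacent pair above 0.4, not all below 0.35
    alternating <- rep(c(0.45, 0.30), 5)
    expect_identical(status(classifySite(siteEScoreTable(site, alternating),
                                         site)), "ambiguous")
})

test_that("bound requires two consecutive overlapping 8-mers above threshold", {
    site <- distinctWindowSite()
    ## two high 8-mers far apart: not adjacent, so not bound
    sc <- rep(0.1, 10); sc[c(2, 7)] <- 0.45
    expect_identical(status(classifySite(siteEScoreTable(site, sc), site)),
                     "ambiguous")
    ## adjacent pair: bound
    sc2 <- rep(0.1, 10); sc2[c(4, 5)] <- 0.45
    expect_identical(status(classifySite(siteEScoreTable(site, sc2), site)),
                     "bound")
})

test_that("threshold comparisons are strict at the printed cutoffs", {
    site <- distinctWindowSite()
    ## all exactly 0.4: fails "> 0.4", fails "< 0.35" -> ambiguous
    expect_identical(status(classifySite(siteEScoreTable(site, rep(0.4, 10)),
                                         site)), "ambiguous")
    ## all exactly 0.35: blocks the unbound call
    expect_identical(status(classifySite(siteEScoreTable(site, rep(0.35, 10)),
                                         site)), "ambiguous")
    ## just below 0.35 everywhere: unbound
    expect_identical(status(classifySite(siteEScoreTable(site,
                                                         rep(0.3499, 10)),
                                         site)), "unbound")
    ## just above 0.4 on an adjacent pair: bound
    sc <- rep(0.1, 10); sc[c(1, 2)] <- 0.4001
    expect_identical(status(classifySite(siteEScoreTable(site, sc), site)),
                     "bound")
})

test_that("status calls are monotone in the thresholds", {
    set.seed(131)
    for (i in 1:30) {
        site <- distinctWindowSite(seed = 131 + i)
        es <- siteEScoreTable(site, runif(10, -0.4, 0.5))
        base <- classifySite(es, site)
        stricter <- classifySite(es, site, thetaBound = 0.45)
        if (status(stricter) == "bound")
            expect_identical(status(base), "bound")
        looser <- classifySite(es, site, thetaUnbound = 0.30)
        if (status(looser) == "unbound")
            expect_identical(status(base), "unbound")
    }
})

test_that("classification is strand symmetric and total", {
    set.seed(132)
    for (i in 1:20) {
        site <- distinctWindowSite(seed = 200 + i)
        es <- siteEScoreTable(site, runif(10, -0.4, 0.5))
        fwd <- classifySite(es, site)
        rev <- classifySite(es, oracleRevComp(site))
        expect_identical(status(fwd), status(rev))
        expect_true(status(fwd) %in% c("bound", "unbound", "ambiguous"))
    }
})

test_that("degenerate sites and mismatched calls error", {
    site <- distinctWindowSite()
    es <- siteEScoreTable(site, rep(0.1, 10))
    bad <- site
    substr(bad, 9, 9) <- "N"
    expect_error(classifySite(es, bad), "cannot classify")
    expect_error(classifySite(es, substr(site, 1, 16)), "17-bp")
    expect_error(classifySite(es, site, thetaBound = 0.3,
                              thetaUnbound = 0.35), "exceed")

    ## a partial table missing the site's 8-mers cannot classify
    tiny <- EScoreTable(c(AAAAAAAA = 0.2))
    expect_error(classifySite(tiny, site), "missing")
})

test_that("transitions combine the two calls into nine possible labels", {
    site <- distinctWindowSite()
    esB <- siteEScoreTable(site, rep(0.45, 10))
    esU <- siteEScoreTable(site, rep(0.10, 10))
    b <- classifySite(esB, site)
    u <- classifySite(esU, site)
    expect_identical(statusTransition(u, b), "unbound>bound")
    expect_identical(statusTransition(b, b), "bound>bound")
    expect_identical(statusTransition(b, u), "bound>unbound")
    ## identity variant: same site on both sides, so X>X
    expect_identical(statusTransition(u, u), "unbound>unbound")

    other <- classifySite(esB, site, thetaBound = 0.42)
    expect_error(statusTransition(b, other), "different thresholds")
})
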