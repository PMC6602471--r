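## Independent oracle helpers, deliberately implemented without touching
## the package's own k-mer / linear-algebra code paths.

## reverse complement via chartr + explicit reversal
oracleRevComp <- function(x) {
    vapply(x, function(s) {
        paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]),
              collapse = "")
    }, "", USE.NAMES = FALSE)
}

oracleCanonical <- function(x) {
    rc <- oracleRevComp(x)
    ifelse(x <= rc, x, rc)
}

## all k-mers by explicit recursion (independent of .codeToKmer)
oracleAllKmers <- function(k) {
    out <- ""
    for (i in seq_len(k))
        out <- as.vector(outer(out, c("A", "C", "G", "T"), paste0))
    sort(out)
}

## window counts by explicit enumeration
oracleWindowCounts <- function(sequence, k) {
    n <- nchar(sequence) - k + 1L
    table(oracleCanonical(substring(sequence, 1:n, k:(n + k - 1L))))
}

## brute-force per-feature count difference for a centered SNV
oracleContrast <- function(context, alt, k = 6L) {
    mut <- context
    substr(mut, k, k) <- alt
    wt <- oracleWindowCounts(context, k)
    mu <- oracleWindowCounts(mut, k)
    all <- union(names(wt), names(mu))
    d <- vapply(all, function(w) {
        as.integer(sum(mu[names(mu) == w])) -
            as.integer(sum(wt[names(wt) == w]))
    }, 0L)
    d[d != 0L]
}

## explicit normal-equations + covariance linear-hypothesis oracle
oracleOLS <- function(X, y) {
    X <- as.matrix(X)
    XtX <- t(X) %*% X
    beta <- solve(XtX, t(X) %*% y)
    resid <- y - X %*% beta
    sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
    list(beta = drop(beta), sigma2 = sigma2, inv = solve(XtX),
         df = nrow(X) - ncol(X))
}

oracleContrastTest <- function(orc, cvec) {
    est <- sum(cvec * orc$beta)
    se <- sqrt(orc$sigma2 * drop(t(cvec) %*% orc$inv %*% cvec))
    z <- est / se
    list(estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

randomSeqs <- function(n, width) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
              collapse = ""), "")
}
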