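## Internal helpers shared across modules.

DNA_BASES4 <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet reverseComplement
.revCompChar <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Base-4 integer code of k-mers (A=0, C=1, G=2, T=3), big-endian so that
## numeric order equals lexicographic order.  Returns NA for non-ACGT input.
.kmerCode <- function(x, k = nchar(x[1L])) {
    if (length(x) == 0L) return(integer(0))
    m <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)), DNA_BASES4) - 1L,
                nrow = k)
    pow <- 4^((k - 1L):0L)
    as.integer(colSums(m * pow))
}

.codeToKmer <- function(code, k) {
    if (length(code) == 0L) return(character(0))
    m <- matrix("", nrow = k, ncol = length(code))
    rem <- as.numeric(code)
    for (i in k:1L) {
        m[i, ] <- DNA_BASES4[rem %% 4 + 1]
        rem <- rem %/% 4
    }
    do.call(paste0, split(m, row(m)))
}

.isACGT <- function(x) {
    !is.na(x) & grepl("^[ACGT]+$", x)
}

## Run expr with a local RNG state seeded by `seed`; the caller's RNG
## state is untouched.
.withLocalSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Classed errors so the CLI can map failures to exit categories.
.dbStop <- function(msg, class, call. = FALSE) {
    stop(errorCondition(msg, class = c(class, "deltaBind_error", "error", "condition")))
}

## Round-trip a double through IEEE single precision (the storage type of
## prediction tables).
.asFloat32 <- function(x) {
    readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
            n = length(x), size = 4L)
}

## Random DNA of given widths, vectorised (one string per element of n).
.randomDNA <- function(n, width) {
    chars <- matrix(sample(DNA_BASES4, n * width, replace = TRUE), nrow = width)
    do.call(paste0, split(chars, row(chars)))
}
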