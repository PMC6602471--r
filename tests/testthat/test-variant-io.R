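writeVcf <- function(rows, path) {
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT",
                 vapply(rows, paste, "", collapse = "\t")), path)
    path
}

genomeBase <- function(gen, chrom, pos) {
    substr(as.character(gen[[chrom]]), pos, pos)
}

test_that("VCF SNVs get 17-bp contexts with full line accounting", {
    gen <- testGenome()
    ref100 <- genomeBase(gen, "chr1", 100)
    alt100 <- setdiff(c("A", "C", "G", "T"), ref100)[1]
    wrongRef <- setdiff(c("A", "C", "G", "T"), genomeBase(gen, "chr1", 150))[1]
    path <- withr::local_tempfile(fileext = ".vcf")
    writeVcf(list(c("chr1", 100, ".", ref100, alt100),
                  c("chr1", 4, ".", "A", "C"),
                  c("chr1", 150, ".", wrongRef, "A"),
                  c("chr1", 60, ".", genomeBase(gen, "chr1", 60), "AT"),
                  c("chrX", 50, ".", "A", "C")),
             path)
    recs <- parseVCF(path, gen)

    ok <- recs[recs$status == "ok", ]
    expect_identical(nrow(ok), 1L)
    expect_identical(ok$context17,
                     substr(as.character(gen[["chr1"]]), 92, 108))
    expect_identical(substr(ok$context17, 9, 9), ref100)

    skipped <- recs[recs$status == "skipped", ]
    expect_setequal(skipped$reason,
                    c("edge_of_contig", "ref_mismatch", "not_snv",
                      "missing_chromosome"))
    ## every data line accounted for
    expect_setequal(recs$line, 3:7)

    ## multi-allelic rows expand to one record per alternate allele
    path2 <- withr::local_tempfile(fileext = ".vcf")
    alts2 <- setdiff(c("A", "C", "G", "T"), ref100)
    writeVcf(list(c("chr1", 100, ".", ref100,
                    paste(c(alts2[1], alts2[2], "ATT"), collapse = ","))),
             path2)
    recs2 <- parseVCF(path2, gen)
    expect_identical(nrow(recs2), 3L)
    expect_identical(sum(recs2$status == "ok"), 2L)
    expect_identical(recs2$reason[recs2$status == "skipped"], "not_snv")

    ## headerless files are a format error
    bad <- withr::local_tempfile()
    writeLines("chr1\t100\t.\tA\tC", bad)
    expect_error(parseVCF(bad, gen), "header")
})

test_that("ICGC and tabular dialects parse to equivalent records", {
    gen <- testGenome()
    ref <- genomeBase(gen, "chr1", 120)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]

    vcf <- withr::local_tempfile(fileext = ".vcf")
    writeVcf(list(c("chr1", 120, ".", ref, alt)), vcf)

    icgc <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(paste("icgc_mutation_id", "chromosome", "chromosome_start",
                       "mutated_from_allele", "mutated_to_allele",
                       "assembly_version", sep = "\t"),
                 paste("MU1", "1", 120, ref, alt, "hg19", sep = "\t")),
               icgc)

    tab <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("chromosome,chromosome_pos,mutated_from,mutated_to",
                 sprintf("chr1,120,%s,%s", ref, alt)), tab)

    a <- parseVCF(vcf, gen)
    b <- parseICGC(icgc, gen)
    d <- parseTabular(tab, gen)
    core <- c("chrom", "pos", "ref", "alt", "context17", "status", "reason")
    expect_identical(a[, core], b[, core])
    expect_identical(a[, core], d[, core])
    ## "1" resolved against a "chr1" genome
    expect_identical(b$chrom, "chr1")

    ## ICGC insertion rows are skipped as not_snv
    icgc2 <- withr::local_tempfile()
    writeLines(c(paste("chromosome", "chromosome_start",
                       "mutated_from_allele", "mutated_to_allele", sep = "\t"),
                 paste("1", 120, "-", "A", sep = "\t")), icgc2)
    r2 <- parseICGC(icgc2, gen)
    expect_identical(r2$reason, "not_snv")

    ## assembly mismatch warns, missing columns error
    expect_warning(parseICGC(icgc, gen, assembly = "hg38"), "assembly")
    icgc3 <- withr::local_tempfile()
    writeLines("chromosome\tchromosome_start\tmutated_from_allele", icgc3)
    expect_error(parseICGC(icgc3, gen), "missing column")
    tab2 <- withr::local_tempfile()
    writeLines(c("chromosome,chromosome_pos,mutated_from", "chr1,5,A"), tab2)
    expect_error(parseTabular(tab2, gen), "missing column")

    ## identity rows are flagged, not dropped
    tab3 <- withr::local_tempfile()
    writeLines(c("chromosome,chromosome_pos,mutated_from,mutated_to",
                 sprintf("chr1,120,%s,%s", ref, ref)), tab3)
    expect_identical(parseTabular(tab3, gen)$status, "identity")
})

test_that("an indexed FASTA behaves like the in-memory genome", {
    gen <- testGenome()
    fa <- withr::local_tempfile(fileext = ".fa")
    Biostrings::writeXStringSet(gen, fa)
    ref <- genomeBase(gen, "chr2", 60)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    vcf <- withr::local_tempfile(fileext = ".vcf")
    writeVcf(list(c("chr2", 60, ".", ref, alt)), vcf)
    a <- parseVCF(vcf, gen)
    b <- parseVCF(vcf, fa)
    expect_identical(a$context17, b$context17)
    expect_identical(a$status, b$status)
})

test_that("17-bp sequence files parse without a genome", {
    path <- withr::local_tempfile()
    writeLines(c("ACGTACGTACGTACGTA C",
                 "ACGTACGTACGTACGT C",
                 "ACGTACGTNCGTACGTA C",
                 "ACGTACGTACGTACGTA A"), path)
    recs <- parseSeq17(path)
    expect_identical(recs$status, c("ok", "skipped", "skipped", "identity"))
    expect_identical(recs$reason[2:3], c("bad_length", "bad_alphabet"))
    expect_identical(recs$ref[1], "A")
    expect_identical(recs$alt[1], "C")
    expect_identical(recs$context17[1], "ACGTACGTACGTACGTA")
    ## line 4 alt equals the center base: identity, prediction will be 0
    expect_identical(recs$line, 1:4)
})

test_that("parseVariants dispatches and demands a genome when needed", {
    path <- withr::local_tempfile()
    writeLines("ACGTACGTACGTACGTA C", path)
    expect_identical(nrow(parseVariants(path, "seq")), 1L)
    expect_error(parseVariants(path, "vcf"), "reference genome")
})

test_that("reports filter rows and survive empty results", {
    recs <- data.frame(
        variantId = c("v1", "v2", "v3"), chrom = "chr1", pos = 1:3,
        ref = "A", alt = "C", tf = "TF1",
        delta = c(1.5, -0.2, 0.7), z = c(4, -0.5, 2),
        p = c(0.001, 0.2, 0.04),
        statusWild = c("unbound", "bound", "bound"),
        statusMut = c("bound", "bound", "unbound"),
        transition = c("unbound>bound", "bound>bound", "bound>unbound"),
        stringsAsFactors = FALSE)
    path <- withr::local_tempfile(fileext = ".tsv")

    writeReport(recs, path, pCutoff = 0.05)
    out <- read.delim(path, comment.char = "#")
    expect_identical(nrow(out), 2L)

    writeReport(recs, path, transitionFilter = "unbound>bound")
    out <- read.delim(path, comment.char = "#")
    expect_identical(out$variantId, "v1")

    writeReport(recs, path, pCutoff = 1e-9)
    out <- read.delim(path, comment.char = "#")
    expect_identical(nrow(out), 0L)
    expect_identical(colnames(out), colnames(recs))

    writeReport(recs, path, format = "csv",
                config = list(command = "predict", pCutoff = 0.5))
    lines <- readLines(path)
    expect_true(any(startsWith(lines, "# command=predict")))
    expect_identical(nrow(read.csv(path, comment.char = "#")), 3L)
})
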