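#' @include bindingStatus.R
NULL

.checkVariantFile <- function(path) {
    if (!file.exists(path))
        .dbStop(sprintf("variant file not found: %s", path), "db_io_error")
    invisible(path)
}

.emptyRecords <- function() {
    data.frame(id = character(0), line = integer(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               context17 = character(0), status = character(0),
               reason = character(0), stringsAsFactors = FALSE)
}

.mkRecord <- function(id, line, chrom = NA_character_, pos = NA_integer_,
                      ref = NA_character_, alt = NA_character_,
                      context17 = NA_character_, status, reason = NA_character_) {
    data.frame(id = id, line = line, chrom = chrom, pos = pos, ref = ref,
               alt = alt, context17 = context17, status = status,
               reason = reason, stringsAsFactors = FALSE)
}

## Open a reference genome: an indexed FASTA path, an Rsamtools::FaFile, or
## a named DNAStringSet (handy for tests and small genomes).
#' @importFrom Rsamtools FaFile indexFa scanFaIndex
.openGenome <- function(genome) {
    if (is.null(genome)) return(NULL)
    if (is.character(genome)) {
        if (!file.exists(genome))
            .dbStop(sprintf("reference FASTA not found: %s", genome),
                    "db_io_error")
        if (!file.exists(paste0(genome, ".fai")))
            Rsamtools::indexFa(genome)
        genome <- Rsamtools::FaFile(genome)
    }
    genome
}

.genomeSeqnames <- function(genome) {
    if (is(genome, "DNAStringSet")) names(genome)
    else as.character(GenomicRanges::seqnames(Rsamtools::scanFaIndex(genome)))
}

.genomeSeqlengths <- function(genome) {
    if (is(genome, "DNAStringSet"))
        stats::setNames(Biostrings::width(genome), names(genome))
    else {
        idx <- Rsamtools::scanFaIndex(genome)
        stats::setNames(GenomicRanges::width(idx),
                        as.character(GenomicRanges::seqnames(idx)))
    }
}

.normalizeChrom <- function(chrom, available) {
    out <- chrom
    hit <- out %in% available
    alt1 <- paste0("chr", chrom)
    out[!hit & alt1 %in% available] <- alt1[!hit & alt1 %in% available]
    hit <- out %in% available
    alt2 <- sub("^chr", "", chrom)
    out[!hit & alt2 %in% available] <- alt2[!hit & alt2 %in% available]
    out[!(out %in% available)] <- NA_character_
    out
}

#' @importFrom GenomicRanges GRanges seqnames width
#' @importFrom IRanges IRanges
.extractContexts <- function(genome, chrom, pos) {
    if (is(genome, "DNAStringSet")) {
        ctx <- as.character(Biostrings::subseq(genome[chrom], pos - 8L,
                                               pos + 8L))
    } else {
        gr <- GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(pos - 8L, pos + 8L))
        ctx <- as.character(Biostrings::getSeq(genome, gr))
    }
    toupper(ctx)
}

## Shared coordinate-based record builder: takes parallel vectors already
## classified as candidate SNVs and fills in 17-bp contexts, flagging edge,
## ambiguous-base, ref-mismatch and identity cases.
.buildCoordRecords <- function(ids, lines, chrom, pos, ref, alt, genome) {
    n <- length(ids)
    status <- rep("ok", n)
    reason <- rep(NA_character_, n)
    context <- rep(NA_character_, n)
    available <- .genomeSeqnames(genome)
    seqlen <- .genomeSeqlengths(genome)
    chromN <- .normalizeChrom(chrom, available)
    bad <- is.na(chromN)
    status[bad] <- "skipped"; reason[bad] <- "missing_chromosome"
    edge <- !bad & (pos < 9L | pos + 8L > seqlen[chromN])
    status[edge] <- "skipped"; reason[edge] <- "edge_of_contig"
    get <- status == "ok"
    if (any(get)) {
        ctx <- .extractContexts(genome, chromN[get], pos[get])
        hasN <- !.isACGT(ctx)
        gi <- which(get)
        status[gi[hasN]] <- "skipped"
        reason[gi[hasN]] <- "ambiguous_base"
        context[gi[!hasN]] <- ctx[!hasN]
        mism <- !hasN & substr(ctx, 9L, 9L) != ref[gi]
        status[gi[mism]] <- "skipped"
        reason[gi[mism]] <- "ref_mismatch"
        context[gi[mism]] <- NA_character_
    }
    ident <- status == "ok" & ref == alt
    status[ident] <- "identity"
    data.frame(id = ids, line = lines, chrom = chromN, pos = pos, ref = ref,
               alt = alt, context17 = context, status = status,
               reason = reason, stringsAsFactors = FALSE)
}

#' Parse a VCF variant file
#'
#' Reads VCF v4.x text and returns one record per biallelic SNV;
#' multi-allelic rows expand to one record per alternate allele.  Indels
#' and symbolic alleles are skipped with reason \code{"not_snv"}; records
#' whose REF disagrees with the genome are skipped with
#' \code{"ref_mismatch"}; positions too close to a contig edge for a 17-bp
#' window with \code{"edge_of_contig"}; windows containing N with
#' \code{"ambiguous_base"}.  Every data line of the input yields at least
#' one record, so lines are fully accounted for.
#'
#' @param path VCF file path (plain text).
#' @param genome reference genome: an indexed FASTA path, an
#'   \link[Rsamtools]{FaFile}, or a named \link[Biostrings]{DNAStringSet}.
#' @return A data.frame of variant records with columns \code{id},
#'   \code{line}, \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{context17}, \code{status} (\code{ok} / \code{identity} /
#'   \code{skipped}) and \code{reason}.
#' @export
parseVCF <- function(path, genome) {
    .checkVariantFile(path)
    genome <- .openGenome(genome)
    lines <- readLines(path)
    body <- !startsWith(lines, "##")
    headerLine <- which(body & startsWith(lines, "#CHROM"))
    if (length(headerLine) != 1L)
        .dbStop("VCF header line (#CHROM ...) not found", "db_format_error")
    dataIdx <- which(body & !startsWith(lines, "#"))
    dataIdx <- dataIdx[nzchar(trimws(lines[dataIdx]))]
    recs <- list()
    coord <- list()
    for (i in dataIdx) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        id <- sprintf("%s:%d", basename(path), i)
        if (length(f) < 5L) {
            recs[[length(recs) + 1L]] <-
                .mkRecord(id, i, status = "skipped", reason = "malformed_line")
            next
        }
        ref <- toupper(f[4L])
        altAll <- toupper(strsplit(f[5L], ",", fixed = TRUE)[[1L]])
        pos <- suppressWarnings(as.integer(f[2L]))
        if (is.na(pos)) {
            recs[[length(recs) + 1L]] <-
                .mkRecord(id, i, status = "skipped", reason = "malformed_line")
            next
        }
        for (alt in altAll) {
            if (nchar(ref) != 1L || nchar(alt) != 1L ||
                !.isACGT(ref) || !alt %in% c(DNA_BASES4, ref)) {
                recs[[length(recs) + 1L]] <-
                    .mkRecord(id, i, chrom = f[1L], pos = pos, ref = ref,
                              alt = alt, status = "skipped",
                              reason = "not_snv")
            } else {
                coord[[length(coord) + 1L]] <-
                    list(id = id, line = i, chrom = f[1L], pos = pos,
                         ref = ref, alt = alt)
            }
        }
    }
    .assembleRecords(recs, coord, genome)
}

.assembleRecords <- function(recs, coord, genome) {
    parts <- list()
    if (length(coord)) {
        parts[[1L]] <- .buildCoordRecords(
            vapply(coord, `[[`, "", "id"),
            vapply(coord, `[[`, 1L, "line"),
            vapply(coord, `[[`, "", "chrom"),
            vapply(coord, `[[`, 1L, "pos"),
            vapply(coord, `[[`, "", "ref"),
            vapply(coord, `[[`, "", "alt"), genome)
    }
    out <- do.call(rbind, c(parts, recs))
    if (is.null(out)) out <- .emptyRecords()
    out[order(out$line, out$alt), , drop = FALSE]
}

#' Parse an ICGC simple somatic mutation file
#'
#' Tab-separated with a header containing \code{chromosome},
#' \code{chromosome_start}, \code{mutated_from_allele} and
#' \code{mutated_to_allele}.  Only single-base substitutions become
#' records; insertions/deletions (alleles like \code{"-"} or multi-base)
#' are skipped with reason \code{"not_snv"}.  An \code{assembly_version}
#' column, when present, is checked against \code{assembly} with a warning
#' on mismatch.
#'
#' @param path ICGC TSV path.
#' @param genome reference genome (see \code{\link{parseVCF}}).
#' @param assembly optional genome label (e.g. \code{"hg19"},
#'   \code{"GRCh37"}) to check against the file's assembly column.
#' @return A variant record data.frame (see \code{\link{parseVCF}}).
#' @export
parseICGC <- function(path, genome, assembly = NULL) {
    .checkVariantFile(path)
    genome <- .openGenome(genome)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "",
                             check.names = FALSE, quote = "")
    need <- c("chromosome", "chromosome_start", "mutated_from_allele",
              "mutated_to_allele")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        .dbStop(sprintf("ICGC file missing column(s): %s",
                        paste(miss, collapse = ", ")), "db_format_error")
    if (!is.null(assembly) && "assembly_version" %in% colnames(tab)) {
        seen <- unique(as.character(tab$assembly_version))
        if (!any(tolower(seen) == tolower(assembly)))
            warning(sprintf("assembly_version in file (%s) does not match declared genome label (%s)",
                            paste(seen, collapse = ","), assembly))
    }
    .parseCoordTable(tab, path,
                     chrom = "chromosome", pos = "chromosome_start",
                     from = "mutated_from_allele", to = "mutated_to_allele",
                     genome = genome)
}

#' Parse a generic tabular variant file
#'
#' Tab- or comma-separated (auto-detected) with header columns
#' \code{chromosome}, \code{chromosome_pos}, \code{mutated_from},
#' \code{mutated_to}.
#'
#' @inheritParams parseICGC
#' @return A variant record data.frame (see \code{\link{parseVCF}}).
#' @export
parseTabular <- function(path, genome) {
    .checkVariantFile(path)
    genome <- .openGenome(genome)
    sep <- .sniffSep(path)
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, comment.char = "",
                             check.names = FALSE, quote = "")
    need <- c("chromosome", "chromosome_pos", "mutated_from", "mutated_to")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        .dbStop(sprintf("tabular file missing column(s): %s",
                        paste(miss, collapse = ", ")), "db_format_error")
    .parseCoordTable(tab, path, chrom = "chromosome",
                     pos = "chromosome_pos", from = "mutated_from",
                     to = "mutated_to", genome = genome)
}

.parseCoordTable <- function(tab, path, chrom, pos, from, to, genome) {
    n <- nrow(tab)
    if (n == 0L) return(.emptyRecords())
    lineNo <- seq_len(n) + 1L   # header is line 1
    ids <- sprintf("%s:%d", basename(path), lineNo)
    ref <- toupper(as.character(tab[[from]]))
    alt <- toupper(as.character(tab[[to]]))
    posv <- suppressWarnings(as.integer(tab[[pos]]))
    snv <- nchar(ref) == 1L & nchar(alt) == 1L & .isACGT(ref) &
        .isACGT(alt) & !is.na(posv)
    recs <- list()
    if (any(!snv)) {
        w <- which(!snv)
        recs <- lapply(w, function(i)
            .mkRecord(ids[i], lineNo[i], chrom = as.character(tab[[chrom]])[i],
                      pos = posv[i], ref = ref[i], alt = alt[i],
                      status = "skipped", reason = "not_snv"))
    }
    coordDf <- if (any(snv))
        .buildCoordRecords(ids[snv], lineNo[snv],
                           as.character(tab[[chrom]])[snv], posv[snv],
                           ref[snv], alt[snv], genome)
    else NULL
    out <- do.call(rbind, c(list(coordDf), recs))
    if (is.null(out)) out <- .emptyRecords()
    out[order(out$line), , drop = FALSE]
}

#' Parse a 17-bp sequence variant file
#'
#' One record per line: a 17-bp ACGT sequence with the variant at the
#' center (position 9), a space, and the alternate base.  No reference
#' genome is needed.  Lines with a wrong-length sequence are skipped with
#' reason \code{"bad_length"}; non-ACGT characters with
#' \code{"bad_alphabet"}.  Records whose alternate base equals the center
#' base are flagged \code{identity} (their predicted change is 0).
#'
#' @param path text file path.
#' @return A variant record data.frame (see \code{\link{parseVCF}});
#'   \code{chrom} and \code{pos} are NA.
#' @export
parseSeq17 <- function(path) {
    .checkVariantFile(path)
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    recs <- lapply(which(keep), function(i) {
        id <- sprintf("%s:%d", basename(path), i)
        f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
        if (length(f) != 2L)
            return(.mkRecord(id, i, status = "skipped",
                             reason = "malformed_line"))
        seq17 <- toupper(f[1L]); alt <- toupper(f[2L])
        if (nchar(seq17) != 17L || nchar(alt) != 1L)
            return(.mkRecord(id, i, status = "skipped",
                             reason = "bad_length"))
        if (!.isACGT(seq17) || !alt %in% DNA_BASES4)
            return(.mkRecord(id, i, status = "skipped",
                             reason = "bad_alphabet"))
        ref <- substr(seq17, 9L, 9L)
        .mkRecord(id, i, ref = ref, alt = alt, context17 = seq17,
                  status = if (ref == alt) "identity" else "ok")
    })
    out <- do.call(rbind, recs)
    if (is.null(out)) out <- .emptyRecords()
    out
}

#' Parse variants in any supported dialect
#'
#' Dispatches to \code{\link{parseVCF}}, \code{\link{parseICGC}},
#' \code{\link{parseTabular}} or \code{\link{parseSeq17}}.
#'
#' @param path variant file path.
#' @param format one of \code{"vcf"}, \code{"icgc"}, \code{"tab"},
#'   \code{"seq"}.
#' @param genome reference genome (required for coordinate dialects).
#' @param assembly optional genome label for ICGC checking.
#' @return A variant record data.frame.
#' @export
parseVariants <- function(path, format = c("vcf", "icgc", "tab", "seq"),
                          genome = NULL, assembly = NULL) {
    format <- match.arg(format)
    if (format != "seq" && is.null(genome))
        .dbStop(sprintf("a reference genome is required for the %s format",
                        format), "db_input_error")
    switch(format,
           vcf = parseVCF(path, genome),
           icgc = parseICGC(path, genome, assembly = assembly),
           tab = parseTabular(path, genome),
           seq = parseSeq17(path))
}
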