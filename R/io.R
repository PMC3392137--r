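## Readers and writers for the formats the pipeline touches: target BED,
## the quality-binned pileup dialect, junction-allele FASTA, VCF output.
## Coordinate conventions are centralized here: BED is 0-based half-open,
## pileup and VCF are 1-based.

#' @importFrom GenomicRanges GRanges sort mcols
#' @importFrom IRanges IRanges
#' @importFrom Biostrings readDNAStringSet DNAStringSet
NULL

#' Read capture-target regions from BED
#'
#' Parses a 4- or 5-column BED file: chrom, start (0-based), end
#' (exclusive), gene symbol, and an optional GC fraction in [0,1]
#' (defaulting to 0.5 when absent). Regions are returned sorted by
#' (chrom, start) as a \code{GRanges} with metadata columns
#' \code{gene_symbol} and \code{gc_fraction}.
#'
#' @param file path to a BED file, or a character vector of BED lines.
#' @return a sorted \code{GRanges}.
#' @export
readTargets <- function(file) {
    lines <- if (length(file) == 1L && file.exists(file))
        readLines(file, warn = FALSE) else as.character(file)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
    if (!length(lines))
        return(GRanges(gene_symbol = character(), gc_fraction = numeric()))
    fields <- strsplit(lines, "[ \t]+")
    n <- vapply(fields, length, integer(1L))
    if (any(n < 4L))
        stop("BED row ", which(n < 4L)[1L], " has fewer than 4 columns")
    s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 2L)))
    e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 3L)))
    if (anyNA(s) || anyNA(e))
        stop("non-numeric coordinates at BED row ", which(is.na(s) | is.na(e))[1L])
    if (any(s >= e))
        stop("start >= end at BED row ", which(s >= e)[1L])
    gc <- rep(0.5, length(lines))
    has5 <- n >= 5L
    gc[has5] <- suppressWarnings(as.numeric(
        vapply(fields[has5], `[[`, character(1L), 5L)))
    if (anyNA(gc) || any(gc < 0 | gc > 1))
        stop("gc_fraction must be numeric in [0,1]")
    chrom <- vapply(fields, `[[`, character(1L), 1L)
    o <- order(chrom, s)
    GRanges(factor(chrom[o], levels = unique(chrom[o])),
            IRanges(start = s[o] + 1L, end = e[o]),
            gene_symbol = vapply(fields, `[[`, character(1L), 4L)[o],
            gc_fraction = gc[o])
}

#' Write target regions to BED
#'
#' Inverse of [readTargets()]: emits 5-column BED (0-based half-open)
#' with the GC fraction in column 5.
#'
#' @param targets a \code{GRanges} with \code{gene_symbol} and
#'   \code{gc_fraction} metadata columns.
#' @param file output path, or \code{NULL} to only return the lines.
#' @return invisibly, the BED lines.
#' @export
writeTargets <- function(targets, file = NULL) {
    lines <- paste(as.character(GenomicRanges::seqnames(targets)),
                   GenomicRanges::start(targets) - 1L,
                   GenomicRanges::end(targets),
                   mcols(targets)$gene_symbol,
                   mcols(targets)$gc_fraction, sep = "\t")
    if (!is.null(file)) writeLines(lines, file)
    invisible(lines)
}

.parse_allele_counts <- function(txt, line_no) {
    parts <- strsplit(txt, ",", fixed = TRUE)[[1L]]
    trip <- strsplit(parts, ":", fixed = TRUE)
    if (any(vapply(trip, length, integer(1L)) != 3L))
        stop("malformed allele counts at pileup row ", line_no)
    al <- vapply(trip, `[[`, character(1L), 1L)
    hq <- as.integer(vapply(trip, `[[`, character(1L), 2L))
    all_ <- as.integer(vapply(trip, `[[`, character(1L), 3L))
    if (anyNA(hq) || anyNA(all_))
        stop("non-numeric allele count at pileup row ", line_no)
    if (any(hq > all_))
        stop("hq count exceeds total count at pileup row ", line_no)
    if (anyDuplicated(al))
        stop("duplicate allele at pileup row ", line_no)
    list(hq = setNames(hq, al), all = setNames(all_, al))
}

#' Read quality-binned pileup observations
#'
#' Parses the pileup dialect used throughout the pipeline: a header line
#' \code{#chrom pos ref depth allele:hq:all[,allele:hq:all...]} followed
#' by one whitespace-delimited row per site. \code{hq} counts reads with
#' base quality exceeding the caller's quality cutoff, \code{all} counts
#' all reads; alleles are substitution bases or indel tokens of the form
#' \code{+SEQ} (insertion after pos) and \code{-SEQ} (deletion of SEQ
#' starting at pos+1). Per-allele totals must sum to the site depth and
#' every hq count must not exceed its total count.
#'
#' @param file path to a pileup file, or a character vector of lines.
#' @return a \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{depth} and list-columns \code{counts_hq},
#'   \code{counts_all} (named integer vectors per site).
#' @export
readPileup <- function(file) {
    lines <- if (length(file) == 1L && file.exists(file))
        readLines(file, warn = FALSE) else as.character(file)
    lines <- lines[nzchar(trimws(lines))]
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) return(.empty_pileup())
    fields <- strsplit(lines, "[ \t]+")
    n <- vapply(fields, length, integer(1L))
    if (any(n != 5L))
        stop("pileup row ", which(n != 5L)[1L], " must have 5 fields")
    pos <- as.integer(vapply(fields, `[[`, character(1L), 2L))
    if (anyNA(pos) || any(pos <= 0L))
        stop("pileup position must be a positive integer (row ",
             which(is.na(pos) | pos <= 0L)[1L], ")")
    depth <- as.integer(vapply(fields, `[[`, character(1L), 4L))
    if (anyNA(depth) || any(depth < 0L))
        stop("pileup depth must be a nonnegative integer")
    counts <- lapply(seq_along(fields), function(i)
        .parse_allele_counts(fields[[i]][5L], i))
    all_sum <- vapply(counts, function(x) sum(x$all), numeric(1L))
    if (any(all_sum != depth))
        stop("allele totals must sum to depth at pileup row ",
             which(all_sum != depth)[1L])
    data.frame(
        chrom = vapply(fields, `[[`, character(1L), 1L),
        pos = pos,
        ref = vapply(fields, `[[`, character(1L), 3L),
        depth = depth,
        counts_hq = I(lapply(counts, `[[`, "hq")),
        counts_all = I(lapply(counts, `[[`, "all")),
        stringsAsFactors = FALSE)
}

.empty_pileup <- function() {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               depth = integer(), counts_hq = I(list()),
               counts_all = I(list()), stringsAsFactors = FALSE)
}

#' Write pileup observations
#'
#' Inverse of [readPileup()]; write-then-read round trips to identical
#' observations.
#'
#' @param pileup a pileup \code{data.frame} as returned by
#'   [readPileup()] or [simulatePileup()].
#' @param file output path, or \code{NULL} to only return the lines.
#' @return invisibly, the text lines.
#' @export
writePileup <- function(pileup, file = NULL) {
    body <- vapply(seq_len(nrow(pileup)), function(i) {
        hq <- pileup$counts_hq[[i]]
        all_ <- pileup$counts_all[[i]]
        paste(pileup$chrom[i], pileup$pos[i], pileup$ref[i], pileup$depth[i],
              paste(names(all_), hq[names(all_)], all_, sep = ":",
                    collapse = ","))
    }, character(1L))
    lines <- c("#chrom pos ref depth allele:hq:all[,allele:hq:all...]", body)
    if (!is.null(file)) writeLines(lines, file)
    invisible(lines)
}

#' Read deletion junction alleles from FASTA
#'
#' Each record describes one gross-deletion allele: the record id is the
#' allele id and the sequence spans the deletion breakpoint. The central
#' window of 2 x \code{flank} bases (the breakpoint midpoint at its
#' centre) is extracted as the junction sequence. A record may carry a
#' \code{region=chrom:start-end} token in its description giving the
#' deleted interval (1-based, inclusive).
#'
#' @param file FASTA path.
#' @param flank bases retained on each side of the breakpoint midpoint.
#' @return \code{data.frame} with columns \code{allele_id},
#'   \code{junction} (character sequence of length 2*flank),
#'   \code{flank}, and \code{chrom}, \code{start}, \code{end} of the
#'   deleted region (\code{NA} when not annotated).
#' @export
readJunctionFasta <- function(file, flank) {
    stopifnot(flank >= 1L)
    seqs <- readDNAStringSet(file)
    if (!length(seqs))
        return(data.frame(allele_id = character(), junction = character(),
                          flank = integer(), chrom = character(),
                          start = integer(), end = integer(),
                          stringsAsFactors = FALSE))
    chars <- as.character(seqs)
    if (any(grepl("[^ACGT]", chars)))
        stop("junction record ", which(grepl("[^ACGT]", chars))[1L],
             " contains non-ACGT characters")
    len <- nchar(chars)
    if (any(len < 2L * flank))
        stop("junction record '", names(seqs)[len < 2L * flank][1L],
             "' is shorter than 2*flank = ", 2L * flank)
    off <- (len - 2L * flank) %/% 2L
    junction <- substr(chars, off + 1L, off + 2L * flank)
    hdr <- names(seqs)
    id <- sub("[ \t].*$", "", hdr)
    region <- rep(NA_character_, length(hdr))
    has <- grepl("region=([^ \t]+)", hdr)
    region[has] <- sub(".*region=([^ \t]+).*", "\\1", hdr[has])
    m <- regmatches(region, regexec("^(.+):([0-9]+)-([0-9]+)$", region))
    chrom <- vapply(m, function(x) if (length(x)) x[2L] else NA_character_,
                    character(1L))
    start <- vapply(m, function(x) if (length(x)) as.integer(x[3L]) else
        NA_integer_, integer(1L))
    end <- vapply(m, function(x) if (length(x)) as.integer(x[4L]) else
        NA_integer_, integer(1L))
    data.frame(allele_id = id, junction = junction, flank = as.integer(flank),
               chrom = chrom, start = start, end = end,
               stringsAsFactors = FALSE)
}

.vcf_indel_rep <- function(pos, ref, alt) {
    ## convert "+SEQ"/"-SEQ" tokens to anchored REF/ALT
    if (startsWith(alt, "+"))
        list(pos = pos, ref = ref, alt = paste0(ref, substring(alt, 2L)))
    else if (startsWith(alt, "-"))
        list(pos = pos, ref = paste0(ref, substring(alt, 2L)), alt = ref)
    else list(pos = pos, ref = ref, alt = alt)
}

#' Write calls as VCF v4.2
#'
#' Emits small-variant calls (and optionally gross-deletion calls as
#' symbolic \code{<DEL>} records with an \code{END} key) as VCF v4.2
#' with FORMAT \code{GT:DP:AD:AF}. Calls are sorted by (chrom, pos)
#' before writing. Indel alleles given as \code{+SEQ}/\code{-SEQ}
#' tokens are converted to anchored REF/ALT representation.
#'
#' @param calls \code{data.frame} of variant calls with columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{zygosity}
#'   (\code{het}/\code{hom}), \code{depth}, \code{hq_alt_reads},
#'   \code{filter_label}.
#' @param sampleId sample name for the VCF column header.
#' @param file output path, or \code{NULL} to only return the lines.
#' @param deletions optional \code{data.frame} of deletion calls with
#'   columns \code{chrom}, \code{start}, \code{end}, \code{zygosity},
#'   \code{junction_read_count}, \code{evidence}.
#' @return invisibly, the VCF lines.
#' @export
writeVcf <- function(calls, sampleId, file = NULL, deletions = NULL) {
    header <- c(
        "##fileformat=VCFv4.2",
        "##source=recesscan",
        "##FILTER=<ID=LowCov,Description=\"Site below minimum fold coverage\">",
        "##FILTER=<ID=LowSupport,Description=\"Fewer quality-passing alternate reads than required\">",
        "##FILTER=<ID=SubthresholdFraction,Description=\"Alternate allele fraction below the heterozygous band\">",
        "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of a symbolic deletion\">",
        "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
        "##INFO=<ID=EVIDENCE,Number=1,Type=String,Description=\"Deletion evidence channel: junction, coverage or both\">",
        "##ALT=<ID=DEL,Description=\"Gross deletion\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Reference and alternate read depths\">",
        "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction of reported depths\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", sampleId, sep = "\t"))
    rows <- character()
    keys <- list(chrom = character(), pos = integer())
    if (!is.null(calls) && nrow(calls)) {
        for (i in seq_len(nrow(calls))) {
            rep <- .vcf_indel_rep(calls$pos[i], calls$ref[i], calls$alt[i])
            gt <- if (identical(calls$zygosity[i], "hom")) "1/1" else "0/1"
            dp <- calls$depth[i]
            ad_alt <- calls$hq_alt_reads[i]
            ad_ref <- dp - ad_alt
            af <- sprintf("%.3f", ad_alt / dp)
            rows <- c(rows, paste(calls$chrom[i], rep$pos, ".", rep$ref,
                rep$alt, ".", calls$filter_label[i], ".",
                "GT:DP:AD:AF",
                paste(gt, dp, paste(ad_ref, ad_alt, sep = ","), af, sep = ":"),
                sep = "\t"))
            keys$chrom <- c(keys$chrom, calls$chrom[i])
            keys$pos <- c(keys$pos, as.integer(rep$pos))
        }
    }
    if (!is.null(deletions) && nrow(deletions)) {
        for (i in seq_len(nrow(deletions))) {
            gt <- if (identical(deletions$zygosity[i], "hom")) "1/1" else "0/1"
            info <- sprintf("END=%d;SVTYPE=DEL;EVIDENCE=%s",
                            as.integer(deletions$end[i]),
                            deletions$evidence[i])
            jr <- deletions$junction_read_count[i]
            samp <- paste(gt, if (is.na(jr)) "." else jr, ".", ".", sep = ":")
            rows <- c(rows, paste(deletions$chrom[i], deletions$start[i], ".",
                "N", "<DEL>", ".", "PASS", info, "GT:DP:AD:AF", samp,
                sep = "\t"))
            keys$chrom <- c(keys$chrom, deletions$chrom[i])
            keys$pos <- c(keys$pos, as.integer(deletions$start[i]))
        }
    }
    if (length(rows)) rows <- rows[order(keys$chrom, keys$pos)]
    lines <- c(header, rows)
    if (!is.null(file)) writeLines(lines, file)
    invisible(lines)
}
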