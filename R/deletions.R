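## Gross-deletion detection: exact read matches to breakpoint-junction
## reference sequences, plus per-target decreases in normalized coverage
## relative to an unaffected baseline.

#' @importFrom Biostrings DNAString DNAStringSet vcountPattern
NULL

#' Construct coverage-ratio bands
#'
#' @param homMaxRatio upper edge of the homozygous-deletion band
#'   (default 0.10).
#' @param hetLowRatio,hetHighRatio heterozygous-deletion band (defaults
#'   0.35 and 0.65).
#' @return a [CoverageBands-class].
#' @export
coverageBands <- function(homMaxRatio = 0.10, hetLowRatio = 0.35,
                          hetHighRatio = 0.65) {
    new("CoverageBands", homMaxRatio = homMaxRatio,
        hetLowRatio = hetLowRatio, hetHighRatio = hetHighRatio)
}

#' Count reads perfectly matching deletion junctions
#'
#' A read supports a junction allele when it contains, as an exact
#' substring, a window of the junction sequence covering at least
#' \code{minSpan} bases on each side of the breakpoint midpoint; this is
#' equivalent to containing the central 2 x \code{minSpan} window
#' exactly (perfect match, no mismatches). An allele is present when at
#' least \code{minSupport} reads support it.
#'
#' @param reads character vector or \code{DNAStringSet} of read
#'   sequences (uppercase ACGTN).
#' @param alleles junction-allele \code{data.frame} from
#'   [readJunctionFasta()].
#' @param minSpan required bases on each side of the breakpoint
#'   midpoint (default 10); must not exceed any allele's flank.
#' @param minSupport reads required for presence (default 8, the
#'   clinical alternate-read support threshold).
#' @return \code{data.frame} with \code{allele_id},
#'   \code{junction_read_count}, \code{present}.
#' @export
matchJunctionReads <- function(reads, alleles, minSpan = 10L,
                               minSupport = 8L) {
    stopifnot(minSpan >= 1L)
    if (any(alleles$flank < minSpan))
        stop("minSpan (", minSpan, ") exceeds the flank of allele(s): ",
             paste(alleles$allele_id[alleles$flank < minSpan],
                   collapse = ", "))
    reads <- DNAStringSet(toupper(as.character(reads)))
    counts <- integer(nrow(alleles))
    for (i in seq_len(nrow(alleles))) {
        f <- alleles$flank[i]
        window <- substr(alleles$junction[i], f - minSpan + 1L, f + minSpan)
        counts[i] <- sum(vcountPattern(DNAString(window), reads,
                                       fixed = TRUE) > 0)
    }
    data.frame(allele_id = alleles$allele_id,
               junction_read_count = counts,
               present = counts >= minSupport,
               stringsAsFactors = FALSE)
}

#' Normalize a coverage track to total sequence generated
#'
#' Rescales per-position depths by \code{referenceTotal /
#' totalAlignedBases} so coverage is comparable across samples with
#' different sequence yield. Exactly linear: scaling both the track and
#' the total by the same factor leaves the result unchanged.
#'
#' @param track coverage \code{data.frame} (\code{chrom}, \code{pos},
#'   \code{depth}).
#' @param totalAlignedBases the sample's total aligned bases (> 0).
#' @param referenceTotal the reference yield to normalize to (> 0).
#' @return the track with rescaled \code{depth}.
#' @export
normalizeCoverage <- function(track, totalAlignedBases, referenceTotal) {
    if (!isTRUE(totalAlignedBases > 0) || !isTRUE(referenceTotal > 0))
        stop("totals must be positive")
    track$depth <- track$depth * (referenceTotal / totalAlignedBases)
    track
}

.target_mean_depth <- function(track, chrom, s, e) {
    inside <- track$chrom == chrom & track$pos >= s & track$pos <= e
    ## positions absent from the track are uncovered
    sum(track$depth[inside]) / (e - s + 1)
}

#' Detect deletions from normalized coverage ratios
#'
#' For each capture target, the ratio of the sample's mean normalized
#' coverage to the baseline's is banded: at or below
#' \code{homMaxRatio} a homozygous deletion, within
#' \code{[hetLowRatio, hetHighRatio]} a heterozygous deletion, anything
#' else no call. Targets whose baseline mean is zero are skipped with a
#' warning.
#'
#' @param normTrack the sample's normalized coverage track.
#' @param baselineTrack normalized coverage of unaffected reference
#'   sample(s).
#' @param targets \code{GRanges} of capture targets.
#' @param bands a [CoverageBands-class].
#' @return \code{data.frame} with one row per target:
#'   \code{chrom}, \code{start}, \code{end}, \code{gene_symbol},
#'   \code{mean_coverage_ratio}, \code{zygosity} (\code{hom},
#'   \code{het}, or \code{none}).
#' @export
detectCoverageDeletions <- function(normTrack, baselineTrack, targets,
                                    bands = coverageBands()) {
    stopifnot(is(bands, "CoverageBands"))
    n <- length(targets)
    chrom <- as.character(GenomicRanges::seqnames(targets))
    s <- GenomicRanges::start(targets)
    e <- GenomicRanges::end(targets)
    ratio <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        base <- .target_mean_depth(baselineTrack, chrom[i], s[i], e[i])
        if (base == 0) {
            warning("baseline mean is zero over target ", chrom[i], ":",
                    s[i], "-", e[i], "; target skipped")
            next
        }
        ratio[i] <- .target_mean_depth(normTrack, chrom[i], s[i], e[i]) / base
    }
    zyg <- rep("none", n)
    zyg[!is.na(ratio) & ratio <= bands@homMaxRatio] <- "hom"
    zyg[!is.na(ratio) & ratio >= bands@hetLowRatio &
        ratio <= bands@hetHighRatio] <- "het"
    zyg[is.na(ratio)] <- NA_character_
    data.frame(chrom = chrom, start = s, end = e,
               gene_symbol = GenomicRanges::mcols(targets)$gene_symbol,
               mean_coverage_ratio = ratio, zygosity = zyg,
               stringsAsFactors = FALSE)
}

#' Combine junction and coverage evidence into deletion calls
#'
#' Junction and coverage channels are joined per allele (through the
#' allele's annotated deleted region overlapping a target). The combined
#' genotype follows the coverage band when the junction is present
#' (evidence \code{both}); a present junction without a banded ratio is
#' the minimum claim, a heterozygous deletion (evidence
#' \code{junction}); a banded ratio without junction presence is called
#' from coverage alone (evidence \code{coverage}), flagged as a
#' conflict when the coverage band is homozygous but the tested
#' junction was absent.
#'
#' @param junctionResults \code{data.frame} from [matchJunctionReads()];
#'   may carry \code{chrom}, \code{start}, \code{end} columns (as from
#'   [readJunctionFasta()]) linking alleles to regions.
#' @param coverageResults \code{data.frame} from
#'   [detectCoverageDeletions()].
#' @param alleles optional junction-allele table supplying the
#'   deleted-region annotation when \code{junctionResults} lacks it.
#' @return \code{data.frame} of deletion calls: \code{allele_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{zygosity},
#'   \code{junction_read_count}, \code{mean_coverage_ratio},
#'   \code{evidence}, \code{conflict}.
#' @export
combineEvidence <- function(junctionResults, coverageResults,
                            alleles = NULL) {
    jr <- junctionResults
    if (!is.null(alleles) && !"chrom" %in% names(jr))
        jr <- merge(jr, alleles[, c("allele_id", "chrom", "start", "end")],
                    by = "allele_id", sort = FALSE)
    cov <- coverageResults[!is.na(coverageResults$zygosity) &
                           coverageResults$zygosity != "none", , drop = FALSE]
    out <- list()
    used_cov <- logical(nrow(cov))
    for (i in seq_len(nrow(jr))) {
        hit <- which(!is.na(jr$chrom[i]) & cov$chrom == jr$chrom[i] &
                     cov$start <= jr$end[i] & cov$end >= jr$start[i])
        ratio <- if (length(hit)) cov$mean_coverage_ratio[hit[1L]] else NA_real_
        band <- if (length(hit)) cov$zygosity[hit[1L]] else "none"
        if (length(hit)) used_cov[hit[1L]] <- TRUE
        if (jr$present[i]) {
            zyg <- if (band %in% c("het", "hom")) band else "het"
            evid <- if (band %in% c("het", "hom")) "both" else "junction"
            conflict <- FALSE
        } else if (band %in% c("het", "hom")) {
            zyg <- band
            evid <- "coverage"
            conflict <- band == "hom"   # hom dropout yet junction unseen
        } else next
        out[[length(out) + 1L]] <- data.frame(
            allele_id = jr$allele_id[i], chrom = jr$chrom[i],
            start = jr$start[i], end = jr$end[i], zygosity = zyg,
            junction_read_count = jr$junction_read_count[i],
            mean_coverage_ratio = ratio, evidence = evid,
            conflict = conflict, stringsAsFactors = FALSE)
    }
    ## coverage-banded targets with no junction allele at all
    for (k in which(!used_cov)) {
        out[[length(out) + 1L]] <- data.frame(
            allele_id = NA_character_, chrom = cov$chrom[k],
            start = cov$start[k], end = cov$end[k],
            zygosity = cov$zygosity[k],
            junction_read_count = NA_integer_,
            mean_coverage_ratio = cov$mean_coverage_ratio[k],
            evidence = "coverage", conflict = FALSE,
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(allele_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          zygosity = character(),
                          junction_read_count = integer(),
                          mean_coverage_ratio = numeric(),
                          evidence = character(), conflict = logical(),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
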