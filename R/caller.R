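## The automated decision tree: per-site variant retention thresholds,
## allele-fraction zygosity bands, and no-call target labelling.

#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

.caller_profiles <- list(
    ## clinical test description: >= 8 reads of quality > 25, >= 16-fold
    "clinical-v2" = list(minAltReadsHq = 8, minBaseQuality = 25,
                         minCoverage = 16),
    ## research version: > 20x coverage and > 10 reads of quality > 20,
    ## encoded as the >= thresholds fixed for that profile
    "research-v1" = list(minAltReadsHq = 10, minBaseQuality = 20,
                         minCoverage = 20),
    ## planned clinical refinement: > 16x coverage, > 6 reads of quality > 25
    "clinical-v2-improved" = list(minAltReadsHq = 7, minBaseQuality = 25,
                                  minCoverage = 17))

#' Construct decision-tree caller parameters
#'
#' Builds a [CallerParams-class] from a named profile, optionally
#' overriding individual thresholds. Profiles: \code{"clinical-v2"}
#' (default; variants retained with >= 8 quality-passing reads, Phred
#' cutoff 25, >= 16-fold coverage), \code{"research-v1"} (>= 10 reads of
#' quality above 20, >= 20-fold coverage), and
#' \code{"clinical-v2-improved"} (> 6 reads above quality 25, > 16-fold
#' coverage). All profiles share the zygosity bands: allele fractions
#' above 0.86 are homozygous, fractions within [0.14, 0.86]
#' heterozygous (both band edges heterozygous), fractions below 0.14
#' subthreshold.
#'
#' @param profile profile name.
#' @param minAltReadsHq,minBaseQuality,minCoverage,hetLow,hetHigh,gcThreshold,fractionDenominator
#'   optional overrides of the corresponding slots; see
#'   [CallerParams-class].
#' @return a [CallerParams-class].
#' @examples
#' callerParams()
#' callerParams("research-v1")
#' callerParams(minCoverage = 20)
#' @export
callerParams <- function(profile = "clinical-v2", minAltReadsHq = NULL,
                         minBaseQuality = NULL, minCoverage = NULL,
                         hetLow = 0.14, hetHigh = 0.86, gcThreshold = 0.75,
                         fractionDenominator = c("hq", "total")) {
    if (!profile %in% names(.caller_profiles))
        stop("unknown profile '", profile, "'; available: ",
             paste(names(.caller_profiles), collapse = ", "))
    base <- .caller_profiles[[profile]]
    new("CallerParams",
        minAltReadsHq = if (is.null(minAltReadsHq)) base$minAltReadsHq
            else minAltReadsHq,
        minBaseQuality = if (is.null(minBaseQuality)) base$minBaseQuality
            else minBaseQuality,
        minCoverage = if (is.null(minCoverage)) base$minCoverage
            else minCoverage,
        hetLow = hetLow, hetHigh = hetHigh, gcThreshold = gcThreshold,
        fractionDenominator = match.arg(fractionDenominator),
        profileLabel = profile)
}

#' Assign zygosity from an alternate allele fraction
#'
#' Implements the zygosity bands of the decision tree: fractions
#' strictly above \code{hetHigh} (default 0.86) are homozygous,
#' fractions within \code{[hetLow, hetHigh]} (default [0.14, 0.86],
#' both edges inclusive) heterozygous, fractions strictly below
#' \code{hetLow} subthreshold. Every fraction in [0, 1] maps to exactly
#' one label.
#'
#' @param altFraction numeric vector of fractions in [0, 1].
#' @param params a [CallerParams-class].
#' @return character vector over \code{c("hom", "het", "subthreshold")}.
#' @examples
#' zygosityOf(c(0.93, 0.5, 0.86, 0.139), callerParams())
#' @export
zygosityOf <- function(altFraction, params = callerParams()) {
    stopifnot(is(params, "CallerParams"),
              all(altFraction >= 0 & altFraction <= 1))
    ifelse(altFraction > params@hetHigh, "hom",
           ifelse(altFraction >= params@hetLow, "het", "subthreshold"))
}

## Vectorized per-site evidence summary: top non-reference allele by hq
## count (ties broken alphabetically), its hq support, and the fraction
## denominator. Shared by callSite/callSample/rocSweep.
.site_stats <- function(pileup, params) {
    n <- nrow(pileup)
    alt_allele <- character(n)
    alt_hq <- integer(n)
    hq_total <- integer(n)
    for (i in seq_len(n)) {
        hq <- pileup$counts_hq[[i]]
        hq_total[i] <- sum(hq)
        nonref <- hq[names(hq) != pileup$ref[i]]
        if (length(nonref)) {
            nonref <- nonref[order(names(nonref))]   # alphabetical tie-break
            j <- which.max(nonref)
            alt_allele[i] <- names(nonref)[j]
            alt_hq[i] <- nonref[[j]]
        } else {
            alt_allele[i] <- NA_character_
            alt_hq[i] <- 0L
        }
    }
    denom <- if (params@fractionDenominator == "hq") hq_total else pileup$depth
    frac <- ifelse(denom > 0, alt_hq / denom, 0)
    data.frame(chrom = pileup$chrom, pos = pileup$pos, ref = pileup$ref,
               depth = pileup$depth, alt = alt_allele, hq_alt_reads = alt_hq,
               hq_total = hq_total, alt_fraction = frac,
               stringsAsFactors = FALSE)
}

## Apply the decision-tree thresholds to a site-stats table. Vectorized
## so threshold sweeps re-use one evidence pass.
.apply_tree <- function(stats, params) {
    status <- rep("no_variant", nrow(stats))
    filter <- rep("LowSupport", nrow(stats))
    zyg <- rep(NA_character_, nrow(stats))
    lowcov <- stats$depth < params@minCoverage
    status[lowcov] <- "no_call"
    filter[lowcov] <- "LowCov"
    sup <- !lowcov & stats$hq_alt_reads >= params@minAltReadsHq
    z <- zygosityOf(pmin(stats$alt_fraction[sup], 1), params)
    sub <- z == "subthreshold"
    idx <- which(sup)
    status[idx[sub]] <- "no_variant"
    filter[idx[sub]] <- "SubthresholdFraction"
    status[idx[!sub]] <- "PASS"
    filter[idx[!sub]] <- "PASS"
    zyg[idx[!sub]] <- z[!sub]
    cbind(stats, data.frame(status = status, filter_label = filter,
                            zygosity = zyg, stringsAsFactors = FALSE))
}

#' Call a single site
#'
#' Runs the decision tree on one pileup observation: sites below the
#' coverage minimum are no-calls (\code{LowCov}); otherwise the top
#' non-reference allele by quality-passing count is evaluated, requiring
#' \code{minAltReadsHq} supporting reads (\code{LowSupport} otherwise)
#' and an allele fraction inside or above the heterozygous band
#' (\code{SubthresholdFraction} otherwise); surviving sites are
#' \code{PASS} variants with zygosity from [zygosityOf()].
#'
#' @param obs a single-row pileup \code{data.frame} (see
#'   [readPileup()]), or a list with elements \code{chrom}, \code{pos},
#'   \code{ref}, \code{depth}, \code{counts_hq}, \code{counts_all}.
#' @param params a [CallerParams-class].
#' @return a one-row \code{data.frame} with the site evidence plus
#'   \code{status} (\code{PASS}, \code{no_variant} or \code{no_call}),
#'   \code{filter_label} and \code{zygosity}.
#' @export
callSite <- function(obs, params = callerParams()) {
    if (is.list(obs) && !is.data.frame(obs))
        obs <- data.frame(chrom = obs$chrom, pos = obs$pos, ref = obs$ref,
                          depth = obs$depth,
                          counts_hq = I(list(obs$counts_hq)),
                          counts_all = I(list(obs$counts_all)),
                          stringsAsFactors = FALSE)
    stopifnot(nrow(obs) == 1L)
    .apply_tree(.site_stats(obs, params), params)
}

.check_sorted <- function(chrom, pos) {
    if (!length(chrom)) return(invisible(TRUE))
    r <- rle(chrom)
    if (anyDuplicated(r$values) ||
        any(diff(pos) < 0 & chrom[-1L] == chrom[-length(chrom)]))
        stop("pileup must be coordinate-sorted")
    invisible(TRUE)
}

.positions_in_targets <- function(chrom, pos, targets) {
    if (!length(chrom)) return(logical(0))
    q <- GRanges(chrom, IRanges(pos, pos))
    GenomicRanges::countOverlaps(q, targets, ignore.strand = TRUE) > 0
}

#' Call variants over a sample's pileup
#'
#' Applies the decision tree to every observation falling inside the
#' capture targets (positions outside all targets are masked) and
#' returns the PASS variant calls, the full per-site verdict table, and
#' the per-position coverage track needed for no-call labelling and
#' deletion detection. Deterministic for fixed input; the pileup must be
#' coordinate-sorted.
#'
#' @param pileup pileup \code{data.frame} sorted by (chrom, pos).
#' @param targets \code{GRanges} of capture targets ([readTargets()]).
#' @param params a [CallerParams-class].
#' @return a list with elements \code{calls} (PASS rows), \code{sites}
#'   (every evaluated site with status), and \code{track}
#'   (\code{data.frame} of \code{chrom}, \code{pos}, \code{depth}).
#' @export
callSample <- function(pileup, targets, params = callerParams()) {
    .check_sorted(pileup$chrom, pileup$pos)
    keep <- .positions_in_targets(pileup$chrom, pileup$pos, targets)
    pileup <- pileup[keep, , drop = FALSE]
    sites <- .apply_tree(.site_stats(pileup, params), params)
    rownames(sites) <- NULL
    list(calls = sites[sites$status == "PASS", , drop = FALSE],
         sites = sites,
         track = data.frame(chrom = pileup$chrom, pos = pileup$pos,
                            depth = pileup$depth, stringsAsFactors = FALSE))
}

.target_callable_fraction <- function(track, target, minCoverage) {
    chrom <- as.character(GenomicRanges::seqnames(target))
    s <- GenomicRanges::start(target)
    e <- GenomicRanges::end(target)
    inside <- track$chrom == chrom & track$pos >= s & track$pos <= e
    covered <- sum(track$depth[inside] >= minCoverage)
    covered / (e - s + 1)
}

#' Label no-call target regions
#'
#' Reports every target whose callable fraction (share of positions at
#' or above the coverage minimum; positions absent from a track count as
#' uncovered) is below 1 in any replicate. A reported target is labelled
#' \code{high_gc_reproducible} when its GC fraction is at or above
#' \code{gcThreshold} and it drops out in every replicate — the
#' reproducibly missed high-GC targets — and \code{low_coverage}
#' otherwise.
#'
#' @param coverageTracks list of coverage tracks (one per replicate),
#'   each a \code{data.frame} with \code{chrom}, \code{pos},
#'   \code{depth}.
#' @param targets \code{GRanges} with \code{gc_fraction} metadata.
#' @param params a [CallerParams-class]; supplies \code{minCoverage}
#'   and \code{gcThreshold}.
#' @return \code{data.frame} with one row per no-call target:
#'   \code{chrom}, \code{start}, \code{end}, \code{gene_symbol},
#'   \code{gc_fraction}, \code{callable_fraction} (minimum across
#'   replicates), \code{reason}.
#' @export
labelNoCallTargets <- function(coverageTracks, targets,
                               params = callerParams()) {
    if (is.data.frame(coverageTracks)) coverageTracks <- list(coverageTracks)
    stopifnot(length(coverageTracks) >= 1L)
    out <- list()
    for (i in seq_along(targets)) {
        tgt <- targets[i]
        cf <- vapply(coverageTracks, .target_callable_fraction,
                     numeric(1L), target = tgt,
                     minCoverage = params@minCoverage)
        if (all(cf >= 1)) next
        gc <- GenomicRanges::mcols(tgt)$gc_fraction
        reason <- if (gc >= params@gcThreshold && all(cf < 1))
            "high_gc_reproducible" else "low_coverage"
        out[[length(out) + 1L]] <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(tgt)),
            start = GenomicRanges::start(tgt), end = GenomicRanges::end(tgt),
            gene_symbol = GenomicRanges::mcols(tgt)$gene_symbol,
            gc_fraction = gc, callable_fraction = min(cf), reason = reason,
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), gene_symbol = character(),
                          gc_fraction = numeric(),
                          callable_fraction = numeric(), reason = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, out)
}
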