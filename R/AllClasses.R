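#' @import methods
#' @importFrom stats rpois rbinom rbeta setNames
NULL

## Central S4 containers for the screening pipeline. Tabular results
## (variant calls, deletion calls, disease genotypes) stay plain
## data.frames, as is usual for per-row result tables.

#' Recessive-disease panel registry
#'
#' A \code{Panel} holds the disease-gene registry of the screening test:
#' one row per (OMIM disease, gene) association, in input order. The same
#' OMIM accession may appear with several genes (locus heterogeneity) and
#' the same gene may serve several diseases, so disease identity is the
#' (OMIM accession, disease name) pair and gene identity is the exact
#' HGNC-style symbol.
#'
#' @slot entries \code{data.frame} with columns \code{omim_id} (integer,
#'   6-digit accession), \code{disease_name} (character),
#'   \code{gene_symbol} (character), \code{inheritance} (\code{"AR"} or
#'   \code{"XL"}).
#' @slot versionLabel free-text label for the panel release.
#'
#' @seealso [loadPanel()], [countUniqueGenes()], [countDiseases()],
#'   [genesForPhenotype()]
#' @export
setClass("Panel",
    representation(entries = "data.frame", versionLabel = "character"))

setValidity("Panel", function(object) {
    e <- object@entries
    need <- c("omim_id", "disease_name", "gene_symbol", "inheritance")
    if (!all(need %in% names(e)))
        return(paste("entries must have columns:", paste(need, collapse = ", ")))
    msgs <- character()
    if (nrow(e)) {
        if (!is.integer(e$omim_id) || anyNA(e$omim_id))
            msgs <- c(msgs, "omim_id must be integer and non-missing")
        else if (any(e$omim_id < 100000L | e$omim_id > 999999L))
            msgs <- c(msgs, "omim_id must be a 6-digit accession in [100000, 999999]")
        if (any(!nzchar(e$gene_symbol)) || any(grepl("[[:space:]]", e$gene_symbol)))
            msgs <- c(msgs, "gene_symbol must be non-empty without whitespace")
        if (any(!nzchar(e$disease_name)))
            msgs <- c(msgs, "disease_name must be non-empty")
        if (!all(e$inheritance %in% c("AR", "XL")))
            msgs <- c(msgs, "inheritance must be 'AR' or 'XL'")
        key <- paste(e$omim_id, e$disease_name, e$gene_symbol, sep = "\r")
        if (anyDuplicated(key))
            msgs <- c(msgs, "duplicate (omim_id, disease_name, gene_symbol) entries")
    }
    if (length(object@versionLabel) != 1L)
        msgs <- c(msgs, "versionLabel must be a single string")
    if (length(msgs)) msgs else TRUE
})

#' Decision-tree caller thresholds and zygosity bands
#'
#' Parameters of the automated decision tree that retains and genotypes
#' variants. A variant is retained when it is supported by at least
#' \code{minAltReadsHq} reads whose base quality exceeds
#' \code{minBaseQuality}, at a site with at least \code{minCoverage}-fold
#' total read depth. Retained variants are genotyped from the alternate
#' allele fraction: above \code{hetHigh} homozygous, within
#' \code{[hetLow, hetHigh]} heterozygous, below \code{hetLow}
#' subthreshold (not reported).
#'
#' @slot minAltReadsHq minimum quality-passing reads supporting the
#'   alternate allele (count).
#' @slot minBaseQuality Phred base-quality cutoff defining a
#'   quality-passing ("hq") read base.
#' @slot minCoverage minimum total read depth (fold coverage) for a site
#'   to be callable.
#' @slot hetLow,hetHigh allele-fraction band edges for heterozygous
#'   calls; fractions above \code{hetHigh} are homozygous.
#' @slot gcThreshold GC fraction at or above which a reproducibly
#'   dropped-out target is labelled as a high-GC no-call region.
#' @slot fractionDenominator \code{"hq"} (default) computes the allele
#'   fraction over quality-passing reads only; \code{"total"} divides
#'   quality-passing alternate reads by total depth.
#' @slot profileLabel name of the parameter profile.
#'
#' @seealso [callerParams()], [zygosityOf()], [callSite()]
#' @export
setClass("CallerParams",
    representation(
        minAltReadsHq = "numeric",
        minBaseQuality = "numeric",
        minCoverage = "numeric",
        hetLow = "numeric",
        hetHigh = "numeric",
        gcThreshold = "numeric",
        fractionDenominator = "character",
        profileLabel = "character"))

setValidity("CallerParams", function(object) {
    msgs <- character()
    for (s in c("minAltReadsHq", "minBaseQuality", "minCoverage")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v <= 0)
            msgs <- c(msgs, paste(s, "must be a single positive number"))
    }
    if (!(length(object@hetLow) == 1L && length(object@hetHigh) == 1L &&
          object@hetLow > 0 && object@hetLow < object@hetHigh &&
          object@hetHigh < 1))
        msgs <- c(msgs, "need 0 < hetLow < hetHigh < 1")
    if (length(object@gcThreshold) != 1L || object@gcThreshold < 0 ||
        object@gcThreshold > 1)
        msgs <- c(msgs, "gcThreshold must be in [0,1]")
    if (!identical(length(object@fractionDenominator), 1L) ||
        !object@fractionDenominator %in% c("hq", "total"))
        msgs <- c(msgs, "fractionDenominator must be 'hq' or 'total'")
    if (length(msgs)) msgs else TRUE
})

#' Normalized-coverage ratio bands for gross-deletion genotyping
#'
#' Band edges applied to the per-target ratio of a sample's normalized
#' coverage to an unaffected baseline: ratios at or below
#' \code{homMaxRatio} indicate a homozygous deletion, ratios within
#' \code{[hetLowRatio, hetHighRatio]} a heterozygous deletion, all other
#' ratios no deletion.
#'
#' @slot homMaxRatio upper edge of the homozygous-deletion band.
#' @slot hetLowRatio,hetHighRatio heterozygous-deletion band.
#'
#' @seealso [coverageBands()], [detectCoverageDeletions()]
#' @export
setClass("CoverageBands",
    representation(homMaxRatio = "numeric", hetLowRatio = "numeric",
                   hetHighRatio = "numeric"))

setValidity("CoverageBands", function(object) {
    ok <- length(object@homMaxRatio) == 1L && length(object@hetLowRatio) == 1L &&
        length(object@hetHighRatio) == 1L &&
        object@homMaxRatio >= 0 && object@homMaxRatio < object@hetLowRatio &&
        object@hetLowRatio < object@hetHighRatio && object@hetHighRatio < 1
    if (ok) TRUE else "need 0 <= homMaxRatio < hetLowRatio < hetHighRatio < 1"
})

#' Simulation configuration
#'
#' Parameters of the synthetic read-evidence generator used for testing
#' and analytic-validity estimation. Depth can be given either directly
#' as mean fold coverage or as gigabases of sequence, converted linearly
#' at 150-fold coverage per 3.0 GB of sequence per sample.
#'
#' @slot nSites number of variant-candidate sites to place in targets.
#' @slot meanDepth mean fold coverage (Poisson mean of site depth).
#' @slot errorRate per-base miscall probability.
#' @slot hqProb probability a read base exceeds the quality cutoff.
#' @slot genotypeMix length-3 proportions of ref/het/hom sites (sums to 1).
#' @slot overdispersion beta-binomial overdispersion rho in [0,1); 0
#'   (default) draws plain binomial read counts.
#' @slot seed integer seed; all generator output is a pure function of
#'   the configuration including this seed.
#'
#' @seealso [simConfig()], [simulateTruth()], [simulatePileup()]
#' @export
setClass("SimConfig",
    representation(
        nSites = "integer",
        meanDepth = "numeric",
        errorRate = "numeric",
        hqProb = "numeric",
        genotypeMix = "numeric",
        overdispersion = "numeric",
        seed = "integer"))

setValidity("SimConfig", function(object) {
    msgs <- character()
    if (length(object@nSites) != 1L || object@nSites < 1L)
        msgs <- c(msgs, "nSites must be a positive integer")
    if (length(object@meanDepth) != 1L || object@meanDepth <= 0)
        msgs <- c(msgs, "meanDepth must be positive")
    if (length(object@errorRate) != 1L || object@errorRate < 0 ||
        object@errorRate >= 0.5)
        msgs <- c(msgs, "errorRate must be in [0, 0.5)")
    if (length(object@hqProb) != 1L || object@hqProb <= 0 || object@hqProb > 1)
        msgs <- c(msgs, "hqProb must be in (0, 1]")
    gm <- object@genotypeMix
    if (length(gm) != 3L || any(gm < 0) || abs(sum(gm) - 1) > 1e-8)
        msgs <- c(msgs, "genotypeMix must be 3 nonnegative proportions summing to 1")
    if (length(object@overdispersion) != 1L || object@overdispersion < 0 ||
        object@overdispersion >= 1)
        msgs <- c(msgs, "overdispersion must be in [0, 1)")
    if (length(object@seed) != 1L || is.na(object@seed))
        msgs <- c(msgs, "seed must be a single integer")
    if (length(msgs)) msgs else TRUE
})

#' Carrier or diagnostic screening report
#'
#' The interpreted outcome of a sample. In carrier mode every gene's
#' carrier status is reportable. In diagnostic mode only genes relevant
#' to the clinical presentation are reported (positive and negative);
#' carrier-level findings in non-relevant genes are suppressed and
#' counted in \code{suppressedCount}.
#'
#' @slot sampleId sample identifier.
#' @slot mode \code{"carrier"} or \code{"diagnostic"}.
#' @slot relevantGenes genes relevant to the presentation (diagnostic
#'   mode only; empty in carrier mode).
#' @slot results \code{data.frame} of reported disease genotypes.
#' @slot suppressedCount number of non-negative findings masked in
#'   diagnostic mode.
#' @slot negativeGeneCount genes summarized as negative (carrier mode).
#' @slot appendix \code{data.frame} of variants excluded from genotype
#'   assembly because the knowledge base marks them misannotated.
#'
#' @seealso [makeReport()], [formatReport()]
#' @export
setClass("Report",
    representation(
        sampleId = "character",
        mode = "character",
        relevantGenes = "character",
        results = "data.frame",
        suppressedCount = "integer",
        negativeGeneCount = "integer",
        appendix = "data.frame"))

setValidity("Report", function(object) {
    msgs <- character()
    if (!object@mode %in% c("carrier", "diagnostic"))
        msgs <- c(msgs, "mode must be 'carrier' or 'diagnostic'")
    if (object@mode == "carrier" && length(object@relevantGenes))
        msgs <- c(msgs, "carrier mode must not restrict to relevant genes")
    if (object@mode == "carrier" && object@suppressedCount != 0L)
        msgs <- c(msgs, "carrier mode suppresses nothing")
    if (object@mode == "diagnostic" && !length(object@relevantGenes))
        msgs <- c(msgs, "diagnostic mode requires relevant genes")
    if (object@mode == "diagnostic" && nrow(object@results) &&
        !all(object@results$gene_symbol %in% object@relevantGenes))
        msgs <- c(msgs, "diagnostic results restricted to relevant genes")
    if (length(msgs)) msgs else TRUE
})
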