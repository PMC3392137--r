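## Analytic-validity harness: confusion counting against truth,
## accuracy/sensitivity/specificity/PPV/NPV, ROC over threshold grids,
## and the sequencing-depth sweep.

#' Tally site-level confusion counts against truth
#'
#' Compares called genotypes with the truth set over the same sites.
#' At a true variant site, an exact genotype match (same alternate
#' allele and zygosity) is a true positive; a call of a different
#' (spurious) alternate allele is a false positive; a missed variant or
#' a het/hom zygosity error is a false negative. At a true reference
#' site, the absence of a variant call is a true negative and any
#' variant call a false positive. No-call sites are excluded from the
#' four counts and tallied separately.
#'
#' @param sites per-site verdict table from [callSample()]
#'   (\code{$sites}).
#' @param truth truth set from [simulateTruth()].
#' @return list with \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{nocall}; the four counts sum to the evaluable sites.
#' @export
confusionCounts <- function(sites, truth) {
    key_s <- paste(sites$chrom, sites$pos)
    key_t <- paste(truth$chrom, truth$pos)
    idx <- match(key_t, key_s)
    if (anyNA(idx) || length(key_s) != length(key_t))
        stop("truth and call sites do not cover the same coordinates")
    s <- sites[idx, , drop = FALSE]
    nocall <- s$status == "no_call"
    called <- s$status == "PASS"
    is_var <- truth$genotype %in% c("het", "hom")
    tp <- sum(!nocall & is_var & called & s$alt == truth$alt &
              s$zygosity == truth$genotype, na.rm = TRUE)
    fp_spur <- sum(!nocall & is_var & called & s$alt != truth$alt,
                   na.rm = TRUE)
    fp_ref <- sum(!nocall & !is_var & called)
    fn <- sum(!nocall & is_var) - tp - fp_spur
    tn <- sum(!nocall & !is_var & !called)
    list(tp = tp, fp = fp_spur + fp_ref, tn = tn, fn = fn,
         nocall = sum(nocall))
}

#' Analytic-validity metrics from confusion counts
#'
#' Accuracy (tp+tn)/total, sensitivity tp/(tp+fn), specificity
#' tn/(tn+fp), positive predictive value tp/(tp+fp) and negative
#' predictive value tn/(tn+fn). A ratio with a zero denominator is
#' reported as \code{NA} (absent), never as 0.
#'
#' @param counts list from [confusionCounts()].
#' @return named list of the five metrics in [0, 1] (or \code{NA}).
#' @examples
#' validityMetrics(list(tp = 90, fp = 1, tn = 899, fn = 10))
#' @export
validityMetrics <- function(counts) {
    ratio <- function(num, den) if (den > 0) num / den else NA_real_
    with(counts, list(
        accuracy = ratio(tp + tn, tp + fp + tn + fn),
        sensitivity = ratio(tp, tp + fn),
        specificity = ratio(tn, tn + fp),
        ppv = ratio(tp, tp + fp),
        npv = ratio(tn, tn + fn)))
}

.pareto_frontier <- function(fpr, tpr) {
    ok <- !is.na(fpr) & !is.na(tpr)
    fpr <- fpr[ok]; tpr <- tpr[ok]
    ## best tpr at each fpr, made monotone (upper-right staircase)
    ufpr <- sort(unique(fpr))
    utpr <- vapply(ufpr, function(x) max(tpr[fpr == x]), numeric(1L))
    utpr <- cummax(utpr)
    list(fpr = ufpr, tpr = utpr)
}

#' ROC over a grid of caller thresholds
#'
#' Sweeps the decision tree's alternate-read support threshold and the
#' lower edge of the heterozygous band over a grid, computes one
#' (false-positive rate, true-positive rate) point per grid cell
#' against truth, takes the Pareto frontier, anchors it at (0,0) and
#' (1,1), and integrates the area under the curve by the trapezoid
#' rule.
#'
#' @param pileup pileup \code{data.frame} over the truth sites.
#' @param truth truth set from [simulateTruth()]; must contain variant
#'   sites.
#' @param minAltGrid,hetLowGrid numeric vectors spanned by the grid.
#' @param params baseline [CallerParams-class]; all other thresholds
#'   are held at its values.
#' @return list with \code{points} (the full grid as a
#'   \code{data.frame}), \code{curve} (frontier plus anchors) and
#'   \code{auc}.
#' @export
rocSweep <- function(pileup, truth,
                     minAltGrid = c(1, 2, 4, 6, 8, 12, 16, 24, 32),
                     hetLowGrid = c(0.02, 0.05, 0.10, 0.14, 0.20, 0.30),
                     params = callerParams()) {
    if (!any(truth$genotype %in% c("het", "hom")))
        stop("degenerate truth: no variant sites to sweep")
    stopifnot(length(minAltGrid) >= 1L, length(hetLowGrid) >= 1L)
    stats <- .site_stats(pileup, params)
    grid <- expand.grid(min_alt = minAltGrid, het_low = hetLowGrid,
                        KEEP.OUT.ATTRS = FALSE)
    tpr <- fpr <- numeric(nrow(grid))
    for (i in seq_len(nrow(grid))) {
        p <- params
        p@minAltReadsHq <- grid$min_alt[i]
        p@hetLow <- grid$het_low[i]
        validObject(p)
        sites <- .apply_tree(stats, p)
        cc <- confusionCounts(sites, truth)
        tpr[i] <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
        fpr[i] <- if (cc$fp + cc$tn > 0) cc$fp / (cc$fp + cc$tn) else NA_real_
    }
    grid$tpr <- tpr; grid$fpr <- fpr
    fr <- .pareto_frontier(c(0, fpr, 1), c(0, tpr, 1))
    auc <- sum(diff(fr$fpr) * (head(fr$tpr, -1) + tail(fr$tpr, -1)) / 2)
    list(points = grid,
         curve = data.frame(fpr = fr$fpr, tpr = fr$tpr), auc = auc)
}

#' Sensitivity and PPV across a sequencing-depth sweep
#'
#' Re-simulates read evidence for one fixed truth set at each requested
#' sequence yield (gigabases, mapped to mean fold coverage at 150x per
#' 3.0 GB), calls variants, and reports the analytic metrics per depth.
#'
#' @param truth truth set from [simulateTruth()].
#' @param targets \code{GRanges} of capture targets.
#' @param gigabasesList ascending positive yields in GB.
#' @param params a [CallerParams-class].
#' @param config a [SimConfig-class] providing error and quality
#'   parameters; its depth is overridden per sweep point.
#' @param seedOffset pileup seed offset (vary for replicate sweeps).
#' @return \code{data.frame} with one row per yield: \code{gigabases},
#'   \code{mean_depth}, \code{sensitivity}, \code{specificity},
#'   \code{ppv}, \code{nocall}.
#' @export
depthSweep <- function(truth, targets, gigabasesList = c(0.7, 1.2, 1.7, 2.2, 2.7),
                       params = callerParams(), config = simConfig(),
                       seedOffset = 1L) {
    stopifnot(all(gigabasesList > 0), !is.unsorted(gigabasesList))
    rows <- lapply(seq_along(gigabasesList), function(i) {
        cfg <- config
        cfg@meanDepth <- gigabasesToDepth(gigabasesList[i])
        pu <- simulatePileup(truth, cfg,
                             seedOffset = seedOffset + (i - 1L) * 1000L)
        res <- callSample(pu, targets, params)
        m <- validityMetrics(cc <- confusionCounts(res$sites, truth))
        data.frame(gigabases = gigabasesList[i], mean_depth = cfg@meanDepth,
                   sensitivity = m$sensitivity, specificity = m$specificity,
                   ppv = m$ppv, nocall = cc$nocall)
    })
    do.call(rbind, rows)
}
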