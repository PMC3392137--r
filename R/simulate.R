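## Synthetic truth sets, pileups, junction reads and coverage tracks
## with the statistical structure the decision tree assumes, so every
## pipeline stage is testable without external data.

.BASES <- c("A", "C", "G", "T")

#' Construct a simulation configuration
#'
#' Depth may be given as \code{meanDepth} (fold coverage) or as
#' \code{gigabases}, converted with [gigabasesToDepth()] (150-fold per
#' 3.0 GB of sequence). Defaults emulate the test's stated operating
#' point: ~150-fold mean target coverage, 1% per-base miscall rate, 90%
#' of read bases passing the quality cutoff, and a site mix of 80% ref /
#' 15% het / 5% hom.
#'
#' @param nSites number of candidate sites.
#' @param meanDepth mean fold coverage; ignored when \code{gigabases}
#'   is supplied.
#' @param gigabases optional sequence yield in GB.
#' @param errorRate per-base miscall probability.
#' @param hqProb probability a read base exceeds the quality cutoff.
#' @param genotypeMix proportions of ref/het/hom sites (sum 1).
#' @param overdispersion beta-binomial overdispersion in [0, 1);
#'   0 keeps plain binomial sampling.
#' @param seed integer seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nSites = 10000L, meanDepth = 150, gigabases = NULL,
                      errorRate = 0.01, hqProb = 0.9,
                      genotypeMix = c(ref = 0.8, het = 0.15, hom = 0.05),
                      overdispersion = 0, seed = 0L) {
    if (!is.null(gigabases)) meanDepth <- gigabasesToDepth(gigabases)
    new("SimConfig", nSites = as.integer(nSites), meanDepth = meanDepth,
        errorRate = errorRate, hqProb = hqProb,
        genotypeMix = unname(genotypeMix), overdispersion = overdispersion,
        seed = as.integer(seed))
}

#' Convert sequence yield to mean fold coverage
#'
#' Linear map anchored at 3.0 GB of sequence per sample covering each
#' target nucleotide ~150 times: 0.7 GB -> 35x, 2.7 GB -> 135x.
#'
#' @param gigabases numeric vector of yields in GB.
#' @return mean fold coverage.
#' @examples
#' gigabasesToDepth(c(0.7, 2.7))
#' @export
gigabasesToDepth <- function(gigabases) {
    stopifnot(all(gigabases > 0))
    150 * gigabases / 3.0
}

#' Simulate a genotype truth set
#'
#' Places \code{nSites} sites uniformly without replacement within the
#' capture targets, draws a true genotype per site from
#' \code{genotypeMix}, and assigns reference and alternate bases.
#' Deterministic given the configuration seed.
#'
#' @param targets \code{GRanges} of capture targets.
#' @param config a [SimConfig-class].
#' @return \code{data.frame} with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{genotype} (\code{ref}/\code{het}/\code{hom}),
#'   sorted by (chrom, pos).
#' @export
simulateTruth <- function(targets, config) {
    stopifnot(is(config, "SimConfig"))
    total <- sum(GenomicRanges::width(targets))
    if (config@nSites > total)
        stop("nSites (", config@nSites, ") exceeds total target length (",
             total, ")")
    set.seed(config@seed)
    chrom <- as.character(GenomicRanges::seqnames(targets))
    offsets <- cumsum(c(0, GenomicRanges::width(targets)))
    flat <- sample.int(total, config@nSites)
    tgt_i <- findInterval(flat - 1L, offsets[-length(offsets)],
                          rightmost.closed = FALSE)
    ## findInterval over cumulative starts: index of hosting target
    tgt_i <- pmax(1L, pmin(length(targets), tgt_i))
    pos <- GenomicRanges::start(targets)[tgt_i] +
        (flat - offsets[tgt_i] - 1L)
    geno <- sample(c("ref", "het", "hom"), config@nSites, replace = TRUE,
                   prob = config@genotypeMix)
    ref <- sample(.BASES, config@nSites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1L),
                  character(1L), USE.NAMES = FALSE)
    out <- data.frame(chrom = chrom[tgt_i], pos = as.integer(pos), ref = ref,
                      alt = alt, genotype = geno, stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.rbinom_od <- function(n, size, prob, rho) {
    if (rho <= 0) return(rbinom(n, size, prob))
    ## beta-binomial with correlation rho
    shape <- (1 - rho) / rho
    p <- rbeta(n, prob * shape, (1 - prob) * shape)
    rbinom(n, size, p)
}

#' Simulate a pileup from a truth set
#'
#' Per site, total depth is Poisson with mean \code{meanDepth};
#' alternate reads are binomial in depth with success probability 0.5
#' (het), \code{1 - errorRate} (hom) or \code{errorRate / 3} (ref);
#' quality-passing counts thin each allele's reads binomially with
#' \code{hqProb}. With \code{overdispersion > 0} the alternate-read
#' draw is beta-binomial. Output is a pure function of (truth, config,
#' seedOffset).
#'
#' @param truth truth set from [simulateTruth()].
#' @param config a [SimConfig-class].
#' @param seedOffset added to the configuration seed so several
#'   pileups (replicates, depth points) can be drawn from one truth.
#' @return a pileup \code{data.frame} (see [readPileup()]).
#' @export
simulatePileup <- function(truth, config, seedOffset = 1L) {
    stopifnot(is(config, "SimConfig"))
    n <- nrow(truth)
    set.seed(config@seed + as.integer(seedOffset))
    depth <- rpois(n, config@meanDepth)
    p_alt <- c(ref = config@errorRate / 3, het = 0.5,
               hom = 1 - config@errorRate)[truth$genotype]
    alt <- .rbinom_od(n, depth, p_alt, config@overdispersion)
    ref_n <- depth - alt
    hq_alt <- rbinom(n, alt, config@hqProb)
    hq_ref <- rbinom(n, ref_n, config@hqProb)
    counts_hq <- vector("list", n)
    counts_all <- vector("list", n)
    for (i in seq_len(n)) {
        if (alt[i] > 0) {
            counts_hq[[i]] <- setNames(c(hq_ref[i], hq_alt[i]),
                                       c(truth$ref[i], truth$alt[i]))
            counts_all[[i]] <- setNames(c(ref_n[i], alt[i]),
                                        c(truth$ref[i], truth$alt[i]))
        } else {
            counts_hq[[i]] <- setNames(hq_ref[i], truth$ref[i])
            counts_all[[i]] <- setNames(ref_n[i], truth$ref[i])
        }
    }
    data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
               depth = as.integer(depth), counts_hq = I(counts_hq),
               counts_all = I(counts_all), stringsAsFactors = FALSE)
}

.random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

#' Simulate gross deletions with junction reads and coverage tracks
#'
#' Plants \code{nAlleles} non-overlapping known-boundary deletions, one
#' per capture target, each spanning the central half of its target.
#' For every deletion a junction reference sequence (2 x \code{flank}
#' bases across the breakpoint) is generated; homozygous deletions emit
#' junction-spanning reads at full depth and drop the region's coverage
#' to near zero, heterozygous deletions emit junction reads at ~half
#' depth and halve the region's coverage. The baseline track is an
#' unaffected sample at full depth. Decoy reads that match no junction
#' are mixed in.
#'
#' @param targets \code{GRanges} of capture targets; needs at least
#'   \code{nAlleles} targets.
#' @param nAlleles number of deletions to plant (default 11).
#' @param zygosities character vector recycled over alleles
#'   (\code{"het"}/\code{"hom"}); default alternates.
#' @param config a [SimConfig-class]; \code{meanDepth} sets coverage
#'   and junction read counts.
#' @param flank junction flank length (default 30).
#' @param readLength simulated read length (default 125).
#' @return list with \code{truth} (planted deletions), \code{alleles}
#'   (junction table as from [readJunctionFasta()]), \code{fasta}
#'   (junction FASTA lines), \code{reads} (character vector),
#'   \code{track} (affected sample) and \code{baseline} coverage
#'   tracks.
#' @export
simulateDeletions <- function(targets, nAlleles = 11L, zygosities = NULL,
                              config = simConfig(), flank = 30L,
                              readLength = 125L) {
    stopifnot(is(config, "SimConfig"))
    if (length(targets) < nAlleles)
        stop("need at least ", nAlleles, " targets to host the deletions")
    if (is.null(zygosities))
        zygosities <- rep(c("het", "hom"), length.out = nAlleles)
    zygosities <- rep(zygosities, length.out = nAlleles)
    set.seed(config@seed + 7L)
    host <- seq_len(nAlleles)            # one deletion per target, no overlap
    chrom <- as.character(GenomicRanges::seqnames(targets))[host]
    ts <- GenomicRanges::start(targets)[host]
    te <- GenomicRanges::end(targets)[host]
    ## each deletion removes its whole host target (the unit at which
    ## coverage ratios are banded), so boundaries are known
    del_s <- ts
    del_e <- te
    gene <- GenomicRanges::mcols(targets)$gene_symbol[host]
    allele_id <- sprintf("%s:del%02d", gene, seq_len(nAlleles))
    junction <- vapply(seq_len(nAlleles), function(i) .random_dna(2L * flank),
                       character(1L))
    truth <- data.frame(allele_id = allele_id, chrom = chrom,
                        start = del_s, end = del_e, gene_symbol = gene,
                        zygosity = zygosities, stringsAsFactors = FALSE)
    ## junction-spanning reads: full depth for hom, half for het
    reads <- character()
    for (i in seq_len(nAlleles)) {
        lambda <- config@meanDepth * if (zygosities[i] == "hom") 1 else 0.5
        k <- rpois(1L, lambda)
        if (k > 0) {
            pre_n <- pmax(0L, (readLength - 2L * flank) %/% 2L)
            reads <- c(reads, vapply(seq_len(k), function(j)
                paste0(.random_dna(pre_n), junction[i],
                       .random_dna(readLength - 2L * flank - pre_n)),
                character(1L)))
        }
    }
    reads <- c(reads, vapply(seq_len(50L), function(j)
        .random_dna(readLength), character(1L)))   # decoys
    ## coverage tracks over all targets
    all_chrom <- as.character(GenomicRanges::seqnames(targets))
    pos_l <- lapply(seq_along(targets), function(i)
        seq.int(GenomicRanges::start(targets)[i],
                GenomicRanges::end(targets)[i]))
    track <- data.frame(
        chrom = rep(all_chrom, lengths(pos_l)),
        pos = unlist(pos_l), stringsAsFactors = FALSE)
    base_depth <- rpois(nrow(track), config@meanDepth)
    mult <- rep(1, nrow(track))
    for (i in seq_len(nAlleles)) {
        inside <- track$chrom == chrom[i] & track$pos >= del_s[i] &
            track$pos <= del_e[i]
        mult[inside] <- if (zygosities[i] == "hom") 0.01 else 0.5
    }
    affected <- rpois(nrow(track), config@meanDepth * mult)
    baseline <- track; baseline$depth <- base_depth
    track$depth <- affected
    fasta <- as.vector(rbind(
        sprintf(">%s region=%s:%d-%d", allele_id, chrom, del_s, del_e),
        junction))
    alleles <- data.frame(allele_id = allele_id, junction = junction,
                          flank = rep(as.integer(flank), nAlleles),
                          chrom = chrom,
                          start = del_s, end = del_e,
                          stringsAsFactors = FALSE)
    list(truth = truth, alleles = alleles, fasta = fasta, reads = reads,
         track = track, baseline = baseline)
}
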