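## Shared fixtures and independent brute-force oracles. The oracles
## re-derive expected results with straight-line per-site logic and no
## calls into the package's calling path.

make_targets <- function(n = 32L, width = 1500L, gap = 500L) {
    starts <- seq(0L, by = width + gap, length.out = n)
    readTargets(sprintf("chr%d\t%d\t%d\tG%03d\t0.45",
                        rep(1:4, length.out = n), starts, starts + width,
                        seq_len(n)))
}

mini_panel_lines <- c(
    "OMIM#\tNAME\tGENE\tINHERITANCE",
    "219700\tCYSTIC FIBROSIS; CF\tCFTR\tAR",
    "230400\tGALACTOSEMIA\tGALT\tAR",
    "226700\tEPIDERMOLYSIS BULLOSA, JUNCTIONAL, HERLITZ\tLAMA3\tAR",
    "226700\tEPIDERMOLYSIS BULLOSA, JUNCTIONAL, HERLITZ\tLAMB3\tAR",
    "226700\tEPIDERMOLYSIS BULLOSA, JUNCTIONAL, HERLITZ\tLAMC2\tAR",
    "310200\tMUSCULAR DYSTROPHY, DUCHENNE ; DMD\tDMD\tXL",
    "272800\tTAY-SACHS DISEASE; TSD\tHEXA\tAR")

table1_path <- function()
    system.file("extdata", "table1_panel.tsv", package = "recesscan",
                mustWork = TRUE)

## One pileup row from explicit allele counts (named vectors hq, all).
pileup_row <- function(chrom, pos, ref, hq, all_) {
    data.frame(chrom = chrom, pos = pos, ref = ref,
               depth = as.integer(sum(all_)), counts_hq = I(list(hq)),
               counts_all = I(list(all_)), stringsAsFactors = FALSE)
}

## Random multi-allele pileup over given targets (independent of the
## simulator so caller tests do not assume biallelic sites).
random_pileup <- function(n, targets, seed) {
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    chrom <- as.character(GenomicRanges::seqnames(targets))
    rows <- lapply(seq_len(n), function(i) {
        t <- sample(length(targets), 1L)
        pos <- sample(GenomicRanges::start(targets)[t]:
                      GenomicRanges::end(targets)[t], 1L)
        ref <- sample(bases, 1L)
        k <- sample(1:3, 1L)                        # alleles present
        alleles <- unique(c(ref, sample(bases, k, replace = TRUE)))
        all_ <- stats::setNames(stats::rmultinom(1L, sample(5:220, 1L),
                                rep(1, length(alleles)))[, 1L], alleles)
        hq <- stats::setNames(stats::rbinom(length(all_), all_, 0.9),
                              names(all_))
        pileup_row(chrom[t], pos, ref, hq, all_)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
}

## Brute-force decision tree: checks the three thresholds independently
## per site, scalar logic only.
oracle_call_site <- function(row, min_alt, min_cov, het_low, het_high) {
    if (row$depth < min_cov)
        return(list(status = "no_call", zygosity = NA_character_,
                    alt = NA_character_))
    hq <- row$counts_hq[[1L]]
    nonref <- hq[names(hq) != row$ref]
    if (!length(nonref))
        return(list(status = "no_variant", zygosity = NA_character_,
                    alt = NA_character_))
    best <- max(nonref)
    cand <- sort(names(nonref)[nonref == best])
    alt <- cand[1L]
    if (best < min_alt)
        return(list(status = "no_variant", zygosity = NA_character_,
                    alt = alt))
    frac <- best / sum(hq)
    if (frac < het_low)
        return(list(status = "no_variant", zygosity = NA_character_,
                    alt = alt))
    list(status = "PASS",
         zygosity = if (frac > het_high) "hom" else "het", alt = alt)
}

oracle_call_all <- function(pileup, min_alt = 8, min_cov = 16,
                            het_low = 0.14, het_high = 0.86) {
    res <- lapply(seq_len(nrow(pileup)), function(i)
        oracle_call_site(pileup[i, , drop = FALSE], min_alt, min_cov,
                         het_low, het_high))
    data.frame(status = vapply(res, `[[`, character(1L), "status"),
               zygosity = vapply(res, `[[`, character(1L), "zygosity"),
               alt = vapply(res, `[[`, character(1L), "alt"),
               stringsAsFactors = FALSE)
}

## Brute-force confusion tally, looping sites with explicit branches.
oracle_confusion <- function(sites, truth) {
    tp <- fp <- tn <- fn <- nc <- 0L
    for (i in seq_len(nrow(truth))) {
        j <- which(sites$chrom == truth$chrom[i] & sites$pos == truth$pos[i])
        s <- sites[j, ]
        if (s$status == "no_call") { nc <- nc + 1L; next }
        truth_var <- truth$genotype[i] %in% c("het", "hom")
        called <- s$status == "PASS"
        if (truth_var) {
            if (called && !is.na(s$alt) && s$alt == truth$alt[i] &&
                s$zygosity == truth$genotype[i]) tp <- tp + 1L
            else if (called && !is.na(s$alt) && s$alt != truth$alt[i])
                fp <- fp + 1L
            else fn <- fn + 1L
        } else {
            if (called) fp <- fp + 1L else tn <- tn + 1L
        }
    }
    list(tp = tp, fp = fp, tn = tn, fn = fn, nocall = nc)
}

## Brute-force junction support: scan every window of every junction
## explicitly rather than reducing to the central window.
oracle_junction_count <- function(reads, junction, flank, min_span) {
    L <- nchar(junction)
    mid <- flank                                   # breakpoint after base mid
    sum(vapply(reads, function(rd) {
        ## any window [s, e] with >= min_span bases on each side of the
        ## breakpoint midpoint, contained exactly in the read
        for (s in 1:(mid - min_span + 1)) {
            for (e in seq(mid + min_span, L)) {
                if (grepl(substr(junction, s, e), rd, fixed = TRUE))
                    return(TRUE)
            }
        }
        FALSE
    }, logical(1L)))
}

random_dna <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
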