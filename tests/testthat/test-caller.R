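test_that("zygosity bands honor the quoted boundaries", {
    p <- callerParams()
    expect_equal(zygosityOf(0.93, p), "hom")
    expect_equal(zygosityOf(0.50, p), "het")
    expect_equal(zygosityOf(0.86, p), "het")       # band edge het
    expect_equal(zygosityOf(0.861, p), "hom")
    expect_equal(zygosityOf(0.14, p), "het")       # band edge het
    expect_equal(zygosityOf(0.139, p), "subthreshold")
})

test_that("zygosity partitions [0,1] exhaustively", {
    p <- callerParams()
    fr <- seq(0, 1, by = 0.001)
    z <- zygosityOf(fr, p)
    expect_true(all(z %in% c("subthreshold", "het", "hom")))
    expect_equal(sum(z == "subthreshold") + sum(z == "het") +
                 sum(z == "hom"), length(fr))
})

test_that("retention thresholds behave exactly at their edges", {
    p <- callerParams()                            # >=8 hq reads, >=16x
    pass <- callSite(pileup_row("chr7", 100L, "G",
                                c(G = 70, A = 74), c(G = 72, A = 78)), p)
    expect_equal(pass$status, "PASS")
    expect_equal(pass$zygosity, "het")
    expect_equal(pass$alt, "A")

    lowcov <- callSite(pileup_row("chr1", 10L, "A",
                                  c(A = 5, T = 10), c(A = 5, T = 10)), p)
    expect_equal(lowcov$status, "no_call")         # depth 15 < 16
    expect_equal(lowcov$filter_label, "LowCov")
    at16 <- callSite(pileup_row("chr1", 10L, "A",
                                c(A = 6, T = 10), c(A = 6, T = 10)), p)
    expect_equal(at16$status, "PASS")              # depth 16 callable

    seven <- callSite(pileup_row("chr1", 10L, "A",
                                 c(A = 143, T = 7), c(A = 143, T = 7)), p)
    expect_equal(seven$status, "no_variant")       # 7 < 8 supporting reads
    expect_equal(seven$filter_label, "LowSupport")
    eight <- callSite(pileup_row("chr1", 10L, "A",
                                 c(A = 42, T = 8), c(A = 42, T = 8)), p)
    expect_equal(eight$status, "PASS")             # 8 reads, fraction 0.16

    sub <- callSite(pileup_row("chr1", 10L, "A",
                               c(A = 92, T = 8), c(A = 92, T = 8)), p)
    expect_equal(sub$status, "no_variant")         # fraction 0.08 < 0.14
    expect_equal(sub$filter_label, "SubthresholdFraction")
})

test_that("caller equals the brute-force oracle on random pileups", {
    tg <- make_targets()
    for (seed in c(101L, 202L)) {
        pu <- random_pileup(1000L, tg, seed = seed)
        got <- callSample(pu, tg, callerParams())$sites
        want <- oracle_call_all(pu)
        expect_equal(got$status, want$status)
        expect_equal(got$zygosity, want$zygosity)
        expect_equal(got$alt[got$status == "PASS"],
                     want$alt[want$status == "PASS"])
    }
})

test_that("raising thresholds never increases PASS calls", {
    tg <- make_targets()
    pu <- random_pileup(600L, tg, seed = 77L)
    n_pass <- function(p) nrow(callSample(pu, tg, p)$calls)
    base <- callerParams()
    for (alt in c(2, 8, 14, 20))
        for (cov in c(8, 16, 30)) {
            lo <- n_pass(callerParams(minAltReadsHq = alt, minCoverage = cov))
            hi <- n_pass(callerParams(minAltReadsHq = alt + 4,
                                      minCoverage = cov))
            hic <- n_pass(callerParams(minAltReadsHq = alt,
                                       minCoverage = cov + 10))
            expect_lte(hi, lo)
            expect_lte(hic, lo)
        }
})

test_that("allele order within a row never changes the call", {
    p <- callerParams()
    hq <- c(G = 40, A = 40, T = 12)
    all_ <- c(G = 45, A = 42, T = 14)
    base <- callSite(pileup_row("chr1", 5L, "G", hq, all_), p)
    expect_equal(base$alt, "A")                    # tie A vs T? no: A=40 top
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
        alt <- callSite(pileup_row("chr1", 5L, "G", hq[perm], all_[perm]), p)
        expect_equal(alt$status, base$status)
        expect_equal(alt$alt, base$alt)
        expect_equal(alt$alt_fraction, base$alt_fraction)
    }
    ## exact tie between alternates broken alphabetically
    tie <- callSite(pileup_row("chr1", 5L, "G",
                               c(G = 20, T = 40, A = 40),
                               c(G = 20, T = 40, A = 40)), p)
    expect_equal(tie$alt, "A")
})

test_that("masking and sortedness are enforced in callSample", {
    tg <- readTargets("chr1\t100\t200\tG1\t0.5")
    inside <- pileup_row("chr1", 150L, "A", c(A = 50, G = 50),
                         c(A = 50, G = 50))
    outside <- pileup_row("chr1", 500L, "A", c(A = 50, G = 50),
                          c(A = 50, G = 50))
    both <- rbind(inside, outside)
    res <- callSample(both, tg, callerParams())
    expect_equal(nrow(res$calls), 1L)              # outside target masked
    expect_equal(res$calls$pos, 150L)
    expect_error(callSample(both[c(2, 1), ], tg, callerParams()),
                 "coordinate-sorted")
    empty <- callSample(both[0, ], tg, callerParams())
    expect_equal(nrow(empty$calls), 0L)
    expect_equal(nrow(empty$track), 0L)
})

test_that("caller profiles carry their documented thresholds", {
    cl <- callerParams("clinical-v2")
    expect_equal(c(cl@minAltReadsHq, cl@minBaseQuality, cl@minCoverage),
                 c(8, 25, 16))
    rs <- callerParams("research-v1")
    expect_equal(c(rs@minAltReadsHq, rs@minBaseQuality, rs@minCoverage),
                 c(10, 20, 20))
    im <- callerParams("clinical-v2-improved")
    expect_equal(c(im@minAltReadsHq, im@minCoverage), c(7, 17))
    expect_error(callerParams("nope"), "unknown profile")
})

test_that("no-call targets are labelled by coverage and GC reproducibility", {
    tg <- readTargets(c("chr1\t0\t10\tLOWGC\t0.40",
                       "chr1\t100\t110\tHIGHGC\t0.80",
                       "chr1\t200\t210\tFINE\t0.50"))
    full <- function(chrom, s, e, depth)
        data.frame(chrom = chrom, pos = s:e, depth = depth,
                   stringsAsFactors = FALSE)
    cover_all <- rbind(full("chr1", 1, 10, 100), full("chr1", 201, 210, 100))
    rep1 <- cover_all                               # HIGHGC absent -> 0x
    rep2 <- rbind(cover_all, full("chr1", 101, 110, 100))

    ## high-GC target dead in both replicates -> reproducible high-GC label
    nc <- labelNoCallTargets(list(rep1, rep1), tg, callerParams())
    expect_equal(nc$gene_symbol, "HIGHGC")
    expect_equal(nc$reason, "high_gc_reproducible")
    expect_equal(nc$callable_fraction, 0)

    ## covered in one of two replicates -> plain low coverage
    nc2 <- labelNoCallTargets(list(rep1, rep2), tg, callerParams())
    expect_equal(nc2$reason, "low_coverage")

    ## low-GC dropout is low_coverage even when reproducible
    tg_low <- readTargets("chr1\t100\t110\tX\t0.40")
    nc3 <- labelNoCallTargets(list(rep1, rep1), tg_low, callerParams())
    expect_equal(nc3$reason, "low_coverage")

    ## fully covered targets are not reported
    expect_equal(nrow(labelNoCallTargets(list(rep2), tg[3], callerParams())),
                 0L)
})
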