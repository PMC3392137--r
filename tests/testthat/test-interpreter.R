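kb_lines <- c(
    "gene\tvariant_key\tclassification\tnote",
    "CFTR\tchr7:117199644:G>A\tpathogenic\tcommon severe allele",
    "CFTR\tchr7:117227792:A>G\tpathogenic\t",
    "GALT\tchr9:34648167:C>T\tpathogenic\t",
    "HEXA\tchr15:72638892:T>C\tbenign_common\tcommon polymorphism",
    "DMD\tchrX:31496398:G>T\tpathogenic\t",
    "LAMB3\tLAMB3:del01\tpathogenic\tknown gross deletion",
    "GALT\tchr9:34646000:G>A\tmisannotated\tliterature allele incorrect")

mk_call <- function(chrom, pos, ref, alt, zyg)
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               zygosity = zyg, stringsAsFactors = FALSE)

test_that("knowledge-base lookup classifies exact keys and leaves VUS", {
    kb <- readKnowledgeBase(kb_lines)
    calls <- rbind(mk_call("chr7", 117199644L, "G", "A", "het"),
                   mk_call("chr7", 1L, "G", "A", "het"),
                   mk_call("chr15", 72638892L, "T", "C", "hom"))
    cl <- classifyVariants(calls, kb)
    expect_equal(cl$classification, c("pathogenic", "vus", "benign_common"))
    expect_equal(cl$gene_symbol[1], "CFTR")
    expect_true(is.na(cl$gene_symbol[2]))          # VUS without gene map
    expect_error(readKnowledgeBase(c("h\tk\tc", "G1\tk1\tweird")),
                 "classification")
    expect_error(readKnowledgeBase(c("h\tk\tc", "G1\tk1\tpathogenic",
                                     "G2\tk1\tpathogenic")), "duplicate")
})

test_that("genotype assembly follows the recessive rule table", {
    panel <- loadPanel(mini_panel_lines)
    kb <- readKnowledgeBase(kb_lines)
    two_het_cftr <- classifyVariants(
        rbind(mk_call("chr7", 117199644L, "G", "A", "het"),
              mk_call("chr7", 117227792L, "A", "G", "het")), kb)
    g <- assembleGenotypes(two_het_cftr, panel)
    expect_equal(g$status[g$omim_id == 219700],
                 "affected_presumed_compound_het")

    one_galt <- classifyVariants(mk_call("chr9", 34648167L, "C", "T", "het"),
                                 kb)
    g2 <- assembleGenotypes(one_galt, panel)
    expect_equal(g2$status[g2$omim_id == 230400], "carrier")
    expect_equal(g2$status[g2$omim_id == 219700], "negative")

    hom_galt <- classifyVariants(mk_call("chr9", 34648167L, "C", "T", "hom"),
                                 kb)
    expect_equal(assembleGenotypes(hom_galt, panel)$status[
        g2$omim_id == 230400], "affected_hom")

    ## benign_common variants never contribute
    benign <- classifyVariants(mk_call("chr15", 72638892L, "T", "C", "hom"),
                               kb)
    g3 <- assembleGenotypes(benign, panel)
    expect_equal(g3$status[g3$omim_id == 272800], "negative")
})

test_that("X-linked hemizygote logic keys on sex", {
    panel <- loadPanel(mini_panel_lines)
    kb <- readKnowledgeBase(kb_lines)
    dmd <- classifyVariants(mk_call("chrX", 31496398L, "G", "T", "het"), kb)
    row_of <- function(g) which(g$gene_symbol == "DMD")
    male <- assembleGenotypes(dmd, panel, sex = "male")
    expect_equal(male$status[row_of(male)], "affected_hemizygous")
    female <- assembleGenotypes(dmd, panel, sex = "female")
    expect_equal(female$status[row_of(female)], "carrier")
    unk <- assembleGenotypes(dmd, panel, sex = "unknown")
    expect_equal(unk$status[row_of(unk)], "carrier")
    expect_match(unk$flag[row_of(unk)], "xl_sex_unknown")
})

test_that("VUS alongside one pathogenic het flags review, never affected", {
    panel <- loadPanel(mini_panel_lines)
    kb <- readKnowledgeBase(kb_lines)
    mixed <- classifyVariants(
        rbind(mk_call("chr9", 34648167L, "C", "T", "het"),
              mk_call("chr9", 34648200L, "G", "A", "het")), kb)
    mixed$gene_symbol[2] <- "GALT"                 # VUS mapped to same gene
    g <- assembleGenotypes(mixed, panel)
    row <- g[g$omim_id == 230400, ]
    expect_equal(row$status, "carrier")
    expect_match(row$flag, "possible_compound_het_review")
})

test_that("variants in non-panel genes warn and are ignored; no-call genes are indeterminate", {
    panel <- loadPanel(mini_panel_lines)
    kb <- readKnowledgeBase(c("gene\tkey\tclass",
                              "BRCA1\tchr17:1:G>A\tpathogenic"))
    odd <- classifyVariants(mk_call("chr17", 1L, "G", "A", "het"), kb)
    expect_warning(g <- assembleGenotypes(odd, panel), "BRCA1")
    expect_true(all(g$status == "negative"))
    g2 <- assembleGenotypes(odd[0, ], panel, indeterminateGenes = "HEXA")
    expect_equal(g2$status[g2$gene_symbol == "HEXA"], "indeterminate")
    expect_equal(sum(g2$status == "indeterminate"), 1L)
})

test_that("carrier reports all findings; diagnostic masks non-relevant genes", {
    panel <- loadPanel(mini_panel_lines)
    kb <- readKnowledgeBase(kb_lines)
    cl <- classifyVariants(
        rbind(mk_call("chr9", 34648167L, "C", "T", "het"),   # GALT carrier
              mk_call("chr7", 117199644L, "G", "A", "het")), # CFTR carrier
        kb)
    g <- assembleGenotypes(cl, panel)

    carrier <- makeReport(g, "carrier", sampleId = "s1")
    expect_equal(nrow(carrier@results), 2L)
    expect_equal(carrier@suppressedCount, 0L)
    expect_setequal(carrier@results$gene_symbol, c("GALT", "CFTR"))

    relevant <- genesForPhenotype(panel, 230400L)  # {GALT}
    diag <- makeReport(g, "diagnostic", relevant, sampleId = "s1")
    expect_equal(diag@results$gene_symbol, "GALT") # CFTR row suppressed
    expect_equal(diag@suppressedCount, 1L)

    ## negative relevant gene is still reported explicitly
    none <- assembleGenotypes(cl[0, ], panel)
    diag0 <- makeReport(none, "diagnostic", relevant)
    expect_equal(diag0@results$status, "negative")
    expect_equal(diag0@results$gene_symbol, "GALT")

    expect_error(makeReport(g, "diagnostic", character()), "non-empty")
})

test_that("diagnostic and carrier reports agree on relevant genes", {
    panel <- loadPanel(mini_panel_lines)
    kb <- readKnowledgeBase(kb_lines)
    cl <- classifyVariants(
        rbind(mk_call("chr9", 34648167L, "C", "T", "hom"),
              mk_call("chr7", 117199644L, "G", "A", "het")), kb)
    g <- assembleGenotypes(cl, panel)
    carrier <- makeReport(g, "carrier")
    diag <- makeReport(g, "diagnostic", "GALT")
    in_both <- carrier@results[carrier@results$gene_symbol == "GALT", ]
    rownames(in_both) <- NULL
    only_pos <- diag@results[diag@results$status != "negative", ]
    rownames(only_pos) <- NULL
    expect_equal(in_both, only_pos)
})

test_that("suppression conserves findings over random genotype sets", {
    panel <- loadPanel(mini_panel_lines)
    statuses <- c("negative", "carrier", "affected_hom",
                  "affected_presumed_compound_het", "indeterminate")
    set.seed(99)
    genes <- panelEntries(panel)$gene_symbol
    for (i in 1:1000) {
        g <- data.frame(
            omim_id = panelEntries(panel)$omim_id,
            disease_name = panelEntries(panel)$disease_name,
            gene_symbol = genes,
            status = sample(statuses, length(genes), replace = TRUE),
            flag = "", supporting_variants = "", stringsAsFactors = FALSE)
        rel <- sample(unique(genes), sample(1:4, 1))
        rep_ <- makeReport(g, "diagnostic", rel)
        total_nonneg <- sum(g$status != "negative")
        reported_nonneg <- sum(rep_@results$status != "negative")
        expect_identical(rep_@suppressedCount + reported_nonneg,
                         as.integer(total_nonneg))
    }
})

test_that("report text and list rendering carry the masking summary", {
    panel <- loadPanel(mini_panel_lines)
    g <- assembleGenotypes(
        data.frame(chrom = "chr9", pos = 34648167L, ref = "C", alt = "T",
                   zygosity = "het", variant_key = "chr9:34648167:C>T",
                   classification = "pathogenic", gene_symbol = "GALT",
                   stringsAsFactors = FALSE), panel)
    rep_ <- makeReport(g, "carrier", sampleId = "sX")
    txt <- formatReport(rep_)
    expect_match(txt[1], "carrier report - sample sX")
    expect_true(any(grepl("GALACTOSEMIA\tGALT\tcarrier", txt)))
    lst <- reportAsList(rep_)
    expect_equal(lst$mode, "carrier")
    expect_equal(lst$suppressed_count, 0L)
})
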