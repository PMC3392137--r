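## Variant classification against the mutation knowledge base,
## per-disease genotype assembly, and carrier/diagnostic reporting.

#' Read a mutation knowledge base
#'
#' Parses a tab-delimited knowledge base with a header row and columns
#' gene symbol, variant key, classification and an optional free-text
#' note. Variant keys are \code{chrom:pos:ref>alt} for small variants
#' and the junction allele id for gross deletions. Classifications are
#' \code{pathogenic}, \code{benign_common} (known common polymorphism)
#' or \code{misannotated} (literature annotation found incorrect or
#' incomplete).
#'
#' @param file path or character vector of lines.
#' @return \code{data.frame} with columns \code{gene_symbol},
#'   \code{variant_key}, \code{classification}, \code{note}.
#' @export
readKnowledgeBase <- function(file) {
    lines <- if (length(file) == 1L && file.exists(file))
        readLines(file, warn = FALSE) else as.character(file)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) <= 1L)
        return(data.frame(gene_symbol = character(),
                          variant_key = character(),
                          classification = character(), note = character(),
                          stringsAsFactors = FALSE))
    fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
    n <- vapply(fields, length, integer(1L))
    if (any(n < 3L))
        stop("knowledge base row ", which(n < 3L)[1L] + 1L,
             " needs >= 3 columns")
    kb <- data.frame(
        gene_symbol = vapply(fields, `[[`, character(1L), 1L),
        variant_key = vapply(fields, `[[`, character(1L), 2L),
        classification = vapply(fields, `[[`, character(1L), 3L),
        note = vapply(fields, function(f)
            if (length(f) >= 4L) f[[4L]] else "", character(1L)),
        stringsAsFactors = FALSE)
    if (!all(kb$classification %in% c("pathogenic", "benign_common",
                                      "misannotated")))
        stop("classification must be pathogenic, benign_common or misannotated")
    if (anyDuplicated(kb$variant_key))
        stop("duplicate variant_key in knowledge base: ",
             kb$variant_key[duplicated(kb$variant_key)][1L])
    kb
}

#' Variant key of a call
#'
#' \code{chrom:pos:ref>alt} for small-variant calls; deletion calls are
#' keyed by their junction allele id.
#'
#' @param calls \code{data.frame} of calls.
#' @return character vector of keys.
#' @export
variantKey <- function(calls) {
    if ("allele_id" %in% names(calls) && !"alt" %in% names(calls))
        return(calls$allele_id)
    paste0(calls$chrom, ":", calls$pos, ":", calls$ref, ">", calls$alt)
}

#' Classify calls against the knowledge base
#'
#' An exact variant-key match returns the stored classification; any
#' call absent from the knowledge base is a variant of uncertain
#' significance (\code{vus}). Small-variant calls also need a
#' \code{gene_symbol} mapping, taken from the knowledge base entry when
#' matched or from an optional \code{targets} overlap otherwise.
#'
#' @param calls \code{data.frame} of variant or deletion calls.
#' @param kb knowledge base from [readKnowledgeBase()].
#' @param targets optional \code{GRanges} with \code{gene_symbol} used
#'   to annotate unmatched calls with their gene.
#' @return the calls with added \code{variant_key},
#'   \code{classification} and \code{gene_symbol} columns.
#' @export
classifyVariants <- function(calls, kb, targets = NULL) {
    if (!nrow(calls)) {
        calls$variant_key <- character(0)
        calls$classification <- character(0)
        if (!"gene_symbol" %in% names(calls))
            calls$gene_symbol <- character(0)
        return(calls)
    }
    key <- variantKey(calls)
    idx <- match(key, kb$variant_key)
    cls <- ifelse(is.na(idx), "vus", kb$classification[idx])
    gene <- if ("gene_symbol" %in% names(calls)) calls$gene_symbol
        else rep(NA_character_, nrow(calls))
    gene[!is.na(idx)] <- kb$gene_symbol[idx[!is.na(idx)]]
    if (!is.null(targets) && any(is.na(gene)) && "pos" %in% names(calls)) {
        need <- which(is.na(gene))
        q <- GenomicRanges::GRanges(calls$chrom[need],
                                    IRanges::IRanges(calls$pos[need],
                                                     calls$pos[need]))
        ov <- GenomicRanges::findOverlaps(q, targets, ignore.strand = TRUE)
        gene[need[S4Vectors::queryHits(ov)]] <-
            GenomicRanges::mcols(targets)$gene_symbol[S4Vectors::subjectHits(ov)]
    }
    calls$variant_key <- key
    calls$classification <- cls
    calls$gene_symbol <- gene
    calls
}

.genotype_status <- function(zygs, inheritance, sex, n_vus_het) {
    n_hom <- sum(zygs == "hom")
    n_het <- sum(zygs == "het")
    flag <- ""
    if (n_hom >= 1L) {
        status <- if (inheritance == "XL" && sex == "male")
            "affected_hemizygous" else "affected_hom"
    } else if (inheritance == "XL" && sex == "male" && n_het >= 1L) {
        ## a single pathogenic allele on the X is hemizygous in males
        status <- "affected_hemizygous"
    } else if (n_het >= 2L) {
        status <- "affected_presumed_compound_het"
    } else if (n_het == 1L) {
        status <- "carrier"
        if (inheritance == "XL" && sex == "unknown")
            flag <- "xl_sex_unknown"
        if (n_vus_het >= 1L)
            flag <- paste0(flag, if (nzchar(flag)) ";" else "",
                           "possible_compound_het_review")
    } else {
        status <- "negative"
    }
    list(status = status, flag = flag)
}

#' Assemble per-disease genotypes
#'
#' Combines the pathogenic variant calls in each panel gene into a
#' disease-level status: homozygous pathogenic (including homozygous
#' gross deletions) gives \code{affected_hom}; two or more distinct
#' heterozygous pathogenic variants give
#' \code{affected_presumed_compound_het} (phase is unknown, hence
#' presumed); exactly one heterozygous pathogenic variant gives
#' \code{carrier} for autosomal genes and X-linked females, and
#' \code{affected_hemizygous} for X-linked genes in males; genes with no
#' pathogenic variant are \code{negative}, or \code{indeterminate} when
#' wholly uncallable. Only \code{pathogenic} classifications contribute;
#' \code{benign_common} and \code{misannotated} variants are excluded
#' (the latter surfaced separately in the report appendix) and VUS never
#' produce affected status — one pathogenic plus one VUS heterozygote
#' stays \code{carrier} with a review flag.
#'
#' @param classified classified calls from [classifyVariants()] (must
#'   carry \code{gene_symbol}, \code{zygosity}, \code{classification}).
#' @param panel a [Panel-class].
#' @param sex \code{"male"}, \code{"female"} or \code{"unknown"};
#'   drives hemizygote logic for X-linked genes.
#' @param indeterminateGenes genes wholly no-call, reported
#'   \code{indeterminate} instead of \code{negative}.
#' @return \code{data.frame} with one row per panel (disease, gene):
#'   \code{omim_id}, \code{disease_name}, \code{gene_symbol},
#'   \code{status}, \code{flag}, \code{supporting_variants}
#'   (';'-separated keys).
#' @export
assembleGenotypes <- function(classified, panel,
                              sex = c("unknown", "male", "female"),
                              indeterminateGenes = character()) {
    sex <- match.arg(sex)
    e <- panelEntries(panel)
    if (nrow(classified)) {
        unknown <- !is.na(classified$gene_symbol) &
            !(classified$gene_symbol %in% e$gene_symbol)
        if (any(unknown))
            warning("ignoring variant(s) in gene(s) absent from panel: ",
                    paste(unique(classified$gene_symbol[unknown]),
                          collapse = ", "))
    }
    out <- vector("list", nrow(e))
    for (i in seq_len(nrow(e))) {
        g <- e$gene_symbol[i]
        in_gene <- if (nrow(classified))
            !is.na(classified$gene_symbol) & classified$gene_symbol == g
        else logical(0)
        path <- classified[in_gene & classified$classification == "pathogenic", ,
                           drop = FALSE]
        n_vus_het <- sum(in_gene & classified$classification == "vus" &
                         classified$zygosity == "het", na.rm = TRUE)
        if (g %in% indeterminateGenes && !nrow(path)) {
            st <- list(status = "indeterminate", flag = "")
        } else {
            st <- .genotype_status(path$zygosity, e$inheritance[i], sex,
                                   n_vus_het)
        }
        out[[i]] <- data.frame(
            omim_id = e$omim_id[i], disease_name = e$disease_name[i],
            gene_symbol = g, status = st$status, flag = st$flag,
            supporting_variants = paste(variantKey(path), collapse = ";"),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Build a carrier or diagnostic report
#'
#' Carrier mode reports every non-negative disease genotype and
#' summarizes the remaining genes as negative; nothing is suppressed.
#' Diagnostic mode reports every status — positive and negative — for
#' diseases whose gene is relevant to the clinical presentation, and
#' suppresses (but counts) non-negative findings in non-relevant genes;
#' it requires a non-empty relevant gene set.
#'
#' @param genotypes disease genotypes from [assembleGenotypes()].
#' @param mode \code{"carrier"} or \code{"diagnostic"}.
#' @param relevantGenes character vector of phenotype-relevant genes
#'   (diagnostic mode; see [genesForPhenotype()]).
#' @param sampleId sample identifier.
#' @param appendix optional \code{data.frame} of misannotated-variant
#'   findings surfaced without contributing to genotypes.
#' @return a [Report-class].
#' @export
makeReport <- function(genotypes, mode = c("carrier", "diagnostic"),
                       relevantGenes = character(), sampleId = "sample",
                       appendix = NULL) {
    mode <- match.arg(mode)
    if (is.null(appendix))
        appendix <- data.frame(variant_key = character(),
                               gene_symbol = character(),
                               note = character(), stringsAsFactors = FALSE)
    nonneg <- genotypes$status != "negative"
    if (mode == "carrier") {
        res <- genotypes[nonneg, , drop = FALSE]
        rownames(res) <- NULL
        return(new("Report", sampleId = sampleId, mode = "carrier",
                   relevantGenes = character(), results = res,
                   suppressedCount = 0L,
                   negativeGeneCount = length(unique(
                       genotypes$gene_symbol[!nonneg])),
                   appendix = appendix))
    }
    if (!length(relevantGenes))
        stop("diagnostic mode requires a non-empty relevant gene set")
    relevant <- genotypes$gene_symbol %in% relevantGenes
    res <- genotypes[relevant, , drop = FALSE]
    rownames(res) <- NULL
    suppressed <- sum(nonneg & !relevant)
    new("Report", sampleId = sampleId, mode = "diagnostic",
        relevantGenes = unique(relevantGenes), results = res,
        suppressedCount = as.integer(suppressed), negativeGeneCount = 0L,
        appendix = appendix)
}

#' Render a report as text
#'
#' @param report a [Report-class].
#' @return character vector of report lines.
#' @export
formatReport <- function(report) {
    r <- report@results
    lines <- c(sprintf("# recesscan %s report - sample %s", report@mode,
                       report@sampleId))
    if (report@mode == "diagnostic")
        lines <- c(lines, sprintf("# genes relevant to presentation: %s",
                                  paste(report@relevantGenes, collapse = ", ")))
    if (nrow(r))
        lines <- c(lines, sprintf("%d\t%s\t%s\t%s%s\t%s", r$omim_id,
                                  r$disease_name, r$gene_symbol, r$status,
                                  ifelse(nzchar(r$flag),
                                         paste0(" [", r$flag, "]"), ""),
                                  r$supporting_variants))
    else lines <- c(lines, "# no reportable findings")
    if (report@mode == "carrier")
        lines <- c(lines, sprintf("# %d additional gene(s) negative",
                                  report@negativeGeneCount))
    else
        lines <- c(lines, sprintf(
            "# %d finding(s) in non-relevant genes not reported",
            report@suppressedCount))
    if (nrow(report@appendix))
        lines <- c(lines, "# appendix: knowledge-base entries flagged misannotated",
                   sprintf("# %s (%s): %s", report@appendix$variant_key,
                           report@appendix$gene_symbol, report@appendix$note))
    lines
}

#' Report as a plain list (for JSON serialization)
#'
#' @param report a [Report-class].
#' @return a named list mirroring the report slots.
#' @export
reportAsList <- function(report) {
    list(sample_id = report@sampleId, mode = report@mode,
         relevant_genes = report@relevantGenes, results = report@results,
         suppressed_count = report@suppressedCount,
         negative_gene_count = report@negativeGeneCount,
         appendix = report@appendix)
}

setMethod("show", "Report", function(object) {
    cat(formatReport(object), sep = "\n")
})
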