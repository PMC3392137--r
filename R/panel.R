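## Panel registry: load, validate and query the disease-gene table.

.split_panel_row <- function(line) {
    ## tab first, else runs of >= 2 spaces, else single-space split with
    ## OMIM as first token and the gene symbol as the last
    if (grepl("\t", line)) {
        f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    } else if (grepl("  +", line)) {
        f <- strsplit(line, " {2,}")[[1L]]
    } else {
        tok <- strsplit(trimws(line), " +")[[1L]]
        if (length(tok) < 3L) return(tok)
        inh <- if (tok[length(tok)] %in% c("AR", "XL") && length(tok) > 3L) {
            i <- tok[length(tok)]; tok <- tok[-length(tok)]; i
        } else NULL
        f <- c(tok[1L], paste(tok[-c(1L, length(tok))], collapse = " "),
               tok[length(tok)], inh)
    }
    trimws(f)
}

#' Load a disease-gene panel
#'
#' Reads a delimiter-separated panel table with a header row and columns
#' OMIM accession, disease name, gene symbol, and an optional fourth
#' inheritance column (\code{AR} or \code{XL}; missing values default to
#' autosomal recessive). Rows may be tab-delimited or aligned with runs
#' of two or more spaces; as a last resort single-space rows are split
#' with the accession first and the gene symbol last. Exact duplicate
#' rows are collapsed; input order is preserved.
#'
#' @param file path to the panel file, or a character vector of lines.
#' @param versionLabel free-text label stored on the returned object.
#' @return a [Panel-class] object.
#' @examples
#' p <- loadPanel(c("OMIM#\tNAME\tGENE",
#'                  "219700\tCYSTIC FIBROSIS; CF\tCFTR",
#'                  "230400\tGALACTOSEMIA\tGALT"))
#' countDiseases(p)
#' @export
loadPanel <- function(file, versionLabel = "research-448") {
    lines <- if (length(file) == 1L && file.exists(file))
        readLines(file, warn = FALSE) else as.character(file)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 1L) stop("empty panel")
    lines <- lines[-1L]                   # header row required
    if (!length(lines)) stop("empty panel")
    fields <- lapply(lines, .split_panel_row)
    n <- vapply(fields, length, integer(1L))
    if (any(n < 3L))
        stop("malformed panel row (need >= 3 columns) at line ",
             which(n < 3L)[1L] + 1L)
    omim_chr <- vapply(fields, `[[`, character(1L), 1L)
    bad <- !grepl("^[0-9]+$", omim_chr)
    if (any(bad))
        stop("malformed OMIM field '", omim_chr[bad][1L], "' at line ",
             which(bad)[1L] + 1L)
    entries <- data.frame(
        omim_id = as.integer(omim_chr),
        disease_name = vapply(fields, `[[`, character(1L), 2L),
        gene_symbol = vapply(fields, `[[`, character(1L), 3L),
        inheritance = vapply(fields, function(f)
            if (length(f) >= 4L && nzchar(f[[4L]])) f[[4L]] else "AR",
            character(1L)),
        stringsAsFactors = FALSE)
    key <- paste(entries$omim_id, entries$disease_name, entries$gene_symbol,
                 sep = "\r")
    entries <- entries[!duplicated(key), , drop = FALSE]
    rownames(entries) <- NULL
    new("Panel", entries = entries, versionLabel = versionLabel)
}

#' Write a panel back to delimiter-separated text
#'
#' Serializes a [Panel-class] as a tab-delimited table with header, the
#' exact inverse of [loadPanel()] (load-write-load round trips to an
#' identical panel).
#'
#' @param panel a [Panel-class].
#' @param file output path; with \code{file = NULL} the lines are
#'   returned invisibly instead of written.
#' @return invisibly, the text lines.
#' @export
writePanel <- function(panel, file = NULL) {
    stopifnot(is(panel, "Panel"))
    e <- panelEntries(panel)
    lines <- c("OMIM#\tNAME\tGENE\tINHERITANCE",
               paste(e$omim_id, e$disease_name, e$gene_symbol, e$inheritance,
                     sep = "\t"))
    if (!is.null(file)) writeLines(lines, file)
    invisible(lines)
}

#' Panel accessors and summaries
#'
#' \code{panelEntries} returns the entry table; \code{countUniqueGenes}
#' the number of distinct gene symbols; \code{countDiseases} the number
#' of distinct (OMIM accession, disease name) pairs — the convention
#' under which one accession printed with several clinically distinct
#' sub-entries counts once per distinct name, while one disease served
#' by several genes counts once.
#'
#' @param panel a [Panel-class].
#' @return \code{panelEntries}: a \code{data.frame}; the counts: a
#'   single integer.
#' @export
panelEntries <- function(panel) {
    stopifnot(is(panel, "Panel"))
    panel@entries
}

#' @rdname panelEntries
#' @export
countUniqueGenes <- function(panel)
    length(unique(panelEntries(panel)$gene_symbol))

#' @rdname panelEntries
#' @export
countDiseases <- function(panel) {
    e <- panelEntries(panel)
    nrow(unique(e[, c("omim_id", "disease_name")]))
}

#' Genes implicated by a set of diseases
#'
#' Maps OMIM accessions to the union of their panel genes; used by
#' diagnostic-mode reporting to derive the phenotype-relevant gene set.
#'
#' @param panel a [Panel-class].
#' @param relevantOmimIds integer vector of OMIM accessions, all of
#'   which must exist in the panel.
#' @return character vector of gene symbols (sorted, unique).
#' @export
genesForPhenotype <- function(panel, relevantOmimIds) {
    e <- panelEntries(panel)
    ids <- unique(as.integer(relevantOmimIds))
    if (!length(ids)) return(character())
    missing <- setdiff(ids, e$omim_id)
    if (length(missing))
        stop("OMIM accession(s) not in panel: ",
             paste(missing, collapse = ", "))
    sort(unique(e$gene_symbol[e$omim_id %in% ids]))
}

#' Merge two panels
#'
#' Concatenates entries, collapsing exact duplicates while preserving
#' first-occurrence order; equivalent to loading the concatenated files.
#'
#' @param x,y [Panel-class] objects.
#' @return a [Panel-class] labelled after \code{x}.
#' @export
mergePanels <- function(x, y) {
    stopifnot(is(x, "Panel"), is(y, "Panel"))
    e <- rbind(panelEntries(x), panelEntries(y))
    key <- paste(e$omim_id, e$disease_name, e$gene_symbol, sep = "\r")
    e <- e[!duplicated(key), , drop = FALSE]
    rownames(e) <- NULL
    new("Panel", entries = e, versionLabel = x@versionLabel)
}

setMethod("show", "Panel", function(object) {
    cat("Panel '", object@versionLabel, "': ",
        nrow(object@entries), " entries, ",
        countDiseases(object), " diseases, ",
        countUniqueGenes(object), " genes\n", sep = "")
})
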