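#' Read a log2 expression matrix from TSV
#'
#' Reads a genes x samples table whose first column holds gene identifiers
#' and whose header row holds sample identifiers. Two dialects are
#' supported: plain TSV, and the GEO series-matrix dialect in which metadata
#' lines start with `!` and the expression table sits between the
#' `!series_matrix_table_begin` and `!series_matrix_table_end` markers.
#'
#' Values are assumed to be already normalised and log2-transformed; if more
#' than 1% of values exceed 30 a warning suggests the input may be on the
#' linear scale. Row order and column order are preserved exactly as read.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"geo"` for the series-matrix dialect.
#' @param missing Policy for missing cells: `"reject"` (default, error) or
#'   `"drop"` (drop genes with any missing value, with a message).
#' @param assumeLog2 If `TRUE` (default) run the linear-scale heuristic
#'   warning.
#' @return Numeric matrix with gene ids as rownames, sample ids as colnames.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "G1\t1.5\t2", "G2\t8\t7.5"), f)
#' readExpressionTsv(f)
readExpressionTsv <- function(path, dialect = c("tsv", "geo"),
                              missing = c("reject", "drop"),
                              assumeLog2 = TRUE) {
    dialect <- match.arg(dialect)
    missing <- match.arg(missing)
    if (!file.exists(path))
        stop("expression file not found: ", path)
    lines <- readLines(path)
    if (dialect == "geo") {
        beg <- grep("^!series_matrix_table_begin", lines)
        end <- grep("^!series_matrix_table_end", lines)
        if (length(beg) == 1L && length(end) == 1L && end > beg + 1L) {
            lines <- lines[(beg + 1L):(end - 1L)]
        } else {
            lines <- lines[!startsWith(lines, "!")]
        }
        lines <- gsub("\"", "", lines, fixed = TRUE)
    }
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L)
        stop("expression file has no data rows: ", path)
    # sentinel keeps trailing empty cells (strsplit drops them otherwise)
    fields <- lapply(strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE),
        function(f) f[-length(f)])
    header <- fields[[1L]]
    sampleIds <- header[-1L]
    if (anyDuplicated(sampleIds))
        stop("duplicate sample id in header: ",
             sampleIds[duplicated(sampleIds)][1L])
    body <- fields[-1L]
    nc <- lengths(body)
    if (any(nc != length(header)))
        stop("ragged row at line ", which(nc != length(header))[1L] + 1L)
    geneIds <- vapply(body, `[[`, character(1), 1L)
    if (anyDuplicated(geneIds))
        stop("duplicate gene id: ", geneIds[duplicated(geneIds)][1L])
    raw <- t(vapply(body, function(f) f[-1L],
                    character(length(sampleIds))))
    if (length(sampleIds) == 1L) raw <- matrix(raw, ncol = 1L)
    vals <- suppressWarnings(matrix(as.numeric(raw), nrow = length(geneIds)))
    bad <- !is.finite(vals) & !(raw %in% c("", "NA", "na", "NaN"))
    if (any(bad)) {
        idx <- which(bad, arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
            geneIds[idx[1L]], sampleIds[idx[2L]], raw[idx[1L], idx[2L]]))
    }
    miss <- !is.finite(vals)
    if (any(miss)) {
        if (missing == "reject") {
            idx <- which(miss, arr.ind = TRUE)[1L, ]
            stop(sprintf(
                "missing value at gene '%s', sample '%s' (policy: reject)",
                geneIds[idx[1L]], sampleIds[idx[2L]]))
        }
        keep <- rowSums(miss) == 0L
        message(sum(!keep), " genes with missing values dropped")
        vals <- vals[keep, , drop = FALSE]
        geneIds <- geneIds[keep]
    }
    dimnames(vals) <- list(geneIds, sampleIds)
    if (assumeLog2 && mean(vals > 30) > 0.01)
        warning(">1% of values exceed 30; input may be linear-scale, ",
                "not log2")
    message(sprintf("read expression matrix: %d genes x %d samples",
        nrow(vals), ncol(vals)))
    vals
}

#' Write an expression matrix as plain TSV
#'
#' Writes the companion format of [readExpressionTsv()]: first column
#' `gene_id`, header of sample ids, values at 6 significant digits, UTF-8,
#' tab-separated, Unix newlines.
#'
#' @param mat Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeExpressionTsv <- function(mat, path) {
    stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
    body <- apply(mat, 1L, function(v)
        paste(formatC(v, digits = 6, format = "g"), collapse = "\t"))
    writeLines(paste(rownames(mat), body, sep = "\t"), con)
    invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet is a TSV with columns `sample_id`, `group`, `case_id`
#' (extra covariate columns such as age or post-mortem delay are carried
#' through untouched). Group labels must come from [msGroups()]; a case id
#' may appear at most once per group (one GML and one NAGM array per MS
#' case).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with at least the three required columns.
#' @export
readSampleSheet <- function(path) {
    sheet <- read.delim(path, colClasses = "character",
        check.names = FALSE, stringsAsFactors = FALSE)
    req <- c("sample_id", "group", "case_id")
    if (!all(req %in% names(sheet)))
        stop("sample sheet must have columns: ",
             paste(req, collapse = ", "))
    validateSampleSheet(sheet)
    tab <- table(factor(sheet$group, levels = msGroups()))
    message("sample sheet groups: ",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
    sheet
}

validateSampleSheet <- function(sheet) {
    if (anyDuplicated(sheet$sample_id))
        stop("duplicate sample_id: ",
             sheet$sample_id[duplicated(sheet$sample_id)][1L])
    bad <- setdiff(unique(sheet$group), msGroups())
    if (length(bad))
        stop("unknown group label(s): ", paste(bad, collapse = ", "),
             "; allowed: ", paste(msGroups(), collapse = ", "))
    dup <- duplicated(sheet[, c("group", "case_id")])
    if (any(dup))
        stop(sprintf("case_id '%s' appears more than once in group '%s'",
            sheet$case_id[dup][1L], sheet$group[dup][1L]))
    invisible(sheet)
}

#' Write a sample sheet as TSV
#'
#' @param sheet Data frame with columns `sample_id`, `group`, `case_id`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSampleSheet <- function(sheet, path) {
    validateSampleSheet(sheet)
    write.table(sheet, path, sep = "\t", quote = FALSE,
        row.names = FALSE, eol = "\n")
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each GMT line holds a set name, a description, and tab-separated member
#' ids. Empty sets are rejected; lines with fewer than three fields raise a
#' parse error naming the line.
#'
#' @param path Path to the GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("GMT line ", short[1L], " has fewer than 3 fields")
    nm <- vapply(fields, `[[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop("duplicate gene set name: ", nm[duplicated(nm)][1L])
    desc <- vapply(fields, `[[`, character(1), 2L)
    sets <- lapply(fields, function(f) {
        members <- f[-(1:2)]
        members[nzchar(members)]
    })
    if (any(lengths(sets) == 0L))
        stop("empty gene set: ", nm[lengths(sets) == 0L][1L])
    names(sets) <- nm
    names(desc) <- nm
    GeneSetCollection(sets, desc)
}

#' Write a GeneSetCollection as GMT
#'
#' @param gsc A [GeneSetCollection-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGmt <- function(gsc, path) {
    stopifnot(is(gsc, "GeneSetCollection"))
    lines <- vapply(names(gsc), function(nm)
        paste(c(nm, gsc@descriptions[[nm]], gsc@sets[[nm]]),
              collapse = "\t"),
        character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}

#' Resolve gene-set members against an expression matrix
#'
#' Intersects each set with the available gene identifiers, preserving
#' member order, and reports (rather than silently dropping) unresolvable
#' members. Sets falling below `minSetSize` resolved members are moved to
#' the `skipped` list.
#'
#' @param gsc A [GeneSetCollection-class].
#' @param geneIds Character vector of available gene ids (e.g.
#'   `rownames(se)`).
#' @param minSetSize Minimum resolved size to keep a set (default 3).
#' @return List with `resolved` (named list of member vectors), `skipped`
#'   (names of sets below the minimum size), and `unresolved` (named integer
#'   count of absent members per set).
#' @export
resolveGeneSets <- function(gsc, geneIds, minSetSize = 3L) {
    stopifnot(is(gsc, "GeneSetCollection"))
    resolved <- lapply(gsc@sets, function(m) m[m %in% geneIds])
    unresolved <- lengths(gsc@sets) - lengths(resolved)
    if (any(unresolved > 0L))
        message(sum(unresolved), " gene-set members unresolvable against ",
                "the matrix (", sum(unresolved > 0L), " sets affected)")
    keep <- lengths(resolved) >= minSetSize
    list(resolved = resolved[keep],
         skipped = names(resolved)[!keep],
         unresolved = unresolved)
}

#' Assemble a SummarizedExperiment from matrix and sample sheet
#'
#' Pairs a log2 expression matrix with its sample sheet, enforcing that the
#' sample ids match exactly (the sheet is aligned to the matrix column
#' order, which is never changed).
#'
#' @param mat Numeric genes x samples matrix with dimnames.
#' @param sheet Sample sheet data frame (see [readSampleSheet()]).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"log2"` and colData columns `group` (factor over [msGroups()]) and
#'   `case_id`.
#' @export
#' @examples
#' mat <- matrix(rnorm(12, 8), 3, 4,
#'     dimnames = list(paste0("G", 1:3), paste0("s", 1:4)))
#' sheet <- data.frame(sample_id = paste0("s", 1:4),
#'     group = c("CTRL", "CTRL", "FPOS_GML", "FNEG_GML"),
#'     case_id = c("C1", "C2", "P1", "N1"))
#' msExperiment(mat, sheet)
msExperiment <- function(mat, sheet) {
    stopifnot(is.matrix(mat), is.numeric(mat))
    if (is.null(rownames(mat)) || is.null(colnames(mat)))
        stop("expression matrix needs gene rownames and sample colnames")
    if (!all(is.finite(mat)))
        stop("expression matrix contains non-finite values")
    validateSampleSheet(sheet)
    if (!setequal(colnames(mat), sheet$sample_id) ||
        ncol(mat) != nrow(sheet))
        stop("sample ids of matrix and sheet must match exactly")
    sheet <- sheet[match(colnames(mat), sheet$sample_id), , drop = FALSE]
    cd <- S4Vectors::DataFrame(
        group = factor(sheet$group, levels = msGroups()),
        case_id = sheet$case_id,
        row.names = sheet$sample_id)
    extra <- setdiff(names(sheet), c("sample_id", "group", "case_id"))
    for (col in extra) cd[[col]] <- sheet[[col]]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = mat), colData = cd)
}

#' Group labels of a SummarizedExperiment built by msExperiment
#'
#' @param se A `SummarizedExperiment` with a `group` colData column.
#' @return Factor of group labels, one per sample.
#' @export
sampleGroups <- function(se) {
    grp <- SummarizedExperiment::colData(se)$group
    if (is.null(grp)) stop("no 'group' column in colData")
    grp
}

#' Case (donor) identifiers of a SummarizedExperiment
#'
#' @param se A `SummarizedExperiment` with a `case_id` colData column.
#' @return Character vector of case ids, one per sample.
#' @export
caseIds <- function(se) {
    ci <- SummarizedExperiment::colData(se)$case_id
    if (is.null(ci)) stop("no 'case_id' column in colData")
    as.character(ci)
}
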