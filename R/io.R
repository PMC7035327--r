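## Readers/writers for the plain-text interchange formats (expression TSV,
## GMT gene sets, purity/label/infiltration tables) and the preprocessing
## rules applied at load time: drop features with zero raw signal in every
## sample, then log-transform.

#' Remove features with zero raw signal in all samples
#'
#' @param m numeric matrix of raw (pre-log) expression, features x samples.
#' @return `m` without rows that are zero across every sample. Idempotent.
#' @export
filterZeroRows <- function(m) {
    m[rowSums(m != 0) > 0L, , drop = FALSE]
}

.checkNumericColumns <- function(df, path) {
    for (j in seq_along(df)) {
        col <- df[[j]]
        if (is.numeric(col)) next
        suppress <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(suppress) & !is.na(col))[1L]
        stop(sprintf(
            "non-numeric value %s in '%s' (feature row %d, sample column %d)",
            deparse(col[bad]), path, bad, j))
    }
    df
}

#' Read a feature-annotation table
#'
#' Two-or-three-column TSV with header: `feature_id`, `biotype`, optional
#' `gene_symbol`. Biotypes must be in `coding`, `lincRNA`, `antisense`,
#' `other_lncRNA`.
#'
#' @param path file path.
#' @return data.frame with columns `feature_id`, `biotype`, `gene_symbol`.
#' @export
readAnnotation <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                     check.names = FALSE)
    if (!all(c("feature_id", "biotype") %in% colnames(df)))
        stop("annotation needs 'feature_id' and 'biotype' columns")
    if (anyDuplicated(df$feature_id))
        stop("duplicate feature_id in annotation: ",
             df$feature_id[duplicated(df$feature_id)][1L])
    bad <- setdiff(unique(df$biotype), .ALL_BIOTYPES)
    if (length(bad))
        stop("unknown biotype(s) in annotation: ", paste(bad, collapse = ", "))
    if (!"gene_symbol" %in% colnames(df)) df$gene_symbol <- df$feature_id
    df[, c("feature_id", "biotype", "gene_symbol")]
}

#' Read an expression matrix and apply preprocessing
#'
#' Reads a features-x-samples TSV (header row of sample ids, first column
#' feature ids), removes features whose raw value is zero in every sample,
#' log-transforms as `log(raw + pseudocount, base)`, and attaches biotypes
#' from an annotation table. Lines starting with `#` are ignored.
#'
#' @param path expression TSV path.
#' @param annotation data.frame as returned by [readAnnotation()].
#' @param pseudocount offset added before the log; must be > 0 so that raw
#'   zeros map to a finite value (default 1, so raw 0 maps to 0).
#' @param base logarithm base (default 2).
#' @param transform `"log"` (default) applies the filter+log pipeline;
#'   `"none"` reads values as-is (already transformed), only validating
#'   finiteness.
#' @param unannotated what to do with features missing from `annotation`:
#'   `"other_lncRNA"` keeps them under that label (default) or `"drop"`.
#' @return a [LncExperiment-class] (no purity/condition attached).
#' @export
readExpression <- function(path, annotation, pseudocount = 1, base = 2,
                           transform = c("log", "none"),
                           unannotated = c("other_lncRNA", "drop")) {
    transform <- match.arg(transform)
    unannotated <- match.arg(unannotated)
    stopifnot(pseudocount > 0, base > 1)
    df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                     check.names = FALSE, colClasses = "character")
    if (ncol(df) < 2L) stop("expression table needs feature ids plus samples")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate feature id in '", path, "': ",
             ids[duplicated(ids)][1L])
    df <- df[, -1L, drop = FALSE]
    if (anyDuplicated(colnames(df)))
        stop("duplicate sample id in '", path, "'")
    df[] <- lapply(df, type.convert, as.is = TRUE)
    .checkNumericColumns(df, path)
    m <- as.matrix(df)
    mode(m) <- "numeric"
    rownames(m) <- ids
    if (transform == "log") {
        m <- filterZeroRows(m)
        if (any(m < 0)) stop("negative raw expression value in '", path, "'")
        m <- log(m + pseudocount, base = base)
    }
    if (any(!is.finite(m))) stop("non-finite expression value in '", path, "'")
    bt <- annotation$biotype[match(rownames(m), annotation$feature_id)]
    if (anyNA(bt)) {
        if (unannotated == "drop") {
            m <- m[!is.na(bt), , drop = FALSE]
            bt <- bt[!is.na(bt)]
        } else bt[is.na(bt)] <- "other_lncRNA"
    }
    LncExperiment(m, biotype = bt)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()]: with `transform = "delog"` the stored log
#' values are mapped back to the raw scale (`base^v - pseudocount`, floored
#' at 0); with `"none"` the log values are written as-is (read back with
#' `transform = "none"` for a full-precision round trip).
#'
#' @param x a [LncExperiment-class].
#' @param path output path.
#' @param transform `"none"` or `"delog"`.
#' @param pseudocount,base must match the values used at read time when
#'   `transform = "delog"`.
#' @param provenance optional character vector written as `#`-prefixed header
#'   lines.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, transform = c("none", "delog"),
                            pseudocount = 1, base = 2, provenance = NULL) {
    transform <- match.arg(transform)
    m <- exprValues(x)
    if (transform == "delog") m <- pmax(base^m - pseudocount, 0)
    .writeTsv(data.frame(feature_id = rownames(m), m, check.names = FALSE),
              path, provenance)
    invisible(path)
}

.writeTsv <- function(df, path, provenance = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(provenance)) writeLines(paste0("# ", provenance), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member ids. Duplicate members within a set are removed; sets empty after
#' deduplication are skipped with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors (pathway id -> member ids).
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines)) {
        warning("empty gene-set file: ", path)
        return(setNames(list(), character()))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
    ids <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(ids))
        stop("duplicate pathway id in GMT: ", ids[duplicated(ids)][1L])
    sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)][nzchar(f[-c(1L, 2L)])]))
    names(sets) <- ids
    empty <- lengths(sets) == 0L
    if (any(empty)) {
        warning("skipping empty gene set(s): ",
                paste(ids[empty], collapse = ", "))
        sets <- sets[!empty]
    }
    sets
}

.readKeyedTable <- function(path, valueCol, bounds = NULL) {
    df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                     check.names = FALSE)
    if (ncol(df) < 2L) stop("'", path, "' needs a key column plus values")
    key <- df[[1L]]
    if (anyDuplicated(key))
        stop("duplicate sample id in '", path, "': ",
             key[duplicated(key)][1L])
    if (!is.null(bounds)) {
        v <- df[[valueCol]]
        if (!is.numeric(v)) stop("column ", valueCol, " must be numeric")
        if (any(v < bounds[1L] | v > bounds[2L], na.rm = TRUE))
            stop(sprintf("values in '%s' outside [%g, %g]", path,
                         bounds[1L], bounds[2L]))
    }
    df
}

#' Read a per-sample tumor-purity table
#'
#' Two-column TSV with header (`sample_id`, `purity`); purity must lie in
#' \[0,1\].
#'
#' @param path file path.
#' @return named numeric vector (sample id -> purity).
#' @export
readPurity <- function(path) {
    df <- .readKeyedTable(path, 2L, bounds = c(0, 1))
    setNames(as.numeric(df[[2L]]), df[[1L]])
}

#' Read tumor/normal sample labels
#'
#' Two-column TSV with header (`sample_id`, `condition`); conditions must be
#' `tumor` or `normal`, each sample labeled exactly once.
#'
#' @param path file path.
#' @return named character vector (sample id -> condition).
#' @export
readSampleLabels <- function(path) {
    df <- .readKeyedTable(path, 2L)
    lab <- as.character(df[[2L]])
    bad <- setdiff(unique(lab), c("tumor", "normal"))
    if (length(bad)) stop("unknown condition label(s): ",
                          paste(bad, collapse = ", "))
    setNames(lab, df[[1L]])
}

#' Read a per-sample immune-infiltration table
#'
#' TSV with header: first column sample ids, remaining columns one
#' infiltration score per immune cell type (TIMER-style output, but any
#' column set is accepted).
#'
#' @param path file path.
#' @return numeric matrix, samples x cell types.
#' @export
readInfiltration <- function(path) {
    df <- .readKeyedTable(path, 2L)
    m <- as.matrix(df[, -1L, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- df[[1L]]
    m
}

#' Attach tumor purity, restricting to the shared samples
#'
#' Analyses run on the intersection of samples present in both the expression
#' matrix and the purity table; purity is never imputed. Purity-table samples
#' absent from the expression matrix are dropped with a warning.
#'
#' @param x a [LncExperiment-class].
#' @param purity named numeric vector as from [readPurity()].
#' @return `x` subset to the shared samples, with `purity` in `colData()`.
#' @export
attachPurity <- function(x, purity) {
    extra <- setdiff(names(purity), colnames(x))
    if (length(extra))
        warning(length(extra),
                " purity sample(s) absent from expression, dropped")
    shared <- intersect(colnames(x), names(purity))
    if (length(shared) < 4L)
        stop("fewer than 4 samples shared between expression and purity")
    x <- x[, shared]
    SummarizedExperiment::colData(x)$purity <- as.numeric(purity[shared])
    validObject(x)
    x
}

#' Attach tumor/normal labels
#'
#' Every retained sample must be labeled; label-table samples absent from the
#' expression matrix are dropped with a warning.
#'
#' @param x a [LncExperiment-class].
#' @param labels named character vector as from [readSampleLabels()].
#' @return `x` with `condition` in `colData()`.
#' @export
attachLabels <- function(x, labels) {
    extra <- setdiff(names(labels), colnames(x))
    if (length(extra))
        warning(length(extra),
                " labeled sample(s) absent from expression, dropped")
    missing <- setdiff(colnames(x), names(labels))
    if (length(missing))
        stop("unlabeled sample(s): ", paste(utils::head(missing, 3L),
                                            collapse = ", "))
    SummarizedExperiment::colData(x)$condition <-
        as.character(labels[colnames(x)])
    validObject(x)
    x
}

#' Persist a ranked gene list as two-column TSV
#'
#' @param x a [RankedGeneList-class].
#' @param path output path.
#' @param provenance optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
writeRankedList <- function(x, path, provenance = NULL) {
    .writeTsv(data.frame(gene_id = geneIds(x), rs = rsScores(x)),
              path, provenance)
}
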