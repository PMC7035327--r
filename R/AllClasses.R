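#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor pt p.adjust rbeta rnorm runif wilcox.test setNames sd
#' @importFrom utils read.delim write.table packageVersion type.convert head
NULL

## biotype vocabulary used throughout; "coding" genes form the ranked list,
## the three lncRNA classes are candidate regulators
.LNC_BIOTYPES <- c("lincRNA", "antisense", "other_lncRNA")
.ALL_BIOTYPES <- c("coding", .LNC_BIOTYPES)

#' Container for a sample-matched expression cohort
#'
#' `LncExperiment` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `logexpr` assay holding log-transformed expression (features x
#' samples), a mandatory `biotype` column in `rowData()` (one of `"coding"`,
#' `"lincRNA"`, `"antisense"`, `"other_lncRNA"`), and optional `purity`
#' (tumor purity in \[0,1\], `NA` allowed e.g. for normal samples) and
#' `condition` (`"tumor"`/`"normal"`) columns in `colData()`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [LncExperiment()] the constructor, [biotype()], [purity()],
#'   [condition()], [exprValues()].
#' @export
setClass("LncExperiment", contains = "SummarizedExperiment")

setValidity("LncExperiment", function(object) {
    msg <- character()
    if (!"logexpr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'logexpr' is required")
    else {
        v <- SummarizedExperiment::assay(object, "logexpr")
        if (!is.numeric(v))
            msg <- c(msg, "assay 'logexpr' must be numeric")
        else if (any(!is.finite(v)))
            msg <- c(msg, "assay 'logexpr' contains non-finite values")
    }
    rn <- rownames(object)
    cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "feature ids must be present and unique")
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "sample ids must be present and unique")
    rd <- SummarizedExperiment::rowData(object)
    if (!"biotype" %in% colnames(rd))
        msg <- c(msg, "rowData must contain a 'biotype' column")
    else if (!all(rd$biotype %in% .ALL_BIOTYPES))
        msg <- c(msg, sprintf("biotype values must be in {%s}",
                              paste(.ALL_BIOTYPES, collapse = ", ")))
    cd <- SummarizedExperiment::colData(object)
    if ("purity" %in% colnames(cd)) {
        p <- cd$purity
        bad <- !is.na(p) & (p < 0 | p > 1)
        if (any(bad)) msg <- c(msg, "purity values must lie in [0,1]")
    }
    if ("condition" %in% colnames(cd)) {
        cc <- cd$condition
        if (!all(is.na(cc) | cc %in% c("tumor", "normal")))
            msg <- c(msg, "condition must be 'tumor' or 'normal'")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a LncExperiment
#'
#' @param values numeric matrix of log-transformed expression, features x
#'   samples, with unique row and column names.
#' @param biotype character vector, one label per feature, each one of
#'   `"coding"`, `"lincRNA"`, `"antisense"`, `"other_lncRNA"`.
#' @param purity optional numeric vector of per-sample tumor purity in
#'   \[0,1\]; `NA` marks samples without an estimate.
#' @param condition optional character vector of `"tumor"`/`"normal"` labels.
#' @return a [LncExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("G1", "G2", "L1"), paste0("S", 1:4)))
#' x <- LncExperiment(m, biotype = c("coding", "coding", "lincRNA"),
#'                    purity = c(0.4, 0.6, 0.5, 0.7))
#' @export
LncExperiment <- function(values, biotype, purity = NULL, condition = NULL) {
    values <- as.matrix(values)
    if (length(biotype) != nrow(values))
        stop("'biotype' must have one entry per feature")
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
    if (!is.null(purity)) {
        if (length(purity) != ncol(values))
            stop("'purity' must have one entry per sample")
        cd$purity <- as.numeric(purity)
    }
    if (!is.null(condition)) {
        if (length(condition) != ncol(values))
            stop("'condition' must have one entry per sample")
        cd$condition <- as.character(condition)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(logexpr = values),
        rowData = S4Vectors::DataFrame(biotype = as.character(biotype)),
        colData = cd)
    new("LncExperiment", se)
}

#' Ranked coding-gene list for one lncRNA
#'
#' Coding genes ordered best-to-worst by the signed rank score
#' RS = -log10(p) * sign(partial correlation) against one lncRNA.
#'
#' @slot lncrnaId single lncRNA identifier.
#' @slot geneIds character vector of coding gene ids, sorted by decreasing RS
#'   (ties broken lexicographically by gene id).
#' @slot rsScores numeric vector of RS values, same order as `geneIds`.
#' @export
setClass("RankedGeneList",
         representation(lncrnaId = "character",
                        geneIds = "character",
                        rsScores = "numeric"))

setValidity("RankedGeneList", function(object) {
    msg <- character()
    if (length(object@lncrnaId) != 1L)
        msg <- c(msg, "lncrnaId must be a single id")
    if (length(object@geneIds) != length(object@rsScores))
        msg <- c(msg, "geneIds and rsScores lengths differ")
    if (anyDuplicated(object@geneIds))
        msg <- c(msg, "duplicate gene ids")
    if (any(!is.finite(object@rsScores)))
        msg <- c(msg, "rsScores must be finite")
    if (is.unsorted(rev(object@rsScores)))
        msg <- c(msg, "rsScores must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' Synthetic-cohort simulation settings
#'
#' Holds the knobs of the latent-activity cohort generator: cohort sizes,
#' pathway layout, planted-role counts, and signal/confounding strengths.
#' See [simConfig()] for defaults and meanings.
#'
#' @export
setClass("SimulationConfig",
         representation(nTumor = "integer", nNormal = "integer",
                        nCoding = "integer", nLncrna = "integer",
                        nPathways = "integer", pathwaySize = "integer",
                        nRegulators = "integer", nConfounders = "integer",
                        nConfoundedGenes = "integer", nPerturbed = "integer",
                        effectSize = "numeric", geneLoading = "numeric",
                        directEffect = "numeric",
                        purityLoading = "numeric",
                        confounderStrength = "numeric",
                        noiseSd = "numeric", foldChange = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    cnt <- c(nTumor = object@nTumor, nCoding = object@nCoding,
             nLncrna = object@nLncrna, nPathways = object@nPathways,
             pathwaySize = object@pathwaySize)
    if (any(cnt < 1L))
        msg <- c(msg, "cohort/pathway counts must be positive")
    if (object@nNormal < 0L || object@nRegulators < 0L ||
        object@nConfounders < 0L || object@nConfoundedGenes < 0L ||
        object@nPerturbed < 0L)
        msg <- c(msg, "role counts must be non-negative")
    if (object@effectSize < 0 || object@effectSize >= 1)
        msg <- c(msg, "effectSize must lie in [0, 1)")
    if (object@geneLoading <= 0 || object@geneLoading >= 1)
        msg <- c(msg, "geneLoading must lie in (0, 1)")
    if (object@directEffect < 0 ||
        object@geneLoading^2 + object@directEffect^2 >= 1)
        msg <- c(msg, "need directEffect >= 0 and geneLoading^2 + directEffect^2 < 1")
    if (abs(object@purityLoading) >= 1)
        msg <- c(msg, "purityLoading must lie in (-1, 1)")
    if (object@confounderStrength < 0 || object@confounderStrength >= 1)
        msg <- c(msg, "confounderStrength must lie in [0, 1)")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
    if (object@foldChange <= 0) msg <- c(msg, "foldChange must be positive")
    if (object@nPathways * object@pathwaySize + object@nConfoundedGenes >
        object@nCoding)
        msg <- c(msg, "pathway blocks plus confounded block exceed nCoding")
    if (object@nRegulators + object@nConfounders + object@nPerturbed >
        object@nLncrna)
        msg <- c(msg, "planted roles exceed nLncrna")
    if (length(msg)) msg else TRUE
})
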