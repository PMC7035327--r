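#' Feature biotypes
#'
#' @param x a [LncExperiment-class].
#' @return character vector of biotype labels, one per feature.
#' @export
setGeneric("biotype", function(x) standardGeneric("biotype"))

#' @rdname biotype
#' @export
setMethod("biotype", "LncExperiment", function(x)
    as.character(SummarizedExperiment::rowData(x)$biotype))

#' Per-sample tumor purity
#'
#' @param x a [LncExperiment-class].
#' @return numeric vector of purity values (NA where unknown), or `NULL` when
#'   no purity has been attached.
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))

#' @rdname purity
#' @export
setMethod("purity", "LncExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("purity" %in% colnames(cd)) as.numeric(cd$purity) else NULL
})

#' Tumor/normal sample labels
#'
#' @param x a [LncExperiment-class].
#' @return character vector of `"tumor"`/`"normal"` labels, or `NULL`.
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname condition
#' @export
setMethod("condition", "LncExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("condition" %in% colnames(cd)) as.character(cd$condition) else NULL
})

#' Log-expression matrix
#'
#' @param x a [LncExperiment-class].
#' @return the `logexpr` assay (features x samples).
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname exprValues
#' @export
setMethod("exprValues", "LncExperiment", function(x)
    SummarizedExperiment::assay(x, "logexpr"))

#' Feature ids by biotype class
#'
#' `codingIds()` returns the coding genes (the ranked-list universe);
#' `lncrnaIds()` the candidate regulators (any lncRNA biotype, or a subset of
#' classes).
#'
#' @param x a [LncExperiment-class].
#' @param classes lncRNA biotype classes to include.
#' @return character vector of feature ids.
#' @export
codingIds <- function(x) rownames(x)[biotype(x) == "coding"]

#' @rdname codingIds
#' @export
lncrnaIds <- function(x, classes = .LNC_BIOTYPES)
    rownames(x)[biotype(x) %in% classes]

setMethod("show", "LncExperiment", function(object) {
    callNextMethod()
    tab <- table(factor(biotype(object), levels = .ALL_BIOTYPES))
    cat("biotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
    cat("purity:", if (is.null(purity(object))) "absent" else
        sprintf("%d samples with estimates", sum(!is.na(purity(object)))),
        "\n")
})

#' @rdname lncrnaId
#' @export
setGeneric("lncrnaId", function(x) standardGeneric("lncrnaId"))

#' Accessors for RankedGeneList
#'
#' @param x a [RankedGeneList-class].
#' @return `lncrnaId()` the lncRNA id; `geneIds()` the ordered coding gene
#'   ids; `rsScores()` the matching rank scores.
#' @name lncrnaId
#' @export
setMethod("lncrnaId", "RankedGeneList", function(x) x@lncrnaId)

#' @rdname lncrnaId
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname lncrnaId
#' @export
setMethod("geneIds", "RankedGeneList", function(x) x@geneIds)

#' @rdname lncrnaId
#' @export
setGeneric("rsScores", function(x) standardGeneric("rsScores"))

#' @rdname lncrnaId
#' @export
setMethod("rsScores", "RankedGeneList", function(x) x@rsScores)

setMethod("show", "RankedGeneList", function(object) {
    n <- length(object@geneIds)
    cat(sprintf("RankedGeneList for %s: %d coding genes\n",
                object@lncrnaId, n))
    if (n) {
        k <- min(3L, n)
        cat("top:", paste(sprintf("%s (RS=%.3g)", object@geneIds[seq_len(k)],
                                  object@rsScores[seq_len(k)]),
                          collapse = ", "), "\n")
    }
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0(
        "SimulationConfig: %d tumor + %d normal samples, %d coding, ",
        "%d lncRNA\n  %d pathways x %d genes; regulators=%d confounders=%d ",
        "perturbed=%d\n  effectSize=%.2f confounderStrength=%.2f ",
        "purityLoading=%.2f seed=%d\n"),
        object@nTumor, object@nNormal, object@nCoding, object@nLncrna,
        object@nPathways, object@pathwaySize, object@nRegulators,
        object@nConfounders, object@nPerturbed, object@effectSize,
        object@confounderStrength, object@purityLoading, object@seed))
})
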