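## Purity-adjusted association between lncRNAs and coding genes.
##
## For lncRNA expression L, gene expression G and tumor purity P over the same
## m samples, the first-order partial correlation
##   PCC = (R_LG - R_LP * R_GP) / (sqrt(1 - R_LP^2) * sqrt(1 - R_GP^2))
## removes the component of the L-G association that is explained by purity
## (equivalently, the Pearson correlation of the purity-regression residuals).
## Its two-sided p-value uses a t statistic on m - 3 degrees of freedom, and
## the signed rank score RS = -log10(p) * sign(PCC) orders the coding genes
## for enrichment analysis.

.rowStandardize <- function(M) {
    c0 <- M - rowMeans(M)
    s <- sqrt(rowSums(c0 * c0))
    list(z = c0 / ifelse(s == 0, NA_real_, s), sd0 = s == 0)
}

## Vectorized engine: L (nl x m) vs G (ng x m), optionally adjusting for
## purity. Returns pcc/pvalue matrices plus an `ok` mask (FALSE where a
## vector is constant or a purity correlation is +/-1, making the partial
## correlation undefined).
.correlationMatrix <- function(L, G, purity = NULL) {
    m <- ncol(L)
    stopifnot(ncol(G) == m)
    zl <- .rowStandardize(L)
    zg <- .rowStandardize(G)
    if (is.null(purity)) {
        if (m < 3L) stop("need at least 3 samples")
        pcc <- tcrossprod(zl$z, zg$z)
        df <- m - 2L
        rlpBad <- rep(FALSE, nrow(L))
        rgpBad <- rep(FALSE, nrow(G))
    } else {
        if (m < 4L) stop("need at least 4 samples for purity adjustment")
        stopifnot(length(purity) == m)
        zp <- purity - mean(purity)
        np <- sqrt(sum(zp * zp))
        if (np == 0) stop("purity has zero variance")
        zp <- zp / np
        rlg <- tcrossprod(zl$z, zg$z)
        rlp <- as.numeric(zl$z %*% zp)
        rgp <- as.numeric(zg$z %*% zp)
        rlpBad <- !is.na(rlp) & abs(rlp) >= 1 - 1e-12
        rgpBad <- !is.na(rgp) & abs(rgp) >= 1 - 1e-12
        den <- sqrt(pmax(1 - rlp^2, 0)) %o% sqrt(pmax(1 - rgp^2, 0))
        pcc <- (rlg - rlp %o% rgp) / den
        df <- m - 3L
    }
    pcc <- pmin(pmax(pcc, -1), 1)
    tstat <- abs(pcc) * sqrt(df / pmax(1 - pcc^2, .Machine$double.eps))
    pval <- 2 * pt(tstat, df = df, lower.tail = FALSE)
    pval[abs(pcc) >= 1 - 1e-15] <- 0
    pval <- pmin(pval, 1)
    badL <- zl$sd0 | rlpBad
    badG <- zg$sd0 | rgpBad
    ok <- outer(!badL, !badG, `&`) & is.finite(pcc)
    list(pcc = pcc, pvalue = pval, ok = ok)
}

#' Purity-adjusted partial correlation between two expression vectors
#'
#' First-order partial correlation of `l` and `g` given `purity`, with a
#' two-sided p-value from a t statistic on `m - 3` degrees of freedom. The
#' estimate equals the Pearson correlation of the residuals of `l` and `g`
#' after least-squares regression on purity.
#'
#' @param l,g numeric vectors of log expression over the same samples
#'   (length m >= 4, nonzero variance).
#' @param purity numeric vector of tumor purity for the same samples.
#' @return list with `estimate` (clamped to \[-1,1\]) and `p.value`.
#' @examples
#' partialCor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5), c(.2, .2, .5, .5, .8))
#' @export
partialCor <- function(l, g, purity) {
    stopifnot(length(l) == length(g), length(l) == length(purity),
              length(l) >= 4L)
    res <- .correlationMatrix(rbind(l), rbind(g), purity)
    if (!res$ok[1L, 1L])
        stop("partial correlation undefined (constant vector or |R with purity| = 1)")
    list(estimate = res$pcc[1L, 1L], p.value = res$pvalue[1L, 1L])
}

#' Signed rank score from a correlation test
#'
#' `RS = -log10(max(p, floor)) * sign(pcc)`. The floor keeps RS finite when p
#' underflows; `sign(0)` is 0 so an exactly-zero correlation scores 0.
#'
#' @param pcc correlation estimate(s).
#' @param pvalue p-value(s) in \[0,1\].
#' @param floor positive lower clamp applied to `pvalue` (default 1e-300).
#' @return numeric vector of rank scores.
#' @examples
#' rankScore(0.5, 0.01)   # 2
#' rankScore(-0.3, 0.001) # -3
#' @export
rankScore <- function(pcc, pvalue, floor = 1e-300) {
    stopifnot(floor > 0)
    -log10(pmax(pvalue, floor)) * sign(pcc)
}

#' Rank all coding genes against one lncRNA
#'
#' Computes the purity-adjusted partial correlation (or plain Pearson
#' correlation when `adjustPurity = FALSE`) between the lncRNA and every
#' coding gene, converts each test to a signed rank score, and returns the
#' genes sorted by decreasing RS with lexicographic tie-breaking on gene id.
#' Genes whose correlation is undefined (constant expression, or perfectly
#' correlated with purity) are excluded so the list length reflects evaluable
#' genes only.
#'
#' @param x a [LncExperiment-class] with purity attached (unless
#'   `adjustPurity = FALSE`).
#' @param lncrnaId id of a feature with a lncRNA biotype.
#' @param pvalueFloor floor passed to [rankScore()].
#' @param adjustPurity adjust for tumor purity (default TRUE).
#' @return a [RankedGeneList-class].
#' @export
buildRankedList <- function(x, lncrnaId, pvalueFloor = 1e-300,
                            adjustPurity = TRUE) {
    stopifnot(is(x, "LncExperiment"))
    if (!lncrnaId %in% rownames(x)) stop("unknown feature: ", lncrnaId)
    if (!biotype(x)[match(lncrnaId, rownames(x))] %in% .LNC_BIOTYPES)
        stop(lncrnaId, " does not have a lncRNA biotype")
    genes <- codingIds(x)
    if (!length(genes)) stop("no coding genes in the experiment")
    v <- exprValues(x)
    pur <- NULL
    if (adjustPurity) {
        pur <- purity(x)
        if (is.null(pur)) stop("no purity attached; see attachPurity()")
        keep <- !is.na(pur)
        v <- v[, keep, drop = FALSE]
        pur <- pur[keep]
    }
    l <- v[lncrnaId, ]
    if (stats::sd(l) == 0)
        stop("lncRNA ", lncrnaId, " has zero expression variance")
    res <- .correlationMatrix(rbind(l), v[genes, , drop = FALSE], pur)
    ok <- res$ok[1L, ]
    rs <- rankScore(unname(res$pcc[1L, ok]), unname(res$pvalue[1L, ok]),
                    pvalueFloor)
    ids <- genes[ok]
    ord <- order(-rs, ids, method = "radix")
    new("RankedGeneList", lncrnaId = lncrnaId, geneIds = ids[ord],
        rsScores = rs[ord])
}

#' Spearman screen of lncRNAs against immune-infiltration scores
#'
#' Spearman's rank correlation (average ranks at ties, computed as Pearson
#' correlation of the rank transforms) between every lncRNA-biotype feature
#' and every infiltration column, with a two-sided p-value from the t
#' approximation on n - 2 degrees of freedom. A pair passes when
#' `|rho| > rhoThreshold` and `p < alpha`, both strict. Constant infiltration
#' columns are not evaluable (`NA` rho and passes flag).
#'
#' @param x a [LncExperiment-class].
#' @param infiltration samples x cell-types numeric matrix
#'   (see [readInfiltration()]); rows are matched to shared samples.
#' @param rhoThreshold absolute-correlation threshold (default 0.3).
#' @param alpha p-value threshold (default 0.05).
#' @param classes lncRNA biotype classes screened.
#' @return data.frame with columns `lncrna_id`, `cell_type`, `rho`, `pvalue`,
#'   `passes`.
#' @export
infiltrationCorrelation <- function(x, infiltration, rhoThreshold = 0.3,
                                    alpha = 0.05, classes = .LNC_BIOTYPES) {
    stopifnot(is(x, "LncExperiment"), is.matrix(infiltration))
    shared <- intersect(colnames(x), rownames(infiltration))
    if (length(shared) < 4L) stop("fewer than 4 shared samples")
    lnc <- lncrnaIds(x, classes)
    if (!length(lnc)) stop("no lncRNA-biotype features")
    L <- exprValues(x)[lnc, shared, drop = FALSE]
    Iv <- infiltration[shared, , drop = FALSE]
    n <- length(shared)
    rL <- t(apply(L, 1L, rank))          # average ranks at ties
    rI <- apply(Iv, 2L, rank)
    constI <- apply(Iv, 2L, function(col) length(unique(col)) == 1L)
    res <- .correlationMatrix(rL, t(rI))
    rho <- res$pcc
    pv <- res$pvalue
    rho[, constI] <- NA_real_
    pv[, constI] <- NA_real_
    passes <- abs(rho) > rhoThreshold & pv < alpha
    data.frame(
        lncrna_id = rep(lnc, times = ncol(Iv)),
        cell_type = rep(colnames(Iv), each = length(lnc)),
        rho = as.numeric(rho), pvalue = as.numeric(pv),
        passes = as.logical(passes),
        stringsAsFactors = FALSE)
}
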