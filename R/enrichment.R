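## Weighted Kolmogorov-Smirnov enrichment of a pathway in a ranked gene list,
## its analytic tail p-value, and the bounded lncRES regulation score.
##
## Walking down a list of N coding genes ranked by RS, hits (pathway members,
## N_I of them after dropping members absent from the list) add
## |r_j|^w / N_R with N_R = sum over hits of |r_j|^w, and misses subtract
## 1 / (N - N_I). ES is the running deviation of maximum absolute value,
## carrying its sign. Under the null the scaled statistic follows the
## Kolmogorov law with effective size n = (N - N_I) * N_I / N, giving the
## two-sided tail probability
##   p = 2 * sum_{q>=1} (-1)^(q-1) * exp(-2 q^2 ES^2 n),
## and lncRES = 1 - 2p (ES > 0) or 2p - 1 (ES < 0), bounded in [-1, 1].

.runningDeviation <- function(rs, hit, weight) {
    n <- length(rs)
    nI <- sum(hit)
    w <- abs(rs)^weight
    nR <- sum(w[hit])
    if (nR == 0)
        stop("all hit weights are zero; enrichment score undefined")
    step <- ifelse(hit, w / nR, -1 / (n - nI))
    cumsum(step)
}

#' Weighted enrichment score of a pathway in a ranked gene list
#'
#' @param ranked a [RankedGeneList-class], or a named numeric vector of RS
#'   values already sorted non-increasing (names are gene ids).
#' @param pathway character vector of member gene ids; members absent from
#'   the list are dropped before anything is computed.
#' @param weight exponent applied to `|RS|` when accumulating hits. The
#'   default 0 gives the classic unweighted KS statistic, the only case whose
#'   null matches the analytic tail law of [esPvalue()]; set 1 for
#'   magnitude-weighted hits (then p-values are conservative only relative to
#'   an empirical null, not calibrated).
#' @return list with `es` (signed score in \[-1,1\]), `profile` (the running
#'   deviation at every list position), `nList` (N) and `nPathwayInList`
#'   (N_I).
#' @examples
#' rs <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2)
#' enrichmentScore(rs, c("g1", "g2"))$es   # 1
#' enrichmentScore(rs, c("g4", "g5"))$es   # -1
#' @export
enrichmentScore <- function(ranked, pathway, weight = 0) {
    stopifnot(weight >= 0)
    if (is(ranked, "RankedGeneList")) {
        ids <- geneIds(ranked)
        rs <- rsScores(ranked)
    } else {
        rs <- ranked
        ids <- names(rs)
        if (is.null(ids)) stop("ranked vector must carry gene ids as names")
        if (is.unsorted(rev(rs))) stop("ranked scores must be non-increasing")
    }
    hit <- ids %in% pathway
    nI <- sum(hit)
    n <- length(ids)
    if (nI == 0L) stop("pathway has no overlap with the ranked list")
    if (nI == n) stop("pathway covers the entire ranked list")
    d <- .runningDeviation(rs, hit, weight)
    i <- which.max(abs(d))   # first index at ties: earliest prefix wins
    list(es = d[i], profile = d, nList = n, nPathwayInList = nI)
}

#' Analytic tail p-value for an enrichment score
#'
#' Kolmogorov-form tail probability evaluated at `|es|` with effective sample
#' size `n = (nList - nPathway) * nPathway / nList`:
#' `p = 2 * sum_{q=1..Q} (-1)^(q-1) exp(-2 q^2 es^2 n)`, truncated when the
#' next term falls below 1e-16 or `q` reaches `truncation`, and clamped to
#' \[1e-300, 1\]. `es = 0` returns 1 by convention (the series degenerates).
#' Strictly decreasing in `|es|` and in `n` for `|es| > 0`.
#'
#' @param es enrichment score(s) in \[-1,1\].
#' @param nList number of genes in the ranked list (N).
#' @param nPathway number of pathway members in the list (N_I), with
#'   `0 < nPathway < nList`.
#' @param truncation maximum number of series terms (default 100).
#' @return p-value(s) in \[1e-300, 1\].
#' @examples
#' esPvalue(1, 5, 2)   # about 0.1813
#' @export
esPvalue <- function(es, nList, nPathway, truncation = 100L) {
    stopifnot(nList > nPathway, nPathway > 0, truncation >= 1L)
    n <- (nList - nPathway) * nPathway / nList
    one <- function(e) {
        if (is.na(e)) return(NA_real_)
        if (e == 0) return(1)
        a <- 2 * e^2 * n
        s <- 0
        for (q in seq_len(truncation)) {
            term <- exp(-a * q^2)
            s <- s + if (q %% 2L == 1L) term else -term
            if (term < 1e-16) break
        }
        min(max(2 * s, 1e-300), 1)
    }
    vapply(abs(es), one, numeric(1L))
}

#' Convert an enrichment score and p-value to the lncRES scale
#'
#' `1 - 2p` for positive ES, `2p - 1` for negative ES, 0 for ES = 0: a score
#' in \[-1, 1\] whose magnitude grows with significance and whose sign is the
#' direction of enrichment.
#'
#' @param es enrichment score(s).
#' @param pvalue p-value(s) in \[0,1\].
#' @return lncRES score(s) in \[-1, 1\].
#' @examples
#' lncresScore(1, 0.0025)  # 0.995, the usual significance boundary
#' @export
lncresScore <- function(es, pvalue) {
    stopifnot(all(pvalue >= 0 & pvalue <= 1, na.rm = TRUE))
    ifelse(es > 0, 1 - 2 * pvalue, ifelse(es < 0, 2 * pvalue - 1, 0))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment over one family of tests
#' (a thin wrapper over [stats::p.adjust()] fixing `method = "BH"`).
#'
#' @param pvalues numeric vector in \[0,1\] (NA allowed).
#' @return adjusted p-values, each in `[p, 1]`.
#' @export
adjustFdr <- function(pvalues) p.adjust(pvalues, method = "BH")

#' Significance rule for a lncRNA-pathway pair
#'
#' Strict inequalities on both thresholds: a pair sitting exactly at
#' `|lncres| = lncresThreshold` fails.
#'
#' @param lncres lncRES score(s).
#' @param fdr adjusted p-value(s).
#' @param lncresThreshold absolute lncRES cutoff (default 0.995).
#' @param fdrThreshold FDR cutoff (default 0.05).
#' @return logical vector (`FALSE` where either input is `NA`).
#' @export
isSignificant <- function(lncres, fdr, lncresThreshold = 0.995,
                          fdrThreshold = 0.05) {
    out <- abs(lncres) > lncresThreshold & fdr < fdrThreshold
    out[is.na(out)] <- FALSE
    out
}

#' Screen every lncRNA against every pathway in one cohort
#'
#' For each lncRNA-biotype feature, ranks all coding genes by the
#' purity-adjusted rank score ([buildRankedList()]), computes the weighted
#' enrichment score, analytic p-value and lncRES for each pathway, adjusts
#' p-values by Benjamini-Hochberg over all evaluable pairs of the run, and
#' flags significant pairs. Pairs with zero pathway overlap (or where the
#' lncRNA is not evaluable) are reported with `NA` statistics and are excluded
#' from the FDR family. Output rows are sorted by (`lncrna_id`,
#' `pathway_id`).
#'
#' @param x a [LncExperiment-class]; when `condition` labels are attached only
#'   tumor samples are used, and when `adjustPurity = TRUE` only samples with
#'   a purity estimate.
#' @param pathways named list of member-id vectors (see [readGMT()]).
#' @param lncresThreshold,fdrThreshold significance cutoffs
#'   (defaults 0.995 and 0.05, strict).
#' @param weight hit-weight exponent (default 0, the unweighted KS statistic;
#'   the analytic p-value of [esPvalue()] is only calibrated at 0).
#' @param pvalueFloor floor for the correlation p-value before `-log10`.
#' @param adjustPurity adjust correlations for tumor purity (default TRUE).
#' @param classes lncRNA biotype classes screened.
#' @return data.frame with columns `lncrna_id`, `pathway_id`, `es`, `n_list`,
#'   `n_pathway_in_list`, `pvalue`, `fdr`, `lncres`, `significant`.
#' @export
screenPathways <- function(x, pathways, lncresThreshold = 0.995,
                           fdrThreshold = 0.05, weight = 0,
                           pvalueFloor = 1e-300, adjustPurity = TRUE,
                           classes = .LNC_BIOTYPES) {
    stopifnot(is(x, "LncExperiment"), is.list(pathways),
              !is.null(names(pathways)))
    keep <- rep(TRUE, ncol(x))
    cond <- condition(x)
    if (!is.null(cond)) keep <- keep & cond == "tumor"
    pur <- NULL
    if (adjustPurity) {
        pur <- purity(x)
        if (is.null(pur))
            stop("purity adjustment requested but no purity attached")
        keep <- keep & !is.na(pur)
    }
    x <- x[, keep]
    if (ncol(x) < 4L) stop("fewer than 4 usable samples")
    if (adjustPurity) pur <- purity(x)
    lnc <- sort(lncrnaIds(x, classes), method = "radix")
    if (!length(lnc)) stop("no lncRNA-biotype features in the experiment")
    genes <- codingIds(x)
    if (!length(genes)) stop("no coding genes in the experiment")
    pwNames <- sort(names(pathways), method = "radix")
    v <- exprValues(x)
    cm <- .correlationMatrix(v[lnc, , drop = FALSE],
                             v[genes, , drop = FALSE], pur)
    badLnc <- rowSums(cm$ok) == 0L
    if (any(badLnc))
        warning(sum(badLnc), " lncRNA(s) not evaluable (constant expression",
                " or collinear with purity)")
    out <- data.frame(
        lncrna_id = rep(lnc, each = length(pwNames)),
        pathway_id = rep(pwNames, times = length(lnc)),
        es = NA_real_, n_list = NA_integer_, n_pathway_in_list = NA_integer_,
        pvalue = NA_real_, fdr = NA_real_, lncres = NA_real_,
        significant = FALSE, stringsAsFactors = FALSE)
    row <- 0L
    for (i in seq_along(lnc)) {
        ok <- cm$ok[i, ]
        if (!any(ok)) { row <- row + length(pwNames); next }
        rs <- rankScore(cm$pcc[i, ok], cm$pvalue[i, ok], pvalueFloor)
        ids <- genes[ok]
        ord <- order(-rs, ids, method = "radix")
        rs <- rs[ord]
        ids <- ids[ord]
        n <- length(ids)
        w <- abs(rs)^weight
        for (k in pwNames) {
            row <- row + 1L
            hit <- ids %in% pathways[[k]]
            nI <- sum(hit)
            if (nI == 0L || nI == n) next
            nR <- sum(w[hit])
            if (nR == 0) next
            d <- cumsum(ifelse(hit, w / nR, -1 / (n - nI)))
            es <- d[which.max(abs(d))]
            p <- esPvalue(es, n, nI)
            out$es[row] <- es
            out$n_list[row] <- n
            out$n_pathway_in_list[row] <- nI
            out$pvalue[row] <- p
        }
    }
    eval <- !is.na(out$pvalue)
    out$fdr[eval] <- adjustFdr(out$pvalue[eval])
    out$lncres <- lncresScore(out$es, out$pvalue)
    out$significant <- isSignificant(out$lncres, out$fdr,
                                     lncresThreshold, fdrThreshold)
    out[order(out$lncrna_id, out$pathway_id, method = "radix"), ,
        drop = FALSE] -> out
    rownames(out) <- NULL
    out
}
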