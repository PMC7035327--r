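## Pan-cancer prioritization: for each intergenic lncRNA, count the cohorts
## (cancer types) in which it significantly regulates each pathway and the
## cohorts in which it is differentially expressed between tumor and normal,
## convert every count to a normalized rank in [0,1] (higher = more
## recurrent), and average the ranks into the final priority score
## F = (sum of pathway ranks + DE rank) / number of criteria.

#' Count per-pathway recurrence across cohorts
#'
#' For every (lincRNA, pathway) pair, the number of cohorts in which the pair
#' is flagged significant. The lncRNA universe is the union over cohorts
#' (absent = not significant, with a warning when cohort universes are
#' disjoint); pairs never observed get a count of 0.
#'
#' @param results list of screen result data.frames (one per cohort, as from
#'   [screenPathways()]).
#' @param lincrnaIds optional character vector restricting the universe (e.g.
#'   to lincRNA-biotype features, the default analysis population).
#' @return data.frame with columns `lincrna_id`, `criterion` (pathway id),
#'   `n_cancers`.
#' @export
countRecurrence <- function(results, lincrnaIds = NULL) {
    stopifnot(is.list(results), length(results) >= 1L)
    universes <- lapply(results, function(r) unique(r$lncrna_id))
    if (length(results) > 1L && !length(Reduce(intersect, universes)))
        warning("cohort feature universes are disjoint; taking the union")
    lnc <- sort(unique(unlist(universes)), method = "radix")
    if (!is.null(lincrnaIds)) lnc <- intersect(lnc, lincrnaIds)
    if (!length(lnc)) stop("empty lincRNA universe")
    pws <- sort(unique(unlist(lapply(results, function(r)
        unique(r$pathway_id)))), method = "radix")
    counts <- matrix(0L, length(lnc), length(pws),
                     dimnames = list(lnc, pws))
    for (r in results) {
        sig <- r[r$significant & r$lncrna_id %in% lnc, , drop = FALSE]
        if (!nrow(sig)) next
        idx <- cbind(match(sig$lncrna_id, lnc), match(sig$pathway_id, pws))
        counts[idx] <- counts[idx] + 1L
    }
    data.frame(lincrna_id = rep(lnc, times = length(pws)),
               criterion = rep(pws, each = length(lnc)),
               n_cancers = as.integer(counts),
               stringsAsFactors = FALSE)
}

#' Tumor-versus-normal expression perturbation within one cohort
#'
#' A feature is perturbed when the two-sided Wilcoxon rank-sum test of tumor
#' versus normal expression survives Benjamini-Hochberg adjustment at
#' `fdrThreshold` and the absolute difference of group means on the log2
#' scale exceeds `lfcThreshold`.
#'
#' @param x a [LncExperiment-class] with `condition` labels attached.
#' @param fdrThreshold BH-adjusted p-value cutoff (default 0.05).
#' @param lfcThreshold absolute log2 fold-change cutoff (default 1).
#' @param classes biotype classes tested (default lincRNA only).
#' @return data.frame with columns `feature_id`, `pvalue`, `fdr`, `lfc`,
#'   `perturbed`.
#' @export
perturbedFeatures <- function(x, fdrThreshold = 0.05, lfcThreshold = 1,
                              classes = "lincRNA") {
    stopifnot(is(x, "LncExperiment"))
    cond <- condition(x)
    if (is.null(cond)) stop("no condition labels attached; see attachLabels()")
    tum <- cond == "tumor"
    nor <- cond == "normal"
    if (!any(tum) || !any(nor)) stop("need both tumor and normal samples")
    ids <- lncrnaIds(x, classes)
    if (!length(ids)) stop("no features of the requested biotype")
    v <- exprValues(x)
    pv <- vapply(ids, function(f)
        suppressWarnings(wilcox.test(v[f, tum], v[f, nor])$p.value),
        numeric(1L))
    lfc <- rowMeans(v[ids, tum, drop = FALSE]) -
        rowMeans(v[ids, nor, drop = FALSE])
    fdr <- adjustFdr(pv)
    data.frame(feature_id = ids, pvalue = pv, fdr = fdr, lfc = lfc,
               perturbed = fdr < fdrThreshold & abs(lfc) > lfcThreshold,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Count expression-perturbation recurrence across cohorts
#'
#' Applies [perturbedFeatures()] per cohort and counts, for each lincRNA, the
#' cohorts in which it is perturbed. Cohorts whose normal-sample count is not
#' above `minNormal` are excluded from this criterion with a warning.
#'
#' @param cohorts list of [LncExperiment-class] objects with `condition`
#'   labels.
#' @param minNormal minimum normal-sample count, exclusive (default 5: a
#'   cohort must have more than five normals).
#' @param fdrThreshold,lfcThreshold,classes passed to [perturbedFeatures()].
#' @return data.frame with columns `lincrna_id`, `criterion` (`"deg"`),
#'   `n_cancers`.
#' @export
perturbationRecurrence <- function(cohorts, minNormal = 5L,
                                   fdrThreshold = 0.05, lfcThreshold = 1,
                                   classes = "lincRNA") {
    stopifnot(is.list(cohorts), length(cohorts) >= 1L)
    counts <- list()
    used <- 0L
    for (i in seq_along(cohorts)) {
        x <- cohorts[[i]]
        nNorm <- sum(condition(x) == "normal")
        if (nNorm <= minNormal) {
            warning(sprintf("cohort %d skipped: %d normal samples (need > %d)",
                            i, nNorm, minNormal))
            next
        }
        used <- used + 1L
        de <- perturbedFeatures(x, fdrThreshold, lfcThreshold, classes)
        counts[[length(counts) + 1L]] <-
            setNames(de$perturbed, de$feature_id)
    }
    if (!used) stop("no cohort has enough normal samples")
    lnc <- sort(unique(unlist(lapply(counts, names))), method = "radix")
    n <- setNames(integer(length(lnc)), lnc)
    for (cc in counts) {
        hit <- names(cc)[cc]
        n[hit] <- n[hit] + 1L
    }
    data.frame(lincrna_id = lnc, criterion = "deg", n_cancers = as.integer(n),
               stringsAsFactors = FALSE)
}

#' Aggregate recurrence counts into the priority table
#'
#' Per criterion (each pathway, plus `"deg"` when supplied), lincRNAs are
#' ranked ascending by recurrence count with average ranks at ties, and the
#' rank is normalized by the number of lincRNAs so that the most recurrent
#' lincRNA scores 1. The final score is the arithmetic mean of the normalized
#' ranks over all criteria present (18 for the canonical 17 pathways plus
#' differential expression). Missing (lincRNA, criterion) combinations count
#' as 0.
#'
#' @param counts data.frame with columns `lincrna_id`, `criterion`,
#'   `n_cancers` — typically `rbind(countRecurrence(...),
#'   perturbationRecurrence(...))`.
#' @return data.frame sorted by decreasing `f_score`: `lincrna_id`, one
#'   `rank_<criterion>` column per criterion, `f_score`.
#' @export
aggregatePriority <- function(counts) {
    stopifnot(all(c("lincrna_id", "criterion", "n_cancers") %in%
                  colnames(counts)))
    lnc <- sort(unique(counts$lincrna_id), method = "radix")
    crit <- sort(unique(counts$criterion), method = "radix")
    cm <- matrix(0L, length(lnc), length(crit),
                 dimnames = list(lnc, crit))
    cm[cbind(match(counts$lincrna_id, lnc),
             match(counts$criterion, crit))] <- counts$n_cancers
    ranks <- apply(cm, 2L, function(col) rank(col) / length(col))
    if (length(lnc) == 1L) ranks <- matrix(1, 1L, length(crit),
                                           dimnames = list(lnc, crit))
    f <- rowMeans(ranks)
    out <- data.frame(lincrna_id = lnc, ranks, f_score = as.numeric(f),
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(out)[seq_along(crit) + 1L] <- paste0("rank_", crit)
    out <- out[order(-out$f_score, out$lincrna_id, method = "radix"), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Recovery metrics of a screen against planted truth
#'
#' @param results screen result data.frame from [screenPathways()].
#' @param truth truth table from [generateCohort()] (`lncrna_id`, `role`,
#'   `pathway_id`, `sign`).
#' @return list with `sensitivity` (recovered planted regulator-pathway pairs
#'   / planted pairs), `specificity` (fraction of null-lncRNA pairs not
#'   flagged), `confounder_rejection` (fraction of purity-confounder lncRNAs
#'   with no significant pathway), and the pair counts behind each.
#' @export
truthMetrics <- function(results, truth) {
    stopifnot(all(c("lncrna_id", "pathway_id", "significant") %in%
                  colnames(results)),
              all(c("lncrna_id", "role") %in% colnames(truth)))
    key <- paste(results$lncrna_id, results$pathway_id, sep = "\r")
    sig <- setNames(results$significant, key)
    reg <- truth[truth$role == "regulator", , drop = FALSE]
    planted <- paste(reg$lncrna_id, reg$pathway_id, sep = "\r")
    sens <- if (nrow(reg)) {
        hits <- sig[planted]
        hits[is.na(hits)] <- FALSE
        mean(hits)
    } else NA_real_
    nullIds <- truth$lncrna_id[truth$role == "null"]
    nullRows <- results$lncrna_id %in% nullIds
    spec <- if (any(nullRows)) mean(!results$significant[nullRows]) else
        NA_real_
    confIds <- truth$lncrna_id[truth$role == "purity_confounder"]
    confRej <- if (length(confIds)) {
        flagged <- vapply(confIds, function(id)
            any(results$significant[results$lncrna_id == id]), logical(1L))
        mean(!flagged)
    } else NA_real_
    list(sensitivity = sens, specificity = spec,
         confounder_rejection = confRej,
         n_planted_pairs = nrow(reg), n_null_pairs = sum(nullRows),
         n_confounders = length(confIds))
}
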