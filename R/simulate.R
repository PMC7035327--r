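## Synthetic cohorts with planted ground truth.
##
## A latent-activity model per pathway: each pathway k has a per-sample
## activity a_k; member genes load on a_k, and in tumor samples a_k carries a
## purity loading (bulk immune-pathway expression tracks the non-malignant
## cell fraction). A planted regulator lncRNA of pathway k is
## l = sign * (effectSize * a_k + sqrt(1-effectSize^2) * u) with idiosyncratic
## component u, and the pathway's member genes additionally receive a direct
## loading on u (scaled by effectSize): a causal modulator moves its targets
## beyond what the shared activity explains. Purity-confounder lncRNAs and a
## matched non-pathway coding block load on purity only, perturbed lincRNAs
## get a tumor-specific mean shift, and null features are independent noise.
## All values are generated directly on the log2 scale.

.PATHWAY_NAMES <- c(
    "TCR_signaling", "BCR_signaling", "Chemokine_signaling",
    "Antigen_processing", "NK_cytotoxicity", "Cytokine_receptor",
    "TGFb_family", "TNF_family", "Interleukin_signaling",
    "Interferon_signaling", "Antimicrobials", "Complement_cascade",
    "Chemokine_receptor", "Cytokine_family", "Interleukin_receptor",
    "Interferon_receptor", "TGFb_receptor")

.CELL_TYPES <- c("B_cell", "CD4_Tcell", "CD8_Tcell", "Macrophage",
                 "Neutrophil", "Dendritic")

#' Build a simulation configuration
#'
#' Defaults describe the reference study condition used throughout the test
#' suite: 100 tumor samples (plus 20 normals for the perturbation criterion),
#' 1000 coding genes, 200 lncRNAs, 5 pathways of 50 genes, regulator effect
#' size 0.6, seed 42.
#'
#' @param nTumor,nNormal tumor / normal sample counts.
#' @param nCoding,nLncrna coding gene and lncRNA counts.
#' @param nPathways,pathwaySize pathway layout; the first
#'   `nPathways * pathwaySize` coding genes form the membership blocks.
#' @param nRegulators planted regulator lncRNAs (assigned to pathways
#'   round-robin; every third one with negative sign).
#' @param nConfounders purity-confounder lncRNAs.
#' @param nConfoundedGenes purity-loaded coding genes outside all pathways.
#' @param nPerturbed lincRNAs mean-shifted in tumor samples.
#' @param effectSize correlation between a regulator and its pathway activity,
#'   in \[0, 1) (0 plants no signal; the direct regulator-to-member channel
#'   scales with it too).
#' @param geneLoading loading of a member gene on its pathway activity.
#' @param directEffect loading of member genes on their regulator's
#'   idiosyncratic component, scaled by `effectSize` (a causal modulator
#'   moves its target genes beyond what the shared activity explains).
#' @param purityLoading loading of pathway activity on standardized tumor
#'   purity (negative default: immune activity falls as purity rises).
#' @param confounderStrength purity loading of confounder features, in
#'   \[0, 1).
#' @param noiseSd multiplier on the idiosyncratic noise (1 keeps the stated
#'   loadings as exact population correlations).
#' @param foldChange tumor/normal fold change of perturbed lincRNAs (the mean
#'   shift on the log2 scale is `log2(foldChange)`).
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return a validated [SimulationConfig-class].
#' @export
simConfig <- function(nTumor = 100L, nNormal = 20L, nCoding = 1000L,
                      nLncrna = 200L, nPathways = 5L, pathwaySize = 50L,
                      nRegulators = 5L, nConfounders = 10L,
                      nConfoundedGenes = 30L, nPerturbed = 10L,
                      effectSize = 0.6, geneLoading = 0.10,
                      directEffect = 0.20,
                      purityLoading = -0.6, confounderStrength = 0.8,
                      noiseSd = 1, foldChange = 4, seed = 42L) {
    cfg <- new("SimulationConfig",
               nTumor = as.integer(nTumor), nNormal = as.integer(nNormal),
               nCoding = as.integer(nCoding), nLncrna = as.integer(nLncrna),
               nPathways = as.integer(nPathways),
               pathwaySize = as.integer(pathwaySize),
               nRegulators = as.integer(nRegulators),
               nConfounders = as.integer(nConfounders),
               nConfoundedGenes = as.integer(nConfoundedGenes),
               nPerturbed = as.integer(nPerturbed),
               effectSize = effectSize, geneLoading = geneLoading,
               directEffect = directEffect,
               purityLoading = purityLoading,
               confounderStrength = confounderStrength,
               noiseSd = noiseSd, foldChange = foldChange,
               seed = as.integer(seed))
    validObject(cfg)
    cfg
}

.pathwayNames <- function(k) {
    if (k <= length(.PATHWAY_NAMES)) .PATHWAY_NAMES[seq_len(k)]
    else c(.PATHWAY_NAMES, sprintf("Pathway%02d",
                                   seq.int(length(.PATHWAY_NAMES) + 1L, k)))
}

#' Generate one synthetic cohort with planted truth
#'
#' @param config a [SimulationConfig-class] (see [simConfig()]).
#' @return list with components `expression` (a [LncExperiment-class] holding
#'   tumor and normal samples, purity for tumors, condition labels),
#'   `pathways` (named member list), `infiltration` (tumor samples x cell
#'   types matrix: noisy copies of the pathway activities), `truth`
#'   (data.frame `lncrna_id`, `role`, `pathway_id`, `sign`) and `config`.
#' @examples
#' cohort <- generateCohort(simConfig(nTumor = 30, nNormal = 8,
#'                                    nCoding = 100, nLncrna = 20,
#'                                    nPathways = 2, pathwaySize = 20,
#'                                    nRegulators = 2, nConfounders = 2,
#'                                    nConfoundedGenes = 5, nPerturbed = 2))
#' @export
generateCohort <- function(config = simConfig()) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    nT <- config@nTumor
    nN <- config@nNormal
    n <- nT + nN
    samples <- c(sprintf("T%04d", seq_len(nT)),
                 if (nN) sprintf("N%04d", seq_len(nN)))
    cond <- rep(c("tumor", "normal"), c(nT, nN))
    pur <- rep(NA_real_, n)
    pur[seq_len(nT)] <- rbeta(nT, 2, 2)
    zp <- rep(0, n)
    zp[seq_len(nT)] <- as.numeric(scale(pur[seq_len(nT)]))
    K <- config@nPathways
    pl <- config@purityLoading
    A <- matrix(rnorm(K * n), K, n)
    A[, seq_len(nT)] <- pl * matrix(zp[seq_len(nT)], K, nT, byrow = TRUE) +
        sqrt(1 - pl^2) * A[, seq_len(nT), drop = FALSE]

    ns <- config@noiseSd
    gl <- config@geneLoading
    cs <- config@confounderStrength
    es <- config@effectSize
    de <- config@directEffect * es

    ## planted regulators: round-robin pathway assignment, every third with
    ## negative sign; drawn before the genes so members can load on u
    nReg <- config@nRegulators
    regPathway <- if (nReg) (seq_len(nReg) - 1L) %% K + 1L else integer()
    regSign <- ifelse(seq_len(nReg) %% 3L == 0L, -1L, 1L)
    U <- if (nReg) matrix(rnorm(nReg * n), nReg, n) else
        matrix(0, 0L, n)

    gIds <- sprintf("G%05d", seq_len(config@nCoding))
    G <- ns * matrix(rnorm(config@nCoding * n), config@nCoding, n)
    pwNames <- .pathwayNames(K)
    pathways <- vector("list", K)
    names(pathways) <- pwNames
    for (k in seq_len(K)) {
        idx <- seq.int((k - 1L) * config@pathwaySize + 1L,
                       k * config@pathwaySize)
        pathways[[k]] <- gIds[idx]
        regs <- which(regPathway == k)
        direct <- if (length(regs))
            de / sqrt(length(regs)) * colSums(U[regs, , drop = FALSE]) else
            rep(0, n)
        resid <- max(1 - gl^2 - de^2, 0)
        G[idx, ] <- gl * matrix(A[k, ], length(idx), n, byrow = TRUE) +
            matrix(direct, length(idx), n, byrow = TRUE) +
            ns * sqrt(resid) *
            matrix(rnorm(length(idx) * n), length(idx), n)
    }
    if (config@nConfoundedGenes) {
        idx <- seq.int(K * config@pathwaySize + 1L,
                       K * config@pathwaySize + config@nConfoundedGenes)
        G[idx, ] <- cs * matrix(zp, length(idx), n, byrow = TRUE) +
            ns * sqrt(1 - cs^2) *
            matrix(rnorm(length(idx) * n), length(idx), n)
    }
    G <- G + runif(config@nCoding, 3, 8)

    lIds <- sprintf("L%04d", seq_len(config@nLncrna))
    Lm <- ns * matrix(rnorm(config@nLncrna * n), config@nLncrna, n)
    role <- rep("null", config@nLncrna)
    rolePw <- rep(NA_character_, config@nLncrna)
    roleSign <- rep(NA_integer_, config@nLncrna)
    i <- 0L
    for (r in seq_len(nReg)) {
        i <- i + 1L
        k <- regPathway[r]
        role[i] <- "regulator"
        rolePw[i] <- pwNames[k]
        roleSign[i] <- regSign[r]
        Lm[i, ] <- regSign[r] *
            (es * A[k, ] + ns * sqrt(1 - es^2) * U[r, ])
    }
    for (r in seq_len(config@nConfounders)) {
        i <- i + 1L
        role[i] <- "purity_confounder"
        Lm[i, ] <- cs * zp + ns * sqrt(1 - cs^2) * rnorm(n)
    }
    shift <- log2(config@foldChange)
    for (r in seq_len(config@nPerturbed)) {
        i <- i + 1L
        role[i] <- "perturbed"
        Lm[i, seq_len(nT)] <- Lm[i, seq_len(nT)] + shift
    }
    Lm <- Lm + runif(config@nLncrna, 2, 6)

    biotypeL <- rep("lincRNA", config@nLncrna)
    nulls <- which(role == "null")
    biotypeL[nulls] <- rep(c("lincRNA", "antisense", "lincRNA",
                             "other_lncRNA"), length.out = length(nulls))

    values <- rbind(G, Lm)
    rownames(values) <- c(gIds, lIds)
    colnames(values) <- samples
    x <- LncExperiment(values,
                       biotype = c(rep("coding", config@nCoding), biotypeL),
                       purity = pur, condition = cond)

    cells <- if (K <= length(.CELL_TYPES)) .CELL_TYPES[seq_len(K)] else
        c(.CELL_TYPES, sprintf("Cell%02d",
                               seq.int(length(.CELL_TYPES) + 1L, K)))
    infiltration <- t(A[, seq_len(nT), drop = FALSE]) +
        0.5 * matrix(rnorm(nT * K), nT, K)
    dimnames(infiltration) <- list(samples[seq_len(nT)], cells)

    truth <- data.frame(lncrna_id = lIds, role = role, pathway_id = rolePw,
                        sign = roleSign, stringsAsFactors = FALSE)
    list(expression = x, pathways = pathways, infiltration = infiltration,
         truth = truth, config = config)
}
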