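# Independent reference implementations used by the unit and acceptance
# tests. These are deliberately written in the most literal way possible
# (plain loops over the defining formulas), not shared with package code.

# Brute-force enrichment score: re-evaluate every prefix from scratch
# (O(n^2)) and take the value at the first index of maximal |deviation|.
bruteForceES <- function(rs, hit, weight) {
  n <- length(rs)
  nI <- sum(hit)
  nR <- sum(abs(rs[hit])^weight)
  inc <- ifelse(hit, abs(rs)^weight / nR, -1 / (n - nI))
  running <- vapply(seq_len(n),
                    function(i) sum(inc[seq_len(i)]), numeric(1))
  running[which.max(abs(running))]
}

# Truncated Kolmogorov series with a fixed number of terms (no early exit).
seriesPvalueOracle <- function(es, nList, nPathway, q = 100L) {
  nEff <- (nList - nPathway) * nPathway / nList
  if (es == 0) return(1)
  s <- 0
  for (k in seq_len(q)) s <- s + (-1)^(k - 1) * exp(-2 * k^2 * es^2 * nEff)
  min(max(2 * s, 1e-300), 1)
}

# From-scratch Benjamini-Hochberg step-up adjustment.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / seq.int(n, 1L) * p[o]))[ro]
}

# Small deterministic experiment: 6 coding genes, 2 lincRNAs, 8 samples.
tinyExperiment <- function() {
  set.seed(7)
  m <- matrix(rnorm(64, mean = 5), 8, 8,
              dimnames = list(c(sprintf("G%d", 1:6), "L1", "L2"),
                              sprintf("S%d", 1:8)))
  m["L1", ] <- m["G1", ] + 0.1 * rnorm(8)   # L1 tracks G1
  LncExperiment(m,
                biotype = c(rep("coding", 6), "lincRNA", "lincRNA"),
                purity = round(seq(0.2, 0.9, length.out = 8), 3),
                condition = rep("tumor", 8))
}

# Minimal screen-result data.frame for prioritization tests.
screenRow <- function(lnc, pw, sig) {
  data.frame(lncrna_id = lnc, pathway_id = pw,
             es = 0.5, n_list = 10L, n_pathway_in_list = 3L,
             pvalue = 0.01, fdr = 0.02, lncres = 0.98, significant = sig,
             stringsAsFactors = FALSE)
}
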