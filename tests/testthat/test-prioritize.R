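test_that("countRecurrence counts cohorts per (lincRNA, pathway) pair", {
  r1 <- rbind(screenRow("L1", "P1", TRUE), screenRow("L1", "P2", FALSE),
              screenRow("L2", "P1", FALSE), screenRow("L2", "P2", TRUE))
  r2 <- rbind(screenRow("L1", "P1", TRUE), screenRow("L1", "P2", TRUE),
              screenRow("L2", "P1", FALSE), screenRow("L2", "P2", FALSE))
  cnt <- countRecurrence(list(r1, r2))
  get <- function(l, p) cnt$n_cancers[cnt$lincrna_id == l & cnt$criterion == p]
  expect_identical(get("L1", "P1"), 2L)
  expect_identical(get("L1", "P2"), 1L)
  expect_identical(get("L2", "P1"), 0L)
  expect_identical(get("L2", "P2"), 1L)
})

test_that("countRecurrence unions universes and can restrict to lincRNAs", {
  r1 <- screenRow("L1", "P1", TRUE)
  r2 <- screenRow("L2", "P1", TRUE)
  expect_warning(cnt <- countRecurrence(list(r1, r2)), "disjoint")
  expect_setequal(cnt$lincrna_id, c("L1", "L2"))
  # feature absent from a cohort counts as not significant there
  expect_identical(cnt$n_cancers[cnt$lincrna_id == "L1"], 1L)
  cnt2 <- countRecurrence(list(r1), lincrnaIds = "L1")
  expect_identical(cnt2$lincrna_id, "L1")
  expect_error(countRecurrence(list(r1), lincrnaIds = "ZZ"), "empty")
})

test_that("perturbedFeatures applies the rank-sum + fold-change rule", {
  set.seed(21)
  n <- 30
  m <- rbind(G1 = rnorm(n, 5),
             Lup = c(rnorm(20, 8), rnorm(10, 5)),   # shifted +3 in tumors
             Lflat = rnorm(n, 5),
             Lsmall = c(rnorm(20, 5.4), rnorm(10, 5)))  # shift below lfc 1
  colnames(m) <- sprintf("S%02d", seq_len(n))
  x <- LncExperiment(m, biotype = c("coding", rep("lincRNA", 3)),
                     condition = rep(c("tumor", "normal"), c(20, 10)))
  de <- perturbedFeatures(x)
  expect_setequal(de$feature_id, c("Lup", "Lflat", "Lsmall"))
  expect_true(de$perturbed[de$feature_id == "Lup"])
  expect_false(de$perturbed[de$feature_id == "Lflat"])
  expect_false(de$perturbed[de$feature_id == "Lsmall"])
  # statistics reproduce the base-R building blocks
  ref <- suppressWarnings(wilcox.test(m["Lup", 1:20], m["Lup", 21:30]))
  expect_equal(de$pvalue[de$feature_id == "Lup"], ref$p.value)
  expect_equal(de$lfc[de$feature_id == "Lup"],
               mean(m["Lup", 1:20]) - mean(m["Lup", 21:30]))
  expect_identical(de$fdr, adjustFdr(de$pvalue))

  expect_error(perturbedFeatures(LncExperiment(
    m, biotype = c("coding", rep("lincRNA", 3)))), "condition")
})

test_that("perturbationRecurrence skips under-powered cohorts", {
  mk <- function(nNorm, seed) {
    set.seed(seed)
    n <- 15 + nNorm
    m <- rbind(G1 = rnorm(n, 5), Lup = c(rnorm(15, 9), rnorm(nNorm, 5)))
    colnames(m) <- sprintf("S%02d", seq_len(n))
    LncExperiment(m, biotype = c("coding", "lincRNA"),
                  condition = rep(c("tumor", "normal"), c(15, nNorm)))
  }
  expect_warning(cnt <- perturbationRecurrence(list(mk(8, 1), mk(3, 2))),
                 "skipped")
  expect_identical(cnt$criterion, "deg")
  expect_identical(cnt$n_cancers, 1L)   # only the first cohort counted
  expect_error(suppressWarnings(perturbationRecurrence(list(mk(2, 3)))),
               "no cohort")
})

test_that("aggregatePriority computes normalized average ranks exactly", {
  counts <- data.frame(
    lincrna_id = rep(c("L1", "L2", "L3", "L4"), times = 2),
    criterion = rep(c("P1", "deg"), each = 4),
    n_cancers = c(3L, 1L, 1L, 0L,   # P1
                  0L, 2L, 0L, 0L),  # deg
    stringsAsFactors = FALSE)
  pri <- aggregatePriority(counts)
  # P1 ranks: counts (3,1,1,0) -> ranks (4, 2.5, 2.5, 1) / 4
  # deg ranks: counts (0,2,0,0) -> ranks (2, 4, 2, 2) / 4
  expect_identical(pri$lincrna_id[1], "L2")   # (0.625 + 1)/2 = 0.8125 tops
  expect_equal(pri$rank_P1[pri$lincrna_id == "L1"], 1)
  expect_equal(pri$rank_P1[pri$lincrna_id == "L2"], 0.625)
  expect_equal(pri$rank_deg[pri$lincrna_id == "L2"], 1)
  expect_equal(pri$f_score[pri$lincrna_id == "L1"], (1 + 0.5) / 2)
  expect_equal(pri$f_score[pri$lincrna_id == "L2"], (0.625 + 1) / 2)
  expect_equal(pri$f_score[pri$lincrna_id == "L4"], (0.25 + 0.5) / 2)
  # sorted by decreasing f_score
  expect_false(is.unsorted(rev(pri$f_score)))
  # missing (lincRNA, criterion) combinations count as zero: dropping the
  # explicit zero rows changes nothing
  counts2 <- counts[counts$n_cancers > 0L, , drop = FALSE]
  counts2 <- rbind(counts2,
                   data.frame(lincrna_id = "L4", criterion = "P1",
                              n_cancers = 0L, stringsAsFactors = FALSE))
  pri2 <- aggregatePriority(counts2)
  expect_equal(pri2, pri)
})

test_that("truthMetrics scores recovery against planted roles", {
  truth <- data.frame(
    lncrna_id = c("R1", "C1", "N1", "N2"),
    role = c("regulator", "purity_confounder", "null", "null"),
    pathway_id = c("P1", NA, NA, NA),
    sign = c(1L, NA, NA, NA), stringsAsFactors = FALSE)
  res <- rbind(screenRow("R1", "P1", TRUE), screenRow("R1", "P2", FALSE),
               screenRow("C1", "P1", TRUE), screenRow("C1", "P2", FALSE),
               screenRow("N1", "P1", FALSE), screenRow("N1", "P2", TRUE),
               screenRow("N2", "P1", FALSE), screenRow("N2", "P2", FALSE))
  m <- truthMetrics(res, truth)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0.75)         # 1 of 4 null pairs flagged
  expect_equal(m$confounder_rejection, 0)   # the confounder was flagged
  expect_identical(m$n_planted_pairs, 1L)
  expect_identical(m$n_null_pairs, 4L)
  expect_identical(m$n_confounders, 1L)
})
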