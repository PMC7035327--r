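test_that("enrichmentScore worked examples and tie rule", {
  rs <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2)
  expect_equal(enrichmentScore(rs, c("g1", "g2"))$es, 1)
  expect_equal(enrichmentScore(rs, c("g4", "g5"))$es, -1)
  out <- enrichmentScore(rs, c("g2", "g9"))
  expect_identical(out$nList, 5L)
  expect_identical(out$nPathwayInList, 1L)   # absent members dropped
  expect_length(out$profile, 5L)
  # symmetric profile: +D and -D at the same magnitude -> earliest index wins
  rs2 <- c(a = 1, b = 1, c = 1, d = 1)
  prof <- enrichmentScore(rs2, c("a", "b"), weight = 0)$profile
  expect_equal(prof, c(0.5, 1, 0.5, 0))
})

test_that("enrichmentScore accepts RankedGeneList and validates input", {
  rgl <- new("RankedGeneList", lncrnaId = "L1",
             geneIds = c("a", "b", "c"), rsScores = c(2, 1, -1))
  expect_equal(enrichmentScore(rgl, c("a"))$es,
               enrichmentScore(c(a = 2, b = 1, c = -1), "a")$es)
  expect_error(enrichmentScore(rgl, c("x", "y")), "no overlap")
  expect_error(enrichmentScore(rgl, c("a", "b", "c")), "entire ranked list")
  expect_error(enrichmentScore(c(1, 2), "a"), "names")
  expect_error(enrichmentScore(c(a = 1, b = 2), "a"), "non-increasing")
  # weight 1 with all-zero hit scores is undefined
  expect_error(enrichmentScore(c(a = 1, b = 0, c = -1), "b", weight = 1),
               "weights are zero")
})

test_that("weight 0 reduces to the classic two-sample KS statistic", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    rs <- sort(rnorm(n), decreasing = TRUE)
    names(rs) <- sprintf("g%02d", seq_len(n))
    hit <- sample(names(rs), sample(seq_len(n - 1L), 1))
    es <- enrichmentScore(rs, hit, weight = 0)$es
    # KS statistic between hit positions and miss positions
    pos <- seq_len(n)
    ks <- suppressWarnings(
      ks.test(pos[names(rs) %in% hit], pos[!names(rs) %in% hit]))
    expect_equal(abs(es), unname(ks$statistic), tolerance = 1e-12)
  }
})

test_that("esPvalue matches its documented example and properties", {
  expect_equal(esPvalue(1, 5, 2), 0.1813004, tolerance = 1e-6)
  expect_equal(esPvalue(0, 100, 10), 1)
  expect_identical(esPvalue(NA, 100, 10), NA_real_)
  # vectorized, symmetric in sign of es
  expect_equal(esPvalue(c(-0.4, 0.4), 100, 10),
               rep(esPvalue(0.4, 100, 10), 2))
  # strictly decreasing in |es|
  es <- seq(0.05, 1, by = 0.05)
  p <- esPvalue(es, 200, 20)
  expect_true(all(diff(p) < 0))
  # decreasing in effective n (larger list, same pathway fraction)
  expect_lt(esPvalue(0.3, 1000, 100), esPvalue(0.3, 100, 10))
  # clamped into [1e-300, 1]
  expect_equal(esPvalue(1, 20000, 2000), 1e-300)
  expect_lte(esPvalue(0.01, 10, 2), 1)
  expect_error(esPvalue(0.5, 10, 10), "nList > nPathway")
})

test_that("lncresScore maps the p-value onto [-1, 1] with ES sign", {
  expect_equal(lncresScore(1, 0.0025), 0.995)
  expect_equal(lncresScore(-1, 0.0025), -0.995)
  expect_equal(lncresScore(0, 0.0025), 0)
  expect_equal(lncresScore(0.7, 0), 1)
  expect_equal(lncresScore(0.7, 1), -1)
  expect_error(lncresScore(1, 2), "pvalue")
})

test_that("adjustFdr is Benjamini-Hochberg", {
  set.seed(5)
  p <- runif(50)
  expect_identical(adjustFdr(p), p.adjust(p, method = "BH"))
  expect_true(all(adjustFdr(p) >= p))
})

test_that("isSignificant is strict on both thresholds and NA-safe", {
  expect_false(isSignificant(0.995, 0.01))      # boundary lncres fails
  expect_true(isSignificant(0.9951, 0.01))
  expect_true(isSignificant(-0.9951, 0.01))     # magnitude rule
  expect_false(isSignificant(0.999, 0.05))      # boundary fdr fails
  expect_false(isSignificant(NA, 0.01))
  expect_false(isSignificant(0.999, NA))
})

test_that("screenPathways produces a complete, sorted pair table", {
  cfg <- simConfig(nTumor = 40L, nNormal = 0L, nCoding = 120L, nLncrna = 10L,
                   nPathways = 2L, pathwaySize = 20L, nRegulators = 2L,
                   nConfounders = 2L, nConfoundedGenes = 10L, nPerturbed = 0L,
                   seed = 9L)
  co <- generateCohort(cfg)
  pw <- c(co$pathways, list(Orphan = c("NOT_A_GENE")))
  res <- screenPathways(co$expression, pw)
  expect_identical(nrow(res), 10L * 3L)
  expect_equal(res, res[order(res$lncrna_id, res$pathway_id,
                              method = "radix"), ],
               ignore_attr = TRUE)
  # zero-overlap pathway reported as NA and excluded from the FDR family
  orphan <- res$pathway_id == "Orphan"
  expect_true(all(is.na(res$es[orphan])))
  expect_false(any(res$significant[orphan]))
  evaluable <- !is.na(res$pvalue)
  expect_identical(res$fdr[evaluable], adjustFdr(res$pvalue[evaluable]))
  # lncres consistent with es and pvalue
  expect_equal(res$lncres[evaluable],
               lncresScore(res$es[evaluable], res$pvalue[evaluable]),
               tolerance = 1e-12)
  # significance flag consistent with the strict rule
  expect_identical(res$significant,
                   isSignificant(res$lncres, res$fdr))
})

test_that("screenPathways agrees with the per-lncRNA primitives", {
  cfg <- simConfig(nTumor = 30L, nNormal = 0L, nCoding = 80L, nLncrna = 4L,
                   nPathways = 2L, pathwaySize = 15L, nRegulators = 1L,
                   nConfounders = 1L, nConfoundedGenes = 5L, nPerturbed = 0L,
                   seed = 4L)
  co <- generateCohort(cfg)
  res <- screenPathways(co$expression, co$pathways)
  rgl <- buildRankedList(co$expression[, condition(co$expression) == "tumor"],
                         "L0002")
  ref <- enrichmentScore(rgl, co$pathways[[2]], weight = 0)
  row <- res[res$lncrna_id == "L0002" &
             res$pathway_id == names(co$pathways)[2], ]
  expect_equal(row$es, ref$es, tolerance = 1e-12)
  expect_identical(row$n_list, ref$nList)
  expect_identical(row$n_pathway_in_list, ref$nPathwayInList)
  expect_equal(row$pvalue, esPvalue(ref$es, ref$nList, ref$nPathwayInList),
               tolerance = 1e-12)
})

test_that("screenPathways warns on unevaluable lncRNAs and validates input", {
  x <- tinyExperiment()
  m <- exprValues(x)
  m["L2", ] <- 3
  y <- LncExperiment(m, biotype = biotype(x), purity = purity(x))
  pw <- list(P1 = c("G1", "G2", "G3"))
  expect_warning(res <- screenPathways(y, pw), "not evaluable")
  expect_true(is.na(res$es[res$lncrna_id == "L2"]))
  expect_error(screenPathways(x, list(c("G1"))), "names")
  noPur <- LncExperiment(exprValues(x), biotype = biotype(x))
  expect_error(screenPathways(noPur, pw), "purity")
})
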