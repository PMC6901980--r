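test_that("signed AFC score cancels mixed directions; direction tracks the sign", {
  fct <- makeFct(c(0.5, -0.5, 0.1, -0.2, 0.3))
  res <- afcScore(fct, c("g1", "g2"), nullEngine(nPerm = 100, seed = 1))
  expect_equal(res$score, 0)
  expect_identical(res$direction, "none")

  up <- afcScore(fct, c("g1", "g5"), nullEngine(nPerm = 100, seed = 1))
  expect_identical(up$direction, "up")
  dn <- afcScore(fct, c("g2", "g4"), nullEngine(nPerm = 100, seed = 1))
  expect_identical(dn$direction, "down")
})

test_that("exhaustive enumeration reproduces the hand-checkable worked example", {
  fct <- makeFct(c(0.1, 0.2, 0.3, 0.4, 0.5))
  ne <- nullEngine(mode = "exhaustive")

  afc <- afcScore(fct, c("g4", "g5"), ne, "top2")
  expect_equal(afc$score, 0.9)
  expect_equal(afc$p_plain, 1 / 10)
  expect_equal(afc$p_perm, 2 / 11)

  aafc <- aafcScore(fct, c("g4", "g5"), ne, "top2")
  expect_equal(aafc$score, 0.45)
  expect_equal(aafc$p_plain, 1 / 10)
  expect_equal(aafc$p_perm, 2 / 11)

  # independent enumeration oracle for the z-score
  subsetMeans <- combn(c(0.1, 0.2, 0.3, 0.4, 0.5), 2, mean)
  expect_length(subsetMeans, 10L)
  expect_equal(aafc$z, (0.45 - mean(subsetMeans)) / sd(subsetMeans))
})

test_that("Fisher's method matches the chi-squared closed form", {
  expect_equal(fisherCombined(0.37), 0.37)
  expect_equal(fisherCombined(rep(1, 4)), 1)
  # two p = 0.05: X = -4 ln 0.05 ~ 11.98, df 4
  expect_equal(fisherCombined(c(0.05, 0.05)),
               pchisq(-4 * log(0.05), df = 4, lower.tail = FALSE))
  expect_equal(fisherCombined(c(0.05, 0.05)), 0.0175, tolerance = 1e-2)
  expect_error(fisherCombined(numeric(0)), "non-empty")
  expect_error(fisherCombined(c(0.5, 1.2)), "0, 1")
  expect_warning(p0 <- fisherCombined(c(0, 0.5)), "clamped")
  expect_true(p0 > 0)
})

test_that("a flat fold-change landscape yields a degenerate null", {
  fct <- makeFct(rep(0.3, 6) * c(1, -1, 1, -1, 1, -1))
  res <- aafcScore(fct, c("g1", "g2"), nullEngine(nPerm = 50, seed = 2))
  expect_equal(res$score, 0.3)
  expect_true(res$degenerate)
  expect_equal(res$z, 0)
  expect_equal(res$p_perm, 1)
})

test_that("Monte-Carlo and exhaustive nulls agree on enumerable instances", {
  set.seed(31)
  fct <- makeFct(rnorm(12), genes = sprintf("g%02d", 1:12))
  sets <- list(c("g01", "g05", "g09"), c("g02", "g03"), c("g11", "g12", "g04"))
  nPerm <- 50000
  for (genes in sets) {
    ex <- aafcScore(fct, genes, nullEngine(mode = "exhaustive"))
    mc <- aafcScore(fct, genes, nullEngine(nPerm = nPerm, seed = 8))
    se <- sqrt(ex$p_plain * (1 - ex$p_plain) / nPerm)
    expect_lt(abs(mc$p_plain - ex$p_plain), 3 * se + 1e-9)
    exA <- afcScore(fct, genes, nullEngine(mode = "exhaustive"))
    mcA <- afcScore(fct, genes, nullEngine(nPerm = nPerm, seed = 8))
    seA <- sqrt(exA$p_plain * (1 - exA$p_plain) / nPerm)
    expect_lt(abs(mcA$p_plain - exA$p_plain), 3 * seA + 1e-9)
  }
  # the cap guards against runaway enumeration
  expect_error(
    aafcScore(makeFct(rnorm(100)), paste0("g", 1:4),
              nullEngine(mode = "exhaustive", exhaustiveCap = 1000)),
    "cap")
})

test_that("z-scores are exactly invariant to aggregation and log base", {
  set.seed(17)
  fct <- makeFct(rnorm(60), genes = sprintf("g%02d", 1:60))
  genes <- sprintf("g%02d", c(3, 7, 11, 19, 23))
  ne <- nullEngine(nPerm = 500, seed = 5)

  byMean <- aafcScore(fct, genes, ne, aggregate = "mean")
  bySum <- aafcScore(fct, genes, ne, aggregate = "sum")
  expect_identical(byMean$z, bySum$z)
  expect_identical(byMean$p_perm, bySum$p_perm)

  # rescaling all fc by 1/ln 2 (natural log -> log2) changes nothing
  fct2 <- fct; fct2$fc <- fct2$fc / log(2)
  rescaled <- aafcScore(fct2, genes, ne)
  expect_equal(rescaled$z, byMean$z, tolerance = 1e-12)
  expect_identical(rescaled$p_perm, byMean$p_perm)
  rescaledAfc <- afcScore(fct2, genes, ne)
  origAfc <- afcScore(fct, genes, ne)
  expect_identical(rescaledAfc$p_perm, origAfc$p_perm)
})

test_that("AAFC ignores the sign pattern inside a set; AFC does not", {
  set.seed(13)
  fct <- makeFct(abs(rnorm(40)), genes = sprintf("g%02d", 1:40))
  genes <- sprintf("g%02d", 1:6)
  ne <- nullEngine(nPerm = 300, seed = 4)
  base <- aafcScore(fct, genes, ne)

  flipped <- fct
  flipped$fc[c(1, 3, 5)] <- -flipped$fc[c(1, 3, 5)]
  flip <- aafcScore(flipped, genes, ne)
  expect_identical(flip$score, base$score)
  expect_identical(flip$z, base$z)
  expect_identical(flip$p_perm, base$p_perm)

  expect_false(isTRUE(all.equal(afcScore(flipped, genes, ne)$score,
                                afcScore(fct, genes, ne)$score)))
})

test_that("set genes absent from the matrix are dropped and gated by coverage", {
  fct <- makeFct(c(0.1, 0.2, 0.3, 0.4, 0.5))
  res <- aafcScore(fct, c("g4", "g5", "absent"), nullEngine(nPerm = 50, seed = 1))
  expect_identical(res$n_measured, 2L)
  expect_equal(res$coverage, 2 / 3)

  expect_warning(
    aafcScore(fct, c("g1", "zz1", "zz2"), nullEngine(nPerm = 50, seed = 1)),
    "coverage")
  expect_error(
    aafcScore(fct, c("zz1", "zz2"), nullEngine(nPerm = 50, seed = 1)),
    "no genes")
  expect_error(
    aafcScore(fct, paste0("g", 1:5), nullEngine(nPerm = 50, seed = 1)),
    "degenerate")
})

test_that("scoreCollection is deterministic and invariant to set order", {
  set.seed(77)
  fct <- makeFct(rnorm(80), genes = sprintf("g%02d", 1:80))
  gsl <- GeneSetList(list(alpha = sprintf("g%02d", 1:8),
                          beta = sprintf("g%02d", 11:18),
                          gamma = sprintf("g%02d", 21:28)))
  ne <- nullEngine(nPerm = 400, seed = 9)
  a <- scoreCollection(fct, gsl, "aafc", ne)
  b <- scoreCollection(fct, gsl, "aafc", ne)
  expect_identical(a, b)

  shuffled <- gsl[c("gamma", "alpha", "beta")]
  c1 <- scoreCollection(fct, shuffled, "aafc", ne)
  expect_identical(a[match(c1$set_name, a$set_name), ]$z, c1$z)
  expect_identical(a[match(c1$set_name, a$set_name), ]$p_perm, c1$p_perm)

  # a set with no measured genes yields a flagged row, not a drop
  gsl2 <- GeneSetList(list(alpha = sprintf("g%02d", 1:8),
                           ghost = c("zz1", "zz2")))
  expect_warning(rows <- scoreCollection(fct, gsl2, "aafc", ne), "flagged")
  expect_identical(nrow(rows), 2L)
  expect_false(rows$passed_coverage[rows$set_name == "ghost"])
  expect_true(is.na(rows$score[rows$set_name == "ghost"]))

  expect_error(scoreCollection(fct, GeneSetList(list()), "aafc", ne), "empty")
})

test_that("mixed-direction activation is visible to AAFC but not to AFC", {
  cfg <- recoveryConfig(seed = 99, delta = log(2), directionMix = 0.5,
                        nGenes = 800, nDecoys = 2, size = 30)
  sim <- simulateExperiment(cfg)
  fct <- computeFoldChanges(sim$experiment)
  genes <- sim$geneSets[["planted"]]
  ne <- nullEngine(nPerm = 1000, seed = 99)
  aafc <- aafcScore(fct, genes, ne, "planted")
  afc <- afcScore(fct, genes, ne, "planted")
  nullSd <- sd(replicate(1000, sum(fct$fc[sample.int(nrow(fct), 30)])))
  zAfc <- afc$score / nullSd
  expect_gt(aafc$z, 5)
  expect_gt(aafc$z, abs(zAfc) + 3)
  expect_gt(afc$p_perm, 0.05)

  # an all-up planted module is reported as up-regulated
  cfgUp <- recoveryConfig(seed = 98, delta = log(2), directionMix = 1,
                          nGenes = 800, nDecoys = 2, size = 30)
  simUp <- simulateExperiment(cfgUp)
  fctUp <- computeFoldChanges(simUp$experiment)
  resUp <- afcScore(fctUp, simUp$geneSets[["planted"]], ne, "planted")
  expect_identical(resUp$direction, "up")
  expect_lt(resUp$p_perm, 0.05)
})
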