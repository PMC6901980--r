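test_that("fold changes and p-values match the textbook pooled-variance t-test", {
  ctrl <- c(1.0, 1.2, 0.9, 1.1, 1.0)
  trt <- c(1.6, 1.5, 1.8, 1.4, 1.7)
  m <- rbind(g1 = c(trt, ctrl))
  meta <- data.frame(sample_id = paste0("s", 1:10), condition_id = "c",
                     cohort = rep(c("treatment", "control"), each = 5))
  # a second gene so the matrix is non-trivial
  m <- rbind(m, g2 = rnorm(10, 5))
  colnames(m) <- meta$sample_id
  fct <- computeFoldChanges(ToxExperiment(m, meta))

  oracle <- t.test(trt, ctrl, var.equal = TRUE)
  expect_equal(fct$fc[1], mean(trt) - mean(ctrl))
  expect_equal(fct$t[1], unname(oracle$statistic))
  expect_equal(fct$p[1], oracle$p.value)

  # parameterised cross-check on random cohorts
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5, sd = 2)
    mm <- rbind(x = c(a, b), y = rnorm(10))
    colnames(mm) <- meta$sample_id
    f <- computeFoldChanges(ToxExperiment(mm, meta))
    o <- t.test(a, b, var.equal = TRUE)
    expect_equal(f$t[1], unname(o$statistic), tolerance = 1e-12)
    expect_equal(f$p[1], o$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate genes follow the documented conventions", {
  meta <- data.frame(sample_id = paste0("s", 1:10), condition_id = "c",
                     cohort = rep(c("treatment", "control"), each = 5))
  # identical cohorts per gene -> fc 0, t 0, p 1
  m <- rbind(g1 = rep(2, 10), g2 = rnorm(10))
  colnames(m) <- meta$sample_id
  fct <- computeFoldChanges(ToxExperiment(m, meta))
  expect_equal(fct$fc[1], 0)
  expect_equal(fct$t[1], 0)
  expect_equal(fct$p[1], 1)

  # constant shift with zero variance -> smallest positive p, warning
  m2 <- rbind(g1 = c(rep(1 + log(2), 5), rep(1, 5)), g2 = rnorm(10))
  colnames(m2) <- meta$sample_id
  expect_warning(fct2 <- computeFoldChanges(ToxExperiment(m2, meta)),
                 "zero variance")
  expect_equal(fct2$fc[1], log(2))
  expect_equal(fct2$p[1], .Machine$double.xmin)

  # the same shift with jitter recovers fc = ln 2
  set.seed(1)
  jit <- rnorm(10, sd = 1e-9)
  m3 <- rbind(g1 = c(rep(1 + log(2), 5), rep(1, 5)) + jit, g2 = rnorm(10))
  colnames(m3) <- meta$sample_id
  fct3 <- computeFoldChanges(ToxExperiment(m3, meta))
  expect_equal(fct3$fc[1], log(2), tolerance = 1e-6)
})

test_that("fold change is antisymmetric under cohort swap, p unchanged", {
  set.seed(9)
  meta <- data.frame(sample_id = paste0("s", 1:10), condition_id = "c",
                     cohort = rep(c("treatment", "control"), each = 5))
  swapped <- meta
  swapped$cohort <- rep(c("control", "treatment"), each = 5)
  m <- matrix(rnorm(200, 5), nrow = 20,
              dimnames = list(paste0("g", 1:20), meta$sample_id))
  f1 <- computeFoldChanges(ToxExperiment(m, meta))
  f2 <- computeFoldChanges(ToxExperiment(m, swapped))
  expect_equal(f1$fc, -f2$fc)
  expect_equal(f1$p, f2$p)
})

test_that("DEG calling applies the q and beta thresholds over BH-adjusted p", {
  # BH oracle: hand computation q_i = min_{j>=i} p_(j) * m / j
  fct <- makeFct(fc = rep(1, 5), p = c(0.01, 0.02, 0.03, 0.04, 0.2))
  degs <- callDegs(fct)
  expect_equal(degs$q, c(0.05, 0.05, 0.05, 0.05, 0.2))
  expect_true(all(degs$is_deg[1:4]))
  expect_false(degs$is_deg[5])

  # all p = 1 -> no DEGs
  expect_identical(sum(callDegs(makeFct(rep(2, 4), p = 1))$is_deg), 0L)

  # |fc| = 0.40 misses the 0.41 natural-log bound even at tiny q
  one <- callDegs(makeFct(c(0.40, 1), p = c(0.001, 0.001)))
  expect_false(one$is_deg[1])
  expect_true(one$is_deg[2])

  expect_error(callDegs(fct, qMax = 2), "qMax")
  expect_error(callDegs(fct, betaMin = -1), "betaMin")
})

test_that("DEG count is monotone in both thresholds and q is monotone in p-rank", {
  set.seed(21)
  fct <- makeFct(fc = rnorm(200), p = runif(200))
  nDeg <- function(q, b) sum(callDegs(fct, qMax = q, betaMin = b)$is_deg)
  for (b in c(0, 0.2, 0.41, 1)) {
    expect_true(nDeg(0.01, b) <= nDeg(0.05, b))
    expect_true(nDeg(0.05, b) <= nDeg(0.2, b))
  }
  for (q in c(0.05, 0.2)) {
    expect_true(nDeg(q, 1) <= nDeg(q, 0.41))
    expect_true(nDeg(q, 0.41) <= nDeg(q, 0))
  }
  degs <- callDegs(fct)
  ord <- order(degs$p)
  expect_true(all(diff(degs$q[ord]) >= 0))
})

test_that("per-gene t-test is calibrated on null simulations", {
  # fraction of p < 0.05 across >= 10,000 null gene-replicates
  ps <- unlist(lapply(1:6, function(r) {
    cfg <- simulationConfig(nGenes = 2000, modules = list(), seed = 400 + r)
    computeFoldChanges(simulateExperiment(cfg)$experiment)$p
  }))
  expect_gte(length(ps), 10000)
  frac <- mean(ps < 0.05)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
})

test_that("DEG overlap reports counts, R^2 and slope over shared DEGs", {
  a <- callDegs(makeFct(fc = c(1, -1, 0.9, 0.2), p = c(0.001, 0.001, 0.001, 0.9)))
  # identical lists with identical fc
  ov <- degOverlap(a, a)
  expect_identical(ov$n_shared, 3L)
  expect_equal(ov$r_squared, 1)
  expect_equal(ov$slope, 1)

  # disjoint DEG lists
  b <- callDegs(makeFct(fc = c(0.1, 0.1, 0.1, 2), p = c(0.9, 0.9, 0.9, 0.001)))
  ov2 <- degOverlap(a, b)
  expect_identical(ov2$n_shared, 0L)
  expect_true(is.na(ov2$r_squared))

  # exact anti-correlation: R^2 = 1 but negative slope carries the sign
  c1 <- a; c1$fc <- -c1$fc
  ov3 <- degOverlap(a, c1)
  expect_equal(ov3$r_squared, 1)
  expect_equal(ov3$slope, -1)
})
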