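test_that("ANOVA F matches the hand-worked two-group example", {
  # group1 = {0.1, 0.2, 0.3}, group2 = {0.2, 0.4}: grand mean 0.24,
  # group means 0.2 / 0.3, dfB = 1, dfW = 3
  X <- matrix(c(0.1, 0.2, 0.3, 0.2, 0.4), ncol = 1,
              dimnames = list(NULL, "f1"))
  lab <- rep(c("ACP", "non-ACP"), c(3, 2))
  fs <- anovaFScores(X, lab)
  tab <- fScores(fs)
  expect_equal(tab$MSB, 0.012)
  expect_equal(tab$MSW, 0.04 / 3)
  expect_equal(tab$F, 0.9)
  expect_identical(tab$direction, -1L)   # positive-group mean is smaller
  expect_identical(fs@dfB, 1L)
  expect_identical(fs@dfW, 3L)
})

test_that("degenerate features get the documented sentinel F values", {
  X <- cbind(equal = c(0, 1, 0, 1),        # equal group means -> F = 0
             separating = c(0, 0, 1, 1),   # MSW = 0, MSB > 0 -> Inf
             constant = rep(0.5, 4))       # MSW = MSB = 0 -> F = 0
  lab <- rep(c("ACP", "non-ACP"), each = 2)
  tab <- fScores(anovaFScores(X, lab))
  expect_equal(tab$F[1], 0)
  expect_identical(tab$F[2], Inf)
  expect_equal(tab$F[3], 0)
  # the separator outranks everything, constants tie-break by index
  expect_identical(rankFeatures(anovaFScores(X, lab)), c(2L, 1L, 3L))
})

test_that("ANOVA F agrees with stats::anova and with squared pooled t", {
  set.seed(202)
  for (i in 1:100) {
    m1 <- sample(3:12, 1); m2 <- sample(3:12, 1)
    X <- matrix(rnorm((m1 + m2) * 4), ncol = 4)
    lab <- rep(c("ACP", "non-ACP"), c(m1, m2))
    mine <- fScores(anovaFScores(X, lab))$F
    grp <- factor(lab)
    for (j in 1:4) {
      oracle <- stats::anova(stats::lm(X[, j] ~ grp))$`F value`[1]
      expect_equal(mine[j], oracle, tolerance = 1e-9)
      tsq <- stats::t.test(X[lab == "ACP", j], X[lab != "ACP", j],
                           var.equal = TRUE)$statistic^2
      expect_equal(mine[j], unname(tsq), tolerance = 1e-9)
    }
  }
})

test_that("feature ranking is descending, tie-stable and deterministic", {
  expect_identical(rankFeatures(c(0.5, 2.0, 1.0)), c(2L, 3L, 1L))
  expect_identical(rankFeatures(c(1.0, 1.0)), c(1L, 2L))
  expect_identical(rankFeatures(rep(0, 5)), 1:5)
  set.seed(9)
  F <- sample(c(runif(50), rep(0.25, 10)))
  expect_identical(rankFeatures(F), rankFeatures(F))
  expect_true(all(diff(F[rankFeatures(F)]) <= 0))
})

test_that("signed F matrix arranges dipeptides by residue pair with class polarity", {
  # build features where AC separates upward (enriched in positives) and
  # CA downward, then check matrix placement and sign
  ds <- labeledPeptides(c(p1 = "ACACAC", p2 = "ACACA"),
                        c(n1 = "CACACA", n2 = "CACAC"))
  fe <- encodePeptides(ds, "ggap", g = 0)
  fs <- anovaFScores(fe)
  m <- signedFMatrix(fs)
  expect_identical(dim(m), c(20L, 20L))
  expect_identical(rownames(m), STANDARD_AA)
  expect_gt(m["A", "C"], 0)   # AC enriched in ACPs
  expect_lt(m["C", "A"], 0)   # CA enriched in non-ACPs
  tab <- fScores(fs)
  expect_equal(m["A", "C"], tab$F[tab$feature == "AC"] *
                 tab$direction[tab$feature == "AC"])
  # zero table -> zero matrix
  X0 <- matrix(0.5, 6, 400, dimnames = list(NULL, dipeptideNames()))
  m0 <- signedFMatrix(anovaFScores(X0, rep(c("ACP", "non-ACP"), 3)))
  expect_true(all(m0 == 0))
  # wrong dimension is an error
  expect_error(signedFMatrix(anovaFScores(X0[, 1:20],
                                          rep(c("ACP", "non-ACP"), 3))),
               "400")
})

test_that("degenerate inputs to anovaFScores error", {
  X <- matrix(rnorm(8), ncol = 2)
  expect_error(anovaFScores(X, rep("ACP", 4)), "non-empty")
  expect_error(anovaFScores(X[1:2, ], c("ACP", "non-ACP")), "M >= 3")
})

test_that("IFS finds a single separating feature at Theta = 1 with Acc = 1", {
  toy <- toySeparable(nPos = 12, nNeg = 12, extraNoise = 2)
  run <- runIFS(toy$X, toy$label, k = 4, seed = 2)
  expect_s4_class(run, "IFSRun")
  expect_identical(theta(run), 1L)
  expect_equal(run@peakAcc, 1)
  expect_identical(nrow(ifsCurve(run)), ncol(toy$X))
  expect_identical(run@ranking[1], 1L)   # the separator ranks first
})

test_that("IFS is reproducible under a fixed seed and validates its ranking", {
  set.seed(31)
  X <- matrix(runif(40 * 3), 40, dimnames = list(NULL, paste0("f", 1:3)))
  lab <- rep(c("ACP", "non-ACP"), each = 20)
  r1 <- runIFS(X, lab, k = 5, seed = 10)
  r2 <- runIFS(X, lab, k = 5, seed = 10)
  expect_identical(ifsCurve(r1), ifsCurve(r2))
  expect_error(runIFS(X, lab, ranking = c(1L, 2L)), "permutation")
  expect_error(runIFS(X, lab, ranking = c(1L, 2L, 2L)), "permutation")
})

test_that("pure-noise IFS stays near the majority-class rate", {
  set.seed(77)
  X <- matrix(runif(200 * 3), 200, dimnames = list(NULL, paste0("f", 1:3)))
  lab <- rep(c("ACP", "non-ACP"), c(80, 120))
  run <- runIFS(X, lab, k = 5, seed = 4)
  majority <- 120 / 200
  band <- 1.96 * sqrt(majority * (1 - majority) / 200)
  expect_lt(abs(run@peakAcc - majority), band + 1e-9)
})

test_that("selectBestG with a single candidate returns it unconditionally", {
  ds <- randomDataset(nPos = 6, nNeg = 6, Lmin = 12, Lmax = 20, seed = 8)
  sel <- selectBestG(ds, gValues = 3, k = 3, seed = 5)
  expect_identical(sel$g, 3)
  expect_named(sel$runs, "g3")
  expect_identical(sel$best, sel$runs$g3)
})

test_that("selection TSV exports carry the documented columns", {
  ds <- randomDataset(nPos = 5, nNeg = 5, seed = 21)
  fe <- encodePeptides(ds, "ggap", g = 1)
  fs <- anovaFScores(fe)
  p1 <- tempfile(); writeFScoreTable(fs, p1)
  tab <- readTableTSV(p1)
  expect_identical(colnames(tab),
                   c("feature", "F", "MSB", "MSW", "direction", "rank"))
  expect_identical(sort(tab$rank), 1:400)
  expect_identical(tab$feature[tab$rank == 1],
                   fScores(fs)$feature[rankFeatures(fs)[1]])
  run <- runIFS(featureValues(fe)[, 1:5],
                encodedLabels(fe), k = 3, seed = 1)
  p2 <- tempfile(); writeIFSCurve(run, p2)
  expect_identical(colnames(readTableTSV(p2)),
                   c("tau", "Sn", "Sp", "Acc", "MCC"))
  p3 <- tempfile(); writeSignedMatrix(signedFMatrix(fs), p3)
  sm <- readTableTSV(p3)
  expect_identical(dim(sm), c(20L, 21L))
  expect_identical(sm$residue, STANDARD_AA)
})
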