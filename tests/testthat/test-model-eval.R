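test_that("the four metrics follow the confusion-count formulas", {
  perfect <- computeMetrics(c(Npos = 138, Nneg = 206, NminusPlus = 0,
                              NplusMinus = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))

  random <- computeMetrics(c(Npos = 100, Nneg = 80, NminusPlus = 50,
                             NplusMinus = 40))
  expect_equal(random[["MCC"]], 0)

  total <- computeMetrics(c(Npos = 10, Nneg = 10, NminusPlus = 10,
                            NplusMinus = 10))
  expect_equal(total[["Acc"]], 0)
  expect_equal(total[["MCC"]], -1)

  m <- computeMetrics(c(Npos = 138, Nneg = 206, NminusPlus = 14,
                        NplusMinus = 3))
  expect_equal(m[["Sn"]], 1 - 14 / 138)
  expect_equal(m[["Sp"]], 1 - 3 / 206)
  expect_equal(m[["Acc"]], 1 - 17 / 344)
  expect_equal(m[["MCC"]], 0.8978, tolerance = 1e-4)

  expect_error(computeMetrics(c(Npos = 5, Nneg = 5, NminusPlus = 6,
                                NplusMinus = 0)), "inconsistent")
})

test_that("accuracy decomposes as the class-size weighted Sn/Sp mean", {
  set.seed(15)
  for (i in 1:50) {
    np <- sample(1:30, 1); nn <- sample(1:30, 1)
    cts <- c(Npos = np, Nneg = nn, NminusPlus = sample(0:np, 1),
             NplusMinus = sample(0:nn, 1))
    m <- computeMetrics(cts)
    expect_equal(m[["Acc"]],
                 (np * m[["Sn"]] + nn * m[["Sp"]]) / (np + nn))
  }
})

test_that("degenerate MCC is an explicit NA marker, never zero", {
  # everything predicted positive: one factor under the root vanishes
  allPos <- computeMetrics(c(Npos = 10, Nneg = 10, NminusPlus = 0,
                             NplusMinus = 10))
  expect_true(is.na(allPos[["MCC"]]))
  expect_equal(allPos[["Acc"]], 0.5)
  # an absent class makes Sn (or Sp) undefined too
  noNeg <- computeMetrics(c(Npos = 5, Nneg = 0, NminusPlus = 1,
                            NplusMinus = 0))
  expect_true(is.na(noNeg[["Sp"]]))
  expect_true(is.na(noNeg[["MCC"]]))
  expect_identical(formatMetrics(noNeg)$MCC, "undefined")
})

test_that("confusionCounts tallies the four cells", {
  truth <- c("ACP", "ACP", "ACP", "non-ACP", "non-ACP")
  pred <- c("ACP", "non-ACP", "ACP", "ACP", "non-ACP")
  expect_identical(confusionCounts(truth, pred),
                   c(Npos = 3L, Nneg = 2L, NminusPlus = 1L,
                     NplusMinus = 1L))
})

test_that("training separates the separable toy and validates its inputs", {
  toy <- toySeparable(10, 10)
  model <- trainACP(toy$X, toy$label)
  expect_s4_class(model, "ACPModel")
  res <- predictACP(model, toy$X)
  expect_identical(res$label, toy$label)
  expect_identical(res$verdict[1], "Anticancer peptide")
  expect_identical(res$verdict[20], "non-Anticancer peptide")
  expect_true(all(res$decision_value[1:10] > 0))

  expect_error(trainACP(toy$X, rep("ACP", 20)), "both classes")
  expect_error(trainACP(toy$X, toy$label, subset = 2L), "subset")
  expect_error(trainACP(toy$X, toy$label, subset = integer()), "subset")
})

test_that("prediction enforces the model's encoding contract", {
  ds <- randomDataset(nPos = 5, nNeg = 5, seed = 17)
  model <- trainACP(ds, g = 1)
  fe2 <- encodePeptides(ds, "ggap", g = 2)
  expect_error(predictACP(model, fe2), "mismatch")
  expect_error(predictACP(model, matrix(0, 2, 20)), "mismatch")
  # empty matrix in the right shape -> empty verdict set
  empty <- matrix(numeric(), 0, 400,
                  dimnames = list(NULL, dipeptideNames()))
  expect_identical(nrow(predictACP(model, empty)), 0L)
  expect_error(predictACP(model, character()), "empty")
})

test_that("grid search honours its grids and finds a separating config", {
  toy <- toySeparable(8, 8)
  single <- gridSearch(toy$X, toy$label, Cgrid = 2, gammaGrid = 0.125,
                       k = 4, seed = 1)
  expect_equal(single$C, 2)
  expect_equal(single$gamma, 0.125)
  wide <- gridSearch(toy$X, toy$label, Cgrid = 2^(0:4),
                     gammaGrid = 2^(-3:1), k = 4, seed = 1)
  expect_equal(wide$Acc, 1)
  expect_error(gridSearch(toy$X, toy$label, Cgrid = numeric()),
               "non-empty")
})

test_that("jackknife is deterministic, order-invariant and exact on the toy", {
  toy <- toySeparable(10, 10, extraNoise = 1)
  jk <- jackknifeEvaluate(toy$X, toy$label)
  expect_equal(jk$metrics[["Acc"]], 1)
  expect_identical(jk$counts[["Npos"]] + jk$counts[["Nneg"]],
                   length(toy$label))
  # permuting rows permutes predictions but leaves pooled counts unchanged
  perm <- sample(seq_along(toy$label))
  jk2 <- jackknifeEvaluate(toy$X[perm, , drop = FALSE], toy$label[perm])
  expect_identical(jk2$counts, jk$counts)
  expect_error(jackknifeEvaluate(toy$X[1:2, , drop = FALSE],
                                 toy$label[1:2]), "3 samples")
})

test_that("k-fold pools predictions and reduces to jackknife at k = M", {
  ds <- randomDataset(nPos = 7, nNeg = 9, seed = 23)
  fe <- encodePeptides(ds, "ggap", g = 0)
  jk <- jackknifeEvaluate(fe)
  kM <- kfoldEvaluate(fe, k = length(ds))
  expect_identical(kM$counts, jk$counts)
  expect_identical(kM$metrics, jk$metrics)
  expect_identical(as.character(kM$predictions),
                   as.character(jk$predictions))

  k5 <- kfoldEvaluate(fe, k = 5, seed = 2)
  expect_identical(sum(table(k5$folds)), length(ds))
  expect_identical(k5$counts[["Npos"]], 7L)
  expect_identical(k5$counts[["Nneg"]], 9L)
  # same seed, same partition; different seed, (generally) different one
  expect_identical(makeFolds(classLabels(ds), 5, seed = 2),
                   makeFolds(classLabels(ds), 5, seed = 2))
  expect_error(makeFolds(classLabels(ds), 1), "k must be")
})

test_that("independent test warns on train/test overlap and reports verdicts", {
  ds <- randomDataset(nPos = 8, nNeg = 8, seed = 29)
  model <- trainACP(ds, g = 1)
  expect_warning(res <- independentTest(model, ds), "training set")
  expect_identical(nrow(res$verdicts), length(ds))
  expect_identical(colnames(res$verdicts),
                   c("id", "decision_value", "label", "verdict", "truth"))
  expect_true(all(res$verdicts$verdict %in%
                    c("Anticancer peptide", "non-Anticancer peptide")))
  # a fresh dataset does not warn
  ds2 <- randomDataset(nPos = 4, nNeg = 4, seed = 31)
  expect_silent(res2 <- independentTest(model, ds2))
  # single-class test set: the absent class's rate is the NA marker
  one <- ds2[1]
  resOne <- independentTest(model, one)
  expect_identical(nrow(resOne$verdicts), 1L)
  expect_true(is.na(resOne$metrics[["Sp"]]))
})

test_that("model persistence round-trips and verifies its archive", {
  ds <- randomDataset(nPos = 6, nNeg = 6, seed = 37)
  model <- trainACP(ds, g = 1, subset = 1:50)
  path <- tempfile(fileext = ".acp")
  saveACPModel(model, path)
  back <- loadACPModel(path)
  expect_identical(predictACP(back, ds), predictACP(model, ds))
  expect_identical(back@subset, 1:50)
  expect_identical(back@cost, 2)
  # version and dimension checks
  broken <- readRDS(path); broken$version <- "other-0"
  p2 <- tempfile(); saveRDS(broken, p2)
  expect_error(loadACPModel(p2), "version")
  broken2 <- readRDS(path); broken2$featureNames <- broken2$featureNames[1:10]
  p3 <- tempfile(); saveRDS(broken2, p3)
  expect_error(loadACPModel(p3), "dimension|inconsistent")
})

test_that("retraining on identical inputs gives identical predictions", {
  ds <- randomDataset(nPos = 6, nNeg = 8, seed = 41)
  probe <- randomDataset(nPos = 3, nNeg = 3, seed = 43)
  m1 <- trainACP(ds, g = 1)
  m2 <- trainACP(ds, g = 1)
  expect_identical(predictACP(m1, probe), predictACP(m2, probe))
})
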