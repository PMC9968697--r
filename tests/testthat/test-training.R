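test_that("Z-score binarization uses a strict threshold and keeps NAs", {
  expect_equal(binarizeZscore(c(-5, -4, 0)), c(1L, 0L, 0L))
  expect_equal(binarizeZscore(c(-4.0001, NA)), c(1L, NA_integer_))
  expect_equal(binarizeZscore(-1, threshold = 0), 1L)
})

test_that("random splits have 80:10:10 floor sizes and are seeded", {
  s <- randomSplit(100, seed = 1)
  expect_equal(lengths(s[c("train", "validation", "test")]),
               c(train = 80L, validation = 10L, test = 10L))
  expect_identical(randomSplit(100, seed = 1), s)
  expect_false(identical(randomSplit(100, seed = 2)$train, s$train))

  s10 <- randomSplit(10, seed = 5)
  expect_equal(lengths(s10[c("train", "validation", "test")]),
               c(train = 8L, validation = 1L, test = 1L))

  for (n in c(3, 17, 53, 101)) {
    sp <- randomSplit(n, seed = n)
    all_idx <- c(sp$train, sp$validation, sp$test)
    expect_equal(sort(all_idx), seq_len(n))  # disjoint and exhaustive
  }
})

test_that("scaffold splits never divide a scaffold group", {
  smi <- c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "CCO", "CCC", "CCCC",
           "C1CCCCC1", "CC1CCCCC1", "c1ccncc1", "Cc1ccncc1")
  sp <- scaffoldSplit(smi)
  scaf <- sp$scaffolds
  subsetOf <- integer(length(smi))
  subsetOf[sp$train] <- 1L
  subsetOf[sp$validation] <- 2L
  subsetOf[sp$test] <- 3L
  for (sc in unique(scaf))
    expect_equal(length(unique(subsetOf[scaf == sc])), 1L,
                 label = paste("scaffold", sc))
  # benzene and toluene share the benzene scaffold
  expect_equal(scaf[1], scaf[2])
  expect_equal(subsetOf[1], subsetOf[2])
  # acyclic molecules share the empty scaffold
  expect_equal(unique(scaf[4:6]), "")
})

test_that("scaffold split sizes follow 8/1/1 for all-distinct scaffolds", {
  smi <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCCC1", "c1ccoc1",
           "c1ccsc1", "c1ccc2ccccc2c1", "C1CCNCC1", "C1CCOC1", "c1cc[nH]c1")
  sp <- scaffoldSplit(smi)
  expect_equal(length(unique(vapply(smi, murckoScaffold, character(1)))),
               10L)
  expect_equal(lengths(sp[c("train", "validation", "test")]),
               c(train = 8L, validation = 1L, test = 1L))
})

test_that("k-fold CV partitions the test folds exactly once", {
  folds <- kfoldCV(10, k = 5, seed = 2)
  expect_equal(length(folds), 5L)
  expect_equal(unique(lengths(lapply(folds, `[[`, "test"))), 2L)
  expect_equal(sort(unlist(lapply(folds, `[[`, "test"))), 1:10)
  expect_identical(kfoldCV(10, k = 5, seed = 2), folds)
  for (f in folds)
    expect_equal(sort(c(f$train, f$validation, f$test)), 1:10)
})

test_that("metrics match hand arithmetic and brute-force oracles", {
  expect_equal(computeMetric(c(1, 2), c(1, 4), "rmse"), sqrt(2))
  expect_equal(computeMetric(c(1, 2), c(1, 4), "mae"), 1)
  expect_equal(aurocScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)

  set.seed(19)
  for (rep in 1:10) {
    n <- 40
    sc <- round(rnorm(n), 1)  # rounding forces ties
    lab <- rbinom(n, 1, 0.4)
    if (sum(lab) == 0 || sum(lab) == n) next
    expect_lt(abs(aurocScore(sc, lab) - oracleAuroc(sc, lab)), 1e-8)
    expect_lt(abs(auprcScore(sc, lab) - oracleAuprc(sc, lab)), 1e-8)
    expect_lt(abs(rmseScore(sc, lab) - oracleRmse(sc, lab)), 1e-8)
    expect_lt(abs(maeScore(sc, lab) - oracleMae(sc, lab)), 1e-8)
  }
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  sc <- rnorm(60)
  lab <- rbinom(60, 1, 0.5)
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(lab, sc, levels = c(0, 1), direction = "<"))))
  expect_equal(aurocScore(sc, lab), ref, tolerance = 1e-10)
})

test_that("random-score AUPRC approaches the positive rate", {
  set.seed(31)
  n <- 4000
  lab <- rep(c(1, 0), times = c(n / 10, n - n / 10))
  sc <- runif(n)
  ap <- auprcScore(sc, lab)
  expect_lt(abs(ap - 0.1), 0.03)
  expect_lt(abs(ap - oracleAuprc(sc, lab)), 1e-8)
})

test_that("multi-task metrics mask missing targets and skip one-class tasks", {
  pred <- cbind(c(1, 2, 3), c(0.9, 0.1, 0.5))
  targ <- cbind(c(1, NA, 4), c(1, 0, NA))
  expect_equal(computeMetric(pred, targ, "rmse"),
               mean(c(sqrt(mean(c(0, 1))), sqrt(mean(c(0.01, 0.01))))))
  targ2 <- cbind(c(1, 0, NA), c(1, 1, NA))  # task 2 has a single class
  expect_warning(v <- computeMetric(pred, targ2, "auroc"), "one class")
  expect_equal(v, aurocScore(pred[1:2, 1], targ2[1:2, 1]))
})

test_that("masking a task leaves the other tasks' gradients unchanged", {
  m <- fixtureModel(nTasks = 2, taskType = "regression", T = 1, d = 12,
                    nHeads = 6, seed = 9)
  g <- fixtureGraphs(16L)[[8]]
  prep <- abtmpnn:::.prepareMolecule(g, m)
  gradFor <- function(target, mask) {
    tape <- abtmpnn:::ag_tape()
    pn <- abtmpnn:::lapply_params_var(m@params, tape)
    out <- abtmpnn:::ag_forward_molecule(prep, pn, m@config, tape)
    # per-task sum so the shared normalizer does not couple the tasks
    loss <- abtmpnn:::ag_mse_masked(out, target, mask, tape)
    loss <- abtmpnn:::ag_scale(loss, sum(mask), tape)
    abtmpnn:::ag_backward(tape, loss)
    abtmpnn:::.collectGrads(pn)
  }
  gBoth <- gradFor(matrix(c(1, 2), 1), matrix(c(1, 1), 1))
  gOne <- gradFor(matrix(c(1, 0), 1), matrix(c(1, 0), 1))
  # gradient of task 1's column of W2 must be identical
  expect_equal(gBoth$W2[, 1], gOne$W2[, 1], tolerance = 1e-12)
  expect_equal(gBoth$b2[1, 1], gOne$b2[1, 1], tolerance = 1e-12)
  # and the masked task contributes nothing in the masked run
  expect_equal(gOne$W2[, 2], rep(0, 12))
})

test_that("training is deterministic and fits degenerate targets", {
  gs <- fixtureGraphs(16L)[1:8]
  y <- matrix(vapply(gs, nAtoms, integer(1)), ncol = 1)
  mk <- function() abtModel(nTasks = 1, taskType = "regression", T = 1,
                            d = 12, nHeads = 6, lambda = 0.1, seed = 5)
  cfg <- trainConfig(epochs = 3, batchSize = 4, lrSchedule = "constant",
                     lr = 1e-3, metric = "rmse", seed = 11)
  f1 <- trainModel(mk(), gs, y, split = NULL, config = cfg)
  f2 <- trainModel(mk(), gs, y, split = NULL, config = cfg)
  expect_identical(f1$history$loss, f2$history$loss)

  yConst <- matrix(5, 8, 1)
  fc <- trainModel(mk(), gs, yConst, split = NULL,
                   config = trainConfig(epochs = 40, batchSize = 8,
                                        lrSchedule = "constant", lr = 5e-3,
                                        metric = "rmse",
                                        stopAtMetric = 0.05, seed = 1))
  expect_lt(fc$bestMetric, 0.1)
})

test_that("noam schedule warms up then decays between its bounds", {
  sch <- list(kind = "noam", initLr = 1e-4, maxLr = 1e-3, finalLr = 1e-4,
              warmupSteps = 10, totalSteps = 100)
  lrs <- vapply(1:100, abtmpnn:::.lrAt, numeric(1), schedule = sch)
  expect_equal(lrs[10], 1e-3)
  expect_true(all(diff(lrs[1:10]) > 0))
  expect_true(all(diff(lrs[11:100]) < 0))
  expect_gte(min(lrs), 1e-4 - 1e-12)
})

test_that("bayesian hyperopt respects the grid, budget and seed", {
  single <- list(T = 3L, lambda = 0.1, d = 300L, p = 0)
  res <- bayesianHyperopt(function(cfg) cfg$lambda,
                          space = lapply(single, function(v) v), iters = 20)
  expect_equal(nrow(res$trials), 1L)
  expect_equal(res$best$T, 3L)

  evalLog <- list()
  obj <- function(cfg) {
    evalLog[[length(evalLog) + 1L]] <<- cfg
    (cfg$T - 4) ^ 2 + (cfg$lambda - 0.2) ^ 2 + (cfg$d / 1000 - 1) ^ 2 +
      cfg$p
  }
  res1 <- bayesianHyperopt(obj, iters = 12, seed = 7)
  grid <- hyperparamGrid()
  expect_lte(nrow(res1$trials), 12L)
  for (i in seq_len(nrow(res1$trials))) {
    expect_true(res1$trials$T[i] %in% grid$T)
    expect_true(any(abs(res1$trials$lambda[i] - grid$lambda) < 1e-9))
    expect_true(res1$trials$d[i] %in% grid$d)
    expect_true(any(abs(res1$trials$p[i] - grid$p) < 1e-9))
  }
  res2 <- bayesianHyperopt(obj, iters = 12, seed = 7)
  expect_identical(res1$trials, res2$trials)
})

test_that("dataset CSVs round-trip with missing targets", {
  path <- tempfile(fileext = ".csv")
  writeDataset(path, c("CCO", "CCC"), cbind(y1 = c(1.5, NA), y2 = c(0, 1)))
  ds <- readDataset(path)
  expect_equal(ds$smiles, c("CCO", "CCC"))
  expect_equal(ds$targets[, "y1"], c(1.5, NA))
  unlink(path)
})
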