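smallModel <- function(...) fixtureModel(nTasks = 1,
  taskType = "regression", T = 2, d = 12, nHeads = 6, lambda = 0.1,
  seed = 3, ...)

test_that("initBondHidden is ReLU of the projected concatenated features", {
  m <- smallModel()
  g <- parseSmiles("CCO")
  mz <- m
  mz@params$Wi <- mz@params$Wi * 0
  expect_equal(initBondHidden(mz, g), matrix(0, 4, 12))

  # negated identity on nonnegative features clips everything to zero
  dIn <- atomFeatureDim() + bondFeatureDim()
  mneg <- abtModel(nTasks = 1, taskType = "regression", T = 1, d = dIn,
                   nHeads = 1, seed = 1)
  mneg@params$Wi <- -diag(dIn)
  expect_equal(initBondHidden(mneg, g), matrix(0, 4, dIn))

  h <- initBondHidden(m, g)
  f0 <- cbind(atomFeatures(g)[g@bondOrigin, ], bondFeatures(g))
  ref <- unname(pmax(f0 %*% m@params$Wi, 0))
  expect_equal(h, ref, tolerance = 1e-12)
})

test_that("bond messages follow the directed no-backflow rule on a path", {
  g <- parseSmiles("CCC")  # path A-B-C
  m <- smallModel()
  h <- initBondHidden(m, g)
  msg <- bondMessageStep(h, g)
  db <- directedBonds(g)
  # identify the path: terminal atoms have degree 1
  deg <- table(factor(db[, 1], levels = 1:3))
  A <- as.integer(names(deg)[deg == 1][1])
  C <- as.integer(names(deg)[deg == 1][2])
  B <- setdiff(1:3, c(A, C))
  idx <- function(v, w) which(db[, 1] == v & db[, 2] == w)
  expect_equal(msg[idx(A, B), ], rep(0, 12))          # leaf origin vanishes
  expect_equal(msg[idx(B, C), ], h[idx(A, B), ])      # only non-reverse input
  expect_equal(msg[idx(B, A), ], h[idx(C, B), ])
})

test_that("bond messages match the double-loop oracle on a star graph", {
  g <- parseSmiles("CC(C)C")  # central atom with three leaves
  m <- smallModel()
  set.seed(2)
  h <- matrix(rnorm(2 * nBonds(g) * 12), 2 * nBonds(g), 12)
  msg <- bondMessageStep(h, g)
  ref <- oracleMessageStep(h, g@bondOrigin, g@bondDest, g@bondReverse)
  expect_lt(max(abs(msg - ref)), 1e-12)
  # message to each leaf = sum of the other two leaf-to-center hiddens
  db <- directedBonds(g)
  ctr <- as.integer(names(which.max(table(db[, 1]))))
  leaves <- setdiff(seq_len(nAtoms(g)), ctr)
  for (lf in leaves) {
    others <- setdiff(leaves, lf)
    inc <- vapply(others, function(o) which(db[, 1] == o & db[, 2] == ctr),
                  integer(1))
    e <- which(db[, 1] == ctr & db[, 2] == lf)
    expect_equal(msg[e, ], colSums(h[inc, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("bondUpdate applies skip connection, projection and ReLU", {
  m <- smallModel()
  g <- parseSmiles("CCO")
  h0 <- initBondHidden(m, g)
  zero <- matrix(0, nrow(h0), 12)
  expect_equal(bondUpdate(m, h0, zero, useBondAttention = FALSE), h0)
  mz <- m
  mz@params$Wh <- mz@params$Wh * 0
  set.seed(4)
  msg <- matrix(rnorm(length(h0)), nrow(h0))
  expect_equal(bondUpdate(mz, h0, msg, useBondAttention = FALSE), h0)

  out <- bondUpdate(m, h0, msg, useBondAttention = TRUE)
  b <- oracleFastformer(m, msg) + msg
  ref <- pmax(h0 + b %*% m@params$Wh, 0)
  expect_lt(max(abs(out - ref)), 1e-6)
})

test_that("atomAggregate sums outgoing bond hiddens per atom", {
  m <- smallModel()
  gIso <- parseSmiles("C")
  agg <- atomAggregate(m, gIso, matrix(0, 0, 12))
  ref <- unname(pmax(cbind(atomFeatures(gIso), matrix(0, 1, 12)) %*% m@params$Wo +
                matrix(as.numeric(m@params$bo), 1, 12, byrow = FALSE), 0))
  expect_equal(agg, ref, tolerance = 1e-12)

  mz <- m
  mz@params$Wo <- mz@params$Wo * 0
  mz@params$bo <- mz@params$bo * 0
  g <- parseSmiles("CCC")
  expect_equal(atomAggregate(mz, g, matrix(1, 4, 12)), matrix(0, 3, 12))

  set.seed(6)
  h <- matrix(rnorm(4 * 12), 4)
  agg2 <- atomAggregate(m, g, h)
  bondSum <- matrix(0, 3, 12)
  for (e in seq_len(4)) bondSum[g@bondOrigin[e], ] <-
    bondSum[g@bondOrigin[e], ] + h[e, ]
  ref2 <- cbind(atomFeatures(g), bondSum) %*% m@params$Wo
  ref2 <- pmax(sweep(ref2, 2, as.numeric(m@params$bo), "+"), 0)
  expect_lt(max(abs(agg2 - ref2)), 1e-12)
})

test_that("atomEmbedding adds the attended states through a skip", {
  m <- smallModel()
  set.seed(7)
  mv <- matrix(rnorm(36), 3)
  mz <- m
  mz@params$aaWQ <- lapply(mz@params$aaWQ, function(w) w * 0)
  mz@params$aaWK <- lapply(mz@params$aaWK, function(w) w * 0)
  mz@params$aaWV <- lapply(mz@params$aaWV, function(w) w * 0)
  mz@params$aaWO <- mz@params$aaWO * 0
  mz@params$aaBO <- mz@params$aaBO * 0
  expect_equal(atomEmbedding(mz, mv), mv)

  out <- atomEmbedding(m, mv)
  ref <- oracleMultihead(m@params$aaWQ, m@params$aaWK, m@params$aaWV,
                         m@params$aaWO, m@params$aaBO, mv) + mv
  expect_lt(max(abs(out - ref)), 1e-9)
})

test_that("moleculeReadout sums atoms order-free and applies the FFN", {
  m <- smallModel()
  desc <- rnorm(200)
  h1 <- matrix(rnorm(12), 1)
  r1 <- moleculeReadout(m, h1, desc)
  expect_equal(r1$embedding, as.numeric(h1))

  set.seed(8)
  h <- matrix(rnorm(60), 5)
  r <- moleculeReadout(m, h, desc)
  rp <- moleculeReadout(m, h[sample(5), ], desc)
  expect_equal(r$output, rp$output, tolerance = 1e-12)

  z <- matrix(c(colSums(h), desc), 1)
  hid <- pmax(z %*% m@params$W1 + as.numeric(m@params$b1)[col(z %*% m@params$W1)], 0)
  ref <- hid %*% m@params$W2 + as.numeric(m@params$b2)
  expect_equal(r$output, as.numeric(ref), tolerance = 1e-10)
})

test_that("batched forward equals per-molecule forward", {
  m <- smallModel()
  gs <- fixtureGraphs(16L)[c(1, 5, 9)]
  batch <- modelForward(m, gs)
  for (i in 1:3)
    expect_equal(batch[i, ], modelForward(m, gs[i])[1, ], tolerance = 1e-12)
  dup <- modelForward(m, gs[c(2, 2)])
  expect_equal(dup[1, ], dup[2, ])
  expect_identical(modelForward(m, gs), batch)  # bit-stable rerun
  expect_equal(dim(modelForward(m, list())), c(0L, 1L))
})

test_that("full-model predictions are invariant to atom relabeling", {
  m <- smallModel()
  set.seed(10)
  gs <- fixtureGraphs(16L)[c(3, 7, 12)]
  for (g in gs) {
    perm <- sample(nAtoms(g))
    p1 <- modelForward(m, list(g))
    p2 <- modelForward(m, list(permuteGraph(g, perm)))
    expect_lt(max(abs(p1 - p2)), 1e-4)
  }
})

test_that("a single small training step decreases the loss", {
  m <- smallModel()
  g <- fixtureGraphs(16L)[[6]]
  y <- matrix(3)
  lossOf <- function(model) {
    pred <- modelForward(model, list(g))
    (pred[1, 1] - y[1, 1]) ^ 2
  }
  prep <- abtmpnn:::.prepareMolecule(g, m)
  tape <- abtmpnn:::ag_tape()
  pn <- abtmpnn:::lapply_params_var(m@params, tape)
  out <- abtmpnn:::ag_forward_molecule(prep, pn, m@config, tape)
  loss <- abtmpnn:::ag_mse_masked(out, y, matrix(1), tape)
  abtmpnn:::ag_backward(tape, loss)
  grads <- abtmpnn:::.collectGrads(pn)
  flat <- abtmpnn:::.flattenParams(m@params)
  lr <- 1e-7
  for (nm in names(flat)) flat[[nm]] <- flat[[nm]] - lr * grads[[nm]]
  m2 <- m
  m2@params <- abtmpnn:::.unflattenParams(flat, m@params)
  expect_lt(lossOf(m2), lossOf(m))
})

test_that("the ablation family is constructible with expected parameter counts", {
  mk <- function(bond, atom, bias) abtModel(nTasks = 1,
    taskType = "regression", T = 2, d = 12, nHeads = 6, lambda = 0.1,
    bondAttention = bond, atomAttention = atom, atomBias = bias, seed = 1)
  cfgs <- list(
    m1 = mk("none", FALSE, FALSE),          # plain directed MPNN baseline
    m2 = mk("transformer", FALSE, FALSE),
    m3 = mk("fastformer", FALSE, FALSE),
    m4 = mk("none", TRUE, FALSE),
    m5 = mk("none", TRUE, TRUE),
    m6 = mk("fastformer", TRUE, FALSE),
    m7 = mk("fastformer", TRUE, TRUE))
  np <- vapply(cfgs, nParams, integer(1))
  expect_lt(np["m1"], np["m2"])
  expect_lt(np["m1"], np["m3"])
  expect_lt(np["m1"], np["m4"])
  expect_equal(np[["m4"]], np[["m5"]])  # bias matrices add no parameters
  expect_lt(np["m3"], np["m6"])
  expect_equal(np[["m6"]], np[["m7"]])
  expect_false(any(grepl("^(ba|bt|aa)", names(abtmpnn:::.flattenParams(cfgs$m1@params)))))
  # every configuration runs forward
  g <- fixtureGraphs(16L)[5]
  for (m in cfgs) expect_equal(dim(modelForward(m, g)), c(1L, 1L))
})

test_that("checkpoints reload bit-compatibly", {
  m <- smallModel()
  gs <- fixtureGraphs(16L)[1:3]
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  expect_identical(modelForward(m, gs), modelForward(m2, gs))
  unlink(path)
})
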