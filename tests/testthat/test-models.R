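# Separable 4-class score-like features for fast SVM/ANN tests, built
# directly in feature space (no profiles needed).
clusterFeatures <- function(nPerClass, d = 20L, sep = 0.12, seed = 1L) {
  set.seed(seed)
  stopifnot(d %% 4 == 0)
  w <- d %/% 4L
  centers <- matrix(0.2, 4, d)
  for (k in 1:4) centers[k, ((k - 1) * w + 1):(k * w)] <- 0.2 + sep
  X <- do.call(rbind, lapply(1:4, function(k)
    matrix(rep(centers[k, ], each = nPerClass), nPerClass, d) +
      matrix(rnorm(nPerClass * d, sd = 0.02), nPerClass, d)))
  X <- abs(X)
  rownames(X) <- paste0("p", seq_len(nrow(X)))
  list(X = X, y = rep(LOCATION_CLASSES, each = nPerClass))
}

test_that("winner-takes-all equals an argmax oracle with fixed tie order", {
  expect_identical(winnerTakesAll(c(N = 0.2, Y = 0.1, C = 0.6, E = 0.1)),
                   list(class = "C", score = 0.6))
  expect_identical(winnerTakesAll(c(N = 0.5, Y = 0.5, C = 0.1, E = 0.1))$class, "N")
  for (s in 1:1000) {
    set.seed(s)
    sv <- structure(round(runif(4), 3), names = LOCATION_CLASSES)
    w <- winnerTakesAll(sv)
    expect_identical(w$class, LOCATION_CLASSES[which.max(sv)])
    expect_identical(w$score, max(sv))
  }
  # across several vectors the global maximum wins
  two <- list(c(N = 0.3, Y = 0.2, C = 0.1, E = 0.4),
              c(N = 0.1, Y = 0.9, C = 0.2, E = 0.1))
  expect_identical(winnerTakesAll(two), list(class = "Y", score = 0.9))
})

test_that("stack inputs have the fixed 12-component layout", {
  z <- structure(numeric(4), names = LOCATION_CLASSES)
  expect_identical(unname(buildStackInput(z, z, z)), rep(0, 12))
  a <- structure(c(0.1, 0.2, 0.3, 0.4), names = LOCATION_CLASSES)
  b <- structure(c(0.5, 0.6, 0.7, 0.8), names = LOCATION_CLASSES)
  cc <- structure(c(0.9, 0.8, 0.7, 0.6), names = LOCATION_CLASSES)
  x <- buildStackInput(a, b, cc)
  expect_identical(unname(x[5]), 0.5)  # set B, class N starts block two
  expect_identical(unname(x["B_Y"]), 0.6)
  # split and rebuild round-trips (blocks renamed back to class order)
  rn <- function(v) structure(unname(v), names = LOCATION_CLASSES)
  expect_identical(buildStackInput(rn(x[1:4]), rn(x[5:8]), rn(x[9:12])), x)
  expect_error(buildStackInput(1:4, a, b), "named")
})

test_that("the perceptron forward pass matches hand arithmetic", {
  zero <- new("AnnModel", W1 = matrix(0, 2, 12), b1 = c(0, 0),
              W2 = matrix(0, 4, 2), b2 = rep(0, 4), seed = 1L, config = list())
  expect_equal(unname(annForward(zero, rep(0.3, 12))), rep(0.5, 4))
  # 2-2-2-style toy embedded in the 12-input frame
  W1 <- matrix(0, 2, 12); W1[1, 1] <- 1; W1[2, 2] <- -2
  W2 <- matrix(0, 4, 2); W2[1, ] <- c(1, 1); W2[2, ] <- c(-1, 0.5)
  m <- new("AnnModel", W1 = W1, b1 = c(0.5, 0), W2 = W2, b2 = c(0, 0.25, 0, 0),
           seed = 1L, config = list())
  x <- c(0.8, 0.4, rep(0, 10))
  h <- 1 / (1 + exp(-(c(0.8 * 1 + 0.5, 0.4 * -2))))
  o <- 1 / (1 + exp(-(c(h[1] + h[2], -h[1] + 0.5 * h[2] + 0.25, 0, 0))))
  expect_equal(unname(annForward(m, x)), o)
  set.seed(5)
  X <- matrix(runif(36), 3, 12)
  O <- annForward(m, X)
  expect_true(all(O > 0 & O < 1))
  expect_equal(unname(O[2, ]), unname(annForward(m, X[2, ])))
  expect_error(annForward(m, rep(0.5, 11)), "length")
})

test_that("connection counting multiplies consecutive layer sizes", {
  expect_identical(countConnections(c(12, 28, 4)), 448L)
  expect_identical(countConnections(c(4, 1, 4)), 8L)
  expect_identical(countConnections(c(16, 28, 4)), 560L)
  expect_error(countConnections(5), "two layers")
})

test_that("backprop training fits separable data deterministically", {
  cl <- clusterFeatures(15L, d = 12L, sep = 0.25, seed = 21L)
  # narrow-range inputs give a long initial error plateau: allow patience
  ann <- trainAnn(cl$X, cl$y, hidden = 8L, seed = 9L, epochs = 1500L, patience = 300L)
  pred <- LOCATION_CLASSES[max.col(annForward(ann, cl$X), ties.method = "first")]
  expect_gte(mean(pred == cl$y), 0.95)
  ann2 <- trainAnn(cl$X, cl$y, hidden = 8L, seed = 9L, epochs = 1500L, patience = 300L)
  expect_identical(ann@W1, ann2@W1)
  expect_identical(ann@W2, ann2@W2)
  # stored weight count matches the connection arithmetic
  expect_identical(length(ann@W1) + length(ann@W2),
                   countConnections(c(12, 8, 4)))
  # one example per class still converges to its labels
  tiny <- clusterFeatures(1L, d = 12L, sep = 0.3, seed = 22L)
  annT <- trainAnn(tiny$X, tiny$y, hidden = 6L, seed = 2L, epochs = 1500L,
                   patience = 300L)
  predT <- LOCATION_CLASSES[max.col(annForward(annT, tiny$X), ties.method = "first")]
  expect_identical(predT, tiny$y)
})

test_that("one-vs-rest training recovers signal and stays at chance on noise", {
  cl <- clusterFeatures(30L, seed = 31L)
  spec <- list(1:6)
  ss <- trainOvrSvm(cl$X, cl$y, spec, grid = svmGridSmall(), cvFolds = 5L, seed = 7L)
  expect_true(all(ss@params$cvAccuracy >= 0.90))
  # identical call reproduces identical tuned parameters
  ss2 <- trainOvrSvm(cl$X, cl$y, spec, grid = svmGridSmall(), cvFolds = 5L, seed = 7L)
  expect_identical(ss@params, ss2@params)
  # shuffled labels: balanced binary CV accuracy near chance (a single
  # hyperparameter point, so no best-of-grid selection bias)
  clBig <- clusterFeatures(100L, seed = 32L)
  set.seed(8)
  yShuf <- sample(clBig$y)
  ssN <- trainOvrSvm(clBig$X, yShuf, spec,
                     grid = data.frame(cost = 1, gamma = 0.05),
                     cvFolds = 5L, seed = 7L)
  expect_true(all(ssN@params$cvAccuracy >= 0.40 & ssN@params$cvAccuracy <= 0.60))
  expect_error(trainOvrSvm(cl$X[1:30, ], cl$y[1:30], spec, cvFolds = 40L), "40-fold")
})

test_that("one-vs-rest scores are calibrated probabilities favouring the true class", {
  cl <- clusterFeatures(30L, seed = 31L)
  ss <- trainOvrSvm(cl$X, cl$y, list(1:6), grid = svmGridSmall(), cvFolds = 5L, seed = 7L)
  sc <- scoreOvr(ss, cl$X)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_identical(colnames(sc), LOCATION_CLASSES)
  # a strongly class-typical example scores its own class highest
  hit <- LOCATION_CLASSES[max.col(sc, ties.method = "first")] == cl$y
  expect_gte(mean(hit), 0.9)
  expect_identical(scoreOvr(ss, cl$X[1, ]), scoreOvr(ss, cl$X[1, ]))
  expect_error(scoreOvr(ss, cl$X[, 1:10]), "dimensionality")
})

test_that("architecture sweep prefers richer stacks and reports every candidate", {
  cl <- clusterFeatures(25L, d = 4L, sep = 0.15, seed = 41L)
  # three score sets: one informative, two noisy copies
  set.seed(42)
  sets <- list(A = cl$X,
               B = cl$X + matrix(rnorm(length(cl$X), sd = 0.10), nrow(cl$X)),
               C = matrix(runif(length(cl$X)), nrow(cl$X)))
  colnames(sets$B) <- colnames(sets$C) <- colnames(sets$A)
  res <- optimizeAnn(sets, cl$y, combos = list("A", "C", c("A", "B", "C")),
                     hiddenSizes = c(4L, 8L), cvFolds = 3L, seed = 5L,
                     epochs = 300L)
  expect_identical(nrow(res$sweep), 6L)
  best12 <- max(res$sweep$cvAccuracy[res$sweep$combo == "A|B|C"])
  bestA <- max(res$sweep$cvAccuracy[res$sweep$combo == "A"])
  expect_gte(best12, bestA - 0.05)
  single <- optimizeAnn(sets["A"], cl$y, combos = list("A"), hiddenSizes = 4L,
                        cvFolds = 3L, seed = 5L, epochs = 100L)
  expect_identical(single$best$combo, "A")
})
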