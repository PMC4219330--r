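#' Hyperparameter grids for the RBF-SVM stage
#'
#' `svmGridDefault()` is the canonical coarse log-spaced grid
#' (cost 2^-5..2^15, gamma 2^-15..2^3, both in steps of x4);
#' `svmGridSmall()` is a reduced grid for quick runs and tests.
#'
#' @return `data.frame` with columns `cost` and `gamma` (full cross).
#' @export
svmGridDefault <- function() {
  expand.grid(cost = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

#' @rdname svmGridDefault
#' @export
svmGridSmall <- function() {
  expand.grid(cost = 2^c(-1, 3, 7), gamma = 2^c(-7, -3, 1))
}

#' Train a one-vs-rest probabilistic SVM set
#'
#' For each of the four location classes, builds a balanced binary problem
#' (that class positive, equal-quota negatives from the other three via
#' [balanceDataset()]), grid-searches the RBF cost/gamma by mean k-fold
#' cross-validated accuracy, and refits on the full balanced set with
#' Platt-calibrated probability output.
#'
#' @param features numeric matrix (rows = proteins, rownames = ids)
#'   matching `spec`'s dimensionality.
#' @param labels factor/character of classes `N`,`Y`,`C`,`E`, aligned to
#'   rows.
#' @param spec the feature specification the matrix was built with.
#' @param grid hyperparameter grid (see [svmGridDefault()]).
#' @param cvFolds cross-validation folds (default 10).
#' @param seed integer seed (balancing, fold assignment, calibration).
#' @return an [OvrSvmSet] with per-class tuned parameters and CV accuracy.
#' @export
trainOvrSvm <- function(features, labels, spec, grid = svmGridDefault(),
                        cvFolds = 10L, seed = 1L) {
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (is.null(rownames(features))) rownames(features) <- as.character(seq_along(labels))
  if (ncol(features) != 20L * length(spec))
    stop("feature matrix does not match the specification's dimensionality")
  members <- split(rownames(features), factor(labels, levels = LOCATION_CLASSES))
  if (any(vapply(members, length, integer(1)) < cvFolds))
    stop(sprintf("every class needs at least %d examples for %d-fold CV", cvFolds, cvFolds))
  models <- list()
  params <- NULL
  for (k in LOCATION_CLASSES) {
    bal <- balanceDataset(members, positive = k, seed = seed + match(k, LOCATION_CLASSES))
    ids <- c(bal$positives, bal$negatives$id)
    X <- features[ids, , drop = FALSE]
    y <- factor(c(rep("pos", length(bal$positives)), rep("rest", nrow(bal$negatives))),
                levels = c("pos", "rest"))
    best <- NULL
    for (g in seq_len(nrow(grid))) {
      set.seed(seed + 1000L * g + match(k, LOCATION_CLASSES))
      fit <- e1071::svm(X, y, kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], cross = cvFolds, scale = FALSE)
      acc <- fit$tot.accuracy / 100
      if (is.null(best) || acc > best$acc)
        best <- list(cost = grid$cost[g], gamma = grid$gamma[g], acc = acc)
    }
    set.seed(seed + match(k, LOCATION_CLASSES))
    final <- e1071::svm(X, y, kernel = "radial", cost = best$cost,
                        gamma = best$gamma, probability = TRUE, scale = FALSE)
    models[[k]] <- final
    params <- rbind(params, data.frame(class = k, cost = best$cost,
                                       gamma = best$gamma, cvAccuracy = best$acc))
  }
  new("OvrSvmSet", spec = spec, models = models, params = params,
      classes = LOCATION_CLASSES, seed = as.integer(seed))
}

#' Score feature vectors with a one-vs-rest set
#'
#' @param svmSet an [OvrSvmSet].
#' @param features a feature vector or matrix matching the set's
#'   specification.
#' @return matrix of class-membership probabilities in [0,1], one row per
#'   input, columns `N`,`Y`,`C`,`E`. Rows need not sum to one: each column
#'   comes from an independent binary classifier.
#' @export
scoreOvr <- function(svmSet, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != 20L * length(svmSet@spec))
    stop("feature dimensionality does not match the SVM set's specification")
  out <- sapply(svmSet@classes, function(k) {
    p <- predict(svmSet@models[[k]], features, probability = TRUE)
    attr(p, "probabilities")[, "pos"]
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, svmSet@classes))
  rownames(out) <- rownames(features)
  out
}

#' Winner-takes-all class call
#'
#' Picks the class with the globally best membership probability over one
#' or more score vectors. Ties break by the fixed class order N, Y, C, E,
#' then by score-vector order.
#'
#' @param scores a named numeric vector over `N`,`Y`,`C`,`E`, or a list of
#'   such vectors (e.g. one per SVM set).
#' @return list with `class` and `score`.
#' @export
winnerTakesAll <- function(scores) {
  if (!is.list(scores)) scores <- list(scores)
  best <- NULL
  for (sv in scores) {
    sv <- sv[LOCATION_CLASSES]
    i <- which.max(sv)  # first maximum: N,Y,C,E order breaks ties
    if (is.null(best) || sv[[i]] > best$score)
      best <- list(class = LOCATION_CLASSES[i], score = sv[[i]])
  }
  best
}

#' Concatenate three score vectors into the stacking input
#'
#' Fixed layout: scores from set A (buried/exposed 40-component split),
#' then set B (most-buried/rest 40-component split), then set C (full
#' 20-component composition), classes ordered N, Y, C, E within each.
#'
#' @param a,b,c score vectors (named over the four classes) from SVM sets
#'   A, B and C.
#' @return numeric vector of length 12 named `A_N` .. `C_E`.
#' @export
buildStackInput <- function(a, b, c) {
  sets <- list(A = a, B = b, C = c)
  out <- unlist(lapply(names(sets), function(nm) {
    sv <- sets[[nm]][LOCATION_CLASSES]
    if (any(is.na(sv))) stop("score vectors must be named over N, Y, C, E")
    structure(as.numeric(sv), names = paste0(nm, "_", LOCATION_CLASSES))
  }))
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of the stacking perceptron
#'
#' `sigmoid(W2 %*% sigmoid(W1 x + b1) + b2)`: four raw per-class outputs in
#' (0,1), deliberately not normalised to sum to one — the reported score of
#' a prediction is the winning raw output.
#'
#' @param model an [AnnModel].
#' @param x input vector of length `ncol(W1)`, or a matrix with one input
#'   per row.
#' @return numeric vector (or matrix) of outputs named by class.
#' @export
annForward <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != ncol(model@W1)) stop("input length does not match the network")
    h <- sigmoid(drop(model@W1 %*% x) + model@b1)
    structure(sigmoid(drop(model@W2 %*% h) + model@b2), names = LOCATION_CLASSES)
  } else {
    if (ncol(x) != ncol(model@W1)) stop("input width does not match the network")
    H <- sigmoid(x %*% t(model@W1) + rep(model@b1, each = nrow(x)))
    O <- sigmoid(H %*% t(model@W2) + rep(model@b2, each = nrow(x)))
    colnames(O) <- LOCATION_CLASSES
    O
  }
}

#' Train the stacking perceptron
#'
#' Fits a fully connected input-hidden-output network with logistic units
#' by batch back-propagation (gradient descent with momentum on the mean
#' squared error against one-hot class targets). One tenth of the data is
#' held out for early stopping: training stops when the held-out error has
#' not improved for `patience` epochs, and the best-seen weights are kept.
#'
#' @param inputs numeric matrix of stacking inputs (rows = examples).
#' @param labels class labels aligned to rows.
#' @param hidden hidden-layer size (default 28).
#' @param seed seed for initialisation and the early-stopping split.
#' @param epochs maximum epochs (default 2000).
#' @param lr learning rate on the mean gradient (default 0.5).
#' @param momentum momentum coefficient (default 0.9).
#' @param patience early-stopping patience in epochs (default 50).
#' @param decay optional L2 weight-decay coefficient (default 0).
#' @return an [AnnModel].
#' @export
trainAnn <- function(inputs, labels, hidden = 28L, seed = 1L,
                     epochs = 2000L, lr = 0.5, momentum = 0.9, patience = 50L,
                     decay = 0) {
  labels <- as.character(labels)
  stopifnot(nrow(inputs) == length(labels), all(labels %in% LOCATION_CLASSES))
  n <- nrow(inputs); d <- ncol(inputs); K <- 4L
  T_ <- matrix(0, n, K, dimnames = list(NULL, LOCATION_CLASSES))
  T_[cbind(seq_len(n), match(labels, LOCATION_CLASSES))] <- 1
  set.seed(seed)
  W1 <- matrix(runif(hidden * d, -0.5, 0.5) / sqrt(d), hidden, d)
  b1 <- numeric(hidden)
  W2 <- matrix(runif(K * hidden, -0.5, 0.5) / sqrt(hidden), K, hidden)
  b2 <- numeric(K)
  val <- if (n >= 10L) sample(n, max(1L, n %/% 10L)) else integer()
  tr <- setdiff(seq_len(n), val)
  if (!length(tr)) { tr <- seq_len(n); val <- integer() }
  Xtr <- inputs[tr, , drop = FALSE]; Ttr <- T_[tr, , drop = FALSE]
  Xv <- inputs[val, , drop = FALSE]; Tv <- T_[val, , drop = FALSE]
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
  best <- list(err = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  wait <- 0L
  m <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    Z1 <- Xtr %*% t(W1) + rep(b1, each = m)
    H <- sigmoid(Z1)
    O <- sigmoid(H %*% t(W2) + rep(b2, each = m))
    E <- O - Ttr
    if (!all(is.finite(E))) stop("training diverged: non-finite loss")
    dO <- E * O * (1 - O)            # m x K
    dH <- (dO %*% W2) * H * (1 - H)  # m x hidden
    gW2 <- t(dO) %*% H / m + decay * W2; gb2 <- colSums(dO) / m
    gW1 <- t(dH) %*% Xtr / m + decay * W1; gb1 <- colSums(dH) / m
    vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
    vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
    vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
    vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    if (length(val)) {
      Hv <- sigmoid(Xv %*% t(W1) + rep(b1, each = nrow(Xv)))
      Ov <- sigmoid(Hv %*% t(W2) + rep(b2, each = nrow(Xv)))
      err <- mean((Ov - Tv)^2)
    } else err <- mean(E^2)
    if (err < best$err - 1e-9) {
      best <- list(err = err, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  new("AnnModel", W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
      seed = as.integer(seed),
      config = list(hidden = hidden, epochs = epochs, lr = lr,
                    momentum = momentum, patience = patience, decay = decay))
}

#' Number of inter-layer connections of a layered network
#'
#' Sum over consecutive layer pairs of the product of their sizes; bias
#' terms are not counted. The selected 12-28-4 architecture has
#' (12 x 28) + (28 x 4) = 448 connections.
#'
#' @param layerSizes integer vector of at least two layer sizes.
#' @return integer connection count.
#' @examples
#' countConnections(c(12, 28, 4))
#' @export
countConnections <- function(layerSizes) {
  if (length(layerSizes) < 2L) stop("need at least two layers")
  as.integer(sum(layerSizes[-length(layerSizes)] * layerSizes[-1]))
}

#' Sweep hidden sizes and SVM-set combinations for the stacking network
#'
#' Exhaustively evaluates every (combination of stage-one score sets,
#' hidden size) candidate by k-fold cross-validated accuracy of the stacked
#' network, and returns the best together with the full sweep table. Ties
#' go to the smaller architecture.
#'
#' @param scoreSets named list of stage-one score matrices (n x 4 each,
#'   columns N,Y,C,E), e.g. out-of-fold scores for sets A, B, C.
#' @param labels true classes aligned to rows.
#' @param combos list of character vectors naming the score sets to
#'   concatenate (default: every non-empty subset in set order).
#' @param hiddenSizes candidate hidden-layer sizes.
#' @param cvFolds folds (default 10).
#' @param seed integer seed.
#' @param ... further arguments to [trainAnn()] (epochs, lr, ...).
#' @return list with `best` (combo, hidden, accuracy) and `sweep`
#'   (`data.frame` with one row per candidate).
#' @export
optimizeAnn <- function(scoreSets, labels, combos = NULL,
                        hiddenSizes = c(7L, 14L, 28L), cvFolds = 10L,
                        seed = 1L, ...) {
  labels <- as.character(labels)
  if (is.null(combos)) {
    nm <- names(scoreSets)
    combos <- unlist(lapply(seq_along(nm), function(k)
      utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  }
  n <- length(labels)
  set.seed(seed)
  fold <- sample(rep(seq_len(cvFolds), length.out = n))
  sweep <- NULL
  for (cb in combos) {
    X <- do.call(cbind, scoreSets[cb])
    for (h in hiddenSizes) {
      accs <- vapply(seq_len(cvFolds), function(f) {
        tr <- fold != f
        m <- trainAnn(X[tr, , drop = FALSE], labels[tr], hidden = h,
                      seed = seed + f, ...)
        pred <- LOCATION_CLASSES[max.col(annForward(m, X[!tr, , drop = FALSE]),
                                         ties.method = "first")]
        mean(pred == labels[!tr])
      }, numeric(1))
      sweep <- rbind(sweep, data.frame(combo = paste(cb, collapse = "|"),
                                       inputs = ncol(X), hidden = h,
                                       cvAccuracy = mean(accs)))
    }
  }
  ord <- order(-sweep$cvAccuracy, sweep$inputs * sweep$hidden + sweep$hidden * 4L)
  best <- sweep[ord[1], ]
  list(best = best, sweep = sweep)
}
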