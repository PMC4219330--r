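#' Train the full two-stage location model
#'
#' Stage one: for each of the three feature specifications (see
#' [defaultFeatureSpecs()]) a one-vs-rest probabilistic SVM set is tuned and
#' fitted on the full training corpus. Stage two: the stacking perceptron is
#' trained on out-of-fold stage-one scores — the corpus is split into
#' `stackFolds` stratified folds and each protein is scored by SVM sets
#' refitted (with the stage-one tuned hyperparameters) on the other folds —
#' so the network never sees optimistically biased probabilities.
#'
#' @param profiles list of [ExposureProfile]s.
#' @param labels classes `N`,`Y`,`C`,`E` aligned to `profiles`.
#' @param grid SVM hyperparameter grid (see [svmGridDefault()]).
#' @param hidden hidden-layer size of the stacking network (default 28).
#' @param cvFolds folds for SVM grid search (default 10).
#' @param stackFolds folds for out-of-fold stage-one scoring (default 5).
#' @param threshold reliability threshold on the winning score (default
#'   0.4).
#' @param seed integer master seed.
#' @param ... further arguments to [trainAnn()].
#' @return a [LocationModel].
#' @export
trainLocationModel <- function(profiles, labels, grid = svmGridDefault(),
                               hidden = 28L, cvFolds = 10L, stackFolds = 5L,
                               threshold = 0.4, seed = 1L, ...) {
  labels <- as.character(labels)
  stopifnot(length(profiles) == length(labels))
  specs <- defaultFeatureSpecs()
  feats <- lapply(specs, function(sp) featureMatrix(profiles, sp))
  svmSets <- lapply(names(specs), function(nm)
    trainOvrSvm(feats[[nm]], labels, specs[[nm]], grid = grid,
                cvFolds = cvFolds, seed = seed + 10L * match(nm, names(specs))))
  names(svmSets) <- names(specs)

  oof <- outOfFoldScores(feats, labels, svmSets, stackFolds, seed)
  stackX <- do.call(cbind, lapply(names(specs), function(nm) {
    m <- oof[[nm]]
    colnames(m) <- paste0(nm, "_", LOCATION_CLASSES)
    m
  }))
  ann <- trainAnn(stackX, labels, hidden = hidden, seed = seed + 97L, ...)
  new("LocationModel", svmSets = svmSets, ann = ann,
      threshold = threshold, classes = LOCATION_CLASSES,
      config = list(seed = as.integer(seed), stackFolds = stackFolds,
                    bounds = defaultRangeBoundaries(), sableMap = defaultSableMap()))
}

# Score every protein with SVM sets trained on the other stratified folds,
# reusing the hyperparameters tuned on the full corpus.
outOfFoldScores <- function(feats, labels, svmSets, stackFolds, seed) {
  n <- length(labels)
  set.seed(seed + 7L)
  fold <- integer(n)
  for (k in LOCATION_CLASSES) {
    idx <- which(labels == k)
    fold[idx] <- sample(rep(seq_len(stackFolds), length.out = length(idx)))
  }
  out <- lapply(feats, function(f) matrix(NA_real_, n, 4L,
                                          dimnames = list(NULL, LOCATION_CLASSES)))
  for (f in seq_len(stackFolds)) {
    tr <- fold != f
    members <- split(which(tr), factor(labels[tr], levels = LOCATION_CLASSES))
    members <- lapply(members, as.character)
    for (nm in names(feats)) {
      X <- feats[[nm]]
      rownames(X) <- as.character(seq_len(n))
      params <- svmSets[[nm]]@params
      for (k in LOCATION_CLASSES) {
        bal <- balanceDataset(members, positive = k,
                              seed = seed + 31L * f + match(k, LOCATION_CLASSES))
        ids <- c(bal$positives, bal$negatives$id)
        y <- factor(c(rep("pos", length(bal$positives)), rep("rest", nrow(bal$negatives))),
                    levels = c("pos", "rest"))
        p <- params[params$class == k, ]
        set.seed(seed + 131L * f + match(k, LOCATION_CLASSES))
        fit <- e1071::svm(X[ids, , drop = FALSE], y, kernel = "radial",
                          cost = p$cost, gamma = p$gamma, probability = TRUE,
                          scale = FALSE)
        pr <- predict(fit, X[!tr, , drop = FALSE], probability = TRUE)
        out[[nm]][!tr, k] <- attr(pr, "probabilities")[, "pos"]
      }
    }
  }
  out
}

#' Stage-one scores for profiles
#'
#' @param model a [LocationModel].
#' @param profiles list of [ExposureProfile]s.
#' @return list of three n x 4 score matrices (sets A, B, C).
#' @export
stageOneScores <- function(model, profiles) {
  lapply(model@svmSets, function(ss)
    scoreOvr(ss, featureMatrix(profiles, ss@spec)))
}

#' Predict subcellular location
#'
#' Runs the full pipeline on exposure profiles: the three feature vectors
#' feed the stage-one SVM sets, their twelve class probabilities feed the
#' stacking network, and the class with the highest network output wins. A
#' prediction whose winning score falls below the reliability threshold is
#' flagged unreliable — such proteins often belong to locations outside the
#' four trained classes. Profiles shorter than `minLength` residues trigger
#' a warning (the model was trained on longer proteins) but are still
#' predicted.
#'
#' @param model a [LocationModel].
#' @param profiles an [ExposureProfile] or list of them.
#' @param threshold reliability threshold; default the model's.
#' @param minLength length below which a warning is emitted (default 150).
#' @return `data.frame`: protein_id, score_N, score_Y, score_C, score_E,
#'   call, score, reliable, source.
#' @export
predictLocation <- function(model, profiles, threshold = model@threshold,
                            minLength = 150L) {
  if (is(profiles, "ExposureProfile")) profiles <- list(profiles)
  covered <- vapply(profiles, function(p) nrow(residueRecords(p)), integer(1))
  if (any(covered == 0L))
    stop("no exposure information for: ",
         paste(vapply(profiles[covered == 0L], proteinId, character(1)), collapse = ", "))
  short <- vapply(profiles, function(p) nchar(p@sequence), integer(1)) < minLength
  if (any(short))
    warning(sprintf("%d sequence(s) shorter than %d residues; predictions may be unstable",
                    sum(short), minLength))
  sc <- stageOneScores(model, profiles)
  stackX <- do.call(cbind, lapply(names(sc), function(nm) {
    m <- sc[[nm]]; colnames(m) <- paste0(nm, "_", LOCATION_CLASSES); m
  }))
  O <- annForward(model@ann, stackX)
  win <- max.col(O, ties.method = "first")  # column order N,Y,C,E breaks ties
  score <- O[cbind(seq_len(nrow(O)), win)]
  data.frame(protein_id = vapply(profiles, proteinId, character(1)),
             score_N = O[, "N"], score_Y = O[, "Y"],
             score_C = O[, "C"], score_E = O[, "E"],
             call = LOCATION_CLASSES[win], score = score,
             reliable = score >= threshold,
             source = vapply(profiles, function(p) p@source, character(1)),
             row.names = NULL)
}

#' Winner-takes-all predictions from stage-one scores
#'
#' The baseline the stacking network is compared against: for each protein,
#' the class with the best probability across the given stage-one score
#' matrices.
#'
#' @param scoreList list of n x 4 score matrices.
#' @return character vector of class calls.
#' @export
wtaPredict <- function(scoreList) {
  if (!is.list(scoreList)) scoreList <- list(scoreList)
  n <- nrow(scoreList[[1]])
  vapply(seq_len(n), function(i)
    winnerTakesAll(lapply(scoreList, function(m) m[i, ]))$class, character(1))
}

#' Save / load a trained model bundle
#'
#' The bundle directory holds a JSON manifest (specifications, class and
#' amino-acid order, seeds, threshold, range boundaries, score map), the
#' stacking-network weights as TSV, and the fitted stage-one SVMs as RDS.
#'
#' @param model a [LocationModel].
#' @param dir bundle directory (created if needed).
#' @return `dir`, invisibly (`loadLocationModel` returns the model).
#' @export
saveLocationModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "exposeloc-model/1",
    classes = model@classes,
    aaOrder = AA_CODES,
    threshold = model@threshold,
    specs = lapply(model@svmSets, function(s) specLabel(s@spec)),
    svmParams = lapply(model@svmSets, function(s) s@params),
    seeds = lapply(model@svmSets, function(s) s@seed),
    annConfig = model@ann@config,
    annSeed = model@ann@seed,
    config = model@config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (w in c("W1", "W2"))
    write.table(slot(model@ann, w), file.path(dir, paste0("ann_", w, ".tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(data.frame(b1 = model@ann@b1), file.path(dir, "ann_b1.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(data.frame(b2 = model@ann@b2), file.path(dir, "ann_b2.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  saveRDS(lapply(model@svmSets, function(s) s@models), file.path(dir, "svm_models.rds"))
  invisible(dir)
}

#' @rdname saveLocationModel
#' @export
loadLocationModel <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  if (!identical(manifest$format, "exposeloc-model/1")) stop("unrecognised model bundle")
  svmModels <- readRDS(file.path(dir, "svm_models.rds"))
  parseSpec <- function(lab) lapply(strsplit(lab, "|", fixed = TRUE)[[1]],
                                    function(x) as.integer(strsplit(trimws(x), " ")[[1]]))
  svmSets <- lapply(names(svmModels), function(nm) {
    new("OvrSvmSet",
        spec = parseSpec(manifest$specs[[nm]]),
        models = svmModels[[nm]],
        params = as.data.frame(manifest$svmParams[[nm]]),
        classes = manifest$classes,
        seed = as.integer(manifest$seeds[[nm]]))
  })
  names(svmSets) <- names(svmModels)
  readMat <- function(f) as.matrix(read.delim(file.path(dir, f), header = FALSE))
  W1 <- unname(readMat("ann_W1.tsv")); W2 <- unname(readMat("ann_W2.tsv"))
  ann <- new("AnnModel", W1 = W1, b1 = as.numeric(readMat("ann_b1.tsv")),
             W2 = W2, b2 = as.numeric(readMat("ann_b2.tsv")),
             seed = as.integer(manifest$annSeed), config = as.list(manifest$annConfig))
  cfg <- as.list(manifest$config)
  new("LocationModel", svmSets = svmSets, ann = ann,
      threshold = as.numeric(manifest$threshold),
      classes = manifest$classes, config = cfg)
}
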