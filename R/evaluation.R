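#' Classification accuracy
#'
#' @param predictions predicted classes.
#' @param truths true classes, same length.
#' @return fraction correctly predicted.
#' @export
accuracy <- function(predictions, truths) {
  if (length(predictions) != length(truths)) stop("lengths differ")
  if (length(truths) == 0L) stop("accuracy undefined on empty input")
  mean(as.character(predictions) == as.character(truths))
}

#' ROC curve points for one class
#'
#' Sweeps a decision threshold over the distinct scores (plus a point above
#' all of them) and records, for prediction rule `score >= threshold`, the
#' true-positive and false-positive rates. Both rates are non-decreasing as
#' the threshold drops.
#'
#' @param scores numeric membership scores.
#' @param truths logical (or 0/1) positive-class indicators.
#' @return `data.frame` with columns `threshold`, `tpr`, `fpr`, ordered
#'   from the strictest threshold down.
#' @export
rocPoints <- function(scores, truths) {
  truths <- as.logical(truths)
  if (length(scores) != length(truths)) stop("lengths differ")
  if (!any(truths) || all(truths))
    stop("ROC needs at least one positive and one negative")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  P <- sum(truths); N <- sum(!truths)
  data.frame(threshold = th,
             tpr = vapply(th, function(t) sum(scores >= t & truths) / P, numeric(1)),
             fpr = vapply(th, function(t) sum(scores >= t & !truths) / N, numeric(1)))
}

#' Area under an ROC curve
#'
#' Trapezoidal area under the points produced by [rocPoints()].
#'
#' @param roc `data.frame` from [rocPoints()].
#' @return area in [0,1].
#' @export
rocAuc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Exposure distribution of one amino acid
#'
#' Normalised histogram of the relative solvent accessibility values of all
#' occurrences of one amino acid across structure-derived profiles — the
#' per-residue exposure signature whose class-to-class differences (e.g.
#' glutamine sitting more buried in extracellular than in intracellular
#' proteins) carry the location signal.
#'
#' @param profiles list of [ExposureProfile]s (structure source).
#' @param aa one-letter code.
#' @param bins number of equal-width RSA bins (default 10).
#' @return numeric vector of bin fractions summing to 1, with attribute
#'   `n` (occurrence count); all-`NA` with `n = 0` when `aa` never occurs.
#' @export
exposureDistribution <- function(profiles, aa, bins = 10L) {
  rsa <- unlist(lapply(profiles, function(p) {
    r <- residueRecords(p)
    r$rsa[r$aa == aa & !is.na(r$rsa)]
  }))
  edges <- seq(0, 1, length.out = bins + 1L)
  if (!length(rsa))
    return(structure(rep(NA_real_, bins), n = 0L))
  idx <- findInterval(rsa, edges, rightmost.closed = TRUE)
  structure(tabulate(idx, bins) / length(rsa), n = length(rsa))
}

#' Evaluate predictions on pairs of paralogous proteins
#'
#' Paralog pairs whose two members live in different compartments are a
#' homology-confounded benchmark: a homology-based predictor necessarily
#' places both members together. Counts how often the two members receive
#' the same predicted location, how many pairs have both members correct,
#' and how many member proteins are correct individually.
#'
#' @param pairs `data.frame` with columns `id1`, `class1`, `id2`, `class2`
#'   (true classes; the two must differ within a pair).
#' @param predictions named character vector mapping protein id to
#'   predicted class.
#' @return list: `n` pairs, `sameLocation`, `bothCorrect`,
#'   `proteinsCorrect` (of 2n).
#' @export
evaluatePairs <- function(pairs, predictions) {
  need <- c(pairs$id1, pairs$id2)
  missing <- setdiff(need, names(predictions))
  if (length(missing))
    stop("missing prediction for: ", paste(missing, collapse = ", "))
  if (any(pairs$class1 == pairs$class2))
    stop("paralog pairs must have differing true locations")
  p1 <- unname(predictions[pairs$id1]); p2 <- unname(predictions[pairs$id2])
  list(n = nrow(pairs),
       sameLocation = sum(p1 == p2),
       bothCorrect = sum(p1 == pairs$class1 & p2 == pairs$class2),
       proteinsCorrect = sum(p1 == pairs$class1) + sum(p2 == pairs$class2))
}

#' Monte Carlo p-value for paralog-pair accuracy
#'
#' Null model: every protein independently receives one of the four
#' locations with equal probability, so a pair is correct with probability
#' 1/16 (`null = "independent"`); the alternative `"ordered"` null assigns
#' the pair two distinct locations at random (success 1/12). The p-value is
#' the plain fraction of simulated draws with at least `observed` correct
#' pairs; `corrected = TRUE` applies the (count+1)/(reps+1) estimator.
#'
#' @param nPairs number of pairs.
#' @param observed observed both-correct count.
#' @param reps Monte Carlo replicates (default 1e6).
#' @param seed integer seed.
#' @param null `"independent"` (1/16) or `"ordered"` (1/12).
#' @param corrected use the add-one estimator (default FALSE).
#' @return estimated p-value in [0,1].
#' @export
permutationPvalue <- function(nPairs, observed, reps = 1e6, seed = 1L,
                              null = c("independent", "ordered"),
                              corrected = FALSE) {
  null <- match.arg(null)
  if (observed < 0 || observed > nPairs) stop("observed must be in 0..nPairs")
  if (reps < 1) stop("reps must be >= 1")
  p <- if (null == "independent") 1 / 16 else 1 / 12
  set.seed(seed)
  sim <- rbinom(reps, nPairs, p)
  hits <- sum(sim >= observed)
  if (corrected) (hits + 1) / (reps + 1) else hits / reps
}

#' Nucleocytoplasmic call from per-class scores of an external tool
#'
#' Tools without a nucleocytoplasmic class still emit nuclear and
#' cytoplasmic scores; after normalising all class scores to sum to one,
#' the protein is treated as nucleocytoplasmic when the nuclear plus
#' cytoplasmic share strictly exceeds one half.
#'
#' @param nuclear nuclear-class score (>= 0).
#' @param cytoplasmic cytoplasmic-class score (>= 0).
#' @param allScores numeric vector of all class scores including the two
#'   above.
#' @return `TRUE` when the protein should be treated as nucleocytoplasmic.
#' @export
mergeNucleocytoplasmic <- function(nuclear, cytoplasmic, allScores) {
  if (any(allScores < 0) || nuclear < 0 || cytoplasmic < 0)
    stop("scores must be non-negative")
  tot <- sum(allScores)
  if (tot == 0) stop("undefined for all-zero scores")
  (nuclear + cytoplasmic) / tot > 0.5
}

#' Read a paralog-pair table
#'
#' TSV with columns `id1`, `class1`, `id2`, `class2`.
#'
#' @param file TSV path.
#' @return `data.frame`.
#' @export
readPairs <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("id1", "class1", "id2", "class2")
  if (!all(need %in% names(df)))
    stop(paste("pair table must have columns", paste(need, collapse = ", ")))
  df
}
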