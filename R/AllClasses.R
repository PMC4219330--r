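#' @import methods
#' @importFrom stats predict quantile runif rbinom rlnorm
#' @importFrom utils read.delim write.table head
NULL

#' Canonical amino acids and location classes
#'
#' `AA_CODES` is the fixed alphabetical ordering of the 20 canonical
#' one-letter amino-acid codes used to index every composition vector;
#' `LOCATION_CLASSES` is the fixed ordering of the four location classes:
#' nuclear (N), nucleocytoplasmic (Y), cytoplasmic (C), extracellular (E).
#' Both orderings are part of the model-serialisation contract.
#'
#' @name constants
#' @aliases AA_CODES LOCATION_CLASSES
#' @export AA_CODES LOCATION_CLASSES
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname constants
LOCATION_CLASSES <- c("N", "Y", "C", "E")

#' Per-residue exposure profile of a protein
#'
#' An `ExposureProfile` holds a protein sequence together with one record per
#' residue covered by exposure information: position, amino acid, absolute
#' accessibility (square Angstrom; `NA` for predicted exposure), relative
#' solvent accessibility (RSA, in [0,1]; `NA` for predicted exposure) and the
#' exposure range index 1 (buried) to 6 (exposed). Residues without coverage
#' or with non-canonical codes stay in `sequence` but have no record.
#'
#' @slot proteinId single identifier string.
#' @slot sequence protein sequence (one-letter codes, may contain X/B/Z/U).
#' @slot residues `data.frame` with columns `position`, `aa`, `acc`, `rsa`,
#'   `range`.
#' @slot source `"structure"` (RSA from absolute accessibility) or
#'   `"predicted"` (ranges from 0-9 exposure scores).
#' @exportClass ExposureProfile
setClass("ExposureProfile",
         representation(proteinId = "character",
                        sequence = "character",
                        residues = "data.frame",
                        source = "character"))

setValidity("ExposureProfile", function(object) {
  msg <- character()
  if (length(object@proteinId) != 1L) msg <- c(msg, "proteinId must be length 1")
  if (length(object@sequence) != 1L) msg <- c(msg, "sequence must be length 1")
  if (!object@source %in% c("structure", "predicted"))
    msg <- c(msg, "source must be 'structure' or 'predicted'")
  r <- object@residues
  need <- c("position", "aa", "acc", "rsa", "range")
  if (!all(need %in% names(r))) {
    msg <- c(msg, paste("residues must have columns", paste(need, collapse = ", ")))
  } else if (nrow(r) > 0L) {
    n <- nchar(object@sequence)
    if (anyDuplicated(r$position)) msg <- c(msg, "residue positions must be unique")
    if (any(r$position < 1L | r$position > n))
      msg <- c(msg, "residue positions must lie within the sequence")
    else {
      seq_aa <- substring(object@sequence, r$position, r$position)
      if (!all(r$aa == seq_aa))
        msg <- c(msg, "residue amino acids must match the sequence")
    }
    if (!all(r$aa %in% AA_CODES)) msg <- c(msg, "residue records restricted to the 20 canonical codes")
    ok_rsa <- is.na(r$rsa) | (r$rsa >= 0 & r$rsa <= 1)
    if (!all(ok_rsa)) msg <- c(msg, "rsa must be in [0,1] or NA")
    if (!all(r$range %in% 1:6)) msg <- c(msg, "range must be an integer in 1..6")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ExposureProfile-class compact display.
#' @param object an `ExposureProfile`.
#' @export
setMethod("show", "ExposureProfile", function(object) {
  cat("ExposureProfile:", object@proteinId,
      sprintf("(%d aa, %d covered, %s exposure)\n",
              nchar(object@sequence), nrow(object@residues), object@source))
  tab <- tabulate(object@residues$range, 6L)
  cat("  residues per range 1..6:", paste(tab, collapse = " "), "\n")
})

#' @describeIn ExposureProfile-class identifier accessor.
#' @export
setGeneric("proteinId", function(object) standardGeneric("proteinId"))

#' @rdname ExposureProfile-class
#' @export
setMethod("proteinId", "ExposureProfile", function(object) object@proteinId)

#' @describeIn ExposureProfile-class residue-record accessor
#'   (`data.frame`: position, aa, acc, rsa, range).
#' @export
setGeneric("residueRecords", function(object) standardGeneric("residueRecords"))

#' @rdname ExposureProfile-class
#' @export
setMethod("residueRecords", "ExposureProfile", function(object) object@residues)

#' One-vs-rest probabilistic SVM set
#'
#' Four binary radial-basis-function SVMs (one per location class, that class
#' versus the rest), trained on balanced data under a common feature
#' specification, each calibrated to emit a membership probability.
#'
#' @slot spec list of integer range sets defining the feature vector.
#' @slot models list of four fitted classifiers named by class.
#' @slot params `data.frame` of tuned hyperparameters (class, cost, gamma,
#'   cvAccuracy).
#' @slot classes class order (`N`, `Y`, `C`, `E`).
#' @slot seed integer training seed.
#' @exportClass OvrSvmSet
setClass("OvrSvmSet",
         representation(spec = "list", models = "list", params = "data.frame",
                        classes = "character", seed = "integer"))

setValidity("OvrSvmSet", function(object) {
  if (length(object@models) != 4L) return("exactly four one-vs-rest classifiers required")
  if (!identical(sort(names(object@models)), sort(object@classes)))
    return("models must be named by the four classes")
  TRUE
})

#' @describeIn OvrSvmSet-class compact display.
#' @param object an `OvrSvmSet`.
#' @export
setMethod("show", "OvrSvmSet", function(object) {
  cat("OvrSvmSet:", specLabel(object@spec),
      sprintf("(%d features)\n", 20L * length(object@spec)))
  print(object@params, row.names = FALSE)
})

#' Stacking perceptron
#'
#' A fully connected 12-H-4 feed-forward network with logistic-sigmoid units
#' throughout, mapping the concatenated class probabilities of three SVM sets
#' to final per-class scores in [0,1]. Trained by batch back-propagation
#' against one-hot targets under squared-error loss.
#'
#' @slot W1 hidden-layer weight matrix (H x inputs).
#' @slot b1 hidden-layer bias vector.
#' @slot W2 output-layer weight matrix (4 x H).
#' @slot b2 output-layer bias vector.
#' @slot seed integer training seed.
#' @slot config list of training settings (lr, momentum, epochs, patience).
#' @exportClass AnnModel
setClass("AnnModel",
         representation(W1 = "matrix", b1 = "numeric",
                        W2 = "matrix", b2 = "numeric",
                        seed = "integer", config = "list"))

setValidity("AnnModel", function(object) {
  if (ncol(object@W2) != nrow(object@W1)) return("layer dimensions inconsistent")
  if (length(object@b1) != nrow(object@W1)) return("b1 length must match hidden size")
  if (length(object@b2) != nrow(object@W2)) return("b2 length must match output size")
  TRUE
})

#' @describeIn AnnModel-class compact display.
#' @param object an `AnnModel`.
#' @export
setMethod("show", "AnnModel", function(object) {
  sizes <- c(ncol(object@W1), nrow(object@W1), nrow(object@W2))
  cat(sprintf("AnnModel: %d-%d-%d perceptron, %d connections\n",
              sizes[1], sizes[2], sizes[3], countConnections(sizes)))
})

#' Trained two-stage location model
#'
#' Bundles the three stage-one [OvrSvmSet]s (40-component buried/exposed
#' split, 40-component most-buried/rest split, 20-component full
#' composition), the stage-two [AnnModel], and the prediction configuration
#' (class order, range boundaries, exposure-score map, reliability
#' threshold).
#'
#' @slot svmSets named list of three `OvrSvmSet`s (`A`, `B`, `C`).
#' @slot ann the stacking `AnnModel`.
#' @slot threshold reliability threshold on the winning score (default 0.4).
#' @slot classes class order.
#' @slot config list: range boundaries, exposure-score map, seeds.
#' @exportClass LocationModel
setClass("LocationModel",
         representation(svmSets = "list", ann = "AnnModel",
                        threshold = "numeric", classes = "character",
                        config = "list"))

setValidity("LocationModel", function(object) {
  if (!identical(names(object@svmSets), c("A", "B", "C")))
    return("svmSets must be named A, B, C")
  if (length(object@threshold) != 1L || object@threshold < 0 || object@threshold > 1)
    return("threshold must be a single value in [0,1]")
  TRUE
})

#' @describeIn LocationModel-class compact display.
#' @param object a `LocationModel`.
#' @export
setMethod("show", "LocationModel", function(object) {
  cat("LocationModel (two-stage SVM + ANN)\n")
  for (nm in names(object@svmSets))
    cat("  set", nm, ":", specLabel(object@svmSets[[nm]]@spec), "\n")
  cat(sprintf("  ANN hidden units: %d; reliability threshold: %.2f\n",
              nrow(object@ann@W1), object@threshold))
})
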