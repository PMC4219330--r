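#' Range-restricted composition vector
#'
#' The 20-component amino-acid composition of the residues of a profile
#' whose exposure range falls in `ranges`: component i is the fraction of
#' those residues that are of amino-acid type i, indexed alphabetically by
#' one-letter code. Components sum to one, or are all zero when no covered
#' residue falls in `ranges` (fixed dimensionality for downstream models).
#'
#' @param profile an [ExposureProfile].
#' @param ranges integer subset of 1..6 (default all six: whole-protein
#'   composition of covered residues).
#' @return named numeric vector of length 20.
#' @export
compositionVector <- function(profile, ranges = 1:6) {
  ranges <- checkRangeSet(ranges)
  r <- residueRecords(profile)
  aa <- r$aa[r$range %in% ranges]
  v <- structure(numeric(20), names = AA_CODES)
  if (length(aa)) {
    tab <- table(factor(aa, levels = AA_CODES))
    v[] <- as.numeric(tab) / length(aa)
  }
  v
}

checkRangeSet <- function(ranges) {
  ranges <- as.integer(ranges)
  if (length(ranges) == 0L || anyDuplicated(ranges) || !all(ranges %in% 1:6))
    stop("a range set is a non-empty duplicate-free subset of 1..6")
  sort(ranges)
}

#' Feature specifications used by the trained model
#'
#' The three specifications whose stage-one scores feed the stacking
#' network, in fixed order: `A` = 40-component buried/exposed split
#' (ranges 1 2 3 | 4 5 6), `B` = 40-component most-buried/rest split
#' (ranges 1 | 2 3 4 5 6), `C` = 20-component full composition
#' (ranges 1 2 3 4 5 6). A specification is a list of 1-2 range sets;
#' output dimensionality is 20 per range set.
#'
#' @return named list of three specifications.
#' @export
defaultFeatureSpecs <- function() {
  list(A = list(1:3, 4:6),
       B = list(1L, 2:6),
       C = list(1:6))
}

specLabel <- function(spec) {
  paste(vapply(spec, function(rs) paste(rs, collapse = " "), character(1)),
        collapse = " | ")
}

#' Feature vector for one profile
#'
#' Concatenates one [compositionVector()] per range set of the
#' specification, giving a 20- or 40-component vector whose 20-blocks each
#' independently sum to one (or are all zero for an empty range set).
#'
#' @param profile an [ExposureProfile].
#' @param spec a list of 1-2 range sets, e.g. `list(1:3, 4:6)`.
#' @return named numeric vector of length 20 x length(spec); names are
#'   `r<ranges>_<aa>`, e.g. `r123_A`.
#' @export
featureVector <- function(profile, spec) {
  if (!is.list(spec) || length(spec) < 1L) stop("spec must be a non-empty list of range sets")
  blocks <- lapply(spec, function(rs) {
    rs <- checkRangeSet(rs)
    v <- compositionVector(profile, rs)
    names(v) <- paste0("r", paste(rs, collapse = ""), "_", AA_CODES)
    v
  })
  do.call(c, blocks)
}

#' Feature matrix for a list of profiles
#'
#' @param profiles list of [ExposureProfile]s.
#' @param spec a feature specification (list of range sets).
#' @return numeric matrix, one row per profile, rownames = protein ids.
#' @export
featureMatrix <- function(profiles, spec) {
  m <- t(vapply(profiles, featureVector, numeric(20L * length(spec)), spec = spec))
  rownames(m) <- vapply(profiles, proteinId, character(1))
  m
}

#' Write a feature table as TSV
#'
#' @param features matrix from [featureMatrix()].
#' @param file output path.
#' @param labels optional class labels, recycled against rows.
#' @export
writeFeaturesTsv <- function(features, file, labels = NULL) {
  df <- data.frame(protein_id = rownames(features), check.names = FALSE)
  if (!is.null(labels)) df$label <- labels
  df <- cbind(df, as.data.frame(features, check.names = FALSE))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
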