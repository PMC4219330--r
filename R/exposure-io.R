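#' Maximum residue accessibility table
#'
#' Per-amino-acid maximum solvent-accessible surface areas (square Angstrom)
#' used to normalise absolute accessibility into relative solvent
#' accessibility (RSA). The packaged default is the Rost & Sander (1994)
#' table; any table with the same 20 names can be supplied instead, either
#' directly or as a JSON file of `{code: max}` entries.
#'
#' @param file optional path to a JSON file with one positive entry per
#'   canonical code; `NULL` loads the packaged default.
#' @return named numeric vector over the 20 canonical codes.
#' @examples
#' maxAccessibilityTable()[["G"]]
#' @export
maxAccessibilityTable <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "max_accessibility.json", package = "exposeloc")
  raw <- jsonlite::read_json(file)
  raw <- raw[names(raw) %in% AA_CODES]
  if (!all(AA_CODES %in% names(raw)))
    stop("accessibility table must cover all 20 canonical amino acids")
  tab <- vapply(raw[AA_CODES], as.numeric, numeric(1))
  if (any(!is.finite(tab)) || any(tab <= 0))
    stop("accessibility maxima must all be positive")
  tab
}

#' Relative solvent accessibility of one residue
#'
#' Normalises an absolute DSSP-style accessibility (square Angstrom) by the
#' maximum attainable for that amino-acid type. Values exceeding the
#' tabulated maximum (terminal or distorted residues) are clamped to 1.
#'
#' @param acc absolute accessibility, >= 0.
#' @param aa one-letter amino-acid code.
#' @param table accessibility maxima, see [maxAccessibilityTable()].
#' @return RSA in [0,1], or `NA` with a `"skipped_residue"` condition class
#'   warning when `aa` is not canonical.
#' @examples
#' relativeAccessibility(53, "G")
#' @export
relativeAccessibility <- function(acc, aa, table = maxAccessibilityTable()) {
  if (!is.numeric(acc) || length(acc) != 1L || is.na(acc) || acc < 0)
    stop("acc must be a single non-negative number")
  if (!aa %in% names(table)) {
    warning(warningCondition(sprintf("unknown amino-acid code '%s'; residue skipped", aa),
                             class = "skipped_residue"))
    return(NA_real_)
  }
  min(acc / table[[aa]], 1.0)
}

#' Default exposure-range boundaries
#'
#' The six RSA intervals used to stratify residues from buried (1) to
#' exposed (6), chosen so that a large structure-derived corpus places
#' near-equal residue counts in each: cut points 0, 0.01, 0.08, 0.21, 0.37,
#' 0.57, 1. Intervals are left-closed/right-open with the last interval
#' closed, so every RSA maps to exactly one range.
#'
#' @return numeric vector of 7 cut points from 0 to 1.
#' @export
defaultRangeBoundaries <- function() c(0, 0.01, 0.08, 0.21, 0.37, 0.57, 1)

checkBoundaries <- function(bounds) {
  if (length(bounds) < 2L || bounds[1] != 0 || bounds[length(bounds)] != 1 ||
      is.unsorted(bounds, strictly = TRUE))
    stop("boundaries must be strictly increasing cut points from 0 to 1")
  bounds
}

#' Assign an RSA value to an exposure range
#'
#' @param rsa relative accessibility in [0,1] (vectorised).
#' @param bounds cut points as from [defaultRangeBoundaries()] or
#'   [deriveRanges()].
#' @return integer range index 1..k (left-closed/right-open convention,
#'   last interval closed).
#' @examples
#' assignRange(c(0, 0.3, 1))
#' @export
assignRange <- function(rsa, bounds = defaultRangeBoundaries()) {
  checkBoundaries(bounds)
  if (any(is.na(rsa)) || any(rsa < 0 | rsa > 1))
    stop("rsa values must lie in [0,1]")
  idx <- findInterval(rsa, bounds, rightmost.closed = TRUE, left.open = FALSE)
  as.integer(idx)
}

#' Derive equal-count exposure ranges from an RSA sample
#'
#' Computes k contiguous intervals over [0,1] whose cut points sit midway
#' between the order statistics flanking each i/k sample split, so that
#' per-interval counts differ by at most one when values are distinct
#' (the left-closed binning convention never disturbs the counts because
#' no cut point coincides with a data value). The packaged
#' default boundaries correspond to such a partition of a large
#' structure-derived corpus; this lets users re-derive boundaries from their
#' own corpus.
#'
#' @param rsaValues non-empty numeric vector in [0,1].
#' @param k number of ranges (default 6).
#' @return cut-point vector of length k+1 usable with [assignRange()].
#' @export
deriveRanges <- function(rsaValues, k = 6L) {
  if (length(rsaValues) == 0L) stop("rsaValues must be non-empty")
  if (any(rsaValues < 0 | rsaValues > 1)) stop("rsa values must lie in [0,1]")
  if (k < 1L) stop("k must be >= 1")
  if (k > length(unique(rsaValues)))
    stop("degenerate partition: k exceeds the number of distinct values")
  xs <- sort(rsaValues)
  n <- length(xs)
  inner <- if (k > 1L) {
    idx <- pmax(1L, as.integer(floor(seq_len(k - 1L) * n / k)))
    (xs[idx] + xs[pmin(idx + 1L, n)]) / 2
  } else numeric()
  bounds <- c(0, inner, 1)
  if (is.unsorted(bounds, strictly = TRUE))
    stop("degenerate partition: tied quantiles; supply more distinct values or smaller k")
  bounds
}

#' Default map from 0-9 exposure scores to ranges
#'
#' Sequence-based exposure predictors score residues on an integer 0
#' (buried) to 9 (exposed) scale. Scores 0-4 correspond to structure-derived
#' ranges 1-5 and the less-populated scores 5-9 collapse onto range 6.
#'
#' @return integer vector of length 10 (range for scores 0..9).
#' @export
defaultSableMap <- function() {
  structure(c(1L, 2L, 3L, 4L, 5L, 6L, 6L, 6L, 6L, 6L), names = as.character(0:9))
}

checkSableMap <- function(map) {
  if (length(map) != 10L || !all(map %in% 1:6))
    stop("exposure-score map must give a range 1..6 for every score 0..9")
  if (is.unsorted(map)) stop("exposure-score map must be monotone non-decreasing")
  if (!all(1:6 %in% map)) stop("exposure-score map must be surjective onto ranges 1..6")
  as.integer(map)
}

#' Map a predicted exposure score to a range
#'
#' @param score integer 0..9 (vectorised).
#' @param map score-to-range map, see [defaultSableMap()].
#' @return integer range index 1..6.
#' @examples
#' mapSableToRange(c(0, 4, 9))
#' @export
mapSableToRange <- function(score, map = defaultSableMap()) {
  map <- checkSableMap(map)
  if (any(is.na(score)) || any(score < 0 | score > 9) || any(score != floor(score)))
    stop("scores must be integers in 0..9")
  map[score + 1L]
}

#' Parse per-residue accessibility records
#'
#' Reads either genuine DSSP output (header lines up to the `#  RESIDUE`
#' banner, then fixed columns: residue code at column 14, ACC in columns
#' 35-38) or the simplified 3-column dialect `position<TAB>aa<TAB>acc`.
#' Chain breaks (`!`) and unresolved residues are dropped; lowercase
#' cysteine-bridge codes are reported as `C`.
#'
#' @param file path to a DSSP file or 3-column TSV.
#' @return `data.frame` with columns `position`, `aa`, `acc`.
#' @export
parseDssp <- function(file) {
  lines <- readLines(file, warn = FALSE)
  banner <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(banner)) {
    body <- lines[seq.int(banner[1] + 1L, length.out = length(lines) - banner[1])]
    recs <- lapply(seq_along(body), function(i) {
      ln <- body[i]
      if (nchar(ln) < 14L) stop(sprintf("malformed DSSP row at line %d", banner[1] + i))
      aa <- substr(ln, 14L, 14L)
      if (aa %in% c("!", "*", " ")) return(NULL)  # chain break / unresolved
      if (nchar(ln) < 38L) stop(sprintf("malformed DSSP row at line %d", banner[1] + i))
      if (aa %in% letters) aa <- "C"              # SS-bridge labelled cysteine
      pos <- suppressWarnings(as.integer(substr(ln, 6L, 10L)))
      acc <- suppressWarnings(as.numeric(substr(ln, 35L, 38L)))
      if (is.na(pos) || is.na(acc))
        stop(sprintf("malformed DSSP row at line %d", banner[1] + i))
      data.frame(position = pos, aa = aa, acc = acc)
    })
    out <- do.call(rbind, recs)
  } else {
    fields <- strsplit(lines[nzchar(lines) & !startsWith(lines, "#")], "\t", fixed = TRUE)
    recs <- lapply(seq_along(fields), function(i) {
      f <- fields[[i]]
      if (length(f) != 3L) stop(sprintf("malformed accessibility row at line %d", i))
      pos <- suppressWarnings(as.integer(f[1]))
      acc <- suppressWarnings(as.numeric(f[3]))
      if (is.na(pos) || is.na(acc)) stop(sprintf("malformed accessibility row at line %d", i))
      aa <- f[2]
      if (aa %in% letters) aa <- "C"
      data.frame(position = pos, aa = aa, acc = acc)
    })
    out <- do.call(rbind, recs)
  }
  if (is.null(out)) out <- data.frame(position = integer(), aa = character(), acc = numeric())
  out
}

#' Parse predicted exposure scores
#'
#' Reads the digit-string dialect: a `>id` header followed by one digit
#' (0-9) per residue, aligned to the protein sequence. Lines may be wrapped.
#'
#' @param file path to the score file.
#' @param sequence the protein sequence the scores must align to.
#' @return `data.frame` with columns `position`, `aa`, `score`.
#' @export
parseSable <- function(file, sequence) {
  lines <- readLines(file, warn = FALSE)
  body <- lines[nzchar(lines) & !startsWith(lines, ">")]
  digits <- gsub("\\s", "", paste(body, collapse = ""))
  n <- nchar(sequence)
  if (nchar(digits) != n || grepl("[^0-9]", digits))
    stop(sprintf("exposure score string must be %d digits (got %d characters)",
                 n, nchar(digits)))
  data.frame(position = seq_len(n),
             aa = strsplit(sequence, "")[[1]],
             score = as.integer(strsplit(digits, "")[[1]]))
}

#' Read protein sequences from FASTA
#'
#' @param file FASTA path.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(file) {
  set <- Biostrings::readBStringSet(file)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Build an exposure profile
#'
#' Combines a sequence with per-residue accessibility records
#' (structure-derived, as from [parseDssp()]) or predicted exposure scores
#' (as from [parseSable()]) into an [ExposureProfile]. Structure records are
#' normalised to RSA and binned with [assignRange()]; predicted scores are
#' binned with [mapSableToRange()]. Residues with non-canonical codes or
#' without coverage are excluded from the records but kept in the sequence.
#'
#' @param proteinId identifier.
#' @param sequence protein sequence string.
#' @param records `data.frame` from [parseDssp()] (columns position, aa,
#'   acc) or [parseSable()] (columns position, aa, score).
#' @param bounds range cut points (structure source).
#' @param map score-to-range map (predicted source).
#' @param accTable accessibility maxima (structure source).
#' @return an [ExposureProfile].
#' @export
buildProfile <- function(proteinId, sequence, records,
                         bounds = defaultRangeBoundaries(),
                         map = defaultSableMap(),
                         accTable = maxAccessibilityTable()) {
  sequence <- toupper(sequence)
  source <- if ("score" %in% names(records)) "predicted" else "structure"
  n <- nchar(sequence)
  if (nrow(records)) {
    if (any(records$position < 1L | records$position > n))
      stop("consistency error: record position outside the sequence")
    seq_aa <- substring(sequence, records$position, records$position)
    if (!all(records$aa == seq_aa))
      stop("consistency error: record amino acid does not match the sequence")
  }
  keep <- records$aa %in% AA_CODES
  records <- records[keep, , drop = FALSE]
  if (source == "structure") {
    rsa <- vapply(seq_len(nrow(records)), function(i)
      relativeAccessibility(records$acc[i], records$aa[i], accTable), numeric(1))
    res <- data.frame(position = as.integer(records$position), aa = records$aa,
                      acc = records$acc, rsa = rsa,
                      range = if (nrow(records)) assignRange(rsa, bounds) else integer())
  } else {
    res <- data.frame(position = as.integer(records$position), aa = records$aa,
                      acc = NA_real_, rsa = NA_real_,
                      range = if (nrow(records)) mapSableToRange(records$score, map) else integer())
  }
  rownames(res) <- NULL
  new("ExposureProfile", proteinId = proteinId, sequence = sequence,
      residues = res, source = source)
}
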