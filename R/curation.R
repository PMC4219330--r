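#' Assign the location class of an annotation record
#'
#' Proteins annotated exclusively nuclear, cytoplasmic or extracellular get
#' classes N, C, E; proteins annotated in exactly both nucleus and cytoplasm
#' form the nucleocytoplasmic class Y (a large fraction of nuclear proteins
#' shuttles between the two compartments). Any other label combination is
#' rejected: the training corpus is restricted to proteins found in no other
#' compartment.
#'
#' @param locations character vector of location labels (lower-cased
#'   matching of `nuclear`/`nucleus`, `cytoplasmic`/`cytoplasm`,
#'   `extracellular`/`secreted`).
#' @return one of `"N"`, `"Y"`, `"C"`, `"E"`, or `NA` with attribute
#'   `reason` when rejected.
#' @export
assignLocationClass <- function(locations) {
  if (length(locations) == 0L || all(!nzchar(locations)))
    return(structure(NA_character_, reason = "no location label"))
  loc <- tolower(trimws(locations))
  canon <- ifelse(loc %in% c("nuclear", "nucleus"), "nuclear",
           ifelse(loc %in% c("cytoplasmic", "cytoplasm", "cytosol"), "cytoplasmic",
           ifelse(loc %in% c("extracellular", "secreted"), "extracellular", loc)))
  canon <- unique(canon)
  if (any(!canon %in% c("nuclear", "cytoplasmic", "extracellular")))
    return(structure(NA_character_, reason = "annotated outside the three locations"))
  if (setequal(canon, c("nuclear", "cytoplasmic"))) return("Y")
  if (identical(canon, "nuclear")) return("N")
  if (identical(canon, "cytoplasmic")) return("C")
  if (identical(canon, "extracellular")) return("E")
  structure(NA_character_, reason = "multiple locations")
}

#' Read an annotation table
#'
#' Tab-delimited with header columns `protein_id`, `length`, `locations`
#' (comma-separated labels), `evidence` (comma-separated qualifiers, may be
#' empty), `reviewed` (`yes`/`no`), `glycosylated` (`yes`/`no`),
#' `structures` (comma-separated `structure_id:covered_residues`, may be
#' empty).
#'
#' @param file TSV path.
#' @return `data.frame`, one row per record, with list-columns parsed.
#' @export
readAnnotations <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("protein_id", "length", "locations", "evidence", "reviewed",
            "glycosylated", "structures")
  if (!all(need %in% names(df)))
    stop(paste("annotation table must have columns", paste(need, collapse = ", ")))
  splitCsv <- function(x) lapply(strsplit(ifelse(is.na(x), "", x), ","), trimws)
  df$locations <- splitCsv(df$locations)
  df$evidence <- splitCsv(df$evidence)
  df$reviewed <- tolower(df$reviewed) %in% c("yes", "true", "1")
  df$glycosylated <- tolower(df$glycosylated) %in% c("yes", "true", "1")
  df$structures <- lapply(splitCsv(df$structures), function(parts) {
    parts <- parts[nzchar(parts)]
    if (!length(parts)) return(data.frame(structure_id = character(), covered = integer()))
    kv <- strsplit(parts, ":", fixed = TRUE)
    data.frame(structure_id = vapply(kv, `[`, character(1), 1),
               covered = as.integer(vapply(kv, `[`, character(1), 2)))
  })
  df
}

#' Curation filters for the training corpus
#'
#' Applies the dataset-selection rules: keep only reviewed records with
#' experimentally verified location (none of the qualifiers "by similarity",
#' "probable", "potential"), an exclusive N/Y/C/E class, length of at least
#' `minLength` residues (shorter proteins have too few residues per exposure
#' range for stable composition), at least one covering structure, and — for
#' extracellular proteins only — no glycosylation (glycans change surface
#' properties).
#'
#' @param records `data.frame` from [readAnnotations()].
#' @param minLength minimum sequence length (default 150).
#' @param badEvidence qualifiers marking unverified annotation.
#' @return list with `kept` (records plus a `class` column) and `rejected`
#'   (`data.frame` of protein_id, rule).
#' @export
filterAnnotations <- function(records, minLength = 150L,
                              badEvidence = c("by similarity", "probable", "potential")) {
  rejections <- list()
  reject <- function(id, rule) rejections[[length(rejections) + 1L]] <<-
    data.frame(protein_id = id, rule = rule)
  keep <- logical(nrow(records))
  cls <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    id <- records$protein_id[i]
    k <- assignLocationClass(records$locations[[i]])
    if (is.na(k)) { reject(id, "location"); next }
    if (!records$reviewed[i]) { reject(id, "unreviewed"); next }
    if (any(tolower(records$evidence[[i]]) %in% badEvidence)) {
      reject(id, "evidence"); next
    }
    if (records$length[i] < minLength) { reject(id, "min-length"); next }
    if (k == "E" && records$glycosylated[i]) { reject(id, "glycosylated"); next }
    if (nrow(records$structures[[i]]) == 0L) { reject(id, "no-structure"); next }
    keep[i] <- TRUE
    cls[i] <- k
  }
  kept <- records[keep, , drop = FALSE]
  kept$class <- cls[keep]
  rejected <- if (length(rejections)) do.call(rbind, rejections)
              else data.frame(protein_id = character(), rule = character())
  list(kept = kept, rejected = rejected)
}

#' Pick the structure with the longest covered fragment
#'
#' When several structures cover a protein, the one covering the most
#' residues is used for exposure computation; ties break lexicographically
#' on the structure id for determinism.
#'
#' @param structures `data.frame` with columns `structure_id`, `covered`.
#' @return the selected structure id.
#' @export
selectLongestStructure <- function(structures) {
  if (!nrow(structures)) stop("no structure segments available")
  best <- structures[structures$covered == max(structures$covered), , drop = FALSE]
  sort(best$structure_id)[1]
}

#' Balanced negative sampling for one-vs-rest training
#'
#' Builds the negative set for one positive class: as many negatives as
#' positives, drawn without replacement from the other three classes with
#' equal per-class quotas. A class with fewer members than its quota
#' contributes all of them and the deficit is split equally over the
#' remaining classes (e.g. 543 cytoplasmic positives against 123
#' extracellular, 347 nucleocytoplasmic and 336 nuclear negatives takes all
#' 123 E plus 210 each from Y and N). When the positive count is not
#' divisible, the remainder is distributed one-by-one over classes in the
#' fixed order N, Y, C, E (positive class skipped).
#'
#' @param classMembers named list (names from `N`,`Y`,`C`,`E`) of member id
#'   vectors.
#' @param positive the positive class name.
#' @param seed integer seed for the without-replacement draws.
#' @return list with `positives` (ids), `negatives` (`data.frame` id,
#'   origin), `quota` (named draw counts) and `seed`.
#' @export
balanceDataset <- function(classMembers, positive, seed = 1L) {
  stopifnot(positive %in% names(classMembers))
  pos <- classMembers[[positive]]
  nPos <- length(pos)
  negClasses <- LOCATION_CLASSES[LOCATION_CLASSES != positive &
                                 LOCATION_CLASSES %in% names(classMembers)]
  avail <- vapply(classMembers[negClasses], length, integer(1))
  if (sum(avail) < nPos)
    stop("insufficient data: fewer negatives available than positives")
  # equal quotas with deficit waterfall: exhausted classes give everything,
  # the shortfall is re-split over classes that still have capacity
  quota <- structure(integer(length(negClasses)), names = negClasses)
  open <- negClasses
  remaining <- nPos
  while (remaining > 0L) {
    share <- remaining %/% length(open)
    extra <- remaining %% length(open)
    want <- structure(rep(share, length(open)), names = open)
    if (extra > 0L) want[seq_len(extra)] <- want[seq_len(extra)] + 1L  # fixed N,Y,C,E order
    give <- pmin(want, avail[open] - quota[open])
    quota[open] <- quota[open] + give
    remaining <- remaining - sum(give)
    open <- open[avail[open] > quota[open]]
  }
  set.seed(seed)
  negatives <- do.call(rbind, lapply(negClasses, function(k) {
    ids <- classMembers[[k]]
    take <- quota[[k]]
    picked <- if (take == length(ids)) ids else sample(ids, take)
    if (take) data.frame(id = picked, origin = k) else NULL
  }))
  if (is.null(negatives)) negatives <- data.frame(id = character(), origin = character())
  rownames(negatives) <- NULL
  list(positives = pos, negatives = negatives, quota = quota, seed = seed)
}

#' Curated-corpus class counts
#'
#' The packaged metadata of the curated structure-covered corpus: number of
#' proteins per location class (N = 336, Y = 347, C = 543, E = 132; 1358
#' in total).
#'
#' @param file optional JSON path overriding the packaged counts.
#' @return named integer vector over `N`, `Y`, `C`, `E`.
#' @export
classCounts <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "class_counts.json", package = "exposeloc")
  cc <- unlist(jsonlite::read_json(file))
  vapply(cc[LOCATION_CLASSES], as.integer, integer(1))
}
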