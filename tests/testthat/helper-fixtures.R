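# Shared fixture builders; everything is generated in code.

# Profile with the given residues (vectors of aa codes and range indices);
# RSA is placed mid-interval of the assigned range.
makeProfile <- function(aa, range, id = "toy") {
  stopifnot(length(aa) == length(range))
  b <- defaultRangeBoundaries()
  rsa <- (b[range] + b[range + 1L]) / 2
  new("ExposureProfile", proteinId = id,
      sequence = paste(aa, collapse = ""),
      residues = data.frame(position = seq_along(aa), aa = aa,
                            acc = NA_real_, rsa = rsa, range = as.integer(range)),
      source = "structure")
}

randomProfile <- function(n = 60L, id = "rnd") {
  aa <- sample(AA_CODES, n, replace = TRUE)
  rng <- sample.int(6L, n, replace = TRUE)
  makeProfile(aa, rng, id = id)
}

# Direct per-residue tally oracle for composition vectors.
oracleComposition <- function(profile, ranges) {
  r <- residueRecords(profile)
  keep <- r$aa[r$range %in% ranges]
  v <- structure(numeric(20), names = AA_CODES)
  for (a in keep) v[a] <- v[a] + 1
  if (length(keep)) v / length(keep) else v
}

# Lazily trained small two-stage model shared across test files.
.modelCache <- new.env(parent = emptyenv())

smallTrainingCorpus <- function() {
  if (is.null(.modelCache$corpus))
    .modelCache$corpus <- generateCorpus(generatorConfig(nPerClass = 40L, seed = 401L))
  .modelCache$corpus
}

smallModel <- function() {
  if (is.null(.modelCache$model))
    .modelCache$model <- {
      co <- smallTrainingCorpus()
      trainLocationModel(co$profiles, co$labels, grid = svmGridSmall(),
                         cvFolds = 5L, stackFolds = 3L, seed = 402L)
    }
  .modelCache$model
}

smallEvalCorpus <- function() {
  if (is.null(.modelCache$eval))
    .modelCache$eval <- generateCorpus(generatorConfig(nPerClass = 30L, seed = 403L))
  .modelCache$eval
}
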