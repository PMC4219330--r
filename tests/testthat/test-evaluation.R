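test_that("accuracy is the fraction of matching calls", {
  expect_identical(accuracy(c("N", "C"), c("N", "C")), 1)
  truths <- sample(LOCATION_CLASSES, 50, replace = TRUE)
  expect_identical(accuracy(truths, truths), 1)
  expect_error(accuracy(character(), character()), "empty")
  expect_error(accuracy("N", c("N", "C")), "differ")
  set.seed(1)
  p <- sample(LOCATION_CLASSES, 10000, replace = TRUE)
  t <- sample(LOCATION_CLASSES, 10000, replace = TRUE)
  expect_equal(accuracy(p, t), 0.25, tolerance = 0.08)  # 0.25 +/- 0.02 abs
  expect_lt(abs(accuracy(p, t) - 0.25), 0.02)
})

test_that("ROC points agree with a brute-force confusion matrix at every threshold", {
  perfect <- rocPoints(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(perfect$tpr == 1 & perfect$fpr == 0))
  for (s in 1:30) {
    set.seed(s)
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)
    truth <- runif(n) < 0.5
    if (!any(truth) || all(truth)) next
    roc <- rocPoints(scores, truth)
    for (i in seq_len(nrow(roc))) {
      pred <- scores >= roc$threshold[i]
      tp <- sum(pred & truth); fp <- sum(pred & !truth)
      fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
      expect_equal(roc$tpr[i], tp / (tp + fn))
      expect_equal(roc$fpr[i], fp / (fp + tn))
    }
    expect_false(is.unsorted(roc$tpr))
    expect_false(is.unsorted(roc$fpr))
  }
  expect_error(rocPoints(1:3 / 3, c(TRUE, TRUE, TRUE)), "negative")
})

test_that("uninformative scores give AUC near one half", {
  set.seed(3)
  n <- 4000
  roc <- rocPoints(runif(n), runif(n) < 0.5)
  expect_equal(rocAuc(roc), 0.5, tolerance = 0.06)
  expect_lt(abs(rocAuc(roc) - 0.5), 0.03)
})

test_that("exposure histograms are normalised per amino acid", {
  p <- makeProfile(rep("Q", 20), rep(1L, 20))  # all buried
  h <- exposureDistribution(list(p), "Q", bins = 10L)
  expect_equal(sum(h), 1)
  expect_equal(h[1], 1)
  expect_identical(attr(h, "n"), 20L)
  hv <- exposureDistribution(list(p), "W", bins = 10L)
  expect_true(all(is.na(hv)))
  expect_identical(attr(hv, "n"), 0L)
  set.seed(4)
  pr <- randomProfile(200L)
  expect_equal(sum(exposureDistribution(list(pr), "A")), 1)
})

test_that("the generator's extracellular class buries glutamine", {
  co <- generateCorpus(generatorConfig(nPerClass = 40L, seed = 31L,
                                       classes = c("N", "E")))
  byClass <- split(co$profiles, co$labels)
  qMassBuried <- function(profiles) {
    h <- exposureDistribution(profiles, "Q", bins = 10L)
    # ranges 1-2 end at RSA 0.08: the first bin of ten
    h[1]
  }
  expect_gt(qMassBuried(byClass$E), qMassBuried(byClass$N))
})

test_that("paralog-pair evaluation counts agreements and correctness", {
  pairs <- data.frame(id1 = c("a1", "b1", "c1"), class1 = c("N", "C", "E"),
                      id2 = c("a2", "b2", "c2"), class2 = c("C", "Y", "N"))
  perfect <- c(a1 = "N", a2 = "C", b1 = "C", b2 = "Y", c1 = "E", c2 = "N")
  ev <- evaluatePairs(pairs, perfect)
  expect_identical(ev$bothCorrect, 3L)
  expect_identical(ev$proteinsCorrect, 6L)
  allSame <- c(a1 = "N", a2 = "N", b1 = "N", b2 = "N", c1 = "N", c2 = "N")
  expect_identical(evaluatePairs(pairs, allSame)$sameLocation, 3L)
  # order of pairs does not matter
  ev2 <- evaluatePairs(pairs[c(3, 1, 2), ], perfect)
  expect_identical(ev2, ev)
  expect_error(evaluatePairs(pairs, perfect[-1]), "a1")
  # hand-tally oracle on random instances
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:12, 1)
    cls <- t(vapply(seq_len(n), function(i) sample(LOCATION_CLASSES, 2), character(2)))
    pp <- data.frame(id1 = paste0("x", 1:n), class1 = cls[, 1],
                     id2 = paste0("y", 1:n), class2 = cls[, 2])
    pred <- structure(sample(LOCATION_CLASSES, 2 * n, replace = TRUE),
                      names = c(pp$id1, pp$id2))
    ev3 <- evaluatePairs(pp, pred)
    both <- 0L; same <- 0L; prot <- 0L
    for (i in 1:n) {
      ok1 <- pred[[pp$id1[i]]] == pp$class1[i]
      ok2 <- pred[[pp$id2[i]]] == pp$class2[i]
      both <- both + (ok1 && ok2); prot <- prot + ok1 + ok2
      same <- same + (pred[[pp$id1[i]]] == pred[[pp$id2[i]]])
    }
    expect_identical(ev3$bothCorrect, both)
    expect_identical(ev3$sameLocation, same)
    expect_identical(ev3$proteinsCorrect, as.integer(prot))
  }
})

test_that("the Monte Carlo pair null matches the exact binomial tail", {
  expect_identical(permutationPvalue(10, 0, reps = 100, seed = 1L), 1)
  # single pair: exact success probability 1/16
  p1 <- permutationPvalue(1, 1, reps = 1e5, seed = 2L)
  se <- sqrt(1 / 16 * 15 / 16 / 1e5)
  expect_lt(abs(p1 - 1 / 16), 3 * se)
  # the published pair-set size: 13 correct of 64 is significant
  expect_lt(permutationPvalue(64, 13, reps = 1e5, seed = 3L), 0.01)
  # convergence to pbinom for several (n, k)
  for (case in list(c(20, 3), c(64, 13), c(50, 6))) {
    exact <- pbinom(case[2] - 1, case[1], 1 / 16, lower.tail = FALSE)
    mc <- permutationPvalue(case[1], case[2], reps = 1e5, seed = 4L)
    se <- sqrt(max(exact * (1 - exact), 1e-12) / 1e5)
    expect_lt(abs(mc - exact), 3 * se + 1e-6)
  }
  # alternative ordered-assignment null uses success probability 1/12
  pOrd <- permutationPvalue(64, 13, reps = 1e5, seed = 5L, null = "ordered")
  exactOrd <- pbinom(12, 64, 1 / 12, lower.tail = FALSE)
  expect_lt(abs(pOrd - exactOrd), 3 * sqrt(exactOrd * (1 - exactOrd) / 1e5) + 1e-6)
  # add-one estimator never returns exactly zero
  expect_gt(permutationPvalue(200, 200, reps = 1000, seed = 6L, corrected = TRUE), 0)
  expect_error(permutationPvalue(5, 6, 10, 1L), "0..nPairs")
})

test_that("nucleocytoplasmic merging uses the normalised score share", {
  expect_true(mergeNucleocytoplasmic(0.3, 0.3, c(0.3, 0.3, 0.4)))
  expect_false(mergeNucleocytoplasmic(0.5, 0.0, c(0.5, 0.0, 0.5)))  # not strict
  expect_false(mergeNucleocytoplasmic(0.2, 0.2, c(0.2, 0.2, 0.6)))
  # unnormalised inputs behave identically after scaling
  expect_true(mergeNucleocytoplasmic(3, 3, c(3, 3, 4)))
  expect_error(mergeNucleocytoplasmic(0, 0, c(0, 0, 0)), "all-zero")
  expect_error(mergeNucleocytoplasmic(-1, 0.5, c(-1, 0.5)), "non-negative")
})
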