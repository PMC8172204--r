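test_that("RFE ranks a perfectly separating feature first (20 seeds)", {
  for (s in 1:20) {
    set.seed(s)
    n <- 40
    y <- rep(c("NS", "WBS"), each = n / 2)
    X <- matrix(rnorm(n * 10), n)
    colnames(X) <- sprintf("f%02d", 1:10)
    X[, 4] <- ifelse(y == "NS", 1, -1) + rnorm(n, 0, 0.05)
    expect_equal(svmRfeRanking(X, y)[1], "f04")
  }
})

test_that("duplicated feature columns occupy adjacent ranks", {
  set.seed(2)
  n <- 30
  y <- rep(c("NS", "WBS"), each = 15)
  X <- matrix(rnorm(n * 8), n)
  X[, 1] <- ifelse(y == "NS", 0.8, -0.8) + rnorm(n, 0, 0.3)
  X <- cbind(X, X[, 1])
  colnames(X) <- c(sprintf("f%02d", 1:8), "f01dup")
  rk <- svmRfeRanking(X, y)
  expect_equal(abs(diff(match(c("f01", "f01dup"), rk))), 1)
})

test_that("step = p gives a single round ranked by |coefficient|", {
  set.seed(5)
  n <- 50
  y <- rep(c("NS", "WBS"), each = 25)
  X <- matrix(rnorm(n * 12), n)
  colnames(X) <- sprintf("f%02d", 1:12)
  X[, 2] <- X[, 2] + ifelse(y == "NS", 1, -1)
  X[, 7] <- X[, 7] + ifelse(y == "NS", 0.5, -0.5)
  rk <- svmRfeRanking(X, y, step = ncol(X))
  fit <- linearSvm(scale(X), y)
  expect_equal(rk, names(sort(abs(fit$w), decreasing = TRUE)))
})

test_that("non-finite features and single-class inputs are rejected", {
  X <- matrix(rnorm(40), 10); colnames(X) <- paste0("f", 1:4)
  y <- rep(c("NS", "WBS"), 5)
  Xb <- X; Xb[2, 2] <- Inf
  expect_error(svmRfeRanking(Xb, y), "finite")
  expect_error(svmRfeRanking(X, rep("NS", 10)), "class")
})

test_that("optimal k is the smallest count within epsilon of the best AUC", {
  auc <- c(`1` = 0.70, `2` = 0.80, `5` = 0.90, `10` = 0.905, `20` = 0.906)
  expect_equal(optimalK(auc, epsilon = 0.01), 5L)
  expect_equal(optimalK(c(`1` = 0.9, `4` = 0.9, `9` = 0.9)), 1L)
  expect_equal(optimalK(c(`1` = 0.85, `3` = 0.90), epsilon = 0.2), 1L)
})

test_that("LOOCV at k = p equals plain leave-one-out of the full model", {
  set.seed(9)
  n <- 20; p <- 5
  y <- rep(c("NS", "WBS"), each = 10)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("f", 1:p)
  X[, 1] <- X[, 1] + ifelse(y == "NS", 1, -1)
  cv <- loocvCurve(list(X = X, y = y), kGrid = p)
  manual <- vapply(seq_len(n), function(i) {
    fit <- linearSvm(X[-i, ], y[-i])
    fit$decision(X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(unname(cv$scores[1, ]), manual, tolerance = 1e-8)

  ## prediction bookkeeping identities
  acc <- cv$curves$accuracy
  nNS <- sum(y == "NS"); nWBS <- sum(y == "WBS")
  expect_equal(acc, (cv$curves$accuracy_NS * nNS +
                       cv$curves$accuracy_WBS * nWBS) / n)
})

test_that("a fold that loses one class entirely is an error", {
  X <- matrix(rnorm(10 * 3), 10); colnames(X) <- paste0("f", 1:3)
  y <- c(rep("NS", 9), "WBS")
  expect_error(loocvCurve(list(X = X, y = y), kGrid = 2), "class")
})

test_that("selectFeatures returns a coherent SelectionResult", {
  set.seed(4)
  n <- 30; p <- 15
  y <- rep(c("NS", "WBS"), each = 15)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- sprintf("f%02d", 1:p)
  rownames(X) <- sprintf("sub%02d", 1:n)
  X[, 1:2] <- X[, 1:2] + ifelse(y == "NS", 1.2, -1.2)
  res <- selectFeatures(list(X = X, y = y), kGrid = c(1:6, 10, 15))
  expect_s4_class(res, "SelectionResult")
  expect_length(selectedFeatures(res), kStar(res))
  expect_identical(selectedFeatures(res),
                   featureRanking(res)[seq_len(kStar(res))])
  pr <- loocvPredictions(res)
  expect_equal(sort(pr$subject), sort(rownames(X)))
  expect_false(anyDuplicated(pr$subject) > 0)
  fs <- featureStats(res)
  expect_equal(fs$feature, selectedFeatures(res))
  expect_true(all(fs$p > 0 & fs$p <= 1))
  ## ranking is a permutation of all features
  expect_setequal(featureRanking(res), colnames(X))
})

test_that("stratified evaluation on a single stratum reduces to the global model", {
  set.seed(8)
  n <- 24; p <- 8
  y <- rep(c("NS", "WBS"), each = 12)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("f", 1:p)
  rownames(X) <- paste0("s", 1:n)
  X[, 3] <- X[, 3] + ifelse(y == "NS", 1.5, -1.5)
  rep1 <- stratifiedEvaluation(list(X = X, y = y,
                                    strata = rep("Caucasian", n)),
                               kGrid = c(1:4, 8))
  expect_equal(rep1$strata$Caucasian$global_accuracy,
               rep1$strata$Caucasian$specific_accuracy)
  expect_equal(rep1$overall$improvement, 0)
  expect_equal(rep1$overall$fisher_p, 1)
  expect_equal(rep1$global$accuracy, rep1$global$accuracy_recombined)
})

test_that("a stratum missing one class is skipped with a warning", {
  set.seed(10)
  n <- 30
  y <- c(rep(c("NS", "WBS"), each = 12), rep("NS", 6))
  strata <- c(rep("Caucasian", 24), rep("Asian", 6))
  X <- matrix(rnorm(n * 6), n); colnames(X) <- paste0("f", 1:6)
  rownames(X) <- paste0("s", 1:n)
  X[, 1] <- X[, 1] + ifelse(y == "NS", 1.5, -1.5)
  expect_warning(
    r <- stratifiedEvaluation(list(X = X, y = y, strata = strata),
                              kGrid = c(1, 3, 6)),
    "Asian")
  expect_named(r$strata, "Caucasian")
  expect_equal(r$overall$n, 24)
})
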