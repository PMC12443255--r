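test_that("confusion tallies match a brute-force pairwise count", {
  cc <- confusion(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 3L, TN = 2L, FP = 0L, FN = 0L))
  inv <- confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(inv$TP + inv$TN, 0L)

  set.seed(2)
  yt <- rbinom(200, 1, 0.4); yp <- rbinom(200, 1, 0.5)
  cc <- confusion(yt, yp)
  brute <- c(sum(yt & yp), sum(!yt & yp), sum(!yt & !yp), sum(yt & !yp))
  expect_equal(c(cc$TP, cc$FP, cc$TN, cc$FN), brute)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 200L)
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
})

test_that("metric suite matches the closed forms", {
  perfect <- metric_suite(list(TP = 50, FP = 0, TN = 50, FN = 0))
  expect_equal(unname(perfect), rep(1, 6))

  # all-positive predictor on a balanced set: SP = 0, MCC = 0
  degen <- metric_suite(list(TP = 50, FP = 50, TN = 0, FN = 0))
  expect_equal(unname(degen["SP"]), 0)
  expect_equal(unname(degen["MCC"]), 0)

  m <- metric_suite(list(TP = 37, FP = 12, TN = 41, FN = 10))
  expect_equal(unname(m["ACC"]), 78 / 100)
  expect_equal(unname(m["SN"]), 37 / 47)
  expect_equal(unname(m["SP"]), 41 / 53)
  expect_equal(unname(m["Precision"]), 37 / 49)
  expect_equal(unname(m["MCC"]),
               (37 * 41 - 12 * 10) / sqrt(49 * 47 * 53 * 51))
  expect_equal(unname(m["F1"]),
               2 * (37 / 49) * (37 / 47) / (37 / 49 + 37 / 47))
})

test_that("metrics stay in range over random confusion tables", {
  set.seed(3)
  for (i in 1:300) {
    counts <- as.list(sample(0:40, 4, replace = TRUE))
    names(counts) <- c("TP", "FP", "TN", "FN")
    m <- metric_suite(counts)
    expect_true(m["MCC"] >= -1 && m["MCC"] <= 1)
    expect_true(all(m[c("ACC", "SN", "SP", "F1", "Precision")] >= 0 &
                    m[c("ACC", "SN", "SP", "F1", "Precision")] <= 1))
  }
})

test_that("trapezoid AUC equals the Mann-Whitney estimator", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)

  set.seed(5)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(scores, y)$auc, oracle_mw_auc(scores, y),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("ROC curve is monotone from (0,0) to (1,1)", {
  set.seed(6)
  r <- roc_auc(runif(50), rbinom(50, 1, 0.5))
  expect_equal(r$curve$FPR[1], 0)
  expect_equal(r$curve$TPR[1], 0)
  expect_equal(r$curve$FPR[nrow(r$curve)], 1)
  expect_equal(r$curve$TPR[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$FPR) >= 0))
  expect_true(all(diff(r$curve$TPR) >= 0))
})

test_that("AUC is invariant under monotone transforms, reflects on swap", {
  set.seed(7)
  s <- runif(80); y <- rbinom(80, 1, 0.5)
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(qlogis(s * 0.98 + 0.01), y)$auc, a)
  expect_equal(roc_auc(-s, 1 - y)$auc, a)
  expect_equal(roc_auc(-s, y)$auc, 1 - a, tolerance = 1e-12)
})

test_that("cross-validation folds partition the data", {
  d <- make_blobs(blob_spec(n_minority = 30, n_majority = 60, dim = 4,
                            seed = 3))
  assignment <- acpkit:::stratified_folds(d$y, 5, seed = 1)
  expect_true(all(assignment %in% 1:5))
  expect_length(assignment, 90)
  # stratification: each fold holds 6 minority and 12 majority
  expect_true(all(table(assignment[d$y == 1]) == 6))
  expect_true(all(table(assignment[d$y == 0]) == 12))
  expect_error(acpkit:::stratified_folds(c(1, 1, 0, 0), 3, 1), "fewer")
})

test_that("cross-validation recovers separable structure reproducibly", {
  d <- make_blobs(blob_spec(n_minority = 30, n_majority = 60, dim = 4,
                            class_separation = 8, seed = 4))
  cv1 <- cross_validate(d, folds = 3, resample_mode = "safe", seed = 2)
  expect_gte(cv1$mean[["ACC"]], 0.95)
  cv2 <- cross_validate(d, folds = 3, resample_mode = "safe", seed = 2)
  expect_identical(cv1$per_fold, cv2$per_fold)
})

test_that("paper and safe resampling modes both run on one fixture", {
  d <- make_blobs(blob_spec(n_minority = 25, n_majority = 60, dim = 4,
                            class_separation = 2, seed = 8))
  safe <- cross_validate(d, folds = 3, resample_mode = "safe", seed = 1)
  paper <- cross_validate(d, folds = 3, resample_mode = "paper", seed = 1)
  expect_true(is.finite(safe$mean[["AUC"]]))
  expect_true(is.finite(paper$mean[["AUC"]]))
  # the balance-then-fold protocol: test folds contain synthetics
  expect_equal(nrow(safe$per_fold), 3L)
  expect_equal(nrow(paper$per_fold), 3L)
})
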