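test_that("euclidean_distance matches the coordinate-wise definition", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(1)
  p1 <- rnorm(10); p2 <- rnorm(10)
  acc <- 0
  for (i in 1:10) acc <- acc + (p1[i] - p2[i])^2
  expect_equal(euclidean_distance(p1, p2), sqrt(acc))
  expect_error(euclidean_distance(1:3, 1:4), "dimension")
})

test_that("adasyn_difficulty reproduces a brute-force k-NN enumeration", {
  # planted 12-point 2-D configuration
  X <- rbind(
    c(0, 0), c(0.1, 0), c(0, 0.1), c(5, 5),            # minority
    c(0.05, 0.05), c(0.2, 0.1), c(0.1, 0.2),           # majority near
    c(10, 10), c(11, 10), c(10, 11), c(12, 12), c(9, 9))
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  data <- labeled_matrix(X, y)
  k <- 3
  plan <- adasyn_difficulty(data, k = k)

  brute_r <- vapply(which(y == 1), function(i) {
    d <- apply(X, 1, function(row) euclidean_distance(row, X[i, ]))
    d[i] <- Inf
    nn <- order(d, seq_along(d))[1:k]
    sum(y[nn] == 0) / k
  }, numeric(1))
  expect_equal(plan$r, brute_r)
  expect_true(all(plan$r >= 0 & plan$r <= 1))
  expect_equal(sum(plan$r_norm), 1)
})

test_that("difficulty hits the bounds for surrounded and isolated points", {
  # 3 minority / 4 majority; (0,0) is engulfed by majority, the
  # (20,20)-(20.5,20) pair is isolated among minority
  X <- rbind(c(0, 0), c(20, 20), c(20.5, 20),
             c(0.1, 0), c(0, 0.1), c(0.1, 0.1), c(30, 30))
  y <- c(1, 1, 1, 0, 0, 0, 0)
  plan <- adasyn_difficulty(labeled_matrix(X, y), k = 3)
  expect_equal(plan$r[1], 1)   # all 3 nearest neighbors are majority
  plan1 <- adasyn_difficulty(labeled_matrix(X, y), k = 1)
  expect_equal(plan1$r[2], 0)  # nearest neighbor is minority
  expect_error(adasyn_difficulty(labeled_matrix(X, y), k = 7), "n - 1")
})

test_that("all-zero difficulty falls back to uniform normalization", {
  # tight minority pair far from all majority
  X <- rbind(c(0, 0), c(0.1, 0), c(100, 100), c(101, 100), c(100, 101))
  y <- c(1, 1, 0, 0, 0)
  plan <- adasyn_difficulty(labeled_matrix(X, y), k = 1)
  expect_equal(plan$r, c(0, 0))
  expect_equal(plan$r_norm, c(0.5, 0.5))
})

test_that("adasyn_allocate conserves G by largest remainder", {
  plan <- structure(list(k = 3L, minority_idx = 1:2,
                         r = c(0.2, 0.8), r_norm = c(0.2, 0.8)),
                    class = "adasyn_plan")
  expect_equal(adasyn_allocate(plan, 10)$G_alloc, c(2L, 8L))
  expect_equal(adasyn_allocate(plan, 0)$G_alloc, c(0L, 0L))

  plan$r_norm <- c(1 / 3, 2 / 3)
  out <- adasyn_allocate(plan, 10)
  expect_equal(sum(out$G_alloc), 10L)
  expect_true(all(abs(out$G_alloc - plan$r_norm * 10) < 1))

  # property over random plans: exact conservation, within-1 rounding
  set.seed(11)
  for (i in 1:25) {
    r <- runif(sample(3:10, 1)); r_norm <- r / sum(r)
    G <- sample(0:50, 1)
    p <- structure(list(k = 3L, minority_idx = seq_along(r),
                        r = r, r_norm = r_norm), class = "adasyn_plan")
    a <- adasyn_allocate(p, G)
    expect_equal(sum(a$G_alloc), G)
    expect_true(all(abs(a$G_alloc - r_norm * G) < 1))
  }
})

test_that("adasyn_synthesize interpolates between minority parents", {
  data <- random_labeled(8, 20, 4, seed = 3)
  plan <- adasyn_allocate(adasyn_difficulty(data, k = 3), 15)

  out <- adasyn_synthesize(data, plan, seed = 5)
  parents <- attr(out, "parents")
  expect_equal(nrow(out$X), 28 + 15)
  expect_equal(nrow(parents), 15)
  new_rows <- out$X[29:43, , drop = FALSE]
  for (j in seq_len(15)) {
    lo <- pmin(data$X[parents[j, 1], ], data$X[parents[j, 2], ])
    hi <- pmax(data$X[parents[j, 1], ], data$X[parents[j, 2], ])
    expect_true(all(new_rows[j, ] >= lo - 1e-12 & new_rows[j, ] <= hi + 1e-12))
  }

  # delta test hook: synthetic points become parent midpoints
  mid <- adasyn_synthesize(data, plan, seed = 5, delta = 0.5)
  pm <- attr(mid, "parents")
  mids <- (data$X[pm[, 1], ] + data$X[pm[, 2], ]) / 2
  expect_equal(unname(mid$X[29:43, ]), unname(mids))

  # zero allocation leaves the data unchanged
  none <- adasyn_synthesize(data, adasyn_allocate(plan, 0), seed = 5)
  expect_equal(none$X, data$X)
})

test_that("anbs balances the canonical 487/1479 imbalance to 1478/1478", {
  d <- make_blobs(blob_spec(seed = 7))
  out <- anbs(d, anbs_config(seed = 3))
  expect_equal(sum(out$y == 1), 1478L)
  expect_equal(sum(out$y == 0), 1478L)
  expect_equal(attr(out, "status"), "converged")
})

test_that("anbs returns already balanced input unchanged", {
  d <- make_blobs(blob_spec(n_minority = 30, n_majority = 30, dim = 4,
                            seed = 2))
  out <- anbs(d, anbs_config())
  expect_equal(out$X, d$X)
  expect_equal(out$y, d$y)
})

test_that("anbs follows the count recurrence on a small example", {
  # 10 minority / 30 majority: one iteration removes 1 majority and
  # tops minority up to 29, reaching ratio 1 -> (29, 29)
  d <- make_blobs(blob_spec(n_minority = 10, n_majority = 30, dim = 2,
                            seed = 5))
  out <- anbs(d, anbs_config(max_iter = 5))
  expect_equal(sum(out$y == 1), 29L)
  expect_equal(sum(out$y == 0), 29L)
  tr <- attr(out, "trace")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$added, 19L)
})

test_that("anbs preserves original rows except pruned boundary majority", {
  d <- random_labeled(12, 36, 3, seed = 9)
  out <- anbs(d, anbs_config(seed = 1))
  removed <- attr(out, "removed")
  expect_true(all(d$y[removed] == 0))
  kept <- setdiff(seq_len(nrow(d$X)), removed)
  originals <- out$X[out$provenance == "original", , drop = FALSE]
  expect_equal(unname(originals), unname(d$X[kept, , drop = FALSE]))
  # monotone class counts
  tr <- attr(out, "trace")
  expect_true(all(diff(c(36, tr$n_majority)) <= 0))
  expect_true(all(diff(c(12, tr$n_minority)) >= 0))
})

test_that("anbs output is bit-reproducible under a fixed seed", {
  d <- random_labeled(15, 45, 4, seed = 13)
  o1 <- anbs(d, anbs_config(seed = 21))
  o2 <- anbs(d, anbs_config(seed = 21))
  expect_identical(o1$X, o2$X)
  o3 <- anbs(d, anbs_config(seed = 22))
  expect_false(identical(o1$X, o3$X))
})

test_that("the top-up rule reaches any target ratio in one iteration", {
  # synthesis tops minority up to ceil(max_ratio * |majority|), so the
  # ratio guard is satisfied after the first pass regardless of max_iter
  d <- random_labeled(5, 50, 2, seed = 4)
  out <- anbs(d, anbs_config(max_iter = 1, seed = 1))
  expect_equal(attr(out, "status"), "converged")
  expect_equal(nrow(attr(out, "trace")), 1L)
  out2 <- anbs(d, anbs_config(max_ratio = 1.5, max_iter = 3, seed = 1))
  expect_gte(sum(out2$y == 1) / sum(out2$y == 0), 1.5)
})

test_that("per-iteration cost grows roughly quadratically, not worse", {
  # loose empirical scaling check at fixed dimensionality
  time_one <- function(n) {
    d <- random_labeled(n, 3 * n, 8, seed = n)
    median(vapply(1:3, function(i) {
      system.time(anbs(d, anbs_config(max_iter = 1, seed = i)))[["elapsed"]]
    }, numeric(1)))
  }
  t1 <- time_one(150)
  t2 <- time_one(300)
  expect_lt(t2, max(t1, 0.02) * 12)
})
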