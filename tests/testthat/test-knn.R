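test_that("Minkowski distance handles standard cases and rejects p < 1", {
  expect_equal(minkowski_distance(c(0.3, 0.7), c(0.3, 0.7), 2), 0)
  expect_equal(minkowski_distance(c(0, 0), c(3, 4), 2), 5)
  set.seed(42)
  for (i in 1:25) {
    a <- rnorm(2); b <- rnorm(2)
    expect_equal(minkowski_distance(a, b, 1), sum(abs(a - b)))
    expect_equal(minkowski_distance(a, b, 3),
                 (abs(a[1] - b[1])^3 + abs(a[2] - b[2])^3)^(1 / 3))
  }
  expect_error(minkowski_distance(c(0, 0), c(1, 1), 0.5),
               class = "airwayspec_parameter_error")
})

test_that("knn model validates k, p, and cohort size", {
  fx <- toy_features(n_per_class = 6)
  expect_s3_class(knn_model(fx, k = 5), "knn_model")
  expect_error(knn_model(fx, k = 12), class = "airwayspec_validation_error")
  expect_error(knn_model(fx, k = 0), class = "airwayspec_parameter_error")
  expect_error(knn_model(fx, p = 0.5), class = "airwayspec_parameter_error")
  one_class <- fx; one_class$label <- "trachea"
  expect_error(knn_model(one_class), class = "airwayspec_validation_error")
})

test_that("a unanimous inclusive neighborhood gives 100% confidence", {
  fx <- toy_features(n_per_class = 15, sep = 50, sd = 0.1)
  m <- knn_model(fx, k = 10)
  res <- knn_classify(m, self_index = 1L)
  expect_identical(res$label, "trachea")
  expect_equal(res$confidence, 100)
  expect_false(res$tie)
})

test_that("knn agrees with the exhaustive-sort oracle on random cohorts", {
  for (p in c(1, 2, 3)) {
    fx <- toy_features(n_per_class = 60, seed = 100 + p, sep = 0.5)
    fx$pair_id <- seq_len(nrow(fx))  # tie rank = row order, as in the oracle
    fx$organ <- fx$label
    X <- cbind(fx$r543, fx$r578)
    m <- knn_model(fx, k = 7, p = p)
    # resubstitution on every training point
    for (i in seq_len(nrow(fx))) {
      got <- knn_classify(m, self_index = i)
      want <- oracle_knn(X, fx$label, X[i, ], k = 7, p = p, self_index = i)
      expect_identical(got$label, want$label)
      expect_equal(got$confidence, want$confidence)
    }
    # external queries
    set.seed(p)
    for (q in 1:40) {
      query <- rnorm(2, 0.25, 0.6)
      got <- knn_classify(m, query = query)
      want <- oracle_knn(X, fx$label, query, k = 7, p = p)
      expect_identical(got$label, want$label)
      expect_equal(got$confidence, want$confidence)
    }
  }
})

test_that("resubstitution guarantees the true class at least one of k+1 votes", {
  fx <- toy_features(n_per_class = 30, seed = 9, sep = 0.1, sd = 1)
  m <- knn_model(fx, k = 10)
  for (i in seq_len(nrow(fx))) {
    res <- knn_classify(m, self_index = i)
    expect_gte(res$votes[[fx$label[i]]], 1L)
    if (res$label == fx$label[i]) {
      expect_gte(res$confidence, 100 / (m$k + 1))
    }
  }
})

test_that("an even split falls back to the nearest neighbor, flagged", {
  fx <- data.frame(
    pair_id = 1:5, organ = c("trachea", "trachea", "esophagus", "esophagus",
                             "trachea"),
    acq_index = 1L,
    r543 = c(0.1, 0.2, -0.1, -0.2, 5),
    r578 = c(0, 0, 0, 0, 0),
    label = c("trachea", "trachea", "esophagus", "esophagus", "trachea"))
  m <- knn_model(fx, k = 4)  # external query: 4 votes, 2-2 split possible
  res <- knn_classify(m, query = c(0, 0))
  expect_true(res$tie)
  expect_identical(res$label, "trachea")  # nearest is (0.1, 0) trachea
  expect_equal(res$confidence, 50)
})

test_that("distance ties at the k-th rank break lexicographically on metadata", {
  # four equidistant points; k = 1 must pick the smallest (pair_id, organ,
  # acq_index), and swapping metadata changes the pick deterministically
  fx <- data.frame(
    pair_id = c(3L, 1L, 2L, 4L, 9L),
    organ = c("trachea", "esophagus", "trachea", "esophagus", "trachea"),
    acq_index = 1L,
    r543 = c(1, -1, 0, 0, 30),
    r578 = c(0, 0, 1, -1, 0),
    label = c("trachea", "esophagus", "trachea", "esophagus", "trachea"))
  m <- knn_model(fx, k = 1)
  res <- knn_classify(m, query = c(0, 0))
  expect_identical(res$label, "esophagus")  # pair_id 1 wins the tie
  fx2 <- fx; fx2$pair_id <- c(1L, 3L, 2L, 4L, 9L)
  res2 <- knn_classify(knn_model(fx2, k = 1), query = c(0, 0))
  expect_identical(res2$label, "trachea")
})

test_that("cohort classification matches per-point calls under both protocols", {
  fx <- toy_features(n_per_class = 12, seed = 4, sep = 0.8)
  m <- knn_model(fx, k = 5)
  resub <- knn_classify_cohort(m, "resubstitution")
  loo <- knn_classify_cohort(m, "loo")
  i <- 7L
  expect_identical(resub$label[i], knn_classify(m, self_index = i)$label)
  expect_identical(loo$label[i],
                   knn_classify(m, self_index = i, self_vote = FALSE)$label)
  # loo confidences use k votes, resub k + 1
  expect_true(all(resub$confidence %in% (100 * (0:6) / 6) |
                    resub$confidence == 50))
  expect_true(all(loo$confidence %in% (100 * (0:5) / 5) |
                    loo$confidence == 50))
})
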