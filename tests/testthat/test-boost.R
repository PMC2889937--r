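test_that("a single stump separates threshold-separable 1-D data", {
  set.seed(801)
  x <- data.frame(v = c(runif(50, 0, 0.4), runif(50, 0.6, 1)))
  y <- rep(c(0L, 1L), each = 50)
  m <- train_multiboost(x, y, n_iterations = 1L, seed = 1)
  expect_identical(nrow(m$stumps), 1L)
  pred <- as.integer(score_features(m, x) > 0.5)
  expect_identical(pred, as.integer(y))
})

test_that("the committee beats any single stump on jittered XOR data", {
  set.seed(802)
  n <- 200
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  y <- as.integer(xor(a, b))
  x <- data.frame(f1 = a + rnorm(n, sd = 0.25), f2 = b + rnorm(n, sd = 0.25))
  m <- train_multiboost(x, y, n_iterations = 40L, seed = 2)
  err_committee <- mean(as.integer(score_features(m, x) > 0.5) != y)
  # best single stump on the same data
  st <- mirsite:::fit_stump(as.matrix(x), ifelse(y == 1, 1, -1), rep(1, n))
  expect_lt(err_committee, 0.5)
  expect_lt(err_committee, st$error)
})

test_that("permuted labels give chance-level held-out AUC", {
  set.seed(803)
  n <- 300
  y <- sample(rep(c(0L, 1L), each = n / 2))
  x <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  cv <- cross_validate(x, y, folds = 5, seed = 4, n_iterations = 40)
  expect_gt(cv$auc, 0.35); expect_lt(cv$auc, 0.65)
})

test_that("scores follow the normalized committee vote arithmetic", {
  m <- permissive_model()
  m$stumps <- data.frame(
    feature = c("a", "a", "b"), split = c(0.5, 0.2, 0),
    left_class = c(1L, 0L, 1L), alpha = c(1, 0.5, 2),
    stringsAsFactors = FALSE)
  m$feature_set <- c("a", "b")
  v <- c(a = 0.3, b = -1)
  # stump votes: a<=0.5 -> +1; a<=0.2 false -> right=1 -> +1; b<=0 -> +1
  expect_equal(score_features(m, v), 1)
  v2 <- c(a = 0.25, b = 5)
  # votes: +1 (alpha 1), +1 (alpha 0.5), -1 (alpha 2) -> margin -0.5 of 3.5
  expect_equal(score_features(m, v2), (-0.5 / 3.5 + 1) / 2)
  m$stumps <- m$stumps[0, ]
  expect_equal(score_features(m, v), 0.5)
  expect_error(score_features(permissive_model(), c(a = 1)), "missing feature")
})

test_that("with one subcommittee MultiBoost reduces exactly to AdaBoost", {
  set.seed(804)
  n <- 150
  y <- rep(c(0L, 1L), each = n / 2)
  x <- data.frame(u = y + rnorm(n), v = rnorm(n), w = y * 0.5 + rnorm(n))
  m <- train_multiboost(x, y, n_iterations = 25L, n_subcommittees = 1L, seed = 5)
  orc <- oracle_adaboost(x, y, 25L)
  expect_identical(nrow(m$stumps), length(orc))
  for (k in seq_along(orc)) {
    expect_identical(m$stumps$feature[k], colnames(x)[orc[[k]]$f])
    expect_equal(m$stumps$split[k], orc[[k]]$s)
    expect_equal(m$stumps$alpha[k], orc[[k]]$alpha)
    expect_identical(m$stumps$left_class[k], as.integer(orc[[k]]$left == 1))
  }
})

test_that("training is bit-reproducible for a fixed seed", {
  set.seed(805)
  n <- 120
  y <- rep(c(0L, 1L), each = n / 2)
  x <- data.frame(a = y + rnorm(n), b = rnorm(n))
  m1 <- train_multiboost(x, y, n_iterations = 60, seed = 11)
  m2 <- train_multiboost(x, y, n_iterations = 60, seed = 11)
  expect_identical(m1, m2)
  cv1 <- cross_validate(x, y, folds = 5, seed = 3, n_iterations = 30)
  cv2 <- cross_validate(x, y, folds = 5, seed = 3, n_iterations = 30)
  expect_identical(cv1, cv2)
})

test_that("trapezoidal AUC equals the rank statistic", {
  set.seed(806)
  for (k in 1:100) {
    n <- sample(20:120, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    # discrete grid scores exercise heavy ties
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    r <- roc_curve(s, y)
    expect_equal(auc(r), auc_rank(s, y), tolerance = 1e-12)
  }
})

test_that("auc agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(807)
  y <- rbinom(200, 1, 0.5); y[1:2] <- c(0L, 1L)
  s <- rnorm(200) + y
  r <- roc_curve(s, y)
  expect_equal(auc(r), as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("cross-validation mechanics: stratification and leave-one-out", {
  set.seed(808)
  y <- rep(c(0L, 1L), each = 10)
  x <- data.frame(a = y + rnorm(20), b = rnorm(20))
  cv <- cross_validate(x, y, folds = 10, seed = 1, n_iterations = 5)
  expect_length(cv$scores, 20)
  for (k in 1:10) expect_identical(sort(unique(y[cv$fold == k])), c(0L, 1L))
  expect_error(cross_validate(x, y, folds = 1, seed = 1), "folds")
  expect_error(cross_validate(x, y, folds = 30, seed = 1), "folds")
})

test_that("calibrated thresholds control the false-positive rate", {
  set.seed(809)
  neg <- runif(1000); pos <- runif(1000, 0.5, 1.5)
  scores <- c(neg, pos); labels <- rep(c(0L, 1L), each = 1000)
  thr <- calibrate_thresholds(scores, labels)
  expect_lte(thr$sens, thr$spec)
  # by construction on the calibration sample itself
  expect_lt(mean(neg >= thr$sens), 0.05)
  expect_lte(mean(neg >= thr$spec), 0.01)
  # on a fresh sample, within binomial tolerance
  fresh <- runif(2000)
  tol <- 2 * sqrt(0.05 * 0.95 / 2000)
  expect_lte(mean(fresh >= thr$sens), 0.05 + tol)
  expect_lte(mean(fresh >= thr$spec), 0.01 + 2 * sqrt(0.01 * 0.99 / 2000))
  # fully separated scores: a single threshold in (0, 1] with zero FPR
  thr2 <- calibrate_thresholds(c(rep(0, 50), rep(1, 50)), rep(c(0L, 1L), each = 50))
  expect_identical(thr2$sens, thr2$spec)
  expect_lte(thr2$spec, 1)
  expect_equal(mean(rep(0, 50) >= thr2$sens), 0)
  expect_error(calibrate_thresholds(rep(0.7, 100), rep(c(0L, 1L), 50)),
               "degenerate")
})

test_that("specific predictions nest inside sensitive predictions", {
  set.seed(810)
  for (k in 1:10) {
    s <- runif(500)
    y <- rbinom(500, 1, 0.4 + 0.3 * s)
    thr <- calibrate_thresholds(s, y)
    expect_true(all(which(s >= thr$spec) %in% which(s >= thr$sens)))
  }
})

test_that("model JSON round trip is lossless", {
  set.seed(811)
  y <- rep(c(0L, 1L), each = 60)
  x <- data.frame(a = y + rnorm(120), b = rnorm(120), c = rnorm(120))
  m <- train_multiboost(x, y, n_iterations = 30, seed = 7)
  m$thresholds <- list(sens = 1 / 3, spec = 2 / 3)
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2, m)
  expect_identical(m2$stumps$split, m$stumps$split)  # full precision
  expect_error(suppressWarnings(load_model(tempfile())))
  # a JSON file that is not a model is rejected by the format check
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(x = 1), f2)
  expect_error(load_model(f2), "not a mirsite model")
})
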