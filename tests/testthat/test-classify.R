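test_that("1-NN returns the label of an identical reference", {
  set.seed(3)
  ref <- matrix(rnorm(20), 5, 4)
  labs <- letters[1:5]
  expect_identical(knn_classify(ref, labs, ref[2, , drop = FALSE], k = 1L), "b")
  # self-query at k = 1 reproduces every reference label
  expect_identical(knn_classify(ref, labs, ref, k = 1L), labs)
})

test_that("vote ties break toward the nearest neighbour's class", {
  ref <- rbind(c(1, 0), c(0.9, 0.1), c(0, 1), c(0.1, 0.9))
  labs <- c("x", "x", "y", "y")
  q <- matrix(c(1, 0.2), 1, 2)  # closer to the x cluster; 2-2 tie at k = 4
  expect_identical(knn_classify(ref, labs, q, k = 4L), "x")
})

test_that("knn matches a brute-force all-pairs cosine oracle", {
  set.seed(11)
  ref <- matrix(rnorm(40 * 6), 40, 6)
  labs <- sample(c("a", "b", "c"), 40, replace = TRUE)
  q <- matrix(rnorm(15 * 6), 15, 6)
  for (k in c(1L, 3L, 5L)) {
    expect_identical(knn_classify(ref, labs, q, k),
                     oracle_knn(ref, labs, q, k))
  }
})

test_that("knn is invariant to common rescaling (cosine metric)", {
  set.seed(4)
  ref <- matrix(rnorm(30 * 5), 30, 5)
  labs <- sample(c("a", "b"), 30, replace = TRUE)
  q <- matrix(rnorm(8 * 5), 8, 5)
  expect_identical(knn_classify(ref, labs, q, 3L),
                   knn_classify(ref * 7.3, labs, q * 0.01, 3L))
})

test_that("k beyond the reference count is an error", {
  ref <- matrix(rnorm(6), 3, 2)
  expect_error(knn_classify(ref, c("a", "b", "c"), ref, k = 4L), "exceeds")
  expect_error(knn_classify(ref, c("a", "b", "c"), ref, k = 0L), ">= 1")
})

test_that("metrics are exact on a perfect confusion matrix", {
  cm <- diag(c(5L, 7L, 9L))
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$cen, 0)
})

test_that("two-class MCC equals the hand-computed covariance form", {
  cm <- matrix(c(8, 1, 2, 9), 2, 2)  # rows truth, cols predicted
  m <- classification_metrics(cm)
  # hand calculation: TP=8 FN=2 FP=1 TN=9
  hand <- (8 * 9 - 1 * 2) / sqrt((8 + 1) * (8 + 2) * (9 + 1) * (9 + 2))
  expect_equal(m$mcc, hand, tolerance = 1e-12)
  expect_equal(m$accuracy, 17 / 20)
})

test_that("uniform confusion has zero MCC and positive CEN", {
  cm <- matrix(5, 3, 3)
  m <- classification_metrics(cm)
  expect_equal(m$mcc, 0, tolerance = 1e-12)
  expect_gt(m$cen, 0)
})

test_that("MCC and CEN are invariant under consistent class relabeling", {
  set.seed(2)
  cm <- matrix(rpois(16, 5), 4, 4)
  perm <- sample(4)
  m1 <- classification_metrics(cm)
  m2 <- classification_metrics(cm[perm, perm])
  expect_equal(m1$mcc, m2$mcc, tolerance = 1e-12)
  expect_equal(m1$cen, m2$cen, tolerance = 1e-12)
  expect_gte(m1$cen, 0)
})

test_that("the MLP separates linearly separable classes", {
  set.seed(8)
  n <- 120
  x <- rbind(matrix(rnorm(n * 2, mean = 0), n, 2),
             matrix(rnorm(n * 2, mean = 4), n, 2))
  y <- rep(c("lo", "hi"), each = n)
  fit <- train_mlp(x, y, hidden_nodes = 8L, epochs = 50L, repeats = 3L,
                   seed = 21L)
  expect_true(all(fit$accuracy >= 0.95))
  # fixed seeds reproduce the accuracy vector
  fit2 <- train_mlp(x, y, hidden_nodes = 8L, epochs = 50L, repeats = 3L,
                    seed = 21L)
  expect_identical(fit$accuracy, fit2$accuracy)
})

test_that("confusion_matrix aligns truth rows with prediction columns", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_identical(as.integer(cm["a", "b"]), 1L)
  expect_identical(as.integer(sum(cm)), 3L)
})
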