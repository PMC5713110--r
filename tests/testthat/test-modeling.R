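test_that("Kennard-Stone starts from the farthest pair and covers the set", {
  X <- matrix(c(0, 1, 10), 3, 1)
  sp <- kennard_stone(X, n_cal = 2L)
  expect_equal(sort(sp$calibration), c(1L, 3L))
  expect_equal(sp$prediction, 2L)

  set.seed(2)
  X2 <- matrix(rnorm(20 * 3), 20, 3)
  all_cal <- kennard_stone(X2, n_cal = 20L)
  expect_length(all_cal$prediction, 0L)
  expect_setequal(all_cal$calibration, 1:20)

  sp2 <- kennard_stone(X2, n_cal = 13L)
  expect_length(intersect(sp2$calibration, sp2$prediction), 0L)
  expect_setequal(c(sp2$calibration, sp2$prediction), 1:20)
  expect_error(kennard_stone(X2, n_cal = 1L), "in 2..")
})

test_that("the 2:1 default split of 365 samples gives 243 calibration samples", {
  set.seed(5)
  X <- matrix(rnorm(365 * 4), 365, 4)
  sp <- kennard_stone(X)
  expect_length(sp$calibration, 243L)
  expect_length(sp$prediction, 122L)
})

test_that("Kennard-Stone matches the exhaustive enumeration oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(5:8, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    n_cal <- sample(3:(n - 1), 1)
    expect_equal(sort(kennard_stone(X, n_cal)$calibration),
                 sort(oracle_kennard_stone(X, n_cal)),
                 info = sprintf("seed %d", seed))
  }
})

test_that("min-max normalization uses calibration extrema and is idempotent", {
  x <- matrix(c(0, 5, 10), 3, 1)
  expect_equal(as.vector(minmax_normalize(x)), c(0, 0.5, 1))

  # prediction values outside the reference range may leave [0, 1]
  n2 <- minmax_normalize(matrix(c(0, 5, 10, 20), 4, 1), reference = 1:3)
  expect_equal(as.vector(n2), c(0, 0.5, 1, 2))

  set.seed(7)
  m <- matrix(rnorm(30), 10, 3)
  once <- minmax_normalize(m, reference = 1:6)
  twice <- minmax_normalize(once[1:6, , drop = FALSE])
  expect_equal(unname(twice[, ]), unname(once[1:6, ]), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_warning(cz <- minmax_normalize(cbind(m[, 1], 3)), "constant")
  expect_equal(unique(cz[, 2]), 0)
})

test_that("fusion concatenates the spectral block before the texture block", {
  s <- matrix(1, 4, 17, dimnames = list(NULL, paste0("wl", 1:17)))
  t <- matrix(2, 4, 16, dimnames = list(NULL, paste0("tex", 1:16)))
  f <- fuse(s, t)
  expect_equal(dim(f), c(4L, 33L))
  expect_equal(colnames(f), c(colnames(s), colnames(t)))
  expect_identical(fuse(s, matrix(numeric(0), 4, 0)), s)
  expect_error(fuse(s, t[1:3, ]), "same samples")
})

test_that("BPNN analytic gradients match central finite differences", {
  set.seed(44)
  X <- matrix(runif(5 * 3), 5, 3)
  y <- c(0L, 2L, 1L, 2L, 0L)
  T <- matrix(0, 5, 3); T[cbind(1:5, y + 1L)] <- 1
  w <- list(W1 = matrix(runif(3 * 4, -0.5, 0.5), 3, 4),
            b1 = runif(4, -0.5, 0.5),
            W2 = matrix(runif(4 * 3, -0.5, 0.5), 4, 3),
            b2 = runif(3, -0.5, 0.5))
  ga <- stemborer:::bpnn_gradients(w, X, T)
  gn <- oracle_fd_gradients(w, X, T)
  for (nm in names(ga)) {
    rel <- abs(ga[[nm]] - gn[[nm]]) / (abs(ga[[nm]]) + abs(gn[[nm]]) + 1e-8)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("BPNN learns XOR", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0L, 1L, 1L, 0L)
  cfg <- bpnn_config(hidden_nodes = 3L, learning_rate = 0.8,
                     max_epochs = 5000L, seed = 2L)
  m <- bpnn_train(X, y, cfg, n_classes = 2L)
  expect_lt(tail(m$training_curve, 1L), 0.05)
  expect_equal(bpnn_predict(m, X)$labels, y)
})

test_that("zero learning rate freezes the initial weights", {
  set.seed(1)
  X <- matrix(runif(12), 6, 2)
  y <- rep(0:1, 3)
  cfg0 <- bpnn_config(learning_rate = 0, max_epochs = 50L, seed = 9L,
                      restarts = 1L)
  m <- bpnn_train(X, y, cfg0, n_classes = 2L)
  init <- stemborer:::with_seed(9L, list(
    W1 = matrix(runif(2 * 5, -0.5, 0.5) / sqrt(2), 2, 5),
    b1 = runif(5, -0.5, 0.5),
    W2 = matrix(runif(5 * 2, -0.5, 0.5) / sqrt(5), 5, 2),
    b2 = runif(2, -0.5, 0.5)))
  expect_equal(m$W1, init$W1)
  expect_equal(m$W2, init$W2)
  expect_equal(m$b1, init$b1)
  expect_equal(m$b2, init$b2)
})

test_that("training error decreases monotonically at a small learning rate", {
  set.seed(3)
  X <- matrix(runif(30), 15, 2)
  y <- as.integer(X[, 1] + X[, 2] > 1)
  cfg <- bpnn_config(learning_rate = 0.01, max_epochs = 200L, seed = 4L)
  m <- bpnn_train(X, y, cfg, n_classes = 2L)
  expect_true(all(diff(m$training_curve) <= 1e-10))
})

test_that("prediction is orderly: permutation-equivariant, scores in (0,1)", {
  set.seed(6)
  X <- matrix(runif(40), 20, 2)
  y <- as.integer(X[, 1] > 0.5)
  m <- bpnn_train(X, y, bpnn_config(max_epochs = 300L, seed = 1L),
                  n_classes = 2L)
  p <- bpnn_predict(m, X)
  expect_true(all(p$scores > 0 & p$scores < 1))
  perm <- sample(20)
  expect_equal(bpnn_predict(m, X[perm, ])$labels, p$labels[perm])
  expect_error(bpnn_predict(m, X[, 1, drop = FALSE]), "expects")

  # a converged separable toy reproduces its training labels
  expect_equal(p$labels, y)
})

test_that("BPNN models survive a JSON round-trip", {
  set.seed(8)
  X <- matrix(runif(24), 12, 2)
  y <- rep(0:2, 4)
  m <- bpnn_train(X, y, bpnn_config(max_epochs = 50L, seed = 3L),
                  n_classes = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  bpnn_save(m, path)
  m2 <- bpnn_load(path)
  expect_equal(m2$W1, m$W1, tolerance = 1e-12)
  expect_equal(m2$b2, m$b2, tolerance = 1e-12)
  expect_equal(bpnn_predict(m2, X)$labels, bpnn_predict(m, X)$labels)
})
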