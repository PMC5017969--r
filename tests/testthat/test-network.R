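test_that("hidden_size implements the 2n+1 rule with its lower bound", {
  expect_identical(hidden_size(12), 25L)
  expect_identical(hidden_size(2), 5L)
  expect_identical(hidden_size(57), 115L)
  expect_error(hidden_size(1), "n_inputs >= 2")
})

test_that("initialization is reproducible with contracted shapes", {
  cfg <- network_config(12, n_outputs = 11, seed = 3)
  expect_equal(cfg$n_hidden, 25L)
  m1 <- init_network(cfg); m2 <- init_network(cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_equal(dim(m1$W1), c(25L, 12L))
  expect_equal(dim(m1$W2), c(11L, 25L))
  expect_length(m1$b1, 25); expect_length(m1$b2, 11)
  # zero-weight override gives zero outputs
  m1$W1[] <- 0; m1$b1[] <- 0; m1$W2[] <- 0; m1$b2[] <- 0
  y <- forward(m1, matrix(rnorm(36), 3, 12), raw = TRUE)
  expect_true(all(y == 0))
})

test_that("forward matches hand arithmetic on a 2-2-1 network", {
  cfg <- network_config(2, n_outputs = 2, n_hidden = 2, seed = 1)
  m <- init_network(cfg)
  m$W1 <- matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2)
  m$b1 <- c(0.1, -0.2)
  m$W2 <- matrix(c(1.0, -0.5, 0.4, 0.7), 2, 2)
  m$b2 <- c(0.05, -0.1)
  x <- c(0.3, -0.6)
  h <- tanh(m$W1 %*% x + m$b1)
  want <- tanh(m$W2 %*% h + m$b2)
  got <- forward(m, x, raw = TRUE)
  expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  expect_true(all(abs(got) < 1))
  expect_error(forward(m, c(1, 2, 3)), "dimension")
})

test_that("analytic gradient matches central finite differences", {
  cfg <- network_config(4, n_outputs = 3, n_hidden = 5, seed = 7)
  m <- init_network(cfg)
  withr::with_seed(8, {
    X <- matrix(rnorm(10 * 4), 10, 4)
    y <- sample(1:3, 10, replace = TRUE)
  })
  T01 <- matrix(0, 10, 3); T01[cbind(1:10, y)] <- 1
  w <- semgvowel:::.pack(m)
  lg <- semgvowel:::.loss_grad(w, cfg, X, T01)
  h <- 1e-6
  num <- vapply(seq_along(w), function(i) {
    wp <- w; wp[i] <- wp[i] + h
    wm <- w; wm[i] <- wm[i] - h
    (semgvowel:::.loss_grad(wp, cfg, X, T01, want_grad = FALSE)$loss -
       semgvowel:::.loss_grad(wm, cfg, X, T01, want_grad = FALSE)$loss) /
      (2 * h)
  }, numeric(1))
  rel <- sqrt(sum((lg$grad - num)^2)) / sqrt(sum(num^2))
  expect_lt(rel, 1e-6)
})

test_that("split_data covers all indices with the contracted sizes", {
  y <- rep(1:4, each = 25)
  # literal unstratified split: exact 70/15/15 at n = 100
  spu <- split_data(y, c(0.7, 0.15, 0.15), seed = 2, stratify = FALSE)
  expect_length(spu$train, 70)
  expect_length(spu$validation, 15)
  expect_length(spu$test, 15)
  # stratified default: sizes within one per class of the fractions
  sp <- split_data(y, c(0.7, 0.15, 0.15), seed = 2)
  expect_lte(abs(length(sp$train) - 70), 4)
  expect_setequal(c(sp$train, sp$validation, sp$test), 1:100)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_identical(sp, split_data(y, c(0.7, 0.15, 0.15), seed = 2))
  # stratification: every class appears in every part
  for (part in sp) expect_setequal(unique(y[part]), 1:4)
  expect_error(split_data(y, c(0.7, 0.2, 0.2), seed = 1), "sum to 1")
})

test_that("SCG solves XOR on a 2-5-2 net in most seeds", {
  withr::with_seed(1, {
    X0 <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
    X <- X0[rep(1:4, 10), ] + matrix(rnorm(80, sd = 0.02), 40, 2)
    y <- rep(c(1, 2, 2, 1), 10)
  })
  solved <- vapply(1:20, function(s) {
    cfg <- network_config(2, n_outputs = 2, n_hidden = 5, seed = s)
    tc <- train_config(split = c(1, 0, 0), max_epochs = 500, seed = s)
    m <- train_scg(init_network(cfg), X, y, tc)
    mean(predict_network(m, X)$labels == y) == 1
  }, logical(1))
  expect_gte(sum(solved), 18)
})

test_that("well-separated Gaussian blobs are learned to >= 95 %", {
  blobs <- gaussian_blobs(120, d = 12, sep = 6, seed = 4)
  cfg <- network_config(12, n_outputs = 2, seed = 5)
  tc <- train_config(seed = 5)
  m <- train_scg(init_network(cfg), blobs$X, blobs$y, tc)
  te <- m$split_idx$test
  acc <- mean(predict_network(m, blobs$X[te, ])$labels == blobs$y[te])
  expect_gte(acc, 0.95)
  # descent sanity + early-stopping invariant
  expect_lte(m$history$train[m$stopped_epoch], m$history$train[1])
  later <- m$history$validation[m$history$epoch >= m$stopped_epoch]
  expect_true(all(m$history$validation[m$stopped_epoch] <= later + 1e-12))
})

test_that("training on shuffled labels stays at chance", {
  withr::with_seed(9, {
    X <- matrix(rnorm(120 * 6), 120, 6)
    y <- rep(1:3, each = 40)
  })
  accs <- vapply(1:20, function(s) {
    ysh <- withr::with_seed(300 + s, sample(y))
    cfg <- network_config(6, n_outputs = 3, seed = s)
    tc <- train_config(max_epochs = 150, seed = s)
    m <- train_scg(init_network(cfg), X, ysh, tc)
    te <- m$split_idx$test
    mean(predict_network(m, X[te, ])$labels == ysh[te])
  }, numeric(1))
  # binomial sd of chance accuracy at n_test = 18
  p0 <- 1 / 3
  sd0 <- sqrt(p0 * (1 - p0) / 18)
  expect_lt(abs(mean(accs) - p0), 3 * sd0)
})

test_that("predict applies argmax with low-index tie-break", {
  cfg <- network_config(2, n_outputs = 3, n_hidden = 2, seed = 1)
  m <- init_network(cfg)
  expect_error(predict_network(m, matrix(0, 1, 2)), "not been trained")
  m$trained <- TRUE
  m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2[] <- 0  # all-zero scores: tie
  pr <- predict_network(m, matrix(rnorm(6), 3, 2))
  expect_true(all(pr$labels == 1))
  expect_equal(pr$labels, apply(pr$scores, 1, which.max))
})

test_that("model artifacts round-trip through JSON", {
  blobs <- gaussian_blobs(30, d = 3, sep = 8, seed = 6)
  cfg <- network_config(3, n_outputs = 2, seed = 2)
  m <- train_scg(init_network(cfg), blobs$X, blobs$y,
                 train_config(max_epochs = 50, seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$W1, m$W1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(forward(m2, blobs$X[1:5, ]), forward(m, blobs$X[1:5, ]),
               tolerance = 1e-12)
})
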