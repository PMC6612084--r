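test_that("hidden-unit rules give the 3/5/10 presets for a 4-1 network", {
  expect_equal(hidden_units_rule(rule = "average"), 3L)
  expect_equal(hidden_units_rule(rule = "summation"), 5L)
  expect_equal(hidden_units_rule(rule = "doubling"), 10L)
})

test_that("encoding min-max scales numeric factors and targets follow the mode", {
  runs <- conditions_to_runs(load_fixture("table4"))
  enc <- encode_records(runs)
  expect_true(all(enc$x >= 0 & enc$x <= 1))
  # the selected combination A=500 (level 1), B=300 (3), C=2.5 (2),
  # D=autologous (2) is not an L9 row, so encode it as a standalone record
  best <- data.frame(condition = 1L, A = 1L, B = 3L, C = 2L, D = 2L,
                     outcome = "good", stringsAsFactors = FALSE)
  encb0 <- encode_records(best, target = "binary")
  expect_equal(unname(encb0$x[1, ]), c(0, 1, 0.5, 2 / 3))
  # proportion targets equal the condition's empirical defect rate
  expect_equal(unique(enc$y[runs$condition == 1]), 7 / 30)
  expect_equal(unique(enc$y[runs$condition == 5]), 16 / 30)
  # binary targets flag the defective runs
  encb <- encode_records(runs, target = "binary")
  expect_equal(encb$y, as.numeric(runs$outcome == "defective"))
  # one-hot vascular access widens the input to 6 columns of 0/1
  enc1 <- encode_records(runs, access = "onehot")
  expect_equal(enc1$n_inputs, 6L)
  expect_true(all(rowSums(enc1$x[, 4:6]) == 1))
  bad <- runs; bad$D[1] <- 7L
  expect_error(encode_records(bad), "unknown factor level")
})

test_that("splitting allocates 216/27/27, stratifies, and is seed-deterministic", {
  runs <- conditions_to_runs(load_fixture("table4"))
  enc <- encode_records(runs)
  s <- split_data(enc, seed = 11)
  expect_equal(length(s$train$y), 216L)
  expect_equal(length(s$validation$y), 27L)
  expect_equal(length(s$test$y), 27L)
  # every condition appears in training
  expect_setequal(unique(s$train$condition), 1:9)
  # within a condition every encoded pattern is identical, so seed effects
  # are only visible on run-distinguishing (binary) targets
  encb <- encode_records(runs, target = "binary")
  b1 <- split_data(encb, seed = 11)
  b2 <- split_data(encb, seed = 11)
  expect_identical(b1$train$y, b2$train$y)
  b3 <- split_data(encb, seed = 12)
  expect_false(identical(b1$train$y, b3$train$y))
  # floor allocation with remainder to train on a 10-record toy set
  toy <- bpn_data(matrix(runif(40), 10, 4), runif(10))
  st <- split_data(toy, seed = 1)
  expect_equal(lengths(lapply(st, `[[`, "y")),
               c(train = 8L, validation = 1L, test = 1L))
  expect_error(split_data(bpn_data(matrix(1, 5, 4), rep(0.5, 5))), "at least 10")
})

test_that("analytic gradients match an independent central-difference oracle", {
  set.seed(202)
  for (rep in 1:5) {
    cfg <- bpn_config(n_inputs = 4L, hidden_units = 5L, seed = sample.int(1e6, 1))
    net <- taguchiomega:::bpn_init(cfg)
    x <- runif(4); y <- runif(1)
    # independent finite-difference oracle, written against the loss only
    eps <- 1e-5
    fd <- function(nm, k) {
      np <- net; np[[nm]][k] <- np[[nm]][k] + eps
      nn <- net; nn[[nm]][k] <- nn[[nm]][k] - eps
      loss <- function(w) {
        h <- 1 / (1 + exp(-(drop(w$W1 %*% x) + w$b1)))
        o <- 1 / (1 + exp(-(drop(w$W2 %*% h) + w$b2)))
        0.5 * (o - y)^2
      }
      (loss(np) - loss(nn)) / (2 * eps)
    }
    ana <- taguchiomega:::bpn_gradient(net, x, y)
    for (nm in c("W1", "b1", "W2", "b2")) {
      for (k in seq_along(net[[nm]])) {
        expect_lt(abs(ana[[nm]][k] - fd(nm, k)) /
                    max(abs(ana[[nm]][k]), abs(fd(nm, k)), 1e-8), 1e-6)
      }
    }
    expect_lt(gradient_check(net, x, y), 1e-6)
    # mutation check: a sign-flipped gradient is far from the oracle
    flipped <- -ana$W2[1, 1]
    expect_gt(abs(flipped - fd("W2", 1)) / max(abs(flipped), 1e-8), 1)
  }
})

test_that("gradient check is well-defined at zero weights and zero input", {
  cfg <- bpn_config(seed = 1)
  net <- taguchiomega:::bpn_init(cfg)
  net$W1[] <- 0; net$b1[] <- 0; net$W2[] <- 0; net$b2 <- 0
  dev <- gradient_check(net, rep(0, 4), 0)
  expect_true(is.finite(dev))
})

test_that("training learns XOR with a 2-2-1 network", {
  x <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  d <- bpn_data(x, c(0, 1, 1, 0))
  cfg <- bpn_config(n_inputs = 2L, hidden_units = 2L, learning_rate = 0.5,
                    momentum = 0.1, epochs = 5000L, seed = 1L)
  fit <- bpn_train(cfg, d)
  expect_lt(attr(fit$report, "final_mse"), 0.01)
  pred <- bpn_predict(fit$network, x)
  expect_equal(round(pred), c(0, 1, 1, 0))
})

test_that("training is reproducible and the report has one row per epoch", {
  runs <- conditions_to_runs(load_fixture("table4"))
  enc <- encode_records(runs)
  s <- split_data(enc, seed = 5)
  cfg <- bpn_config(epochs = 20L, seed = 5L)
  f1 <- bpn_train(cfg, s$train, s$validation, s$test)
  f2 <- bpn_train(cfg, s$train, s$validation, s$test)
  expect_identical(f1$network$W1, f2$network$W1)
  expect_identical(f1$report$train_mse, f2$report$train_mse)
  expect_equal(nrow(f1$report), 20L)
  cfg1 <- bpn_config(epochs = 1L, seed = 5L)
  expect_equal(nrow(bpn_train(cfg1, s$train)$report), 1L)
})

test_that("one tiny-rate zero-momentum step approaches the summed gradient direction", {
  set.seed(9)
  d <- bpn_data(matrix(runif(20), 5, 4), runif(5))
  eta <- 1e-6
  cfg <- bpn_config(learning_rate = eta, momentum = 0, epochs = 1L, seed = 3L)
  fit <- bpn_train(cfg, d)
  net0 <- taguchiomega:::bpn_init(cfg)  # same seed: identical init
  g <- lapply(seq_len(5), function(i)
    taguchiomega:::bpn_gradient(net0, d$x[i, ], d$y[i]))
  summed_W1 <- Reduce(`+`, lapply(g, `[[`, "W1"))
  delta <- (net0$W1 - fit$network$W1) / eta
  expect_equal(delta, summed_W1, tolerance = 1e-3)
})

test_that("achievable MSE improves with hidden capacity on proportion targets", {
  runs <- conditions_to_runs(load_fixture("table4"))
  enc <- encode_records(runs)
  mean_final <- function(h) {
    mean(vapply(1:3, function(s) {
      cfg <- bpn_config(hidden_units = h, epochs = 150L, seed = s)
      attr(bpn_train(cfg, enc)$report, "final_mse")
    }, numeric(1)))
  }
  expect_lt(mean_final(5L), mean_final(1L))
})
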