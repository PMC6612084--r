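#' Hidden-unit count rules
#'
#' Rule-of-thumb hidden layer sizes for a single-hidden-layer network:
#' `"average"` = (inputs + outputs)/2 (simple problems), `"summation"` =
#' inputs + outputs (general problems; the default here, 4 + 1 = 5), and
#' `"doubling"` = 2 * (inputs + outputs) (difficult problems).
#'
#' @param n_inputs,n_outputs Layer sizes.
#' @param rule One of `"summation"`, `"average"`, `"doubling"`.
#' @return Integer hidden-unit count (rounded up for `"average"`).
#' @export
hidden_units_rule <- function(n_inputs = 4L, n_outputs = 1L,
                              rule = c("summation", "average", "doubling")) {
  rule <- match.arg(rule)
  s <- n_inputs + n_outputs
  as.integer(switch(rule, summation = s, average = ceiling(s / 2),
                    doubling = 2L * s))
}

#' Back-propagation network configuration
#'
#' Training hyper-parameters for the single-hidden-layer feed-forward
#' network: logistic-sigmoid units throughout, pattern-by-pattern (online)
#' delta-rule updates with a momentum ("inertia") term, weights initialised
#' uniformly in \[-0.5, 0.5\].  Defaults follow the reference experiment:
#' learning rate 0.1, momentum 0.1, 500 learning cycles, one hidden layer
#' with 5 units from the summation rule, 80/10/10 train/validation/test
#' split.
#'
#' @param n_inputs Number of input units (4 for the ordinal encoding; 6
#'   one-hot).
#' @param hidden_units Hidden layer size.
#' @param learning_rate Step size eta > 0.
#' @param momentum Momentum coefficient alpha in \[0, 1).
#' @param epochs Learning cycles (full passes over the training set).
#' @param seed Integer seed for weight initialisation and epoch shuffling.
#' @param split Named fractions for train/validation/test; must sum to 1.
#' @param early_stopping Stop at the convergence epoch instead of training
#'   the full cycle count.  Off by default: the reference procedure always
#'   runs all 500 cycles and reads convergence off the error curve.
#' @return A `bpn_config` list.
#' @export
bpn_config <- function(n_inputs = 4L, hidden_units = hidden_units_rule(),
                       learning_rate = 0.1, momentum = 0.1, epochs = 500L,
                       seed = 1L,
                       split = c(train = 0.8, validation = 0.1, test = 0.1),
                       early_stopping = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  structure(
    list(n_inputs = as.integer(n_inputs), hidden_units = as.integer(hidden_units),
         n_outputs = 1L, learning_rate = learning_rate, momentum = momentum,
         epochs = epochs, seed = as.integer(seed), split = split,
         early_stopping = early_stopping),
    class = "bpn_config"
  )
}

#' Encode per-run records as network training patterns
#'
#' Numeric factors (anticoagulation, blood flow, dehydration) are min-max
#' scaled to \[0, 1\] using their level ranges; the categorical vascular
#' access is encoded ordinally as level/3 by default, or one-hot (three
#' 0/1 columns, changing the input count to 6).  The target is either the
#' run's binary outcome (defective = 1) or, by default, the run's
#' condition-level empirical defect rate — the proportion encoding under
#' which the network regresses the per-condition rate and very small mean
#' squared errors are attainable.
#'
#' @param runs Per-run data frame (`condition`, `A`-`D`, `outcome`).
#' @param plan An `experiment_plan` supplying the factor level values.
#' @param target `"proportion"` (default) or `"binary"`.
#' @param access Encoding of the vascular-access factor: `"ordinal"` or
#'   `"onehot"`.
#' @return A `bpn_data` list: `x` (pattern matrix, rows in run order),
#'   `y` (target vector), `condition` (integer vector), `target`, `access`,
#'   `n_inputs`.
#' @export
encode_records <- function(runs, plan = make_plan(dialyzer_factors(), 30L),
                           target = c("proportion", "binary"),
                           access = c("ordinal", "onehot")) {
  target <- match.arg(target)
  access <- match.arg(access)
  need <- c("condition", "A", "B", "C", "D", "outcome")
  miss <- setdiff(need, names(runs))
  if (length(miss))
    stop("per-run records lack columns: ", paste(miss, collapse = ", "))
  lev <- as.matrix(runs[, c("A", "B", "C", "D")])
  if (!all(lev %in% 1:3)) stop("unknown factor level; levels must be 1..3")

  scale_numeric <- function(f, l) {
    v <- as.numeric(plan$factors[[f]]$values)
    (v[l] - min(v)) / (max(v) - min(v))
  }
  x_num <- cbind(A = scale_numeric("A", lev[, "A"]),
                 B = scale_numeric("B", lev[, "B"]),
                 C = scale_numeric("C", lev[, "C"]))
  if (access == "ordinal") {
    x <- cbind(x_num, D = lev[, "D"] / 3)
  } else {
    d <- matrix(0, nrow(lev), 3,
                dimnames = list(NULL, paste0("D", 1:3)))
    d[cbind(seq_len(nrow(lev)), lev[, "D"])] <- 1
    x <- cbind(x_num, d)
  }

  if (target == "binary") {
    y <- as.numeric(runs$outcome == "defective")
  } else {
    counts <- runs_to_conditions(runs)
    rate <- counts$defective / counts$sample
    y <- rate[match(runs$condition, counts$condition)]
  }
  structure(list(x = x, y = y, condition = as.integer(runs$condition),
                 target = target, access = access, n_inputs = ncol(x)),
            class = "bpn_data")
}

#' Split encoded records into train/validation/test sets
#'
#' Global set sizes use floor allocation with the remainder going to
#' training (270 records at 80/10/10 give 216/27/27).  Assignment is a
#' seeded shuffle stratified by condition: each condition contributes to
#' validation and test in proportion to its size (largest-remainder
#' apportionment), and at least one record per condition is kept in
#' training whenever the condition has any.
#'
#' @param data A `bpn_data` from [encode_records()].
#' @param split Named train/validation/test fractions summing to 1.
#' @param seed Integer seed for the stratified shuffle.
#' @return List of three `bpn_data` objects: `train`, `validation`, `test`
#'   (the latter two may have zero rows).
#' @export
split_data <- function(data, split = c(train = 0.8, validation = 0.1, test = 0.1),
                       seed = 1L) {
  stopifnot(inherits(data, "bpn_data"))
  n <- length(data$y)
  if (n < 10L) stop("need at least 10 records to split, got ", n)
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  n_val <- floor(n * split[["validation"]])
  n_test <- floor(n * split[["test"]])

  conds <- sort(unique(data$condition))
  n_c <- vapply(conds, function(cc) sum(data$condition == cc), integer(1))

  # largest-remainder apportionment of a set of size N across conditions,
  # bounded by per-condition remaining capacity
  apportion <- function(N, capacity) {
    quota <- n_c * N / n
    take <- pmin(floor(quota), capacity)
    rem <- N - sum(take)
    frac <- quota - floor(quota)
    ord <- order(-frac, seq_along(conds))
    for (i in ord) {
      if (rem == 0L) break
      if (take[i] < capacity[i]) { take[i] <- take[i] + 1L; rem <- rem - 1L }
    }
    if (rem > 0L) stop("cannot apportion split across conditions")
    take
  }
  cap <- pmax(n_c - 1L, 0L)  # keep >= 1 per condition for training
  val_c <- apportion(n_val, cap)
  test_c <- apportion(n_test, cap - val_c)

  set.seed(seed)
  assign <- integer(n)  # 1 = train, 2 = validation, 3 = test
  assign[] <- 1L
  for (i in seq_along(conds)) {
    idx <- which(data$condition == conds[i])
    idx <- sample(idx)
    if (val_c[i] > 0L) assign[idx[seq_len(val_c[i])]] <- 2L
    if (test_c[i] > 0L) assign[idx[val_c[i] + seq_len(test_c[i])]] <- 3L
  }
  subset_data <- function(keep) {
    structure(list(x = data$x[keep, , drop = FALSE], y = data$y[keep],
                   condition = data$condition[keep], target = data$target,
                   access = data$access, n_inputs = data$n_inputs),
              class = "bpn_data")
  }
  list(train = subset_data(assign == 1L),
       validation = subset_data(assign == 2L),
       test = subset_data(assign == 3L))
}

#' Construct a training set from raw matrices
#'
#' Low-level constructor used when patterns do not come from
#' [encode_records()] (e.g. toy problems such as XOR).
#'
#' @param x Pattern matrix (records x inputs).
#' @param y Target vector, one value per record.
#' @param condition Optional integer grouping used by [split_data()].
#' @return A `bpn_data` object.
#' @export
bpn_data <- function(x, y, condition = rep(1L, length(y))) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x and y disagree on record count")
  structure(list(x = x, y = as.numeric(y), condition = as.integer(condition),
                 target = "custom", access = "custom", n_inputs = ncol(x)),
            class = "bpn_data")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bpn_init <- function(config) {
  set.seed(config$seed)
  h <- config$hidden_units; p <- config$n_inputs
  net <- list(
    W1 = matrix(runif(h * p, -0.5, 0.5), h, p),
    b1 = runif(h, -0.5, 0.5),
    W2 = matrix(runif(h, -0.5, 0.5), 1, h),
    b2 = runif(1, -0.5, 0.5),
    config = config
  )
  class(net) <- "bpn"
  net
}

#' Forward pass of a trained network
#'
#' @param net A `bpn` network.
#' @param x Pattern matrix (rows = records) or a single pattern vector.
#' @return Vector of outputs in (0, 1).
#' @export
bpn_predict <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  h <- sigmoid(x %*% t(net$W1) + rep(net$b1, each = nrow(x)))
  drop(sigmoid(h %*% t(net$W2) + net$b2))
}

bpn_mse <- function(net, data) {
  if (length(data$y) == 0L) return(NA_real_)
  mean((bpn_predict(net, data$x) - data$y)^2)
}

# analytic gradient of the per-pattern loss E = 0.5 * (o - y)^2
bpn_gradient <- function(net, x, y) {
  h <- sigmoid(drop(net$W1 %*% x) + net$b1)
  o <- sigmoid(drop(net$W2 %*% h) + net$b2)
  delta_o <- (o - y) * o * (1 - o)
  delta_h <- drop(t(net$W2) * delta_o) * h * (1 - h)
  list(W1 = outer(delta_h, x), b1 = delta_h,
       W2 = matrix(delta_o * h, 1), b2 = delta_o)
}

bpn_loss <- function(net, x, y) 0.5 * (bpn_predict(net, x) - y)^2

#' Train the back-propagation network
#'
#' Online (pattern-by-pattern) delta-rule training with momentum:
#' `dw(t) = -eta * dE/dw + alpha * dw(t-1)`, patterns reshuffled each epoch
#' from the configured seed.  The mean squared error (1/Q) * sum (T_q -
#' A_q)^2 between network estimates and actual values is recorded per epoch
#' on the training, validation and test sets; the convergence epoch is the
#' first epoch from which the validation MSE stays within an absolute
#' tolerance of its running minimum for `patience` consecutive epochs
#' (training MSE is used when no validation set is supplied).
#'
#' @param config A `bpn_config`.
#' @param train,validation,test `bpn_data` sets; validation and test may be
#'   empty (their MSE columns are then `NA`).
#' @param tol,patience Convergence tolerance (absolute, on the monitored
#'   MSE) and the number of consecutive epochs it must hold.
#' @return A `bpn_fit` list: `network` (trained `bpn`), `report` (a
#'   `convergence_report` data frame with columns `epoch`, `train_mse`,
#'   `val_mse`, `test_mse` and attributes `final_mse`, `convergence_epoch`,
#'   `converged`).
#' @export
bpn_train <- function(config, train, validation = NULL, test = NULL,
                      tol = 1e-4, patience = 10L) {
  stopifnot(inherits(config, "bpn_config"), inherits(train, "bpn_data"))
  if (length(train$y) == 0L) stop("training set is empty")
  if (ncol(train$x) != config$n_inputs)
    stop("config expects ", config$n_inputs, " inputs, data has ",
         ncol(train$x))
  empty <- structure(list(x = matrix(0, 0, config$n_inputs), y = numeric(0)),
                     class = "bpn_data")
  if (is.null(validation)) validation <- empty
  if (is.null(test)) test <- empty

  net <- bpn_init(config)  # also seeds the shuffling stream
  eta <- config$learning_rate; alpha <- config$momentum
  prev <- list(W1 = net$W1 * 0, b1 = net$b1 * 0, W2 = net$W2 * 0, b2 = 0)
  n_tr <- length(train$y)
  mse <- matrix(NA_real_, config$epochs, 3,
                dimnames = list(NULL, c("train_mse", "val_mse", "test_mse")))
  monitored <- rep(NA_real_, config$epochs)
  run_min <- Inf
  streak <- 0L
  convergence_epoch <- NA_integer_
  last_epoch <- config$epochs

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    for (i in ord) {
      x <- train$x[i, ]; y <- train$y[i]
      h <- sigmoid(drop(net$W1 %*% x) + net$b1)
      o <- sigmoid(drop(net$W2 %*% h) + net$b2)
      delta_o <- (o - y) * o * (1 - o)
      delta_h <- drop(t(net$W2) * delta_o) * h * (1 - h)
      dW2 <- -eta * matrix(delta_o * h, 1) + alpha * prev$W2
      db2 <- -eta * delta_o + alpha * prev$b2
      dW1 <- -eta * outer(delta_h, x) + alpha * prev$W1
      db1 <- -eta * delta_h + alpha * prev$b1
      net$W2 <- net$W2 + dW2; net$b2 <- net$b2 + db2
      net$W1 <- net$W1 + dW1; net$b1 <- net$b1 + db1
      prev <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    }
    mse[epoch, 1] <- bpn_mse(net, train)
    mse[epoch, 2] <- bpn_mse(net, validation)
    mse[epoch, 3] <- bpn_mse(net, test)
    if (!is.finite(mse[epoch, 1]))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    monitored[epoch] <- if (length(validation$y)) mse[epoch, 2] else mse[epoch, 1]
    # converged once the monitored MSE neither improves on nor departs from
    # its running minimum by more than tol, for `patience` epochs in a row
    if (abs(monitored[epoch] - run_min) <= tol) streak <- streak + 1L
    else streak <- 0L
    if (monitored[epoch] < run_min) run_min <- monitored[epoch]
    if (is.na(convergence_epoch) && streak >= patience)
      convergence_epoch <- epoch - patience + 1L
    if (config$early_stopping && !is.na(convergence_epoch)) {
      last_epoch <- epoch
      break
    }
  }
  report <- data.frame(epoch = seq_len(last_epoch),
                       mse[seq_len(last_epoch), , drop = FALSE])
  attr(report, "final_mse") <- report$train_mse[last_epoch]
  attr(report, "convergence_epoch") <- convergence_epoch
  attr(report, "converged") <- !is.na(convergence_epoch)
  class(report) <- c("convergence_report", class(report))
  structure(list(network = net, report = report), class = "bpn_fit")
}

#' @export
print.bpn_fit <- function(x, ...) {
  r <- x$report
  n <- nrow(r)
  cat(sprintf("BPN %d-%d-1, %d epochs; final training MSE %.3g\n",
              x$network$config$n_inputs, x$network$config$hidden_units, n,
              attr(r, "final_mse")))
  if (attr(r, "converged"))
    cat(sprintf("Converged at epoch %d (monitored MSE stable thereafter)\n",
                attr(r, "convergence_epoch")))
  else cat("Did not meet the convergence criterion\n")
  invisible(x)
}

#' Compare analytic and finite-difference gradients
#'
#' Central-difference check of the back-propagation gradient on a single
#' pattern: for every weight and bias the analytic derivative of the
#' per-pattern loss is compared with (E(w + eps) - E(w - eps)) / (2 eps).
#' This is the correctness oracle for the training implementation.
#'
#' @param net A `bpn` network (e.g. from `bpn_train()$network`).
#' @param x Input pattern vector.
#' @param y Target value.
#' @param epsilon Finite-difference step.
#' @return Maximum relative deviation over all parameters (denominator
#'   floored at 1e-8 to keep zero gradients well-defined).
#' @export
gradient_check <- function(net, x, y, epsilon = 1e-5) {
  stopifnot(inherits(net, "bpn"), epsilon > 0)
  ana <- bpn_gradient(net, x, y)
  max_dev <- 0
  for (nm in c("W1", "b1", "W2", "b2")) {
    par <- net[[nm]]
    for (k in seq_along(par)) {
      np <- net; np[[nm]][k] <- par[k] + epsilon
      nm_ <- net; nm_[[nm]][k] <- par[k] - epsilon
      num <- (bpn_loss(np, x, y) - bpn_loss(nm_, x, y)) / (2 * epsilon)
      denom <- max(abs(ana[[nm]][k]), abs(num), 1e-8)
      max_dev <- max(max_dev, abs(ana[[nm]][k] - num) / denom)
    }
  }
  max_dev
}

#' Serialize a trained network to JSON
#'
#' @param net A `bpn` network.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written).
#' @export
bpn_to_json <- function(net, path = NULL) {
  stopifnot(inherits(net, "bpn"))
  obj <- list(W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
              config = unclass(net$config))
  out <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
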