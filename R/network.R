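# One-hidden-layer tanh network sized by the 2*n_i + 1 rule, trained by
# scaled conjugate gradient (Moller 1993) on a cross-entropy loss, with
# early stopping on a held-out validation split.

#' Hidden-layer size by the Kolmogorov-mapping rule
#'
#' For `n_inputs >= 2` the hidden layer gets `2 * n_inputs + 1` neurons.
#' @param n_inputs number of input features.
#' @return integer hidden-layer size.
#' @export
hidden_size <- function(n_inputs) {
  n_inputs <- as.integer(n_inputs)
  if (is.na(n_inputs) || n_inputs < 2L)
    stop("the sizing rule requires n_inputs >= 2")
  2L * n_inputs + 1L
}

#' Network configuration
#'
#' @param n_inputs input dimension.
#' @param n_outputs output dimension (one per class).
#' @param n_hidden hidden size; defaults to the 2n+1 rule.
#' @param seed initialization seed.
#' @return A `network_config` list.
#' @export
network_config <- function(n_inputs, n_outputs = N_VOWEL_CLASSES,
                           n_hidden = hidden_size(n_inputs), seed = 1) {
  stopifnot(n_inputs >= 2, n_outputs >= 2, n_hidden >= 1)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden),
                 n_outputs = as.integer(n_outputs),
                 hidden_activation = "tanh", output_activation = "tanh",
                 seed = seed),
            class = "network_config")
}

#' Training configuration
#'
#' @param split train/validation/test fractions (must sum to 1).
#' @param max_epochs SCG iteration cap.
#' @param patience consecutive validation-loss increases tolerated before
#'   stopping.
#' @param sigma,lambda_init SCG constants (Moller's published defaults).
#' @param seed split + initialization seed.
#' @return A `train_config` list.
#' @export
train_config <- function(split = c(0.70, 0.15, 0.15), max_epochs = 1000,
                         patience = 6, sigma = 5e-5, lambda_init = 5e-7,
                         seed = 1) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  stopifnot(length(split) == 3, patience >= 1, max_epochs >= 1)
  structure(list(split = split, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), sigma = sigma,
                 lambda_init = lambda_init, seed = seed),
            class = "train_config")
}

#' Initialize a network with Nguyen-Widrow-style scaled uniform weights
#'
#' @param cfg a [network_config()].
#' @return A `network_model` (untrained) with weight matrices `W1`
#'   (hidden x inputs), `b1`, `W2` (outputs x hidden), `b2`.
#' @export
init_network <- function(cfg) {
  withr_seed(cfg$seed, {
    beta <- 0.7 * cfg$n_hidden^(1 / cfg$n_inputs)
    W1 <- matrix(stats::runif(cfg$n_hidden * cfg$n_inputs, -0.5, 0.5),
                 cfg$n_hidden, cfg$n_inputs)
    nrm <- sqrt(rowSums(W1^2))
    W1 <- W1 * beta / pmax(nrm, 1e-12)
    b1 <- stats::runif(cfg$n_hidden, -beta, beta)
    W2 <- matrix(stats::runif(cfg$n_outputs * cfg$n_hidden, -0.5, 0.5),
                 cfg$n_outputs, cfg$n_hidden)
    b2 <- stats::runif(cfg$n_outputs, -0.5, 0.5)
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, config = cfg,
                   trained = FALSE, history = NULL, stopped_epoch = NA,
                   center = rep(0, cfg$n_inputs),
                   scale = rep(1, cfg$n_inputs)),
              class = "network_model")
  })
}

#' Forward pass
#'
#' `y = tanh(W2 tanh(W1 x + b1) + b2)`; outputs lie strictly in (-1, 1).
#' Inputs are standardized with the model's stored center/scale.
#'
#' @param model a `network_model`.
#' @param x numeric vector or matrix (samples x n_inputs).
#' @param raw skip the stored standardization (used internally).
#' @return matrix of output scores (samples x n_outputs).
#' @export
forward <- function(model, x, raw = FALSE) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != model$config$n_inputs)
    stop("input dimension ", ncol(X), " != n_inputs ",
         model$config$n_inputs)
  if (!raw) X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  H <- tanh(X %*% t(model$W1) + matrix(model$b1, nrow(X),
                                       length(model$b1), byrow = TRUE))
  tanh(H %*% t(model$W2) + matrix(model$b2, nrow(X),
                                  length(model$b2), byrow = TRUE))
}

# ---- loss and gradient (vectorized weights) ----------------------------

.pack <- function(m) c(m$W1, m$b1, m$W2, m$b2)

.unpack <- function(w, cfg) {
  ni <- cfg$n_inputs; nh <- cfg$n_hidden; no <- cfg$n_outputs
  i1 <- nh * ni
  list(W1 = matrix(w[1:i1], nh, ni),
       b1 = w[(i1 + 1):(i1 + nh)],
       W2 = matrix(w[(i1 + nh + 1):(i1 + nh + no * nh)], no, nh),
       b2 = w[(i1 + nh + no * nh + 1):(i1 + nh + no * nh + no)])
}

# cross-entropy of tanh outputs mapped to (0,1) against 0/1 targets,
# averaged over samples and outputs; returns loss and gradient
.loss_grad <- function(w, cfg, X, T01, want_grad = TRUE) {
  m <- .unpack(w, cfg)
  n <- nrow(X)
  Z1 <- X %*% t(m$W1) + matrix(m$b1, n, cfg$n_hidden, byrow = TRUE)
  H <- tanh(Z1)
  Z2 <- H %*% t(m$W2) + matrix(m$b2, n, cfg$n_outputs, byrow = TRUE)
  Y <- tanh(Z2)
  P <- (Y + 1) / 2
  eps <- 1e-12
  Pc <- pmin(pmax(P, eps), 1 - eps)
  loss <- -mean(T01 * log(Pc) + (1 - T01) * log(1 - Pc))
  if (!want_grad) return(list(loss = loss))
  # dL/dZ2 = (P - T) * (1 - Y^2) / (2 P (1-P)) / (n * no)
  dZ2 <- (Pc - T01) * (1 - Y^2) / (2 * Pc * (1 - Pc)) /
    (n * cfg$n_outputs)
  gW2 <- t(dZ2) %*% H
  gb2 <- colSums(dZ2)
  dH <- dZ2 %*% m$W2
  dZ1 <- dH * (1 - H^2)
  gW1 <- t(dZ1) %*% X
  gb1 <- colSums(dZ1)
  list(loss = loss, grad = c(gW1, gb1, gW2, gb2))
}

#' Stratified random train/validation/test split
#'
#' Sizes rounded to the fractions per class; every index lands in exactly
#' one of the three sets.
#'
#' @param y class labels.
#' @param fractions length-3 fractions summing to 1.
#' @param seed RNG seed.
#' @param stratify set FALSE for the literal unstratified random split.
#' @return list of index vectors train, validation, test.
#' @export
split_data <- function(y, fractions = c(0.70, 0.15, 0.15), seed = 1,
                       stratify = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(y)
  withr_seed(seed, {
    groups <- if (stratify) split(seq_len(n), y) else list(seq_len(n))
    out <- list(train = integer(0), validation = integer(0),
                test = integer(0))
    for (g in groups) {
      g <- sample(g)
      ng <- length(g)
      n1 <- round(ng * fractions[1])
      n2 <- round(ng * (fractions[1] + fractions[2])) - n1
      out$train <- c(out$train, g[seq_len(n1)])
      out$validation <- c(out$validation,
                          if (n2 > 0) g[n1 + seq_len(n2)] else integer(0))
      out$test <- c(out$test,
                    if (ng > n1 + n2) g[(n1 + n2 + 1):ng] else integer(0))
    }
    lapply(out, sort)
  })
}

#' Train a network by scaled conjugate gradient with early stopping
#'
#' Inputs are z-scored with statistics of the training split only (stored
#' in the model).  SCG minimizes the cross-entropy of the (0,1)-mapped
#' tanh outputs against one-hot targets; training stops at `max_epochs`
#' or after `patience` consecutive validation-loss increases, returning
#' the best-validation weights.
#'
#' @param model an initialized `network_model`.
#' @param X feature matrix (samples x n_inputs), unstandardized.
#' @param y integer class labels in 1..n_outputs.
#' @param tc a [train_config()].
#' @param stratify stratify the internal split by class.
#' @return the trained `network_model` with `history` and
#'   `stopped_epoch`.
#' @export
train_scg <- function(model, X, y, tc = train_config(), stratify = TRUE) {
  cfg <- model$config
  X <- as.matrix(X)
  stopifnot(ncol(X) == cfg$n_inputs, length(y) == nrow(X))
  if (any(y < 1 | y > cfg$n_outputs)) stop("labels outside 1..n_outputs")
  idx <- split_data(y, tc$split, seed = tc$seed, stratify = stratify)
  if (length(unique(y[idx$train])) < length(unique(y)))
    stop("a class is empty in the training split; use stratified ",
         "resampling or more data")
  ctr <- colMeans(X[idx$train, , drop = FALSE])
  scl <- apply(X[idx$train, , drop = FALSE], 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  model$center <- ctr; model$scale <- scl
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  onehot <- function(yy) {
    T01 <- matrix(0, length(yy), cfg$n_outputs)
    T01[cbind(seq_along(yy), yy)] <- 1
    T01
  }
  Xtr <- Z[idx$train, , drop = FALSE]; Ttr <- onehot(y[idx$train])
  has_val <- length(idx$validation) > 0
  Xva <- Z[idx$validation, , drop = FALSE]
  Tva <- if (has_val) onehot(y[idx$validation]) else NULL
  Xte <- Z[idx$test, , drop = FALSE]
  Tte <- if (length(idx$test) > 0) onehot(y[idx$test]) else NULL

  w <- .pack(model)
  res <- .scg_run(w, cfg, Xtr, Ttr, Xva, Tva, Xte, Tte, tc, has_val)
  m2 <- .unpack(res$w, cfg)
  model$W1 <- m2$W1; model$b1 <- m2$b1; model$W2 <- m2$W2; model$b2 <- m2$b2
  model$history <- res$history
  model$stopped_epoch <- res$stopped
  model$trained <- TRUE
  model$split_idx <- idx
  model
}

# Moller's SCG with validation-based early stopping; returns best weights
.scg_run <- function(w, cfg, Xtr, Ttr, Xva, Tva, Xte, Tte, tc, has_val) {
  fg <- .loss_grad(w, cfg, Xtr, Ttr)
  f_w <- fg$loss
  r <- -fg$grad
  p <- r
  lambda <- tc$lambda_init; lambda_bar <- 0
  success <- TRUE
  nw <- length(w)
  best_w <- w; best_val <- Inf; best_epoch <- 0L; bad <- 0L
  hist <- data.frame(epoch = integer(0), train = numeric(0),
                     validation = numeric(0), test = numeric(0))
  stopped <- 0L
  delta <- 0; mu <- 0
  for (k in seq_len(tc$max_epochs)) {
    if (success) {
      pn2 <- sum(p * p)
      if (pn2 < 1e-300) break
      sigma_k <- tc$sigma / sqrt(pn2)
      gplus <- .loss_grad(w + sigma_k * p, cfg, Xtr, Ttr)$grad
      s <- (gplus - (-r)) / sigma_k
      delta <- sum(p * s)
    }
    pn2 <- sum(p * p)
    delta_adj <- delta + (lambda - lambda_bar) * pn2
    if (delta_adj <= 0) {
      lambda_bar <- 2 * (lambda - delta_adj / pn2)
      delta_adj <- -delta_adj + lambda * pn2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta_adj
    f_new <- .loss_grad(w + alpha * p, cfg, Xtr, Ttr,
                        want_grad = FALSE)$loss
    Delta <- 2 * delta_adj * (f_w - f_new) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      w <- w + alpha * p
      fg <- .loss_grad(w, cfg, Xtr, Ttr)
      f_w <- fg$loss
      r_new <- -fg$grad
      lambda_bar <- 0
      success <- TRUE
      if (k %% nw == 0) {
        p <- r_new
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (is.finite(Delta) && Delta < 0.25) lambda <- lambda + delta_adj *
        (1 - max(Delta, -1)) / pn2
    if (lambda > 1e100) break
    vl <- if (has_val) .loss_grad(w, cfg, Xva, Tva,
                                  want_grad = FALSE)$loss else f_w
    tl <- if (!is.null(Tte)) .loss_grad(w, cfg, Xte, Tte,
                                        want_grad = FALSE)$loss else NA
    hist <- rbind(hist, data.frame(epoch = k, train = f_w,
                                   validation = vl, test = tl))
    stopped <- k
    if (vl < best_val - 1e-12) {
      best_val <- vl; best_w <- w; best_epoch <- k; bad <- 0L
    } else {
      bad <- bad + 1L
      if (has_val && bad >= tc$patience) break
    }
  }
  list(w = best_w, history = hist,
       stopped = if (best_epoch > 0) best_epoch else stopped)
}

#' Predict class labels and scores
#'
#' Label is the argmax of the output scores; ties break toward the lower
#' class index.
#'
#' @param model a trained `network_model`.
#' @param X feature matrix.
#' @return list with `labels` (integer) and `scores` (matrix).
#' @export
predict_network <- function(model, X) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  S <- forward(model, X)
  list(labels = apply(S, 1, which.max), scores = S)
}

#' Save a model artifact as JSON
#' @param model a `network_model`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    center = model$center, scale = model$scale,
    config = unclass(model$config), stopped_epoch = model$stopped_epoch,
    trained = model$trained), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model artifact written by [write_model()]
#' @param path input path.
#' @return A `network_model`.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config,
                 j$config[c("n_inputs", "n_outputs", "n_hidden", "seed")])
  structure(list(W1 = matrix(unlist(j$W1), nrow = cfg$n_hidden),
                 b1 = as.numeric(j$b1),
                 W2 = matrix(unlist(j$W2), nrow = cfg$n_outputs),
                 b2 = as.numeric(j$b2),
                 center = as.numeric(j$center),
                 scale = as.numeric(j$scale),
                 config = cfg, trained = isTRUE(j$trained),
                 history = NULL, stopped_epoch = j$stopped_epoch),
            class = "network_model")
}
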