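# Online (streaming) logistic regression: stochastic-gradient updates of the
# L2-regularized logistic loss, one sample at a time, with the standard
# decaying learning-rate schedule eta_t = eta0 / (1 + eta0 * lambda * t).
# This is the Experts' per-decision classifier; it is deterministic in the
# stream order.

online_logistic_new <- function(d, eta0 = 0.5, lambda = 1e-4) {
  list(w = numeric(d), b = 0, t = 0L, eta0 = eta0, lambda = lambda,
       n_pos = 0L, n = 0L)
}

# single SGD step on one labeled sample (y in {0,1})
online_logistic_update <- function(model, x, y) {
  x <- unname(x)
  y <- as.numeric(y)[1]
  model$t <- model$t + 1L
  lr <- model$eta0 / (1 + model$eta0 * model$lambda * model$t)
  p <- stats::plogis(sum(model$w * x) + model$b)
  g <- p - y
  model$w <- model$w - lr * (g * x + model$lambda * model$w)
  model$b <- model$b - lr * g
  model$n <- model$n + 1L
  model$n_pos <- model$n_pos + as.integer(y)
  model
}

# one pass over the rows of x in order; returns the trained model
online_logistic_fit <- function(x, y, eta0 = 0.5, lambda = 1e-4) {
  model <- online_logistic_new(ncol(x), eta0, lambda)
  w <- model$w; b <- model$b
  for (i in seq_len(nrow(x))) {
    model$t <- model$t + 1L
    lr <- eta0 / (1 + eta0 * lambda * model$t)
    xi <- unname(x[i, ])
    p <- stats::plogis(sum(w * xi) + b)
    g <- p - y[i]
    w <- w - lr * (g * xi + lambda * w)
    b <- b - lr * g
  }
  model$w <- w; model$b <- b
  model$n <- nrow(x); model$n_pos <- sum(y)
  model
}

online_logistic_prob <- function(model, x) {
  stats::plogis(drop(x %*% model$w) + model$b)
}
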