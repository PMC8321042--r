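# Internal fully-connected network used by every trainable stage:
# ReLU hidden layers, sigmoid output, binary cross-entropy, Adam updates.
# Supports a one-cycle learning-rate schedule and "head-only" training
# (output layer updated, hidden layers frozen) for two-phase fine-tuning.

mlp_init <- function(n_in, hidden, seed) {
  sizes <- c(n_in, hidden, 1L)
  withr::with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      # He initialisation, appropriate for ReLU units
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                       nrow = sizes[l], ncol = sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, x) {
  L <- length(par$W)
  a <- vector("list", L + 1L)
  a[[1L]] <- x
  for (l in seq_len(L - 1L)) {
    z <- sweep(a[[l]] %*% par$W[[l]], 2L, par$b[[l]], "+")
    a[[l + 1L]] <- pmax(z, 0)
  }
  z <- sweep(a[[L]] %*% par$W[[L]], 2L, par$b[[L]], "+")
  a[[L + 1L]] <- 1 / (1 + exp(-z))
  a
}

# One-cycle schedule: linear warm-up to lr_max over the first 30% of steps,
# cosine anneal down to lr_max/100 for the remainder.
onecycle_lr <- function(step, total, lr_max) {
  warm <- max(1, floor(0.3 * total))
  if (step <= warm) {
    lr_max / 10 + (lr_max - lr_max / 10) * step / warm
  } else {
    frac <- (step - warm) / max(1, total - warm)
    lr_min <- lr_max / 100
    lr_min + (lr_max - lr_min) * (1 + cos(pi * frac)) / 2
  }
}

# Mini-batch Adam training. phase = "full" updates all layers, "head" only
# the output layer (two-phase fine-tuning). The one-cycle schedule spans
# all update steps of the run. Returns updated parameters plus a per-epoch
# metric log computed on the full training set.
mlp_train <- function(par, x, y, epochs, lr_max,
                      schedule = c("onecycle", "constant"),
                      phase = c("full", "head"),
                      monitor = c("none", "precision", "accuracy"),
                      batch_size = 32L) {
  schedule <- match.arg(schedule)
  phase <- match.arg(phase)
  monitor <- match.arg(monitor)
  if (epochs < 1L) return(list(par = par, log = numeric(0)))
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(x)
  batch_size <- min(batch_size, n)
  steps_per_epoch <- ceiling(n / batch_size)
  total_steps <- epochs * steps_per_epoch
  metric_log <- numeric(epochs)
  first <- if (phase == "head") L else 1L
  t_adam <- 0L
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    for (s in seq_len(steps_per_epoch)) {
      idx <- perm[((s - 1L) * batch_size + 1L):min(s * batch_size, n)]
      xb <- x[idx, , drop = FALSE]; yb <- y[idx]
      a <- mlp_forward(par, xb)
      p <- a[[L + 1L]]
      # BCE gradient at the pre-sigmoid output simplifies to (p - y)/m
      delta <- matrix((p - yb) / length(idx), ncol = 1L)
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in L:1) {
        gW[[l]] <- crossprod(a[[l]], delta)
        gb[[l]] <- colSums(delta)
        if (l > first) {
          delta <- (delta %*% t(par$W[[l]])) * (a[[l]] > 0)
        } else break
      }
      t_adam <- t_adam + 1L
      lr <- if (schedule == "onecycle") {
        onecycle_lr(t_adam, total_steps, lr_max)
      } else lr_max
      for (l in first:L) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        mWh <- mW[[l]] / (1 - beta1^t_adam); vWh <- vW[[l]] / (1 - beta2^t_adam)
        mbh <- mb[[l]] / (1 - beta1^t_adam); vbh <- vb[[l]] / (1 - beta2^t_adam)
        par$W[[l]] <- par$W[[l]] - lr * mWh / (sqrt(vWh) + eps)
        par$b[[l]] <- par$b[[l]] - lr * mbh / (sqrt(vbh) + eps)
      }
    }
    if (monitor != "none") {
      p_all <- mlp_predict(par, x)
      call <- as.numeric(p_all >= 0.5)
      metric_log[ep] <- if (monitor == "accuracy") {
        mean(call == y)
      } else if (sum(call) > 0) {
        sum(call == 1 & y == 1) / sum(call)
      } else NA_real_
    }
  }
  list(par = par, log = metric_log)
}

mlp_predict <- function(par, x) {
  as.numeric(mlp_forward(par, x)[[length(par$W) + 1L]])
}
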