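# Internal engine of the point-wise linear model: a densely connected
# ("mesh") feed-forward network g_theta mapping a feature vector x to a
# per-sample logistic weight vector (w, b) in R^{d+1}. Every hidden layer
# receives the concatenation of the raw input and ALL previous layers'
# outputs; the linear head reads the full concatenation. Prediction is
# sigma(w(x)' x + b(x)). Gradients are computed by hand-written
# backpropagation (verified against numerical differentiation in the test
# suite) and optimized with Adam.

pwl_init_params <- function(d, depth, width) {
  params <- list(W = vector("list", depth), b = vector("list", depth))
  fan_in <- d
  for (l in seq_len(depth)) {
    params$W[[l]] <- matrix(rnorm(fan_in * width) * sqrt(2 / fan_in),
                            fan_in, width)
    params$b[[l]] <- numeric(width)
    fan_in <- fan_in + width
  }
  # small head init: the emitted (w, b) start near 0, so p starts near 0.5
  params$Wo <- matrix(rnorm(fan_in * (d + 1)) * 0.01, fan_in, d + 1)
  params$bo <- numeric(d + 1)
  params
}

# forward pass; returns emitted weights, probabilities and (optionally)
# the caches needed for backprop
pwl_forward <- function(params, X, keep_cache = FALSE) {
  n <- nrow(X)
  d <- ncol(X)
  depth <- length(params$W)
  C <- X
  Zs <- vector("list", depth)
  Cs <- vector("list", depth)
  for (l in seq_len(depth)) {
    Cs[[l]] <- C
    Z <- sweep(C %*% params$W[[l]], 2, params$b[[l]], `+`)
    Zs[[l]] <- Z
    C <- cbind(C, pmax(Z, 0))
  }
  O <- sweep(C %*% params$Wo, 2, params$bo, `+`)
  w <- O[, seq_len(d), drop = FALSE]
  b <- O[, d + 1]
  eta <- rowSums(w * X) + b
  p <- plogis(eta)
  out <- list(w = w, b = b, eta = eta, p = p)
  if (keep_cache) {
    out$Zs <- Zs
    out$Cs <- Cs
    out$Chead <- C
  }
  out
}

pwl_loss_value <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

pwl_penalty <- function(params, weight_decay) {
  weight_decay * (sum(vapply(params$W, function(W) sum(W^2), numeric(1))) +
                    sum(params$Wo^2))
}

# loss and analytic gradients for one full batch
pwl_grad <- function(params, X, y, weight_decay = 0, lambda_w = 0) {
  n <- nrow(X)
  d <- ncol(X)
  depth <- length(params$W)
  fwd <- pwl_forward(params, X, keep_cache = TRUE)

  loss <- pwl_loss_value(fwd$p, y) + pwl_penalty(params, weight_decay) +
    lambda_w * mean(rowSums(fwd$w^2))

  g_eta <- (fwd$p - y) / n
  dO <- cbind(X * g_eta, g_eta)
  if (lambda_w > 0) {
    dO[, seq_len(d)] <- dO[, seq_len(d)] + (2 * lambda_w / n) * fwd$w
  }

  grads <- list(W = vector("list", depth), b = vector("list", depth))
  grads$Wo <- crossprod(fwd$Chead, dO) + 2 * weight_decay * params$Wo
  grads$bo <- colSums(dO)

  width <- if (depth > 0) ncol(params$W[[1]]) else 0L
  dA <- vector("list", depth)
  dC <- dO %*% t(params$Wo) # n x (d + depth*width)
  for (l in seq_len(depth)) {
    dA[[l]] <- dC[, d + (l - 1) * width + seq_len(width), drop = FALSE]
  }
  for (l in rev(seq_len(depth))) {
    dZ <- dA[[l]] * (fwd$Zs[[l]] > 0)
    grads$W[[l]] <- crossprod(fwd$Cs[[l]], dZ) + 2 * weight_decay * params$W[[l]]
    grads$b[[l]] <- colSums(dZ)
    if (l > 1) {
      dCl <- dZ %*% t(params$W[[l]])
      for (j in seq_len(l - 1)) {
        dA[[j]] <- dA[[j]] +
          dCl[, d + (j - 1) * width + seq_len(width), drop = FALSE]
      }
    }
  }
  list(loss = loss, grads = grads)
}

# flatten/unflatten helpers shared by Adam and the numerical-gradient test
pwl_param_names <- function(params) {
  c(paste0("W", seq_along(params$W)), paste0("b", seq_along(params$b)),
    "Wo", "bo")
}

pwl_get <- function(params, name) {
  if (name == "Wo") return(params$Wo)
  if (name == "bo") return(params$bo)
  idx <- as.integer(substring(name, 2))
  params[[substring(name, 1, 1)]][[idx]]
}

pwl_set <- function(params, name, value) {
  if (name == "Wo") params$Wo <- value
  else if (name == "bo") params$bo <- value
  else {
    idx <- as.integer(substring(name, 2))
    params[[substring(name, 1, 1)]][[idx]] <- value
  }
  params
}

pwl_adam_step <- function(params, grads, state, lr,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in pwl_param_names(params)) {
    g <- pwl_get(grads, nm)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params <- pwl_set(params, nm,
                      pwl_get(params, nm) - lr * mhat / (sqrt(vhat) + eps))
  }
  list(params = params, state = state)
}

pwl_adam_init <- function(params) {
  zeros <- lapply(setNames(pwl_param_names(params), pwl_param_names(params)),
                  function(nm) pwl_get(params, nm) * 0)
  list(t = 0, m = zeros, v = zeros)
}

# full training loop: optional stratified internal holdout with patience
pwl_train <- function(X, y, config) {
  d <- ncol(X)
  params <- pwl_init_params(d, config$depth, config$width)
  adam <- pwl_adam_init(params)

  n <- nrow(X)
  use_holdout <- config$holdout > 0 && n >= 20
  if (use_holdout) {
    folds <- make_stratified_folds(y, k = max(2L, round(1 / config$holdout)))
    hold <- folds == 1L
  } else {
    hold <- rep(FALSE, n)
  }
  Xtr <- X[!hold, , drop = FALSE]
  ytr <- y[!hold]
  Xho <- X[hold, , drop = FALSE]
  yho <- y[hold]

  best <- list(loss = Inf, params = params, epoch = 0L)
  since_best <- 0L
  history <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    gr <- pwl_grad(params, Xtr, ytr, config$weight_decay, config$lambda_w)
    history[epoch] <- gr$loss
    step <- pwl_adam_step(params, gr$grads, adam, config$learning_rate)
    params <- step$params
    adam <- step$state

    monitor <- if (use_holdout) {
      pwl_loss_value(pwl_forward(params, Xho)$p, yho)
    } else {
      gr$loss
    }
    if (monitor < best$loss - 1e-8) {
      best <- list(loss = monitor, params = params, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (use_holdout && since_best >= config$patience) {
        history <- history[seq_len(epoch)]
        break
      }
    }
  }
  list(params = best$params, history = history, best_epoch = best$epoch,
       holdout_loss = if (use_holdout) best$loss else NA_real_)
}

#' Stratified fold assignment
#'
#' Assigns samples to `k` folds so that fold sizes are as equal as possible
#' overall (e.g. 82 samples in 5 folds gives sizes 17, 17, 16, 16, 16) and
#' each class is spread evenly across folds.
#'
#' @param y Binary labels (0/1).
#' @param k Number of folds.
#' @param seed Optional integer seed for the within-class shuffle; `NULL`
#'   uses the current RNG state.
#' @return Integer vector of fold labels in 1..k, one per sample.
#' @export
make_stratified_folds <- function(y, k = 5L, seed = NULL) {
  n <- length(y)
  if (n < k) {
    abort("Need at least `k` samples for `k` folds.",
          class = "pwlscore_invalid_parameter")
  }
  assign_in_order <- function() {
    ord <- unlist(lapply(sort(unique(y)), function(cl) {
      idx <- which(y == cl)
      idx[sample.int(length(idx))]
    }))
    folds <- integer(n)
    folds[ord] <- rep_len(seq_len(k), n)
    folds
  }
  if (is.null(seed)) assign_in_order()
  else withr::with_seed(check_seed(seed), assign_in_order())
}
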