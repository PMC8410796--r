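# Adam and the triangular2 cyclical learning rate.

#' Cyclical learning rate configuration
#'
#' Triangular waveform between `base_lr` and a ceiling that halves after
#' each full cycle (one cycle = `2 * step_size_epochs` epochs), stepped per
#' training iteration.
#'
#' @param base_lr Floor of the schedule. Default `1e-7`.
#' @param max_lr Initial ceiling. Default `1e-4`.
#' @param step_size_epochs Half-cycle length in epochs. Default 4.
#' @param mode Only `"triangular2"` is supported.
#' @return An object of class `clr_config`.
#' @export
clr_config <- function(base_lr = 1e-7, max_lr = 1e-4, step_size_epochs = 4,
                       mode = "triangular2") {
  check_scalar(base_lr, "base_lr", min = 1e-300)
  check_scalar(max_lr, "max_lr", min = base_lr + 1e-300)
  check_count(step_size_epochs, "step_size_epochs", min = 1L)
  mode <- match.arg(mode, "triangular2")
  structure(list(base_lr = base_lr, max_lr = max_lr,
                 step_size_epochs = as.integer(step_size_epochs), mode = mode),
            class = "clr_config")
}

#' Learning rate at a given training iteration
#'
#' Closed form of the triangular2 schedule: with half-cycle
#' `s = step_size_epochs * iterations_per_epoch` iterations,
#' `cycle = floor(1 + it / (2 s))`, `x = |it / s - 2 cycle + 1|`, and
#' `lr = base_lr + (max_lr - base_lr) * max(0, 1 - x) / 2^(cycle - 1)`.
#' Iteration 0 sits at `base_lr`, iteration `s` at `max_lr`, iteration `3 s`
#' (the second peak) at `base_lr + (max_lr - base_lr) / 2`.
#'
#' @param iteration Integer iteration index (0-based); vectorised.
#' @param iterations_per_epoch Number of mini-batches per epoch.
#' @param config A [clr_config()].
#' @return Numeric vector of learning rates.
#' @export
clr_at <- function(iteration, iterations_per_epoch, config = clr_config()) {
  stopifnot(inherits(config, "clr_config"))
  check_count(iterations_per_epoch, "iterations_per_epoch", min = 1L)
  if (any(iteration < 0)) {
    abort("`iteration` must be >= 0.", class = "melbalance_invalid_input")
  }
  s <- config$step_size_epochs * iterations_per_epoch
  cycle <- floor(1 + iteration / (2 * s))
  x <- abs(iteration / s - 2 * cycle + 1)
  config$base_lr +
    (config$max_lr - config$base_lr) * pmax(0, 1 - x) / 2^(cycle - 1)
}

#' Optimizer configuration
#'
#' Adam defaults follow the usual convention: `lr = 1e-4`, `beta1 = 0.9`,
#' `beta2 = 0.999`, no decay, no amsgrad. The learning rate is overridden
#' per iteration by the cyclical schedule when one is supplied to
#' [train_classifier()].
#'
#' @param kind `"adam"` or `"sgd"`.
#' @param lr Base learning rate.
#' @param beta1,beta2 Adam moment decay rates, in (0, 1).
#' @param epsilon Adam numerical stabiliser.
#' @param decay Per-iteration multiplicative lr decay (0 disables).
#' @param amsgrad Use the AMSGrad variant.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(kind = c("adam", "sgd"), lr = 1e-4, beta1 = 0.9,
                             beta2 = 0.999, epsilon = 1e-7, decay = 0,
                             amsgrad = FALSE) {
  kind <- match.arg(kind)
  check_scalar(lr, "lr", min = 1e-300)
  check_scalar(beta1, "beta1", min = 1e-12, max = 1 - 1e-12)
  check_scalar(beta2, "beta2", min = 1e-12, max = 1 - 1e-12)
  check_scalar(epsilon, "epsilon", min = 0)
  check_scalar(decay, "decay", min = 0)
  structure(list(kind = kind, lr = lr, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, decay = decay, amsgrad = isTRUE(amsgrad)),
            class = "optimizer_config")
}

# rebuild a nested parameter structure from a flat numeric vector
relist_like <- function(values, skeleton) {
  pos <- 0L
  rebuild <- function(sk) {
    if (is.list(sk)) return(lapply(sk, rebuild))
    n <- length(sk)
    out <- values[pos + seq_len(n)]
    pos <<- pos + n
    attributes(out) <- attributes(sk)
    out
  }
  rebuild(skeleton)
}

optimizer_init <- function(params) {
  n <- length(unlist(params))
  list(m = numeric(n), v = numeric(n), vhat = numeric(n), t = 0L)
}

optimizer_step <- function(params, grads, state, opt, lr) {
  theta <- unlist(params)
  g <- unlist(grads)
  if (opt$decay > 0) lr <- lr / (1 + opt$decay * state$t)
  if (opt$kind == "sgd") {
    theta <- theta - lr * g
  } else {
    state$t <- state$t + 1L
    state$m <- opt$beta1 * state$m + (1 - opt$beta1) * g
    state$v <- opt$beta2 * state$v + (1 - opt$beta2) * g^2
    mhat <- state$m / (1 - opt$beta1^state$t)
    vhat <- state$v / (1 - opt$beta2^state$t)
    if (opt$amsgrad) {
      state$vhat <- pmax(state$vhat, vhat)
      vhat <- state$vhat
    }
    theta <- theta - lr * mhat / (sqrt(vhat) + opt$epsilon)
  }
  list(params = relist_like(theta, params), state = state)
}
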