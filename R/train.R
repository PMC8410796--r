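# Scenario-driven training loop.
#
# Three scenarios over one shared architecture isolate the two
# imbalance-handling devices:
#   ORI: naive sampler + baseline loss (conventional training)
#   BON: fixed-ratio sampler + baseline loss (sampler only)
#   BLF: fixed-ratio sampler + class-wise loss (both)
# Training uses Adam with a triangular2 cyclical learning rate stepped per
# mini-batch, monitors validation loss each epoch, and keeps the parameters
# from the epoch with the smallest validation loss (the checkpoint).

#' Scenario configuration
#'
#' @param name `"ORI"`, `"BON"` or `"BLF"`. Fills `loss`/`sampler` defaults:
#'   ORI = (mse, naive), BON = (mse, fixed_ratio), BLF = (clf, fixed_ratio).
#'   The baseline loss of ORI/BON can be overridden to `"bce"` or `"focal"`;
#'   the scenario invariants (only BLF uses the class-wise loss, ORI never
#'   uses the fixed-ratio sampler) are enforced.
#' @param loss One of `"mse"`, `"bce"`, `"focal"`, `"clf"`, or `NULL` for
#'   the scenario default.
#' @param sampler One of `"naive"`, `"fixed_ratio"`, or `NULL` for the
#'   scenario default.
#' @param epochs Number of training epochs. Default 50.
#' @param batch_size Mini-batch size. Default 32.
#' @param positive_fraction Per-batch positive fraction for the fixed-ratio
#'   sampler; `NULL` (default) uses the training-set prevalence.
#' @param loss_params List of loss parameters (`a`, `b` for clf; `gamma`,
#'   `alpha` for focal).
#' @param seed Integer seed governing weight initialization, batch
#'   shuffling, dropout masks and (if enabled) augmentation draws.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name = c("BLF", "ORI", "BON"), loss = NULL,
                            sampler = NULL, epochs = 50, batch_size = 32,
                            positive_fraction = NULL,
                            loss_params = list(a = 0.5, b = 1), seed = 1) {
  name <- match.arg(name)
  defaults <- list(ORI = c("mse", "naive"),
                   BON = c("mse", "fixed_ratio"),
                   BLF = c("clf", "fixed_ratio"))[[name]]
  loss <- loss %||% defaults[1]
  sampler <- sampler %||% defaults[2]
  loss <- match.arg(loss, c("mse", "bce", "focal", "clf"))
  sampler <- match.arg(sampler, c("naive", "fixed_ratio"))
  ok <- switch(name,
    ORI = loss != "clf" && sampler == "naive",
    BON = loss != "clf" && sampler == "fixed_ratio",
    BLF = loss == "clf" && sampler == "fixed_ratio")
  if (!ok) {
    abort(sprintf(
      "Scenario %s requires %s loss and the %s sampler; got (%s, %s).",
      name, if (name == "BLF") "the clf" else "a baseline (non-clf)",
      defaults[2], loss, sampler), class = "melbalance_invalid_input")
  }
  check_count(epochs, "epochs", min = 1L)
  check_count(batch_size, "batch_size", min = 2L)
  if (!is.null(positive_fraction)) {
    check_scalar(positive_fraction, "positive_fraction", min = 1e-9, max = 1 - 1e-9)
  }
  check_count(seed, "seed")
  structure(list(name = name, loss = loss, sampler = sampler,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 positive_fraction = positive_fraction,
                 loss_params = loss_params, seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s: loss=%s, sampler=%s, %d epochs, batch %d, seed %d\n",
              x$name, x$loss, x$sampler, x$epochs, x$batch_size, x$seed))
  invisible(x)
}

sen_spe_at <- function(scores, labels, threshold = 0.5) {
  pos <- labels == 1
  c(sen = if (any(pos)) mean(scores[pos] >= threshold) else NA_real_,
    spe = if (any(!pos)) mean(scores[!pos] < threshold) else NA_real_)
}

#' Train the classifier head under a scenario
#'
#' Runs the scenario's sampler and loss over the feature matrix for
#' `scenario$epochs` epochs, stepping Adam under the cyclical learning rate
#' once per mini-batch. Validation loss is computed on the whole validation
#' set in evaluation mode after each epoch; the returned model carries the
#' parameters of the epoch with the smallest validation loss.
#'
#' Weight initialization depends only on `init_seed` (default: the scenario
#' seed), so scenarios trained with the same seed start from identical
#' weights and differ only through sampler and loss.
#'
#' @param x_train,x_val Feature matrices (`n x feature_dim`), e.g. from
#'   [backbone_features()] — or lists of image arrays, in which case
#'   `backbone` is required and features are extracted on draw (with
#'   real-time augmentation when `augment` is supplied).
#' @param y_train,y_val 0/1 label vectors.
#' @param scenario A [scenario_config()].
#' @param head A [head_config()].
#' @param clr A [clr_config()], or `NULL` for a constant `optimizer$lr`.
#' @param optimizer An [optimizer_config()].
#' @param backbone A backbone object, required when images are passed.
#' @param augment An [augment_config()] for on-draw training augmentation;
#'   `NULL` disables it. Ignored for feature-matrix input.
#' @param init_seed Seed for weight initialization only.
#' @param monitor_threshold Threshold for the SEN/SPE columns of the
#'   history. Default 0.5.
#' @return An object of class `imbalance_fit`: list with elements `head`
#'   (checkpoint parameters), `final_head`, `history` (per-epoch tibble),
#'   `checkpoint_epoch`, `scenario`.
#' @export
train_classifier <- function(x_train, y_train, x_val, y_val, scenario,
                             head = head_config(), clr = clr_config(),
                             optimizer = optimizer_config(), backbone = NULL,
                             augment = NULL, init_seed = NULL,
                             monitor_threshold = 0.5) {
  stopifnot(inherits(scenario, "scenario_config"))
  from_images <- is.list(x_train) && !is.matrix(x_train)
  if (from_images) {
    if (is.null(backbone)) {
      abort("`backbone` is required when training from images.",
            class = "melbalance_invalid_input")
    }
    if (length(x_train) == 0L || length(x_val) == 0L) {
      abort("Training and validation splits must be non-empty.",
            class = "melbalance_invalid_input")
    }
    stopifnot(length(x_train) == length(y_train),
              length(x_val) == length(y_val))
    images_train <- x_train
    x_val <- backbone_features(backbone, x_val)
    # plain (non-augmented) features reused whenever augmentation is off
    x_train <- backbone_features(backbone, images_train)
  } else {
    if (!is.matrix(x_train) || !is.matrix(x_val)) {
      abort("`x_train` and `x_val` must be feature matrices or image lists.",
            class = "melbalance_invalid_input")
    }
    if (nrow(x_train) == 0L || nrow(x_val) == 0L) {
      abort("Training and validation splits must be non-empty.",
            class = "melbalance_invalid_input")
    }
    stopifnot(nrow(x_train) == length(y_train), nrow(x_val) == length(y_val))
  }
  use_augment <- from_images && !is.null(augment)

  net <- build_head(head, feature_dim = ncol(x_train),
                    seed = init_seed %||% scenario$seed)
  opt_state <- optimizer_init(net$params)

  plan <- NULL
  if (scenario$sampler == "fixed_ratio") {
    pf <- scenario$positive_fraction %||% mean(y_train == 1)
    plan <- sampling_plan(scenario$batch_size, positive_fraction = pf)
  }

  # one seeded stream drives shuffling and dropout for the whole run
  withr::local_seed(derive_seed(scenario$seed, 0L))

  history <- vector("list", scenario$epochs)
  best <- list(val_loss = Inf, epoch = NA_integer_, net = NULL)
  iteration <- 0L
  ipe <- NULL

  for (epoch in seq_len(scenario$epochs)) {
    sched <- if (scenario$sampler == "fixed_ratio") {
      make_epoch(y_train, plan, seed = NULL)
    } else {
      naive_epoch(y_train, scenario$batch_size, seed = NULL)
    }
    batches <- epoch_batches(sched)
    ipe <- ipe %||% length(batches)
    ep_loss <- 0
    tr_scores <- numeric(0); tr_labels <- numeric(0)
    lr <- optimizer$lr
    for (idx in batches) {
      xb <- if (use_augment) {
        # real-time augmentation: fresh raster per draw, then features
        backbone_features(backbone, lapply(images_train[idx], augment_image,
                                           config = augment, seed = NULL))
      } else {
        x_train[idx, , drop = FALSE]
      }
      yb <- y_train[idx]
      fw <- head_forward(net, xb, training = TRUE)
      net <- fw$head
      l <- batch_loss(fw$scores, yb, scenario$loss, scenario$loss_params,
                      missing_class = "zero")
      if (!is.finite(l)) {
        abort(sprintf(
          "Training diverged: non-finite %s loss at epoch %d, iteration %d.",
          scenario$loss, epoch, iteration),
          class = "melbalance_divergence")
      }
      g <- loss_grad(fw$scores, yb, loss = scenario$loss,
                     params = scenario$loss_params, missing_class = "zero")
      grads <- head_backward(net, fw$cache, g)
      if (!is.null(clr)) lr <- clr_at(iteration, ipe, clr)
      step <- optimizer_step(net$params, grads, opt_state, optimizer, lr)
      net$params <- step$params
      opt_state <- step$state
      iteration <- iteration + 1L
      ep_loss <- ep_loss + l
      tr_scores <- c(tr_scores, fw$scores)
      tr_labels <- c(tr_labels, yb)
    }
    tr <- sen_spe_at(tr_scores, tr_labels, monitor_threshold)
    val_scores <- head_predict(net, x_val)
    val_loss <- batch_loss(val_scores, y_val, scenario$loss,
                           scenario$loss_params, missing_class = "zero")
    if (!is.finite(val_loss)) {
      abort(sprintf("Training diverged: non-finite validation loss at epoch %d.",
                    epoch), class = "melbalance_divergence")
    }
    vl <- sen_spe_at(val_scores, y_val, monitor_threshold)
    history[[epoch]] <- tibble(
      epoch = epoch, lr = lr,
      train_loss = ep_loss / length(batches), val_loss = val_loss,
      train_sen = unname(tr["sen"]), train_spe = unname(tr["spe"]),
      val_sen = unname(vl["sen"]), val_spe = unname(vl["spe"]))
    if (val_loss < best$val_loss) {
      best <- list(val_loss = val_loss, epoch = epoch, net = net)
    }
  }

  structure(
    list(head = best$net, final_head = net,
         history = dplyr::bind_rows(history),
         checkpoint_epoch = best$epoch, scenario = scenario),
    class = "imbalance_fit")
}

#' @export
print.imbalance_fit <- function(x, ...) {
  h <- x$history[x$checkpoint_epoch, ]
  cat(sprintf(
    "<imbalance_fit> %s (%s loss, %s sampler), %d epochs\n  checkpoint at epoch %d: val_loss=%.4g, val SEN=%.3f, val SPE=%.3f\n",
    x$scenario$name, x$scenario$loss, x$scenario$sampler,
    nrow(x$history), x$checkpoint_epoch, h$val_loss, h$val_sen, h$val_spe))
  invisible(x)
}

#' Predict scores from a trained scenario fit
#'
#' @param object An `imbalance_fit`.
#' @param x Feature matrix `n x feature_dim`.
#' @param use_checkpoint Use the min-validation-loss parameters (default);
#'   `FALSE` uses the final-epoch parameters.
#' @param ... Unused.
#' @return Numeric score vector in `(0, 1)`.
#' @export
predict.imbalance_fit <- function(object, x, use_checkpoint = TRUE, ...) {
  head_predict(if (use_checkpoint) object$head else object$final_head, x)
}

#' @describeIn train_classifier Tidy per-epoch training history.
#' @param x An `imbalance_fit` (for `tidy`/`glance`).
#' @export
tidy.imbalance_fit <- function(x, ...) {
  dplyr::mutate(x$history, scenario = x$scenario$name, .before = 1)
}

#' @describeIn train_classifier One-row model summary.
#' @export
glance.imbalance_fit <- function(x, ...) {
  h <- x$history[x$checkpoint_epoch, ]
  tibble(scenario = x$scenario$name, loss = x$scenario$loss,
         sampler = x$scenario$sampler, epochs = nrow(x$history),
         checkpoint_epoch = x$checkpoint_epoch,
         val_loss = h$val_loss, val_sen = h$val_sen, val_spe = h$val_spe,
         n_params = head_n_params(x$head))
}
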