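# Loss family for imbalanced binary classification.
#
# The class-wise loss (CLF) splits the mean squared error into a positive-class
# term (pmse, computed over melanoma-labelled examples) and a negative-class
# term (nmse, over nevus-labelled examples) and combines them as
#
#   clf = a * (pmse + nmse)^2 + b * (pmse - nmse)^2
#
# so that both the total class-wise error and the *gap* between the two class
# errors are penalised. Minimising pmse drives sensitivity up; minimising nmse
# drives specificity up; the b-term pushes the two towards each other.
# Defaults a = 0.5, b = 1 weight the balance term more heavily than the sum.

#' Mean squared error of a scored batch
#'
#' @param scores Numeric vector of predicted positive-class probabilities in
#'   `[0, 1]`.
#' @param labels Numeric/integer vector of the same length with values 0
#'   (negative, e.g. nevus) or 1 (positive, e.g. melanoma).
#' @return A single non-negative number in `[0, 1]`.
#' @examples
#' loss_mse(c(0.5, 0.5), c(0, 1))   # 0.25
#' @export
loss_mse <- function(scores, labels) {
  check_batch(scores, labels)
  mean((labels - scores)^2)
}

handle_missing_class <- function(n, class_name, missing_class) {
  # n: number of examples of the class; returns TRUE if caller should emit 0
  if (n > 0L) return(FALSE)
  if (missing_class == "error") {
    abort(sprintf("Batch contains no %s examples; class-wise loss undefined.",
                  class_name),
          class = "melbalance_missing_class")
  }
  warn(sprintf("Batch contains no %s examples; treating its class loss as 0.",
               class_name),
       class = "melbalance_missing_class_warning")
  TRUE
}

#' Class-wise mean squared errors
#'
#' `loss_pmse()` is the mean squared error restricted to positive-labelled
#' examples, `(1/P) * sum((1 - s_i)^2)`; `loss_nmse()` is the mirror image on
#' negative-labelled examples, `(1/N) * sum(s_i^2)`.
#'
#' @inheritParams loss_mse
#' @param missing_class What to do when the batch has no example of the
#'   required class: `"error"` (strict mode, for evaluation) or `"zero"`
#'   (training mode: the undefined term contributes 0 and a warning is
#'   emitted). The fixed-ratio sampler guarantees both classes in every
#'   training batch, so the zero branch is only reachable with the naive
#'   sampler.
#' @return A single non-negative number.
#' @examples
#' loss_pmse(c(0.5, 1), c(1, 1))   # 0.125
#' loss_nmse(c(0.2, 0.4), c(0, 0)) # 0.10
#' @export
loss_pmse <- function(scores, labels, missing_class = c("error", "zero")) {
  check_batch(scores, labels)
  missing_class <- match.arg(missing_class)
  pos <- labels == 1
  if (handle_missing_class(sum(pos), "positive", missing_class)) return(0)
  mean((1 - scores[pos])^2)
}

#' @rdname loss_pmse
#' @export
loss_nmse <- function(scores, labels, missing_class = c("error", "zero")) {
  check_batch(scores, labels)
  missing_class <- match.arg(missing_class)
  neg <- labels == 0
  if (handle_missing_class(sum(neg), "negative", missing_class)) return(0)
  mean(scores[neg]^2)
}

#' Class-wise loss for imbalanced binary training
#'
#' Combines the positive and negative class-wise mean squared errors as
#' `a * (pmse + nmse)^2 + b * (pmse - nmse)^2`. The first term penalises the
#' total class-wise error (driving sensitivity + specificity up), the second
#' penalises any imbalance between the two class errors (driving
#' |sensitivity - specificity| towards zero). Both terms are squared so that
#' positive and negative contributions cannot cancel. The loss is
#' differentiable in the scores everywhere, so it can drive backpropagation
#' directly on sigmoid outputs.
#'
#' @inheritParams loss_pmse
#' @param a Non-negative coefficient of the sum term. Default 0.5.
#' @param b Non-negative coefficient of the difference (balance) term.
#'   Default 1.0, deliberately larger than `a` so that a gap between the two
#'   class errors is punished harder than their common level.
#' @return A single non-negative number.
#' @examples
#' # hard predictions: 12/20 positives right, 78/80 negatives right
#' s <- c(rep(1, 12), rep(0, 8), rep(1, 2), rep(0, 78))
#' y <- c(rep(1, 20), rep(0, 80))
#' loss_clf(s, y)  # 0.2309375
#' @export
loss_clf <- function(scores, labels, a = 0.5, b = 1,
                     missing_class = c("error", "zero")) {
  check_scalar(a, "a", min = 0)
  check_scalar(b, "b", min = 0)
  if (a + b <= 0) {
    abort("At least one of `a`, `b` must be positive.",
          class = "melbalance_invalid_input")
  }
  missing_class <- match.arg(missing_class)
  p <- loss_pmse(scores, labels, missing_class = missing_class)
  n <- loss_nmse(scores, labels, missing_class = missing_class)
  a * (p + n)^2 + b * (p - n)^2
}

#' Binary cross-entropy and focal loss (baseline losses)
#'
#' Standard baselines used by the ORI/BON comparison scenarios. Scores are
#' clipped to `[eps, 1 - eps]` before taking logarithms.
#'
#' @inheritParams loss_mse
#' @param eps Clipping epsilon, default `1e-7`.
#' @param gamma Focusing exponent of the focal loss; `gamma = 0` reduces it to
#'   alpha-weighted cross-entropy.
#' @param alpha Weight of the positive class in the focal loss.
#' @return A single non-negative number.
#' @export
loss_bce <- function(scores, labels, eps = 1e-7) {
  check_batch(scores, labels)
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(s) + (1 - labels) * log(1 - s))
}

#' @rdname loss_bce
#' @export
loss_focal <- function(scores, labels, gamma = 2, alpha = 0.25, eps = 1e-7) {
  check_batch(scores, labels)
  check_scalar(gamma, "gamma", min = 0)
  check_scalar(alpha, "alpha", min = 0, max = 1)
  s <- pmin(pmax(scores, eps), 1 - eps)
  pt <- labels * s + (1 - labels) * (1 - s)
  at <- labels * alpha + (1 - labels) * (1 - alpha)
  -mean(at * (1 - pt)^gamma * log(pt))
}

#' All four losses of one batch as a tibble
#'
#' @inheritParams loss_clf
#' @return A one-row tibble with columns `mse`, `pmse`, `nmse`, `clf`.
#' @export
classwise_losses <- function(scores, labels, a = 0.5, b = 1,
                             missing_class = c("error", "zero")) {
  missing_class <- match.arg(missing_class)
  p <- loss_pmse(scores, labels, missing_class = missing_class)
  n <- loss_nmse(scores, labels, missing_class = missing_class)
  tibble(
    mse  = loss_mse(scores, labels),
    pmse = p,
    nmse = n,
    clf  = a * (p + n)^2 + b * (p - n)^2
  )
}

#' Class-wise losses from hard confusion counts
#'
#' The closed form of the loss family on hard 0/1 predictions: with P = tp +
#' fn positives and N = tn + fp negatives, `pmse = fn / P`, `nmse = fp / N`,
#' `mse = (fn + fp) / (P + N)`, and `clf` by its defining formula. The result
#' is bit-identical to applying [loss_clf()] to the corresponding batch of
#' hard scores. Vectorised over the counts.
#'
#' @param tp,fp,tn,fn Non-negative integer counts (true/false
#'   positives/negatives). Both classes must be non-empty.
#' @inheritParams loss_clf
#' @return A tibble with one row per confusion matrix and columns `tp`, `fp`,
#'   `tn`, `fn`, `mse`, `pmse`, `nmse`, `clf`, `accuracy`, `sensitivity`,
#'   `specificity`.
#' @examples
#' clf_from_confusion(tp = 12, fp = 2, tn = 78, fn = 8)$clf   # 0.2309375
#' clf_from_confusion(tp = 17, fp = 10, tn = 70, fn = 3)$clf  # 0.0384375
#' @export
clf_from_confusion <- function(tp, fp, tn, fn, a = 0.5, b = 1) {
  counts <- cbind(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.",
          class = "melbalance_invalid_input")
  }
  col <- function(nm) as.vector(counts[, nm])   # single-row-safe, unnamed
  P <- col("tp") + col("fn")
  N <- col("tn") + col("fp")
  if (any(P == 0) || any(N == 0)) {
    abort("Class-wise losses need both classes non-empty (tp + fn > 0 and tn + fp > 0).",
          class = "melbalance_invalid_input")
  }
  check_scalar(a, "a", min = 0)
  check_scalar(b, "b", min = 0)
  pmse <- col("fn") / P
  nmse <- col("fp") / N
  tibble(
    tp = as.integer(col("tp")), fp = as.integer(col("fp")),
    tn = as.integer(col("tn")), fn = as.integer(col("fn")),
    mse = (col("fn") + col("fp")) / (P + N),
    pmse = pmse, nmse = nmse,
    clf = a * (pmse + nmse)^2 + b * (pmse - nmse)^2,
    accuracy = (col("tp") + col("tn")) / (P + N),
    sensitivity = col("tp") / P,
    specificity = col("tn") / N
  )
}

#' Gradient of a training loss with respect to the scores
#'
#' Analytic `dL/dscores` for the losses used in training; verified against
#' central finite differences in the test suite.
#'
#' @inheritParams loss_clf
#' @param loss One of `"mse"`, `"clf"`, `"bce"`, `"focal"`.
#' @param params List of loss parameters (`a`, `b` for clf; `gamma`, `alpha`,
#'   `eps` for focal; `eps` for bce).
#' @return Numeric vector of the same length as `scores`.
#' @export
loss_grad <- function(scores, labels, loss = c("clf", "mse", "bce", "focal"),
                      params = list(), missing_class = c("error", "zero")) {
  check_batch(scores, labels)
  loss <- match.arg(loss)
  missing_class <- match.arg(missing_class)
  M <- length(scores)
  switch(loss,
    mse = 2 * (scores - labels) / M,
    clf = {
      a <- params$a %||% 0.5
      b <- params$b %||% 1
      pos <- labels == 1
      P <- sum(pos); N <- M - P
      p_ok <- !handle_missing_class(P, "positive", missing_class)
      n_ok <- !handle_missing_class(N, "negative", missing_class)
      p <- if (p_ok) mean((1 - scores[pos])^2) else 0
      n <- if (n_ok) mean(scores[!pos]^2) else 0
      dp <- 2 * a * (p + n) + 2 * b * (p - n)   # d clf / d pmse
      dn <- 2 * a * (p + n) - 2 * b * (p - n)   # d clf / d nmse
      g <- numeric(M)
      if (p_ok) g[pos]  <- dp * (-2 * (1 - scores[pos]) / P)
      if (n_ok) g[!pos] <- dn * (2 * scores[!pos] / N)
      g
    },
    bce = {
      eps <- params$eps %||% 1e-7
      s <- pmin(pmax(scores, eps), 1 - eps)
      g <- (s - labels) / (s * (1 - s)) / M
      g[scores < eps | scores > 1 - eps] <- 0  # flat where clipped
      g
    },
    focal = {
      gamma <- params$gamma %||% 2
      alpha <- params$alpha %||% 0.25
      eps <- params$eps %||% 1e-7
      s <- pmin(pmax(scores, eps), 1 - eps)
      pt <- labels * s + (1 - labels) * (1 - s)
      at <- labels * alpha + (1 - labels) * (1 - alpha)
      dpt <- -at * (-gamma * (1 - pt)^(gamma - 1) * log(pt) + (1 - pt)^gamma / pt)
      g <- dpt * (2 * labels - 1) / M
      g[scores < eps | scores > 1 - eps] <- 0
      g
    }
  )
}

# internal dispatcher used by the training loop
batch_loss <- function(scores, labels, loss, params = list(),
                       missing_class = "zero") {
  switch(loss,
    mse   = loss_mse(scores, labels),
    clf   = loss_clf(scores, labels, a = params$a %||% 0.5,
                     b = params$b %||% 1, missing_class = missing_class),
    bce   = loss_bce(scores, labels, eps = params$eps %||% 1e-7),
    focal = loss_focal(scores, labels, gamma = params$gamma %||% 2,
                       alpha = params$alpha %||% 0.25,
                       eps = params$eps %||% 1e-7),
    abort(sprintf("Unknown loss '%s'.", loss), class = "melbalance_invalid_input")
  )
}
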