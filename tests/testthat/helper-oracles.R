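# Independent oracles and small fixture builders used across the suite.

# brute-force AUC: pairwise concordance with half credit for ties
auc_pairwise <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive sensitivity/specificity at a threshold (pred positive iff >=)
sen_spe_brute <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  c(sen = sum(pred & labels == 1) / sum(labels == 1),
    spe = sum(!pred & labels == 0) / sum(labels == 0))
}

# enumerate all candidate thresholds for sweep/balance oracles
candidate_thresholds <- function(scores) c(Inf, sort(unique(scores), decreasing = TRUE))

# random scored batch with both classes present
random_batch <- function(n = NULL) {
  n <- n %||% sample(4:40, 1)
  labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
  list(scores = runif(n), labels = labels)
}

# random valid confusion counts with both classes non-empty
random_confusion <- function() {
  P <- sample(1:30, 1); N <- sample(1:60, 1)
  tp <- sample(0:P, 1); tn <- sample(0:N, 1)
  list(tp = tp, fn = P - tp, tn = tn, fp = N - tn)
}

# hard 0/1 score batch matching a confusion matrix
batch_from_confusion <- function(cc) {
  list(scores = c(rep(1, cc$tp), rep(0, cc$fn), rep(1, cc$fp), rep(0, cc$tn)),
       labels = c(rep(1, cc$tp + cc$fn), rep(0, cc$fp + cc$tn)))
}

# tiny deterministic test image: smooth gradient + one dark disc
toy_image <- function(h = 48, w = 64) {
  x <- matrix(rep(seq_len(w), each = h), h, w) / w
  y <- matrix(rep(seq_len(h), times = w), h, w) / h
  disc <- ((x - 0.5)^2 + (y - 0.5)^2) < 0.04
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- pmin(pmax(0.3 + 0.4 * x + 0.1 * y - 0.35 * disc, 0), 1)
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a
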