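# Fixed-class-ratio mini-batch sampling.
#
# Naive shuffling of an imbalanced dataset produces batches whose minority
# count fluctuates (often to zero), which starves the class-wise loss of
# positive examples. The fixed-ratio sampler pins the number of positives
# (NPI) and negatives (NNI) in every batch: negatives are a shuffled
# partition of the majority class (one full pass per epoch), positives are
# drawn from an independently shuffled cycling stream so each minority
# example is used equally often.

#' Fixed-ratio batch composition rule
#'
#' @param batch_size Number of images per mini-batch. Default 32.
#' @param positive_fraction Target fraction of positives per batch, in
#'   (0, 1). `round(positive_fraction * batch_size)` positives are placed in
#'   every batch; the result must be between 1 and `batch_size - 1`. A
#'   common choice is the training-set prevalence (keeps batch composition
#'   equal to the dataset's), or 0.5 for fully balanced batches.
#' @param seed Optional integer seed used by [make_epoch()] when no explicit
#'   seed is passed there.
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(batch_size = 32, positive_fraction, seed = NULL) {
  check_count(batch_size, "batch_size", min = 2L)
  check_scalar(positive_fraction, "positive_fraction")
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    abort("`positive_fraction` must lie strictly between 0 and 1.",
          class = "melbalance_invalid_input")
  }
  n_pos <- as.integer(round(positive_fraction * batch_size))
  if (n_pos < 1L || n_pos > batch_size - 1L) {
    abort(sprintf(
      "round(positive_fraction * batch_size) = %d must be in [1, %d].",
      n_pos, batch_size - 1L), class = "melbalance_invalid_input")
  }
  structure(
    list(batch_size = as.integer(batch_size),
         positive_fraction = positive_fraction,
         n_pos = n_pos, n_neg = as.integer(batch_size) - n_pos,
         seed = seed),
    class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> batch_size=%d, %d positives + %d negatives per batch\n",
              x$batch_size, x$n_pos, x$n_neg))
  invisible(x)
}

new_epoch_schedule <- function(batch, index, label, batch_size, n_pos, kind) {
  structure(
    tibble(batch = as.integer(batch), index = as.integer(index),
           label = as.integer(label)),
    class = c("epoch_schedule", class(tibble())),
    batch_size = batch_size, n_pos = n_pos, kind = kind)
}

#' Build one epoch of fixed-ratio mini-batches
#'
#' Negatives are partitioned by a single shuffle and consumed exactly once;
#' the epoch length is `floor(n_negatives / negatives_per_batch)` (a short
#' final batch would break the ratio and is dropped). Positives come from a
#' cycling stream that is reshuffled on exhaustion, so across the epoch each
#' positive is drawn either `floor(k)` or `ceiling(k)` times, with
#' `k = n_batches * n_pos / n_positives`.
#'
#' @param labels Vector of 0/1 labels of the training set.
#' @param plan A [sampling_plan()].
#' @param seed Integer seed; `NULL` uses `plan$seed`, and if that is also
#'   `NULL` the current RNG stream (so a caller can manage determinism).
#' @return An `epoch_schedule`: a tibble with columns `batch`, `index`
#'   (1-based position in `labels`) and `label`, ordered by batch.
#' @examples
#' plan <- sampling_plan(32, positive_fraction = 0.25)
#' sched <- make_epoch(rep(c(1, 0), c(20, 80)), plan, seed = 1)
#' dplyr::count(sched, batch, label)
#' @export
make_epoch <- function(labels, plan, seed = NULL) {
  stopifnot(inherits(plan, "sampling_plan"))
  if (!all(labels %in% c(0, 1)) || length(labels) == 0L) {
    abort("`labels` must be a non-empty 0/1 vector.",
          class = "melbalance_invalid_input")
  }
  pos_idx <- which(labels == 1)
  neg_idx <- which(labels == 0)
  if (length(pos_idx) < plan$n_pos) {
    abort(sprintf(
      "Too few positive examples: need at least %d, have %d.",
      plan$n_pos, length(pos_idx)), class = "melbalance_invalid_input")
  }
  if (length(neg_idx) < plan$n_neg) {
    abort(sprintf(
      "Too few negative examples: need at least %d, have %d.",
      plan$n_neg, length(neg_idx)), class = "melbalance_invalid_input")
  }
  seed <- seed %||% plan$seed
  with_seed_maybe(seed, {
    n_batches <- length(neg_idx) %/% plan$n_neg
    negs <- sample(neg_idx)[seq_len(n_batches * plan$n_neg)]
    need <- n_batches * plan$n_pos
    stream <- integer(0)
    while (length(stream) < need) stream <- c(stream, sample(pos_idx))
    poss <- stream[seq_len(need)]
    batch_of_pos <- rep(seq_len(n_batches), each = plan$n_pos)
    batch_of_neg <- rep(seq_len(n_batches), each = plan$n_neg)
    ord <- order(c(batch_of_pos, batch_of_neg))
    all_idx <- c(poss, negs)[ord]
    new_epoch_schedule(
      batch = sort(c(batch_of_pos, batch_of_neg)),
      index = all_idx, label = labels[all_idx],
      batch_size = plan$batch_size, n_pos = plan$n_pos, kind = "fixed_ratio")
  })
}

#' Build one epoch of naive (unconstrained) mini-batches
#'
#' The conventional baseline: a uniform shuffle partitioned into consecutive
#' batches, the last one possibly short. Per-batch class counts are whatever
#' the shuffle produces; with strong imbalance some batches contain no
#' positives at all.
#'
#' @inheritParams make_epoch
#' @param batch_size Number of examples per batch. Default 32.
#' @return An `epoch_schedule` tibble (see [make_epoch()]).
#' @export
naive_epoch <- function(labels, batch_size = 32, seed = NULL) {
  if (length(labels) == 0L || !all(labels %in% c(0, 1))) {
    abort("`labels` must be a non-empty 0/1 vector.",
          class = "melbalance_invalid_input")
  }
  check_count(batch_size, "batch_size", min = 1L)
  with_seed_maybe(seed, {
    idx <- sample(length(labels))
    batch <- rep(seq_len(ceiling(length(idx) / batch_size)),
                 each = batch_size)[seq_along(idx)]
    new_epoch_schedule(batch = batch, index = idx, label = labels[idx],
                       batch_size = as.integer(batch_size), n_pos = NA_integer_,
                       kind = "naive")
  })
}

#' Split an epoch schedule into a list of index vectors
#'
#' @param schedule An `epoch_schedule` from [make_epoch()] or
#'   [naive_epoch()].
#' @return List of integer vectors, one per batch, in epoch order.
#' @export
epoch_batches <- function(schedule) {
  stopifnot(inherits(schedule, "epoch_schedule"))
  unname(split(schedule$index, schedule$batch))
}

#' Write a plain-text dump of an epoch schedule
#'
#' One line per batch: comma-separated dataset indices. Debug aid.
#'
#' @inheritParams epoch_batches
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_schedule <- function(schedule, path) {
  lines <- vapply(epoch_batches(schedule), paste, "", collapse = ",")
  writeLines(lines, path)
  invisible(path)
}
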