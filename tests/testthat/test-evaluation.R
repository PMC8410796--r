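# ROC/AUC, threshold sweeps, balanced operating points, reader comparison.

test_that("sensitivity and specificity follow their defining ratios", {
  cc <- tibble::tibble(tp = 12, fp = 2, tn = 78, fn = 8)
  expect_equal(sensitivity(cc), 0.60)
  expect_equal(specificity(cc), 0.975)
  cc3 <- tibble::tibble(tp = 17, fp = 10, tn = 70, fn = 3)
  expect_equal(specificity(cc3), 0.875)
  expect_equal(sensitivity(tibble::tibble(tp = 5, fp = 0, tn = 1, fn = 0)), 1)
  expect_error(sensitivity(tibble::tibble(tp = 0, fp = 1, tn = 1, fn = 0)),
               class = "melbalance_undefined_metric")
  expect_error(specificity(tibble::tibble(tp = 1, fp = 0, tn = 0, fn = 1)),
               class = "melbalance_undefined_metric")
})

test_that("confusion counts respect the ties-to-positive convention", {
  cc <- confusion_counts(c(0.5, 0.5, 0.4), c(1, 0, 0), threshold = 0.5)
  expect_equal(unlist(cc), c(tp = 1L, fp = 1L, tn = 1L, fn = 0L))
})

test_that("ROC endpoints, monotonicity and hand-computable AUCs", {
  roc <- roc_curve(c(0.9, 0.8, 0.4, 0.3, 0.2), c(1, 1, 1, 0, 0))
  expect_equal(attr(roc, "auc"), 1)
  expect_equal(roc$sen[1], 0); expect_equal(roc$spe[1], 1)
  expect_equal(roc$sen[nrow(roc)], 1); expect_equal(roc$spe[nrow(roc)], 0)
  expect_true(all(diff(roc$sen) >= 0))
  expect_true(all(diff(roc$spe) <= 0))
  # one discordant swap drops exactly one of six pairs
  expect_equal(auc(c(0.9, 0.8, 0.25, 0.3, 0.2), c(1, 1, 1, 0, 0)), 5 / 6)
  expect_error(roc_curve(c(0.1, 0.9), c(1, 1)),
               class = "melbalance_undefined_metric")
})

test_that("trapezoidal AUC equals brute-force pairwise concordance", {
  set.seed(71)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- if (i %% 3 == 0) {
      sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    } else {
      runif(n)
    }
    expect_equal(auc(scores, labels), auc_pairwise(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC at chance level for labels independent of scores", {
  set.seed(72)
  scores <- runif(4000)
  labels <- rep(c(1, 0), 2000)
  expect_lt(abs(auc(scores, labels) - 0.5), 0.03)
})

test_that("AUC and reader comparisons are invariant to monotone score transforms", {
  set.seed(73)
  b <- random_batch(40)
  mono <- function(s) plogis(3 * qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)))
  expect_equal(auc(b$scores, b$labels), auc(mono(b$scores), b$labels),
               tolerance = 1e-12)
  readers <- tibble::tibble(sen = runif(5), spe = runif(5))
  r1 <- readers_outperformed(roc_curve(b$scores, b$labels), readers)
  r2 <- readers_outperformed(roc_curve(mono(b$scores), b$labels), readers)
  expect_equal(r1$status, r2$status)
})

test_that("threshold sweep matches exhaustive enumeration and is recomputable", {
  set.seed(74)
  for (i in 1:15) {
    b <- random_batch(20)
    sen_targets <- c(1, 0.9, 0.75, 0.5)
    spe_targets <- c(1, 0.9, 0.6)
    sw <- threshold_sweep(b$scores, b$labels, sen_targets, spe_targets)
    cand <- candidate_thresholds(b$scores)
    stats <- t(vapply(cand, function(t) sen_spe_brute(b$scores, b$labels, t),
                      c(sen = 0, spe = 0)))
    for (j in seq_len(nrow(sw))) {
      row <- sw[j, ]
      if (row$target_metric == "sen") {
        ok <- which(stats[, "sen"] >= row$target)
        expect_true(length(ok) > 0)           # sen targets always attainable
        best <- ok[1]                          # largest threshold achieving it
      } else {
        ok <- which(stats[, "spe"] >= row$target)
        best <- ok[length(ok)]                 # smallest threshold achieving it
      }
      expect_equal(c(row$sen, row$spe),
                   unname(stats[best, c("sen", "spe")]), tolerance = 1e-12)
      # reported operating point recomputes from raw scores at its threshold
      redo <- sen_spe_brute(b$scores, b$labels, row$threshold)
      expect_equal(c(row$sen, row$spe), unname(redo), tolerance = 1e-12)
    }
  }
})

test_that("sweep handles boundary targets the way the definitions say", {
  b <- list(scores = c(0.9, 0.7, 0.6, 0.4, 0.3, 0.2),
            labels = c(1, 1, 0, 1, 0, 0))
  sw <- threshold_sweep(b$scores, b$labels, sen_targets = 1, spe_targets = 1)
  sen_row <- sw[sw$target_metric == "sen", ]
  # sen = 1 needs threshold at or below the lowest positive score (0.4);
  # spe there = fraction of negatives below 0.4 = 2/3
  expect_equal(sen_row$threshold, 0.4)
  expect_equal(sen_row$spe, 2 / 3)
  # perfectly separated toy scores: everything attainable with spe 1
  sep <- threshold_sweep(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                         sen_targets = c(1, 0.5), spe_targets = 1)
  expect_true(all(sep$attained))
  expect_true(all(sep$spe[sep$target_metric == "sen"] == 1))
})

test_that("balanced thresholds optimise their criteria with declared tie-breaks", {
  set.seed(75)
  for (i in 1:15) {
    b <- random_batch(25)
    cand <- candidate_thresholds(b$scores)
    stats <- t(vapply(cand, function(t) sen_spe_brute(b$scores, b$labels, t),
                      c(sen = 0, spe = 0)))
    thr_f <- ifelse(is.finite(cand), cand, 1)
    # min_gap oracle with tie-breaks: larger sen+spe, then larger threshold
    gap <- abs(stats[, "sen"] - stats[, "spe"])
    ssum <- stats[, "sen"] + stats[, "spe"]
    ord <- order(gap, -ssum, -thr_f)
    bt <- balanced_threshold(b$scores, b$labels, "min_gap")
    expect_equal(bt$threshold, thr_f[ord[1]])
    expect_equal(c(bt$sen, bt$spe), unname(stats[ord[1], ]), tolerance = 1e-12)
    # youden oracle
    ordy <- order(-(ssum - 1), -thr_f)
    by <- balanced_threshold(b$scores, b$labels, "youden")
    expect_equal(by$threshold, thr_f[ordy[1]])
  }
  # perfectly separated scores: both criteria land on sen = spe = 1
  for (crit in c("min_gap", "youden")) {
    bt <- balanced_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), crit)
    expect_equal(c(bt$sen, bt$spe), c(1, 1))
  }
})

test_that("reader comparison geometry: below, on-curve and above are separated", {
  # staircase curve from hard-ish scores: vertices at known places
  scores <- c(0.9, 0.8, 0.6, 0.4, 0.2)
  labels <- c(1, 1, 0, 1, 0)
  roc <- roc_curve(scores, labels)
  readers <- tibble::tibble(
    group = c("clearly_below", "on_vertex", "above", "far_below", "on_segment"),
    sen = c(0.2, 2 / 3, 0.99, 0.05, 1 / 3),
    spe = c(0.8, 1, 0.9, 0.5, 1))
  out <- readers_outperformed(roc, readers)
  expect_equal(out$status,
               c("below", "on", "above", "below", "on"))
  expect_equal(attr(out, "n_outperformed"), 2L)
  expect_equal(attr(out, "n_on_curve"), 2L)
  # perfect classifier outperforms any imperfect reader
  perfect <- roc_curve(c(0.9, 0.8, 0.1, 0.05), c(1, 1, 0, 0))
  rd <- tibble::tibble(sen = c(0.9, 0.5), spe = c(0.9, 0.99))
  expect_equal(attr(readers_outperformed(perfect, rd), "n_outperformed"), 2L)
})

test_that("the packaged reader fixture loads as proportions", {
  rd <- reader_points()
  expect_equal(nrow(rd), 11L)
  expect_equal(rd$n[1], 157)
  expect_equal(rd$sen[1], 0.741)
  expect_equal(rd$spe[1], 0.60)
  expect_true(all(rd$sen <= 1 & rd$spe <= 1 & rd$auc <= 1))
})

test_that("evaluate_scores bundles a consistent report", {
  set.seed(76)
  d <- generate_scores(30, 120, 0.9)
  rep <- evaluate_scores(d$score, d$label, threshold = 0.5)
  expect_equal(rep$metrics$auc, auc(d$score, d$label))
  cc <- confusion_counts(d$score, d$label, 0.5)
  expect_equal(rep$metrics$sen, sensitivity(cc))
  expect_equal(rep$metrics$spe, specificity(cc))
  expect_s3_class(rep$roc, "mb_roc")
  expect_true(all(c("target_metric", "threshold", "attained") %in%
                    names(rep$sweep)))
  expect_equal(nrow(rep$balanced), 2L)
})
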