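test_that("confusion counts enumerate a hand-built fixture", {
  labels <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 1, 0), c(0, 0, 1))
  preds <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 1, 0), c(1, 0, 1))
  ct <- confusion_counts(preds, labels)
  expect_equal(ct$tp, c(1, 2, 1))
  expect_equal(ct$fp, c(1, 0, 0))
  expect_equal(ct$fn, c(1, 0, 1))
  expect_equal(ct$tn, c(1, 2, 2))
  expect_true(all(ct$tp + ct$tn + ct$fp + ct$fn == 4))

  perfect <- confusion_counts(labels, labels)
  expect_true(all(perfect$fp == 0 & perfect$fn == 0))
  allpos <- confusion_counts(matrix(1, 4, 3), labels)
  expect_true(all(allpos$tn == 0))
})

test_that("metrics from counts handle undefined denominators with flags", {
  ct <- tibble::tibble(class = 0L, tp = 1, tn = 1, fp = 0, fn = 0)
  m <- clf_metrics(ct)
  expect_equal(m$per_class$accuracy, 1)
  expect_equal(m$per_class$f1, 1)

  none <- tibble::tibble(class = 0L, tp = 0, tn = 4, fp = 0, fn = 0)
  m2 <- clf_metrics(none)
  expect_equal(m2$per_class$precision, 0)
  expect_true(m2$per_class$precision_undefined)
  expect_equal(m2$per_class$f1, 0)

  # per-class recomputation matches hand arithmetic on random tables
  withr::with_seed(11, {
    for (i in 1:25) {
      tp <- sample(0:20, 1); tn <- sample(0:20, 1)
      fp <- sample(0:20, 1); fn <- sample(0:20, 1)
      if (tp + tn + fp + fn == 0) next
      m3 <- clf_metrics(tibble::tibble(class = 0L, tp = tp, tn = tn,
                                       fp = fp, fn = fn))$per_class
      expect_equal(m3$accuracy, (tp + tn) / (tp + tn + fp + fn))
      if (tp + fp > 0) expect_equal(m3$precision, tp / (tp + fp))
      if (tp + fn > 0) expect_equal(m3$recall, tp / (tp + fn))
      if (m3$precision + m3$recall > 0) {
        expect_equal(m3$f1, 2 * m3$precision * m3$recall /
                       (m3$precision + m3$recall))
      }
    }
  })
})

test_that("exact-match and balanced accuracy", {
  labels <- rbind(c(1, 0), c(0, 1), c(1, 1))
  expect_equal(exact_match_accuracy(labels, labels), 1)
  one_off <- labels; one_off[1, 2] <- 1
  expect_equal(exact_match_accuracy(one_off, labels), 2 / 3)
  expect_error(exact_match_accuracy(labels[0, , drop = FALSE],
                                    labels[0, , drop = FALSE]), "empty")

  expect_equal(balanced_accuracy(confusion_counts(labels, labels)), 1)
  # random coin on balanced labels is near 0.5
  withr::with_seed(12, {
    y <- matrix(rbinom(4000, 1, 0.5), 2000, 2)
    p <- matrix(rbinom(4000, 1, 0.5), 2000, 2)
    expect_lt(abs(balanced_accuracy(confusion_counts(p, y)) - 0.5), 0.05)
  })
  # invariant to prevalence rescaling (duplicating positives)
  y1 <- matrix(c(rep(1, 5), rep(0, 20)), ncol = 1)
  p1 <- matrix(c(rep(1, 4), 0, rep(0, 15), rep(1, 5)), ncol = 1)
  dup <- rep(seq_len(5), times = 3)
  y2 <- rbind(y1, y1[dup, , drop = FALSE])
  p2 <- rbind(p1, p1[dup, , drop = FALSE])
  expect_equal(balanced_accuracy(confusion_counts(p1, y1)),
               balanced_accuracy(confusion_counts(p2, y2)))
})

test_that("threshold optimization matches an exhaustive oracle", {
  withr::with_seed(13, {
    probs <- matrix(runif(30), 10, 3)
    labels <- matrix(rbinom(30, 1, 0.4), 10, 3)
    labels[, 3] <- 0  # degenerate class
    got <- optimize_thresholds(probs, labels)
    for (kcl in 1:2) {
      cand <- seq(0.25, 0.45, by = 0.01)
      f1s <- vapply(cand, function(th) {
        p <- probs[, kcl] >= th
        tp <- sum(p & labels[, kcl] == 1)
        fp <- sum(p & labels[, kcl] == 0)
        fn <- sum(!p & labels[, kcl] == 1)
        if (tp == 0) return(0)
        pr <- tp / (tp + fp); rc <- tp / (tp + fn)
        2 * pr * rc / (pr + rc)
      }, numeric(1))
      expect_equal(got$threshold[kcl], cand[which.max(f1s)])
      expect_equal(got$f1[kcl], max(f1s))
    }
    expect_true(got$degenerate[3])
    expect_equal(got$threshold[3], 0.35)
  })

  # a separable class resolves ties to the lowest threshold in the gap
  probs <- matrix(c(0.9, 0.9, 0.1, 0.1), ncol = 1)
  labels <- matrix(c(1, 1, 0, 0), ncol = 1)
  expect_equal(optimize_thresholds(probs, labels)$threshold, 0.25)
})

test_that("minority and robustness summaries reproduce printed columns", {
  r <- minority_report(0.762, 0.881)
  expect_equal(round(r$improvement_ratio, 3), 1.156)
  r2 <- minority_report(0.777, 0.896)
  expect_equal(round(r2$improvement_pct, 1), 15.3)
  same <- minority_report(0.8, 0.8)
  expect_equal(same$improvement_ratio, 1)
  expect_equal(same$improvement_pct, 0)

  # published derived columns agree with the recomputation to one unit in
  # the last printed digit
  tab <- reference_table("minority_class")
  ratios <- tab$minority_f1_after / tab$minority_f1_before
  expect_true(all(abs(ratios - tab$improvement_ratio_printed) <=
                    0.001 + 1e-12))
  expect_equal(round(ratios[1], 3), 1.156)

  gm <- reference_table("gan_minority_comparison")
  pct <- 100 * (gm$minority_f1_after - gm$minority_f1_before) /
    gm$minority_f1_before
  expect_true(all(abs(pct - gm$improvement_pct_printed) <= 0.1 + 1e-12))
  expect_equal(round(pct[1], 1), 15.3)

  rb <- robustness_report(6.2, 2.7, 74.8, 86.8)
  expect_equal(round(rb$gap_reduction_pct, 1), 56.5)
  expect_equal(round(rb$cross_improvement_pct, 1), 16.0)
  flat <- robustness_report(5, 5, 70, 70)
  expect_equal(flat$gap_reduction_pct, 0)
  expect_equal(flat$robustness_score, 1)

  rt <- reference_table("robustness")
  scores <- rt$cross_after / rt$cross_before
  # the printed column matches the after/before ratio for 9 of 10 models
  # (one printed value is off by 0.001 at 3 d.p.)
  expect_gte(sum(round(scores, 3) == rt$robustness_score_printed), 9)

  cb <- reference_table("classification_before_after")
  expect_equal(round(mean(cb$accuracy_before), 1), 85.2)
  expect_equal(round(mean(cb$accuracy_after), 1), 92.6)
  expect_equal(round(mean(cb$f1_before), 3), 0.847)
  expect_equal(round(mean(cb$f1_after), 3), 0.922)
})

test_that("the toy augmentation experiment is deterministic end-to-end", {
  scenes <- generate_scene_set(60, 16, 16, seed = 47)
  cfg <- list(epochs = 8L, hidden = 16L, lr = 3e-3, batch = 16L)
  tx <- toy_experiment(scenes, simulator_augmenter(16, 16),
                       classifier_cfg = cfg, seed = 3)
  expect_named(tx, c("before", "after", "minority_classes",
                     "minority_comparison"))
  expect_identical(names(tx$before$summary), names(tx$after$summary))
  expect_true(all(is.finite(unlist(tx$before$summary))))
  expect_gte(tx$before$exact_match, 0)

  tx2 <- toy_experiment(scenes, simulator_augmenter(16, 16),
                        classifier_cfg = cfg, seed = 3)
  expect_equal(tx$before$summary, tx2$before$summary)
  expect_equal(tx$after$summary, tx2$after$summary)
})
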