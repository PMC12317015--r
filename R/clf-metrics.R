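# Multi-label classification metrics (per-class confusion arithmetic,
# exact-match and balanced accuracy, threshold optimization), the
# minority-class and robustness summaries, and a toy before/after
# augmentation experiment with a small dense classifier.

#' Apply per-class decision thresholds
#'
#' @param probs `n x K` matrix of class probabilities.
#' @param thresholds scalar or length-`K` vector (default 0.35).
#' @return binary `n x K` prediction matrix.
#' @export
apply_thresholds <- function(probs, thresholds = 0.35) {
  probs <- as.matrix(probs)
  th <- if (length(thresholds) == 1L) rep(thresholds, ncol(probs)) else
    thresholds
  stopifnot(length(th) == ncol(probs))
  (probs >= matrix(th, nrow(probs), ncol(probs), byrow = TRUE)) * 1L
}

#' Per-class confusion counts
#'
#' @param preds,labels binary `n x K` matrices.
#' @return tibble with `class` (0-based), `tp`, `tn`, `fp`, `fn`; counts sum
#'   to `n` per class.
#' @export
confusion_counts <- function(preds, labels) {
  preds <- as.matrix(preds); labels <- as.matrix(labels)
  stopifnot(identical(dim(preds), dim(labels)),
            all(preds %in% c(0, 1)), all(labels %in% c(0, 1)))
  tibble::tibble(
    class = seq_len(ncol(preds)) - 1L,
    tp = colSums(preds == 1 & labels == 1),
    tn = colSums(preds == 0 & labels == 0),
    fp = colSums(preds == 1 & labels == 0),
    fn = colSums(preds == 0 & labels == 1))
}

safe_ratio <- function(num, den) {
  list(value = ifelse(den > 0, num / ifelse(den > 0, den, 1), 0),
       undefined = den == 0)
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, and the F1 harmonic mean, per class plus macro and micro
#' averages. Zero-denominator cases return 0 and are flagged in the
#' `*_undefined` columns rather than propagating NaN.
#'
#' @param counts tibble from [confusion_counts()].
#' @return list with `per_class` tibble and one-row `summary` tibble
#'   (macro/micro averages).
#' @export
clf_metrics <- function(counts) {
  acc <- (counts$tp + counts$tn) /
    (counts$tp + counts$tn + counts$fp + counts$fn)
  prec <- safe_ratio(counts$tp, counts$tp + counts$fp)
  rec <- safe_ratio(counts$tp, counts$tp + counts$fn)
  f1 <- purrr::map2_dbl(prec$value, rec$value, f1_score)
  per_class <- tibble::tibble(
    class = counts$class, accuracy = acc,
    precision = prec$value, precision_undefined = prec$undefined,
    recall = rec$value, recall_undefined = rec$undefined,
    f1 = f1)
  tp <- sum(counts$tp); tn <- sum(counts$tn)
  fp <- sum(counts$fp); fn <- sum(counts$fn)
  micro_p <- if (tp + fp > 0) tp / (tp + fp) else 0
  micro_r <- if (tp + fn > 0) tp / (tp + fn) else 0
  summary <- tibble::tibble(
    macro_accuracy = mean(acc), macro_precision = mean(prec$value),
    macro_recall = mean(rec$value), macro_f1 = mean(f1),
    micro_precision = micro_p, micro_recall = micro_r,
    micro_f1 = f1_score(micro_p, micro_r))
  list(per_class = per_class, summary = summary)
}

#' Exact-match (subset) accuracy
#'
#' Fraction of samples whose full predicted label vector matches the
#' ground truth.
#'
#' @param preds,labels binary `n x K` matrices.
#' @return scalar in `[0, 1]`.
#' @export
exact_match_accuracy <- function(preds, labels) {
  preds <- as.matrix(preds); labels <- as.matrix(labels)
  stopifnot(identical(dim(preds), dim(labels)))
  if (nrow(preds) == 0L) stop("prediction set is empty")
  mean(rowSums(preds != labels) == 0L)
}

#' Balanced accuracy
#'
#' Mean over classes of `(TPR + TNR) / 2`, giving every localization class
#' equal weight regardless of prevalence. Classes with an undefined rate
#' (no positives or no negatives) contribute the defined rate only.
#'
#' @param counts tibble from [confusion_counts()].
#' @return scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(counts) {
  per_class <- vapply(seq_len(nrow(counts)), function(i) {
    tpr <- if (counts$tp[i] + counts$fn[i] > 0) {
      counts$tp[i] / (counts$tp[i] + counts$fn[i])
    } else NA_real_
    tnr <- if (counts$tn[i] + counts$fp[i] > 0) {
      counts$tn[i] / (counts$tn[i] + counts$fp[i])
    } else NA_real_
    mean(c(tpr, tnr), na.rm = TRUE)
  }, numeric(1))
  mean(per_class, na.rm = TRUE)
}

#' Optimize per-class decision thresholds
#'
#' Grid search maximizing per-class F1 on the supplied (validation) set over
#' `[0.25, 0.45]` in steps of `grid`; ties resolve to the lowest threshold.
#' Classes without positive labels keep the 0.35 default and are flagged.
#'
#' @param probs,labels `n x K` probability and binary label matrices.
#' @param range search range (default `c(0.25, 0.45)`).
#' @param grid step size (default 0.01).
#' @param default fallback threshold for degenerate classes.
#' @return tibble with `class`, `threshold`, `f1`, `degenerate`.
#' @export
optimize_thresholds <- function(probs, labels, range = c(0.25, 0.45),
                                grid = 0.01, default = 0.35) {
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  stopifnot(identical(dim(probs), dim(labels)))
  cand <- seq(range[1], range[2], by = grid)
  rows <- lapply(seq_len(ncol(probs)), function(kcl) {
    y <- labels[, kcl]
    if (sum(y) == 0) {
      return(tibble::tibble(class = kcl - 1L, threshold = default,
                            f1 = 0, degenerate = TRUE))
    }
    f1s <- vapply(cand, function(th) {
      p <- probs[, kcl] >= th
      tp <- sum(p & y == 1); fp <- sum(p & y == 0); fn <- sum(!p & y == 1)
      pr <- if (tp + fp > 0) tp / (tp + fp) else 0
      rc <- if (tp + fn > 0) tp / (tp + fn) else 0
      f1_score(pr, rc)
    }, numeric(1))
    best <- which.max(f1s)  # which.max returns the first (lowest) maximizer
    tibble::tibble(class = kcl - 1L, threshold = cand[best],
                   f1 = f1s[best], degenerate = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Minority-class improvement summary
#'
#' `improvement_ratio = F1_after / F1_before` and
#' `improvement_pct = 100 * (F1_after - F1_before) / F1_before`, evaluated
#' on minority-class F1 scores.
#'
#' @param f1_before,f1_after minority-class F1 values (scalars).
#' @return list with `improvement_ratio` and `improvement_pct`.
#' @export
minority_report <- function(f1_before, f1_after) {
  stopifnot(f1_before > 0)
  list(improvement_ratio = f1_after / f1_before,
       improvement_pct = 100 * (f1_after - f1_before) / f1_before)
}

#' Robustness and generalization summary
#'
#' From validation-test gaps and cross-dataset performance before/after
#' augmentation: `gap_reduction_pct = 100 * (gap_before - gap_after) /
#' gap_before`, `cross_improvement_pct = 100 * (cross_after - cross_before)
#' / cross_before`, and `robustness_score = cross_after / cross_before`.
#'
#' @param gap_before,gap_after validation-test gaps (percentage points).
#' @param cross_before,cross_after cross-dataset performance (percent).
#' @return list with the three summaries.
#' @export
robustness_report <- function(gap_before, gap_after, cross_before,
                              cross_after) {
  stopifnot(gap_before > 0, cross_before > 0)
  list(gap_reduction_pct = 100 * (gap_before - gap_after) / gap_before,
       cross_improvement_pct = 100 * (cross_after - cross_before) /
         cross_before,
       robustness_score = cross_after / cross_before)
}

scene_class_id <- function(scene) which(scene$class_labels == 1L)[1L] - 1L

stratified_split <- function(class_ids, fracs = c(0.7, 0.15, 0.15)) {
  split_ids <- rep(1L, length(class_ids))
  for (cl in unique(class_ids)) {
    idx <- which(class_ids == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_tr <- max(1L, round(fracs[1] * n))
    n_va <- max(0L, min(round(fracs[2] * n), n - n_tr))
    split_ids[idx[seq_len(n_tr)]] <- 1L
    if (n_va > 0) split_ids[idx[n_tr + seq_len(n_va)]] <- 2L
    rest <- idx[setdiff(seq_len(n), seq_len(n_tr + n_va))]
    split_ids[rest] <- 3L
  }
  split_ids
}

train_toy_classifier <- function(x, y, cfg) {
  net <- mlp_init(c(ncol(x), cfg$hidden, ncol(y)))
  opt <- adam_init(net)
  t_step <- 0L
  n <- nrow(x)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    for (b in seq_len(max(1L, floor(n / cfg$batch)))) {
      bi <- perm[((b - 1L) * cfg$batch + 1L):min(b * cfg$batch, n)]
      fw <- mlp_forward(net, x[bi, , drop = FALSE])
      p <- clamp_prob(fw$out)
      # binary cross-entropy; gradient w.r.t. sigmoid output
      d_out <- (p - y[bi, , drop = FALSE]) / (p * (1 - p)) /
        length(bi) / ncol(y)
      bg <- mlp_backward(net, fw$cache, d_out)
      t_step <- t_step + 1L
      upd <- adam_update(net, bg$grads, opt, cfg$lr, t_step,
                         beta1 = 0.9, beta2 = 0.999, l2 = 1e-5,
                         clip_norm = 5)
      net <- upd$net; opt <- upd$opt
    }
  }
  net
}

classifier_report <- function(net, x, y, thresholds = 0.35) {
  probs <- mlp_forward(net, x)$out
  if (is.null(thresholds)) thresholds <- 0.35
  preds <- apply_thresholds(probs, thresholds)
  counts <- confusion_counts(preds, y)
  m <- clf_metrics(counts)
  list(counts = counts, per_class = m$per_class, summary = m$summary,
       exact_match = exact_match_accuracy(preds, y),
       balanced_accuracy = balanced_accuracy(counts),
       probs = probs)
}

#' Toy before/after augmentation experiment
#'
#' Trains a small dense multi-label classifier on embedded scene features
#' twice with identical seeds and configuration: once on the original
#' training split and once with minority classes topped up by synthetic
#' samples from `augmenter`. Scenes are split 70/15/15 stratified by class;
#' per-class decision thresholds are tuned on the validation split. Minority
#' classes are those with fewer training samples than half the largest
#' class count.
#'
#' @param scenes list of `cell_scene` objects.
#' @param augmenter `function(class_id, n, seed) -> list of images`
#'   producing synthetic samples of the requested class (for example the
#'   simulator, or a wrapper around [dg_sample()]).
#' @param classifier_cfg list with `epochs`, `hidden`, `lr`, `batch`.
#' @param embedder feature embedder.
#' @param seed integer seed controlling split, initialization and batching
#'   identically for both runs.
#' @return list with `before` and `after` classifier reports, the
#'   `minority_classes`, and the [minority_report()] comparison of macro F1
#'   on minority classes.
#' @export
toy_experiment <- function(scenes, augmenter,
                           classifier_cfg = list(epochs = 60L, hidden = 64L,
                                                 lr = 3e-3, batch = 16L),
                           embedder = default_embedder(), seed = 1L) {
  class_ids <- vapply(scenes, scene_class_id, numeric(1))
  emb <- embed_images(lapply(scenes, function(s) s$image), embedder)
  y_all <- t(vapply(scenes, function(s) as.numeric(s$class_labels),
                    numeric(19L)))
  withr::with_seed(seed, {
    split_ids <- stratified_split(class_ids)
    tr <- split_ids == 1L; te <- split_ids == 3L
    if (!any(te)) te <- split_ids == 2L

    counts <- table(factor(class_ids[tr], levels = 0:18))
    minority <- as.integer(names(counts))[counts > 0 &
                                            counts < max(counts) / 2]

    va <- split_ids == 2L
    run <- function(x, y, run_seed) {
      withr::with_seed(run_seed, {
        net <- train_toy_classifier(x, y, classifier_cfg)
        # per-class decision thresholds tuned on the validation split
        th <- if (any(va)) {
          optimize_thresholds(mlp_forward(net, emb[va, , drop = FALSE])$out,
                              y_all[va, , drop = FALSE])$threshold
        } else 0.35
        classifier_report(net, emb[te, , drop = FALSE],
                          y_all[te, , drop = FALSE], thresholds = th)
      })
    }
    before <- run(emb[tr, , drop = FALSE], y_all[tr, , drop = FALSE],
                  seed + 1L)

    aug_x <- list(); aug_y <- list()
    if (length(minority) > 0) {
      target <- max(counts)
      for (cl in minority) {
        need <- min(target - counts[[as.character(cl)]], 2L * target)
        imgs <- augmenter(cl, need, seed + cl)
        aug_x[[length(aug_x) + 1L]] <- embed_images(imgs, embedder)
        yv <- numeric(19L); yv[cl + 1L] <- 1
        aug_y[[length(aug_y) + 1L]] <-
          matrix(yv, nrow = length(imgs), ncol = 19L, byrow = TRUE)
      }
    }
    x_aug <- rbind(emb[tr, , drop = FALSE], do.call(rbind, aug_x))
    y_aug <- rbind(y_all[tr, , drop = FALSE], do.call(rbind, aug_y))
    after <- run(x_aug, y_aug, seed + 1L)

    min_f1 <- function(rep) {
      f <- rep$per_class$f1[rep$per_class$class %in% minority]
      if (length(f) == 0) NA_real_ else mean(f)
    }
    cmp <- if (length(minority) > 0 && min_f1(before) > 0) {
      minority_report(min_f1(before), min_f1(after))
    } else NULL
    list(before = before, after = after, minority_classes = minority,
         minority_comparison = cmp)
  })
}

#' Simulator-backed augmenter
#'
#' Default augmentation source for [toy_experiment()]: renders synthetic
#' scenes of the requested class with the simulator.
#'
#' @param height,width scene size.
#' @return `function(class_id, n, seed) -> list of images`.
#' @export
simulator_augmenter <- function(height = 32L, width = 32L) {
  function(class_id, n, seed) {
    lapply(seq_len(n), function(i) {
      generate_scene(scene_spec(height, width, localization_class = class_id,
                                seed = as.integer(
                                  (as.numeric(seed) * 7919 + i) %%
                                    2147483647)))$image
    })
  }
}
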