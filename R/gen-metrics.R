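# Generative evaluation stack: analytic feature embedding, FID, Inception
# Score, SSIM / PSNR, MS-SSIM diversity, k-NN generative precision/recall,
# and the combined quality-diversity scoring with min-max normalization.

#' Analytic feature embedder
#'
#' Deterministic image embedding used in place of a learned feature
#' extractor: each channel is block-averaged to 8x8 and a 16-bin intensity
#' histogram (density-normalized) is appended, giving a fixed-length vector
#' (320 for 4-channel images). A learned embedder can be substituted
#' anywhere a `function(image) -> numeric` is accepted.
#'
#' @param pool_size block-pooling grid side (default 8).
#' @param bins histogram bins (default 16).
#' @return embedding `function(image) -> numeric vector`.
#' @export
default_embedder <- function(pool_size = 8L, bins = 16L) {
  function(image) {
    arr <- as_channel_array(image)
    h <- dim(arr)[1L]; w <- dim(arr)[2L]
    rb <- floor((seq_len(h) - 1L) / h * pool_size)
    cb <- floor((seq_len(w) - 1L) / w * pool_size)
    feats <- c()
    for (ch in seq_len(dim(arr)[3L])) {
      m <- arr[, , ch]
      pooled <- tapply(c(m), list(rb[row(m)], cb[col(m)]), mean)
      hist_ <- tabulate(pmin(floor(clip01(c(m)) * bins) + 1L, bins), bins) /
        length(m)
      feats <- c(feats, as.numeric(pooled), hist_)
    }
    feats
  }
}

#' Embed a set of images
#'
#' @param images list of images.
#' @param embedder embedding function (default [default_embedder()]).
#' @param center,scale optional standardization vectors (for example the
#'   real set's feature means/sds) applied to every embedding.
#' @return numeric matrix, one row per image.
#' @export
embed_images <- function(images, embedder = default_embedder(),
                         center = NULL, scale = NULL) {
  m <- t(vapply(images, embedder, embedder(images[[1L]])))
  if (!is.null(center)) m <- sweep(m, 2L, center, `-`)
  if (!is.null(scale)) {
    # floor the per-feature sd so near-constant reference features do not
    # blow up standardized coordinates; the default embedder's features all
    # live in [0, 1], for which 0.01 is a negligible spread
    m <- sweep(m, 2L, pmax(scale, 0.01), `/`)
  }
  m
}

sqrtm_sym <- function(sigma, jitter = 1e-6) {
  e <- eigen(sigma + jitter * diag(nrow(sigma)), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Frechet distance between Gaussian feature summaries
#'
#' `FID = ||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^(1/2))`, the matrix
#' square root computed by symmetric eigendecomposition with a `1e-6`
#' diagonal jitter; the result is clamped at 0 against numerical noise.
#'
#' @param mu_r,mu_g mean vectors.
#' @param sigma_r,sigma_g covariance matrices.
#' @return nonnegative scalar.
#' @export
fid_from_stats <- function(mu_r, sigma_r, mu_g, sigma_g) {
  if (length(mu_r) != length(mu_g)) stop("feature dimensions differ")
  sigma_r <- as.matrix(sigma_r); sigma_g <- as.matrix(sigma_g)
  s_r_half <- sqrtm_sym(sigma_r)
  inner <- s_r_half %*% sigma_g %*% s_r_half
  tr_sqrt <- sum(sqrt(pmax(eigen(inner, symmetric = TRUE,
                                 only.values = TRUE)$values, 0)))
  val <- sum((mu_r - mu_g)^2) + sum(diag(sigma_r)) + sum(diag(sigma_g)) -
    2 * tr_sqrt
  max(val, 0)
}

#' Frechet Inception Distance between two feature sets
#'
#' Fits a Gaussian to each feature set (sample mean and covariance) and
#' computes the Frechet distance between them; 0 for identical sets, lower
#' is better.
#'
#' @param feats_real,feats_gen numeric matrices, one row per sample (at
#'   least 2 rows each).
#' @return nonnegative scalar.
#' @export
fid <- function(feats_real, feats_gen) {
  feats_real <- as.matrix(feats_real); feats_gen <- as.matrix(feats_gen)
  if (ncol(feats_real) != ncol(feats_gen)) stop("feature dimensions differ")
  if (nrow(feats_real) < 2L || nrow(feats_gen) < 2L) {
    stop("need at least 2 samples per set")
  }
  fid_from_stats(colMeans(feats_real), stats::cov(feats_real),
                 colMeans(feats_gen), stats::cov(feats_gen))
}

#' Inception Score from class posteriors
#'
#' `IS = exp(mean_i KL(p(y | x_i) || p(y)))` with `p(y)` the marginal
#' (column mean); natural logarithms. Bounded between 1 (all posteriors
#' identical) and the number of classes K (confident, uniformly spread
#' one-hot posteriors).
#'
#' @param class_probs `n x K` matrix of class posteriors; rows must sum
#'   to 1.
#' @return scalar in `[1, K]`.
#' @export
inception_score <- function(class_probs) {
  class_probs <- as.matrix(class_probs)
  if (any(class_probs < -1e-12) ||
      any(abs(rowSums(class_probs) - 1) > 1e-6)) {
    stop("rows of class_probs must be probability distributions")
  }
  p_y <- colMeans(class_probs)
  kl <- apply(class_probs, 1L, function(p) {
    nz <- p > 0
    sum(p[nz] * (log(p[nz]) - log(pmax(p_y[nz], 1e-300))))
  })
  exp(mean(kl))
}

ssim_window <- function(x, y, c1, c2) {
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Structural similarity index
#'
#' Standard SSIM (luminance/contrast/structure form) averaged over
#' non-overlapping `window x window` tiles, with population moments and
#' stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for dynamic range `L`.
#' Multi-channel images are averaged over channels. `ssim(x, x) = 1`.
#'
#' @param x,y images of identical shape, values in `[0, max_val]`.
#' @param window tile side (default 8).
#' @param max_val dynamic range (default 1).
#' @return scalar, at most 1.
#' @export
ssim <- function(x, y, window = 8L, max_val = 1) {
  stop_if_shape_mismatch(x, y)
  ax <- as_channel_array(x); ay <- as_channel_array(y)
  c1 <- (0.01 * max_val)^2; c2 <- (0.03 * max_val)^2
  h <- dim(ax)[1L]; w <- dim(ax)[2L]
  rs <- split(seq_len(h), ceiling(seq_len(h) / window))
  cs <- split(seq_len(w), ceiling(seq_len(w) / window))
  vals <- c()
  for (ch in seq_len(dim(ax)[3L])) {
    for (rr in rs) for (cc in cs) {
      vals <- c(vals, ssim_window(ax[rr, cc, ch], ay[rr, cc, ch], c1, c2))
    }
  }
  mean(vals)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_val^2 / MSE)`; `Inf` for identical images.
#'
#' @param x,y images of identical shape.
#' @param max_val dynamic range (default 1).
#' @return scalar in decibels.
#' @export
psnr <- function(x, y, max_val = 1) {
  stop_if_shape_mismatch(x, y)
  mse <- mean((as_channel_array(x) - as_channel_array(y))^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

#' Multi-scale SSIM
#'
#' Geometric mean of per-scale SSIM values over a 3-level Gaussian pyramid
#' (blur + downsample by 2 between levels). When any per-scale value is
#' nonpositive the minimum per-scale value is returned (keeping the result
#' in `[-1, 1]` without complex roots).
#'
#' @param x,y images of identical shape.
#' @param scales pyramid levels (default 3).
#' @param window SSIM tile side.
#' @return scalar in `[-1, 1]`; 1 for identical images.
#' @export
ms_ssim <- function(x, y, scales = 3L, window = 8L) {
  px <- pyramid_features(x, scales)
  py <- pyramid_features(y, scales)
  vals <- vapply(seq_len(scales),
                 function(s) ssim(px[[s]], py[[s]], window), numeric(1))
  if (all(vals > 0)) prod(vals)^(1 / scales) else min(vals)
}

#' MS-SSIM diversity of a sample set
#'
#' Mean pairwise multi-scale SSIM over all unordered pairs of up to
#' `max_samples` samples (a seeded subsample beyond that). Lower values
#' indicate greater diversity; identical samples score 1.
#'
#' @param samples list of images.
#' @param max_samples cap on samples entering the pairwise computation.
#' @param seed subsampling seed.
#' @return scalar in `[-1, 1]`.
#' @export
msssim_diversity <- function(samples, max_samples = 100L, seed = 1L) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples")
  if (n > max_samples) {
    keep <- withr::with_seed(seed, sample.int(n, max_samples))
    samples <- samples[keep]
    n <- max_samples
  }
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      vals <- c(vals, ms_ssim(samples[[i]], samples[[j]]))
    }
  }
  mean(vals)
}

#' Generative precision and recall (k-NN manifold estimate)
#'
#' The real manifold is estimated as the union of balls around each real
#' feature vector with radius equal to its distance to its k-th nearest
#' real neighbour; precision is the fraction of generated points inside the
#' estimated real manifold, recall the symmetric quantity with the roles
#' exchanged.
#'
#' @param feats_real,feats_gen feature matrices with at least `k + 1` rows
#'   each.
#' @param k neighbourhood size (default 3).
#' @return named numeric `c(precision, recall)`, both in `[0, 1]`.
#' @export
gen_precision_recall <- function(feats_real, feats_gen, k = 3L) {
  feats_real <- as.matrix(feats_real); feats_gen <- as.matrix(feats_gen)
  if (nrow(feats_real) < k + 1L || nrow(feats_gen) < k + 1L) {
    stop("need at least k + 1 points per set")
  }
  knn_radius <- function(m) {
    d <- as.matrix(stats::dist(m))
    diag(d) <- Inf
    apply(d, 1L, function(r) sort(r)[k])
  }
  cross <- function(a, b) {
    # distance matrix between rows of a and rows of b
    sq_a <- rowSums(a^2); sq_b <- rowSums(b^2)
    d2 <- outer(sq_a, sq_b, `+`) - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
  }
  in_manifold <- function(pts, anchors, radii) {
    d <- cross(pts, anchors)
    mean(apply(sweep(d, 2L, radii, `<=`), 1L, any))
  }
  c(precision = in_manifold(feats_gen, feats_real, knn_radius(feats_real)),
    recall = in_manifold(feats_real, feats_gen, knn_radius(feats_gen)))
}

#' Harmonic-mean F1 score
#'
#' `2 p r / (p + r)`, defined as 0 when `p + r = 0`.
#'
#' @param precision,recall scalars in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Min-max normalization across a comparison cohort
#'
#' `(v - min) / (max - min)`; with `invert = TRUE` values are negated first
#' (for lower-is-better metrics such as FID or MS-SSIM diversity). A
#' constant vector maps to 0.5 everywhere.
#'
#' @param values numeric vector.
#' @param invert negate before normalizing.
#' @return values in `[0, 1]`.
#' @export
minmax_normalize <- function(values, invert = FALSE) {
  v <- if (invert) -values else values
  rng <- range(v)
  if (rng[2] - rng[1] < 1e-300) return(rep(0.5, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Quality score
#'
#' Weighted sum `0.4 * fid_n + 0.35 * is_n + 0.25 * precision_n` of
#' normalized metrics (FID already inverted during normalization).
#'
#' @param fid_n,is_n,precision_n normalized metric values in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
quality_score <- function(fid_n, is_n, precision_n) {
  0.4 * fid_n + 0.35 * is_n + 0.25 * precision_n
}

#' Diversity score
#'
#' Weighted sum `0.6 * msssim_n + 0.4 * recall_n` (MS-SSIM diversity
#' inverted during normalization, since lower raw values mean more
#' diversity).
#'
#' @param msssim_n,recall_n normalized metric values in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
diversity_score <- function(msssim_n, recall_n) {
  0.6 * msssim_n + 0.4 * recall_n
}

#' Combined quality-diversity score
#'
#' Geometric mean `sqrt(quality * diversity)`: neither dimension can
#' compensate for a collapse in the other.
#'
#' @param quality,diversity scores in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
combined_score <- function(quality, diversity) {
  sqrt(quality * diversity)
}

#' Relative improvement in percent
#'
#' `100 * (a - b) / b`.
#'
#' @param a,b scalar scores (`b` the baseline).
#' @return percentage.
#' @export
relative_improvement <- function(a, b) 100 * (a - b) / b

#' Score a cohort of generators from raw metric columns
#'
#' Applies cohort min-max normalization (FID and MS-SSIM diversity
#' inverted), the quality/diversity weightings, the geometric-mean combined
#' score, and the relative improvement of the reference architecture over
#' every other row. Scores are cohort-relative by construction.
#'
#' @param metrics tibble with columns `architecture`, `fid`, `is_mean`,
#'   `msssim_diversity`, `precision`, `recall`.
#' @param reference architecture name used for relative improvement
#'   (default: first row).
#' @return the input with `f1`, `quality`, `diversity`, `combined`,
#'   `relative_improvement_pct` columns appended; class `dg_eval_report`.
#' @export
score_report <- function(metrics, reference = metrics$architecture[1L]) {
  out <- dplyr::mutate(
    metrics,
    f1 = purrr::map2_dbl(.data$precision, .data$recall, f1_score),
    quality = quality_score(minmax_normalize(.data$fid, invert = TRUE),
                            minmax_normalize(.data$is_mean),
                            minmax_normalize(.data$precision)),
    diversity = diversity_score(
      minmax_normalize(.data$msssim_diversity, invert = TRUE),
      minmax_normalize(.data$recall)),
    combined = combined_score(.data$quality, .data$diversity))
  ref_comb <- out$combined[out$architecture == reference][1L]
  out$relative_improvement_pct <- ifelse(
    out$architecture == reference, NA_real_,
    relative_improvement(ref_comb, out$combined))
  class(out) <- c("dg_eval_report", class(out))
  out
}

# Heuristic localization-family posterior used for the Inception Score when
# no trained classifier is available: evidence for nuclear / cytosolic /
# organellar / punctate placement of the protein channel, softmaxed.
heuristic_class_probs <- function(image) {
  arr <- as_channel_array(image)
  m <- infer_scene_masks(arr)
  prot <- arr[, , 1L]
  cell <- m$cell_mask
  inside <- function(mask) if (any(mask)) mean(prot[mask]) else 0
  ev <- c(nuclear = inside(m$labels == 1L),
          cytosolic = inside(cell & m$labels == 0L),
          organellar = inside(m$labels == 2L | m$labels == 3L),
          punctate = max(prot) - mean(prot[cell | !cell]))
  e <- exp(4 * (ev - max(ev)))
  e / sum(e)
}

#' Evaluate one or more generators against a real sample set
#'
#' Computes the full generative metric panel per generator (FID, Inception
#' Score from a class-posterior function, MS-SSIM diversity, k-NN
#' precision/recall) and the cohort quality/diversity/combined scoring.
#'
#' @param real list of real images.
#' @param gen_sets named list of lists of generated images.
#' @param embedder feature embedder (default [default_embedder()]);
#'   embeddings are standardized with the real set's statistics.
#' @param class_prob_fn `function(image) -> probability vector` for the
#'   Inception Score (default: analytic localization-family posterior).
#' @param k neighbourhood size for precision/recall.
#' @param reference architecture used for relative improvement (default:
#'   first generator).
#' @return a `dg_eval_report` tibble, one row per generator.
#' @export
evaluate_generators <- function(real, gen_sets,
                                embedder = default_embedder(),
                                class_prob_fn = heuristic_class_probs,
                                k = 3L, reference = names(gen_sets)[1L]) {
  stopifnot(length(real) >= 2L, length(gen_sets) >= 1L,
            !is.null(names(gen_sets)))
  f_real_raw <- embed_images(real, embedder)
  ctr <- colMeans(f_real_raw)
  scl <- apply(f_real_raw, 2L, stats::sd)
  # FID on raw embeddings (the conventional scale); the k-NN manifold
  # estimate on standardized ones so no feature dominates the metric
  f_real <- embed_images(real, embedder, ctr, scl)
  rows <- purrr::imap(gen_sets, function(gens, nm) {
    f_gen <- embed_images(gens, embedder, ctr, scl)
    pr <- gen_precision_recall(f_real, f_gen, k)
    probs <- t(vapply(gens, class_prob_fn, class_prob_fn(gens[[1L]])))
    tibble::tibble(architecture = nm,
                   fid = fid(f_real_raw, embed_images(gens, embedder)),
                   is_mean = inception_score(probs),
                   msssim_diversity = msssim_diversity(gens),
                   precision = pr[["precision"]],
                   recall = pr[["recall"]])
  })
  score_report(dplyr::bind_rows(rows), reference)
}

#' Plot a generator evaluation report
#'
#' @param object a `dg_eval_report`.
#' @param ... unused.
#' @return a ggplot object (combined scores by architecture).
#' @method autoplot dg_eval_report
#' @export
autoplot.dg_eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("architecture", "quality", "diversity", "combined")],
    -"architecture", names_to = "score", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$architecture,
                                                      .data$value),
                                   y = .data$value, fill = .data$score)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Quality-diversity evaluation") +
    ggplot2::theme_minimal()
}
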