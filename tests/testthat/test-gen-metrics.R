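test_that("FID identities: zero on identical sets, closed form in 1-D", {
  f <- matrix(rnorm(100), 20, 5)
  expect_equal(fid(f, f), 0, tolerance = 1e-6)
  # population statistics supplied directly: N(0,1) vs N(1,1)
  expect_equal(fid_from_stats(0, matrix(1), 1, matrix(1)), 1.0,
               tolerance = 1e-5)
  expect_equal(fid_from_stats(0, matrix(1), 0, matrix(4)), 1.0,
               tolerance = 1e-3)  # (sigma_r - sigma_g)^2 = (1 - 2)^2
  # symmetry
  withr::with_seed(3, {
    a <- matrix(rnorm(60), 12); b <- matrix(rnorm(60, 1), 12)
    expect_equal(fid(a, b), fid(b, a), tolerance = 1e-5)
    # monotone under mean translation of one set
    shifts <- c(0, 0.5, 1, 2)
    vals <- vapply(shifts, function(s) fid(a, sweep(a, 2, rep(s, 5))),
                   numeric(1))
    expect_true(all(diff(vals) > 0))
  })
  expect_error(fid(matrix(0, 5, 3), matrix(0, 5, 4)), "dimension")
  expect_error(fid(matrix(0, 1, 3), matrix(0, 5, 3)), "2 samples")
})

test_that("Inception Score spans [1, K] with both bounds attained", {
  expect_equal(inception_score(matrix(0.25, 8, 4)), 1.0)
  expect_equal(inception_score(diag(4)), 4.0)
  expect_equal(inception_score(diag(7)), 7.0, tolerance = 1e-12)
  withr::with_seed(4, {
    for (i in 1:20) {
      p <- matrix(rexp(40), 10, 4)
      p <- p / rowSums(p)
      is_val <- inception_score(p)
      expect_gte(is_val, 1 - 1e-9)
      expect_lte(is_val, 4 + 1e-9)
      expect_equal(inception_score(p[sample(10), ]), is_val,
                   tolerance = 1e-12)
    }
  })
  expect_error(inception_score(matrix(0.3, 4, 4)), "probability")
})

test_that("SSIM is 1 on identity, symmetric, negative for anticorrelation", {
  x <- random_image(16, 16, seed = 5)
  expect_equal(ssim(x, x), 1.0)
  y <- random_image(16, 16, seed = 6)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)

  # anti-correlated zero-mean patch within one window: hand computation
  a <- matrix(c(0.4, 0.6, 0.6, 0.4), 2, 2)
  b <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2)
  c1 <- 1e-4; c2 <- 9e-4
  mx <- 0.5; vx <- 0.01; cxy <- -0.01
  want <- ((2 * mx * mx + c1) * (2 * cxy + c2)) /
    ((2 * mx^2 + c1) * (2 * vx + c2))
  expect_equal(ssim(a, b, window = 2), want, tolerance = 1e-12)
  expect_lt(ssim(a, b, window = 2), 0)
})

test_that("PSNR follows its logarithmic form", {
  x <- matrix(0.5, 8, 8)
  expect_equal(psnr(x, x), Inf)
  y <- x + 0.1  # MSE 0.01
  expect_equal(psnr(x, y), 20, tolerance = 1e-9)
  expect_equal(psnr(matrix(0, 4, 4), matrix(1, 4, 4)), 0)  # MSE = MAX^2
})

test_that("MS-SSIM diversity scores identical and constant sets correctly", {
  img <- random_image(16, 16, seed = 7)
  same <- list(img, img, img)
  expect_equal(msssim_diversity(same), 1.0, tolerance = 1e-9)

  # two distinct constant images: closed form with stabilizers only
  z <- matrix(0, 16, 16); o <- matrix(1, 16, 16)
  c1 <- 1e-4; c2 <- 9e-4
  per_scale <- (c1 * c2) / ((1 + c1) * c2)  # mu 0 vs 1, zero variance
  expect_equal(ms_ssim(z, o), per_scale, tolerance = 1e-9)
  expect_equal(msssim_diversity(list(z, o)), per_scale, tolerance = 1e-9)

  # permutation invariance
  set1 <- lapply(1:5, function(i) random_image(16, 16, seed = 10 + i))
  expect_equal(msssim_diversity(set1), msssim_diversity(rev(set1)),
               tolerance = 1e-12)
  expect_error(msssim_diversity(list(img)), "2 samples")
})

test_that("generative precision/recall via k-NN manifolds", {
  withr::with_seed(8, {
    f <- matrix(rnorm(40), 20, 2)
    pr <- gen_precision_recall(f, f)
    expect_equal(unname(pr), c(1, 1))

    far <- matrix(rnorm(40, mean = 1000), 20, 2)
    pr2 <- gen_precision_recall(f, far)
    expect_equal(unname(pr2), c(0, 0))

    a <- matrix(rnorm(30), 15, 2); b <- matrix(rnorm(30, 0.5), 15, 2)
    ab <- gen_precision_recall(a, b)
    ba <- gen_precision_recall(b, a)
    expect_equal(ab[["precision"]], ba[["recall"]])
    expect_equal(ab[["recall"]], ba[["precision"]])
  })
  expect_error(gen_precision_recall(matrix(0, 3, 2), matrix(0, 10, 2)),
               "k \\+ 1")
})

test_that("F1 matches the published generative table", {
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(0, 0), 0)
  tab <- reference_table("gen_precision_recall")
  recomputed <- mapply(f1_score, tab$precision, tab$recall)
  # the published column agrees with the harmonic mean to one unit in the
  # last printed digit
  expect_true(all(abs(recomputed - tab$f1_printed) <= 0.001 + 1e-12))
  expect_equal(round(recomputed[1], 3), 0.853)
})

test_that("min-max normalization and the score weightings", {
  expect_equal(minmax_normalize(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(1, 2, 3), invert = TRUE), c(1, 0.5, 0))
  expect_equal(minmax_normalize(rep(2, 4)), rep(0.5, 4))
  v <- c(3, 1, 7, 5)
  expect_equal(minmax_normalize(2.5 * v + 4), minmax_normalize(v))

  expect_equal(quality_score(1, 1, 1), 1)
  expect_equal(quality_score(1, 0, 0), 0.4)
  expect_equal(diversity_score(1, 0), 0.6)
  expect_equal(combined_score(0.8, 0.8), 0.8)
  expect_equal(relative_improvement(3, 3), 0)
})

test_that("combined scores and improvements regenerate the published table", {
  tab <- reference_table("quality_diversity")
  combined <- combined_score(tab$quality, tab$diversity)
  expect_equal(round(combined, 3), tab$combined_printed)
  # geometric-mean bounds
  expect_true(all(combined <= pmax(tab$quality, tab$diversity) + 1e-12))
  expect_true(all(combined >= pmin(tab$quality, tab$diversity) - 1e-12))

  # the published relative-improvement column derives from the combined
  # scores at printed precision
  comb3 <- round(combined, 3)
  ours <- comb3[tab$architecture == "Dual-Gland GAN"]
  rel <- relative_improvement(ours, comb3)
  idx <- tab$architecture != "Dual-Gland GAN"
  expect_equal(round(rel[idx], 1), tab$relative_improvement_printed[idx])
  expect_equal(round(rel[tab$architecture == "Traditional GAN"], 1), 98.9)
  expect_equal(round(rel[tab$architecture == "ECP-IGANN"], 1), 7.0)
})

test_that("evaluate_generators produces a coherent cohort report", {
  scenes <- generate_scene_set(12, 16, 16, seed = 9)
  real <- lapply(scenes, function(s) s$image)
  gens <- list(
    self = real[1:8],
    noisy = lapply(real[1:8], function(x) {
      dualgland:::clip01(x + array(rnorm(length(x), 0, 0.2), dim(x)))
    }))
  rep <- withr::with_seed(10, evaluate_generators(real, gens))
  expect_s3_class(rep, "dg_eval_report")
  expect_equal(nrow(rep), 2)
  expect_lt(rep$fid[rep$architecture == "self"],
            rep$fid[rep$architecture == "noisy"])
  expect_true(all(rep$quality >= 0 & rep$quality <= 1))
  expect_equal(rep$combined, sqrt(rep$quality * rep$diversity),
               tolerance = 1e-9)
  expect_s3_class(autoplot(rep), "ggplot")
})
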