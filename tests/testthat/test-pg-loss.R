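make_label_map <- function() {
  # nucleus (1) touching ER (3); mitochondria (2) far away
  labels <- matrix(0L, 8, 8)
  labels[2:4, 2:4] <- 1L
  labels[2:4, 5] <- 3L
  labels[7:8, 7:8] <- 2L
  labels
}

test_that("compartment factors follow the same/adjacent/distant rule", {
  map <- compartment_map(make_label_map())
  expect_equal(compartment_factor(map, c(2, 2), c(3, 3)), 1.0)   # nucleus pair
  expect_equal(compartment_factor(map, c(2, 4), c(2, 5)), 0.5)   # nucleus vs touching ER
  expect_equal(compartment_factor(map, c(2, 2), c(7, 7)), 0.1)   # nucleus vs far mito
  expect_equal(compartment_factor(map, c(1, 1), c(6, 6)), 0.1)   # background pair
  # adjacency is irreflexive and symmetric
  expect_true(all(!diag(map$adjacency)))
  expect_identical(map$adjacency, t(map$adjacency))
  expect_true(map$adjacency[1, 3])
  expect_false(map$adjacency[1, 2])
})

test_that("temporal decay is the exponential with time constant tau", {
  expect_equal(temporal_decay(0), 1.0)
  expect_equal(temporal_decay(5, 5), exp(-1))
  ts <- seq(0, 20, by = 0.5)
  expect_true(all(diff(temporal_decay(ts)) < 0))
})

test_that("adaptive weights obey the closed form and its bound", {
  f <- c(0.2, 0.4)
  expect_equal(adaptive_weight(f, f, 1.0, t = 0), 1.0)
  f2 <- f + c(sqrt(0.5), 0)  # squared distance 0.5, beta 2 -> exp(-1)
  expect_equal(adaptive_weight(f, f2, 1.0, t = 0), exp(-1), tolerance = 1e-12)
  withr::with_seed(5, {
    ok <- TRUE
    for (i in 1:20) {
      fi <- runif(3); fj <- runif(3)
      cfac <- sample(c(1, 0.5, 0.1), 1)
      t <- runif(1, 0, 10)
      a <- adaptive_weight(fi, fj, cfac, t)
      ok <- ok && a > 0 && a <= cfac * temporal_decay(t) + 1e-12
    }
    expect_true(ok)
  })
})

test_that("pg_smoothness handles the enumerable cases", {
  labels <- matrix(1L, 1, 2)
  map <- compartment_map(labels)
  feats <- array(0, dim = c(1, 2, 1))
  gen <- matrix(c(0, 1), 1, 2)
  expect_equal(pg_smoothness(gen, feats, map, t = 0), 1.0)

  const <- matrix(0.3, 6, 6)
  map6 <- compartment_map(matrix(1L, 6, 6))
  expect_equal(pg_smoothness(const, NULL, map6), 0)

  # invariance to a global constant offset
  g <- random_image(6, 6, seed = 2)
  f <- array(0, dim = c(6, 6, 1))
  expect_equal(pg_smoothness(g, f, map6), pg_smoothness(g + 0.2, f, map6),
               tolerance = 1e-12)

  # halving alpha (via the temporal decay) halves the result
  s1 <- pg_smoothness(g, f, map6, t = 0)
  s2 <- pg_smoothness(g, f, map6, t = 5 * log(2))
  expect_equal(s2, s1 / 2, tolerance = 1e-12)
})

test_that("pg_smoothness equals the brute-force double loop", {
  labels <- make_label_map()
  map <- compartment_map(labels)
  for (trial in 1:4) {
    gen <- random_image(8, 8, channels = 2, seed = 50 + trial)
    feats <- pixel_features(gen)
    t <- trial - 1
    got <- pg_smoothness(gen, feats, map, t = t)
    want <- oracle_pg_smoothness(gen, feats, labels, map$adjacency,
                                 beta = 2, t = t, tau = 5)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # 4-neighbourhood variant
  cfg4 <- pg_config(neighborhood = 4L)
  gen <- random_image(6, 6, seed = 60)
  feats <- pixel_features(gen)
  labels6 <- matrix(1L, 6, 6)
  got4 <- pg_smoothness(gen, feats, compartment_map(labels6), cfg = cfg4)
  want4 <- oracle_pg_smoothness(gen, feats, labels6,
                                matrix(FALSE, 1, 1), 2, 0, 5,
                                neighborhood = 4)
  expect_equal(got4, want4, tolerance = 1e-10)
})

test_that("smoothness with symmetric weights is a Laplacian quadratic form", {
  # with constant features alpha is symmetric; the penalty then equals
  # (1/P) * x' L x for the weighted graph Laplacian L built explicitly
  labels <- matrix(c(1L, 1L, 0L, 2L, 2L, 0L), 2, 3)
  map <- compartment_map(labels)
  gen <- random_image(2, 3, seed = 70)
  feats <- array(0.5, dim = c(2, 3, 2))
  n <- 6
  coords <- expand.grid(r = 1:2, cl = 1:3)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dr <- abs(coords$r[i] - coords$r[j])
      dc <- abs(coords$cl[i] - coords$cl[j])
      if (max(dr, dc) != 1) next
      la <- labels[coords$r[i], coords$cl[i]]
      lb <- labels[coords$r[j], coords$cl[j]]
      cfac <- if (la == lb && la != 0) 1 else
        if (la != 0 && lb != 0 &&
            map$adjacency[la, lb]) 0.5 else 0.1
      W[i, j] <- cfac  # exp(0) * cfac * exp(0)
    }
  }
  L <- diag(rowSums(W)) - W
  x <- as.numeric(gen)  # column-major matches expand.grid order
  n_pairs <- sum(W > 0)  # ordered pairs
  # sum over ordered pairs of W_ij (x_i - x_j)^2 equals 2 x'Lx
  want <- 2 * as.numeric(t(x) %*% L %*% x) / n_pairs
  got <- pg_smoothness(gen, feats, map)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("homeostatic penalty is zero at the references, quadratic around", {
  labels <- matrix(0L, 6, 6)
  labels[1:3, 1:3] <- 1L
  refs <- organelle_reference(mu = c(nucleus = 0.6))
  gen <- matrix(0, 6, 6)
  gen[labels == 1L] <- 0.6
  expect_equal(homeostatic_penalty(gen, labels, refs), 0)

  gen[labels == 1L] <- 0.7
  expect_equal(homeostatic_penalty(gen, labels, refs), 0.01,
               tolerance = 1e-12)

  # quadratic growth via symmetric finite difference
  h <- 1e-4
  f <- function(d) {
    g <- gen; g[labels == 1L] <- 0.6 + d
    homeostatic_penalty(g, labels, refs)
  }
  second <- (f(h) - 2 * f(0) + f(-h)) / h^2
  expect_equal(second, 2, tolerance = 1e-4)

  # absent organelles contribute nothing
  refs2 <- organelle_reference(mu = c(nucleus = 0.6, mitochondria = 0.45))
  expect_equal(homeostatic_penalty(gen, labels, refs2), f(0.1))
})

test_that("pg_loss composes smoothness and weighted homeostasis", {
  sc <- tiny_scene(seed = 3, size = 32)
  map <- compartment_map(sc$organelle_labels)
  out <- pg_loss(sc$image, map = map, t = 1)
  expect_equal(out$total, out$smoothness + out$homeostasis)
  out0 <- pg_loss(sc$image, map = map, t = 1,
                  cfg = pg_config(lambda_homeostasis = 0))
  expect_equal(out0$total, out0$smoothness)
  expect_gte(out$total, 0)
})

test_that("organelle structural loss follows the decided formula", {
  masks <- list(nucleus = {
    m <- matrix(FALSE, 10, 10); m[3:7, 3:7] <- TRUE; m
  })
  cfg <- pg_config(organelle_weights = c(nucleus = 2))
  # constant image: only the boundary hinge remains, (0.1)^2 per organelle
  expect_equal(organelle_structural_loss(array(0.5, c(10, 10, 1)), masks,
                                         cfg),
               2 * 0.01, tolerance = 1e-12)
  # a sharp step across the mask boundary with a flat interior scores ~0
  step <- matrix(0, 10, 10)
  step[3:7, 3:7] <- 1
  expect_lt(organelle_structural_loss(array(step, c(10, 10, 1)), masks,
                                      pg_config(organelle_weights =
                                                  c(nucleus = 1))),
            0.05)
  # zero weights and zero regularizer give exactly zero
  cfg0 <- pg_config(organelle_weights = c(nucleus = 0), lambda_reg = 0)
  expect_equal(organelle_structural_loss(random_image(10, 10, seed = 4),
                                         masks, cfg0), 0)
  # empty masks contribute nothing
  empty <- list(nucleus = matrix(FALSE, 10, 10))
  expect_equal(organelle_structural_loss(random_image(10, 10, seed = 5),
                                         empty, cfg), 0)
})
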