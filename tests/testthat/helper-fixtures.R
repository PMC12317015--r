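# Shared fixtures: small deterministic scenes and brute-force loss oracles
# kept deliberately independent of the package implementation (double loops
# over pixels, explicit formulas).

tiny_scene <- function(seed = 1, size = 48, class_id = 0,
                       missing_rate = 0) {
  generate_scene(scene_spec(size, size, localization_class = class_id,
                            missing_rate = missing_rate, seed = seed))
}

random_image <- function(h, w, channels = 1, seed = 1) {
  withr::with_seed(seed, {
    if (channels == 1) matrix(runif(h * w), h, w) else
      array(runif(h * w * channels), dim = c(h, w, channels))
  })
}

# Reflection of an out-of-range index about the image edges.
oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
  }
  i
}

# Brute-force Gaussian 5x5 blur + decimation pyramid, per-pixel loops.
oracle_pyramid <- function(mat, S) {
  half <- 2
  g <- exp(-(-half:half)^2 / 2)
  k <- outer(g, g); k <- k / sum(k)
  blur <- function(m) {
    out <- m
    for (r in seq_len(nrow(m))) {
      for (cl in seq_len(ncol(m))) {
        acc <- 0
        for (dr in -half:half) {
          for (dc in -half:half) {
            acc <- acc + k[dr + half + 1, dc + half + 1] *
              m[oracle_reflect(r + dr, nrow(m)), oracle_reflect(cl + dc, ncol(m))]
          }
        }
        out[r, cl] <- acc
      }
    }
    out
  }
  levels <- list(mat)
  for (s in seq_len(S - 1)) {
    b <- blur(levels[[s]])
    levels[[s + 1]] <- b[seq(1, nrow(b), 2), seq(1, ncol(b), 2), drop = FALSE]
  }
  levels
}

# Brute-force 4-neighbour Laplacian with reflective padding.
oracle_laplacian <- function(m) {
  out <- m
  for (r in seq_len(nrow(m))) {
    for (cl in seq_len(ncol(m))) {
      out[r, cl] <- m[oracle_reflect(r - 1, nrow(m)), cl] +
        m[oracle_reflect(r + 1, nrow(m)), cl] +
        m[r, oracle_reflect(cl - 1, ncol(m))] +
        m[r, oracle_reflect(cl + 1, ncol(m))] - 4 * m[r, cl]
    }
  }
  out
}

# Brute-force SG loss (single channel, MSE distance) per its definition.
oracle_sg_loss <- function(real, gen, weights, lambda_gradient,
                           lambda_cont = 0) {
  S <- length(weights)
  pr <- oracle_pyramid(real, S)
  pg <- oracle_pyramid(gen, S)
  total <- 0
  for (s in seq_len(S)) {
    mse <- mean((pr[[s]] - pg[[s]])^2)
    lap <- oracle_laplacian(pg[[s]])
    total <- total + weights[s] * (mse + lambda_gradient * mean(lap^2))
  }
  if (lambda_cont > 0) {
    acc <- c()
    for (r in seq_len(nrow(real))) {
      for (cl in seq_len(ncol(real))) {
        if (r < nrow(real)) {
          acc <- c(acc, ((gen[r + 1, cl] - gen[r, cl]) -
                           (real[r + 1, cl] - real[r, cl]))^2)
        }
        if (cl < ncol(real)) {
          acc <- c(acc, ((gen[r, cl + 1] - gen[r, cl]) -
                           (real[r, cl + 1] - real[r, cl]))^2)
        }
      }
    }
    total <- total + lambda_cont * mean(acc)
  }
  total
}

# Brute-force PG smoothness: explicit double loop over ordered
# pixel/neighbour pairs.
oracle_pg_smoothness <- function(gen, feats, labels, adjacency, beta, t,
                                 tau, neighborhood = 8) {
  offs <- if (neighborhood == 8) {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  h <- nrow(labels); w <- ncol(labels)
  nc <- dim(feats)[3]
  nch <- if (length(dim(gen)) == 3) dim(gen)[3] else 1
  gen <- if (nch == 1) array(gen, c(h, w, 1)) else gen
  total <- 0; count <- 0
  for (r in seq_len(h)) {
    for (cl in seq_len(w)) {
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs$dr[k]; c2 <- cl + offs$dc[k]
        if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
        ssd <- sum((feats[r, cl, ] - feats[r2, c2, ])^2)
        la <- labels[r, cl]; lb <- labels[r2, c2]
        cfac <- if (la == lb && la != 0) 1.0 else
          if (la != 0 && lb != 0 && adjacency[la, lb]) 0.5 else 0.1
        alpha <- exp(-beta * ssd) * cfac * exp(-t / tau)
        d2 <- mean((gen[r2, c2, ] - gen[r, cl, ])^2)
        total <- total + alpha * d2
        count <- count + 1
      }
    }
  }
  total / count
}

# Hand-written Kruskal MST over a symmetric distance matrix; returns the
# edge set as sorted (i, j) pairs.
oracle_kruskal <- function(d) {
  n <- nrow(d)
  if (n < 2) return(matrix(integer(0), 0, 2))
  edges <- expand.grid(i = seq_len(n), j = seq_len(n))
  edges <- edges[edges$i < edges$j, ]
  edges$w <- d[cbind(edges$i, edges$j)]
  edges <- edges[order(edges$w, edges$i, edges$j), ]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  out <- NULL
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges$i[e]); rj <- find(edges$j[e])
    if (ri != rj) {
      parent[ri] <- rj
      out <- rbind(out, c(edges$i[e], edges$j[e]))
      if (nrow(out) == n - 1) break
    }
  }
  out
}
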