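# Analytic gradients of the SG and PG reconstruction losses with respect to
# the generated image, used by the training loop. The pyramid and Laplacian
# are linear, so they are materialized once per image size as sparse
# operators and differentiated by transposition; the PG adaptive weights are
# treated as constants of the current iterate (computed from the generated
# image, held fixed during the gradient step).

# Sparse operator applying a small kernel with reflective padding to a
# vectorized h x w image (column-major).
kernel_operator <- function(h, w, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  n <- h * w
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  idx <- function(r, cl) (cl - 1L) * h + r
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (kernel[i, j] == 0) next
      sr <- reflect_index(rr + (i - 1L - ph), h)
      sc <- reflect_index(cc + (j - 1L - pw), w)
      rows <- c(rows, idx(rr, cc))
      cols <- c(cols, idx(sr, sc))
      vals <- c(vals, rep(kernel[i, j], n))
    }
  }
  # duplicate (row, col) pairs (from reflection) are summed by sparseMatrix
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
}

# Row-selection operator for the every-other-pixel downsampling.
downsample_operator <- function(h, w) {
  keep_r <- seq(1L, h, by = 2L); keep_c <- seq(1L, w, by = 2L)
  sel <- as.vector(outer(keep_r, (keep_c - 1L) * h, `+`))
  n_out <- length(sel)
  Matrix::sparseMatrix(i = seq_len(n_out), j = sel, x = rep(1, n_out),
                       dims = c(n_out, h * w))
}

#' @noRd
sg_operators <- function(h, w, S) {
  lap_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  g_k <- gaussian_kernel(5L, 1)
  ops <- vector("list", S)
  A <- Matrix::Diagonal(h * w)
  dims <- c(h, w)
  for (s in seq_len(S)) {
    ops[[s]] <- list(A = A, L = kernel_operator(dims[1L], dims[2L], lap_k),
                     n = prod(dims), dims = dims)
    if (s < S) {
      B <- kernel_operator(dims[1L], dims[2L], g_k)
      D <- downsample_operator(dims[1L], dims[2L])
      A <- D %*% B %*% A
      dims <- c(length(seq(1L, dims[1L], by = 2L)),
                length(seq(1L, dims[2L], by = 2L)))
    }
  }
  ops
}

# SG loss (MSE distance) and its gradient w.r.t. the generated image.
# real, gen: H x W x C arrays; ops from sg_operators. Returns list(loss, grad).
#' @noRd
sg_backward <- function(real, gen, cfg, ops) {
  real <- as_channel_array(real); gen <- as_channel_array(gen)
  nc <- dim(real)[3L]
  w_s <- cfg$weights$values
  loss <- 0
  grad <- array(0, dim = dim(gen))
  for (ch in seq_len(nc)) {
    rv <- as.numeric(real[, , ch]); gv <- as.numeric(gen[, , ch])
    g_ch <- numeric(length(gv))
    for (s in seq_len(cfg$S)) {
      A <- ops[[s]]$A; L <- ops[[s]]$L; ns <- ops[[s]]$n
      fr <- as.numeric(A %*% rv); fg <- as.numeric(A %*% gv)
      diff <- fg - fr
      loss <- loss + w_s[s] * mean(diff^2) / nc
      g_ch <- g_ch + w_s[s] * (2 / ns) *
        as.numeric(Matrix::crossprod(A, diff)) / nc
      if (cfg$lambda_gradient > 0) {
        lap <- as.numeric(L %*% fg)
        loss <- loss + w_s[s] * cfg$lambda_gradient * mean(lap^2) / nc
        g_ch <- g_ch + w_s[s] * cfg$lambda_gradient * (2 / ns) *
          as.numeric(Matrix::crossprod(A, Matrix::crossprod(L, lap))) / nc
      }
    }
    grad[, , ch] <- matrix(g_ch, dim(gen)[1L], dim(gen)[2L])
  }
  list(loss = loss, grad = grad)
}

# PG loss (smoothness + homeostasis) and its gradient w.r.t. the generated
# image; adaptive weights computed from the current iterate and treated as
# constants. Returns list(loss, grad).
#' @noRd
pg_backward <- function(gen, map, refs, t, cfg) {
  gen <- as_channel_array(gen)
  h <- dim(gen)[1L]; w <- dim(gen)[2L]; nc <- dim(gen)[3L]
  feats <- pixel_features(gen)
  offs <- neighbourhood_offsets(cfg$neighborhood)
  tdecay <- temporal_decay(t, cfg$tau)
  loss_s <- 0; count <- 0
  grad <- array(0, dim = dim(gen))
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1L]; dc <- offs[k, 2L]
    ri <- seq_len(h) + dr; ci <- seq_len(w) + dc
    vr <- ri >= 1L & ri <= h; vc <- ci >= 1L & ci <= w
    if (!any(vr) || !any(vc)) next
    r0 <- seq_len(h)[vr]; c0 <- seq_len(w)[vc]
    r1 <- ri[vr]; c1 <- ci[vc]
    ssd <- matrix(0, length(r0), length(c0))
    for (f in seq_len(dim(feats)[3L])) {
      ssd <- ssd + (feats[r0, c0, f] - feats[r1, c1, f])^2
    }
    cfac <- compartment_factor_codes(
      map, as.integer(map$labels[r0, c0]), as.integer(map$labels[r1, c1]))
    alpha <- exp(-cfg$beta * ssd) * matrix(cfac, length(r0), length(c0)) *
      tdecay
    for (ch in seq_len(nc)) {
      d <- gen[r1, c1, ch] - gen[r0, c0, ch]
      loss_s <- loss_s + sum(alpha * d^2) / nc
      # each ordered pair contributes alpha * d^2; d/dg_i = -2 alpha d,
      # d/dg_j = +2 alpha d (normalization applied after the loop)
      gplane <- grad[, , ch]
      contrib <- 2 * alpha * d
      gplane[r0, c0] <- gplane[r0, c0] - contrib
      gplane[r1, c1] <- gplane[r1, c1] + contrib
      grad[, , ch] <- gplane
    }
    count <- count + length(ssd)
  }
  if (count > 0) {
    loss_s <- loss_s / count
    grad <- grad / (count * nc)
  }
  # homeostatic term
  hloss <- 0
  if (cfg$lambda_homeostasis > 0) {
    for (org in names(refs$mu)) {
      code <- ORGANELLE_CODES[[org]]
      mask <- map$labels == code
      n_o <- sum(mask)
      if (n_o == 0) next
      mval <- mean(vapply(seq_len(nc),
                          function(ch) mean(gen[, , ch][mask]), numeric(1)))
      dev <- mval - refs$mu[[org]]
      hloss <- hloss + dev^2
      gcontrib <- cfg$lambda_homeostasis * 2 * dev / (n_o * nc)
      for (ch in seq_len(nc)) {
        gplane <- grad[, , ch]
        gplane[mask] <- gplane[mask] + gcontrib
        grad[, , ch] <- gplane
      }
    }
  }
  list(loss = loss_s + cfg$lambda_homeostasis * hloss, grad = grad,
       smoothness = loss_s, homeostasis = hloss)
}
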