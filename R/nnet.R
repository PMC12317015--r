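# Minimal dense neural-network machinery (forward, backward, Adam) used by
# the dual-generator GAN and the toy multi-label classifier. Written against
# base matrix algebra; all randomness flows through the caller's RNG state.

xavier_init <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

#' @noRd
mlp_init <- function(sizes, final_act = c("sigmoid", "none")) {
  final_act <- match.arg(final_act)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    layers[[l]] <- list(W = xavier_init(sizes[l], sizes[l + 1L]),
                        b = rep(0, sizes[l + 1L]))
  }
  structure(list(layers = layers, final_act = final_act), class = "dg_mlp")
}

lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
lrelu_grad <- function(x) ifelse(x > 0, 1, 0.2)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
mlp_forward <- function(net, x, dropout = 0, training = FALSE) {
  n_l <- length(net$layers)
  cache <- list(a = vector("list", n_l + 1L),
                z = vector("list", n_l),
                drop = vector("list", n_l))
  cache$a[[1L]] <- x
  for (l in seq_len(n_l)) {
    z <- cache$a[[l]] %*% net$layers[[l]]$W +
      matrix(net$layers[[l]]$b, nrow(x), length(net$layers[[l]]$b),
             byrow = TRUE)
    cache$z[[l]] <- z
    if (l < n_l) {
      a <- lrelu(z)
      if (training && dropout > 0) {
        keep <- matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a))
        a <- a * keep / (1 - dropout)
        cache$drop[[l]] <- keep
      }
    } else {
      a <- if (net$final_act == "sigmoid") sigmoid(z) else z
    }
    cache$a[[l + 1L]] <- a
  }
  list(out = cache$a[[n_l + 1L]], cache = cache)
}

# Backward pass given the gradient w.r.t. the network OUTPUT (post
# activation). Returns parameter gradients and the gradient w.r.t. the input.
#' @noRd
mlp_backward <- function(net, cache, d_out, dropout = 0) {
  n_l <- length(net$layers)
  grads <- vector("list", n_l)
  d_a <- d_out
  for (l in rev(seq_len(n_l))) {
    if (l == n_l) {
      d_z <- if (net$final_act == "sigmoid") {
        a <- cache$a[[l + 1L]]
        d_a * a * (1 - a)
      } else d_a
    } else {
      d_act <- d_a
      if (!is.null(cache$drop[[l]])) {
        d_act <- d_act * cache$drop[[l]] / (1 - dropout)
      }
      d_z <- d_act * lrelu_grad(cache$z[[l]])
    }
    grads[[l]] <- list(W = crossprod(cache$a[[l]], d_z),
                       b = colSums(d_z))
    d_a <- d_z %*% t(net$layers[[l]]$W)
  }
  list(grads = grads, d_input = d_a)
}

#' @noRd
adam_init <- function(net) {
  lapply(net$layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

# One Adam update with global-norm gradient clipping and L2 weight decay.
#' @noRd
adam_update <- function(net, grads, opt, lr, t, beta1 = 0.5, beta2 = 0.999,
                        l2 = 1e-5, clip_norm = 1.0, eps = 1e-8) {
  total_sq <- 0
  for (l in seq_along(grads)) {
    total_sq <- total_sq + sum(grads[[l]]$W^2) + sum(grads[[l]]$b^2)
  }
  scale <- if (clip_norm > 0 && sqrt(total_sq) > clip_norm) {
    clip_norm / sqrt(total_sq)
  } else 1
  for (l in seq_along(grads)) {
    gW <- grads[[l]]$W * scale + l2 * net$layers[[l]]$W
    gb <- grads[[l]]$b * scale
    opt[[l]]$mW <- beta1 * opt[[l]]$mW + (1 - beta1) * gW
    opt[[l]]$vW <- beta2 * opt[[l]]$vW + (1 - beta2) * gW^2
    opt[[l]]$mb <- beta1 * opt[[l]]$mb + (1 - beta1) * gb
    opt[[l]]$vb <- beta2 * opt[[l]]$vb + (1 - beta2) * gb^2
    mW_hat <- opt[[l]]$mW / (1 - beta1^t)
    vW_hat <- opt[[l]]$vW / (1 - beta2^t)
    mb_hat <- opt[[l]]$mb / (1 - beta1^t)
    vb_hat <- opt[[l]]$vb / (1 - beta2^t)
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
  }
  list(net = net, opt = opt)
}

# Cosine annealing with warm restarts.
#' @noRd
cosine_lr <- function(lr0, epoch, period) {
  t_cur <- (epoch - 1L) %% period
  0.5 * lr0 * (1 + cos(pi * t_cur / period))
}
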