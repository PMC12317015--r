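# Low-level image helpers shared across the loss, constraint and metric code.
# All images are numeric arrays: matrices (H x W) for single channels, or
# H x W x C arrays with channel order (protein, nucleus, microtubule, ER).

CHANNEL_NAMES <- c("protein", "nucleus", "microtubule", "er")

ORGANELLE_CODES <- c(background = 0L, nucleus = 1L, mitochondria = 2L,
                     er = 3L, other = 4L)

#' @noRd
as_channel_array <- function(image) {
  if (is.matrix(image)) array(image, dim = c(dim(image), 1L)) else image
}

#' @noRd
reflect_index <- function(idx, n) {
  # Reflect out-of-range indices about the edges (no repeated edge pixel
  # beyond single reflection handled by recursion for deep padding).
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n - 2L
  m <- (idx - 1L) %% period
  m <- ifelse(m < 0L, m + period, m)
  ifelse(m < n, m + 1L, period - m + 1L)
}

#' @noRd
pad_reflect <- function(mat, pad) {
  rows <- reflect_index(seq_len(nrow(mat) + 2L * pad) - pad, nrow(mat))
  cols <- reflect_index(seq_len(ncol(mat) + 2L * pad) - pad, ncol(mat))
  mat[rows, cols, drop = FALSE]
}

#' @noRd
conv2_reflect <- function(mat, kernel) {
  # Direct 2-D correlation with reflect padding; kernels are small (3x3, 5x5)
  # so the sum-of-shifted-submatrices form is fast in R.
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  padded <- pad_reflect(mat, max(ph, pw))
  extra <- max(ph, pw)
  out <- matrix(0, nrow(mat), ncol(mat))
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (kernel[i, j] == 0) next
      r0 <- extra - ph + i - 1L
      c0 <- extra - pw + j - 1L
      out <- out + kernel[i, j] *
        padded[r0 + seq_len(nrow(mat)), c0 + seq_len(ncol(mat)), drop = FALSE]
    }
  }
  out
}

#' @noRd
gaussian_kernel <- function(size = 5L, sigma = 1) {
  half <- (size - 1L) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' @noRd
sobel_magnitude <- function(mat) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- conv2_reflect(mat, kx)
  gy <- conv2_reflect(mat, ky)
  sqrt(gx^2 + gy^2)
}

#' @noRd
shift_mat <- function(mat, dr, dc, fill = NA_real_) {
  # Shift contents by (dr, dc); vacated cells get `fill`.
  h <- nrow(mat); w <- ncol(mat)
  out <- matrix(fill, h, w)
  if (abs(dr) >= h || abs(dc) >= w) return(out)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- mat[rs - dr, cs - dc, drop = FALSE]
  out
}

NEIGH8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
NEIGH4 <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))

#' @noRd
label_components8 <- function(mask) {
  # 8-connected component labelling via flood fill; labels assigned in
  # raster order of each component's first (topmost-leftmost in row-major
  # (row, col) order) pixel, so the numbering is deterministic.
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  # visit column-major? we want (row, col) lexicographic: iterate rows outer
  for (r in seq_len(h)) {
    for (cl in seq_len(w)) {
      if (mask[r, cl] && lab[r, cl] == 0L) {
        nxt <- nxt + 1L
        queue <- matrix(c(r, cl), 1L, 2L)
        lab[r, cl] <- nxt
        while (nrow(queue) > 0L) {
          cur <- queue[nrow(queue), , drop = FALSE]
          queue <- queue[-nrow(queue), , drop = FALSE]
          nr <- cur[1L] + NEIGH8[, "dr"]
          nc <- cur[2L] + NEIGH8[, "dc"]
          ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
          nr <- nr[ok]; nc <- nc[ok]
          idx <- cbind(nr, nc)
          hit <- mask[idx] & lab[idx] == 0L
          if (any(hit)) {
            idx <- idx[hit, , drop = FALSE]
            lab[idx] <- nxt
            queue <- rbind(queue, idx)
          }
        }
      }
    }
  }
  lab
}

#' @noRd
dilate1 <- function(mask) {
  mask <- mask > 0
  out <- mask
  for (k in seq_len(nrow(NEIGH8))) {
    out <- out | shift_mat(mask * 1, NEIGH8[k, 1L], NEIGH8[k, 2L], fill = 0) > 0
  }
  out
}

#' @noRd
clip01 <- function(x) {
  # pmin/pmax with a leading scalar would drop dim attributes
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' @noRd
stop_if_shape_mismatch <- function(a, b) {
  if (!identical(dim(as_channel_array(a)), dim(as_channel_array(b)))) {
    stop("image shapes do not match: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), call. = FALSE)
  }
}

#' @noRd
downsample2 <- function(mat) {
  mat[seq(1L, nrow(mat), by = 2L), seq(1L, ncol(mat), by = 2L), drop = FALSE]
}

#' @noRd
local_mean3 <- function(mat) conv2_reflect(mat, matrix(1 / 9, 3, 3))

#' @noRd
local_sd3 <- function(mat) {
  m <- local_mean3(mat)
  v <- local_mean3(mat^2) - m^2
  sqrt(pmax(v, 0))
}

#' Moran's I spatial autocorrelation with 4-neighbour weights
#'
#' Standard Moran's I on the pixel lattice with binary rook (4-neighbour)
#' weights. Returns 0 (by convention the degenerate midpoint is handled by
#' the caller) when the input has zero variance.
#'
#' @param mat numeric matrix.
#' @return scalar in \[-1, 1\], or `NA` when variance is zero.
#' @keywords internal
#' @noRd
morans_i <- function(mat) {
  n <- length(mat)
  dev <- mat - mean(mat)
  denom <- sum(dev^2)
  if (denom == 0) return(NA_real_)
  num <- 0
  s0 <- 0
  for (k in seq_len(nrow(NEIGH4))) {
    sh <- shift_mat(dev, NEIGH4[k, 1L], NEIGH4[k, 2L], fill = NA_real_)
    ok <- !is.na(sh)
    num <- num + sum(dev[ok] * sh[ok])
    s0 <- s0 + sum(ok)
  }
  (n / s0) * (num / denom)
}
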