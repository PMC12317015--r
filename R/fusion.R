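# Confidence-weighted fusion of the two generator outputs. A single scalar
# weight pair per sample combines the secretion-specialized and
# structure-specialized generators.

#' Secretory activity measure
#'
#' Mean Sobel gradient magnitude of the protein channel: actively secreting
#' cells show strong spatial gradients in protein distribution.
#'
#' @param image 4-channel image (`H x W x 4`, protein channel first).
#' @return nonnegative scalar; 0 iff the protein channel is constant.
#' @export
secretion_measure <- function(image) {
  arr <- as_channel_array(image)
  mean(sobel_magnitude(arr[, , 1L]))
}

#' Structural organization measure
#'
#' Variance of Sobel gradient magnitudes sampled at organelle boundary
#' pixels (label transitions): structurally stable cells maintain uniformly
#' sharp organellar boundaries. Returns 0 when fewer than two boundary
#' pixels exist.
#'
#' @param image 4-channel image.
#' @param labels integer organelle label map.
#' @return nonnegative scalar.
#' @export
structure_measure <- function(image, labels) {
  arr <- as_channel_array(image)
  gm <- Reduce(`+`, lapply(seq_len(dim(arr)[3L]),
                           function(ch) sobel_magnitude(arr[, , ch]))) /
    dim(arr)[3L]
  boundary <- matrix(FALSE, nrow(labels), ncol(labels))
  for (k in seq_len(nrow(NEIGH4))) {
    sh <- shift_mat(labels + 0, NEIGH4[k, 1L], NEIGH4[k, 2L], fill = NA_real_)
    boundary <- boundary | (!is.na(sh) & sh != labels & (labels > 0 | sh > 0))
  }
  vals <- gm[boundary]
  if (length(vals) < 2L) return(0)
  stats::var(vals)
}

#' Fusion weights from generator confidences and state measures
#'
#' Temperature-scaled softmax weighting:
#' `gamma_SG = exp(C_SG / T) * S_sec / (exp(C_SG / T) * S_sec +
#' exp(C_PG / T) * S_str)`, `gamma_PG = 1 - gamma_SG`. At temperature 1 this
#' is the plain confidence-times-state weighting. When both state measures
#' are zero the weights fall back to a softmax of the confidences alone.
#'
#' @param c_sg,c_pg generator confidence scalars (for example mean
#'   discriminator realness scores of each generator's recent batches).
#' @param s_sec,s_str nonnegative secretion / structure state measures.
#' @param temperature softmax temperature (default 2.0).
#' @return named numeric `c(gamma_sg, gamma_pg)`, summing to 1.
#' @export
#' @examples
#' fusion_weights(0.5, 0.5, 1, 1)  # c(0.5, 0.5)
fusion_weights <- function(c_sg, c_pg, s_sec, s_str, temperature = 2.0) {
  if (!all(is.finite(c(c_sg, c_pg, s_sec, s_str, temperature)))) {
    stop("fusion inputs must be finite")
  }
  stopifnot(s_sec >= 0, s_str >= 0, temperature > 0)
  # stabilized exponentials
  m <- max(c_sg, c_pg) / temperature
  e_sg <- exp(c_sg / temperature - m)
  e_pg <- exp(c_pg / temperature - m)
  if (s_sec + s_str == 0) {
    g <- e_sg / (e_sg + e_pg)
  } else {
    g <- (e_sg * s_sec) / (e_sg * s_sec + e_pg * s_str)
  }
  g <- min(max(g, 1e-12), 1 - 1e-12)
  c(gamma_sg = g, gamma_pg = 1 - g)
}

#' Fuse two generator outputs
#'
#' Pixelwise convex combination `gamma_sg * g_sg + gamma_pg * g_pg`.
#'
#' @param g_sg,g_pg images of identical shape.
#' @param weights weight pair from [fusion_weights()].
#' @return fused image, elementwise between the two inputs.
#' @export
fuse <- function(g_sg, g_pg, weights) {
  stop_if_shape_mismatch(g_sg, g_pg)
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  weights[[1L]] * g_sg + weights[[2L]] * g_pg
}

#' Compute the full fusion state for a pair of generated images
#'
#' Convenience wrapper assembling confidences, state measures and the
#' resulting weights.
#'
#' @param g_sg,g_pg generated 4-channel images.
#' @param labels organelle label map used for the structure measure.
#' @param c_sg,c_pg generator confidences.
#' @param temperature softmax temperature.
#' @return list with measures, weights and the fused image.
#' @export
fusion_state <- function(g_sg, g_pg, labels, c_sg = 0.5, c_pg = 0.5,
                         temperature = 2.0) {
  s_sec <- secretion_measure(g_sg)
  s_str <- structure_measure(g_pg, labels)
  w <- fusion_weights(c_sg, c_pg, s_sec, s_str, temperature)
  list(c_sg = c_sg, c_pg = c_pg, s_secretion = s_sec, s_structure = s_str,
       temperature = temperature, gamma_sg = w[[1L]], gamma_pg = w[[2L]],
       fused = fuse(g_sg, g_pg, w))
}
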