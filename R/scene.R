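# Synthetic cell-scene simulator. A scene emulates one segmented cell from a
# 4-channel fluorescence acquisition (protein of interest, nuclear stain,
# microtubule stain, ER stain) together with organelle label maps and a
# multi-label localization class vector.

#' Specify a synthetic cell scene
#'
#' Parameter object for [generate_scene()]. Organelle area targets are
#' expressed as fractions of the cell footprint; the defaults sit at the
#' midpoints of the physiological ranges used by the biological constraint
#' penalties (nucleus 15-20%, mitochondria 10-15%, ER 8-12%).
#'
#' @param height,width image size in pixels.
#' @param target_volume_fractions named numeric vector with entries
#'   `nucleus`, `mitochondria`, `er`; must sum to less than 1.
#' @param target_aspect_ratio cell major/minor axis ratio, `>= 1`.
#' @param localization_class integer 0-18, the protein localization class
#'   painted into the protein channel.
#' @param missing_rate fraction of pixels zeroed across all channels to
#'   emulate missing-pixel (photobleaching) artifacts; in `[0, 1)`.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param seed integer seed; scenes are bit-for-bit reproducible.
#' @return an object of class `scene_spec`.
#' @export
#' @examples
#' sp <- scene_spec(64, 64, localization_class = 0, seed = 1)
#' sc <- generate_scene(sp)
#' dim(sc$image)
scene_spec <- function(height = 64L, width = 64L,
                       target_volume_fractions = c(nucleus = 0.175,
                                                   mitochondria = 0.125,
                                                   er = 0.10),
                       target_aspect_ratio = 1.8,
                       localization_class = 0L,
                       missing_rate = 0,
                       noise_sd = 0.02,
                       seed = 1L) {
  stopifnot(height >= 16, width >= 16)
  need <- c("nucleus", "mitochondria", "er")
  if (!all(need %in% names(target_volume_fractions))) {
    stop("target_volume_fractions must name nucleus, mitochondria and er")
  }
  f <- target_volume_fractions[need]
  if (any(f < 0) || sum(f) >= 1) {
    stop("organelle fractions must be nonnegative and sum to < 1")
  }
  if (target_aspect_ratio < 1) stop("target_aspect_ratio must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (!localization_class %in% 0:18) {
    stop("localization_class must be an integer in 0..18")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 target_volume_fractions = f,
                 target_aspect_ratio = target_aspect_ratio,
                 localization_class = as.integer(localization_class),
                 missing_rate = missing_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Rasterize an ellipse: TRUE where ((x'/a)^2 + (y'/b)^2) <= 1 after rotating
# centred coordinates by theta.
ellipse_mask <- function(h, w, cr, cc, a, b, theta) {
  rr <- matrix(seq_len(h), h, w) - cr
  cc_ <- matrix(seq_len(w), h, w, byrow = TRUE) - cc
  x <- cos(theta) * cc_ + sin(theta) * rr
  y <- -sin(theta) * cc_ + cos(theta) * rr
  (x / a)^2 + (y / b)^2 <= 1
}

# Elliptical "potential" (higher = closer to the centre) used to pick an
# exact pixel count with top-k selection.
ellipse_potential <- function(h, w, cr, cc, a, b, theta) {
  rr <- matrix(seq_len(h), h, w) - cr
  cc_ <- matrix(seq_len(w), h, w, byrow = TRUE) - cc
  x <- cos(theta) * cc_ + sin(theta) * rr
  y <- -sin(theta) * cc_ + cos(theta) * rr
  -((x / a)^2 + (y / b)^2)
}

# Select exactly `k` pixels among `candidates` (logical matrix) by
# decreasing potential; ties broken by linear index for determinism.
top_k_pixels <- function(potential, candidates, k, organelle) {
  idx <- which(candidates)
  if (k > length(idx)) {
    stop("infeasible volume fraction for organelle '", organelle,
         "' at this image size (need ", k, " pixels, ",
         length(idx), " available)", call. = FALSE)
  }
  out <- matrix(FALSE, nrow(potential), ncol(potential))
  if (k == 0) return(out)
  ord <- idx[order(-potential[idx], idx)]
  out[ord[seq_len(k)]] <- TRUE
  out
}

# Geodesic-ish distance (in dilation steps) from a skeleton, restricted to a
# candidate region. Unreached pixels get Inf.
skeleton_distance <- function(skeleton, candidates, max_steps = 12L) {
  d <- matrix(Inf, nrow(skeleton), ncol(skeleton))
  frontier <- skeleton & candidates
  d[frontier] <- 0
  for (s in seq_len(max_steps)) {
    grown <- dilate1(frontier) & candidates
    fresh <- grown & !is.finite(d)
    if (!any(fresh)) break
    d[fresh] <- s
    frontier <- grown
  }
  d
}

smooth5 <- function(mat) conv2_reflect(mat, gaussian_kernel(5L, 1))

# Draw a digital line between two points, returning a logical mask.
line_mask <- function(h, w, r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0), 1L)
  rs <- round(seq(r0, r1, length.out = n + 1L))
  cs <- round(seq(c0, c1, length.out = n + 1L))
  ok <- rs >= 1 & rs <= h & cs >= 1 & cs <= w
  m <- matrix(FALSE, h, w)
  m[cbind(rs[ok], cs[ok])] <- TRUE
  m
}

#' Generate a synthetic 4-channel cell scene
#'
#' Renders one cell: an elliptical footprint, an elliptical nucleus,
#' mitochondria as blob clusters, the ER as a reticular network grown from
#' the nuclear envelope, microtubules as rays from a centrosome, and the
#' protein channel painted according to the localization class family.
#' Organelle pixel counts are selected exactly, so achieved area fractions
#' match the targets up to one pixel. Gaussian noise is added and intensities
#' clipped to `[0, 1]`; if `missing_rate > 0` pixels are zeroed across all
#' channels and recorded in `missing_mask`.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `cell_scene`: a list with `image`
#'   (`H x W x 4`, channels protein/nucleus/microtubule/ER), `organelle_labels`
#'   (integer map: 0 background, 1 nucleus, 2 mitochondria, 3 ER, 4 other),
#'   `cell_mask`, `class_labels` (binary length-19 vector), `missing_mask`,
#'   and the generating `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  fr <- spec$target_volume_fractions

  ## cell footprint: ellipse at ~55% of the frame, requested aspect ratio
  cr <- h / 2 + stats::runif(1, -h * 0.02, h * 0.02)
  cc <- w / 2 + stats::runif(1, -w * 0.02, w * 0.02)
  theta <- stats::runif(1, 0, pi)
  area <- 0.55 * h * w
  ar <- spec$target_aspect_ratio
  a <- sqrt(area * ar / pi)
  b <- a / ar
  lim <- 0.48 * min(h, w)
  if (a > lim) { b <- b * lim / a; a <- lim }
  cell <- ellipse_mask(h, w, cr, cc, a, b, theta)
  cell_area <- sum(cell)
  if (cell_area < 32) stop("image too small to host a cell footprint")

  ## capacity check: requested organelle pixels (plus the fixed accessory
  ## allocation) must fit inside the cell footprint
  k_other_reserved <- round(0.03 * cell_area)
  cum <- k_other_reserved
  for (org in c("nucleus", "mitochondria", "er")) {
    cum <- cum + round(fr[[org]] * cell_area)
    if (cum > cell_area) {
      stop("infeasible volume fraction for organelle '", org,
           "' at this image size", call. = FALSE)
    }
  }

  ## nucleus: exact pixel count via elliptical potential
  k_nuc <- round(fr[["nucleus"]] * cell_area)
  nuc_ar <- 1.3
  a_n <- sqrt(1.25 * k_nuc * nuc_ar / pi)
  off <- c(stats::runif(1, -0.1, 0.1) * b, stats::runif(1, -0.1, 0.1) * b)
  pot_n <- ellipse_potential(h, w, cr + off[1], cc + off[2],
                             a_n, a_n / nuc_ar, stats::runif(1, 0, pi))
  nucleus <- top_k_pixels(pot_n, cell, k_nuc, "nucleus")

  cyto <- cell & !nucleus

  ## mitochondria: blob clusters (Gaussian bumps around sampled centres)
  k_mit <- round(fr[["mitochondria"]] * cell_area)
  cand <- cyto
  n_blob <- max(3L, round(k_mit / 25))
  centers <- which(cand)
  centers <- centers[sample.int(length(centers), min(n_blob, length(centers)))]
  pot_m <- matrix(0, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (ctr in centers) {
    r0 <- ((ctr - 1) %% h) + 1
    c0 <- ((ctr - 1) %/% h) + 1
    s <- stats::runif(1, 1.5, 3)
    pot_m <- pmax(pot_m, exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * s^2)))
  }
  pot_m <- pot_m + stats::runif(h * w) * 1e-4
  mito <- top_k_pixels(pot_m, cand, k_mit, "mitochondria")

  ## ER: reticular network grown around random-walk skeleton from the
  ## nuclear envelope
  k_er <- round(fr[["er"]] * cell_area)
  cand <- cyto & !mito
  envelope <- dilate1(nucleus) & cand
  skel <- matrix(FALSE, h, w)
  starts <- which(envelope)
  if (length(starts) > 0) {
    n_walk <- 6L
    starts <- starts[sample.int(length(starts), min(n_walk, length(starts)))]
    for (st in starts) {
      r0 <- ((st - 1) %% h) + 1
      c0 <- ((st - 1) %/% h) + 1
      dir <- stats::runif(1, 0, 2 * pi)
      for (step in seq_len(max(h, w))) {
        skel[r0, c0] <- TRUE
        dir <- dir + stats::rnorm(1, 0, 0.5)
        r1 <- r0 + round(sin(dir)); c1 <- c0 + round(cos(dir))
        if (r1 < 1 || r1 > h || c1 < 1 || c1 > w || !cand[r1, c1]) break
        r0 <- r1; c0 <- c1
      }
    }
  }
  if (!any(skel & cand)) skel <- envelope
  d_er <- skeleton_distance(skel, cand)
  pot_e <- -d_er + stats::runif(h * w) * 1e-4
  er <- top_k_pixels(pot_e, cand, k_er, "er")

  ## a couple of small accessory organelles (Golgi-like) near the nucleus
  k_oth <- round(0.03 * cell_area)
  cand <- cyto & !mito & !er
  pot_o <- matrix(-Inf, h, w)
  oth_centers <- which(dilate1(dilate1(nucleus)) & cand)
  if (length(oth_centers) > 0 && k_oth > 0) {
    oth_centers <- oth_centers[sample.int(length(oth_centers),
                                          min(2L, length(oth_centers)))]
    pot_o <- matrix(0, h, w)
    for (ctr in oth_centers) {
      r0 <- ((ctr - 1) %% h) + 1
      c0 <- ((ctr - 1) %/% h) + 1
      pot_o <- pmax(pot_o, exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * 2^2)))
    }
    pot_o <- pot_o + stats::runif(h * w) * 1e-4
  }
  other <- if (k_oth > 0 && any(is.finite(pot_o))) {
    top_k_pixels(pot_o, cand, min(k_oth, sum(cand)), "other")
  } else matrix(FALSE, h, w)

  labels <- matrix(0L, h, w)
  labels[nucleus] <- ORGANELLE_CODES[["nucleus"]]
  labels[mito] <- ORGANELLE_CODES[["mitochondria"]]
  labels[er] <- ORGANELLE_CODES[["er"]]
  labels[other] <- ORGANELLE_CODES[["other"]]

  ## stain channels
  nucleus_ch <- 0.6 * smooth5(nucleus * 1) + 0.05 * (cyto * 1)

  centrosome <- which(dilate1(dilate1(nucleus)) & cyto)
  mt <- matrix(FALSE, h, w)
  if (length(centrosome) > 0) {
    ctr <- centrosome[sample.int(length(centrosome), 1L)]
    r0 <- ((ctr - 1) %% h) + 1
    c0 <- ((ctr - 1) %/% h) + 1
    for (ang in stats::runif(12L, 0, 2 * pi)) {
      reach <- max(a, 4)
      mt <- mt | line_mask(h, w, r0, c0, r0 + reach * sin(ang),
                           c0 + reach * cos(ang))
    }
    mt <- mt & cyto
  }
  mt_ch <- 0.5 * smooth5(mt * 1) + 0.05 * (cyto * 1)

  er_ch <- 0.5 * smooth5(er * 1) + 0.05 * (cyto * 1)

  ## protein channel by class family
  tab <- hpa_class_table()
  row <- tab[tab$class_id == spec$localization_class, ]
  target <- row$target[[1L]]
  protein <- matrix(0, h, w)
  if (target == "nucleus") {
    protein <- 0.7 * (nucleus * 1)
  } else if (target == "cytoplasm") {
    protein <- 0.55 * (cyto * 1)
  } else if (target == "mitochondria") {
    protein <- 0.75 * (mito * 1) + 0.05 * (cyto * 1)
  } else if (target == "er") {
    protein <- 0.75 * (er * 1) + 0.05 * (cyto * 1)
  } else if (target == "other") {
    protein <- 0.75 * (other * 1) + 0.05 * (cyto * 1)
  } else if (target == "punctate") {
    pts <- which(cyto)
    pts <- pts[sample.int(length(pts), min(12L, length(pts)))]
    for (ctr in pts) {
      r0 <- ((ctr - 1) %% h) + 1
      c0 <- ((ctr - 1) %/% h) + 1
      protein <- pmax(protein,
                      0.8 * exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * 1.2^2)))
    }
    protein <- protein * cell
  } # "none" (negative class): protein stays dark
  protein <- smooth5(protein)

  img <- array(0, dim = c(h, w, 4L))
  img[, , 1L] <- protein
  img[, , 2L] <- nucleus_ch
  img[, , 3L] <- mt_ch
  img[, , 4L] <- er_ch
  img <- clip01(img + array(stats::rnorm(length(img), 0, spec$noise_sd),
                            dim = dim(img)))

  class_labels <- integer(19L)
  class_labels[spec$localization_class + 1L] <- 1L

  missing_mask <- matrix(FALSE, h, w)
  if (spec$missing_rate > 0) {
    cm <- corrupt_missing_impl(img, spec$missing_rate)
    img <- cm$image
    missing_mask <- cm$missing_mask
  }

  structure(list(image = img, organelle_labels = labels,
                 cell_mask = cell, class_labels = class_labels,
                 missing_mask = missing_mask, spec = spec),
            class = "cell_scene")
}

#' @export
print.cell_scene <- function(x, ...) {
  d <- dim(x$image)
  cat("<cell_scene> ", d[1], "x", d[2], " px, 4 channels; class ",
      which(x$class_labels == 1L) - 1L, "; cell area ", sum(x$cell_mask),
      " px\n", sep = "")
  invisible(x)
}

corrupt_missing_impl <- function(image, rate) {
  image <- as_channel_array(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  k <- round(rate * h * w)
  mask <- matrix(FALSE, h, w)
  if (k > 0) {
    pos <- sample.int(h * w, k)
    mask[pos] <- TRUE
    for (ch in seq_len(dim(image)[3L])) {
      plane <- image[, , ch]
      plane[mask] <- 0
      image[, , ch] <- plane
    }
  }
  list(image = image, missing_mask = mask)
}

#' Corrupt an image with missing pixels
#'
#' Zeroes exactly `round(rate * H * W)` pixel positions across all channels,
#' emulating the missing-pixel artifacts of high-resolution fluorescence
#' acquisitions, and returns the corrupted image together with the mask of
#' affected positions.
#'
#' @param image `H x W` matrix or `H x W x C` array.
#' @param rate fraction of pixels to corrupt, in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `image` and `missing_mask`.
#' @export
corrupt_missing <- function(image, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  withr::with_seed(seed, corrupt_missing_impl(image, rate))
}

#' Generate a labelled set of synthetic scenes
#'
#' Convenience wrapper used for training/evaluation experiments: draws
#' localization classes from the frequency table and renders one scene per
#' draw with per-scene derived seeds.
#'
#' @param n number of scenes.
#' @param height,width scene size.
#' @param class_table frequency table, see [hpa_class_table()].
#' @param missing_rate,noise_sd forwarded to [scene_spec()].
#' @param seed integer master seed.
#' @return list of `cell_scene` objects.
#' @export
generate_scene_set <- function(n, height = 32L, width = 32L,
                               class_table = hpa_class_table(),
                               missing_rate = 0, noise_sd = 0.02, seed = 1L) {
  classes <- sample_classes(n, class_table, seed = seed)
  lapply(seq_len(n), function(i) {
    generate_scene(scene_spec(height, width,
                              localization_class = classes[i],
                              missing_rate = missing_rate,
                              noise_sd = noise_sd,
                              seed = as.integer(
                                (as.numeric(seed) * 131071 + i) %%
                                  2147483647)))
  })
}
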