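# Pituitary-gland (PG) structural loss: compartment-aware adaptive-weight
# smoothness plus a homeostatic organelle-intensity penalty, and an
# organelle-weighted structural variant.

#' Configuration of the PG loss
#'
#' @param beta sensitivity to per-pixel feature differences (default 2.0).
#' @param tau characteristic time constant of the temporal decay
#'   (default 5.0, in epochs).
#' @param lambda_homeostasis weight of the homeostatic intensity penalty
#'   (default 1.0).
#' @param neighborhood 8 (Moore, default) or 4 (von Neumann) pixel
#'   neighbourhood for the smoothness term.
#' @param organelle_weights named weights for the organelle-structural
#'   variant [organelle_structural_loss()].
#' @param lambda_reg weight of the plausibility regularizer in the
#'   structural variant (default 0).
#' @return object of class `pg_config`.
#' @export
pg_config <- function(beta = 2.0, tau = 5.0, lambda_homeostasis = 1.0,
                      neighborhood = 8L,
                      organelle_weights = c(nucleus = 1, mitochondria = 1,
                                            er = 1, other = 1),
                      lambda_reg = 0) {
  stopifnot(beta > 0, tau > 0, lambda_homeostasis >= 0,
            neighborhood %in% c(4L, 8L), lambda_reg >= 0)
  structure(list(beta = beta, tau = tau,
                 lambda_homeostasis = lambda_homeostasis,
                 neighborhood = as.integer(neighborhood),
                 organelle_weights = organelle_weights,
                 lambda_reg = lambda_reg),
            class = "pg_config")
}

#' Reference organelle intensities and volume ranges
#'
#' Package defaults for the homeostatic penalty's per-organelle reference
#' mean intensities (values in `[0, 1]`; user-overridable, as reference
#' intensities depend on staining and normalization) and the physiological
#' volume-fraction ranges.
#'
#' @param mu named numeric vector of reference mean intensities.
#' @param volume_range named list of `c(lo, hi)` fraction ranges.
#' @return object of class `organelle_reference`.
#' @export
organelle_reference <- function(mu = c(nucleus = 0.60, mitochondria = 0.45,
                                       er = 0.30),
                                volume_range = list(
                                  nucleus = c(0.15, 0.20),
                                  mitochondria = c(0.10, 0.15),
                                  er = c(0.08, 0.12))) {
  stopifnot(all(mu >= 0 & mu <= 1))
  for (r in volume_range) stopifnot(r[1] < r[2])
  structure(list(mu = mu, volume_range = volume_range),
            class = "organelle_reference")
}

#' Compartment map: organelle labels plus adjacency
#'
#' Builds the pairwise adjacency relation over nonzero organelle labels:
#' two organelle classes are adjacent when their masks touch after 1-pixel
#' dilation. The relation is irreflexive and symmetric.
#'
#' @param labels integer organelle label map (0 background).
#' @return object of class `compartment_map` with `labels` and the logical
#'   `adjacency` matrix indexed by label code.
#' @export
compartment_map <- function(labels) {
  codes <- sort(setdiff(unique(as.integer(labels)), 0L))
  maxc <- max(c(codes, 1L))
  adj <- matrix(FALSE, maxc, maxc)
  for (a in codes) {
    da <- dilate1(labels == a)
    for (b in codes) {
      if (b <= a) next
      if (any(da & labels == b)) {
        adj[a, b] <- TRUE; adj[b, a] <- TRUE
      }
    }
  }
  structure(list(labels = labels, adjacency = adj),
            class = "compartment_map")
}

#' Compartmentalization factor between two pixels
#'
#' Discrete coupling strength: 1.0 when both pixels carry the same nonzero
#' organelle label, 0.5 when they lie in distinct but adjacent organelles,
#' 0.1 otherwise (including background).
#'
#' @param map a [compartment_map()].
#' @param i,j pixel positions as `c(row, col)`.
#' @return 1.0, 0.5 or 0.1.
#' @export
compartment_factor <- function(map, i, j) {
  la <- map$labels[i[1L], i[2L]]
  lb <- map$labels[j[1L], j[2L]]
  compartment_factor_codes(map, la, lb)
}

compartment_factor_codes <- function(map, la, lb) {
  out <- rep(0.1, length(la))
  same <- la == lb & la != 0L
  out[same] <- 1.0
  both <- la != 0L & lb != 0L & la != lb
  if (any(both)) {
    adj <- map$adjacency[cbind(la[both], lb[both])]
    out[both][adj] <- 0.5
  }
  out
}

#' Temporal decay of the adaptive weighting
#'
#' `exp(-t / tau)`: transient constraint responses decay back to baseline on
#' the characteristic time scale `tau`.
#'
#' @param t nonnegative scalar (epochs since the last constraint trigger).
#' @param tau time constant.
#' @return value in `(0, 1]`.
#' @export
temporal_decay <- function(t, tau = 5.0) {
  stopifnot(t >= 0, tau > 0)
  exp(-t / tau)
}

#' Adaptive pixel-pair weight
#'
#' `alpha_ij = exp(-beta * ||f_i - f_j||^2) * C_compartment * exp(-t / tau)`.
#'
#' @param f_i,f_j per-pixel feature vectors of equal length.
#' @param compartment compartmentalization factor (1.0 / 0.5 / 0.1).
#' @param t epochs since last trigger.
#' @param cfg a [pg_config()].
#' @return scalar weight in `(0, compartment]`.
#' @export
adaptive_weight <- function(f_i, f_j, compartment, t = 0, cfg = pg_config()) {
  stopifnot(length(f_i) == length(f_j))
  exp(-cfg$beta * sum((f_i - f_j)^2)) * compartment *
    temporal_decay(t, cfg$tau)
}

#' Per-pixel analytic feature descriptors
#'
#' Default feature map for the adaptive weighting: for each channel, the
#' pixel value, its 3x3 local mean, and its 3x3 local standard deviation
#' (scaled into `[0, 1]`), concatenated over channels.
#'
#' @param image `H x W` matrix or `H x W x C` array.
#' @return `H x W x (3C)` feature array.
#' @export
pixel_features <- function(image) {
  arr <- as_channel_array(image)
  nc <- dim(arr)[3L]
  out <- array(0, dim = c(dim(arr)[1:2], 3L * nc))
  for (ch in seq_len(nc)) {
    m <- arr[, , ch]
    out[, , 3L * ch - 2L] <- m
    out[, , 3L * ch - 1L] <- local_mean3(m)
    out[, , 3L * ch] <- clip01(2 * local_sd3(m))  # sd of [0,1] data <= 0.5
  }
  out
}

neighbourhood_offsets <- function(neighborhood) {
  if (neighborhood == 8L) NEIGH8 else NEIGH4
}

#' Compartment-aware adaptive smoothness
#'
#' Mean over ordered pixel/neighbour pairs `(i, j)` (8-neighbourhood by
#' default, pairs within bounds) of `alpha_ij * (gen_j - gen_i)^2`, squared
#' differences averaged over channels. The adaptive weights couple the
#' penalty strongly within organelles and weakly across compartments, so
#' smoothing never blurs across organellar boundaries indiscriminately.
#'
#' @param gen generated image (`H x W` or `H x W x C`).
#' @param feats per-pixel features, see [pixel_features()]; defaults to
#'   `pixel_features(gen)`.
#' @param map a [compartment_map()].
#' @param t epochs since the last constraint trigger.
#' @param cfg a [pg_config()].
#' @return nonnegative scalar; 0 for a constant image.
#' @export
pg_smoothness <- function(gen, feats = NULL, map, t = 0, cfg = pg_config()) {
  arr <- as_channel_array(gen)
  if (is.null(feats)) feats <- pixel_features(gen)
  feats <- as_channel_array(feats)
  h <- dim(arr)[1L]; w <- dim(arr)[2L]
  stopifnot(identical(dim(map$labels), c(h, w)))
  offs <- neighbourhood_offsets(cfg$neighborhood)
  tdecay <- temporal_decay(t, cfg$tau)
  total <- 0; count <- 0
  for (k in seq_len(nrow(offs))) {
    dr <- offs[k, 1L]; dc <- offs[k, 2L]
    rr <- seq_len(h); cc <- seq_len(w)
    ri <- rr + dr; ci <- cc + dc
    vr <- ri >= 1L & ri <= h; vc <- ci >= 1L & ci <= w
    if (!any(vr) || !any(vc)) next
    r0 <- rr[vr]; c0 <- cc[vc]
    r1 <- ri[vr]; c1 <- ci[vc]
    # squared feature distance
    ssd <- matrix(0, length(r0), length(c0))
    for (f in seq_len(dim(feats)[3L])) {
      ssd <- ssd + (feats[r0, c0, f] - feats[r1, c1, f])^2
    }
    cfac <- compartment_factor_codes(
      map, as.integer(map$labels[r0, c0]), as.integer(map$labels[r1, c1]))
    alpha <- exp(-cfg$beta * ssd) * matrix(cfac, length(r0), length(c0)) *
      tdecay
    d2 <- matrix(0, length(r0), length(c0))
    for (ch in seq_len(dim(arr)[3L])) {
      d2 <- d2 + (arr[r1, c1, ch] - arr[r0, c0, ch])^2
    }
    d2 <- d2 / dim(arr)[3L]
    total <- total + sum(alpha * d2)
    count <- count + length(d2)
  }
  if (count == 0) 0 else total / count
}

#' Homeostatic organelle-intensity penalty
#'
#' `H = sum_k (mean(O_k) - mu_k)^2`: squared deviation of the mean generated
#' intensity over each organelle's pixels (averaged over channels) from its
#' biological reference. Organelles absent from the label map contribute 0.
#'
#' @param gen generated image.
#' @param labels integer organelle label map.
#' @param refs an [organelle_reference()].
#' @return nonnegative scalar.
#' @export
homeostatic_penalty <- function(gen, labels, refs = organelle_reference()) {
  arr <- as_channel_array(gen)
  total <- 0
  for (org in names(refs$mu)) {
    code <- ORGANELLE_CODES[[org]]
    mask <- labels == code
    if (!any(mask)) next
    vals <- vapply(seq_len(dim(arr)[3L]),
                   function(ch) mean(arr[, , ch][mask]), numeric(1))
    total <- total + (mean(vals) - refs$mu[[org]])^2
  }
  total
}

#' Pituitary-gland structural loss
#'
#' `total = smoothness + lambda_homeostasis * H`.
#'
#' @inheritParams pg_smoothness
#' @param labels organelle label map for the homeostatic term (defaults to
#'   `map$labels`).
#' @param refs an [organelle_reference()].
#' @return list with `total`, `smoothness`, `homeostasis`.
#' @export
pg_loss <- function(gen, feats = NULL, map, labels = map$labels,
                    refs = organelle_reference(), t = 0, cfg = pg_config()) {
  sm <- pg_smoothness(gen, feats, map, t, cfg)
  hp <- homeostatic_penalty(gen, labels, refs)
  list(total = sm + cfg$lambda_homeostasis * hp,
       smoothness = sm, homeostasis = hp)
}

mask_boundary <- function(mask) {
  mask <- mask > 0
  mask & dilate1(!mask)
}

#' Organelle-weighted structural loss variant
#'
#' For each organelle mask: the mean squared Sobel gradient magnitude over
#' the mask interior (penalizing texture where the organelle should be
#' smooth) plus a hinge on under-defined boundaries,
#' `max(0, 0.1 - mean boundary gradient magnitude)^2` (rewarding a sharp
#' organelle outline). Organelle terms are weighted by
#' `cfg$organelle_weights`; an optional plausibility regularizer `reg_fn(gen)`
#' is added with weight `cfg$lambda_reg`.
#'
#' @param gen generated image.
#' @param masks named list of logical organelle masks.
#' @param cfg a [pg_config()].
#' @param reg_fn optional `function(gen) -> scalar` regularizer (for example
#'   a biological-constraint loss); used when `cfg$lambda_reg > 0`.
#' @return nonnegative scalar.
#' @export
organelle_structural_loss <- function(gen, masks, cfg = pg_config(),
                                      reg_fn = NULL) {
  arr <- as_channel_array(gen)
  gm <- Reduce(`+`, lapply(seq_len(dim(arr)[3L]),
                           function(ch) sobel_magnitude(arr[, , ch]))) /
    dim(arr)[3L]
  total <- 0
  for (org in names(masks)) {
    lam <- cfg$organelle_weights[[org]]
    if (is.null(lam) || lam == 0) next
    mask <- masks[[org]] > 0
    if (!any(mask)) next
    boundary <- mask_boundary(mask)
    interior <- mask & !boundary
    int_term <- if (any(interior)) mean(gm[interior]^2) else 0
    bnd_mean <- if (any(boundary)) mean(gm[boundary]) else 0
    hinge <- max(0, 0.1 - bnd_mean)^2
    total <- total + lam * (int_term + hinge)
  }
  if (cfg$lambda_reg > 0 && !is.null(reg_fn)) {
    total <- total + cfg$lambda_reg * reg_fn(gen)
  }
  total
}
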