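# Image preprocessing: contrast enhancement, patch extraction with reflective
# boundary handling, and geometric augmentation.

#' Contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE to a single channel (clip limit 2.0, 8x8 tiles by default,
#' matching common practice for fluorescence protein channels). Tile counts
#' are reduced automatically for small images so each tile spans at least
#' 8 pixels.
#'
#' @param channel numeric matrix with values in `[0, 1]`.
#' @param clip_limit contrast clip limit.
#' @param tiles integer vector of length 2, tiles along rows/columns.
#' @return enhanced channel, values in `[0, 1]`.
#' @export
clahe_enhance <- function(channel, clip_limit = 2.0, tiles = c(8L, 8L)) {
  stopifnot(is.matrix(channel))
  if (min(channel) < -1e-9 || max(channel) > 1 + 1e-9) {
    stop("channel values must lie in [0, 1]")
  }
  nx <- max(1L, min(tiles[1L], nrow(channel) %/% 8L))
  ny <- max(1L, min(tiles[2L], ncol(channel) %/% 8L))
  out <- EBImage::clahe(EBImage::as.Image(channel), nx = nx, ny = ny,
                        limit = clip_limit)
  clip01(matrix(as.numeric(out), nrow(channel), ncol(channel)))
}

#' Extract overlapping patches with reflective boundary padding
#'
#' Tiles the image with `size x size` patches at the given stride; the patch
#' grid always covers the full image, and content beyond the boundary is
#' filled by reflection rather than zero-padding. Offsets are 0-based
#' `(row, col)` positions of each patch's top-left corner.
#'
#' @param image `H x W` matrix or `H x W x C` array.
#' @param size patch side length.
#' @param stride stride between patch origins; `size >= stride`.
#' @return list with `patches` (list of arrays/matrices) and `offsets`
#'   (tibble with `row`, `col`).
#' @export
extract_patches <- function(image, size = 256L, stride = 128L) {
  if (size < stride) stop("size must be >= stride")
  arr <- as_channel_array(image)
  h <- dim(arr)[1L]; w <- dim(arr)[2L]; nc <- dim(arr)[3L]
  n_axis <- function(d) {
    if (d <= size) 1L else as.integer(ceiling((d - size) / stride) + 1L)
  }
  nr <- n_axis(h); nw <- n_axis(w)
  starts_r <- (seq_len(nr) - 1L) * stride
  starts_c <- (seq_len(nw) - 1L) * stride
  patches <- list()
  offs <- list()
  k <- 0L
  for (sr in starts_r) {
    rows <- reflect_index(sr + seq_len(size), h)
    for (sc in starts_c) {
      cols <- reflect_index(sc + seq_len(size), w)
      k <- k + 1L
      p <- arr[rows, cols, , drop = FALSE]
      if (is.matrix(image)) p <- p[, , 1L]
      patches[[k]] <- p
      offs[[k]] <- c(sr, sc)
    }
  }
  om <- do.call(rbind, offs)
  list(patches = patches,
       offsets = tibble::tibble(row = om[, 1L], col = om[, 2L]))
}

#' Reassemble patches by centre-cropping
#'
#' Inverse of [extract_patches()] on the image interior: each pixel is taken
#' from the patch whose centre is closest, which reconstructs the interior
#' exactly when the patches came from a regular grid.
#'
#' @param patches,offsets as returned by [extract_patches()].
#' @param height,width output image size.
#' @return reassembled image.
#' @export
reassemble_patches <- function(patches, offsets, height, width) {
  first <- as_channel_array(patches[[1L]])
  size <- dim(first)[1L]
  nc <- dim(first)[3L]
  out <- array(0, dim = c(height, width, nc))
  # responsibility: midpoints between neighbouring patch origins
  rows_u <- sort(unique(offsets$row)); cols_u <- sort(unique(offsets$col))
  bounds <- function(starts, d) {
    lo <- integer(length(starts)); hi <- integer(length(starts))
    for (i in seq_along(starts)) {
      lo[i] <- if (i == 1L) 0L else floor((starts[i] + starts[i - 1L] + size) / 2)
      hi[i] <- if (i == length(starts)) d - 1L else
        floor((starts[i] + starts[i + 1L] + size) / 2) - 1L
    }
    cbind(lo, hi)
  }
  br <- bounds(rows_u, height); bc <- bounds(cols_u, width)
  for (k in seq_along(patches)) {
    p <- as_channel_array(patches[[k]])
    ir <- match(offsets$row[k], rows_u); ic <- match(offsets$col[k], cols_u)
    rr <- br[ir, 1L]:br[ir, 2L]; cc <- bc[ic, 1L]:bc[ic, 2L]
    rr <- rr[rr - offsets$row[k] < size & rr < height]
    cc <- cc[cc - offsets$col[k] < size & cc < width]
    out[rr + 1L, cc + 1L, ] <- p[rr - offsets$row[k] + 1L,
                                 cc - offsets$col[k] + 1L, , drop = FALSE]
  }
  if (is.matrix(patches[[1L]])) out[, , 1L] else out
}

# Bilinear sampling of `mat` at fractional (row, col) coordinates with
# reflective boundary handling.
bilinear_sample <- function(mat, rr, cc) {
  h <- nrow(mat); w <- ncol(mat)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  ri <- function(i) reflect_index(i, h)
  ci <- function(j) reflect_index(j, w)
  v00 <- mat[cbind(ri(r0), ci(c0))]
  v01 <- mat[cbind(ri(r0), ci(c0 + 1))]
  v10 <- mat[cbind(ri(r0 + 1), ci(c0))]
  v11 <- mat[cbind(ri(r0 + 1), ci(c0 + 1))]
  v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
}

#' Geometric augmentation: rotation, flips, zoom
#'
#' Applies a centre-anchored affine transform (rotation within +/- 20
#' degrees, optional horizontal/vertical flips, zoom in `[0.8, 1.2]`) with
#' bilinear resampling and reflective boundary handling; the output shape
#' equals the input shape. Parameters left `NULL` are drawn uniformly within
#' their allowed ranges using `seed`, so calls are reproducible.
#'
#' @param image `H x W` matrix or `H x W x C` array.
#' @param rotation_deg rotation angle in degrees, `|angle| <= 20`.
#' @param flip_h,flip_v logical flips.
#' @param zoom zoom factor in `[0.8, 1.2]`.
#' @param seed integer seed for sampled parameters.
#' @return augmented image, same shape as the input.
#' @export
augment <- function(image, rotation_deg = NULL, flip_h = NULL, flip_v = NULL,
                    zoom = NULL, seed = 1L) {
  pars <- withr::with_seed(seed, list(
    rot = if (is.null(rotation_deg)) stats::runif(1, -20, 20) else rotation_deg,
    fh = if (is.null(flip_h)) stats::runif(1) < 0.5 else flip_h,
    fv = if (is.null(flip_v)) stats::runif(1) < 0.5 else flip_v,
    zm = if (is.null(zoom)) stats::runif(1, 0.8, 1.2) else zoom))
  if (abs(pars$rot) > 20 + 1e-9) stop("rotation_deg must lie within +/- 20")
  if (pars$zm < 0.8 - 1e-9 || pars$zm > 1.2 + 1e-9) {
    stop("zoom must lie within [0.8, 1.2]")
  }
  arr <- as_channel_array(image)
  h <- dim(arr)[1L]; w <- dim(arr)[2L]
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  grid_r <- matrix(seq_len(h), h, w) - cr
  grid_c <- matrix(seq_len(w), h, w, byrow = TRUE) - cc
  th <- -pars$rot * pi / 180   # inverse rotation
  src_r <- (cos(th) * grid_r - sin(th) * grid_c) / pars$zm
  src_c <- (sin(th) * grid_r + cos(th) * grid_c) / pars$zm
  if (pars$fv) src_r <- -src_r
  if (pars$fh) src_c <- -src_c
  src_r <- src_r + cr; src_c <- src_c + cc
  out <- arr
  for (ch in seq_len(dim(arr)[3L])) {
    out[, , ch] <- matrix(bilinear_sample(arr[, , ch], c(src_r), c(src_c)), h, w)
  }
  if (is.matrix(image)) out[, , 1L] else out
}

# Run-length encode a matrix of small integers for the JSON sidecar.
rle_encode <- function(mat) {
  r <- rle(as.integer(mat))
  list(dim = dim(mat), lengths = r$lengths, values = r$values)
}

rle_decode <- function(enc) {
  matrix(inverse.rle(list(lengths = as.integer(enc$lengths),
                          values = as.integer(enc$values))),
         enc$dim[[1L]], enc$dim[[2L]])
}

#' Write a cell scene to disk
#'
#' Stores the image as a multi-page 32-bit float TIFF (`<path>.tif`, one page
#' per channel) and the masks, labels and generation parameters in a JSON
#' sidecar (`<path>.json`, masks run-length encoded). The round trip through
#' [read_scene()] is lossless.
#'
#' @param scene a `cell_scene`.
#' @param path file path without extension.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "cell_scene"))
  pages <- lapply(seq_len(dim(scene$image)[3L]),
                  function(ch) scene$image[, , ch])
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  spec_out <- unclass(scene$spec)
  spec_out$target_volume_fractions <-
    as.list(spec_out$target_volume_fractions)  # keep names in JSON
  sidecar <- list(
    format = "dualgland-scene",
    lossy = FALSE,
    channels = CHANNEL_NAMES,
    class_labels = as.integer(scene$class_labels),
    organelle_labels = rle_encode(scene$organelle_labels),
    cell_mask = rle_encode(scene$cell_mask * 1L),
    missing_mask = rle_encode(scene$missing_mask * 1L),
    spec = spec_out)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cell scene written by [write_scene()]
#'
#' @param path file path without extension.
#' @return a `cell_scene`.
#' @export
read_scene <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  for (field in c("class_labels", "organelle_labels", "cell_mask",
                  "missing_mask")) {
    if (is.null(side[[field]])) {
      stop("scene sidecar is missing required field '", field, "'")
    }
  }
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  img <- array(0, dim = c(h, w, length(pages)))
  for (ch in seq_along(pages)) img[, , ch] <- pages[[ch]]
  spec <- side$spec
  sp <- scene_spec(spec$height, spec$width,
                   target_volume_fractions = unlist(spec$target_volume_fractions),
                   target_aspect_ratio = spec$target_aspect_ratio,
                   localization_class = spec$localization_class,
                   missing_rate = spec$missing_rate,
                   noise_sd = spec$noise_sd, seed = spec$seed)
  structure(list(image = img,
                 organelle_labels = rle_decode(side$organelle_labels),
                 cell_mask = rle_decode(side$cell_mask) > 0,
                 class_labels = as.integer(side$class_labels),
                 missing_mask = rle_decode(side$missing_mask) > 0,
                 spec = sp),
            class = "cell_scene")
}

#' Export a scene's channels as 8-bit PNGs
#'
#' Quantizes each channel to 8 bits (a lossy export, flagged as such in the
#' returned metadata) and writes one PNG per channel.
#'
#' @param scene a `cell_scene`.
#' @param path file path prefix; files are `<path>_<channel>.png`.
#' @return metadata list with `lossy = TRUE` and the written file names.
#' @export
export_scene_png <- function(scene, path) {
  files <- character(0)
  for (ch in seq_len(dim(scene$image)[3L])) {
    f <- paste0(path, "_", CHANNEL_NAMES[ch], ".png")
    png::writePNG(clip01(scene$image[, , ch]), f)
    files <- c(files, f)
  }
  list(lossy = TRUE, bit_depth = 8L, files = files)
}
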