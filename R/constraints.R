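# Biological plausibility constraints: organelle volume fractions,
# minimum-spanning-tree connectivity of organelle components, and cell
# morphology, each penalized with a smooth hinge-squared outside its
# physiological range.

#' Constraint configuration
#'
#' Physiological ranges (organelle volume fractions relative to the cell
#' footprint; cell aspect ratio) and the component weights of the combined
#' biological loss.
#'
#' @param volume_ranges named list of `c(lo, hi)` fraction ranges.
#' @param aspect_range `c(lo, hi)` allowed cell aspect ratios.
#' @param lambda_volume,lambda_connectivity,lambda_morphology component
#'   weights (defaults 1).
#' @return object of class `constraint_config`.
#' @export
constraint_config <- function(volume_ranges = list(nucleus = c(0.15, 0.20),
                                                   mitochondria = c(0.10, 0.15),
                                                   er = c(0.08, 0.12)),
                              aspect_range = c(1.2, 2.5),
                              lambda_volume = 1, lambda_connectivity = 1,
                              lambda_morphology = 1) {
  for (r in volume_ranges) stopifnot(r[1] < r[2])
  stopifnot(aspect_range[1] < aspect_range[2])
  structure(list(volume_ranges = volume_ranges, aspect_range = aspect_range,
                 lambda_volume = lambda_volume,
                 lambda_connectivity = lambda_connectivity,
                 lambda_morphology = lambda_morphology),
            class = "constraint_config")
}

#' Organelle volume fractions
#'
#' Organelle pixel count divided by cell footprint pixel count.
#'
#' @param labels integer organelle label map.
#' @param cell_mask logical cell footprint; must be nonempty.
#' @return named numeric fractions for nucleus, mitochondria, er, other.
#' @export
volume_fractions <- function(labels, cell_mask) {
  n_cell <- sum(cell_mask > 0)
  if (n_cell == 0) stop("cell mask is empty")
  out <- vapply(c("nucleus", "mitochondria", "er", "other"), function(org) {
    sum(labels == ORGANELLE_CODES[[org]]) / n_cell
  }, numeric(1))
  out
}

hinge_range <- function(value, range) {
  if (value < range[1]) (range[1] - value)^2
  else if (value > range[2]) (value - range[2])^2
  else 0
}

#' Volume-range penalty
#'
#' Hinge-squared penalty outside each organelle's physiological range:
#' `(lo - f)^2` below, `(f - hi)^2` above, 0 inside.
#'
#' @param fractions named fractions from [volume_fractions()].
#' @param ranges named list of `c(lo, hi)` ranges.
#' @return nonnegative scalar.
#' @export
volume_penalty <- function(fractions,
                           ranges = constraint_config()$volume_ranges) {
  total <- 0
  for (org in names(ranges)) {
    f <- if (org %in% names(fractions)) fractions[[org]] else 0
    total <- total + hinge_range(f, ranges[[org]])
  }
  total
}

#' Connected-component graph of an organelle mask
#'
#' 8-connected components with area-weighted centroids; nodes ordered by the
#' `(row, col)` position of each component's topmost-leftmost pixel; the
#' complete graph is weighted by centroid Euclidean distance.
#'
#' @param labels organelle label map (or a logical mask).
#' @param organelle organelle name (ignored when `labels` is already a mask).
#' @return object of class `component_graph` with a `nodes` tibble
#'   (`id`, `row`, `col`, `area`) and the `dist` matrix.
#' @export
component_graph <- function(labels, organelle = NULL) {
  mask <- if (is.logical(labels)) labels else
    labels == ORGANELLE_CODES[[organelle]]
  lab <- label_components8(mask)
  n <- max(lab)
  if (n == 0) {
    return(structure(list(nodes = tibble::tibble(id = integer(0),
                                                 row = numeric(0),
                                                 col = numeric(0),
                                                 area = integer(0)),
                          dist = matrix(0, 0, 0)),
                     class = "component_graph"))
  }
  rows <- matrix(seq_len(nrow(lab)), nrow(lab), ncol(lab))
  cols <- matrix(seq_len(ncol(lab)), nrow(lab), ncol(lab), byrow = TRUE)
  nodes <- tibble::tibble(
    id = seq_len(n),
    row = vapply(seq_len(n), function(i) mean(rows[lab == i]), numeric(1)),
    col = vapply(seq_len(n), function(i) mean(cols[lab == i]), numeric(1)),
    area = vapply(seq_len(n), function(i) sum(lab == i), integer(1)))
  d <- as.matrix(stats::dist(cbind(nodes$row, nodes$col)))
  structure(list(nodes = nodes, dist = d), class = "component_graph")
}

# MST edge set of a component graph as a 2-column matrix of node ids
# (smaller id first), deterministic via tiny index-based tie-breaking.
mst_edges <- function(graph) {
  n <- nrow(graph$nodes)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  w <- graph$dist
  # symmetric, deterministic tie-breaking by unordered node pair
  eps <- outer(seq_len(n), seq_len(n),
               function(i, j) (pmin(i, j) * n + pmax(i, j)) * 1e-12)
  g <- igraph::graph_from_adjacency_matrix(w + eps, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, algorithm = "prim")
  e <- igraph::as_edgelist(mst, names = FALSE)
  t(apply(e, 1L, function(x) sort(as.integer(x))))
}

#' Minimum-spanning-tree topology penalty
#'
#' Compares the connectivity structure of two component graphs. Components
#' are matched greedily by centroid distance (globally nearest pairs first);
#' the generated graph's MST edges are mapped through the matching and the
#' penalty is the normalized symmetric difference of the two MST edge sets,
#' `|E_ref delta E_gen_mapped| / max(1, |E_ref| + |E_gen|)`. Edges incident
#' to unmatched components can never match and therefore count as
#' violations. 0 when the graphs agree under the matching; bounded by 1;
#' symmetric in its arguments.
#'
#' @param ref,gen [component_graph()] objects.
#' @return scalar in `[0, 1]`.
#' @export
mst_topology_penalty <- function(ref, gen) {
  n_r <- nrow(ref$nodes); n_g <- nrow(gen$nodes)
  e_ref <- mst_edges(ref); e_gen <- mst_edges(gen)
  denom <- max(1L, nrow(e_ref) + nrow(e_gen))
  if (n_r == 0 && n_g == 0) return(0)
  # greedy matching over globally sorted centroid distances
  match_gen <- rep(NA_integer_, n_g)
  if (n_r > 0 && n_g > 0) {
    dd <- outer(seq_len(n_r), seq_len(n_g), function(i, j) {
      sqrt((ref$nodes$row[i] - gen$nodes$row[j])^2 +
             (ref$nodes$col[i] - gen$nodes$col[j])^2)
    })
    ord <- order(dd, row(dd), col(dd))
    used_r <- logical(n_r); used_g <- logical(n_g)
    for (k in ord) {
      i <- row(dd)[k]; j <- col(dd)[k]
      if (!used_r[i] && !used_g[j]) {
        used_r[i] <- TRUE; used_g[j] <- TRUE
        match_gen[j] <- i
        if (all(used_r) || all(used_g)) break
      }
    }
  }
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ref_keys <- if (nrow(e_ref)) edge_key(e_ref[, 1L], e_ref[, 2L]) else
    character(0)
  gen_keys <- if (nrow(e_gen)) {
    a <- match_gen[e_gen[, 1L]]; b <- match_gen[e_gen[, 2L]]
    k <- character(nrow(e_gen))
    ok <- !is.na(a) & !is.na(b)
    k[ok] <- edge_key(a[ok], b[ok])
    k[!ok] <- paste0("unmatched", seq_len(sum(!ok)))
    k
  } else character(0)
  sym_diff <- length(setdiff(ref_keys, gen_keys)) +
    length(setdiff(gen_keys, ref_keys))
  sym_diff / denom
}

#' Cell aspect ratio from second central moments
#'
#' Ratio of major to minor axis length, computed as the square root of the
#' eigenvalue ratio of the 2x2 covariance matrix of pixel coordinates.
#' Rotation invariant; 1 for a disc. Degenerate (collinear) masks report
#' `Inf`.
#'
#' @param cell_mask logical mask with at least 2 pixels.
#' @return scalar `>= 1` (possibly `Inf`).
#' @export
aspect_ratio <- function(cell_mask) {
  pix <- which(cell_mask > 0, arr.ind = TRUE)
  if (nrow(pix) < 2L) stop("mask must contain at least 2 pixels")
  cv <- stats::cov(pix)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] < 1e-12) return(Inf)
  sqrt(ev[1L] / ev[2L])
}

#' Morphology penalty
#'
#' Hinge-squared penalty on the cell aspect ratio outside its allowed range.
#'
#' @param ratio aspect ratio.
#' @param range allowed `c(lo, hi)` (default `c(1.2, 2.5)`).
#' @return nonnegative scalar.
#' @export
morphology_penalty <- function(ratio, range = c(1.2, 2.5)) {
  if (!is.finite(ratio)) return((range[2])^2)  # degenerate masks: large fixed penalty
  hinge_range(ratio, range)
}

# Threshold-based organelle mask inference for raw generated images
# (which carry no label maps). Heuristic: nuclear stain and ER stain
# channels segment their organelles; mitochondria fall back to bright
# protein-channel foci outside nucleus/ER. Documented as approximate.
infer_scene_masks <- function(image) {
  arr <- as_channel_array(image)
  cell <- smooth5(pmax(arr[, , 1L],
                       pmax(arr[, , 2L], pmax(arr[, , 3L], arr[, , 4L])))) > 0.08
  nucleus <- arr[, , 2L] > 0.3 & cell
  er <- arr[, , 4L] > 0.25 & cell & !nucleus
  mito <- arr[, , 1L] > 0.35 & cell & !nucleus & !er
  labels <- matrix(0L, nrow(nucleus), ncol(nucleus))
  labels[nucleus] <- ORGANELLE_CODES[["nucleus"]]
  labels[mito] <- ORGANELLE_CODES[["mitochondria"]]
  labels[er] <- ORGANELLE_CODES[["er"]]
  list(labels = labels, cell_mask = cell)
}

scene_like <- function(x) {
  if (inherits(x, "cell_scene")) {
    list(labels = x$organelle_labels, cell_mask = x$cell_mask,
         image = x$image)
  } else {
    m <- infer_scene_masks(x)
    list(labels = m$labels, cell_mask = m$cell_mask,
         image = as_channel_array(x))
  }
}

#' Combined biological constraint loss
#'
#' `lambda_volume * L_volume + lambda_connectivity * L_connectivity +
#' lambda_morphology * L_morphology`. Volume and morphology are evaluated on
#' the generated scene's own masks; connectivity compares the generated
#' organelle component graphs against a paired reference scene (itself by
#' default, giving 0). Raw images (without label maps) get masks inferred by
#' channel thresholding.
#'
#' @param scene_gen a `cell_scene` or a raw 4-channel image.
#' @param ref reference scene for the connectivity term (default:
#'   `scene_gen` itself).
#' @param cfg a [constraint_config()].
#' @return list with `total`, `volume`, `connectivity`, `morphology`.
#' @export
biological_loss <- function(scene_gen, ref = scene_gen,
                            cfg = constraint_config()) {
  g <- scene_like(scene_gen)
  r <- scene_like(ref)
  vol <- volume_penalty(volume_fractions(g$labels, g$cell_mask),
                        cfg$volume_ranges)
  conn_parts <- vapply(c("nucleus", "mitochondria", "er"), function(org) {
    mst_topology_penalty(component_graph(r$labels, org),
                         component_graph(g$labels, org))
  }, numeric(1))
  conn <- mean(conn_parts)
  morph <- morphology_penalty(aspect_ratio(g$cell_mask), cfg$aspect_range)
  list(total = cfg$lambda_volume * vol + cfg$lambda_connectivity * conn +
         cfg$lambda_morphology * morph,
       volume = vol, connectivity = conn, morphology = morph)
}

#' Plausibility metrics for the adaptive constraint monitor
#'
#' Three bounded scores consumed by the training-time constraint monitor:
#' `boundary_definition` maps the mean Sobel magnitude at organelle boundary
#' pixels through `x / (1 + x)`; `coherence` rescales Moran's I spatial
#' autocorrelation of the protein channel into `[0, 1]` (constant channels
#' score the neutral 0.5); `plausibility` is `1 - clamp(volume penalty +
#' morphology penalty, 0, 1)`.
#'
#' @param image 4-channel image.
#' @param labels organelle label map.
#' @param cell_mask cell footprint (default: labelled pixels).
#' @param cfg a [constraint_config()].
#' @return named numeric vector with `boundary_definition`, `coherence`,
#'   `plausibility`, each in `[0, 1]`.
#' @export
plausibility_metrics <- function(image, labels, cell_mask = labels > 0,
                                 cfg = constraint_config()) {
  arr <- as_channel_array(image)
  gm <- Reduce(`+`, lapply(seq_len(dim(arr)[3L]),
                           function(ch) sobel_magnitude(arr[, , ch]))) /
    dim(arr)[3L]
  boundary <- matrix(FALSE, nrow(labels), ncol(labels))
  for (k in seq_len(nrow(NEIGH4))) {
    sh <- shift_mat(labels + 0, NEIGH4[k, 1L], NEIGH4[k, 2L], fill = NA_real_)
    boundary <- boundary | (!is.na(sh) & sh != labels &
                              (labels > 0 | sh > 0))
  }
  bd <- if (any(boundary)) {
    m <- mean(gm[boundary]); m / (1 + m)
  } else 0
  mi <- morans_i(arr[, , 1L])
  coh <- if (is.na(mi)) 0.5 else (max(min(mi, 1), -1) + 1) / 2
  pen <- volume_penalty(volume_fractions(labels, cell_mask),
                        cfg$volume_ranges) +
    morphology_penalty(aspect_ratio(cell_mask), cfg$aspect_range)
  c(boundary_definition = bd, coherence = coh,
    plausibility = 1 - min(max(pen, 0), 1))
}
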