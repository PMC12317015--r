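test_that("scene generation is seeded-deterministic and hits its targets", {
  sp <- scene_spec(128, 128, localization_class = 0, seed = 4)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a, b)

  fr <- volume_fractions(a$organelle_labels, a$cell_mask)
  expect_gte(fr[["nucleus"]], 0.155)
  expect_lte(fr[["nucleus"]], 0.195)
  expect_lt(abs(fr[["mitochondria"]] - 0.125), 0.02)
  expect_lt(abs(fr[["er"]] - 0.10), 0.02)

  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_true(all(is.finite(a$image)))
  # labels only inside the cell footprint
  expect_true(all(a$organelle_labels[!a$cell_mask] == 0))
  expect_identical(dim(a$organelle_labels), dim(a$cell_mask))
  expect_false(any(a$missing_mask))
  expect_equal(sum(a$class_labels), 1)
})

test_that("protein channel painters follow the class family", {
  nucl <- tiny_scene(seed = 2, class_id = 0)     # nucleoplasm
  mito <- tiny_scene(seed = 2, class_id = 14)    # mitochondria
  neg <- tiny_scene(seed = 2, class_id = 18)     # negative
  in_mask_mean <- function(s, code) {
    mean(s$image[, , 1][s$organelle_labels == code])
  }
  out_mean <- function(s, code) {
    mean(s$image[, , 1][s$cell_mask & s$organelle_labels != code])
  }
  expect_gt(in_mask_mean(nucl, 1), out_mean(nucl, 1))
  expect_gt(in_mask_mean(mito, 2), out_mean(mito, 2))
  expect_lt(mean(neg$image[, , 1]), 0.1)
})

test_that("infeasible organelle fractions fail naming the organelle", {
  sp <- scene_spec(32, 32,
                   target_volume_fractions = c(nucleus = 0.33,
                                               mitochondria = 0.33,
                                               er = 0.33))
  expect_error(generate_scene(sp), "er")
  expect_error(scene_spec(32, 32,
                          target_volume_fractions = c(nucleus = 0.5,
                                                      mitochondria = 0.4,
                                                      er = 0.2)),
               "sum")
})

test_that("missing-pixel corruption zeroes the exact count", {
  img <- random_image(100, 100, channels = 4, seed = 9)
  out <- corrupt_missing(img, 0.1, seed = 3)
  expect_equal(sum(out$missing_mask), 1000)
  for (ch in 1:4) {
    expect_true(all(out$image[, , ch][out$missing_mask] == 0))
    expect_identical(out$image[, , ch][!out$missing_mask],
                     img[, , ch][!out$missing_mask])
  }
  unchanged <- corrupt_missing(img, 0, seed = 3)
  expect_identical(unchanged$image, img)
  expect_false(any(unchanged$missing_mask))
  expect_error(corrupt_missing(img, 1.0), "rate")
})

test_that("class sampling reproduces the frequency table within 3 sigma", {
  tab <- hpa_class_table()
  expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
  n <- 10000
  draws <- sample_classes(n, tab, seed = 123)
  counts <- table(factor(draws, levels = tab$class_id))
  for (i in seq_len(nrow(tab))) {
    expected <- n * tab$prob[i]
    sigma <- sqrt(n * tab$prob[i] * (1 - tab$prob[i]))
    expect_lt(abs(counts[[i]] - expected), 3 * sigma + 1e-9)
  }
})

test_that("CLAHE preserves degenerate histograms and the [0,1] range", {
  flat <- matrix(0.5, 32, 32)
  out <- clahe_enhance(flat, tiles = c(4, 4))
  expect_lt(max(out) - min(out), 1e-9)         # constant stays constant
  expect_lt(abs(mean(out) - 0.5), 0.05)        # up to bin quantization

  # 50/50 two-level checkerboard: every tile sees the same histogram, so
  # the remapping is shared and the output stays two-level
  two <- matrix(0.2, 32, 32)
  two[(row(two) + col(two)) %% 2 == 0] <- 0.8
  out2 <- clahe_enhance(two, tiles = c(2, 2))
  expect_lte(length(unique(round(as.numeric(out2), 6))), 2)

  rnd <- random_image(64, 64, seed = 5)
  out3 <- clahe_enhance(rnd)
  expect_gte(min(out3), 0)
  expect_lte(max(out3), 1)
})

test_that("patch extraction covers the grid and reflects at boundaries", {
  img <- random_image(512, 512, seed = 6)
  p <- extract_patches(img, size = 256, stride = 128)
  expect_length(p$patches, 9)
  expect_identical(sort(unique(p$offsets$row)), c(0, 128, 256))

  one <- extract_patches(random_image(256, 256, seed = 7), 256, 128)
  expect_length(one$patches, 1)
  expect_identical(one$patches[[1]], one$patches[[1]])
  expect_equal(one$offsets$row, 0)

  # reflection: a patch starting beyond the right edge mirrors the interior
  small <- matrix(1:16, 4, 4)
  ref <- extract_patches(small, size = 6, stride = 6)
  # out-of-bounds coordinate 5 reflects to coordinate 3
  expect_equal(ref$patches[[1]][5, 1], small[3, 1])
  expect_equal(ref$patches[[1]][1, 5], small[1, 3])
})

test_that("patch reassembly reconstructs the interior exactly", {
  img <- random_image(64, 64, seed = 8)
  p <- extract_patches(img, size = 32, stride = 16)
  back <- reassemble_patches(p$patches, p$offsets, 64, 64)
  expect_equal(back, img)
})

test_that("augmentation is seeded, shape-preserving, and involutive flips", {
  img <- random_image(32, 32, channels = 4, seed = 10)
  ident <- augment(img, rotation_deg = 0, flip_h = FALSE, flip_v = FALSE,
                   zoom = 1)
  expect_equal(ident, img, tolerance = 1e-12)

  once <- augment(img, 0, TRUE, FALSE, 1)
  twice <- augment(once, 0, TRUE, FALSE, 1)
  expect_equal(twice, img, tolerance = 1e-12)

  a <- augment(img, seed = 21)
  b <- augment(img, seed = 21)
  expect_identical(a, b)
  expect_identical(dim(a), dim(img))

  expect_error(augment(img, rotation_deg = 45), "rotation")
  expect_error(augment(img, zoom = 2), "zoom")
})

test_that("scene IO round-trips losslessly and flags lossy PNG export", {
  sc <- tiny_scene(seed = 12, class_id = 14, missing_rate = 0.05)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "scene1")
  write_scene(sc, path)
  back <- read_scene(path)
  expect_equal(back$image, sc$image, tolerance = 1e-6)  # float32 storage
  expect_identical(back$organelle_labels, sc$organelle_labels)
  expect_identical(back$cell_mask, sc$cell_mask)
  expect_identical(back$missing_mask, sc$missing_mask)
  expect_identical(back$class_labels, as.integer(sc$class_labels))

  # sidecar missing a required field
  side <- jsonlite::read_json(paste0(path, ".json"))
  side$class_labels <- NULL
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_scene(path), "class_labels")

  meta <- export_scene_png(sc, file.path(dir, "scene1"))
  expect_true(meta$lossy)
  expect_length(meta$files, 4)
  expect_true(all(file.exists(meta$files)))
})
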