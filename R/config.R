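# Run configuration (YAML, schema-checked against the default tree) and the
# ablation experiment presets.

run_config_defaults <- function() {
  list(
    seed = 1L,
    image_size = 64L,
    latent_dim = 64L,
    initial_lambda_sg = 0.75,
    initial_lambda_pg = 0.5,
    max_epochs = 200L,
    batch_size = 16L,
    learning_rate_g = 2e-4,
    learning_rate_d = 1e-4,
    adam_beta1 = 0.5,
    adam_beta2 = 0.999,
    scale_weights = c(0.6, 0.3, 0.1),
    pg_beta = 2.0,
    pg_tau = 5.0,
    lambda_homeostasis = 1.0,
    neighborhood_size = 8L,
    validation_interval = 5L,
    classification_threshold = 0.35,
    contrast_clip_limit = 2.0,
    patch_size = 256L,
    patch_stride = 128L,
    rotation_deg = 20,
    zoom_range = c(0.8, 1.2),
    dropout_rate = 0.3,
    l2_reg = 1e-5,
    fusion_temp = 2.0,
    lambda_bio = 0.1)
}

#' Load a run configuration
#'
#' Reads a YAML configuration file, validates every key against the default
#' schema (unknown keys are rejected by name), and merges user values over
#' the defaults. With no path, the pure defaults are returned.
#'
#' @param path optional YAML file path.
#' @param overrides optional named list applied after the file.
#' @return named list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(user)) {
    expected_len <- length(cfg[[nm]])
    val <- user[[nm]]
    if (is.list(val)) val <- unlist(val)
    if (!is.numeric(val) || length(val) != expected_len) {
      stop("configuration key '", nm, "' must be numeric of length ",
           expected_len)
    }
    cfg[[nm]] <- if (is.integer(cfg[[nm]])) as.integer(val) else val
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

PRESET_NAMES <- c("full", "sg_only", "pg_only", "no_fusion",
                  "no_multiscale", "no_bio", "single_generator",
                  "weight_grid", "scale_grid")

# Table-driven grids for the weighting ablations.
weight_grid_pairs <- function() {
  list(c(1.0, 0.0), c(0.8, 0.2), c(0.75, 0.5),
       c(0.6, 0.7), c(0.5, 0.8), c(0.0, 1.0))
}

scale_grid_triples <- function() {
  list(c(0.8, 0.2, 0.0), c(0.7, 0.3, 0.0), c(0.6, 0.3, 0.1),
       c(0.5, 0.3, 0.2), c(0.4, 0.4, 0.2), c(1, 1, 1) / 3)
}

#' Ablation preset toggles
#'
#' Maps a preset name to the component switches it flips relative to the
#' full configuration. Grid presets (`weight_grid`, `scale_grid`) expand to
#' one entry per grid point.
#'
#' @param name one of `"full"`, `"sg_only"`, `"pg_only"`, `"no_fusion"`,
#'   `"no_multiscale"`, `"no_bio"`, `"single_generator"`, `"weight_grid"`,
#'   `"scale_grid"`.
#' @return list of configurations, each a list with `label`, the
#'   `use_*` switches, `sg_S`, `sg_weights`, and optional fixed
#'   `lambda_sg`/`lambda_pg`.
#' @export
preset_config <- function(name = PRESET_NAMES) {
  name <- match.arg(name)
  base <- list(label = name, use_sg_loss = TRUE, use_pg_loss = TRUE,
               use_fusion = TRUE, use_bio_loss = TRUE,
               sg_S = 3L, sg_weights = c(0.6, 0.3, 0.1),
               lambda_sg = NULL, lambda_pg = NULL)
  single <- function(mods) {
    list(utils::modifyList(base, mods, keep.null = FALSE))
  }
  switch(name,
    full = single(list()),
    sg_only = single(list(use_pg_loss = FALSE)),
    pg_only = single(list(use_sg_loss = FALSE)),
    no_fusion = single(list(use_fusion = FALSE)),
    no_multiscale = single(list(sg_S = 1L, sg_weights = 1)),
    no_bio = single(list(use_bio_loss = FALSE)),
    single_generator = single(list(use_pg_loss = FALSE,
                                   use_fusion = FALSE)),
    weight_grid = lapply(weight_grid_pairs(), function(p) {
      utils::modifyList(base, list(
        label = sprintf("weights_sg%.2f_pg%.2f", p[1], p[2]),
        lambda_sg = p[1], lambda_pg = p[2]))
    }),
    scale_grid = lapply(scale_grid_triples(), function(w) {
      utils::modifyList(base, list(
        label = sprintf("scales_%.2f_%.2f_%.2f", w[1], w[2], w[3]),
        sg_weights = w))
    }))
}

#' Run an ablation preset at desk scale
#'
#' Trains the dual-gland GAN once per preset configuration on the supplied
#' scenes, samples each trained model, and evaluates the samples against
#' the real scenes, emitting one comparison row per configuration (the
#' shape of an ablation summary table).
#'
#' @param name preset name, see [preset_config()].
#' @param scenes training scenes.
#' @param epochs training epochs per configuration (desk scale, default 3).
#' @param n_eval samples drawn per configuration for evaluation.
#' @param seed integer seed.
#' @param ... forwarded to [dg_train()] (for example `net`, `ctrl`).
#' @return list with `summary` (tibble, one row per configuration) and
#'   `fits` (the trained models).
#' @export
run_preset <- function(name, scenes, epochs = 3L, n_eval = 24L, seed = 1L,
                       ...) {
  configs <- preset_config(name)
  net <- net_spec(image_size = dim(scenes[[1L]]$image)[1L])
  real_imgs <- lapply(scenes, function(s) s$image)
  fits <- list()
  gen_sets <- list()
  for (pc in configs) {
    sgc <- sg_config(S = pc$sg_S,
                     weights = scale_weights(pc$sg_weights / sum(pc$sg_weights)))
    st <- controller_state(
      lambda_sg = if (is.null(pc$lambda_sg)) 0.75 else pc$lambda_sg,
      lambda_pg = if (is.null(pc$lambda_pg)) 0.5 else pc$lambda_pg)
    ctrl <- if (is.null(pc$lambda_sg)) controller_config() else
      controller_config(validation_interval = epochs + 1L)  # frozen weights
    fit <- dg_train(scenes, net = net,
                    cfg = train_config(max_epochs = epochs, seed = seed),
                    ctrl = ctrl, sg_cfg = sgc,
                    use_sg_loss = pc$use_sg_loss,
                    use_pg_loss = pc$use_pg_loss,
                    use_bio_loss = pc$use_bio_loss,
                    use_fusion = pc$use_fusion,
                    state = st, ...)
    fits[[pc$label]] <- fit
    gen_sets[[pc$label]] <- dg_sample(fit, n_eval, seed = seed,
                                      use_fusion = pc$use_fusion)
  }
  report <- evaluate_generators(real_imgs, gen_sets)
  list(summary = report, fits = fits)
}

#' Consolidated report over multiple training runs
#'
#' Binds one [glance()] row per fitted model into a single tibble.
#'
#' @param fits named list of `dg_gan` fits.
#' @return tibble with one row per run.
#' @export
run_report <- function(fits) {
  stopifnot(length(fits) > 0)
  dplyr::bind_rows(lapply(fits, glance), .id = "run")
}
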