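# Dual-generator / shared-discriminator adversarial core. Two specialized
# generators (secretion-oriented SG, structure-oriented PG) are trained
# against one discriminator; each generator couples the non-saturating
# adversarial signal with its reconstruction loss (SG or PG), weighted by
# the adaptive controller, plus a biological-plausibility penalty.

#' Network specification
#'
#' @param latent_dim latent noise dimension (default 64).
#' @param base_channels hidden-layer width (default 128).
#' @param image_size square image side, a power of 2, at least 16
#'   (default 64; 32 is the usual desk-scale setting).
#' @param n_channels image channels (4).
#' @return object of class `net_spec`.
#' @export
net_spec <- function(latent_dim = 64L, base_channels = 128L,
                     image_size = 64L, n_channels = 4L) {
  if (image_size < 16L || bitwAnd(image_size, image_size - 1L) != 0L) {
    stop("image_size must be a power of 2, >= 16")
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 base_channels = as.integer(base_channels),
                 image_size = as.integer(image_size),
                 n_channels = as.integer(n_channels)),
            class = "net_spec")
}

#' Training configuration
#'
#' Defaults follow the framework's standard recipe: Adam(0.5, 0.999),
#' generator/discriminator learning rates 2e-4 / 1e-4 with cosine annealing
#' and warm restarts every 40 epochs, batch size 16, gradient clipping at
#' norm 1, dropout 0.3 and L2 regularization 1e-5, early stopping with
#' patience 10 and minimum delta 1e-4.
#'
#' @param max_epochs,batch_size,lr_g,lr_d,adam_beta1,adam_beta2 optimizer
#'   settings.
#' @param cosine_restart_period warm-restart period in epochs.
#' @param early_stop_patience,early_stop_min_delta early-stopping rule on
#'   the validation objective.
#' @param grad_clip_norm global gradient-norm clip.
#' @param dropout discriminator hidden dropout rate.
#' @param l2_reg L2 weight decay.
#' @param val_frac fraction of scenes held out for validation.
#' @param lambda_bio weight of the biological constraint penalty in each
#'   generator objective.
#' @param seed integer seed; training is deterministic given the seed.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 200L, batch_size = 16L, lr_g = 2e-4,
                         lr_d = 1e-4, adam_beta1 = 0.5, adam_beta2 = 0.999,
                         cosine_restart_period = 40L,
                         early_stop_patience = 10L,
                         early_stop_min_delta = 1e-4,
                         grad_clip_norm = 1.0, dropout = 0.3,
                         l2_reg = 1e-5, val_frac = 0.15,
                         lambda_bio = 0.1, seed = 1L) {
  stopifnot(max_epochs >= 1, batch_size >= 2, lr_g > 0, lr_d > 0,
            cosine_restart_period >= 1, early_stop_patience >= 1,
            grad_clip_norm > 0, dropout >= 0, dropout < 1, l2_reg >= 0,
            val_frac >= 0, val_frac < 0.5)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), lr_g = lr_g,
                 lr_d = lr_d, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2,
                 cosine_restart_period = as.integer(cosine_restart_period),
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_min_delta = early_stop_min_delta,
                 grad_clip_norm = grad_clip_norm, dropout = dropout,
                 l2_reg = l2_reg, val_frac = val_frac,
                 lambda_bio = lambda_bio, seed = as.integer(seed)),
            class = "train_config")
}

clamp_prob <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

#' Adversarial losses of the dual-generator value function
#'
#' Discriminator loss
#' `L_D = -mean log D(x) - mean log(1 - D(G_SG(z))) - mean log(1 - D(G_PG(z)))`
#' (both generators feed the shared discriminator); generator adversarial
#' terms use the non-saturating form `-mean log D(G(z))`. Probabilities are
#' clamped to `[1e-7, 1 - 1e-7]`, so all values are finite.
#'
#' @param d_real,d_fake_sg,d_fake_pg discriminator probabilities.
#' @return list with `l_d`, `l_adv_sg`, `l_adv_pg`.
#' @export
#' @examples
#' adversarial_losses(0.5, 0.5, 0.5)$l_d  # 3 * log(2)
adversarial_losses <- function(d_real, d_fake_sg, d_fake_pg) {
  p_r <- clamp_prob(d_real)
  p_s <- clamp_prob(d_fake_sg)
  p_p <- clamp_prob(d_fake_pg)
  list(l_d = -mean(log(p_r)) - mean(log(1 - p_s)) - mean(log(1 - p_p)),
       l_adv_sg = -mean(log(p_s)),
       l_adv_pg = -mean(log(p_p)))
}

#' Per-generator objective bookkeeping
#'
#' `total = adversarial + lambda_recon * reconstruction + lambda_bio * bio`,
#' where the reconstruction term is the SG or PG loss and `lambda_recon` the
#' controller-supplied weight.
#'
#' @param gen_kind `"sg"` or `"pg"`.
#' @param adv,recon,bio component values.
#' @param lambda_recon controller weight for the reconstruction loss.
#' @param lambda_bio biological penalty weight.
#' @return list with `total` and the named `components`.
#' @export
generator_objective <- function(gen_kind = c("sg", "pg"), adv, recon, bio,
                                lambda_recon, lambda_bio = 0.1) {
  gen_kind <- match.arg(gen_kind)
  comp <- c(adversarial = adv, reconstruction = lambda_recon * recon,
            biological = lambda_bio * bio)
  list(gen_kind = gen_kind, total = sum(comp), components = comp)
}

scene_to_vec <- function(scene, net) {
  img <- if (inherits(scene, "cell_scene")) scene$image else scene
  as.numeric(img)
}

vec_to_img <- function(v, net) {
  array(v, dim = c(net$image_size, net$image_size, net$n_channels))
}

#' Train the dual-gland GAN
#'
#' Alternating updates: one discriminator step per batch on the shared
#' value function, then one step for each generator combining the
#' non-saturating adversarial signal with its analytic reconstruction
#' gradient (multi-scale SG loss paired with the batch's real images;
#' compartment-aware PG loss using each paired scene's organelle map). The
#' adaptive controller adjusts the loss weights every validation interval;
#' the constraint monitor evaluates plausibility metrics every monitor
#' interval and resets the PG temporal decay on violation. Training stops
#' early when the validation objective stops improving.
#'
#' @param scenes list of `cell_scene` objects (all of the size given in
#'   `net`).
#' @param net a [net_spec()].
#' @param cfg a [train_config()].
#' @param ctrl a [controller_config()].
#' @param sg_cfg,pg_cfg loss configurations.
#' @param refs an [organelle_reference()].
#' @param constraint_cfg a [constraint_config()].
#' @param controller_mode `"pi"` or `"p"`.
#' @param use_sg_loss,use_pg_loss,use_bio_loss,use_fusion ablation switches.
#' @return object of class `dg_gan` with the networks, the per-epoch `log`
#'   tibble, and the best-validation checkpoint.
#' @export
dg_train <- function(scenes, net = net_spec(image_size = 32L),
                     cfg = train_config(), ctrl = controller_config(),
                     sg_cfg = sg_config(), pg_cfg = pg_config(),
                     refs = organelle_reference(),
                     constraint_cfg = constraint_config(),
                     controller_mode = c("pi", "p"),
                     use_sg_loss = TRUE, use_pg_loss = TRUE,
                     use_bio_loss = TRUE, use_fusion = TRUE,
                     state = controller_state()) {
  controller_mode <- match.arg(controller_mode)
  if (length(scenes) == 0) stop("dataset is empty")
  if (length(scenes) < cfg$batch_size) {
    stop("dataset must contain at least one full batch")
  }
  withr::with_seed(cfg$seed, dg_train_impl(
    scenes, net, cfg, ctrl, sg_cfg, pg_cfg, refs, constraint_cfg,
    controller_mode, use_sg_loss, use_pg_loss, use_bio_loss, use_fusion,
    state))
}

dg_train_impl <- function(scenes, net, cfg, ctrl, sg_cfg, pg_cfg, refs,
                          constraint_cfg, controller_mode,
                          use_sg_loss, use_pg_loss, use_bio_loss,
                          use_fusion, state = controller_state()) {
  d_img <- net$image_size^2 * net$n_channels
  x_all <- t(vapply(scenes, scene_to_vec, numeric(d_img), net = net))
  n <- nrow(x_all)
  n_val <- floor(cfg$val_frac * n)
  val_idx <- if (n_val >= 1) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  cmaps <- lapply(scenes, function(s) compartment_map(s$organelle_labels))

  g_sg <- mlp_init(c(net$latent_dim, net$base_channels, d_img))
  g_pg <- mlp_init(c(net$latent_dim, net$base_channels, d_img))
  disc <- mlp_init(c(d_img, net$base_channels, 1L))
  opt_sg <- adam_init(g_sg); opt_pg <- adam_init(g_pg)
  opt_d <- adam_init(disc)
  t_sg <- 0L; t_pg <- 0L; t_d <- 0L

  ops <- sg_operators(net$image_size, net$image_size, sg_cfg$S)
  t_since_trigger <- 0
  z_val <- matrix(stats::rnorm(max(length(val_idx), 4L) * net$latent_dim),
                  ncol = net$latent_dim)

  log_rows <- list()
  best_val <- Inf; best_nets <- NULL; best_epoch <- 0L; wait <- 0L
  gamma_sg <- 0.5; gamma_pg <- 0.5

  for (epoch in seq_len(cfg$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    lr_g <- cosine_lr(cfg$lr_g, epoch, cfg$cosine_restart_period)
    lr_d <- cosine_lr(cfg$lr_d, epoch, cfg$cosine_restart_period)
    perm <- sample(tr_idx)
    n_batch <- floor(length(perm) / cfg$batch_size)
    ep <- c(d = 0, adv_sg = 0, adv_pg = 0, rec_sg = 0, rec_pg = 0,
            bio_sg = 0, bio_pg = 0, tot_sg = 0, tot_pg = 0,
            c_sg = 0, c_pg = 0)
    for (b in seq_len(n_batch)) {
      bi <- perm[((b - 1L) * cfg$batch_size + 1L):(b * cfg$batch_size)]
      x <- x_all[bi, , drop = FALSE]
      nb <- length(bi)
      z1 <- matrix(stats::rnorm(nb * net$latent_dim), nb)
      z2 <- matrix(stats::rnorm(nb * net$latent_dim), nb)

      fw_sg <- mlp_forward(g_sg, z1)
      fw_pg <- mlp_forward(g_pg, z2)

      ## --- discriminator step (full value-function loss) ---
      fr <- mlp_forward(disc, x, cfg$dropout, training = TRUE)
      fs <- mlp_forward(disc, fw_sg$out, cfg$dropout, training = TRUE)
      fp <- mlp_forward(disc, fw_pg$out, cfg$dropout, training = TRUE)
      adv <- adversarial_losses(fr$out, fs$out, fp$out)
      # d(-mean log p)/dz = (p - 1)/n; d(-mean log(1-p))/dz = p/n
      gr <- mlp_backward(disc, fr$cache, grad_from_logit(fr$out,
                                                         (fr$out - 1) / nb),
                         cfg$dropout)
      gs <- mlp_backward(disc, fs$cache, grad_from_logit(fs$out, fs$out / nb),
                         cfg$dropout)
      gp <- mlp_backward(disc, fp$cache, grad_from_logit(fp$out, fp$out / nb),
                         cfg$dropout)
      gd <- add_grads(add_grads(gr$grads, gs$grads), gp$grads)
      t_d <- t_d + 1L
      upd <- adam_update(disc, gd, opt_d, lr_d, t_d, cfg$adam_beta1,
                         cfg$adam_beta2, cfg$l2_reg, cfg$grad_clip_norm)
      disc <- upd$net; opt_d <- upd$opt

      ## --- SG generator step ---
      res_sg <- generator_step(
        g_sg, opt_sg, fw_sg, disc, nb, cfg, lr_g, t_sg + 1L,
        recon_fn = if (use_sg_loss) function(img, i) {
          sg_backward(scenes[[bi[i]]]$image, img, sg_cfg, ops)
        } else NULL,
        lambda_recon = state$lambda_sg, net = net)
      g_sg <- res_sg$gnet; opt_sg <- res_sg$opt; t_sg <- t_sg + 1L

      ## --- PG generator step ---
      res_pg <- generator_step(
        g_pg, opt_pg, fw_pg, disc, nb, cfg, lr_g, t_pg + 1L,
        recon_fn = if (use_pg_loss) function(img, i) {
          pg_backward(img, cmaps[[bi[i]]], refs, t_since_trigger, pg_cfg)
        } else NULL,
        lambda_recon = state$lambda_pg, net = net)
      g_pg <- res_pg$gnet; opt_pg <- res_pg$opt; t_pg <- t_pg + 1L

      ## --- biological penalty (value only, one sample per batch) ---
      bio_sg <- bio_pg <- 0
      if (use_bio_loss) {
        img_s <- vec_to_img(fw_sg$out[1L, ], net)
        img_p <- vec_to_img(fw_pg$out[1L, ], net)
        bio_sg <- biological_loss(img_s, scenes[[bi[1L]]],
                                  constraint_cfg)$total
        bio_pg <- biological_loss(img_p, scenes[[bi[1L]]],
                                  constraint_cfg)$total
      }
      obj_sg <- generator_objective("sg", res_sg$adv, res_sg$recon, bio_sg,
                                    state$lambda_sg, cfg$lambda_bio)
      obj_pg <- generator_objective("pg", res_pg$adv, res_pg$recon, bio_pg,
                                    state$lambda_pg, cfg$lambda_bio)

      ep <- ep + c(adv$l_d, res_sg$adv, res_pg$adv, res_sg$recon,
                   res_pg$recon, bio_sg, bio_pg, obj_sg$total, obj_pg$total,
                   mean(fs$out), mean(fp$out))
    }
    ep <- ep / max(n_batch, 1L)

    ## fusion weights from mean discriminator confidences + state measures
    if (use_fusion) {
      img_s <- vec_to_img(mlp_forward(g_sg, z_val[1L, , drop = FALSE])$out[1L, ],
                          net)
      img_p <- vec_to_img(mlp_forward(g_pg, z_val[1L, , drop = FALSE])$out[1L, ],
                          net)
      mask_p <- infer_scene_masks(img_p)
      fst <- fusion_state(img_s, img_p, mask_p$labels,
                          c_sg = ep[["c_sg"]], c_pg = ep[["c_pg"]])
      gamma_sg <- fst$gamma_sg; gamma_pg <- fst$gamma_pg
    }

    ## constraint monitor
    pm <- c(boundary_definition = NA_real_, coherence = NA_real_,
            plausibility = NA_real_)
    t_since_trigger <- t_since_trigger + 1
    if (epoch %% ctrl$monitor_interval == 0L) {
      img_f <- dg_decode_fused(g_sg, g_pg, z_val[1L, , drop = FALSE], net,
                               gamma_sg, use_fusion)
      m <- infer_scene_masks(img_f)
      if (any(m$cell_mask) && sum(m$cell_mask) >= 2) {
        pm <- plausibility_metrics(img_f, m$labels, m$cell_mask,
                                   constraint_cfg)
        trig <- constraint_trigger(pm, ctrl, epoch)
        if (trig$triggered) t_since_trigger <- 0
      }
    }

    ## controller
    if (epoch %% ctrl$validation_interval == 0L) {
      state <- controller_step(state, ep[["tot_sg"]], ep[["tot_pg"]], ctrl,
                               controller_mode)
    }

    ## validation objective (fixed z, held-out reals)
    val_loss <- validation_objective(g_sg, g_pg, disc, x_all, val_idx,
                                     z_val, net)
    if (val_loss < best_val - cfg$early_stop_min_delta) {
      best_val <- val_loss
      best_nets <- list(g_sg = g_sg, g_pg = g_pg, disc = disc)
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
    }

    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, d_loss = ep[["d"]],
      adv_sg = ep[["adv_sg"]], adv_pg = ep[["adv_pg"]],
      recon_sg = ep[["rec_sg"]], recon_pg = ep[["rec_pg"]],
      bio_sg = ep[["bio_sg"]], bio_pg = ep[["bio_pg"]],
      loss_sg = ep[["tot_sg"]], loss_pg = ep[["tot_pg"]],
      lambda_sg = state$lambda_sg, lambda_pg = state$lambda_pg,
      conv_rate_sg = state$conv_rate_sg, conv_rate_pg = state$conv_rate_pg,
      gamma_sg = gamma_sg, gamma_pg = gamma_pg,
      boundary_definition = pm[["boundary_definition"]],
      coherence = pm[["coherence"]], plausibility = pm[["plausibility"]],
      lr_g = lr_g, val_loss = val_loss,
      wall_time = proc.time()[["elapsed"]] - t0)

    if (wait >= cfg$early_stop_patience) break
  }

  if (is.null(best_nets)) {
    best_nets <- list(g_sg = g_sg, g_pg = g_pg, disc = disc)
    best_epoch <- length(log_rows)
  }
  structure(list(g_sg = g_sg, g_pg = g_pg, disc = disc,
                 best = best_nets, best_epoch = best_epoch,
                 net = net, cfg = cfg, ctrl = ctrl,
                 controller_state = state,
                 gamma = c(gamma_sg = gamma_sg, gamma_pg = gamma_pg),
                 log = dplyr::bind_rows(log_rows)),
            class = "dg_gan")
}

grad_from_logit <- function(p, d_logit) {
  # convert a gradient expressed w.r.t. the pre-sigmoid logit into one
  # w.r.t. the sigmoid output, as mlp_backward expects d(out)
  d_logit / pmax(p * (1 - p), 1e-12)
}

add_grads <- function(a, b) {
  Map(function(x, y) list(W = x$W + y$W, b = x$b + y$b), a, b)
}

# One generator update: non-saturating adversarial gradient through the
# discriminator plus the reconstruction gradient, backpropagated jointly.
generator_step <- function(gnet, opt, fw, disc, nb, cfg, lr, t_step,
                           recon_fn, lambda_recon, net) {
  fd <- mlp_forward(disc, fw$out)
  p <- fd$out
  adv_loss <- -mean(log(clamp_prob(p)))
  bd <- mlp_backward(disc, fd$cache, grad_from_logit(p, (p - 1) / nb))
  d_gen_out <- bd$d_input
  recon_loss <- 0
  if (!is.null(recon_fn)) {
    for (i in seq_len(nb)) {
      img <- vec_to_img(fw$out[i, ], net)
      rb <- recon_fn(img, i)
      recon_loss <- recon_loss + rb$loss / nb
      d_gen_out[i, ] <- d_gen_out[i, ] +
        lambda_recon * as.numeric(rb$grad) / nb
    }
  }
  bg <- mlp_backward(gnet, fw$cache, d_gen_out)
  upd <- adam_update(gnet, bg$grads, opt, lr, t_step, cfg$adam_beta1,
                     cfg$adam_beta2, cfg$l2_reg, cfg$grad_clip_norm)
  list(gnet = upd$net, opt = upd$opt, adv = adv_loss, recon = recon_loss)
}

validation_objective <- function(g_sg, g_pg, disc, x_all, val_idx, z_val,
                                 net) {
  z <- z_val
  out_sg <- mlp_forward(g_sg, z)$out
  out_pg <- mlp_forward(g_pg, z)$out
  p_s <- mlp_forward(disc, out_sg)$out
  p_p <- mlp_forward(disc, out_pg)$out
  adv <- -mean(log(clamp_prob(p_s))) - mean(log(clamp_prob(p_p)))
  rec <- 0
  if (length(val_idx) > 0) {
    k <- min(length(val_idx), nrow(z))
    for (i in seq_len(k)) {
      rec <- rec + mean((out_sg[i, ] - x_all[val_idx[i], ])^2) / k +
        mean((out_pg[i, ] - x_all[val_idx[i], ])^2) / k
    }
  }
  adv + rec
}

dg_decode_fused <- function(g_sg, g_pg, z, net, gamma_sg, use_fusion) {
  img_s <- vec_to_img(mlp_forward(g_sg, z)$out[1L, ], net)
  if (!use_fusion) return(img_s)
  img_p <- vec_to_img(mlp_forward(g_pg, z)$out[1L, ], net)
  gamma_sg * img_s + (1 - gamma_sg) * img_p
}

#' Sample images from a trained dual-gland GAN
#'
#' Draws latent vectors and decodes them with the best-validation
#' checkpoint; with `use_fusion` the two generator outputs are combined per
#' sample with confidence weights computed from the stored discriminator
#' confidences and the per-sample secretion/structure measures.
#'
#' @param fit a `dg_gan` from [dg_train()].
#' @param n number of samples.
#' @param seed integer seed.
#' @param use_fusion fuse the two generators (default `TRUE`); otherwise
#'   returns SG-generator samples.
#' @param weights optional fixed `c(gamma_sg, gamma_pg)` overriding the
#'   adaptive weights.
#' @return list of `H x W x 4` arrays with values in `[0, 1]`.
#' @export
dg_sample <- function(fit, n, seed = 1L, use_fusion = TRUE, weights = NULL) {
  stopifnot(inherits(fit, "dg_gan"), n >= 0)
  if (n == 0) return(list())
  net <- fit$net
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n * net$latent_dim), n)
    out_sg <- mlp_forward(fit$best$g_sg, z)$out
    if (!use_fusion) {
      return(lapply(seq_len(n), function(i) vec_to_img(out_sg[i, ], net)))
    }
    out_pg <- mlp_forward(fit$best$g_pg, z)$out
    lapply(seq_len(n), function(i) {
      img_s <- vec_to_img(out_sg[i, ], net)
      img_p <- vec_to_img(out_pg[i, ], net)
      w <- weights
      if (is.null(w)) {
        mask_p <- infer_scene_masks(img_p)
        s_sec <- secretion_measure(img_s)
        s_str <- structure_measure(img_p, mask_p$labels)
        w <- fusion_weights(fit$gamma[["gamma_sg"]],
                            fit$gamma[["gamma_pg"]], s_sec, s_str)
      }
      clip01(fuse(img_s, img_p, w))
    })
  })
}

#' @export
print.dg_gan <- function(x, ...) {
  cat("<dg_gan> dual-generator GAN, image size ", x$net$image_size,
      ", trained ", nrow(x$log), " epochs (best epoch ", x$best_epoch,
      ")\n", sep = "")
  invisible(x)
}

#' Per-epoch training log of a fitted dual-gland GAN
#'
#' @param x a `dg_gan`.
#' @param ... unused.
#' @return the per-epoch log as a tibble.
#' @method tidy dg_gan
#' @export
tidy.dg_gan <- function(x, ...) x$log

#' One-row summary of a fitted dual-gland GAN
#'
#' @param x a `dg_gan`.
#' @param ... unused.
#' @return a one-row tibble with epochs run, best epoch, final losses and
#'   final loss weights.
#' @method glance dg_gan
#' @export
glance.dg_gan <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(epochs = nrow(x$log), best_epoch = x$best_epoch,
                 d_loss = last$d_loss, loss_sg = last$loss_sg,
                 loss_pg = last$loss_pg, lambda_sg = last$lambda_sg,
                 lambda_pg = last$lambda_pg, val_loss = last$val_loss)
}

#' Plot loss traces and adaptive-weight trajectories
#'
#' @param object a `dg_gan`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dg_gan
#' @export
autoplot.dg_gan <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$log[, c("epoch", "d_loss", "loss_sg", "loss_pg", "lambda_sg",
                   "lambda_pg")],
    -"epoch", names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Dual-gland GAN training trajectories") +
    ggplot2::theme_minimal()
}
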