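# Epoch-level adaptive loss-weight controller: exponentially weighted
# convergence-rate tracking, proportional-integral weight updates with step
# clipping and hard bounds, the biological constraint monitor, and a
# proportional-only fallback mode.

#' Controller configuration
#'
#' @param alpha_p proportional gain (default 0.05).
#' @param alpha_i integral gain (default 0.01).
#' @param target_rate desired convergence rate (default 0.02).
#' @param divergence_trigger the PI update applies only when the two
#'   convergence rates differ by more than this (default 0.3).
#' @param bounds_sg,bounds_pg hard weight bounds (defaults `[0.3, 1.2]` and
#'   `[0.2, 0.9]`).
#' @param max_step maximum per-epoch weight adjustment (default 0.15).
#' @param ewma_old,ewma_new convergence-rate EWMA coefficients (0.9 / 0.1).
#' @param monitor_interval epochs between constraint-monitor evaluations.
#' @param thresholds named monitor thresholds (`boundary_definition`,
#'   `coherence`, `plausibility`).
#' @param validation_interval epochs between controller invocations.
#' @return object of class `controller_config`.
#' @export
controller_config <- function(alpha_p = 0.05, alpha_i = 0.01,
                              target_rate = 0.02, divergence_trigger = 0.3,
                              bounds_sg = c(0.3, 1.2),
                              bounds_pg = c(0.2, 0.9),
                              max_step = 0.15, ewma_old = 0.9,
                              ewma_new = 0.1, monitor_interval = 10L,
                              thresholds = c(boundary_definition = 0.85,
                                             coherence = 0.80,
                                             plausibility = 0.75),
                              validation_interval = 5L) {
  stopifnot(bounds_sg[1] < bounds_sg[2], bounds_pg[1] < bounds_pg[2],
            ewma_new > 0, ewma_new < 1,
            abs(ewma_old + ewma_new - 1) < 1e-9, max_step > 0)
  structure(list(alpha_p = alpha_p, alpha_i = alpha_i,
                 target_rate = target_rate,
                 divergence_trigger = divergence_trigger,
                 bounds_sg = bounds_sg, bounds_pg = bounds_pg,
                 max_step = max_step, ewma_old = ewma_old,
                 ewma_new = ewma_new,
                 monitor_interval = as.integer(monitor_interval),
                 thresholds = thresholds,
                 validation_interval = as.integer(validation_interval)),
            class = "controller_config")
}

#' Initial controller state
#'
#' @param lambda_sg,lambda_pg initial loss weights (0.75 / 0.5).
#' @return object of class `controller_state`.
#' @export
controller_state <- function(lambda_sg = 0.75, lambda_pg = 0.5) {
  structure(list(lambda_sg = lambda_sg, lambda_pg = lambda_pg,
                 conv_rate_sg = 0, conv_rate_pg = 0,
                 integral_error_sg = 0, integral_error_pg = 0,
                 prev_loss_sg = NA_real_, prev_loss_pg = NA_real_,
                 epoch = 0L),
            class = "controller_state")
}

#' Convergence-rate EWMA update
#'
#' `rate <- 0.9 * rate_prev + 0.1 * |L_t - L_prev| / L_prev`: exponentially
#' weighted moving average of relative loss change.
#'
#' @param rate_prev previous rate.
#' @param l_t,l_prev current and previous loss values; `l_prev` must be
#'   positive.
#' @param ewma_old,ewma_new EWMA coefficients.
#' @return updated nonnegative rate.
#' @export
update_convergence <- function(rate_prev, l_t, l_prev,
                               ewma_old = 0.9, ewma_new = 0.1) {
  if (l_prev <= 0) stop("previous loss must be positive")
  ewma_old * rate_prev + ewma_new * abs(l_t - l_prev) / l_prev
}

clamp_step <- function(lambda, proposed, bounds, max_step) {
  delta <- min(max(proposed - lambda, -max_step), max_step)
  min(max(lambda + delta, bounds[1]), bounds[2])
}

#' Proportional-integral weight update
#'
#' Applied only when the convergence rates of the two generators diverge
#' (`|conv_sg - conv_pg| > divergence_trigger`). For each weight:
#' `error = target_rate - conv_rate`, the multiplicative proposal
#' `lambda * (1 + alpha_p * error + alpha_i * integral)` is computed with
#' the integral accumulated from previous applied steps, the change is
#' clipped to `max_step`, the result clamped to the bounds, and the error is
#' then added to the integral. Slow convergence (small rate) yields positive
#' error and a weight increase.
#'
#' @param state a [controller_state()].
#' @param cfg a [controller_config()].
#' @return updated `controller_state`.
#' @export
pi_step <- function(state, cfg = controller_config()) {
  if (abs(state$conv_rate_sg - state$conv_rate_pg) <= cfg$divergence_trigger) {
    return(state)
  }
  err_sg <- cfg$target_rate - state$conv_rate_sg
  err_pg <- cfg$target_rate - state$conv_rate_pg
  prop_sg <- state$lambda_sg *
    (1 + cfg$alpha_p * err_sg + cfg$alpha_i * state$integral_error_sg)
  prop_pg <- state$lambda_pg *
    (1 + cfg$alpha_p * err_pg + cfg$alpha_i * state$integral_error_pg)
  state$lambda_sg <- clamp_step(state$lambda_sg, prop_sg, cfg$bounds_sg,
                                cfg$max_step)
  state$lambda_pg <- clamp_step(state$lambda_pg, prop_pg, cfg$bounds_pg,
                                cfg$max_step)
  state$integral_error_sg <- state$integral_error_sg + err_sg
  state$integral_error_pg <- state$integral_error_pg + err_pg
  state
}

#' Proportional-only weight update
#'
#' The simpler alternative controller mode:
#' `lambda' = lambda * (1 + alpha * (conv_rate - target))`, with the same
#' step clipping and bounds as the PI rule.
#'
#' @param lambda current weight.
#' @param conv_rate convergence rate.
#' @param alpha adaptation rate (default 0.05).
#' @param target target rate (default 0.02).
#' @param bounds weight bounds.
#' @param max_step maximum change per call.
#' @return updated weight.
#' @export
simple_multiplicative_step <- function(lambda, conv_rate, alpha = 0.05,
                                       target = 0.02,
                                       bounds = c(0.3, 1.2),
                                       max_step = 0.15) {
  clamp_step(lambda, lambda * (1 + alpha * (conv_rate - target)), bounds,
             max_step)
}

#' Biological constraint monitor trigger
#'
#' True when any plausibility metric falls strictly below its threshold.
#' Meant to be evaluated at epochs divisible by the monitor interval.
#'
#' @param metrics named vector from [plausibility_metrics()].
#' @param cfg a [controller_config()].
#' @param epoch current epoch (must be divisible by `monitor_interval`).
#' @return list with `triggered` (logical) and `violated` (character vector
#'   of failing metric names).
#' @export
constraint_trigger <- function(metrics, cfg = controller_config(),
                               epoch = 0L) {
  if (epoch %% cfg$monitor_interval != 0L) {
    stop("constraint monitor runs only at epochs divisible by ",
         cfg$monitor_interval)
  }
  viol <- names(cfg$thresholds)[metrics[names(cfg$thresholds)] <
                                  cfg$thresholds]
  list(triggered = length(viol) > 0L, violated = viol)
}

#' Weight sensitivity probe
#'
#' Evaluates a user-supplied deterministic scoring function at the current
#' weight perturbed by -20%, 0 and +20%, without mutating any state.
#'
#' @param objective `function(lambda) -> scalar score`.
#' @param lambda_current current weight.
#' @param delta relative perturbation (default 0.20).
#' @return tibble with `lambda` and `score`.
#' @export
sensitivity_probe <- function(objective, lambda_current, delta = 0.20) {
  lams <- lambda_current * c(1 - delta, 1, 1 + delta)
  tibble::tibble(lambda = lams,
                 score = vapply(lams, objective, numeric(1)))
}

#' One controller invocation from fresh loss values
#'
#' Updates convergence-rate EWMAs from the latest SG / PG generator losses
#' (first call only records them), then applies the requested weight-update
#' rule.
#'
#' @param state a [controller_state()].
#' @param loss_sg,loss_pg current generator losses.
#' @param cfg a [controller_config()].
#' @param mode `"pi"` (default) or `"p"` for the proportional-only rule.
#' @return updated `controller_state`.
#' @export
controller_step <- function(state, loss_sg, loss_pg,
                            cfg = controller_config(),
                            mode = c("pi", "p")) {
  mode <- match.arg(mode)
  if (is.finite(state$prev_loss_sg) && state$prev_loss_sg > 0) {
    state$conv_rate_sg <- update_convergence(state$conv_rate_sg, loss_sg,
                                             state$prev_loss_sg,
                                             cfg$ewma_old, cfg$ewma_new)
  }
  if (is.finite(state$prev_loss_pg) && state$prev_loss_pg > 0) {
    state$conv_rate_pg <- update_convergence(state$conv_rate_pg, loss_pg,
                                             state$prev_loss_pg,
                                             cfg$ewma_old, cfg$ewma_new)
  }
  state$prev_loss_sg <- loss_sg
  state$prev_loss_pg <- loss_pg
  if (mode == "pi") {
    state <- pi_step(state, cfg)
  } else {
    state$lambda_sg <- simple_multiplicative_step(
      state$lambda_sg, state$conv_rate_sg, cfg$alpha_p, cfg$target_rate,
      cfg$bounds_sg, cfg$max_step)
    state$lambda_pg <- simple_multiplicative_step(
      state$lambda_pg, state$conv_rate_pg, cfg$alpha_p, cfg$target_rate,
      cfg$bounds_pg, cfg$max_step)
  }
  state$epoch <- state$epoch + 1L
  state
}
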