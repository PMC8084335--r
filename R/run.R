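#' Run a full adaptation/de-adaptation schedule through a learning model
#'
#' Simulates the 305-trial schedule (155 adaptation trials in the condition's
#' force field, then 150 de-adaptation trials in the null field, or under the
#' partial error clamp for LIPF_PEC) with either the point-mass OFC learner
#' or the two-joint six-muscle V-shaped learner, in the flat
#' (internal-model-only) or hierarchical (failure-driven kinematic plan)
#' variant. Simulation field gains follow the model configurations, not the
#' experimental gains. Deterministic and noise-free.
#'
#' @param model `"ofc"` or `"vs"`.
#' @param variant `"flat"` or `"hierarchical"`.
#' @param condition `"VDCF"`, `"LIPF_NULL"`, `"LIPF_PEC"`, `"PSPF"` or
#'   `"CPVF"`.
#' @param cfg An [ofc_config()] or [vs_config()] matching `model`; defaults
#'   are built when `NULL`.
#' @param keep_trajectories Keep every per-trial trajectory table (memory
#'   permitting); otherwise only per-trial metrics are retained.
#' @return Object of class `"condition_result"`: a list with `model`,
#'   `variant`, `condition`, a per-trial data frame `trials` (columns
#'   `trial`, `phase`, `trial_in_phase`, `TE_mm`, `LD_mm`, `plan` (aim bias
#'   in degrees for OFC, via-point deflection in mm for VS), `alpha` (OFC
#'   only), `cost`, `valid`), and optionally `trajectories`.
#' @export
#' @examples
#' \donttest{
#' res <- run_condition("ofc", "hierarchical", "LIPF_NULL")
#' summary(res)
#' }
run_condition <- function(model = c("ofc", "vs"),
                          variant = c("flat", "hierarchical"),
                          condition = c("VDCF", "LIPF_NULL", "LIPF_PEC",
                                        "PSPF", "CPVF"),
                          cfg = NULL, keep_trajectories = FALSE) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  condition <- match.arg(condition)
  if (model == "ofc")
    run_condition_ofc(variant, condition, cfg %||% ofc_config(),
                      keep_trajectories)
  else
    run_condition_vs(variant, condition, cfg %||% vs_config(),
                     keep_trajectories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ofc_sim_field <- function(cfg, condition) {
  switch(condition,
    VDCF = field_spec("VDCF", b1 = cfg$vdcf_b1),
    LIPF_NULL = , LIPF_PEC = field_spec("LIPF", k1 = cfg$lipf_k1),
    PSPF = field_spec("PSPF", k2 = cfg$pspf_k2),
    CPVF = field_spec("CPVF", b1 = cfg$cpvf_b1, k1 = cfg$cpvf_k1))
}

run_condition_ofc <- function(variant, condition, cfg, keep_trajectories) {
  trained <- ofc_sim_field(cfg, condition)
  null_f <- field_spec("NULL")
  pec <- if (condition == "LIPF_PEC")
    channel_spec(cfg$pec_stiffness, cfg$pec_damping) else NULL
  n_adapt <- 155L; n_deadapt <- 150L; n_total <- n_adapt + n_deadapt
  bias <- bias_state(b = cfg$bias_b, r = cfg$bias_r,
                     cost_threshold = cfg$cost_threshold)
  rows <- vector("list", n_total)
  trajs <- if (keep_trajectories) vector("list", n_total) else NULL
  for (i in seq_len(n_total)) {
    adapt <- i <= n_adapt
    alpha <- alpha_schedule(i, n_adapt = n_adapt, n_total = n_total)
    phi <- if (variant == "hierarchical") bias$phi else 0
    pol <- ofc_policy(cfg, trained, alpha = alpha, phi_deg = phi)
    traj <- ofc_simulate_reach(pol,
                               true_field = if (adapt) trained else null_f,
                               clamp = if (adapt) NULL else pec)
    mt <- trial_metrics(traj)
    cost <- attr(traj, "motor_cost")
    if (variant == "hierarchical") {
      theta <- endpoint_theta_deg(attr(traj, "endpoint"))
      failed <- abs(mt$TE_mm) > TARGET_RADIUS_MM
      bias <- update_bias(bias, theta, failed, cost)
    }
    rows[[i]] <- data.frame(
      trial = i,
      phase = if (adapt) "adaptation" else "de_adaptation",
      trial_in_phase = if (adapt) i else i - n_adapt,
      TE_mm = mt$TE_mm, LD_mm = mt$LD_mm,
      plan = phi, alpha = alpha, cost = cost, valid = mt$valid)
    if (keep_trajectories) trajs[[i]] <- traj
  }
  new_condition_result("ofc", variant, condition,
                       do.call(rbind, rows), cfg, trajs)
}

new_condition_result <- function(model, variant, condition, trials, cfg,
                                 trajectories = NULL) {
  structure(list(model = model, variant = variant, condition = condition,
                 trials = trials, cfg = cfg, trajectories = trajectories),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result> %s model, %s variant, condition %s\n",
              toupper(x$model), x$variant, x$condition))
  tr <- x$trials
  cat(sprintf("  %d trials (%d adaptation + %d de-adaptation)\n",
              nrow(tr), sum(tr$phase == "adaptation"),
              sum(tr$phase == "de_adaptation")))
  cat(sprintf("  first-trial TE %.1f mm; final de-adaptation LD %.2f mm\n",
              tr$TE_mm[1L],
              mean(utils::tail(tr$LD_mm[tr$phase == "de_adaptation"], 20L),
                   na.rm = TRUE)))
  invisible(x)
}

#' Epoch summary of a simulated condition
#'
#' Means of TE and LD over the six canonical reporting epochs (1st, 3rd-5th
#' and last-20 trials of each phase).
#'
#' @param object A [run_condition()] result.
#' @param ... Unused.
#' @return Data frame with one row per epoch: `epoch`, `phase`, `TE_mm`,
#'   `LD_mm`.
#' @export
summary.condition_result <- function(object, ...) {
  tr <- object$trials
  eps <- epoch_spec()
  rows <- lapply(names(eps), function(nm) {
    e <- eps[[nm]]
    sel <- tr[tr$phase == e$phase & tr$trial_in_phase %in% e$trials, ]
    data.frame(epoch = nm, phase = e$phase,
               TE_mm = mean(sel$TE_mm, na.rm = TRUE),
               LD_mm = mean(sel$LD_mm, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Learning curves of a simulated condition
#'
#' Base-graphics plot of per-trial TE (open circles) and LD (filled circles)
#' with the target radius band and the phase boundary.
#'
#' @param x A [run_condition()] result.
#' @param ... Passed to [plot()].
#' @export
plot.condition_result <- function(x, ...) {
  tr <- x$trials
  ylim <- range(c(tr$TE_mm, tr$LD_mm, 10, -10), na.rm = TRUE)
  plot(tr$trial, tr$TE_mm, pch = 1, cex = 0.6, ylim = ylim,
       xlab = "trial", ylab = "deviation (mm)",
       main = sprintf("%s %s, %s", toupper(x$model), x$variant,
                      x$condition), ...)
  graphics::points(tr$trial, tr$LD_mm, pch = 16, cex = 0.6,
                   col = "grey40")
  graphics::abline(h = c(-TARGET_RADIUS_MM, TARGET_RADIUS_MM),
                   col = "darkgreen", lty = 3)
  graphics::abline(v = sum(tr$phase == "adaptation") + 0.5, lty = 2)
  graphics::legend("topright", c("TE", "LD"), pch = c(1, 16),
                   col = c("black", "grey40"), bty = "n")
  invisible(x)
}

#' Tidy per-trial table of a condition result
#'
#' @param x A [run_condition()] result.
#' @param ... Unused.
#' @return The per-trial data frame with a `model`, `variant` and
#'   `condition` column prepended.
#' @export
as.data.frame.condition_result <- function(x, ...) {
  cbind(model = x$model, variant = x$variant, condition = x$condition,
        x$trials)
}
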