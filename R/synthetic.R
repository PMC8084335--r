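#' @title Synthetic multi-participant behavioral data
#'
#' @description A phenomenological generator (not a third learning model):
#' it produces per-trial TE/LD series and trajectory tables with the
#' statistical structure the analysis pipeline assumes — first-trial target
#' errors matching the reported group statistics, a latent via-point-style
#' deflection following the retention/sensitivity recursion, Gaussian trial
#' noise, and optional injected pathologies (short reaches, an unstable
#' participant) to exercise the exclusion and screening rules. Everything is
#' seeded and reproducible.
#' @name synthetic-data
NULL

#' Generator configuration
#'
#' Defaults emulate the TE-inducing field groups: the first-trial TE
#' distribution is 112.6 +/- 38.0 mm (n = 15) as reported for the linearly
#' increasing position-dependent field, pushing toward -x; the first
#' de-adaptation TE is scaled by `deadapt_frac` (default 44.3/112.6, the
#' reported ratio) with opposite sign (after-effect). The latent deflection
#' follows `dx' = b dx - r TE` with retention `b` and sensitivity `r`.
#'
#' @param n_participants Number of participants.
#' @param te1_mean,te1_sd First-adaptation-trial TE distribution across
#'   participants, mm (magnitude; the field sign is applied internally).
#' @param field_sign Sign of the field push on TE (-1: toward -x).
#' @param deadapt_frac First de-adaptation trial drive as a fraction of the
#'   participant's adaptation drive (opposite sign).
#' @param b,r Retention and sensitivity of the latent deflection recursion.
#' @param noise_sd Trial-to-trial TE/LD noise, mm.
#' @param n_baseline,n_adapt,n_deadapt Trials per phase.
#' @param ld_scale LD produced per mm of latent deflection (mid-reach
#'   expression of the plan).
#' @param duration_mean,duration_sd Movement duration, s (reaches take
#'   400 +/- 50 ms over 150 mm).
#' @param reach_mm Reach distance, mm.
#' @param target_radius_mm Target radius, mm.
#' @return List of class `"gen_config"`.
#' @export
gen_config <- function(n_participants = 15L,
                       te1_mean = 112.6, te1_sd = 38.0, field_sign = -1,
                       deadapt_frac = 44.3 / 112.6,
                       b = 0.95, r = 0.45, noise_sd = 2,
                       n_baseline = 50L, n_adapt = 155L, n_deadapt = 150L,
                       ld_scale = 0.55,
                       duration_mean = 0.400, duration_sd = 0.050,
                       reach_mm = 150, target_radius_mm = 7.5) {
  stopifnot(te1_sd >= 0, noise_sd >= 0, n_participants >= 1,
            abs(field_sign) == 1)
  structure(as.list(environment()), class = "gen_config")
}

#' Generate per-trial TE/LD series for each participant
#'
#' Each participant draws an adaptation drive `D ~ N(te1_mean, te1_sd)`
#' (signed by `field_sign`); on trial `i`, `TE_i = D_phase + dx_i + noise`
#' and the latent deflection follows `dx' = b dx - r TE` (active from the
#' first failure), so TE relaxes geometrically toward the recursion's fixed
#' point `(1 - b) D / (1 - b + r)`. De-adaptation flips the drive to the
#' after-effect `-deadapt_frac * D`. LD mixes the mid-reach expression of
#' the latent deflection (`ld_scale * dx`) with a drive-proportional push.
#'
#' @param cfg A [gen_config()].
#' @param seed Integer seed (mandatory: the generator is stochastic).
#' @return Data frame with columns `participant`, `phase`, `trial`
#'   (within-phase), `TE_mm`, `LD_mm`, `dx_mm` (the latent deflection).
#' @export
gen_te_series <- function(cfg, seed) {
  stopifnot(inherits(cfg, "gen_config"), is.numeric(seed))
  set.seed(seed)
  out <- vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    D <- cfg$field_sign * stats::rnorm(1, cfg$te1_mean, cfg$te1_sd)
    drive <- c(rep(0, cfg$n_baseline), rep(D, cfg$n_adapt),
               rep(-cfg$deadapt_frac * D, cfg$n_deadapt))
    phase <- rep(c("baseline", "adaptation", "de_adaptation"),
                 c(cfg$n_baseline, cfg$n_adapt, cfg$n_deadapt))
    n <- length(drive)
    te <- ld <- dx <- numeric(n)
    dxi <- 0
    active <- FALSE
    for (i in seq_len(n)) {
      dx[i] <- dxi
      te[i] <- drive[i] + dxi + stats::rnorm(1, 0, cfg$noise_sd)
      ld[i] <- cfg$ld_scale * dxi + 0.15 * drive[i] +
        stats::rnorm(1, 0, cfg$noise_sd)
      failed <- abs(te[i]) > cfg$target_radius_mm
      if (failed) active <- TRUE
      if (active)
        dxi <- if (failed) cfg$b * dxi - cfg$r * te[i] else cfg$b * dxi
    }
    out[[p]] <- data.frame(
      participant = p, phase = phase,
      trial = c(seq_len(cfg$n_baseline), seq_len(cfg$n_adapt),
                seq_len(cfg$n_deadapt)),
      TE_mm = te, LD_mm = ld, dx_mm = dx)
  }
  res <- do.call(rbind, out)
  attr(res, "seed") <- seed
  res
}

# lateral shape bases on the forward axis: f_end is 1 at the target and 0 at
# mid-reach; f_mid is 1 at mid-reach and 0 at start/target
shape_end <- function(s) pmax(0, (s - 0.5) / 0.5)^2
shape_mid <- function(s) sin(pi * pmin(pmax(s, 0), 1))

#' Generate a full trajectory dataset
#'
#' Turns [gen_te_series()] output into per-sample trajectory tables in the
#' standard format: forward motion is a minimum-jerk profile over the
#' participant's drawn duration, and the lateral profile is a two-basis
#' expansion (an endpoint-loaded ramp and a mid-reach bump) solved so the
#' measured TE and LD of each trial equal the generated series values.
#' Pathologies can be injected to exercise the analysis rules: trials with
#' reach distance under 75 mm, and one participant with an unstable
#' (jumping, outlying) late de-adaptation LD series.
#'
#' @param cfg A [gen_config()].
#' @param seed Integer seed.
#' @param condition Condition label written to the table.
#' @param short_trials Integer vector of row indices into the generated
#'   series (one row per participant-trial) simulated as short reaches
#'   (60 mm).
#' @param unstable_participant Optional participant index whose last-100
#'   de-adaptation LDs get three >20 mm sign-flipping jumps and an offset.
#' @param dt Sample step, s.
#' @return List with `trajectories` (one trajectory table, with columns
#'   `participant`, `condition`, `phase`, `trial`, `t_s`, `x_m`, `y_m`,
#'   `vx_ms`, `vy_ms`), `series` (the generated per-trial table) and
#'   `seed`.
#' @export
gen_trajectory_dataset <- function(cfg, seed, condition = "LIPF_NULL",
                                   short_trials = integer(0),
                                   unstable_participant = NULL,
                                   dt = 0.010) {
  series <- gen_te_series(cfg, seed)
  # durations drawn after the series, still under the same seed stream
  if (!is.null(unstable_participant)) {
    stopifnot(unstable_participant %in% seq_len(cfg$n_participants))
    sel <- series$participant == unstable_participant &
      series$phase == "de_adaptation"
    idx <- which(sel)
    last100 <- utils::tail(idx, 100L)
    jump_at <- last100[c(10L, 40L, 70L)]
    series$LD_mm[sel] <- series$LD_mm[sel] + 25      # outlying mean
    for (j in jump_at) {
      series$LD_mm[j] <- 30
      series$LD_mm[j + 1L] <- -30                    # >20 mm sign flip
    }
  }
  rows <- vector("list", nrow(series))
  for (k in seq_len(nrow(series))) {
    rec <- series[k, ]
    dur <- max(0.2, stats::rnorm(1, cfg$duration_mean, cfg$duration_sd))
    reach <- if (k %in% short_trials) 60 else cfg$reach_mm
    short <- reach < 75
    tt <- seq(0, dur * 1.25, by = dt)
    s <- pmin(tt / dur, 1)
    pos <- 10 * s^3 - 15 * s^4 + 6 * s^5
    y <- reach / 1000 * pos
    # lateral profile: solve the two-basis expansion for the trial's TE/LD
    a_end <- rec$TE_mm
    a_mid <- rec$LD_mm - shape_end(0.5) * a_end
    x <- (a_end * shape_end(pos) + a_mid * shape_mid(pos)) / 1000
    if (short) x <- x * 0
    vy <- c(diff(y) / dt, 0)
    vx <- c(diff(x) / dt, 0)
    rows[[k]] <- data.frame(
      participant = rec$participant, condition = condition,
      phase = rec$phase, trial = rec$trial,
      t_s = tt, x_m = x, y_m = y, vx_ms = vx, vy_ms = vy)
  }
  list(trajectories = do.call(rbind, rows), series = series, seed = seed)
}

#' Recover retention and sensitivity of the deflection update rule
#'
#' Least-squares fit of the linear recursion `dx_{i+1} = b dx_i - r TE_i`
#' from observed deflection and target-error series; exact on noiseless
#' data generated by the recursion.
#'
#' @param te Per-trial TE series (mm or m, consistent with `dx`).
#' @param dx Per-trial deflection series, same length.
#' @return Object of class `"update_rule_fit"` with elements `b`, `r`,
#'   `sigma` (residual sd), `n`, and `identifiable` (`FALSE`, with `b`/`r`
#'   `NA`, when the regressors are rank-deficient, e.g. a constant-zero TE
#'   series).
#' @export
#' @examples
#' dx <- Reduce(function(d, te) 0.95 * d - 0.45 * te, rep(-10, 30),
#'              accumulate = TRUE)
#' fit_update_rule(rep(-10, 30), dx[1:30])
fit_update_rule <- function(te, dx) {
  stopifnot(length(te) == length(dx), length(te) >= 10)
  n <- length(dx)
  y <- dx[-1L]
  X <- cbind(dx_prev = dx[-n], te_neg = -te[-n])
  qrX <- qr(X)
  if (qrX$rank < 2L) {
    fit <- structure(list(b = NA_real_, r = NA_real_, sigma = NA_real_,
                          n = n, identifiable = FALSE),
                     class = "update_rule_fit")
    return(fit)
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  structure(list(b = unname(beta[1L]), r = unname(beta[2L]),
                 sigma = sqrt(sum(res^2) / max(1, n - 3)), n = n,
                 identifiable = TRUE),
            class = "update_rule_fit")
}

#' @export
coef.update_rule_fit <- function(object, ...) {
  c(b = object$b, r = object$r)
}

#' @export
print.update_rule_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("<update_rule_fit> unidentifiable (rank-deficient series)\n")
  } else {
    cat(sprintf(
      "<update_rule_fit> b = %.4f, r = %.4f (residual sd %.3g, n = %d)\n",
      x$b, x$r, x$sigma, x$n))
  }
  invisible(x)
}
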