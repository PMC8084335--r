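#' Force-field specification
#'
#' Describes one of the force environments used in the reaching task: the
#' velocity-dependent curl field (VDCF), the linearly increasing
#' position-dependent field (LIPF), the positively skewed position-dependent
#' field (PSPF), the combined position- and velocity-dependent field (CPVF),
#' or the unperturbed null field. Coordinates are in meters relative to the
#' start-circle center, with +y pointing at the target 0.150 m away.
#'
#' Experimental gains are the defaults (`b1` = 14 N s/m, `k1` = 60 N/m,
#' `k2` = 20868 N/m); the model simulations use their own gains (see
#' [ofc_config()] and [vs_config()]). Only the gains relevant to `kind` are
#' ever read.
#'
#' @param kind Field type, one of `"NULL"`, `"VDCF"`, `"LIPF"`, `"PSPF"`,
#'   `"CPVF"`.
#' @param b1 Viscous curl gain, N s/m (VDCF and CPVF).
#' @param k1 Linear position gain, N/m (LIPF and CPVF).
#' @param k2 Skewed-field gain, N/m (PSPF).
#' @return An object of class `"field_spec"`.
#' @export
#' @examples
#' f <- field_spec("VDCF", b1 = 14)
#' field_force(f, pos = c(0, 0.05), vel = c(0, 0.5))
field_spec <- function(kind = c("NULL", "VDCF", "LIPF", "PSPF", "CPVF"),
                       b1 = 14, k1 = 60, k2 = 20868) {
  kind <- match.arg(kind)
  stopifnot(b1 >= 0, k1 >= 0, k2 >= 0)
  structure(list(kind = kind, b1 = b1, k1 = k1, k2 = k2),
            class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  gains <- switch(x$kind,
    "NULL" = "",
    VDCF = sprintf(" (b1 = %g N s/m)", x$b1),
    LIPF = sprintf(" (k1 = %g N/m)", x$k1),
    PSPF = sprintf(" (k2 = %g N/m)", x$k2),
    CPVF = sprintf(" (k1 = %g N/m, b1 = %g N s/m)", x$k1, x$b1))
  cat(sprintf("<field_spec> %s%s\n", x$kind, gains))
  invisible(x)
}

#' Evaluate a force field at a hand state
#'
#' Literal evaluation of the field equations. The PSPF argument
#' `pi + 40 y` is in radians with `y` in meters, which with the default gain
#' yields order-1 N forces that vanish at the start and near the target, and
#' peak in the first half of the reach. The CPVF is the LIPF term minus the
#' VDCF term, with the printed minus sign kept as written (this flips the
#' curl direction relative to the plain VDCF).
#'
#' @param spec A [field_spec()].
#' @param pos Hand position, 2-vector, m (origin at start-circle center).
#' @param vel Hand velocity, 2-vector, m/s.
#' @return Force on the hand, `c(Fx, Fy)`, N.
#' @export
field_force <- function(spec, pos, vel = c(0, 0)) {
  stopifnot(inherits(spec, "field_spec"),
            length(pos) == 2L, length(vel) == 2L)
  if (!all(is.finite(pos)) || !all(is.finite(vel)))
    stop("non-finite hand state: invalid trajectory sample")
  switch(spec$kind,
    "NULL" = c(0, 0),
    VDCF = spec$b1 * c(-vel[2L], vel[1L]),
    LIPF = c(-spec$k1 * pos[2L], 0),
    PSPF = {
      a <- pi + 40 * pos[2L]
      c(-spec$k2 * (cos(a) + 1) / a^5, 0)
    },
    CPVF = c(-spec$k1 * pos[2L], 0) - spec$b1 * c(-vel[2L], vel[1L]))
}

#' Partial error clamp (PEC) channel
#'
#' A one-dimensional spring-damper channel along the straight start-to-target
#' line (x = 0), active only over the last part of the movement
#' (y > `activation_y`, default 75 mm), so the mid-reach lateral deviation is
#' left unconstrained while endpoint errors are suppressed. The experimental
#' clamp used 800 N/m and 45 N s/m; the model simulations use stiffer
#' channels (see [ofc_config()], [vs_config()]).
#'
#' @param stiffness Channel spring constant, N/m.
#' @param damping Channel damper, N s/m.
#' @param activation_y y threshold above which the channel acts, m.
#' @return An object of class `"channel_spec"`.
#' @export
channel_spec <- function(stiffness = 800, damping = 45, activation_y = 0.075) {
  stopifnot(stiffness >= 0, damping >= 0)
  structure(list(stiffness = stiffness, damping = damping,
                 activation_y = activation_y),
            class = "channel_spec")
}

#' Channel force of the partial error clamp
#'
#' @param spec A [channel_spec()].
#' @inheritParams field_force
#' @return `c(Fx, 0)`, N; zero while `y <= activation_y`.
#' @export
channel_force <- function(spec, pos, vel = c(0, 0)) {
  stopifnot(inherits(spec, "channel_spec"))
  if (pos[2L] <= spec$activation_y) return(c(0, 0))
  c(-spec$stiffness * pos[1L] - spec$damping * vel[1L], 0)
}

#' Endpoint lock (terminal spring)
#'
#' The stiff two-dimensional spring-damper that freezes the hand at its final
#' position: it engages, permanently for the rest of the trial, at the first
#' sample where hand speed drops below `speed_threshold` (20 mm/s), anchoring
#' at the position at engagement. It both defines the movement endpoint and
#' prevents corrective sub-movements.
#'
#' @param stiffness Spring constant, N/m.
#' @param damping Damper, N s/m.
#' @param speed_threshold Engagement speed, m/s.
#' @return An object of class `"endpoint_lock"` (initially disengaged).
#' @export
endpoint_lock_spec <- function(stiffness = 500, damping = 50,
                               speed_threshold = 0.020) {
  structure(list(stiffness = stiffness, damping = damping,
                 speed_threshold = speed_threshold,
                 engaged = FALSE, anchor = c(NA_real_, NA_real_)),
            class = "endpoint_lock")
}

#' Advance the endpoint lock by one simulation step
#'
#' Latching: once engaged the lock stays engaged and its anchor is fixed.
#' The caller is responsible for only stepping the lock after movement onset
#' (the hand starts at rest, below threshold).
#'
#' @param spec An [endpoint_lock_spec()] (possibly already engaged).
#' @inheritParams field_force
#' @return `list(force = c(Fx, Fy), spec = updated lock)`.
#' @export
endpoint_lock_step <- function(spec, pos, vel) {
  stopifnot(inherits(spec, "endpoint_lock"))
  newly <- FALSE
  if (!spec$engaged && sqrt(sum(vel^2)) < spec$speed_threshold) {
    spec$engaged <- TRUE
    spec$anchor <- pos
    newly <- TRUE
  }
  # zero at the engagement instant: the spring is at rest at its anchor
  force <- if (spec$engaged && !newly)
    -spec$stiffness * (pos - spec$anchor) - spec$damping * vel
  else c(0, 0)
  list(force = force, spec = spec)
}
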