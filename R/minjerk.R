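#' @title Minimum-jerk desired trajectories
#'
#' @description Point-to-point and via-point minimum-jerk paths. The
#' via-point solution is the exact quintic-spline minimizer of integrated
#' squared jerk subject to rest boundary conditions and exact interpolation
#' of the via-point: two quintic segments joined with continuity through the
#' fourth derivative at the via time.
#' @name minjerk
NULL

# quintic coefficient solve for one axis: segment 1 on [0, tv] with
# rest start at x0, segment 2 on [tv, T] (local time) with rest end at x1,
# via value xv at tv. Returns list(a = coef seg 1, b = coef seg 2), both
# length 6, ascending powers.
minjerk_axis_coefs <- function(x0, xv, x1, tv, T) {
  t2 <- T - tv
  # unknowns: a3, a4, a5, b0..b5  (a0 = x0, a1 = a2 = 0)
  pow <- function(t, i) t^i
  A <- matrix(0, 9, 9)
  rhs <- numeric(9)
  # 1: p1(tv) = xv
  A[1, 1:3] <- c(tv^3, tv^4, tv^5); rhs[1] <- xv - x0
  # 2: b0 = xv
  A[2, 4] <- 1; rhs[2] <- xv
  # 3: velocity continuity  p1'(tv) = b1
  A[3, 1:3] <- c(3 * tv^2, 4 * tv^3, 5 * tv^4); A[3, 5] <- -1
  # 4: acceleration continuity  p1''(tv) = 2 b2
  A[4, 1:3] <- c(6 * tv, 12 * tv^2, 20 * tv^3); A[4, 6] <- -2
  # 5: jerk continuity  p1'''(tv) = 6 b3
  A[5, 1:3] <- c(6, 24 * tv, 60 * tv^2); A[5, 7] <- -6
  # 6: snap continuity  p1''''(tv) = 24 b4
  A[6, 2:3] <- c(24, 120 * tv); A[6, 8] <- -24
  # 7-9: rest end: p2(t2) = x1, p2'(t2) = 0, p2''(t2) = 0
  A[7, 4:9] <- c(1, t2, t2^2, t2^3, t2^4, t2^5); rhs[7] <- x1
  A[8, 5:9] <- c(1, 2 * t2, 3 * t2^2, 4 * t2^3, 5 * t2^4)
  A[9, 6:9] <- c(2, 6 * t2, 12 * t2^2, 20 * t2^3)
  sol <- solve(A, rhs)
  list(a = c(x0, 0, 0, sol[1:3]), b = sol[4:9])
}

poly_eval <- function(coef, t, deriv = 0L) {
  p <- length(coef) - 1L
  out <- 0
  for (i in deriv:p) {
    fac <- prod(seq.int(i, by = -1, length.out = deriv)) # i!/(i-d)!
    if (deriv == 0L) fac <- 1
    out <- out + coef[i + 1L] * fac * t^(i - deriv)
  }
  out
}

# integral of squared jerk of a quintic over [0, L]
jerk_sq_integral <- function(coef, L) {
  c3 <- 6 * coef[4]; c4 <- 24 * coef[5]; c5 <- 60 * coef[6]
  # jerk(t) = c3 + c4 t + c5 t^2
  c3^2 * L + c3 * c4 * L^2 + (c4^2 + 2 * c3 * c5) * L^3 / 3 +
    c4 * c5 * L^4 / 2 + c5^2 * L^5 / 5
}

minjerk_viapoint_coefs <- function(start, via, end, T, t_via) {
  list(x = minjerk_axis_coefs(start[1L], via[1L], end[1L], t_via, T),
       y = minjerk_axis_coefs(start[2L], via[2L], end[2L], t_via, T),
       t_via = t_via, T = T)
}

minjerk_viapoint_cost <- function(cf) {
  tv <- cf$t_via; t2 <- cf$T - tv
  jerk_sq_integral(cf$x$a, tv) + jerk_sq_integral(cf$x$b, t2) +
    jerk_sq_integral(cf$y$a, tv) + jerk_sq_integral(cf$y$b, t2)
}

minjerk_viapoint_sample <- function(cf, t, deriv = 0L) {
  vapply(t, function(ti) {
    if (ti <= cf$t_via)
      c(poly_eval(cf$x$a, ti, deriv), poly_eval(cf$y$a, ti, deriv))
    else
      c(poly_eval(cf$x$b, ti - cf$t_via, deriv),
        poly_eval(cf$y$b, ti - cf$t_via, deriv))
  }, numeric(2L))
}

#' Minimum-jerk trajectory through a via-point
#'
#' Desired hand path from `start` to `end` passing exactly through `via`,
#' with zero velocity and acceleration at both ends. When `t_via` is `NULL`
#' the passage time is chosen by minimizing the integrated squared jerk over
#' the passage time (the free-via-time optimum); for a via-point on the
#' straight line this recovers the straight point-to-point minimum-jerk path.
#'
#' @param start,via,end 2-vectors, m.
#' @param T Movement duration, s.
#' @param dt Sample step, s.
#' @param t_via Via passage time, s, or `NULL` for the jerk-optimal time.
#' @return Data frame with columns `t_s`, `x_m`, `y_m`, `vx_ms`, `vy_ms`,
#'   `ax_ms2`, `ay_ms2`, with attributes `t_via` and `coefs`.
#' @export
#' @examples
#' d <- minjerk_viapoint(c(0, 0), c(0.02, 0.12), c(0, 0.15), T = 0.4, dt = 0.01)
#' max(d$x_m)  # deflects toward +x
minjerk_viapoint <- function(start, via, end, T, dt, t_via = NULL) {
  stopifnot(T > 0, dt > 0)
  if (isTRUE(all.equal(start, end)) && isTRUE(all.equal(start, via)))
    stop("degenerate geometry: start, via and end coincide")
  if (is.null(t_via)) {
    opt <- stats::optimize(
      function(tv) minjerk_viapoint_cost(
        minjerk_viapoint_coefs(start, via, end, T, tv)),
      interval = c(0.15 * T, 0.85 * T))
    t_via <- opt$minimum
  }
  stopifnot(t_via > 0, t_via < T)
  cf <- minjerk_viapoint_coefs(start, via, end, T, t_via)
  t <- seq(0, T, by = dt)
  p <- minjerk_viapoint_sample(cf, t, 0L)
  v <- minjerk_viapoint_sample(cf, t, 1L)
  a <- minjerk_viapoint_sample(cf, t, 2L)
  out <- data.frame(t_s = t, x_m = p[1L, ], y_m = p[2L, ],
                    vx_ms = v[1L, ], vy_ms = v[2L, ],
                    ax_ms2 = a[1L, ], ay_ms2 = a[2L, ])
  attr(out, "t_via") <- t_via
  attr(out, "coefs") <- cf
  out
}

#' Straight point-to-point minimum-jerk trajectory
#'
#' @inheritParams minjerk_viapoint
#' @return Same layout as [minjerk_viapoint()].
#' @export
minjerk_straight <- function(start, end, T, dt) {
  t <- seq(0, T, by = dt)
  s <- t / T
  pos <- 10 * s^3 - 15 * s^4 + 6 * s^5
  vel <- (30 * s^2 - 60 * s^3 + 30 * s^4) / T
  acc <- (60 * s - 180 * s^2 + 120 * s^3) / T^2
  d <- end - start
  data.frame(t_s = t,
             x_m = start[1L] + d[1L] * pos, y_m = start[2L] + d[2L] * pos,
             vx_ms = d[1L] * vel, vy_ms = d[2L] * vel,
             ax_ms2 = d[1L] * acc, ay_ms2 = d[2L] * acc)
}
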