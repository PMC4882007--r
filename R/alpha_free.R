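#' Fit a cubic smoothing spline to a body-weight series
#'
#' Natural cubic smoothing spline minimising
#' \deqn{p \sum_i (y_i - f(x_i))^2 + (1 - p) \int f''(t)^2 dt}
#' over natural cubic splines with knots at the observation days, so that
#' `smoothing = 0` returns the least-squares line and `smoothing = 1` the
#' natural interpolating spline. Note this classical convention is not
#' numerically interchangeable with other ecosystems' "smoothing factor"
#' parameters (e.g. `stats::smooth.spline`'s `spar`); to transfer a setting
#' across conventions, match effective degrees of freedom rather than the
#' raw parameter value.
#'
#' The fitted object evaluates both the smoothed body weight and its analytic
#' first derivative (see [predict.bw_spline()]); beyond the knot range it
#' extrapolates linearly, consistent with the natural boundary conditions.
#'
#' @param days Observation days (>= 4 distinct values).
#' @param bw Body weights (g), same length as `days`.
#' @param smoothing Smoothing parameter `p` in \[0, 1\] (default 0.2).
#' @return An object of class `bw_spline`.
#' @examples
#' d <- -3:22
#' s <- fit_bw_spline(d, 640 - 1.5 * d + rnorm(length(d), 0, 2), smoothing = 0.2)
#' predict(s, 10)            # smoothed BW at day 10
#' predict(s, 10, deriv = 1) # dBW/dt at day 10
#' @export
fit_bw_spline <- function(days, bw, smoothing = 0.2) {
  x <- as.numeric(days); y <- as.numeric(bw)
  if (length(x) != length(y)) stop("days and bw differ in length")
  if (anyNA(x) || anyNA(y)) stop("days and bw must not contain NA")
  if (anyDuplicated(x)) stop("duplicate days: ", x[duplicated(x)][1])
  if (length(x) < 4L) stop("need at least 4 distinct days")
  if (!is.finite(smoothing) || smoothing < 0 || smoothing > 1)
    stop("smoothing must lie in [0, 1]")
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(x)

  if (smoothing == 0) {
    fit <- stats::lm.fit(cbind(1, x), y)
    b <- fit$coefficients
    yhat <- b[1] + b[2] * x
    coefs <- cbind(yhat[-n], b[2], 0, 0)
  } else {
    h <- diff(x)
    # Green-Silverman band matrices: Q (n x (n-2)), R ((n-2) x (n-2))
    Q <- matrix(0, n, n - 2)
    Rm <- matrix(0, n - 2, n - 2)
    for (j in seq_len(n - 2)) {
      Q[j, j] <- 1 / h[j]
      Q[j + 1, j] <- -1 / h[j] - 1 / h[j + 1]
      Q[j + 2, j] <- 1 / h[j + 1]
      Rm[j, j] <- (h[j] + h[j + 1]) / 3
      if (j < n - 2) Rm[j, j + 1] <- Rm[j + 1, j] <- h[j + 1] / 6
    }
    if (smoothing == 1) {
      yhat <- y
    } else {
      mu <- (1 - smoothing) / smoothing
      K <- Q %*% solve(Rm, t(Q))
      yhat <- solve(diag(n) + mu * K, y)
    }
    gam <- c(0, solve(Rm, crossprod(Q, yhat)), 0) # f'' at knots, natural BC
    i <- seq_len(n - 1)
    bcoef <- (yhat[i + 1] - yhat[i]) / h - h * (2 * gam[i] + gam[i + 1]) / 6
    coefs <- cbind(yhat[i], bcoef, gam[i] / 2, (gam[i + 1] - gam[i]) / (6 * h))
  }
  structure(list(knots = x, coefs = coefs, yhat = as.numeric(coefs[, 1]),
                 smoothing = smoothing),
            class = "bw_spline")
}

#' Evaluate a smoothed body-weight input
#'
#' @param object A `bw_spline` from [fit_bw_spline()] or
#'   [bw_from_trajectory()].
#' @param t Times (days) at which to evaluate.
#' @param deriv 0 for body weight (g), 1 for its time derivative (g/day).
#' @param ... Unused.
#' @return Numeric vector of values.
#' @export
predict.bw_spline <- function(object, t, deriv = 0, ...) {
  stopifnot(deriv %in% c(0, 1))
  res <- pp_eval_cpp(as.numeric(t), object$knots, object$coefs)
  res[, deriv + 1]
}

#' @export
print.bw_spline <- function(x, ...) {
  cat(sprintf("<body-weight spline: %d knots on [%g, %g], smoothing p = %s>\n",
              length(x$knots), min(x$knots), max(x$knots),
              format(x$smoothing)))
  invisible(x)
}

#' Exact body-weight input from a simulated trajectory
#'
#' Builds a piecewise-cubic Hermite representation of a two-compartment model
#' trajectory's body weight, using the model's own right-hand side for the
#' nodal derivatives (per-interval, so intake discontinuities at day
#' boundaries are respected). This is the noise-free "interpolated exactly"
#' body-weight input used when checking that the alpha-free model reproduces
#' the partition model it was derived from.
#'
#' @param traj An `ebm_traj` from [simulate_ebm()].
#' @param p The [ebm_params()] used to produce `traj`.
#' @param dp,dose Drug parameters and dose used to produce `traj` (or `NULL`).
#' @return A `bw_spline` object.
#' @export
bw_from_trajectory <- function(traj, p, dp = NULL, dose = 0) {
  stopifnot(inherits(traj, "ebm_traj"), inherits(p, "ebm_params"))
  tt <- traj$t
  n <- length(tt)
  day <- floor(tt[-n] + 1e-9)
  I <- traj$intake[-n]
  d <- if (is.null(dp)) rep(0, n - 1) else drug_effect(dose, day, dp)
  denom <- p$rho_fm + p$alpha * p$rho_ffm
  bwp <- function(fm, ffm, I, d)
    (1 + p$alpha) * (I - energy_expenditure(fm, ffm, I, p, d)) / denom
  dl <- bwp(traj$fm[-n], traj$ffm[-n], I, d)            # left node, same day
  dr <- bwp(traj$fm[-1], traj$ffm[-1], I, d)            # right node, left limit
  h <- diff(tt)
  delta <- diff(traj$bw) / h
  coefs <- cbind(traj$bw[-n], dl,
                 (3 * delta - 2 * dl - dr) / h,
                 (dl + dr - 2 * delta) / h^2)
  structure(list(knots = tt, coefs = coefs, yhat = traj$bw[-n],
                 smoothing = NA_real_),
            class = "bw_spline")
}

af_check <- function(p) {
  if (p$rho_fm == p$rho_ffm)
    stop("alpha-free model is degenerate when rho_fm == rho_ffm")
}

sched_intake_at <- function(sched, t) {
  day <- floor(t + 1e-9)
  idx <- match(day, sched$days)
  if (anyNA(idx)) stop("intake schedule gap: missing day ", day[is.na(idx)][1])
  sched$intake[idx]
}

#' Right-hand side of the alpha-free fat-mass ODE
#'
#' The alpha-free model removes the constant-partition constraint by taking
#' body weight as a measured input: differentiating the mass balance
#' `BW = FM + FFM` and substituting into the energy balance gives
#' \deqn{(\rho_{FM} - \rho_{FFM}) \, dFM/dt = I - E - \rho_{FFM} \, dBW/dt.}
#' The implicit expenditure equation (deposition costs contain the
#' derivatives) is again linear in `E` and solved in closed form: with
#' `c' = (eta_fm - eta_ffm)/(rho_fm - rho_ffm)` and `B' = dBW/dt`,
#' `E = (E0 + eta_ffm B' + c' (I - rho_ffm B')) / (1 + c')`.
#'
#' @param fm Fat mass (g).
#' @param t Time (days).
#' @param sbw A `bw_spline` body-weight input.
#' @param sched An [intake_schedule()].
#' @param p An [ebm_params()] object (`alpha` is unused here).
#' @param d Drug effect (kcal/day), default 0.
#' @return `dFM/dt` in g/day.
#' @export
alpha_free_rhs <- function(fm, t, sbw, sched, p, d = 0) {
  af_check(p)
  I <- sched_intake_at(sched, t)
  S <- predict(sbw, t)
  Sp <- predict(sbw, t, deriv = 1)
  E <- af_ee(fm, I, S, Sp, p, d)
  (I - E - p$rho_ffm * Sp) / (p$rho_fm - p$rho_ffm)
}

af_ee <- function(fm, I, S, Sp, p, d) {
  ffm <- S - fm
  e0 <- p$K + p$beta * (I - p$I0) + p$lam * S + p$gamma_fm * fm +
    p$gamma_ffm * ffm + d
  cp <- (p$eta_fm - p$eta_ffm) / (p$rho_fm - p$rho_ffm)
  (e0 + p$eta_ffm * Sp + cp * (I - p$rho_ffm * Sp)) / (1 + cp)
}

#' Instantaneous body-composition partition ratio of the alpha-free model
#'
#' The alpha-free analogue of the constant partition slope:
#' \deqn{dFFM/dFM = -\frac{I - E - \rho_{FM} \, dBW/dt}
#'                        {I - E - \rho_{FFM} \, dBW/dt},}
#' a time-varying diagnostic. Near-stationary fat mass (denominator close to
#' zero) is reported as `NA` rather than an infinity.
#'
#' @inheritParams alpha_free_rhs
#' @return The dimensionless ratio, or `NA` where fat mass is stationary.
#' @export
dffm_dfm <- function(fm, t, sbw, sched, p, d = 0) {
  af_check(p)
  I <- sched_intake_at(sched, t)
  S <- predict(sbw, t)
  Sp <- predict(sbw, t, deriv = 1)
  E <- af_ee(fm, I, S, Sp, p, d)
  den <- I - E - p$rho_ffm * Sp
  num <- I - E - p$rho_fm * Sp
  ifelse(abs(den) < 1e-8, NA_real_, -num / den)
}

#' Simulate the alpha-free model
#'
#' Integrates the single fat-mass ODE with the same fixed-step RK4 grid as
#' [simulate_ebm()]; fat-free mass is recovered from the mass balance
#' `FFM(t) = BW(t) - FM(t)` at every output point, and the time-varying
#' [dffm_dfm()] diagnostic is recorded alongside.
#'
#' @param init_fm Initial fat mass (g); must be below the spline body weight
#'   at `t0`.
#' @param sbw A `bw_spline` body-weight input covering the horizon.
#' @param sched An [intake_schedule()] covering `[t0, t_end - 1]`.
#' @param p An [ebm_params()] object.
#' @param dp A [drug_params()] object or `NULL`.
#' @param dose Drug dose (mg/kg).
#' @param t0,t_end Integration horizon (integer days).
#' @param steps_per_day RK4 steps per day (default 10).
#' @return An `ebm_traj` data frame with columns `t`, `fm`, `ffm`, `bw`,
#'   `ee`, `intake`, `cum_imbalance`, `dffm_dfm`.
#' @export
simulate_alpha_free <- function(init_fm, sbw, sched, p, dp = NULL, dose = 0,
                                t0, t_end, steps_per_day = 10) {
  stopifnot(inherits(sbw, "bw_spline"), inherits(sched, "intake_schedule"),
            inherits(p, "ebm_params"))
  af_check(p)
  if (t0 != round(t0) || t_end != round(t_end) || t_end <= t0)
    stop("t0 and t_end must be integers with t_end > t0")
  if (init_fm < 0 || init_fm >= predict(sbw, t0))
    stop("init_fm must lie in [0, BW(t0))")
  sched_check_cover(sched, t0, t_end)
  res <- simaf_cpp(init_fm, t0, t_end, sched$intake, sched$days[1],
                   params_vec(p), drug_vec(dp), dose,
                   as.integer(steps_per_day), sbw$knots, sbw$coefs)
  if (is.finite(res$violation_t))
    stop(sprintf("fat mass left (0, BW) at t = %.2f days", res$violation_t))
  traj <- as.data.frame(res$traj)
  names(traj) <- c("t", "fm", "ffm", "bw", "ee", "intake", "cum_imbalance",
                   "dffm_dfm")
  structure(traj, class = c("ebm_traj", "data.frame"), model = "alpha_free")
}

#' Write a trajectory as tidy CSV
#'
#' @param traj An `ebm_traj` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
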