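#' Piecewise-constant daily food-intake schedule
#'
#' Intake is the model's only exogenous driver: the value for day `d` applies
#' on the interval `[d, d + 1)`. Days must be consecutive integers; a gap is
#' an error naming the missing day (use [impute_intake()] to fill gaps by the
#' study rules first).
#'
#' @param days Integer vector of consecutive study days.
#' @param intake Intake energy per day (kcal/day), same length as `days`.
#' @param I0 Baseline intake (kcal/day) associated with the schedule.
#' @return An object of class `intake_schedule`.
#' @export
intake_schedule <- function(days, intake, I0) {
  days <- as.numeric(days)
  if (length(days) != length(intake)) stop("days and intake differ in length")
  if (length(days) == 0L) stop("empty schedule")
  if (any(days != round(days))) stop("days must be integers")
  o <- order(days)
  days <- days[o]; intake <- as.numeric(intake)[o]
  if (anyDuplicated(days)) stop("duplicated day in schedule")
  gaps <- which(diff(days) != 1)
  if (length(gaps))
    stop("intake schedule gap: missing day ", days[gaps[1]] + 1)
  if (anyNA(intake)) stop("intake schedule gap: missing day ",
                          days[which(is.na(intake))[1]])
  if (any(intake < 0)) stop("intake values must be >= 0")
  if (!is.numeric(I0) || length(I0) != 1L || !is.finite(I0) || I0 < 0)
    stop("I0 must be a single non-negative number")
  structure(list(days = days, intake = intake, I0 = I0),
            class = "intake_schedule")
}

#' @export
print.intake_schedule <- function(x, ...) {
  cat(sprintf("Intake schedule: days %g..%g, mean %.1f kcal/day (I0 = %.1f)\n",
              min(x$days), max(x$days), mean(x$intake), x$I0))
  invisible(x)
}

sched_check_cover <- function(sched, t0, t_end) {
  need <- seq(t0, t_end - 1)
  miss <- setdiff(need, sched$days)
  if (length(miss))
    stop("intake schedule gap: missing day ", miss[1])
}

#' Drug effect on energy expenditure
#'
#' Evaluates the Hill dose-response effect \eqn{d(X) = D_0 + D_{max} X /
#' (ED_{50} + X)} at time `t`: the full value inside the treatment window
#' `[t_start, t_end)`, zero outside. The handling-stress term `d0` applies to
#' every dosed arm including vehicle (dose 0).
#'
#' @param dose Drug dose (mg/kg, >= 0).
#' @param t Time (study days).
#' @param dp A [drug_params()] object.
#' @return Effect on energy expenditure (kcal/day); vectorised over `t`
#'   and `dose`.
#' @export
drug_effect <- function(dose, t, dp) {
  stopifnot(inherits(dp, "drug_params"))
  if (any(dose < 0)) stop("dose must be >= 0")
  n <- max(length(dose), length(t))
  dose <- rep_len(dose, n)
  t <- rep_len(t, n)
  hill <- dp$d0 + dp$dmax * dose / (dp$ed50 + dose)
  hill * (t >= dp$t_start & t < dp$t_end)
}

#' Total energy expenditure, implicit equation resolved in closed form
#'
#' The expenditure equation contains the deposition-cost terms
#' \eqn{\eta_{FM} dFM/dt + \eta_{FFM} dFFM/dt}, whose derivatives themselves
#' contain `E` through the partition equations; the equation is linear in `E`
#' and is solved exactly: with
#' \eqn{E_0 = K + \beta (I - I_0) + \lambda BW + \gamma_{FM} FM +
#' \gamma_{FFM} FFM + d} and
#' \eqn{c = (\eta_{FM} + \alpha \eta_{FFM}) / (\rho_{FM} + \alpha \rho_{FFM})},
#' \deqn{E = (E_0 + c I) / (1 + c).}
#'
#' @param fm,ffm Fat and fat-free mass (g).
#' @param I Food intake (kcal/day).
#' @param p An [ebm_params()] object.
#' @param d Already-evaluated drug effect (kcal/day), default 0.
#' @return Energy expenditure (kcal/day).
#' @export
energy_expenditure <- function(fm, ffm, I, p, d = 0) {
  stopifnot(inherits(p, "ebm_params"))
  e0 <- p$K + p$beta * (I - p$I0) + p$lam * (fm + ffm) +
    p$gamma_fm * fm + p$gamma_ffm * ffm + d
  cc <- (p$eta_fm + p$alpha * p$eta_ffm) / (p$rho_fm + p$alpha * p$rho_ffm)
  if (any(abs(1 + cc) < .Machine$double.eps)) stop("degenerate parameters: 1 + c = 0")
  (e0 + cc * I) / (1 + cc)
}

#' Right-hand side of the partition ODEs
#'
#' \deqn{dFM/dt = (I - E) / (\rho_{FM} + \alpha \rho_{FFM}), \qquad
#'       dFFM/dt = \alpha \, dFM/dt}
#' so that `dFFM/dFM = alpha` whenever intake and expenditure are unbalanced.
#'
#' @inheritParams energy_expenditure
#' @return Named numeric vector `c(dfm, dffm)` in g/day.
#' @export
partition_rhs <- function(fm, ffm, I, p, d = 0) {
  E <- energy_expenditure(fm, ffm, I, p, d)
  dfm <- (I - E) / (p$rho_fm + p$alpha * p$rho_ffm)
  c(dfm = dfm, dffm = p$alpha * dfm)
}

#' Simulate the two-compartment energy-balance model
#'
#' Integrates the partition ODEs with fixed-step fourth-order Runge-Kutta
#' (default 10 steps/day), restarting at each day boundary so the
#' piecewise-constant intake never straddles a step. The drug effect, when
#' supplied, is constant within each dosing day. A matching-quadrature
#' running integral of the energy imbalance `I - E` is recorded so that the
#' energy-conservation identity
#' \eqn{\rho_{FM} \Delta FM + \rho_{FFM} \Delta FFM = \int (I - E) dt}
#' can be checked exactly.
#'
#' @param init Named list or vector with `t`, `fm`, `ffm` — the initial body
#'   state (days, g, g). `fm >= 0`, `ffm > 0`.
#' @param sched An [intake_schedule()] covering `[init$t, t_end - 1]`.
#' @param p An [ebm_params()] object.
#' @param dp A [drug_params()] object or `NULL` for no drug machinery.
#' @param dose Drug dose (mg/kg), ignored when `dp` is `NULL`.
#' @param t_end End of simulation (days, integer > `init$t`).
#' @param steps_per_day RK4 steps per day (default 10).
#' @param alpha_fun Optional function `alpha(t)` replacing the constant
#'   partition slope (used by the partition-violating study generator).
#' @return An `ebm_traj` data frame with columns `t`, `fm`, `ffm`, `bw`,
#'   `ee`, `intake`, `cum_imbalance`; attribute `clipped` is `TRUE` when the
#'   fat-mass floor at 0 g was reached (also signalled as a warning).
#' @examples
#' p <- ebm_params(I0 = 102)
#' sched <- intake_schedule(-3:21, rep(70, 25), I0 = 102)
#' tr <- simulate_ebm(list(t = -3, fm = 192, ffm = 448), sched, p, t_end = 22)
#' head(tr)
#' @export
simulate_ebm <- function(init, sched, p, dp = NULL, dose = 0, t_end,
                         steps_per_day = 10, alpha_fun = NULL) {
  stopifnot(inherits(p, "ebm_params"), inherits(sched, "intake_schedule"))
  init <- as.list(init)
  if (!all(c("t", "fm", "ffm") %in% names(init)))
    stop("init must provide t, fm, ffm")
  if (init$fm < 0 || init$ffm <= 0) stop("init requires fm >= 0 and ffm > 0")
  if (t_end != round(t_end) || init$t != round(init$t) || t_end <= init$t)
    stop("init$t and t_end must be integers with t_end > init$t")
  if (!is.null(dp) && dose < 0) stop("dose must be >= 0")
  sched_check_cover(sched, init$t, t_end)
  alpha_half <- numeric(0)
  if (!is.null(alpha_fun)) {
    tt <- seq(init$t, t_end, by = 1 / (2 * steps_per_day))
    alpha_half <- vapply(tt, alpha_fun, numeric(1))
    if (any(!is.finite(alpha_half))) stop("alpha_fun returned non-finite values")
  }
  res <- sim2d_cpp(init$fm, init$ffm, init$t, t_end,
                   sched$intake, sched$days[1], params_vec(p),
                   drug_vec(dp), dose, as.integer(steps_per_day), alpha_half)
  if (isTRUE(res$clipped))
    warning("fat mass reached the 0 g floor and was clipped")
  traj <- as.data.frame(res$traj)
  names(traj) <- c("t", "fm", "ffm", "bw", "ee", "intake", "cum_imbalance")
  structure(traj, class = c("ebm_traj", "data.frame"),
            clipped = isTRUE(res$clipped), model = "two_dim")
}

#' @export
print.ebm_traj <- function(x, ...) {
  cat(sprintf("<%s trajectory: %d points, t in [%g, %g]>\n",
              attr(x, "model") %||% "model", nrow(x), min(x$t), max(x$t)))
  cat(sprintf("  BW %.1f -> %.1f g, FM %.1f -> %.1f g\n",
              x$bw[1], x$bw[nrow(x)], x$fm[1], x$fm[nrow(x)]))
  invisible(x)
}

#' Extract trajectory values at specific days
#'
#' @param traj An `ebm_traj` data frame.
#' @param days Days to extract (must lie on the output grid).
#' @return The trajectory rows at `days`.
#' @export
traj_at <- function(traj, days) {
  idx <- match(days, traj$t)
  if (anyNA(idx)) stop("day(s) not on trajectory grid: ",
                       paste(days[is.na(idx)], collapse = ", "))
  traj[idx, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.ebm_traj <- function(x, which = c("bw", "fm", "ffm", "ee"), ...) {
  which <- match.arg(which)
  lab <- c(bw = "Body weight (g)", fm = "Fat mass (g)",
           ffm = "Fat-free mass (g)", ee = "Energy expenditure (kcal/day)")
  graphics::plot(x$t, x[[which]], type = "l", xlab = "Day", ylab = lab[which], ...)
  invisible(x)
}
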