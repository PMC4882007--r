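#' Translate a mass-specific metabolic rate between species by Kleiber's law
#'
#' Whole-body metabolic rate scales as body mass to the 3/4 power, so
#' per-gram rates scale as mass to the -1/4:
#' `gamma_to = gamma_from * (m_to / m_from)^(-1/4)`. Used to carry
#' mouse-derived mass-specific rates to a lean rat (350 g reference).
#'
#' @param gamma_from Mass-specific rate in the source species (kcal/g/day).
#' @param m_from,m_to Reference body masses (g), > 0.
#' @return Translated rate (kcal/g/day).
#' @examples
#' kleiber_translate(0.02, 25, 350)  # mouse -> rat
#' @export
kleiber_translate <- function(gamma_from, m_from, m_to) {
  if (any(m_from <= 0) || any(m_to <= 0)) stop("masses must be > 0")
  gamma_from * (m_to / m_from)^(-0.25)
}

#' Total-least-squares line fit of the body-composition relation
#'
#' Fits `FFM = slope * FM + intercept` by orthogonal (errors-in-both-
#' variables) regression: the line passes through the centroid along the
#' principal eigenvector of the centred second-moment matrix, minimising the
#' summed squared perpendicular distances. The slope estimates the constant
#' energy-partition coefficient.
#'
#' @param fm Fat masses (g), >= 3 points.
#' @param ffm Fat-free masses (g), same length.
#' @return A `tls_line` object with fields `slope`, `intercept`,
#'   `residual_ss` (summed squared orthogonal distance, g^2) and `n`.
#' @examples
#' fm <- c(150, 200, 250)
#' fit_alpha_tls(fm, 0.92 * fm + 357)
#' @export
fit_alpha_tls <- function(fm, ffm) {
  fm <- as.numeric(fm); ffm <- as.numeric(ffm)
  if (length(fm) != length(ffm)) stop("fm and ffm differ in length")
  if (length(fm) < 3L) stop("need at least 3 points")
  X <- cbind(fm - mean(fm), ffm - mean(ffm))
  if (all(abs(X) < .Machine$double.eps)) stop("degenerate input: all points identical")
  M <- crossprod(X)
  e <- eigen(M, symmetric = TRUE)
  scale2 <- sum(diag(M))
  if ((e$values[1] - e$values[2]) < 1e-10 * scale2)
    stop("degenerate scatter: principal direction is not unique (isotropic)")
  v <- e$vectors[, 1]
  if (abs(v[1]) < 1e-10)
    stop("principal direction is vertical: slope dFFM/dFM undefined")
  slope <- v[2] / v[1]
  structure(list(slope = slope,
                 intercept = mean(ffm) - slope * mean(fm),
                 residual_ss = e$values[2], n = length(fm)),
            class = "tls_line")
}

#' @export
print.tls_line <- function(x, ...) {
  cat(sprintf("TLS line: FFM = %.4f * FM + %.2f  (n = %d, orthogonal SS = %.3g g^2)\n",
              x$slope, x$intercept, x$n, x$residual_ss))
  invisible(x)
}

#' Body-weight + fat-mass mean-squared-error objective
#'
#' The calibration error for one comparison:
#' \deqn{\sum (BW - \hat{BW})^2 / N_{BW} + \sum (FM - \hat{FM})^2 / N_{FM}}
#' (units g^2). Body weight is compared on every measurement day, fat mass
#' only on the sparse body-composition days; fat-free mass never enters
#' directly because it is derived as `BW - FM`. Multi-arm studies sum this
#' value over arms with equal weight.
#'
#' @param sim_bw,obs_bw Simulated and observed BW (g) on identical days.
#' @param sim_fm,obs_fm Simulated and observed FM (g) on identical BC days.
#' @return The objective value (g^2).
#' @export
ebm_objective <- function(sim_bw, sim_fm, obs_bw, obs_fm) {
  if (length(sim_bw) != length(obs_bw) || length(sim_fm) != length(obs_fm))
    stop("simulated and observed series differ in length")
  mean((sim_bw - obs_bw)^2) + mean((sim_fm - obs_fm)^2)
}

# --- internal: per-arm fitting context -------------------------------------

# Precomputes everything that does not depend on the parameters being
# estimated: horizon, imputed schedule, initial state, observation indices on
# the RK4 output grid, and (alpha-free) the smoothed BW input.
arm_context <- function(arm, baseline_method, model, smoothing, steps_per_day) {
  if (is.null(arm$bc_days) || length(arm$bc_days) < 2L)
    stop("arm '", arm$arm, "' needs at least 2 body-composition days")
  t0 <- min(arm$bc_days)
  t_end <- max(arm$bc_days)
  I0 <- baseline_intake(arm, baseline_method)
  sched <- impute_intake(arm, c(t0, t_end), I0 = I0)
  i0 <- match(t0, arm$days)
  if (is.na(i0)) stop("arm '", arm$arm, "': no BW measurement on first BC day")
  fm0 <- arm$fm_mean[match(t0, arm$bc_days)]
  bw0 <- arm$bw_mean[i0]
  obs_days <- arm$days[arm$days >= t0 & arm$days <= t_end]
  obs_bw <- arm$bw_mean[match(obs_days, arm$days)]
  grid_t <- seq(t0, t_end, by = 1 / steps_per_day)
  ctx <- list(arm = arm$arm, dose = arm$dose, t0 = t0, t_end = t_end,
              I0 = I0, sched = sched, fm0 = fm0, ffm0 = bw0 - fm0,
              obs_days = obs_days, obs_bw = obs_bw,
              bc_days = arm$bc_days, obs_fm = arm$fm_mean,
              i_bw = round((obs_days - t0) * steps_per_day) + 1L,
              i_fm = round((arm$bc_days - t0) * steps_per_day) + 1L,
              steps_per_day = steps_per_day)
  if (model == "alpha_free") {
    ctx$sbw <- fit_bw_spline(arm$days, arm$bw_mean, smoothing)
    ctx$fm0_af <- fm0
  }
  ctx
}

# Fast objective evaluation straight on the C++ output matrix.
arm_objective <- function(ctx, pvec, dvec, dose, model, sbw = NULL) {
  if (model == "two_dim") {
    res <- sim2d_cpp(ctx$fm0, ctx$ffm0, ctx$t0, ctx$t_end,
                     ctx$sched$intake, ctx$sched$days[1], pvec, dvec, dose,
                     ctx$steps_per_day, numeric(0))
  } else {
    sb <- if (is.null(sbw)) ctx$sbw else sbw
    res <- simaf_cpp(ctx$fm0_af, ctx$t0, ctx$t_end,
                     ctx$sched$intake, ctx$sched$days[1], pvec, dvec, dose,
                     ctx$steps_per_day, sb$knots, sb$coefs)
  }
  m <- res$traj
  bw_mse <- mean((m[ctx$i_bw, 4] - ctx$obs_bw)^2)
  fm_mse <- mean((m[ctx$i_fm, 2] - ctx$obs_fm)^2)
  c(total = bw_mse + fm_mse, bw = bw_mse, fm = fm_mse)
}

# Sum of the per-arm objective over a study; `use_drug` distinguishes the
# CR design (no dosing at all) from the drug design (vehicle arm included).
study_objective <- function(ctxs, p, dp, model) {
  dvec <- drug_vec(dp)
  per_arm <- vapply(ctxs, function(ctx) {
    pv <- params_vec(update_params(p, I0 = ctx$I0))
    arm_objective(ctx, pv, dvec, ctx$dose, model)
  }, numeric(3))
  list(total = sum(per_arm["total", ]), per_arm = per_arm)
}

#' Fit the physical-activity coefficient to a caloric-restriction study
#'
#' The activity coefficient and the basal thermogenesis offset cannot be
#' identified simultaneously from BW/FM data (see [lambda_k_surface()]), so
#' the offset is pinned (to 0 by default, the restriction-study convention)
#' and the activity coefficient is estimated by bounded scalar (Brent)
#' minimisation of the study objective. Each arm is initialised at its first
#' body-composition measurement and simulated to its last; baseline intake
#' uses the pre-study-mean rule.
#'
#' @param arms List of `study_arm` objects (all share one activity
#'   coefficient).
#' @param p An [ebm_params()] object supplying every other parameter; its
#'   `K` field is overridden by `K_fixed` and its `I0` per arm.
#' @param K_fixed Pinned basal-offset value (kcal/day, default 0).
#' @param model `"two_dim"` or `"alpha_free"`.
#' @param interval Search interval for the coefficient (kcal/g/day).
#' @param smoothing Spline smoothing parameter for the alpha-free BW input.
#' @param steps_per_day Integration resolution.
#' @param tol Brent convergence tolerance on the coefficient.
#' @return An `ebm_fit` object.
#' @export
fit_lambda_cr <- function(arms, p, K_fixed = 0, model = c("two_dim", "alpha_free"),
                          interval = c(0, 0.5), smoothing = 0.2,
                          steps_per_day = 10, tol = 1e-8) {
  model <- match.arg(model)
  stopifnot(all(vapply(arms, inherits, TRUE, "study_arm")))
  ctxs <- lapply(arms, arm_context, baseline_method = "pre_study_mean",
                 model = model, smoothing = smoothing,
                 steps_per_day = steps_per_day)
  base <- update_params(p, K = K_fixed)
  f <- function(lam) study_objective(ctxs, update_params(base, lam = lam),
                                     NULL, model)$total
  opt <- stats::optimize(f, interval, tol = tol)
  est <- c(lam = opt$minimum)
  final <- study_objective(ctxs, update_params(base, lam = opt$minimum),
                           NULL, model)
  new_ebm_fit(par = est, fixed = c(K = K_fixed), objective = final$total,
              per_arm = final$per_arm, model = model, ctxs = ctxs,
              params = update_params(base, lam = opt$minimum), drug = NULL,
              optimizer = list(method = "Brent", interval = interval,
                               tol = tol, seed = NA_integer_))
}

#' Default simulated-annealing settings for the drug-parameter fit
#'
#' Geometric cooling (`T_k = cooling^k * T0`), a fixed number of iterations
#' per temperature, Gaussian proposals scaled to a fraction of each
#' parameter's box width, followed by Nelder-Mead polish. Any reasonable
#' annealing schedule reaches the same basin for this smooth 4-parameter
#' objective; the polish step makes the reported optimum schedule-independent.
#'
#' @param n_temps Number of temperature levels.
#' @param iters_per_temp Proposals per temperature.
#' @param cooling Geometric cooling factor.
#' @param prop_frac Proposal standard deviation as a fraction of box width.
#' @param polish_restarts Nelder-Mead polish restarts.
#' @return A list of settings.
#' @export
sa_control <- function(n_temps = 100, iters_per_temp = 200, cooling = 0.95,
                       prop_frac = 0.05, polish_restarts = 2) {
  list(n_temps = n_temps, iters_per_temp = iters_per_temp, cooling = cooling,
       prop_frac = prop_frac, polish_restarts = polish_restarts)
}

#' Fit drug-effect parameters to a dosed study by simulated annealing
#'
#' Estimates the study-specific basal offset and the Hill drug-effect
#' parameters (`K`, `d0`, `dmax`, `ed50`) jointly, with the activity
#' coefficient carried over (fixed) from the caloric-restriction fit.
#' Seeded simulated annealing inside box bounds explores the 4-parameter
#' space, followed by Nelder-Mead polish from the best point; the same seed
#' always reproduces the same fit. Baseline intake uses the day-0 rule.
#'
#' @param arms List of `study_arm` objects (vehicle arm at dose 0 plus dosed
#'   arms).
#' @param p An [ebm_params()] with the activity coefficient (and all
#'   translated constants) fixed.
#' @param seed Integer seed controlling the annealing trajectory.
#' @param bounds Named list of length-2 numeric ranges for `K` (kcal/day),
#'   `d0` (kcal/day), `dmax` (kcal/day), `ed50` (mg/kg).
#' @param window Treatment window `c(t_start, t_end)` in days.
#' @param model `"two_dim"` or `"alpha_free"`.
#' @param control Annealing settings from [sa_control()].
#' @param smoothing,steps_per_day As in [fit_lambda_cr()].
#' @return An `ebm_fit` object; `$trace` records the annealing history.
#' @export
fit_drug_params <- function(arms, p, seed = 1,
                            bounds = list(K = c(-100, 100), d0 = c(0, 100),
                                          dmax = c(0, 200), ed50 = c(0.5, 100)),
                            window = c(0, 23),
                            model = c("two_dim", "alpha_free"),
                            control = sa_control(),
                            smoothing = 0.2, steps_per_day = 10) {
  model <- match.arg(model)
  stopifnot(all(vapply(arms, inherits, TRUE, "study_arm")))
  if (!setequal(names(bounds), c("K", "d0", "dmax", "ed50")))
    stop("bounds must name K, d0, dmax, ed50")
  lo <- vapply(bounds[c("K", "d0", "dmax", "ed50")], `[`, 0, 1L)
  hi <- vapply(bounds[c("K", "d0", "dmax", "ed50")], `[`, 0, 2L)
  if (any(hi <= lo)) stop("bounds violation: each range needs lower < upper")
  if (lo["ed50"] <= 0) stop("bounds violation: ed50 lower bound must be > 0")
  ctxs <- lapply(arms, arm_context, baseline_method = "day0",
                 model = model, smoothing = smoothing,
                 steps_per_day = steps_per_day)
  # hot path: parameter vectors assembled once, only K and the drug vector
  # change between objective evaluations (layout: K is element 9)
  pvs <- lapply(ctxs, function(ctx) params_vec(update_params(p, I0 = ctx$I0)))
  obj4 <- function(th) {
    if (any(th < lo) || any(th > hi)) return(1e10)
    dvec <- c(th[2], th[3], th[4], window[1], window[2])
    tot <- 0
    for (i in seq_along(ctxs)) {
      pv <- pvs[[i]]
      pv[9] <- th[1]
      tot <- tot + arm_objective(ctxs[[i]], pv, dvec, ctxs[[i]]$dose,
                                 model)[[1]]
    }
    tot
  }

  set.seed(seed)
  width <- hi - lo
  cur <- (lo + hi) / 2
  f_cur <- obj4(cur)
  best <- cur; f_best <- f_cur
  temp <- max(f_cur, 1)
  trace <- matrix(NA_real_, control$n_temps, 3,
                  dimnames = list(NULL, c("temperature", "best", "accept_rate")))
  for (k in seq_len(control$n_temps)) {
    acc <- 0L
    for (i in seq_len(control$iters_per_temp)) {
      cand <- cur + stats::rnorm(4, 0, control$prop_frac * width)
      f_cand <- obj4(cand)
      if (f_cand <= f_cur ||
          stats::runif(1) < exp(-(f_cand - f_cur) / temp)) {
        cur <- cand; f_cur <- f_cand; acc <- acc + 1L
        if (f_cur < f_best) { best <- cur; f_best <- f_cur }
      }
    }
    trace[k, ] <- c(temp, f_best, acc / control$iters_per_temp)
    temp <- temp * control$cooling
  }
  for (r in seq_len(control$polish_restarts)) {
    pol <- stats::optim(best, obj4, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
    if (pol$value <= f_best) { best <- pol$par; f_best <- pol$value }
  }
  names(best) <- c("K", "d0", "dmax", "ed50")
  pp <- update_params(p, K = best[["K"]])
  dp <- drug_params(d0 = best[["d0"]], dmax = best[["dmax"]],
                    ed50 = best[["ed50"]], t_start = window[1],
                    t_end = window[2])
  final <- study_objective(ctxs, pp, dp, model)
  new_ebm_fit(par = best, fixed = c(lam = p$lam), objective = final$total,
              per_arm = final$per_arm, model = model, ctxs = ctxs,
              params = pp, drug = dp,
              optimizer = list(method = "simulated annealing + Nelder-Mead",
                               seed = seed, bounds = bounds,
                               control = control, trace = as.data.frame(trace)))
}

#' Error surface over the activity coefficient and basal offset
#'
#' Evaluates the study objective on a grid, exposing the structural
#' non-identifiability of the two energy-expenditure intercept-like
#' parameters: the low-error region forms a diagonal valley (the two
#' estimators are strongly correlated), which motivates pinning the basal
#' offset before fitting the activity coefficient.
#'
#' @param arms List of `study_arm` objects.
#' @param p Base [ebm_params()].
#' @param lam_grid,k_grid Sorted numeric grids (kcal/g/day; kcal/day).
#' @param model `"two_dim"` or `"alpha_free"`.
#' @param smoothing,steps_per_day As in [fit_lambda_cr()].
#' @return An `ebm_surface` object: `objective` matrix
#'   (`length(lam_grid)` x `length(k_grid)`), the grids, and the argmin.
#' @export
lambda_k_surface <- function(arms, p, lam_grid, k_grid,
                             model = c("two_dim", "alpha_free"),
                             smoothing = 0.2, steps_per_day = 10) {
  model <- match.arg(model)
  if (is.unsorted(lam_grid) || is.unsorted(k_grid))
    stop("grids must be sorted increasing")
  ctxs <- lapply(arms, arm_context, baseline_method = "pre_study_mean",
                 model = model, smoothing = smoothing,
                 steps_per_day = steps_per_day)
  obj <- matrix(NA_real_, length(lam_grid), length(k_grid),
                dimnames = list(format(lam_grid), format(k_grid)))
  for (i in seq_along(lam_grid))
    for (j in seq_along(k_grid))
      obj[i, j] <- study_objective(
        ctxs, update_params(p, lam = lam_grid[i], K = k_grid[j]),
        NULL, model)$total
  amin <- which(obj == min(obj), arr.ind = TRUE)[1, ]
  structure(list(lam_grid = lam_grid, k_grid = k_grid, objective = obj,
                 argmin = c(lam = lam_grid[amin[1]], K = k_grid[amin[2]])),
            class = "ebm_surface")
}

#' @export
print.ebm_surface <- function(x, ...) {
  cat(sprintf("<error surface %d x %d; min %.4g g^2 at lam = %g, K = %g>\n",
              length(x$lam_grid), length(x$k_grid), min(x$objective),
              x$argmin["lam"], x$argmin["K"]))
  invisible(x)
}

#' Export an error surface as a CSV matrix with axis headers
#'
#' @param x An `ebm_surface`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(x, path) {
  df <- data.frame(lam = x$lam_grid, x$objective, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
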