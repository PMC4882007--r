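new_ebm_fit <- function(par, fixed, objective, per_arm, model, ctxs, params,
                        drug, optimizer) {
  structure(list(par = par, fixed = fixed, objective = objective,
                 per_arm = per_arm, model = model, ctxs = ctxs,
                 params = params, drug = drug, optimizer = optimizer),
            class = "ebm_fit")
}

#' @export
print.ebm_fit <- function(x, ...) {
  cat(sprintf("Energy-balance model fit (%s model)\n",
              sub("_", "-", x$model)))
  cat("  estimated: ",
      paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "), "\n")
  cat("  fixed:     ",
      paste(sprintf("%s = %.4g", names(x$fixed), x$fixed), collapse = ", "),
      "\n")
  cat(sprintf("  objective:  %.6g g^2 over %d arm(s)\n",
              x$objective, length(x$ctxs)))
  invisible(x)
}

#' @export
coef.ebm_fit <- function(object, ...) object$par

#' @export
summary.ebm_fit <- function(object, ...) {
  pa <- t(object$per_arm)
  rownames(pa) <- vapply(object$ctxs, `[[`, "", "arm")
  structure(list(fit = object, per_arm = pa), class = "summary.ebm_fit")
}

#' @export
print.summary.ebm_fit <- function(x, ...) {
  print(x$fit)
  cat("  per-arm objective breakdown (g^2):\n")
  print(round(x$per_arm, 4))
  if (!is.null(x$fit$optimizer$seed) && !is.na(x$fit$optimizer$seed))
    cat(sprintf("  optimizer: %s (seed %d)\n", x$fit$optimizer$method,
                x$fit$optimizer$seed))
  invisible(x)
}

# Re-simulate one fitted arm at the fit's parameter estimates.
sim_fit_arm <- function(object, ctx) {
  p <- update_params(object$params, I0 = ctx$I0)
  if (object$model == "two_dim") {
    simulate_ebm(list(t = ctx$t0, fm = ctx$fm0, ffm = ctx$ffm0),
                 ctx$sched, p, dp = object$drug, dose = ctx$dose,
                 t_end = ctx$t_end, steps_per_day = ctx$steps_per_day)
  } else {
    simulate_alpha_free(ctx$fm0_af, ctx$sbw, ctx$sched, p,
                        dp = object$drug, dose = ctx$dose,
                        t0 = ctx$t0, t_end = ctx$t_end,
                        steps_per_day = ctx$steps_per_day)
  }
}

#' Re-simulate the fitted model over every study arm
#'
#' @param object An `ebm_fit`.
#' @param nsim,seed Unused (the fitted model is deterministic); present for
#'   the generic's signature.
#' @param ... Unused.
#' @return A named list of `ebm_traj` trajectories, one per arm.
#' @export
simulate.ebm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  out <- lapply(object$ctxs, function(ctx) sim_fit_arm(object, ctx))
  names(out) <- vapply(object$ctxs, `[[`, "", "arm")
  out
}

#' Fitted values at the observation days
#'
#' @param object An `ebm_fit`.
#' @param ... Unused.
#' @return A data frame with columns `arm`, `variable` (`bw` or `fm`),
#'   `day`, `observed`, `fitted`.
#' @export
predict.ebm_fit <- function(object, ...) {
  do.call(rbind, lapply(object$ctxs, function(ctx) {
    tr <- sim_fit_arm(object, ctx)
    rbind(
      data.frame(arm = ctx$arm, variable = "bw", day = ctx$obs_days,
                 observed = ctx$obs_bw,
                 fitted = traj_at(tr, ctx$obs_days)$bw),
      data.frame(arm = ctx$arm, variable = "fm", day = ctx$bc_days,
                 observed = ctx$obs_fm,
                 fitted = traj_at(tr, ctx$bc_days)$fm))
  }))
}

#' @export
residuals.ebm_fit <- function(object, ...) {
  pr <- predict(object)
  pr$residual <- pr$observed - pr$fitted
  pr[c("arm", "variable", "day", "residual")]
}

#' Plot observed and fitted trajectories for every arm
#'
#' @param x An `ebm_fit`.
#' @param which `"bw"` or `"fm"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ebm_fit <- function(x, which = c("bw", "fm"), ...) {
  which <- match.arg(which)
  sims <- simulate(x)
  cols <- grDevices::hcl.colors(length(sims), "Dark 2")
  ylab <- if (which == "bw") "Body weight (g)" else "Fat mass (g)"
  rng <- range(unlist(lapply(sims, `[[`, which)))
  graphics::plot(NA, xlim = range(sims[[1]]$t), ylim = rng,
                 xlab = "Day", ylab = ylab, ...)
  for (i in seq_along(sims)) {
    graphics::lines(sims[[i]]$t, sims[[i]][[which]], col = cols[i])
    ctx <- x$ctxs[[i]]
    if (which == "bw")
      graphics::points(ctx$obs_days, ctx$obs_bw, col = cols[i], pch = 1)
    else
      graphics::points(ctx$bc_days, ctx$obs_fm, col = cols[i], pch = 16)
  }
  graphics::legend("topright", legend = names(sims), col = cols, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
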