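# Independent oracles and shared fixtures for the test suite.

# Damped fixed-point iteration for the implicit energy-expenditure equation;
# deliberately avoids the closed-form solution used by the package.
ee_fixed_point <- function(fm, ffm, I, p, d = 0, tol = 1e-12) {
  e0 <- p$K + p$beta * (I - p$I0) + p$lam * (fm + ffm) +
    p$gamma_fm * fm + p$gamma_ffm * ffm + d
  cc <- (p$eta_fm + p$alpha * p$eta_ffm) / (p$rho_fm + p$alpha * p$rho_ffm)
  E <- e0
  for (i in 1:10000) {
    E_new <- e0 + cc * (I - E)
    if (abs(E_new - E) < tol) return(E_new)
    E <- 0.5 * E + 0.5 * E_new
  }
  stop("fixed point did not converge")
}

# Brute-force orthogonal-distance line fit: scan the line angle, with the
# offset solved at each angle by centroid projection, then refine.
tls_brute_force <- function(x, y) {
  dist2 <- function(theta) {
    # line: sin(t) x - cos(t) y + c = 0; optimal c from the centroid
    c0 <- mean(cos(theta) * y - sin(theta) * x)
    sum((sin(theta) * x - cos(theta) * y + c0)^2)
  }
  grid <- seq(-pi / 2 + 1e-6, pi / 2 - 1e-6, length.out = 2001)
  vals <- vapply(grid, dist2, 0)
  i <- which.min(vals)
  opt <- stats::optimize(dist2, grid[c(max(1, i - 1), min(length(grid), i + 1))],
                         tol = 1e-12)
  theta <- opt$minimum
  c0 <- mean(cos(theta) * y - sin(theta) * x)
  list(slope = tan(theta), intercept = c0 / cos(theta), ss = opt$objective)
}

# Default parameter set used across tests (rat-scale values).
test_params <- function(...) {
  update_params(ebm_params(lam = 0.087, K = 0, alpha = 0.92, I0 = 102), ...)
}

# A generic restriction-like intake schedule over [t0, t_end).
test_sched <- function(t0 = -3, t_end = 22, I0 = 102, frac = 0.7) {
  days <- seq(t0, t_end - 1)
  intake_schedule(days, ifelse(days < 0, I0, frac * I0), I0)
}

# Random plausible model parameters (caller controls the RNG state).
random_params <- function() {
  rho_ffm <- runif(1, 1.2, 2.5)
  ebm_params(rho_fm = runif(1, 8, 10.5), rho_ffm = rho_ffm,
             eta_fm = runif(1, 0, 0.3), eta_ffm = runif(1, 0, 0.3),
             beta = runif(1, 0, 0.4),
             gamma_fm = runif(1, 0, 0.05), gamma_ffm = runif(1, 0.05, 0.15),
             lam = runif(1, 0.05, 0.12), K = runif(1, -20, 20),
             alpha = runif(1, 0.3, 1.5), I0 = runif(1, 80, 120))
}

# Noiseless generator configurations (the deterministic study designs);
# dots override, so e.g. observation noise alone can be switched back on.
noiseless_cfg <- function(study, ...) {
  args <- list(study = study, noise_bw = 0, noise_fm = 0, k_sd = 0,
               intake_frac_sd = 0, intake_daily_cv = 0, fm_frac_sd = 0)
  do.call(generator_config, utils::modifyList(args, list(...)))
}

conservation_residual <- function(tr, p) {
  n <- nrow(tr)
  lhs <- p$rho_fm * (tr$fm[n] - tr$fm[1]) + p$rho_ffm * (tr$ffm[n] - tr$ffm[1])
  abs(lhs - tr$cum_imbalance[n]) / max(1, abs(tr$cum_imbalance[n]))
}
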