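test_that("smoothing spline reproduces a straight line at any smoothing", {
  d <- 0:20
  bw <- 600 - 1.8 * d
  for (sm in c(0, 0.2, 0.7, 1)) {
    s <- fit_bw_spline(d, bw, smoothing = sm)
    tt <- seq(0, 20, by = 0.25)
    expect_lt(max(abs(predict(s, tt) - (600 - 1.8 * tt))), 1e-7)
    expect_lt(max(abs(predict(s, tt, deriv = 1) + 1.8)), 1e-7)
  }
})

test_that("smoothing = 1 interpolates and smoothing = 0 is the LS line", {
  set.seed(411)
  d <- 0:15
  bw <- 620 - 2 * d + rnorm(16, 0, 4)
  s1 <- fit_bw_spline(d, bw, smoothing = 1)
  expect_equal(predict(s1, d), bw, tolerance = 1e-9)
  s0 <- fit_bw_spline(d, bw, smoothing = 0)
  ls <- lm(bw ~ d)
  expect_equal(predict(s0, d), unname(fitted(ls)), tolerance = 1e-9)
  expect_error(fit_bw_spline(c(0, 1, 1, 2), c(1, 2, 3, 4)), "duplicate")
  expect_error(fit_bw_spline(0:2, 1:3), "at least 4")
  expect_error(fit_bw_spline(0:4, 1:5, smoothing = 2), "smoothing")
})

test_that("spline at the study smoothing recovers a noisy simulated BW curve", {
  p <- test_params()
  sched <- intake_schedule(0:44, rep(0.7 * 102, 45), I0 = 102)
  tr <- simulate_ebm(list(t = 0, fm = 192, ffm = 448), sched, p, t_end = 45)
  days <- 0:44
  truth <- traj_at(tr, days)$bw
  set.seed(412)
  s <- fit_bw_spline(days, truth + rnorm(45, 0, 2), smoothing = 0.2)
  interior <- 5:40
  expect_lt(max(abs(predict(s, interior) - traj_at(tr, interior)$bw)), 5)
})

test_that("alpha-free RHS agrees with the 2D model along its own trajectory", {
  set.seed(413)
  for (i in 1:5) {
    p <- random_params()
    fm0 <- runif(1, 120, 240); ffm0 <- runif(1, 380, 520)
    I_eq <- energy_expenditure(fm0, ffm0, p$I0, p)
    days <- 0:44
    sched <- intake_schedule(days, I_eq * ifelse(days < 10, 1, 0.75), p$I0)
    tr <- simulate_ebm(list(t = 0, fm = fm0, ffm = ffm0), sched, p, t_end = 45)
    sbw <- bw_from_trajectory(tr, p)
    idx <- seq(1, nrow(tr) - 1, by = 13)
    rhs_af <- vapply(idx, function(j)
      alpha_free_rhs(tr$fm[j], tr$t[j], sbw, sched, p), 0)
    rhs_2d <- (tr$intake[idx] - tr$ee[idx]) / (p$rho_fm + p$alpha * p$rho_ffm)
    expect_lt(max(abs(rhs_af - rhs_2d)), 1e-4)
  }
})

test_that("explicit limit: equal deposition costs give the direct formula", {
  p <- test_params(eta_fm = 0.2, eta_ffm = 0.2)
  sched <- intake_schedule(0:9, rep(80, 10), I0 = 102)
  sbw <- fit_bw_spline(0:9, 640 - 2 * (0:9), smoothing = 1)
  t <- 4.5
  I <- 80
  S <- predict(sbw, t); Sp <- predict(sbw, t, deriv = 1)
  fm <- 190
  # c' = 0: E explicit
  E <- p$K + p$beta * (I - p$I0) + p$lam * S + p$gamma_fm * fm +
    p$gamma_ffm * (S - fm) + p$eta_ffm * Sp +
    (p$eta_fm - p$eta_ffm) * 0  # c' = 0 so no implicit correction
  expect_equal(alpha_free_rhs(fm, t, sbw, sched, p),
               (I - E - p$rho_ffm * Sp) / (p$rho_fm - p$rho_ffm),
               tolerance = 1e-12)
})

test_that("alpha-free model driven by a 2D BW input reproduces the 2D fat mass", {
  set.seed(414)
  for (i in 1:5) {
    p <- random_params()
    fm0 <- runif(1, 120, 240); ffm0 <- runif(1, 380, 520)
    I_eq <- energy_expenditure(fm0, ffm0, p$I0, p)
    days <- 0:44
    sched <- intake_schedule(days, I_eq * runif(45, 0.7, 1.05), p$I0)
    tr <- simulate_ebm(list(t = 0, fm = fm0, ffm = ffm0), sched, p, t_end = 45)
    sbw <- bw_from_trajectory(tr, p)
    af <- simulate_alpha_free(fm0, sbw, sched, p, t0 = 0, t_end = 45)
    expect_lt(max(abs(af$fm - tr$fm)), 0.1)
    # mass balance is exact by construction
    expect_equal(af$fm + af$ffm, af$bw)
    # conservation: the recorded imbalance quadrature matches the state
    # change up to the derivative jumps at daily intake discontinuities
    expect_lt(conservation_residual(af, p), 2e-3)
  }
})

test_that("the partition diagnostic recovers alpha on constant-slope worlds", {
  p <- test_params()
  # constant deficit: the exactness regime, free of intake discontinuities
  sched <- intake_schedule(-3:21, rep(0.75 * 102, 25), I0 = 102)
  tr <- simulate_ebm(list(t = -3, fm = 192, ffm = 448), sched, p, t_end = 22)
  sbw <- bw_from_trajectory(tr, p)
  af <- simulate_alpha_free(192, sbw, sched, p, t0 = -3, t_end = 22)
  moving <- !is.na(af$dffm_dfm)
  expect_true(any(moving))
  expect_lt(max(abs(af$dffm_dfm[moving] - p$alpha)), 1e-6)
})

test_that("partition diagnostic limiting cases", {
  p <- test_params()
  sched <- intake_schedule(0:9, rep(90, 10), I0 = 102)
  sbw_flat <- fit_bw_spline(0:9, rep(620, 10), smoothing = 1)
  # stationary BW with an energy imbalance: pure recomposition, ratio -1
  v <- dffm_dfm(200, 3, sbw_flat, sched, p)
  expect_equal(v, -1, tolerance = 1e-9)
  # I - E = rho_fm * dBW/dt: all change is fat, ratio 0
  slope <- -1.3
  sbw_dec <- fit_bw_spline(0:9, 620 + slope * (0:9), smoothing = 1)
  f <- function(I) {
    S <- predict(sbw_dec, 3); Sp <- predict(sbw_dec, 3, deriv = 1)
    E <- ratabolic:::af_ee(200, I, S, Sp, p, 0)
    I - E - p$rho_fm * Sp
  }
  I_star <- uniroot(f, c(0, 400))$root
  sched_star <- intake_schedule(0:9, rep(I_star, 10), I0 = 102)
  expect_equal(dffm_dfm(200, 3, sbw_dec, sched_star, p), 0, tolerance = 1e-7)
})

test_that("diagnostic matches finite differences of the integrated series", {
  p <- test_params()
  days <- 0:44
  sched <- intake_schedule(days, rep(0.75 * 102, 45), I0 = 102)
  tr <- simulate_ebm(list(t = 0, fm = 192, ffm = 448), sched, p, t_end = 45)
  sbw <- bw_from_trajectory(tr, p)
  af <- simulate_alpha_free(192, sbw, sched, p, t0 = 0, t_end = 45)
  i <- seq(20, nrow(af) - 20, by = 10)
  fd <- (af$ffm[i + 1] - af$ffm[i - 1]) / (af$fm[i + 1] - af$fm[i - 1])
  expect_lt(max(abs(af$dffm_dfm[i] - fd)), 1e-3)
})

test_that("alpha-free simulation rejects fat mass escaping (0, BW)", {
  p <- test_params()
  sched <- intake_schedule(0:44, rep(320, 45), I0 = 102)
  sbw <- fit_bw_spline(c(0, 15, 30, 44), rep(600, 4), smoothing = 1)
  expect_error(simulate_alpha_free(180, sbw, sched, p, t0 = 0, t_end = 45),
               "left \\(0, BW\\) at t")
  expect_error(simulate_alpha_free(700, sbw, sched, p, t0 = 0, t_end = 45),
               "init_fm")
  expect_error(
    simulate_alpha_free(180, sbw, sched, update_params(p, rho_ffm = 9.4),
                        t0 = 0, t_end = 45),
    "rho_fm > rho_ffm")
})

test_that("trajectories export as tidy CSV", {
  p <- test_params()
  sched <- test_sched()
  tr <- simulate_ebm(list(t = -3, fm = 192, ffm = 448), sched, p, t_end = 22)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read.csv(f)
  expect_equal(back$fm, tr$fm)
  expect_named(back, c("t", "fm", "ffm", "bw", "ee", "intake",
                       "cum_imbalance"))
})
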