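test_that("Kleiber translation scales per-gram rates as mass^(-1/4)", {
  expect_equal(kleiber_translate(0.05, 300, 300), 0.05)
  expect_equal(kleiber_translate(0.05, 25, 16 * 25), 0.025)
  expect_equal(kleiber_translate(1, 25, 350), (350 / 25)^(-0.25))
  expect_equal(kleiber_translate(1, 25, 350), 0.516973, tolerance = 1e-6)
  # log-log slope is -1/4
  sl <- (log(kleiber_translate(1, 25, 50)) - log(kleiber_translate(1, 25, 25))) /
    (log(50) - log(25))
  expect_equal(sl, -0.25)
  expect_error(kleiber_translate(1, 0, 10), "masses")
})

test_that("TLS recovers an exact line to machine precision", {
  fm <- c(120, 150, 180, 210, 260, 300)
  tl <- fit_alpha_tls(fm, 0.92 * fm + 357)
  expect_equal(tl$slope, 0.92, tolerance = 1e-12)
  expect_equal(tl$intercept, 357, tolerance = 1e-9)
  expect_lt(tl$residual_ss, 1e-18 * sum(fm^2))
})

test_that("TLS matches a brute-force orthogonal-distance search on noisy data", {
  set.seed(421)
  for (i in 1:4) {
    fm <- runif(20, 100, 300)
    ffm <- 0.92 * fm + 357 + rnorm(20, 0, 12)
    fm_n <- fm + rnorm(20, 0, 8)
    tl <- fit_alpha_tls(fm_n, ffm)
    bf <- tls_brute_force(fm_n, ffm)
    expect_equal(tl$slope, bf$slope, tolerance = 1e-3)
    expect_equal(tl$intercept, bf$intercept, tolerance = 1e-2)
    expect_equal(tl$residual_ss, bf$ss, tolerance = 1e-6)
  }
})

test_that("TLS is symmetric under exchanging the two masses, unlike OLS", {
  set.seed(422)
  x <- runif(30, 100, 300)
  y <- 0.8 * x + 100 + rnorm(30, 0, 15)
  a <- fit_alpha_tls(x, y)
  b <- fit_alpha_tls(y, x)
  expect_equal(a$slope, 1 / b$slope, tolerance = 1e-10)
  ols_a <- coef(lm(y ~ x))[[2]]
  ols_b <- coef(lm(x ~ y))[[2]]
  expect_gt(abs(ols_a - 1 / ols_b), 0.01)
  # symmetry around y = x forces slope 1
  sym <- fit_alpha_tls(c(x, y), c(y, x))
  expect_equal(sym$slope, 1, tolerance = 1e-10)
})

test_that("TLS rejects degenerate scatter", {
  expect_error(fit_alpha_tls(c(1, 1, 1), c(2, 2, 2)), "identical")
  expect_error(fit_alpha_tls(c(5, 5, 5), c(1, 2, 3)), "vertical")
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  expect_error(fit_alpha_tls(cos(th), sin(th)), "isotropic")
  expect_error(fit_alpha_tls(1:2, 1:2), "3 points")
})

test_that("the error objective behaves as a per-comparison MSE sum", {
  expect_equal(ebm_objective(1:5, 1:3, 1:5, 1:3), 0)
  # constant residuals: +1 g on 26 BW days, +2 g on 3 BC days -> 1 + 4
  expect_equal(ebm_objective(rep(1, 26), rep(2, 3), rep(0, 26), rep(0, 3)), 5)
  set.seed(423)
  sb <- rnorm(26, 600, 10); ob <- rnorm(26, 600, 10)
  sf <- rnorm(3, 200, 5); of <- rnorm(3, 200, 5)
  # independent two-term recomputation
  expect_equal(ebm_objective(sb, sf, ob, of),
               sum((sb - ob)^2) / 26 + sum((sf - of)^2) / 3)
  expect_error(ebm_objective(1:3, 1, 1:2, 1), "length")
})

test_that("activity coefficient is recovered exactly from a noiseless study", {
  std <- generate_study(noiseless_cfg("CR", n_per_arm = 3, seed = 31))
  arms <- aggregate_arms(std$records)
  fit <- fit_lambda_cr(arms, ebm_params(lam = 0.05, K = 0, alpha = 0.92))
  expect_lt(abs(coef(fit)[["lam"]] - 0.087), 1e-4)
  expect_lt(fit$objective, 1e-6)
  # local-minimum certificate: +/- 50 % perturbations are strictly worse
  ctxs <- fit$ctxs
  obj_at <- function(lam) ratabolic:::study_objective(
    ctxs, update_params(fit$params, lam = lam), NULL, "two_dim")$total
  expect_gt(obj_at(0.087 * 1.5), fit$objective)
  expect_gt(obj_at(0.087 * 0.5), fit$objective)
})

test_that("objective sums over arms and is invariant to arm order", {
  std <- generate_study(noiseless_cfg("CR", n_per_arm = 3, seed = 32))
  arms <- aggregate_arms(std$records)
  p <- ebm_params(lam = 0.08, K = 0, alpha = 0.92)
  mk <- function(a) lapply(a, ratabolic:::arm_context,
                           baseline_method = "pre_study_mean",
                           model = "two_dim", smoothing = 0.2,
                           steps_per_day = 10)
  o1 <- ratabolic:::study_objective(mk(arms), p, NULL, "two_dim")
  o2 <- ratabolic:::study_objective(mk(rev(arms)), p, NULL, "two_dim")
  expect_equal(o1$total, o2$total)
  expect_equal(o1$total, sum(o1$per_arm["total", ]))
})

test_that("drug quartet is recovered from a noiseless dosed study", {
  std <- generate_study(noiseless_cfg("CB1Ra", n_per_arm = 3, seed = 33))
  arms <- aggregate_arms(std$records)
  fit <- fit_drug_params(arms, ebm_params(lam = 0.087, K = 0, alpha = 0.92),
                         seed = 133)
  est <- coef(fit)
  expect_lt(abs(est[["K"]] - (-16.6)) / 16.6, 0.01)
  expect_lt(abs(est[["d0"]] - 13) / 13, 0.01)
  expect_lt(abs(est[["dmax"]] - 37) / 37, 0.01)
  expect_lt(abs(est[["ed50"]] - 10) / 10, 0.05)
  # round-trip: reported objective equals re-evaluation at the estimates
  ctxs <- fit$ctxs
  re <- ratabolic:::study_objective(ctxs, fit$params, fit$drug, "two_dim")
  expect_equal(re$total, fit$objective)
})

test_that("the annealing fit is bitwise reproducible under a fixed seed", {
  std <- generate_study(generator_config("CB1Ra", n_per_arm = 3, seed = 34))
  arms <- aggregate_arms(std$records)
  p <- ebm_params(lam = 0.087, K = 0, alpha = 0.92)
  ctrl <- sa_control(n_temps = 12, iters_per_temp = 40)
  f1 <- fit_drug_params(arms, p, seed = 77, control = ctrl)
  f2 <- fit_drug_params(arms, p, seed = 77, control = ctrl)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$optimizer$trace, f2$optimizer$trace)
  expect_error(fit_drug_params(arms, p, bounds = list(K = c(1, -1),
                                                      d0 = c(0, 1),
                                                      dmax = c(0, 1),
                                                      ed50 = c(0.5, 1))),
               "bounds violation")
})

test_that("the activity/basal-offset error surface is a correlated valley", {
  std <- generate_study(generator_config("CR", seed = 35))
  arms <- aggregate_arms(std$records)
  p <- ebm_params(lam = 0.087, K = 0, alpha = 0.92)
  lam_grid <- seq(0.075, 0.099, length.out = 25)
  k_grid <- seq(-8, 8, length.out = 33)
  surf <- lambda_k_surface(arms, p, lam_grid, k_grid)
  expect_equal(dim(surf$objective), c(25, 33))
  expect_true(all(is.finite(surf$objective)))
  low <- which(surf$objective <= 1.05 * min(surf$objective), arr.ind = TRUE)
  expect_gt(nrow(low), 3)
  r <- cor(lam_grid[low[, 1]], k_grid[low[, 2]])
  expect_gt(abs(r), 0.9)
})

test_that("surface argmin tracks the truth and degenerate grids work", {
  std <- generate_study(noiseless_cfg("CR", n_per_arm = 3, seed = 36))
  arms <- aggregate_arms(std$records)
  p <- ebm_params(lam = 0.05, K = 0, alpha = 0.92)
  surf <- lambda_k_surface(arms, p, seq(0.077, 0.097, by = 0.002),
                           seq(-4, 4, by = 1))
  expect_equal(unname(surf$argmin), c(0.087, 0))
  one <- lambda_k_surface(arms, p, 0.087, 0)
  expect_equal(dim(one$objective), c(1, 1))
  expect_equal(one$objective[1, 1],
               ratabolic:::study_objective(
                 lapply(arms, ratabolic:::arm_context,
                        baseline_method = "pre_study_mean", model = "two_dim",
                        smoothing = 0.2, steps_per_day = 10),
                 update_params(p, lam = 0.087, K = 0), NULL, "two_dim")$total)
})

test_that("pinning the basal offset elsewhere shifts the activity estimate monotonically", {
  std <- generate_study(generator_config("CR", n_per_arm = 4, seed = 37))
  arms <- aggregate_arms(std$records)
  p <- ebm_params(lam = 0.087, K = 0, alpha = 0.92)
  lams <- vapply(c(-10, 0, 10), function(k)
    coef(fit_lambda_cr(arms, p, K_fixed = k))[["lam"]], 0)
  expect_true(all(diff(lams) < 0))  # larger offset -> smaller activity term
})

test_that("fit objects expose the standard modelling methods", {
  std <- generate_study(generator_config("CR", n_per_arm = 3, seed = 38))
  arms <- aggregate_arms(std$records)
  fit <- fit_lambda_cr(arms, ebm_params(lam = 0.05, K = 0, alpha = 0.92))
  expect_s3_class(fit, "ebm_fit")
  expect_named(coef(fit), "lam")
  expect_output(print(fit), "objective")
  expect_output(print(summary(fit)), "per-arm")
  sims <- simulate(fit)
  expect_length(sims, length(arms))
  expect_s3_class(sims[[1]], "ebm_traj")
  pr <- predict(fit)
  expect_true(all(c("arm", "variable", "observed", "fitted") %in% names(pr)))
  res <- residuals(fit)
  expect_equal(nrow(res), nrow(pr))
  expect_equal(res$residual, pr$observed - pr$fitted)
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); plot(fit, which = "fm"); grDevices::dev.off()
  expect_true(file.exists(f))
})
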