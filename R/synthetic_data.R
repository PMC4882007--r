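#' Configuration for the synthetic-study generator
#'
#' Describes one of the two emulated study designs. The caloric-restriction
#' (`"CR"`) design: an ad-libitum control plus arms restricted to fixed
#' fractions of baseline intake for 26 days, body composition by DXA on days
#' -3, 12 and 22, baseline intake established over 4 pre-study days, daily
#' body weight during restriction, baseline body weight about 640 (62) g.
#' The CB1-antagonist (`"CB1Ra"`) design: vehicle plus 3/10/30 mg/kg daily
#' oral doses for 23 days with a 15-day washout, body composition on days
#' -3, 24 and 42, daily body weight and intake through day 37, baseline body
#' weight about 695 (75) g.
#'
#' @param study `"CR"` or `"CB1Ra"`.
#' @param arms Restriction fractions in \[0, 1) for `"CR"` (0 = ad libitum),
#'   or doses in mg/kg for `"CB1Ra"` (0 = vehicle).
#' @param n_per_arm Animals per arm (scalar or one value per arm).
#' @param bw_mean,bw_sd Baseline body-weight distribution (g).
#' @param fm_frac_mean Mean baseline fat-mass fraction of body weight; fixes
#'   the anchor of the population partition line on which baseline
#'   compositions are drawn (heavier animals are fatter along the line with
#'   slope `params$alpha`, matching the structure a constant-partition
#'   analysis of pooled body-composition data assumes).
#' @param fm_frac_sd Between-animal composition scatter about that line at
#'   fixed body weight, as a fraction of body weight (SD of fat mass =
#'   `fm_frac_sd * bw`).
#' @param params True [ebm_params()] (its `I0` is replaced per animal by the
#'   animal's own equilibrium intake).
#' @param drug True [drug_params()] (`"CB1Ra"` only; `NULL` for `"CR"`).
#' @param noise_bw,noise_fm Gaussian measurement noise SD for body weight
#'   and fat mass (g).
#' @param k_sd Between-animal SD of the basal offset (kcal/day).
#' @param intake_frac_sd Between-animal SD of baseline intake as a fraction.
#' @param intake_daily_cv Day-to-day lognormal jitter CV of ad-lib intake.
#' @param suppression List describing the drug-arm intake-suppression
#'   profile: maximal fractional suppression `smax` at a saturating dose
#'   (Hill in dose with the drug's `ed50`), decaying after the first treated
#'   day towards a tolerance plateau `floor_frac` of the peak with time
#'   constant `tau` (days). A synthesis choice: real studies measure intake,
#'   so the shape only needs to be qualitatively drug-like.
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(study = c("CR", "CB1Ra"),
                             arms = NULL, n_per_arm = NULL,
                             bw_mean = NULL, bw_sd = NULL,
                             fm_frac_mean = 0.30, fm_frac_sd = 0.03,
                             params = NULL, drug = NULL,
                             noise_bw = 5, noise_fm = 8,
                             k_sd = 5, intake_frac_sd = 0.03,
                             intake_daily_cv = 0.04,
                             suppression = list(smax = 0.35, tau = 7,
                                                floor_frac = 0.3),
                             seed = 1) {
  study <- match.arg(study)
  if (study == "CR") {
    arms <- arms %||% c(0, 0.10, 0.20, 0.30, 0.40)
    n_per_arm <- n_per_arm %||% 10
    bw_mean <- bw_mean %||% 640; bw_sd <- bw_sd %||% 62
    params <- params %||% ebm_params(lam = 0.087, K = 0)
    if (any(arms < 0 | arms >= 1)) stop("restriction fractions must lie in [0, 1)")
  } else {
    arms <- arms %||% c(0, 3, 10, 30)
    n_per_arm <- n_per_arm %||% c(9, 10, 10, 10)
    bw_mean <- bw_mean %||% 695; bw_sd <- bw_sd %||% 75
    params <- params %||% ebm_params(lam = 0.087, K = -16.6)
    drug <- drug %||% drug_params(d0 = 13, dmax = 37, ed50 = 10)
    if (any(arms < 0)) stop("doses must be >= 0")
  }
  n_per_arm <- rep_len(n_per_arm, length(arms))
  if (any(n_per_arm < 1)) stop("need n >= 1 per arm")
  if (any(c(noise_bw, noise_fm, k_sd, intake_frac_sd, intake_daily_cv) < 0))
    stop("noise and variability SDs must be >= 0")
  structure(list(study = study, arms = arms, n_per_arm = n_per_arm,
                 bw_mean = bw_mean, bw_sd = bw_sd,
                 fm_frac_mean = fm_frac_mean, fm_frac_sd = fm_frac_sd,
                 params = params, drug = drug,
                 noise_bw = noise_bw, noise_fm = noise_fm, k_sd = k_sd,
                 intake_frac_sd = intake_frac_sd,
                 intake_daily_cv = intake_daily_cv,
                 suppression = suppression, seed = seed),
            class = "generator_config")
}

cr_design <- list(bc_days = c(-3, 12, 22), restrict_days = 0:25,
                  baseline_days = -15:-12, bw_days = c(-3, 0:26),
                  sim_end = 26)
cb1_design <- list(bc_days = c(-3, 24, 42), treat_days = 0:22,
                   measured_days = 0:37, bw_days = c(-3, 0:37, 42),
                   sim_end = 42)

# Fractional intake suppression of a dosed arm on study day t (>= 1).
supp_frac <- function(dose, t, drug, sup) {
  if (dose <= 0) return(rep(0, length(t)))
  peak <- sup$smax * dose / (drug$ed50 + dose)
  w <- sup$floor_frac + (1 - sup$floor_frac) * exp(-(t - 1) / sup$tau)
  peak * w
}

arm_label <- function(study, a) {
  if (study == "CR") {
    if (a == 0) "adlib" else sprintf("cr%02d", round(100 * a))
  } else {
    if (a == 0) "vehicle" else sprintf("dose%g", a)
  }
}

#' Generate a synthetic longitudinal rat study
#'
#' Draws per-animal baselines (body weight, fat fraction, basal-offset and
#' intake variability), constructs the arm-specific daily intake series,
#' integrates the two-compartment model per animal (optionally with a
#' time-varying partition slope, see
#' [generate_alpha_violating_study()]), and samples noisy observations on
#' the design's measurement days. Intake is deliberately left unmeasured
#' between the first body-composition day and intervention start (and, for
#' the drug design, after the last washout measurement) so the imputation
#' rules are exercised exactly as in a real study.
#'
#' Each animal's baseline intake is its own energy-expenditure equilibrium
#' (so the ad-libitum/vehicle arms are weight-stable up to jitter), and
#' restricted rations are exact fractions of that baseline.
#'
#' @param cfg A [generator_config()].
#' @param partition_profile Optional `function(t, dose)` replacing the
#'   constant partition slope in the generating model.
#' @return A list: `records` (a `study_records` data frame), `truth` (true
#'   parameters, drug parameters, and a per-animal table with each animal's
#'   baseline state, basal offset and baseline intake), `config`.
#' @examples
#' cfg <- generator_config("CR", n_per_arm = 2, seed = 42)
#' std <- generate_study(cfg)
#' head(std$records)
#' @export
generate_study <- function(cfg, partition_profile = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  p <- cfg$params
  des <- if (cfg$study == "CR") cr_design else cb1_design
  rows <- list(); per_animal <- list()
  aid <- 0L
  for (ai in seq_along(cfg$arms)) {
    a <- cfg$arms[ai]
    lab <- arm_label(cfg$study, a)
    dose <- if (cfg$study == "CR") 0 else a
    for (k in seq_len(cfg$n_per_arm[ai])) {
      aid <- aid + 1L
      id <- sprintf("r%03d", aid)
      bw0 <- stats::rnorm(1, cfg$bw_mean, cfg$bw_sd)
      # Baseline composition lies on the population partition line through
      # the design's mean composition (so pooled BC data carry the structure
      # the constant-slope analysis assumes), with composition scatter at
      # fixed body weight.
      b_pop <- cfg$bw_mean * (1 - cfg$fm_frac_mean * (1 + p$alpha))
      fm0 <- (bw0 - b_pop) / (1 + p$alpha) +
        stats::rnorm(1, 0, cfg$fm_frac_sd * bw0)
      ffm0 <- bw0 - fm0
      if (fm0 <= 0 || ffm0 <= 0)
        stop("configuration gives non-positive baseline composition in arm ", lab)
      K_i <- p$K + stats::rnorm(1, 0, cfg$k_sd)
      I0_i <- (K_i + p$lam * bw0 + p$gamma_fm * fm0 + p$gamma_ffm * ffm0) *
        (1 + stats::rnorm(1, 0, cfg$intake_frac_sd))
      if (I0_i <= 0) stop("configuration gives non-positive baseline intake in arm ", lab)
      jit <- function(n) if (cfg$intake_daily_cv > 0)
        exp(stats::rnorm(n, -cfg$intake_daily_cv^2 / 2, cfg$intake_daily_cv))
      else rep(1, n)

      if (cfg$study == "CR") {
        meas_days <- des$restrict_days
        meas_I <- if (a == 0) I0_i * jit(length(meas_days))
                  else rep((1 - a) * I0_i, length(meas_days))
        base_days <- des$baseline_days
        base_I <- I0_i * jit(length(base_days))
      } else {
        meas_days <- des$measured_days
        s <- supp_frac(dose, meas_days, cfg$drug, cfg$suppression)
        s[meas_days == 0] <- 0                 # dosing starts within day 0
        s[meas_days > max(des$treat_days)] <- 0 # washout recovery
        meas_I <- I0_i * (1 - s) * jit(length(meas_days))
        base_days <- integer(0); base_I <- numeric(0)
      }

      # Full truth schedule over the simulation horizon, applying the same
      # fill-in rules the analysis assumes for unmeasured days.
      full_days <- seq(-3, des$sim_end - 1)
      full_I <- meas_I[match(full_days, meas_days)]
      full_I[full_days < min(meas_days)] <- I0_i
      last_m <- max(meas_days[meas_days < des$sim_end])
      full_I[full_days > last_m] <- meas_I[match(last_m, meas_days)]
      sched <- intake_schedule(full_days, full_I, I0_i)

      p_i <- update_params(p, K = K_i, I0 = I0_i)
      afun <- if (is.null(partition_profile)) NULL else
        function(t) partition_profile(t, dose)
      tr <- withCallingHandlers(
        simulate_ebm(list(t = -3, fm = fm0, ffm = ffm0), sched, p_i,
                     dp = if (cfg$study == "CR") NULL else cfg$drug,
                     dose = dose, t_end = des$sim_end, alpha_fun = afun),
        warning = function(w) {
          if (grepl("fat mass reached", conditionMessage(w)))
            stop("configuration drives fat mass negative in arm ", lab)
          invokeRestart("muffleWarning")
        })

      bw_obs <- traj_at(tr, des$bw_days)$bw +
        stats::rnorm(length(des$bw_days), 0, cfg$noise_bw)
      fm_obs <- traj_at(tr, des$bc_days)$fm +
        stats::rnorm(length(des$bc_days), 0, cfg$noise_fm)
      all_days <- sort(unique(c(des$bw_days, meas_days, base_days,
                                des$bc_days)))
      rows[[aid]] <- data.frame(
        animal_id = id, arm = lab, dose_mg_per_kg = dose, day = all_days,
        bw_g = bw_obs[match(all_days, des$bw_days)],
        intake_kcal = c(meas_I, base_I)[match(all_days,
                                              c(meas_days, base_days))],
        fm_g = fm_obs[match(all_days, des$bc_days)],
        stringsAsFactors = FALSE)
      per_animal[[aid]] <- data.frame(
        animal_id = id, arm = lab, dose_mg_per_kg = dose, bw0 = bw0,
        fm0 = fm0, K = K_i, I0 = I0_i, stringsAsFactors = FALSE)
    }
  }
  records <- validate_records(do.call(rbind, rows), NULL)
  list(records = records,
       truth = list(params = p, drug = cfg$drug,
                    per_animal = do.call(rbind, per_animal)),
       config = cfg)
}

#' Generate a study whose body composition violates the constant partition
#' slope
#'
#' Identical to [generate_study()] except that the generating model's
#' partition slope is the supplied time- and dose-dependent profile, e.g. a
#' profile where high drug doses burn almost pure fat. Data generated this
#' way reproduce the situation where a constant-slope model can match body
#' weight yet misfit body composition, while the alpha-free model fits both.
#'
#' @param cfg A [generator_config()].
#' @param partition_profile `function(t, dose)` returning the instantaneous
#'   partition slope dFFM/dFM (finite).
#' @return As [generate_study()].
#' @examples
#' cfg <- generator_config("CB1Ra", n_per_arm = 2, seed = 7)
#' prof <- function(t, dose) 0.92 / (1 + 0.3 * dose)
#' std <- generate_alpha_violating_study(cfg, prof)
#' @export
generate_alpha_violating_study <- function(cfg, partition_profile) {
  stopifnot(is.function(partition_profile))
  generate_study(cfg, partition_profile = partition_profile)
}
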