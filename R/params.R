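#' Physiological parameters of the two-compartment energy-balance model
#'
#' Constructs and validates the full parameter set of the fat-mass /
#' fat-free-mass partition model and its energy-expenditure function.
#'
#' Energy densities and deposition costs default to rodent literature values
#' (see `Details`); the mass-specific metabolic rates default to mouse values
#' translated to a 350 g lean rat by Kleiber allometric scaling (see
#' [kleiber_translate()]). All defaults are literature placeholders intended
#' to be overridden from a study-specific configuration when available; every
#' model operation reads them from this object, never from hard-coded
#' constants.
#'
#' @details The model tracks fat mass `FM` and fat-free mass `FFM` (grams),
#' driven by the imbalance between food-intake energy `I` and energy
#' expenditure `E` (kcal/day):
#' \deqn{dFM/dt = (I - E) / (\rho_{FM} + \alpha \rho_{FFM}), \quad
#'       dFFM/dt = \alpha\, dFM/dt}
#' with energy expenditure
#' \deqn{E = K + \beta (I - I_0) + (\lambda + \gamma_{FM}) FM +
#'       (\lambda + \gamma_{FFM}) FFM + \eta_{FM} dFM/dt + \eta_{FFM} dFFM/dt.}
#' Because the deposition-cost terms contain the derivatives, which in turn
#' contain `E`, the expenditure equation is implicit; it is linear in `E` and
#' solved in closed form by [energy_expenditure()].
#'
#' @param rho_fm,rho_ffm Energy densities of fat and fat-free mass (kcal/g).
#' @param eta_fm,eta_ffm Deposition (synthesis) costs (kcal per g deposited).
#' @param beta Diet-induced thermogenesis fraction of intake above baseline
#'   (dimensionless, in \[0, 1)).
#' @param gamma_fm,gamma_ffm Mass-specific metabolic rates (kcal/g/day).
#' @param lam Physical-activity coefficient per gram of body weight
#'   (kcal/g/day).
#' @param K Basal thermogenesis offset (kcal/day; may be negative).
#' @param alpha Constant energy-partition slope dFFM/dFM (g/g).
#' @param I0 Baseline food intake (kcal/day).
#' @return An object of class `ebm_params` (a named list).
#' @seealso [drug_params()], [read_params_config()], [simulate_ebm()]
#' @examples
#' p <- ebm_params(lam = 0.087, I0 = 102)
#' p
#' @export
ebm_params <- function(rho_fm = 9.4, rho_ffm = 1.8,
                       eta_fm = 0.18, eta_ffm = 0.23,
                       beta = 0.24,
                       gamma_fm = 0.01, gamma_ffm = 0.1,
                       lam = 0.087, K = 0, alpha = 0.92, I0 = 100) {
  p <- list(rho_fm = rho_fm, rho_ffm = rho_ffm, eta_fm = eta_fm,
            eta_ffm = eta_ffm, beta = beta, gamma_fm = gamma_fm,
            gamma_ffm = gamma_ffm, lam = lam, K = K, alpha = alpha, I0 = I0)
  p <- lapply(p, unname)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (p$rho_ffm <= 0 || p$rho_fm <= p$rho_ffm)
    stop("require rho_fm > rho_ffm > 0")
  if (p$eta_fm < 0 || p$eta_ffm < 0) stop("deposition costs must be >= 0")
  if (p$beta < 0 || p$beta >= 1) stop("beta must lie in [0, 1)")
  if (p$gamma_fm < 0 || p$gamma_ffm < 0 || p$lam < 0)
    stop("metabolic rates and lam must be >= 0")
  if (p$I0 < 0) stop("I0 must be >= 0")
  structure(p, class = "ebm_params")
}

#' @export
print.ebm_params <- function(x, ...) {
  cat("Energy-balance model parameters\n")
  cat(sprintf("  energy density   rho_fm = %.3f, rho_ffm = %.3f kcal/g\n",
              x$rho_fm, x$rho_ffm))
  cat(sprintf("  deposition cost  eta_fm = %.3f, eta_ffm = %.3f kcal/g\n",
              x$eta_fm, x$eta_ffm))
  cat(sprintf("  DIT fraction     beta = %.3f\n", x$beta))
  cat(sprintf("  metabolic rate   gamma_fm = %.4f, gamma_ffm = %.4f kcal/g/day\n",
              x$gamma_fm, x$gamma_ffm))
  cat(sprintf("  activity         lam = %.4f kcal/g/day\n", x$lam))
  cat(sprintf("  basal offset     K = %.2f kcal/day\n", x$K))
  cat(sprintf("  partition slope  alpha = %.3f g/g\n", x$alpha))
  cat(sprintf("  baseline intake  I0 = %.1f kcal/day\n", x$I0))
  invisible(x)
}

#' Modify a parameter object
#'
#' Returns a copy of `p` with the named fields replaced, re-validated.
#'
#' @param p An [ebm_params()] object.
#' @param ... Named scalar replacements, e.g. `lam = 0.09`.
#' @return A new `ebm_params` object.
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "ebm_params"))
  repl <- list(...)
  if (length(repl) == 0L) return(p)
  bad <- setdiff(names(repl), names(unclass(p)))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  q <- unclass(p)
  q[names(repl)] <- repl
  do.call(ebm_params, q)
}

#' Hill-type drug-effect parameters
#'
#' The effect of daily drug dosing on energy expenditure is
#' \deqn{d(X) = D_0 + D_{max} X / (ED_{50} + X)}
#' applied only during the treatment window `[t_start, t_end)`. `d0` models
#' handling stress from dosing and so applies to the vehicle arm (dose 0) as
#' well; outside the window the effect is zero.
#'
#' @param d0 Handling-stress effect (kcal/day).
#' @param dmax Maximal drug effect (kcal/day).
#' @param ed50 Dose with half-maximal effect (mg/kg; must be > 0).
#' @param t_start,t_end Treatment window in study days (default `[0, 23)`).
#' @return An object of class `drug_params`.
#' @examples
#' dp <- drug_params(d0 = 13, dmax = 37, ed50 = 10)
#' drug_effect(10, t = 5, dp)  # half-maximal: 13 + 37/2
#' @export
drug_params <- function(d0 = 0, dmax = 0, ed50 = 10, t_start = 0, t_end = 23) {
  vals <- c(d0 = unname(d0), dmax = unname(dmax), ed50 = unname(ed50),
            t_start = unname(t_start), t_end = unname(t_end))
  if (any(!is.finite(vals))) stop("drug parameters must be finite")
  if (ed50 <= 0) stop("ed50 must be > 0")
  if (t_start >= t_end) stop("t_start must be < t_end")
  structure(as.list(vals), class = "drug_params")
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("Hill drug effect: d(X) = %.2f + %.2f X/(%.2f + X), window [%g, %g)\n",
              x$d0, x$dmax, x$ed50, x$t_start, x$t_end))
  invisible(x)
}

# Flat numeric vector in the layout the C++ simulator expects.
params_vec <- function(p) {
  stopifnot(inherits(p, "ebm_params"))
  unlist(p[c("rho_fm", "rho_ffm", "eta_fm", "eta_ffm", "beta", "gamma_fm",
             "gamma_ffm", "lam", "K", "alpha", "I0")])
}

drug_vec <- function(dp) {
  if (is.null(dp)) return(numeric(0))
  stopifnot(inherits(dp, "drug_params"))
  unlist(dp[c("d0", "dmax", "ed50", "t_start", "t_end")])
}

#' Read model parameters from a flat key = value configuration file
#'
#' The configuration format is a flat TOML-style file: one `key = value` pair
#' per line, `#` comments, blank lines ignored. Keys are the field names of
#' [ebm_params()] and, optionally, of [drug_params()] prefixed with `drug_`
#' (e.g. `drug_ed50 = 10`). Values must be plain numbers.
#'
#' @param path Path to the configuration file.
#' @param overrides Optional named numeric vector or list applied after the
#'   file is read (e.g. from command-line `key=value` pairs).
#' @return A list with elements `params` ([ebm_params()]) and `drug`
#'   ([drug_params()] or `NULL` when no `drug_*` keys are present).
#' @examples
#' cfg <- tempfile(fileext = ".toml")
#' writeLines(c("lam = 0.087  # kcal/g/day", "I0 = 102", "drug_d0 = 13",
#'              "drug_dmax = 37", "drug_ed50 = 10"), cfg)
#' read_params_config(cfg)
#' @export
read_params_config <- function(path, overrides = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*([-+0-9.eE]+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: '", ln, "' (expected key = number)")
    kv[[m[2]]] <- as.numeric(m[3])
  }
  if (!is.null(overrides)) kv[names(overrides)] <- as.numeric(overrides)
  is_drug <- grepl("^drug_", names(kv))
  pk <- kv[!is_drug]
  dk <- kv[is_drug]
  names(dk) <- sub("^drug_", "", names(dk))
  params <- do.call(ebm_params, pk)
  drug <- if (length(dk)) do.call(drug_params, dk) else NULL
  list(params = params, drug = drug)
}
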