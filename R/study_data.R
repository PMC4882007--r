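#' Load a longitudinal rat study table
#'
#' Reads per-animal daily records of body weight, food intake and sparse
#' DXA fat-mass measurements. The canonical on-disk format is tidy long CSV
#' with columns `animal_id`, `arm`, `dose_mg_per_kg`, `day`, `bw_g`,
#' `intake_kcal` (or `intake_g`), `fm_g`, empty cells marking unmeasured
#' values. A `wide` dialect is also accepted: one row per animal with
#' day-stamped columns `bw_<day>`, `intake_<day>` (or `intake_g_<day>`),
#' `fm_<day>`. When intake is recorded in grams of food per day it is
#' converted to kcal/day with `diet_kcal_per_g`. XLSX workbooks are read via
#' the same schema (first sheet by default) when the `readxl` package is
#' installed.
#'
#' @param path Path to a CSV or XLSX file.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param diet_kcal_per_g Diet energy density (kcal per g of food); required
#'   when intake is reported in g/day.
#' @param sheet Sheet index or name for XLSX input.
#' @return A `study_records` data frame (tidy long, intake in kcal/day) with
#'   attribute `validation`: a character vector describing missing cells.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(animal_id = "r1", arm = "adlib", dose_mg_per_kg = 0,
#'                      day = 0:2, bw_g = c(640, 641, 642),
#'                      intake_kcal = c(100, 98, 101), fm_g = c(192, NA, NA)),
#'           f, row.names = FALSE)
#' load_study(f)
#' @export
load_study <- function(path, dialect = c("long", "wide"),
                       diet_kcal_per_g = NULL, sheet = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("study file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package")
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (dialect == "wide") df <- wide_to_long(df)
  validate_records(df, diet_kcal_per_g)
}

wide_to_long <- function(df) {
  id_cols <- c("animal_id", "arm", "dose_mg_per_kg")
  miss <- setdiff(id_cols, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  meas <- setdiff(names(df), id_cols)
  m <- regmatches(meas, regexec("^(bw|intake|intake_g|fm)_(-?[0-9]+)$", meas))
  bad <- meas[vapply(m, length, 1L) != 3L]
  if (length(bad)) stop("unknown column(s): ", paste(bad, collapse = ", "))
  var <- vapply(m, `[`, "", 2L)
  day <- as.integer(vapply(m, `[`, "", 3L))
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    data.frame(animal_id = df$animal_id[i], arm = df$arm[i],
               dose_mg_per_kg = df$dose_mg_per_kg[i], day = day,
               var = var, value = as.numeric(unlist(df[i, meas])),
               stringsAsFactors = FALSE)
  }))
  out <- out[!is.na(out$value), ]
  long <- stats::reshape(out, idvar = c("animal_id", "arm", "dose_mg_per_kg",
                                        "day"),
                         timevar = "var", direction = "wide")
  names(long) <- sub("^value\\.", "", names(long))
  ren <- c(bw = "bw_g", intake = "intake_kcal", intake_g = "intake_g",
           fm = "fm_g")
  for (nm in names(ren))
    if (nm %in% names(long)) names(long)[names(long) == nm] <- ren[[nm]]
  rownames(long) <- NULL
  long
}

validate_records <- function(df, diet_kcal_per_g) {
  req <- c("animal_id", "arm", "dose_mg_per_kg", "day")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  known <- c(req, "bw_g", "intake_kcal", "intake_g", "fm_g")
  unk <- setdiff(names(df), known)
  if (length(unk)) stop("unknown column(s): ", paste(unk, collapse = ", "))
  if (!"intake_kcal" %in% names(df)) {
    if (!"intake_g" %in% names(df))
      stop("missing column(s): intake_kcal (or intake_g)")
    if (is.null(diet_kcal_per_g))
      stop("intake is in g/day; supply diet_kcal_per_g to convert")
    df$intake_kcal <- df$intake_g * diet_kcal_per_g
    df$intake_g <- NULL
  }
  if (!"bw_g" %in% names(df)) df$bw_g <- NA_real_
  if (!"fm_g" %in% names(df)) df$fm_g <- NA_real_
  df <- df[c(req, "bw_g", "intake_kcal", "fm_g")]
  dup <- duplicated(df[c("animal_id", "day")])
  if (any(dup)) {
    d <- df[dup, ][1, ]
    stop(sprintf("duplicated (animal, day) record: (%s, %g)",
                 d$animal_id, d$day))
  }
  for (col in c("bw_g", "intake_kcal", "fm_g")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad))
      stop(sprintf("negative %s for animal %s on day %g", col,
                   df$animal_id[bad[1]], df$day[bad[1]]))
  }
  bad <- which(!is.na(df$bw_g) & df$bw_g == 0)
  if (length(bad)) stop("zero body weight for animal ", df$animal_id[bad[1]])
  bad <- which(!is.na(df$fm_g) & !is.na(df$bw_g) & df$fm_g >= df$bw_g)
  if (length(bad))
    stop(sprintf("fat mass >= body weight for animal %s on day %g",
                 df$animal_id[bad[1]], df$day[bad[1]]))
  df <- df[order(df$arm, df$animal_id, df$day), ]
  rownames(df) <- NULL
  val <- character(0)
  n_miss_bw <- sum(is.na(df$bw_g))
  n_miss_fi <- sum(is.na(df$intake_kcal))
  if (n_miss_bw) val <- c(val, sprintf("%d missing BW cells", n_miss_bw))
  if (n_miss_fi) val <- c(val, sprintf("%d missing intake cells", n_miss_fi))
  structure(df, class = c("study_records", "data.frame"), validation = val)
}

#' Write study records as tidy long CSV
#'
#' @param records A `study_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Aggregate per-animal records into treatment-arm summaries
#'
#' Produces per-arm daily mean and SEM body weight, mean intake, and mean and
#' SEM fat mass on the body-composition days; fat-free mass is derived from
#' the means (`FFM = mean BW - mean FM`), since DXA studies do not measure it
#' directly. Means are over the animals present on each day; SEM is
#' `sd / sqrt(n)`.
#'
#' @param records A `study_records` data frame (>= 2 animals per arm).
#' @param diet_kcal_per_g Optional diet energy density carried into each arm.
#' @return A list of `study_arm` objects, one per arm label, each with
#'   fields `arm`, `dose`, `n`, `days`, `bw_mean`, `bw_sem`, `intake_days`,
#'   `intake_mean`, `bc_days`, `fm_mean`, `fm_sem`, `ffm_mean`.
#' @export
aggregate_arms <- function(records, diet_kcal_per_g = NULL) {
  stopifnot(is.data.frame(records))
  arms <- unique(records$arm)
  out <- lapply(arms, function(a) {
    r <- records[records$arm == a, ]
    if (nrow(r) == 0L) stop("empty arm: ", a)
    n <- length(unique(r$animal_id))
    if (n < 2L) stop("arm '", a, "' has fewer than 2 animals")
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    agg <- function(col) {
      v <- r[!is.na(r[[col]]), c("day", col)]
      if (nrow(v) == 0L) return(NULL)
      days <- sort(unique(v$day))
      list(days = days,
           mean = vapply(days, function(d) mean(v[[col]][v$day == d]), 0),
           sem = vapply(days, function(d) sem(v[[col]][v$day == d]), 0))
    }
    bw <- agg("bw_g"); fi <- agg("intake_kcal"); fm <- agg("fm_g")
    if (is.null(bw)) stop("arm '", a, "' has no body-weight data")
    ffm <- if (is.null(fm)) NULL else {
      ib <- match(fm$days, bw$days)
      if (anyNA(ib)) stop("arm '", a, "': FM measured on a day without BW")
      bw$mean[ib] - fm$mean
    }
    structure(list(arm = a, dose = unique(r$dose_mg_per_kg)[1], n = n,
                   days = bw$days, bw_mean = bw$mean, bw_sem = bw$sem,
                   intake_days = fi$days, intake_mean = fi$mean,
                   bc_days = fm$days, fm_mean = fm$mean, fm_sem = fm$sem,
                   ffm_mean = ffm, diet_kcal_per_g = diet_kcal_per_g),
              class = "study_arm")
  })
  names(out) <- arms
  out
}

#' @export
print.study_arm <- function(x, ...) {
  cat(sprintf("Arm '%s' (dose %g mg/kg, n = %d): BW days %g..%g, BC days %s\n",
              x$arm, x$dose, x$n, min(x$days), max(x$days),
              paste(x$bc_days, collapse = "/")))
  invisible(x)
}

#' Baseline food intake of an arm
#'
#' Two study conventions are supported: `"pre_study_mean"` averages the
#' baseline measurement days recorded before the first body-composition day
#' (the caloric-restriction design, where baseline intake was established
#' over 4 pre-study days), and `"day0"` takes the day-0 measurement (the
#' drug-study design).
#'
#' @param arm A `study_arm`.
#' @param method `"pre_study_mean"` or `"day0"`.
#' @return Baseline intake (kcal/day).
#' @export
baseline_intake <- function(arm, method = c("pre_study_mean", "day0")) {
  method <- match.arg(method)
  if (is.null(arm$intake_days)) stop("arm has no intake data")
  if (method == "day0") {
    i <- match(0, arm$intake_days)
    if (is.na(i)) stop("no day-0 intake measurement")
    return(arm$intake_mean[i])
  }
  first_bc <- min(arm$bc_days %||% 0)
  pre <- arm$intake_days < first_bc
  if (!any(pre)) stop("no pre-study baseline intake measurements")
  mean(arm$intake_mean[pre])
}

#' Fill gaps in an arm's intake record by the study rules
#'
#' Missing intake between the first body-composition measurement and the
#' start of intervention is set to the baseline intake; missing intake after
#' the last measured day (before the final body-composition day) is carried
#' forward from the last measured value. Interior gaps are filled by
#' last-observation-carried-forward with a warning, a conservative rule for a
#' case the study designs do not produce. Measured values are never altered.
#'
#' @param arm A `study_arm`.
#' @param horizon Length-2 integer vector `c(t0, t1)`; must not extend before
#'   the first body-composition day.
#' @param I0 Baseline intake (kcal/day); defaults to
#'   [baseline_intake()] with the pre-study-mean rule.
#' @return An [intake_schedule()] covering days `t0 .. t1 - 1`.
#' @export
impute_intake <- function(arm, horizon, I0 = NULL) {
  stopifnot(inherits(arm, "study_arm"), length(horizon) == 2L)
  t0 <- horizon[1]; t1 <- horizon[2]
  first_bc <- min(arm$bc_days %||% t0)
  if (t0 < first_bc)
    stop("horizon starts before the first body-composition day (", first_bc, ")")
  if (is.null(I0)) I0 <- baseline_intake(arm)
  days <- seq(t0, t1 - 1)
  vals <- arm$intake_mean[match(days, arm$intake_days)]
  measured <- !is.na(vals)
  if (!any(measured)) {
    vals[] <- I0
  } else {
    first_m <- which(measured)[1]
    last_m <- which(measured)[length(which(measured))]
    if (first_m > 1) vals[seq_len(first_m - 1)] <- I0  # pre-intervention gap
    if (last_m < length(vals))                          # tail before final BC
      vals[(last_m + 1):length(vals)] <- vals[last_m]
    interior <- which(!measured & seq_along(vals) > first_m &
                        seq_along(vals) < last_m)
    if (length(interior)) {
      warning(length(interior),
              " interior intake gap(s) filled by carrying the last value forward")
      for (i in interior) vals[i] <- vals[i - 1]
    }
  }
  intake_schedule(days, vals, I0)
}
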