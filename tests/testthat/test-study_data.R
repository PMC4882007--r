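make_toy_records <- function() {
  data.frame(
    animal_id = rep(c("r1", "r2"), each = 4),
    arm = "adlib", dose_mg_per_kg = 0,
    day = rep(0:3, 2),
    bw_g = c(640, 641, 643, 642, 650, 652, 651, 653),
    intake_kcal = c(100, 98, 101, 99, 103, 102, 104, 101),
    fm_g = c(192, NA, NA, 195, 200, NA, NA, 203),
    stringsAsFactors = FALSE)
}

test_that("grams-per-day intake is converted with the diet energy density", {
  df <- make_toy_records()
  df$intake_g <- df$intake_kcal
  df$intake_kcal <- NULL
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, na = "")
  rec <- load_study(f, diet_kcal_per_g = 4.55)
  expect_equal(rec$intake_kcal, df$intake_g * 4.55)
  expect_error(load_study(f), "diet_kcal_per_g")
})

test_that("duplicate (animal, day) rows and bad values are rejected by name", {
  df <- make_toy_records()
  f <- tempfile(fileext = ".csv")
  write.csv(rbind(df, df[3, ]), f, row.names = FALSE, na = "")
  expect_error(load_study(f), "\\(r1, 2\\)")
  df2 <- make_toy_records(); df2$intake_kcal[5] <- -3
  write.csv(df2, f, row.names = FALSE, na = "")
  expect_error(load_study(f), "negative intake_kcal.*r2")
  df3 <- make_toy_records(); df3$extra <- 1
  write.csv(df3, f, row.names = FALSE, na = "")
  expect_error(load_study(f), "unknown column")
  df4 <- make_toy_records(); df4$fm_g[1] <- 700
  write.csv(df4, f, row.names = FALSE, na = "")
  expect_error(load_study(f), "fat mass >= body weight")
})

test_that("a synthetic study round-trips through write and load", {
  std <- generate_study(generator_config("CR", n_per_arm = 2, seed = 51))
  f <- tempfile(fileext = ".csv")
  write_study(std$records, f)
  expect_silent(back <- load_study(f))
  expect_equal(as.data.frame(back), as.data.frame(std$records),
               tolerance = 1e-12)
})

test_that("long and wide renderings of a study load identically", {
  df <- make_toy_records()
  flong <- tempfile(fileext = ".csv")
  write.csv(df, flong, row.names = FALSE, na = "")
  rec_long <- load_study(flong)
  # wide rendering: one row per animal, day-stamped columns
  wide <- do.call(rbind, lapply(split(df, df$animal_id), function(a) {
    row <- data.frame(animal_id = a$animal_id[1], arm = a$arm[1],
                      dose_mg_per_kg = a$dose_mg_per_kg[1])
    for (i in seq_len(nrow(a))) {
      row[[paste0("bw_", a$day[i])]] <- a$bw_g[i]
      row[[paste0("intake_", a$day[i])]] <- a$intake_kcal[i]
      row[[paste0("fm_", a$day[i])]] <- a$fm_g[i]
    }
    row
  }))
  fwide <- tempfile(fileext = ".csv")
  write.csv(wide, fwide, row.names = FALSE, na = "")
  rec_wide <- load_study(fwide, dialect = "wide")
  expect_equal(as.data.frame(rec_wide), as.data.frame(rec_long))
})

test_that("arm aggregation produces means, SEMs and derived FFM", {
  df <- data.frame(
    animal_id = rep(c("a", "b", "c", "d"), each = 1),
    arm = "adlib", dose_mg_per_kg = 0, day = 0,
    bw_g = c(640, 650, 630, 660), intake_kcal = 100,
    fm_g = c(200, 210, 205, 225), stringsAsFactors = FALSE)
  arms <- aggregate_arms(ratabolic:::validate_records(df, NULL))
  a <- arms[[1]]
  expect_equal(a$bw_mean, 645)
  expect_equal(a$bw_sem, sd(c(640, 650, 630, 660)) / 2)
  expect_equal(a$ffm_mean, 645 - 210)
  expect_equal(a$n, 4)
})

test_that("aggregation is permutation invariant and FFM derivations agree", {
  std <- generate_study(generator_config("CR", n_per_arm = 4, seed = 52))
  rec <- std$records
  arms1 <- aggregate_arms(rec)
  perm <- rec[sample(nrow(rec)), ]
  arms2 <- aggregate_arms(ratabolic:::validate_records(perm, NULL))
  expect_equal(arms1[["cr40"]]$bw_mean, arms2[["cr40"]]$bw_mean)
  expect_equal(arms1[["cr40"]]$ffm_mean, arms2[["cr40"]]$ffm_mean)
  # FFM from means equals mean of per-animal FFM (linearity)
  a <- arms1[["cr20"]]
  for (j in seq_along(a$bc_days)) {
    d <- a$bc_days[j]
    r <- rec[rec$arm == "cr20" & rec$day == d, ]
    expect_equal(a$ffm_mean[j], mean(r$bw_g - r$fm_g))
  }
})

test_that("single-animal arms are rejected for SEM computation", {
  df <- make_toy_records()
  df <- df[df$animal_id == "r1", ]
  expect_error(aggregate_arms(ratabolic:::validate_records(df, NULL)),
               "fewer than 2")
})

test_that("intake imputation applies the pre-study and tail rules", {
  # drug-study-like arm: measured through day 37, BC day at 42
  days <- c(-3, 0:37, 42)
  df <- do.call(rbind, lapply(c("x", "y"), function(id)
    data.frame(animal_id = id, arm = "dose10", dose_mg_per_kg = 10,
               day = days, bw_g = 700,
               intake_kcal = ifelse(days >= 0 & days <= 37, 95 - days / 10, NA),
               fm_g = ifelse(days %in% c(-3, 24, 42), 210, NA))))
  arm <- aggregate_arms(ratabolic:::validate_records(df, NULL))[[1]]
  sched <- impute_intake(arm, c(-3, 42), I0 = baseline_intake(arm, "day0"))
  expect_equal(sched$days, -3:41)
  # pre-intervention gap filled with baseline (day-0 value)
  expect_equal(sched$intake[sched$days %in% -3:-1], rep(95, 3))
  # tail carried forward from day 38 onwards at the day-37 value
  expect_equal(sched$intake[sched$days %in% 38:41], rep(95 - 3.7, 4))
  # measured values untouched
  expect_equal(sched$intake[sched$days %in% 0:37], 95 - (0:37) / 10)
  expect_error(impute_intake(arm, c(-5, 42)), "before the first")
})

test_that("interior gaps are carried forward with a warning", {
  days <- c(-3, 0:10)
  df <- do.call(rbind, lapply(c("x", "y"), function(id)
    data.frame(animal_id = id, arm = "adlib", dose_mg_per_kg = 0,
               day = days, bw_g = 650,
               intake_kcal = ifelse(days %in% c(4, 5), NA,
                                    ifelse(days >= 0, 100 + days, NA)),
               fm_g = ifelse(days %in% c(-3, 10), 200, NA))))
  arm <- aggregate_arms(ratabolic:::validate_records(df, NULL))[[1]]
  expect_warning(sched <- impute_intake(arm, c(-3, 11), I0 = 100),
                 "carrying the last value forward")
  expect_equal(sched$intake[sched$days == 4], 103)
  expect_equal(sched$intake[sched$days == 5], 103)
  expect_equal(sched$intake[sched$days == 6], 106)
  # a gap-free arm reproduces the measurements exactly
  df2 <- df; df2$intake_kcal[df2$day %in% c(4, 5)] <- 104:105
  arm2 <- aggregate_arms(ratabolic:::validate_records(df2, NULL))[[1]]
  sched2 <- impute_intake(arm2, c(0, 11), I0 = 100)
  expect_equal(sched2$intake, 100 + 0:10)
})

test_that("baseline intake rules distinguish the two study designs", {
  std <- generate_study(noiseless_cfg("CR", n_per_arm = 2, seed = 53))
  arm <- aggregate_arms(std$records)[["adlib"]]
  truth <- std$truth$per_animal
  expect_equal(baseline_intake(arm, "pre_study_mean"),
               mean(truth$I0[truth$arm == "adlib"]), tolerance = 1e-10)
  stdc <- generate_study(noiseless_cfg("CB1Ra", n_per_arm = 2, seed = 54))
  armc <- aggregate_arms(stdc$records)[["vehicle"]]
  truthc <- stdc$truth$per_animal
  expect_equal(baseline_intake(armc, "day0"),
               mean(truthc$I0[truthc$arm == "vehicle"]), tolerance = 1e-10)
})
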