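# direct AgeDev designs: one row per animal, exponential event law with a
# hazard that depends on the agedev score
agedev_design <- function(n, seed, effect = function(a) 0 * a,
                          base_rate = 0.15, censor_at = 8) {
  set.seed(seed)
  agedev <- runif(n, -1, 3)
  t_event <- rexp(n, base_rate * exp(effect(agedev)))
  entry <- runif(n, 0.1, 0.6)
  tibble::tibble(
    animal_id = sprintf("a%04d", 1:n),
    tstart = entry,
    tstop = entry + pmin(t_event, censor_at),
    event = as.integer(t_event < censor_at),
    breed_size = sample(c("small", "medium_large"), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    agedev = agedev
  )
}

test_that("the AgeDev hazard ratio recovers a known log-hazard", {
  rows <- agedev_design(800, seed = 101,
                        effect = function(a) log(1.75) * a)
  res <- cox_agedev(rows)
  expect_true(res$ci_low <= 1.75 & 1.75 <= res$ci_high)

  # permuting AgeDev across animals destroys the association
  set.seed(102)
  rows_perm <- rows |> dplyr::mutate(agedev = sample(agedev))
  null <- cox_agedev(rows_perm)
  expect_true(null$ci_low <= 1 & 1 <= null$ci_high)

  expect_error(cox_agedev(rows |> dplyr::mutate(agedev = 1)), "constant")
})

test_that("quintile boundaries match hand-computed quantile cuts", {
  vals <- c(0.3, -1.2, 2.5, 0.9, 1.7, -0.4, 3.1, 0.1, 1.1, 2.0)
  rows <- agedev_design(10, seed = 103)
  rows$agedev <- vals
  rows$event <- rep(c(0L, 1L), 5)
  q <- quantile(vals, 0:5 / 5, type = 7, names = FALSE)
  res <- suppressWarnings(quintile_hr(rows, covariates = character(0)))
  expect_equal(res$range_low, q[2:5], tolerance = 1e-12)
  expect_equal(res$range_high, q[3:6], tolerance = 1e-12)

  # quintile sizes differ by at most 1
  counts <- table(cut(vals, q, include.lowest = TRUE))
  expect_lte(diff(range(counts)), 1)
})

test_that("quintile hazard ratios rise under a monotone effect", {
  rows <- agedev_design(1200, seed = 104,
                        effect = function(a) 0.8 * a)
  res <- quintile_hr(rows)
  expect_gt(cor(res$quintile, log(res$hr), method = "spearman"), 0)
  expect_gt(res$hr[res$quintile == 5], res$hr[res$quintile == 2])

  null <- quintile_hr(agedev_design(1200, seed = 105))
  covered <- mean(null$ci_low <= 1 & 1 <= null$ci_high)
  expect_gte(covered, 0.75)

  few <- agedev_design(30, seed = 106)
  few$agedev <- rep(1:3, 10)
  expect_error(quintile_hr(few), "fewer bins|distinct")
})

test_that("a single-candidate scan equals a direct log-rank statistic", {
  rows <- agedev_design(120, seed = 107, effect = function(a) 0.5 * (a > 1))
  rows <- rows[!duplicated(rows$tstop) | rows$event == 0, ]  # tie-free events
  scan <- suppressWarnings(cutpoint_scan(rows, candidates = 1.0))
  z_oracle <- oracle_logrank_z(rows, rows$agedev > 1.0)
  expect_equal(scan$statistic, z_oracle, tolerance = 1e-10)
})

test_that("complete separation puts the cutpoint between the groups with HR > 1", {
  rows <- tibble::tibble(
    animal_id = sprintf("a%d", 1:20),
    tstart = 0.1,
    tstop = c(seq(5, 7, length.out = 10), seq(1, 3, length.out = 10)),
    event = c(rep(0L, 10), rep(1L, 10)),
    breed_size = "small", sex = "male",
    agedev = c(rep(0, 10), rep(2, 10))
  )
  scan <- suppressWarnings(cutpoint_scan(rows, candidates = c(0.5, 1, 1.5)))
  best <- attr(scan, "best_cutpoint")
  expect_gt(best, 0)
  expect_lt(best, 2)
  expect_true(all(scan$hr_high_vs_low > 1))
})

test_that("candidates outside the observed range are skipped with a warning", {
  rows <- agedev_design(100, seed = 108)
  expect_warning(scan <- cutpoint_scan(rows, candidates = c(0.5, 99)),
                 "outside")
  expect_equal(nrow(scan), 1)
})

test_that("an uninformative score gives AUC 0.5 and separation gives 1", {
  rows <- agedev_design(150, seed = 109)
  rows$flat <- 3.3
  roc <- incident_dynamic_roc(rows, "flat", entry_age = 0, horizon_age = 10)
  expect_equal(roc$auc, 0.5)

  # perfect separation: every case outscores every control at each event time
  sep <- tibble::tibble(
    animal_id = sprintf("s%d", 1:10),
    tstart = 0.5,
    tstop = c(2, 3, 4, rep(9.5, 7)),
    event = c(1L, 1L, 1L, rep(0L, 7)),
    breed_size = "small", sex = "female",
    agedev = c(5, 4, 3, rep(0, 7))
  )
  roc_sep <- incident_dynamic_roc(sep, "agedev", entry_age = 0,
                                  horizon_age = 10)
  expect_equal(roc_sep$auc, 1.0)
  expect_true(all(roc_sep$auc_by_time$auc == 1))
})

test_that("the true log-hazard outranks a noisy copy of itself", {
  wins <- 0
  n_rep <- 20
  for (s in 1:n_rep) {
    rows <- agedev_design(250, seed = 200 + s,
                          effect = function(a) 0.9 * a)
    rows$noisy <- rows$agedev + rnorm(nrow(rows), sd = 2)
    roc <- incident_dynamic_roc(rows, "agedev", entry_age = 0,
                                horizon_age = 8, alt_score_col = "noisy")
    wins <- wins + (roc$auc > roc$alt_auc)
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("out-of-range counting uses closed bounds on the raw scale", {
  specs <- tibble::tibble(
    marker = c("glucose", "albumin"), units = "",
    log_transform = FALSE, reference_low = c(70, 2.7),
    reference_high = c(120, 4.0)
  )
  panel <- tibble::tibble(
    animal_id = "a", age_at_draw = 1,
    glucose = c(95, 130, 120, 69.9), albumin = c(3.3, 3.3, 2.7, 2.0)
  )
  expect_equal(count_out_of_range(panel, specs), c(0L, 1L, 0L, 2L))
  expect_error(count_out_of_range(panel, specs, markers = c("glucose", "wbc")),
               "wbc")
})

test_that("range strata and quintile profiles match a hand tally", {
  scores <- tibble::tibble(
    animal_id = sprintf("a%d", 1:5), age = 5,
    agedev = c(-1, 0, 0.5, 1.5, 3)
  )
  counts <- c(0L, 0L, 1L, 1L, 5L)
  strata <- agedev_by_range_strata(scores, counts)
  expect_equal(strata$n_obs, c(2L, 2L, 1L))
  expect_equal(strata$n_out_of_range, c(0, 1, 4))
  expect_equal(strata$median[1], median(c(-1, 0)))

  specs <- tibble::tibble(marker = "glucose", units = "",
                          log_transform = FALSE,
                          reference_low = 70, reference_high = 120)
  panel <- tibble::tibble(animal_id = scores$animal_id, age_at_draw = 5,
                          glucose = c(80, 90, 100, 130, 140))
  prof <- quintile_range_profile(scores, panel, specs)
  expect_equal(sum(prof$n_obs), 5)
  expect_equal(prof$n_out_of_range[prof$quintile == 5], 1)
})

test_that("evaluation statistics ignore the ordering of input rows", {
  rows <- agedev_design(300, seed = 110, effect = function(a) 0.5 * a)
  shuffled <- rows[sample(nrow(rows)), ]
  expect_equal(cox_agedev(rows)$hr_per_year,
               cox_agedev(shuffled)$hr_per_year, tolerance = 1e-10)
  expect_equal(
    incident_dynamic_roc(rows, entry_age = 0, horizon_age = 8)$auc,
    incident_dynamic_roc(shuffled, entry_age = 0, horizon_age = 8)$auc,
    tolerance = 1e-12
  )
  s1 <- suppressWarnings(cutpoint_scan(rows, candidates = c(0, 0.5, 1)))
  s2 <- suppressWarnings(cutpoint_scan(shuffled, candidates = c(0, 0.5, 1)))
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-10)
})

test_that("diet comparison detects marker-mediated benefits and keeps AgeDev", {
  truth <- default_sim_truth(seed = 111, censor_rate = 0, max_followup = 14)
  train_cohort <- simulate_cohort(sim_config(400, default_sim_truth(seed = 112)))
  specs <- phenoclock:::sim_marker_specs(truth)
  train_panel <- suppressMessages(suppressWarnings(
    preprocess_panel(train_cohort$panel, specs)
  ))
  train_rows <- suppressWarnings(
    to_counting_process(train_cohort$animals, train_panel)
  )
  clock <- train_clock(train_rows, truth$markers$marker[truth$markers$coef != 0])

  trial <- simulate_cr_trial(sim_config(48, truth),
                             diet_effects = c(glucose = -10, wbc = -2),
                             effect_onset_age = 7)
  trial_panel <- suppressMessages(suppressWarnings(
    apply_log_transforms(trial$panel, specs)
  ))
  scores <- score_cohort(trial_panel, trial$animals, clock) |>
    dplyr::left_join(trial$diet, by = "animal_id")
  cmp <- suppressWarnings(compare_diet_groups(scores, trial$animals))
  expect_lt(cmp$post_onset$difference, 0)
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_true(all(c("agedev", "dietrestricted") %in% cmp$cox$term))

  expect_error(
    compare_diet_groups(scores |> dplyr::mutate(diet = "control"),
                        trial$animals),
    "both diet arms"
  )
})
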