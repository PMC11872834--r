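#' Split animals into training and testing sets
#'
#' Random split at the animal level: every measurement row follows its
#' animal, so repeated measures never straddle the split. Deterministic for a
#' given seed.
#'
#' @param animals Animal metadata tibble.
#' @param frac Training fraction, in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(animals, frac = 0.75, seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  ids <- animals$animal_id
  if (length(ids) < 2) abort("need at least 2 animals to split")
  n_train <- round(frac * length(ids))
  if (n_train == 0 || n_train == length(ids)) {
    abort(sprintf("frac = %g leaves an empty side for %d animals (train size rounds to %d)",
                  frac, length(ids), n_train))
  }
  train <- with_seed(seed, sort(sample(ids, n_train)))
  list(train = train, test = sort(setdiff(ids, train)))
}

# marker specs matching a simulation truth, taken from the bundled panel
sim_marker_specs <- function(truth) {
  default_marker_specs() |>
    filter(.data$marker %in% truth$markers$marker)
}

clock_to_list <- function(clock) {
  model_list <- function(m) {
    list(
      gamma = unname(m$gamma), beta0 = unname(m$beta0),
      coefficients = as.list(m$coefficients),
      vcov = list(parameters = rownames(m$vcov),
                  values = unname(as.vector(m$vcov))),
      loglik = unname(m$loglik), n_rows = m$n_rows, n_events = m$n_events
    )
  }
  list(
    schema = "phenoclock/clock/v1",
    markers = clock$markers,
    covariates = clock$covariates,
    full = model_list(clock$full),
    ref = model_list(clock$ref),
    provenance = clock$provenance
  )
}

#' Run the end-to-end synthetic workflow
#'
#' Executes the full study pipeline on a simulated cohort: generate, curate
#' (log transform, percentile trim, completeness filter), split by animal,
#' screen markers per SD, select markers by cross-validated LASSO-Cox, train
#' the Gompertz clock on the training set, score the test set, and evaluate
#' AgeDev (hazard ratio per year, correlation with chronological age,
#' cutpoint scan, incident/dynamic ROC against the out-of-range count). All
#' artifacts are written to `out_dir` as delimited text/JSON, stamped with
#' the configuration hash and seed; reruns with the same configuration are
#' byte-identical. Filter counts are logged at every stage.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_animals Cohort size.
#' @param seed Integer master seed for simulation, split, and fold
#'   assignment.
#' @param split Training fraction.
#' @param k_folds CV folds for marker selection.
#' @param truth `sim_truth` generator configuration.
#' @param frac_medium_large,frac_male Cohort composition.
#' @return Invisibly, a list with all stage results (`cohort`, `screen`,
#'   `selection`, `clock`, `scores`, `evaluation`).
#' @export
run_pipeline <- function(out_dir, n_animals = 600, seed = 1L, split = 0.75,
                         k_folds = 20, truth = default_sim_truth(seed = seed),
                         frac_medium_large = 0.5, frac_male = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(n_animals = n_animals, seed = seed, split = split,
              k_folds = k_folds, truth = unclass(truth),
              frac_medium_large = frac_medium_large, frac_male = frac_male)
  cfg_hash <- rlang::hash(cfg)
  specs <- sim_marker_specs(truth)
  markers <- truth$markers$marker

  config <- sim_config(n_animals, truth, frac_medium_large, frac_male)
  cohort <- simulate_cohort(config)
  inform(sprintf("simulated %d animals (%d dead), %d draws",
                 nrow(cohort$animals), sum(cohort$animals$status),
                 nrow(cohort$panel)))
  write_table(cohort$animals, file.path(out_dir, "animals.csv"))
  write_table(cohort$panel, file.path(out_dir, "panel.csv"))

  processed <- preprocess_panel(cohort$panel, specs)
  inform(sprintf("curation kept %d of %d draws (%d of %d animals)",
                 nrow(processed), nrow(cohort$panel),
                 length(unique(processed$animal_id)),
                 length(unique(cohort$panel$animal_id))))
  write_table(processed, file.path(out_dir, "processed_panel.csv"))

  ids <- split_train_test(cohort$animals, frac = split,
                          seed = derive_seed(seed, 11L))
  train_animals <- cohort$animals |> filter(.data$animal_id %in% ids$train)
  test_animals <- cohort$animals |> filter(.data$animal_id %in% ids$test)
  train_panel <- processed |> filter(.data$animal_id %in% ids$train)
  test_panel <- processed |> filter(.data$animal_id %in% ids$test)
  train_rows <- to_counting_process(train_animals, train_panel)
  test_rows <- to_counting_process(test_animals, test_panel)
  inform(sprintf("split: %d train / %d test animals; %d / %d rows; %d / %d events",
                 length(ids$train), length(ids$test),
                 nrow(train_rows), nrow(test_rows),
                 sum(train_rows$event), sum(test_rows$event)))

  scaling <- fit_scaling(train_panel, markers)
  scaled_rows <- to_counting_process(train_animals,
                                     apply_scaling(train_panel, scaling))
  screen <- screen_markers(scaled_rows, markers,
                           covariates = c("sex", "breed_size"))
  write_table(screen, file.path(out_dir, "screen.csv"))

  kf <- min(k_folds, length(ids$train), sum(train_rows$event))
  selection <- lasso_cox_cv(train_rows, markers, k_folds = kf,
                            seed = derive_seed(seed, 12L),
                            lambda.min.ratio = 0.01)
  clock_markers <- selection$nonzero_selected
  if (length(clock_markers) == 0) {
    warn(paste(
      "cross-validation favoured the null model (no markers selected);",
      "training the clock on the full candidate set instead"
    ))
    clock_markers <- markers
  }
  jsonlite::write_json(
    list(
      config_hash = cfg_hash, seed = seed,
      lambda_selected = selection$lambda_selected,
      log_lambda_selected = log(selection$lambda_selected),
      nonzero_selected = selection$nonzero_selected,
      selected_coefficients = as.list(selection$selected_coefficients),
      cv = selection$cv
    ),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA
  )

  clock <- train_clock(train_rows, clock_markers,
                       provenance = list(seed = seed, config_hash = cfg_hash,
                                         training_ids = ids$train))
  jsonlite::write_json(clock_to_list(clock),
                       file.path(out_dir, "clock.json"),
                       auto_unbox = TRUE, digits = NA)

  scores <- score_cohort(test_panel, test_animals, clock)
  write_table(scores, file.path(out_dir, "scores.csv"))

  ad_rows <- agedev_rows(scores, test_animals)
  hr <- cox_agedev(ad_rows)
  scan <- cutpoint_scan(ad_rows)
  raw_match <- scores |>
    left_join(cohort$panel |> rename(age = "age_at_draw"),
              by = c("animal_id", "age"))
  ad_rows$oor <- {
    m <- ad_rows |>
      left_join(raw_match |> select(all_of(c("animal_id", "age", markers))),
                by = c("animal_id", "tstart" = "age"))
    count_out_of_range(m, specs, markers)
  }
  roc <- incident_dynamic_roc(ad_rows, "agedev", alt_score_col = "oor")
  evaluation <- list(
    config_hash = cfg_hash, seed = seed,
    hr_per_agedev_year = hr$hr_per_year, hr_ci_low = hr$ci_low,
    hr_ci_high = hr$ci_high, hr_p = hr$p,
    pearson_r_bioage_age = stats::cor(scores$bioage, scores$age),
    best_cutpoint = attr(scan, "best_cutpoint"),
    best_cutpoint_statistic = attr(scan, "best_statistic"),
    auc_agedev = roc$auc, auc_out_of_range = roc$alt_auc,
    n_test_animals = length(ids$test), n_test_events = sum(test_rows$event)
  )
  jsonlite::write_json(evaluation, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config_hash = cfg_hash, seed = seed,
         files = c("animals.csv", "panel.csv", "processed_panel.csv",
                   "screen.csv", "selection.json", "clock.json",
                   "scores.csv", "evaluation.json")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(cohort = cohort, processed = processed, split = ids,
                 screen = screen, selection = selection, clock = clock,
                 scores = scores, evaluation = evaluation))
}
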