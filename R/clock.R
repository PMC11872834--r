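#' Train a biological age clock
#'
#' Fits the pair of Gompertz proportional-hazards models that define the
#' clock on the same counting-process rows: the "full" model with the
#' selected markers plus demographic covariates, and the "reference" model
#' with demographic covariates only. Biological age is then the age at which
#' the reference model's survival probability equals the full model's at the
#' animal's chronological age (see [biological_age()]).
#'
#' Markers must already be on the modelling scale (natural-log where flagged,
#' native units otherwise — see [preprocess_panel()]); coefficients are per
#' native (or ln) unit, not per SD.
#'
#' @param rows Counting-process tibble from [to_counting_process()].
#' @param markers Marker columns entering the full model.
#' @param covariates Demographic covariates shared by both models (default
#'   `breed_size` + `sex`; use `"sex"` only, or none, for other species).
#' @param provenance Optional list stored with the model (seed, config hash,
#'   training ids, ...).
#' @return An object of class `phenoclock` with elements `full`, `ref`,
#'   `markers`, `covariates`, `provenance`.
#' @export
train_clock <- function(rows, markers, covariates = c("breed_size", "sex"),
                        provenance = list()) {
  if (length(markers) == 0) abort("marker set is empty")
  assert_cols(rows, markers, "counting-process rows")
  full <- fit_gompertz_ph(rows, c(markers, covariates))
  ref <- fit_gompertz_ph(rows, covariates)
  structure(
    list(
      full = full, ref = ref, markers = markers, covariates = covariates,
      provenance = c(provenance, list(
        n_animals = full$n_animals, n_rows = full$n_rows,
        n_events = full$n_events
      ))
    ),
    class = "phenoclock"
  )
}

#' @export
print.phenoclock <- function(x, ...) {
  cat(sprintf(
    "phenoclock: %d-marker Gompertz clock (gamma = %.4f, gamma_ref = %.4f)\n",
    length(x$markers), x$full$gamma, x$ref$gamma
  ))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' Full-model linear predictor
#'
#' `xb = beta0 + sum(coef * value) + beta_breed * [medium_large] +
#' beta_sex * [male]` for the clock's full model. Marker values must be on
#' the modelling scale.
#'
#' @param clock A [train_clock()] object (or a bare `gompertz_ph` full
#'   model).
#' @param data Data frame with the model's marker columns plus `breed_size`
#'   and `sex`.
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(clock, data) {
  model <- if (inherits(clock, "phenoclock")) clock$full else clock
  missing <- setdiff(model$covariates, names(data))
  if (length(missing) > 0) {
    abort(sprintf("data is missing model covariate(s): %s",
                  paste(missing, collapse = ", ")))
  }
  gompertz_lp(model, data)
}

#' Biological age from the closed-form survival identity
#'
#' Solves `S_ref(BioAge) = S_full(age)` for BioAge: the age at which a
#' reference animal of the same breed size and sex reaches the survival
#' probability the full marker model assigns at the subject's chronological
#' age. With `gamma0` the reference shape and `ref_lp` the reference linear
#' predictor,
#' \deqn{BioAge = \log(1 + \gamma_0 e^{xb} (e^{\gamma \cdot age} - 1) /
#'   (\gamma e^{ref\_lp})) / \gamma_0}
#' evaluated in log space so extreme linear predictors cannot overflow. When
#' the full model degenerates to the reference model the identity gives
#' `BioAge = age` exactly.
#'
#' @param clock A `phenoclock` object.
#' @param data Data frame with marker columns (modelling scale), `age`,
#'   `breed_size`, `sex`.
#' @return Numeric vector of biological ages, years.
#' @export
biological_age <- function(clock, data) {
  stopifnot(inherits(clock, "phenoclock"))
  assert_cols(data, "age", "scoring data")
  if (any(data$age <= 0)) abort("age must be positive")
  xb <- linear_predictor(clock, data)
  ref <- clock$ref
  ref_lp <- gompertz_lp(ref, data)
  gam <- clock$full$gamma
  gam0 <- ref$gamma
  log_a <- log(gam0) + xb + log(expm1(gam * data$age)) - ref_lp - log(gam)
  log1p_exp(log_a) / gam0
}

#' Age deviation
#'
#' `AgeDev = biological age - chronological age`; positive values indicate
#' accelerated aging.
#'
#' @param bioage Biological age, years.
#' @param age Chronological age, years.
#' @return Numeric vector of deviations, years.
#' @export
age_dev <- function(bioage, age) bioage - age

#' Score a cohort with a fitted clock
#'
#' Computes biological age and AgeDev for every measurement row.
#'
#' @param panel Wide measurement tibble on the modelling scale (i.e. after
#'   [preprocess_panel()] or equivalent), with `animal_id`, `age_at_draw` and
#'   the clock's marker columns.
#' @param animals Animal metadata tibble supplying `breed_size` and `sex`.
#' @param clock A `phenoclock` object.
#' @return Tibble with `animal_id`, `age`, `breed_size`, `sex`, `bioage`,
#'   `agedev`.
#' @export
score_cohort <- function(panel, animals, clock) {
  assert_cols(panel, c("animal_id", "age_at_draw", clock$markers), "panel")
  data <- panel |>
    inner_join(animals |> select(all_of(c("animal_id", "breed_size", "sex"))),
               by = "animal_id") |>
    rename(age = "age_at_draw")
  data |>
    mutate(
      bioage = biological_age(clock, data),
      agedev = age_dev(.data$bioage, .data$age)
    ) |>
    select(all_of(c("animal_id", "age", "breed_size", "sex",
                    "bioage", "agedev")))
}

#' Retrain the clock on a marker subset
#'
#' Refits the full model using only `marker_subset` (the reference model is
#' structurally unchanged and refitted on the same rows), as when a
#' retrospective dataset lacks some of the clock's analytes.
#'
#' @param rows Counting-process training rows.
#' @param clock The original `phenoclock`.
#' @param marker_subset Non-empty subset of `clock$markers`.
#' @return A new `phenoclock` tagged with its subset.
#' @export
refit_subset <- function(rows, clock, marker_subset) {
  if (length(marker_subset) == 0) abort("marker subset is empty")
  extra <- setdiff(marker_subset, clock$markers)
  if (length(extra) > 0) {
    abort(sprintf("subset contains marker(s) not in the clock: %s",
                  paste(extra, collapse = ", ")))
  }
  train_clock(rows, marker_subset, clock$covariates,
              provenance = list(subset_of = clock$markers))
}
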