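# Evaluation of AgeDev as a mortality predictor.

#' Counting-process rows carrying AgeDev as the covariate
#'
#' Convenience bridge from a score table ([score_cohort()]) to the
#' counting-process format: each scored visit starts a risk interval whose
#' `agedev` covariate is the score at the interval start.
#'
#' @param scores Tibble with `animal_id`, `age`, `agedev`.
#' @param animals Animal metadata tibble.
#' @return Counting-process tibble with an `agedev` column.
#' @export
agedev_rows <- function(scores, animals) {
  panel <- scores |>
    select(all_of(c("animal_id", "age", "agedev"))) |>
    rename(age_at_draw = "age")
  to_counting_process(animals, panel)
}

#' Cox model of mortality on AgeDev
#'
#' Hazard ratio per one-year increase in AgeDev, with AgeDev as a
#' time-dependent covariate on the age time axis, adjusted for breed size and
#' sex.
#'
#' @param rows Counting-process tibble with an `agedev` column (see
#'   [agedev_rows()]).
#' @param covariates Adjustment covariates.
#' @return One-row tibble: `hr_per_year`, `ci_low`, `ci_high`, `p`,
#'   `n_rows`, `n_events`.
#' @export
cox_agedev <- function(rows, covariates = c("breed_size", "sex")) {
  if (sum(rows$event) == 0) abort("no events")
  if (sd(rows$agedev) == 0) abort("AgeDev is constant; hazard ratio undefined")
  res <- fit_marker_cox(rows, "agedev", covariates)
  res |>
    select(-all_of(c("marker", "covariates_used"))) |>
    rename(hr_per_year = "hr_per_sd", p = "p_raw")
}

#' Quintile hazard ratios of AgeDev
#'
#' Cuts AgeDev observations (one blood draw = one observation) into quintiles
#' by empirical quantiles and fits a Cox model with the quintile as a 5-level
#' factor, first quintile as reference.
#'
#' @param rows Counting-process tibble with `agedev`.
#' @param covariates Adjustment covariates.
#' @return Tibble with one row per quintile 2-5: `quintile`, `range_low`,
#'   `range_high`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
quintile_hr <- function(rows, covariates = c("breed_size", "sex")) {
  if (length(unique(rows$agedev)) < 5) {
    abort("fewer than 5 distinct AgeDev values")
  }
  breaks <- quantile(rows$agedev, probs = 0:5 / 5, type = 7, names = FALSE)
  if (anyDuplicated(breaks)) {
    abort("ties collapse a quintile; use fewer bins")
  }
  q <- cut(rows$agedev, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  dat <- tibble(
    tstart = rows$tstart, tstop = rows$tstop, event = rows$event,
    q = factor(q, levels = 1:5)
  )
  rhs <- "q"
  if ("sex" %in% covariates) {
    dat$sex_male <- encode_sex(rows$sex)
    rhs <- c(rhs, "sex_male")
  }
  if ("breed_size" %in% covariates) {
    dat$breed_ml <- encode_breed(rows$breed_size)
    rhs <- c(rhs, "breed_ml")
  }
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(tstart, tstop, event) ~",
                            paste(rhs, collapse = " + "))),
    data = dat, ties = "efron"
  )
  idx <- grep("^q", names(coef(fit)))
  est <- coef(fit)[idx]
  se <- sqrt(diag(fit$var))[idx]
  z <- qnorm(0.975)
  tibble(
    quintile = 2:5,
    range_low = breaks[2:5],
    range_high = breaks[3:6],
    hr = exp(est),
    ci_low = exp(est - z * se),
    ci_high = exp(est + z * se),
    p = 2 * pnorm(-abs(est / se))
  )
}

# standardized log-rank statistic for a binary split, via the Cox score test
# with Breslow ties (equal to the two-group log-rank statistic); signed by
# the direction of the high-group effect
logrank_z <- function(tstart, tstop, event, high) {
  dat <- tibble(tstart = tstart, tstop = tstop, event = event,
                g = as.numeric(high))
  fit <- survival::coxph(
    survival::Surv(tstart, tstop, event) ~ g,
    data = dat, ties = "breslow", control = survival::coxph.control(iter.max = 50)
  )
  z <- sqrt(fit$score) * sign(coef(fit)[["g"]])
  list(z = z, hr = exp(coef(fit)[["g"]]))
}

#' Log-rank cutpoint scan over AgeDev
#'
#' The maximally selected log-rank approach of Contal and O'Quigley: each
#' candidate cutpoint dichotomizes AgeDev (low vs high at the interval
#' start), the standardized log-rank statistic is computed for the split, and
#' the best cutpoint maximizes the absolute standardized statistic. The
#' default candidate grid is the unique observed AgeDev values between the
#' 10th and 90th percentiles.
#'
#' @param rows Counting-process tibble with `agedev`.
#' @param candidates Optional numeric candidate cutpoints; values outside the
#'   observed AgeDev range are skipped with a warning.
#' @return Object of class `cutpoint_scan`: tibble `cutpoint`, `statistic`
#'   (signed standardized log-rank), `hr_high_vs_low`, with attributes
#'   `best_cutpoint` and `best_statistic`.
#' @export
cutpoint_scan <- function(rows, candidates = NULL) {
  if (sum(rows$event) < 20) {
    warn(sprintf("only %d events; cutpoint scan may be unstable", sum(rows$event)))
  }
  rng <- range(rows$agedev)
  if (is.null(candidates)) {
    qs <- quantile(rows$agedev, c(0.1, 0.9), type = 7, names = FALSE)
    candidates <- sort(unique(rows$agedev[rows$agedev >= qs[1] &
                                            rows$agedev <= qs[2]]))
  } else {
    outside <- candidates <= rng[1] | candidates >= rng[2]
    if (any(outside)) {
      warn(sprintf("skipped %d candidate(s) outside the AgeDev range",
                   sum(outside)))
      candidates <- candidates[!outside]
    }
    candidates <- sort(unique(candidates))
  }
  stopifnot(length(candidates) >= 1)
  res <- map(candidates, function(cpt) {
    high <- rows$agedev > cpt
    if (all(high) || all(!high)) {
      return(tibble(cutpoint = cpt, statistic = NA_real_,
                    hr_high_vs_low = NA_real_))
    }
    lr <- tryCatch(
      logrank_z(rows$tstart, rows$tstop, rows$event, high),
      error = function(e) list(z = NA_real_, hr = NA_real_)
    )
    tibble(cutpoint = cpt, statistic = lr$z, hr_high_vs_low = lr$hr)
  }) |> list_rbind()
  best <- which.max(abs(res$statistic))
  attr(res, "best_cutpoint") <- res$cutpoint[best]
  attr(res, "best_statistic") <- res$statistic[best]
  class(res) <- c("cutpoint_scan", class(res))
  res
}

#' Incident/dynamic time-dependent ROC for survival prediction
#'
#' Evaluates how well a score measured after `entry_age` discriminates
#' mortality up to `horizon_age` (default: survival to age 10 from scores
#' after age 5). At each event age t, cases are the animals failing at t and
#' controls the remaining risk set; AUC(t) is the case/control concordance of
#' the score, and the summary AUC is the pair-count-weighted mean over event
#' ages in the window. Following the Cox formulation, the score entering the
#' ROC is the fitted Cox linear predictor of `score_col` (falling back to the
#' raw score when the fit is degenerate, e.g. a constant score).
#'
#' @param rows Counting-process tibble containing `score_col`.
#' @param score_col Name of the score column (default `"agedev"`).
#' @param entry_age Scores before this age are clipped out of the window.
#' @param horizon_age Events after this age are censored at it.
#' @param alt_score_col Optional second score for comparison (e.g. the number
#'   of out-of-range markers); both AUCs are reported.
#' @return Object of class `roc_result`: list with `auc`, `auc_by_time`
#'   (tibble `time`, `auc`, `n_cases`, `n_controls`), `alt_auc` (or NULL),
#'   `entry_age`, `horizon_age`, `n_events`.
#' @export
incident_dynamic_roc <- function(rows, score_col = "agedev", entry_age = 5,
                                 horizon_age = 10, alt_score_col = NULL) {
  assert_cols(rows, c("tstart", "tstop", "event", score_col), "rows")
  win <- rows |>
    mutate(
      tstart = pmax(.data$tstart, entry_age),
      event = if_else(.data$tstop > horizon_age, 0L, as.integer(.data$event)),
      tstop = pmin(.data$tstop, horizon_age)
    ) |>
    filter(.data$tstart < .data$tstop)
  if (sum(win$event) == 0) abort("no events inside the evaluation window")

  cox_lp <- function(col) {
    v <- win[[col]]
    if (sd(v) == 0) return(v)
    fit <- tryCatch(
      survival::coxph(survival::Surv(tstart, tstop, event) ~ x,
                      data = tibble(tstart = win$tstart, tstop = win$tstop,
                                    event = win$event, x = v)),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit) || !is.finite(coef(fit)[[1]])) v else coef(fit)[[1]] * v
  }

  auc_for <- function(score) {
    event_times <- sort(unique(win$tstop[win$event == 1]))
    per_t <- map(event_times, function(t) {
      at_risk <- win$tstart < t & win$tstop >= t
      case <- at_risk & win$event == 1 & win$tstop == t
      ctrl <- at_risk & !case
      if (!any(case) || !any(ctrl)) return(NULL)
      sc <- score[case]
      sct <- score[ctrl]
      wins <- sum(outer(sc, sct, ">")) + 0.5 * sum(outer(sc, sct, "=="))
      tibble(time = t, auc = wins / (length(sc) * length(sct)),
             n_cases = length(sc), n_controls = length(sct))
    }) |> list_rbind()
    w <- per_t$n_cases * per_t$n_controls
    list(summary = sum(per_t$auc * w) / sum(w), by_time = per_t)
  }

  main <- auc_for(cox_lp(score_col))
  alt <- if (!is.null(alt_score_col)) auc_for(cox_lp(alt_score_col)) else NULL
  structure(
    list(
      auc = main$summary, auc_by_time = main$by_time,
      alt_auc = if (!is.null(alt)) alt$summary else NULL,
      score_col = score_col, alt_score_col = alt_score_col,
      entry_age = entry_age, horizon_age = horizon_age,
      n_events = sum(win$event)
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "Incident/dynamic ROC on (%g, %g]: AUC = %.3f over %d events\n",
    x$entry_age, x$horizon_age, x$auc, x$n_events
  ))
  if (!is.null(x$alt_auc)) {
    cat(sprintf("  comparison score '%s': AUC = %.3f\n", x$alt_score_col,
                x$alt_auc))
  }
  invisible(x)
}

#' Count markers outside their clinical reference range
#'
#' Per measurement row, counts markers strictly outside
#' `[reference_low, reference_high]` on the raw (untransformed) scale; values
#' exactly on a bound count as in range.
#'
#' @param panel Wide measurement tibble in raw units.
#' @param specs Marker-specification tibble with reference bounds.
#' @param markers Markers to count (default: all specs markers present).
#' @return Integer vector, one count per panel row.
#' @export
count_out_of_range <- function(panel, specs, markers = NULL) {
  markers <- markers %||% intersect(specs$marker, names(panel))
  no_range <- markers[!markers %in%
                        specs$marker[!is.na(specs$reference_low) &
                                       !is.na(specs$reference_high)]]
  if (length(no_range) > 0) {
    abort(sprintf("no reference range configured for marker(s): %s",
                  paste(no_range, collapse = ", ")))
  }
  out <- rep(0L, nrow(panel))
  for (m in markers) {
    sp <- specs[specs$marker == m, ]
    v <- panel[[m]]
    out <- out + as.integer(!is.na(v) &
                              (v < sp$reference_low | v > sp$reference_high))
  }
  out
}

#' AgeDev distribution by out-of-range stratum
#'
#' @param scores Score tibble ([score_cohort()]).
#' @param counts Integer out-of-range counts matched to `scores` rows.
#' @param cap Counts at or above `cap` are pooled into one stratum.
#' @return Tibble `n_out_of_range`, `n_obs`, `median`, `q1`, `q3`.
#' @export
agedev_by_range_strata <- function(scores, counts, cap = 4) {
  stopifnot(length(counts) == nrow(scores))
  scores |>
    mutate(stratum = pmin(counts, cap)) |>
    group_by(.data$stratum) |>
    summarise(
      n_obs = n(),
      median = median(.data$agedev),
      q1 = quantile(.data$agedev, 0.25, type = 7, names = FALSE),
      q3 = quantile(.data$agedev, 0.75, type = 7, names = FALSE),
      .groups = "drop"
    ) |>
    rename(n_out_of_range = "stratum")
}

#' Out-of-range composition of AgeDev quintiles
#'
#' For each observation-level AgeDev quintile, tallies how many measurements
#' have 0, 1, 2, ... markers outside their reference range.
#'
#' @param scores Score tibble; rows matched 1:1 with `panel`.
#' @param panel Raw-unit measurement tibble aligned with `scores`.
#' @param specs Marker-specification tibble.
#' @param markers Markers to count (default: all configured).
#' @param cap Counts pooled at this value.
#' @return Tibble `quintile`, `n_out_of_range`, `n_obs`, `proportion`.
#' @export
quintile_range_profile <- function(scores, panel, specs, markers = NULL,
                                   cap = 4) {
  stopifnot(nrow(scores) == nrow(panel))
  counts <- count_out_of_range(panel, specs, markers)
  breaks <- quantile(scores$agedev, probs = 0:5 / 5, type = 7, names = FALSE)
  q <- cut(scores$agedev, breaks = breaks, include.lowest = TRUE,
           labels = FALSE)
  tibble(quintile = q, n_out_of_range = pmin(counts, cap)) |>
    count(.data$quintile, .data$n_out_of_range, name = "n_obs") |>
    group_by(.data$quintile) |>
    mutate(proportion = .data$n_obs / sum(.data$n_obs)) |>
    ungroup()
}

#' Compare AgeDev trajectories between diet groups
#'
#' The calorie-restriction readout: per-arm AgeDev-versus-age curves smoothed
#' by local regression (loess, fixed span), a test for a group difference in
#' AgeDev after the onset age that is robust to repeated measures (animals
#' are collapsed to their post-onset mean before a Welch t-test), and a Cox
#' model with time-dependent AgeDev plus diet to ask whether AgeDev predicts
#' mortality independently of diet.
#'
#' @param scores Score tibble with an added `diet` column
#'   (`control`/`restricted`).
#' @param animals Animal metadata.
#' @param onset_age Age after which the intervention effect is evaluated.
#' @param span loess span for the trajectory curves.
#' @return Object of class `diet_comparison`: `trajectories` (tibble `diet`,
#'   `age`, `agedev_smooth`), `post_onset` (tibble with per-arm means, the
#'   difference restricted - control, t statistic, p value), `cox` (tibble
#'   with rows for `agedev` and `dietrestricted`).
#' @export
compare_diet_groups <- function(scores, animals, onset_age = 7, span = 0.75) {
  assert_cols(scores, c("animal_id", "age", "agedev", "diet"), "scores")
  arms <- sort(unique(scores$diet))
  if (length(arms) < 2) abort("need both diet arms")

  trajectories <- scores |>
    group_by(.data$diet) |>
    dplyr::group_map(function(df, key) {
      grid <- seq(min(df$age), max(df$age), length.out = 80)
      fit <- loess(agedev ~ age, data = df, span = span, degree = 2)
      tibble(diet = key$diet, age = grid,
             agedev_smooth = predict(fit, newdata = tibble(age = grid)))
    }) |> list_rbind()

  post <- scores |>
    filter(.data$age > onset_age) |>
    group_by(.data$animal_id, .data$diet) |>
    summarise(agedev = mean(.data$agedev), .groups = "drop")
  if (length(unique(post$diet)) < 2) {
    abort("no post-onset observations in one of the arms")
  }
  tt <- t.test(agedev ~ diet, data = post)
  means <- post |>
    group_by(.data$diet) |>
    summarise(mean_agedev = mean(.data$agedev), n_animals = n(),
              .groups = "drop")
  post_onset <- tibble(
    onset_age = onset_age,
    mean_control = means$mean_agedev[means$diet == "control"],
    mean_restricted = means$mean_agedev[means$diet == "restricted"],
    difference = mean_restricted - mean_control,
    statistic = unname(tt$statistic),
    p = tt$p.value
  )

  rows <- agedev_rows(scores, animals) |>
    left_join(distinct(scores, .data$animal_id, .data$diet), by = "animal_id")
  fit <- survival::coxph(
    survival::Surv(tstart, tstop, event) ~ agedev + diet,
    data = rows, ties = "efron"
  )
  est <- coef(fit)
  se <- sqrt(diag(fit$var))
  z <- qnorm(0.975)
  cox <- tibble(
    term = names(est),
    hr = exp(est),
    ci_low = exp(est - z * se),
    ci_high = exp(est + z * se),
    p = 2 * pnorm(-abs(est / se))
  )
  structure(
    list(trajectories = trajectories, post_onset = post_onset, cox = cox,
         onset_age = onset_age),
    class = "diet_comparison"
  )
}

#' @export
print.diet_comparison <- function(x, ...) {
  cat(sprintf(
    "Diet comparison: restricted - control AgeDev after age %g = %+.3f y (p = %.3g)\n",
    x$onset_age, x$post_onset$difference, x$post_onset$p
  ))
  print(x$cox)
  invisible(x)
}
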