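#' Per-marker Cox association with all-cause mortality
#'
#' Fits a Cox proportional-hazards model for one marker on counting-process
#' rows, with age as the time axis (left truncation at the first draw) and
#' the marker as a time-dependent covariate, adjusted for the requested
#' demographic covariates. With the marker standardized to SD 1 (see
#' [apply_scaling()]) the hazard ratio reads per +1 SD. Ties use the Efron
#' approximation.
#'
#' @param rows Counting-process tibble.
#' @param marker Marker column name.
#' @param covariates Adjustment covariates; the species-specific defaults are
#'   dogs `c("sex", "breed_size")`, cats `character(0)`, humans `"sex"`.
#' @return One-row tibble: `marker`, `hr_per_sd`, `ci_low`, `ci_high`,
#'   `p_raw`, `n_rows`, `n_events`, `covariates_used`.
#' @export
fit_marker_cox <- function(rows, marker, covariates = c("sex", "breed_size")) {
  assert_cols(rows, c("tstart", "tstop", "event", marker), "rows")
  if (sum(rows$event) == 0) abort("no events")
  dat <- tibble(
    tstart = rows$tstart, tstop = rows$tstop, event = rows$event,
    x = rows[[marker]]
  )
  rhs <- "x"
  if ("sex" %in% covariates) {
    dat$sex_male <- encode_sex(rows$sex)
    rhs <- c(rhs, "sex_male")
  }
  if ("breed_size" %in% covariates) {
    dat$breed_ml <- encode_breed(rows$breed_size)
    rhs <- c(rhs, "breed_ml")
  }
  fml <- stats::as.formula(
    paste("survival::Surv(tstart, tstop, event) ~", paste(rhs, collapse = " + "))
  )
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  est <- coef(fit)[["x"]]
  se <- sqrt(diag(fit$var))[1]
  if (!is.finite(est) || !is.finite(se)) {
    abort(sprintf("marker '%s' fit did not produce finite estimates", marker))
  }
  z <- qnorm(0.975)
  tibble(
    marker = marker,
    hr_per_sd = exp(est),
    ci_low = exp(est - z * se),
    ci_high = exp(est + z * se),
    p_raw = 2 * pnorm(-abs(est / se)),
    n_rows = nrow(rows),
    n_events = sum(rows$event),
    covariates_used = paste(covariates, collapse = ",")
  )
}

#' Screen a marker panel against mortality
#'
#' Runs [fit_marker_cox()] for every marker and applies Benjamini-Hochberg
#' step-up adjustment across the set. A marker whose fit fails is kept as a
#' flagged row (`failed = TRUE`, statistics `NA`) and excluded from the BH
#' family; results are sorted by marker name for determinism.
#'
#' @param rows Counting-process tibble with markers standardized to SD 1.
#' @param markers Character vector (length >= 2) of marker columns.
#' @param covariates Adjustment covariates (see [fit_marker_cox()]).
#' @return Tibble of class `hazard_screen`: one row per marker with `p_adj`
#'   and `failed` added.
#' @export
screen_markers <- function(rows, markers, covariates = c("sex", "breed_size")) {
  stopifnot(length(markers) >= 1)
  fits <- map(markers, function(m) {
    tryCatch(
      fit_marker_cox(rows, m, covariates) |> mutate(failed = FALSE),
      error = function(e) {
        warn(sprintf("marker '%s' screen failed: %s", m, conditionMessage(e)))
        tibble(
          marker = m, hr_per_sd = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, p_raw = NA_real_, n_rows = nrow(rows),
          n_events = sum(rows$event),
          covariates_used = paste(covariates, collapse = ","), failed = TRUE
        )
      }
    )
  }) |> list_rbind()
  ok <- !fits$failed
  fits$p_adj <- NA_real_
  fits$p_adj[ok] <- p.adjust(fits$p_raw[ok], method = "BH")
  out <- fits |>
    arrange(.data$marker) |>
    relocate("p_adj", .after = "p_raw")
  class(out) <- c("hazard_screen", class(out))
  out
}

#' Cluster a species-by-marker hazard-ratio matrix
#'
#' Hierarchically clusters rows (species) and columns (markers) of a log
#' hazard-ratio matrix by Euclidean distance, first dropping any marker with
#' a missing value in any species ("excluding incomplete observations").
#' Log hazard ratios are used because Euclidean distance on raw ratios is
#' scale-asymmetric around 1. Linkage is complete.
#'
#' @param log_hr_matrix Numeric matrix, rows = species, columns = markers,
#'   entries = log hazard ratios per SD.
#' @return List with `row_order`, `col_order` (leaf orders), `row_hclust`,
#'   `col_hclust`, `markers_used`, `linkage`.
#' @export
cluster_hazard_matrix <- function(log_hr_matrix) {
  stopifnot(is.matrix(log_hr_matrix), nrow(log_hr_matrix) >= 2)
  complete <- colSums(is.na(log_hr_matrix)) == 0
  m <- log_hr_matrix[, complete, drop = FALSE]
  if (ncol(m) < 2) abort("fewer than 2 complete marker columns")
  hc_rows <- hclust(dist(m, method = "euclidean"), method = "complete")
  hc_cols <- hclust(dist(t(m), method = "euclidean"), method = "complete")
  list(
    row_order = hc_rows$order,
    col_order = hc_cols$order,
    row_hclust = hc_rows,
    col_hclust = hc_cols,
    markers_used = colnames(m),
    linkage = "complete"
  )
}
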