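#' Apply natural-log transforms to flagged markers
#'
#' Right-skewed analytes flagged with `log_transform` in the marker
#' specification are replaced by their natural logarithm; other markers pass
#' through unchanged. A nonpositive value on a log-flagged marker makes the
#' whole measurement row unusable and it is excluded with a warning rather
#' than propagated as NaN.
#'
#' @param panel Wide measurement tibble.
#' @param specs Marker-specification tibble (see [read_marker_specs()]).
#' @return The panel with log-flagged columns transformed.
#' @export
apply_log_transforms <- function(panel, specs) {
  log_markers <- intersect(specs$marker[specs$log_transform], names(panel))
  if (length(log_markers) == 0) return(panel)
  nonpos <- rowSums(
    as.matrix(panel[log_markers]) <= 0, na.rm = TRUE
  ) > 0
  if (any(nonpos)) {
    warn(sprintf(
      "excluded %d row(s) with nonpositive values on log-transformed marker(s)",
      sum(nonpos)
    ))
    panel <- panel[!nonpos, ]
  }
  panel |> mutate(across(all_of(log_markers), log))
}

#' Trim extreme marker values by empirical percentiles
#'
#' Removes measurement rows in which any marker falls strictly below its
#' `p_lo`-th or strictly above its `p_hi`-th empirical percentile, the guard
#' against acute conditions and measurement errors. Percentiles use linear
#' interpolation between order statistics (quantile type 7) and are computed
#' per marker over the non-missing values; a flagged cell removes the entire
#' row so that surviving panels stay complete.
#'
#' @param panel Wide measurement tibble.
#' @param markers Character vector of marker columns to trim (default: all
#'   columns except `animal_id`/`age_at_draw`).
#' @param p_lo,p_hi Percentile bounds (defaults 1 and 99).
#' @return The trimmed panel, with attribute `n_trimmed` recording the count.
#' @export
trim_percentiles <- function(panel, markers = NULL, p_lo = 1, p_hi = 99) {
  markers <- markers %||% setdiff(names(panel), c("animal_id", "age_at_draw"))
  stopifnot(p_lo >= 0, p_hi <= 100, p_lo < p_hi)
  flag <- rep(FALSE, nrow(panel))
  for (m in markers) {
    v <- panel[[m]]
    n_obs <- sum(!is.na(v))
    if (n_obs == 0) next
    if (n_obs < 100) {
      warn(sprintf("marker '%s' has only %d observations for percentile trimming",
                   m, n_obs))
    }
    q <- quantile(v, probs = c(p_lo, p_hi) / 100, na.rm = TRUE,
                  type = 7, names = FALSE)
    flag <- flag | (!is.na(v) & (v < q[1] | v > q[2]))
  }
  if (any(flag)) {
    inform(sprintf("percentile trim removed %d of %d rows", sum(flag), nrow(panel)))
  }
  out <- panel[!flag, ]
  attr(out, "n_trimmed") <- sum(flag)
  out
}

#' Keep only measurement rows with a complete panel
#'
#' @param panel Wide measurement tibble.
#' @param required_markers Markers that must be non-missing for a row to
#'   survive.
#' @return The filtered panel.
#' @export
filter_complete <- function(panel, required_markers) {
  stopifnot(length(required_markers) > 0)
  assert_cols(panel, required_markers, "panel")
  keep_row <- complete.cases(panel[required_markers])
  if (any(!keep_row)) {
    inform(sprintf("completeness filter removed %d of %d rows",
                   sum(!keep_row), nrow(panel)))
  }
  panel[keep_row, ]
}

#' Fit per-marker centring/scaling parameters
#'
#' Estimates each marker's mean and standard deviation (unbiased, n-1
#' denominator) on a reference set, typically the training data. Scaled
#' markers are only used for the univariate per-SD hazard screen; clock
#' training stays on native (log-transformed where flagged) units.
#'
#' @param panel Wide measurement tibble (already log-transformed as needed).
#' @param markers Marker columns to scale (default: all non-id columns).
#' @return A tibble with columns `marker`, `mean`, `sd` (class
#'   `scaling_params`).
#' @export
fit_scaling <- function(panel, markers = NULL) {
  markers <- markers %||% setdiff(names(panel), c("animal_id", "age_at_draw"))
  params <- tibble(
    marker = markers,
    mean = map_dbl(markers, ~ mean(panel[[.x]], na.rm = TRUE)),
    sd = map_dbl(markers, ~ sd(panel[[.x]], na.rm = TRUE))
  )
  degenerate <- params$marker[is.na(params$sd) | params$sd == 0]
  if (length(degenerate) > 0) {
    abort(sprintf("zero-variance marker(s): %s",
                  paste(degenerate, collapse = ", ")))
  }
  class(params) <- c("scaling_params", class(params))
  params
}

#' Apply stored centring/scaling parameters
#'
#' Centres and scales markers using parameters from [fit_scaling()]; applying
#' stored parameters to new data never re-fits, so train-set scaling carries
#' to test data unchanged.
#'
#' @param panel Wide measurement tibble.
#' @param params Result of [fit_scaling()].
#' @return The panel with listed markers standardized.
#' @export
apply_scaling <- function(panel, params) {
  markers <- intersect(params$marker, names(panel))
  for (m in markers) {
    p <- params[params$marker == m, ]
    panel[[m]] <- (panel[[m]] - p$mean) / p$sd
  }
  panel
}

#' Run the full preprocessing pipeline
#'
#' Fixed curation order: log-transform flagged markers, trim the 1st/99th
#' percentile tails, keep complete panels. Scaling is separate (see
#' [fit_scaling()]) because only the univariate screen uses standardized
#' values.
#'
#' @param panel Wide measurement tibble in raw units.
#' @param specs Marker-specification tibble.
#' @param p_lo,p_hi Trim percentiles.
#' @return The curated panel on the transformed scale.
#' @export
preprocess_panel <- function(panel, specs, p_lo = 1, p_hi = 99) {
  markers <- intersect(specs$marker, names(panel))
  panel |>
    apply_log_transforms(specs) |>
    trim_percentiles(markers = markers, p_lo = p_lo, p_hi = p_hi) |>
    filter_complete(required_markers = markers)
}
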