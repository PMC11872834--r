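#' Read a marker configuration file
#'
#' Parses a YAML marker configuration into a marker-specification tibble. Each
#' top-level key is a marker name mapping to `units`, `log_transform`,
#' `reference_low` and `reference_high`. `log_transform` flags right-skewed
#' analytes that are modelled on the natural-log scale; reference bounds are
#' the clinically defined normal interval on the raw measurement scale.
#'
#' @param path Path to a YAML marker configuration.
#' @return A tibble with columns `marker`, `units`, `log_transform`,
#'   `reference_low`, `reference_high`.
#' @export
#' @examples
#' specs <- read_marker_specs(
#'   system.file("extdata", "dog_markers.yaml", package = "phenoclock")
#' )
#' specs
read_marker_specs <- function(path) {
  if (!file.exists(path)) abort(sprintf("marker config not found: %s", path))
  raw <- yaml::read_yaml(path)
  specs <- imap(raw, function(m, nm) {
    tibble(
      marker = nm,
      units = as.character(m$units %||% ""),
      log_transform = isTRUE(m$log_transform),
      reference_low = as.numeric(m$reference_low),
      reference_high = as.numeric(m$reference_high)
    )
  }) |> list_rbind()
  validate_marker_specs(specs)
  specs
}

validate_marker_specs <- function(specs) {
  assert_cols(
    specs,
    c("marker", "log_transform", "reference_low", "reference_high"),
    "marker specification"
  )
  bad <- specs$reference_low >= specs$reference_high
  if (any(bad, na.rm = TRUE)) {
    abort(sprintf(
      "reference_low >= reference_high for marker(s): %s",
      paste(specs$marker[which(bad)], collapse = ", ")
    ))
  }
  invisible(specs)
}

#' Default canine marker panel
#'
#' The bundled 28-analyte CBC + serum chemistry configuration, with editable
#' default reference intervals and natural-log flags on the nine right-skewed
#' analytes (alkaline phosphatase, ALT, AST, creatine kinase, bilirubin,
#' creatinine, GGT, triglycerides, urea nitrogen).
#'
#' @return A marker-specification tibble (see [read_marker_specs()]).
#' @export
default_marker_specs <- function() {
  read_marker_specs(
    system.file("extdata", "dog_markers.yaml", package = "phenoclock")
  )
}

#' Published canine clock coefficients
#'
#' Per-native-unit Gompertz log-hazard coefficients of the ten analytes
#' retained in the published canine biological age clock. Coefficients for
#' creatine kinase and alkaline phosphatase apply to ln-transformed values.
#' The published intercept and shape parameters of the full and reference
#' models live in supplementary material and are not reproduced here, so this
#' table alone cannot score biological age: combine it with intercepts/shapes
#' transcribed from the supplement, or retrain on your own cohort with
#' [train_clock()].
#'
#' @return A tibble with columns `marker`, `coefficient`, `scale`
#'   (`"native"` or `"ln"`).
#' @export
dog_clock_coefficients <- function() {
  tibble(
    marker = c(
      "wbc", "hgb", "mcv", "hct", "mch",
      "glucose", "globulin", "creatine_kinase", "albumin", "alp"
    ),
    coefficient = c(
      0.0919, -0.00913, -0.00749, -0.0184, -0.128,
      0.00917, 0.133, 0.333, -0.744, 0.263
    ),
    scale = c(
      "native", "native", "native", "native", "native",
      "native", "native", "ln", "native", "ln"
    )
  )
}
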