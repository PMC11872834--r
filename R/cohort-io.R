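#' Read a longitudinal cohort from delimited files
#'
#' Loads the three tables the pipeline operates on: per-animal metadata, the
#' wide per-visit blood panel, and the marker configuration. Panel rows whose
#' marker cells cannot be parsed as numbers are dropped with a warning; a panel
#' row referencing an animal absent from the animal table is an error.
#'
#' @param animal_path CSV with columns `animal_id`, `species`, `breed`,
#'   `breed_size` (`small`/`medium_large`), `sex` (`male`/`female`), `status`
#'   (0 alive/censored, 1 dead) and `end_age` (years at death, adoption
#'   censoring, or data extraction).
#' @param panel_path CSV with columns `animal_id`, `age_at_draw` and one
#'   column per configured marker (raw units).
#' @param marker_path YAML marker configuration (see [read_marker_specs()]).
#' @return A list with tibbles `animals`, `panel` and `specs`.
#' @export
read_cohort <- function(animal_path, panel_path, marker_path) {
  specs <- read_marker_specs(marker_path)
  animals <- readr::read_csv(animal_path, show_col_types = FALSE) |>
    as_tibble()
  validate_animals(animals)

  panel_raw <- readr::read_csv(
    panel_path,
    col_types = readr::cols(animal_id = readr::col_character(),
                            .default = readr::col_character()),
    show_col_types = FALSE
  )
  assert_cols(panel_raw, c("animal_id", "age_at_draw"), "panel table")
  missing_specs <- setdiff(specs$marker, names(panel_raw))
  if (length(missing_specs) > 0) {
    abort(sprintf(
      "panel table is missing configured marker column(s): %s",
      paste(missing_specs, collapse = ", ")
    ))
  }

  unknown <- setdiff(unique(panel_raw$animal_id), animals$animal_id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "panel references animal id(s) absent from the animal table: %s",
      paste(unknown, collapse = ", ")
    ))
  }

  num_cols <- c("age_at_draw", specs$marker)
  parsed <- panel_raw |>
    mutate(across(all_of(num_cols), ~ suppressWarnings(as.numeric(.x))))
  # a cell that was non-empty text but did not parse marks the row unusable;
  # genuinely empty cells stay NA (missingness handled by filter_complete())
  was_text <- panel_raw |>
    mutate(across(all_of(num_cols),
                  ~ !is.na(.x) & .x != "" &
                    is.na(suppressWarnings(as.numeric(.x)))))
  bad_row <- rowSums(as.matrix(was_text[num_cols])) > 0
  if (any(bad_row)) {
    warn(sprintf("dropped %d panel row(s) with unparseable numeric cells",
                 sum(bad_row)))
  }
  panel <- parsed[!bad_row, c("animal_id", "age_at_draw", specs$marker)]

  list(animals = animals, panel = panel, specs = specs)
}

validate_animals <- function(animals) {
  assert_cols(
    animals,
    c("animal_id", "species", "breed", "breed_size", "sex", "status", "end_age"),
    "animal table"
  )
  if (any(!animals$breed_size %in% BREED_LEVELS)) {
    abort("breed_size must be 'small' or 'medium_large'")
  }
  if (any(!animals$sex %in% SEX_LEVELS)) abort("sex must be 'male' or 'female'")
  if (any(!animals$status %in% c(0, 1))) abort("status must be 0 or 1")
  if (any(animals$end_age <= 0)) abort("end_age must be positive")
  if (anyDuplicated(animals$animal_id)) abort("duplicate animal_id in animal table")
  invisible(animals)
}

#' Write a result table to CSV
#'
#' Plain UTF-8 comma-separated output with a header row. Numeric columns are
#' written with full double precision so that a write/read round trip
#' preserves values to better than 1e-12 relative error.
#'
#' @param x A data frame (counting-process rows, scores, screen results, ...).
#' @param path Output path.
#' @return `x`, invisibly, so the call can sit inside a pipe.
#' @export
write_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(x)
}

#' Read a table written by [write_table()]
#' @param path CSV path.
#' @return A tibble.
#' @export
read_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |> as_tibble()
}
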