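#' Convert longitudinal measurements to counting-process survival records
#'
#' Builds the risk intervals that all survival models in the package consume.
#' For an animal with draws at ages `a1 < a2 < ... < ak` and end-of-follow-up
#' age `T`, the rows are `(a1, a2], ..., (ak, T]`: intervals are open on the
#' left and closed on the right, covariates are the blood values measured at
#' the interval start, and the event indicator sits on the final row only
#' (1 if the animal died at `T`, else 0). The animal therefore enters the risk
#' set at its first draw (left truncation) and its markers act as
#' time-dependent covariates.
#'
#' Duplicate draws at an identical age keep the first occurrence; draws at or
#' after `end_age` are discarded; animals left with no usable draw are
#' excluded. All three situations produce a warning with counts.
#'
#' @param animals Animal metadata tibble (see [read_cohort()]).
#' @param panel Wide measurement tibble with `animal_id`, `age_at_draw` and
#'   marker columns (transformed or raw; passed through unchanged).
#' @return A tibble with `animal_id`, `tstart`, `tstop`, `event`,
#'   `breed_size`, `sex` and the panel's marker columns.
#' @export
#' @examples
#' animals <- tibble::tibble(
#'   animal_id = "d1", species = "dog", breed = "beagle",
#'   breed_size = "small", sex = "female", status = 1, end_age = 4.5
#' )
#' panel <- tibble::tibble(
#'   animal_id = "d1", age_at_draw = c(2, 3), glucose = c(90, 101)
#' )
#' to_counting_process(animals, panel)
to_counting_process <- function(animals, panel) {
  validate_animals(animals)
  assert_cols(panel, c("animal_id", "age_at_draw"), "panel")
  marker_cols <- setdiff(names(panel), c("animal_id", "age_at_draw"))

  joined <- panel |>
    inner_join(
      animals |> select(all_of(c("animal_id", "breed_size", "sex",
                                 "status", "end_age"))),
      by = "animal_id"
    )

  n_dup <- joined |>
    count(.data$animal_id, .data$age_at_draw) |>
    filter(.data$n > 1) |>
    nrow()
  if (n_dup > 0) {
    warn(sprintf(
      "kept first of duplicate draws at %d (animal, age) combination(s)", n_dup
    ))
  }
  joined <- joined |>
    group_by(.data$animal_id, .data$age_at_draw) |>
    dplyr::slice(1) |>
    ungroup()

  late <- joined$age_at_draw >= joined$end_age
  if (any(late)) {
    warn(sprintf("discarded %d draw(s) at or after end_age", sum(late)))
    joined <- joined[!late, ]
  }

  usable_ids <- unique(joined$animal_id)
  dropped_ids <- setdiff(animals$animal_id, usable_ids)
  if (length(dropped_ids) > 0) {
    warn(sprintf("excluded %d animal(s) with no usable draw", length(dropped_ids)))
  }

  rows <- joined |>
    arrange(.data$animal_id, .data$age_at_draw) |>
    group_by(.data$animal_id) |>
    mutate(
      tstart = .data$age_at_draw,
      tstop = dplyr::lead(.data$age_at_draw, default = NA_real_),
      tstop = if_else(is.na(.data$tstop), .data$end_age, .data$tstop),
      event = if_else(row_number() == n(), as.integer(.data$status), 0L)
    ) |>
    ungroup() |>
    select(all_of(c("animal_id", "tstart", "tstop", "event",
                    "breed_size", "sex", marker_cols)))
  stopifnot(all(rows$tstart < rows$tstop))
  rows
}
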