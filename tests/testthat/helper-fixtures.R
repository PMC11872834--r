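# fixture builders shared across test files; everything is generated in code

# three animals / seven draws across the full 28-marker panel, written as the
# CSV + YAML trio read_cohort() expects
write_tiny_cohort <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                              corrupt_cell = FALSE,
                              unknown_animal = FALSE) {
  specs <- default_marker_specs()
  animals <- tibble::tibble(
    animal_id = c("a1", "a2", "a3"),
    species = "dog",
    breed = c("beagle", "labrador_retriever", "beagle"),
    breed_size = c("small", "medium_large", "small"),
    sex = c("female", "male", "male"),
    status = c(1L, 0L, 0L),
    end_age = c(9.3, 7.5, 12.0)
  )
  draws <- tibble::tibble(
    animal_id = c("a1", "a1", "a1", "a2", "a2", "a3", "a3"),
    age_at_draw = c(2.1, 4.0, 6.5, 1.2, 3.3, 5.0, 8.8)
  )
  set.seed(99)
  for (i in seq_len(nrow(specs))) {
    mid <- (specs$reference_low[i] + specs$reference_high[i]) / 2
    spread <- (specs$reference_high[i] - specs$reference_low[i]) / 6
    draws[[specs$marker[i]]] <- round(rnorm(nrow(draws), mid, spread), 4)
  }
  panel_txt <- draws
  if (corrupt_cell) panel_txt$glucose <- as.character(panel_txt$glucose)
  if (corrupt_cell) panel_txt$glucose[2] <- "not-a-number"
  if (unknown_animal) panel_txt$animal_id[5] <- "ghost"

  animal_path <- file.path(dir, "animals.csv")
  panel_path <- file.path(dir, "panel.csv")
  marker_path <- system.file("extdata", "dog_markers.yaml",
                             package = "phenoclock")
  readr::write_csv(animals, animal_path)
  readr::write_csv(panel_txt, panel_path)
  list(animal_path = animal_path, panel_path = panel_path,
       marker_path = marker_path, animals = animals, panel = draws)
}

# minimal two-marker truth for fast simulations
tiny_truth <- function(seed = 1L, coef1 = 0.3, coef2 = -0.5,
                       sd1 = 5 / 3, sd2 = 1, rho = 0.5, gamma = 0.25,
                       beta_breed = 0.4, beta_sex = 0.2,
                       censor_rate = 0.15, visit_interval = 1,
                       max_followup = 15) {
  sim_truth(
    tibble::tibble(
      marker = c("m1", "m2"),
      mean = c(10, 5), sd = c(sd1, sd2), age_slope = 0, rho = rho,
      coef = c(coef1, coef2), log_scale = FALSE
    ),
    gamma = gamma, beta_breed = beta_breed, beta_sex = beta_sex,
    censor_rate = censor_rate, visit_interval = visit_interval,
    max_followup = max_followup, seed = seed
  )
}

# counting-process rows from a tiny simulated cohort (no preprocessing)
sim_rows <- function(n = 300, truth = tiny_truth(), ...) {
  cohort <- simulate_cohort(sim_config(n, truth, ...))
  suppressWarnings(to_counting_process(cohort$animals, cohort$panel))
}

# hand-rolled left-truncated log-rank test over counting-process rows with a
# binary group; returns the signed standardized statistic (no tie correction,
# intended for tie-free fixtures)
oracle_logrank_z <- function(rows, high) {
  times <- sort(unique(rows$tstop[rows$event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- rows$tstart < t & rows$tstop >= t
    d <- sum(rows$event == 1 & rows$tstop == t)
    n <- sum(at_risk)
    n1 <- sum(at_risk & high)
    d1 <- sum(at_risk & high & rows$event == 1 & rows$tstop == t)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e / sqrt(v)
}

# build a clock whose full model is the reference model plus zero marker
# coefficients: the degenerate case in which biological age must equal age
identity_clock <- function(rows, markers) {
  ref <- fit_gompertz_ph(rows, c("breed_size", "sex"))
  full <- ref
  full$coefficients <- c(setNames(rep(0, length(markers)), markers),
                         ref$coefficients)
  full$covariates <- c(markers, "breed_size", "sex")
  full$par <- c(ref$par[1:2],
                setNames(rep(0, length(markers)), markers),
                ref$par[-(1:2)])
  structure(
    list(full = full, ref = ref, markers = markers,
         covariates = c("breed_size", "sex"), provenance = list()),
    class = "phenoclock"
  )
}

# bisection oracle: invert S_ref at the full model's survival probability
oracle_bioage <- function(clock, data_row) {
  xb <- linear_predictor(clock, data_row)
  ref_lp <- phenoclock:::gompertz_lp(clock$ref, data_row)
  gam <- clock$full$gamma
  gam0 <- clock$ref$gamma
  h_full <- exp(xb) * expm1(gam * data_row$age) / gam
  f <- function(b) exp(ref_lp) * expm1(gam0 * b) / gam0 - h_full
  uniroot(f, c(1e-6, 60), tol = 1e-12)$root
}
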