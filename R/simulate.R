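#' Ground-truth parameters for a synthetic cohort
#'
#' Bundles everything the generator needs: the Gompertz event law (shape
#' `gamma`, intercept `beta0`, per-marker log-hazard coefficients, breed-size
#' and sex effects), the marker dynamics (AR(1) around a linear age trend),
#' the exponential adoption-censoring rate, and the visit schedule. Markers
#' flagged `log_scale` are simulated on the natural-log scale — their `mean`,
#' `sd`, `age_slope` and `coef` all refer to ln units — and written to panels
#' as `exp(value)`, so the standard preprocessing log transform recovers
#' exactly the scale the hazard acts on.
#'
#' If `beta0` is `NULL` it is solved so that an animal with average covariates
#' (baseline marker means, half-weight breed/sex) has the requested median
#' lifespan.
#'
#' @param markers Tibble with columns `marker`, `mean`, `sd`, `age_slope`,
#'   `rho` (within-animal lag-1 autocorrelation, in `[0,1)`), `coef`
#'   (per-unit log-hazard), `log_scale` (logical).
#' @param gamma Gompertz shape, 1/years.
#' @param beta0 Log-hazard intercept, or `NULL` to solve from
#'   `median_lifespan`.
#' @param beta_breed Log-hazard of medium/large vs small.
#' @param beta_sex Log-hazard of male vs female.
#' @param censor_rate Exponential adoption hazard, 1/years (0 = none).
#' @param visit_interval Years between scheduled blood draws.
#' @param max_followup Administrative censoring age, years.
#' @param median_lifespan Target median event age used when solving `beta0`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(markers, gamma = 0.25, beta0 = NULL,
                      beta_breed = 0.4, beta_sex = 0.2,
                      censor_rate = 0.15, visit_interval = 1,
                      max_followup = 15, median_lifespan = 11, seed = 1L) {
  assert_cols(markers, c("marker", "mean", "sd", "age_slope", "rho", "coef"),
              "sim_truth markers")
  if (!"log_scale" %in% names(markers)) markers$log_scale <- FALSE
  stopifnot(gamma > 0, all(markers$sd >= 0),
            all(markers$rho >= 0 & markers$rho < 1),
            censor_rate >= 0, visit_interval > 0, max_followup > visit_interval)
  if (is.null(beta0)) {
    xb_target <- log(log(2) * gamma / expm1(gamma * median_lifespan))
    beta0 <- xb_target - sum(markers$coef * markers$mean) -
      0.5 * beta_breed - 0.5 * beta_sex
  }
  structure(
    list(
      markers = markers, gamma = gamma, beta0 = beta0,
      beta_breed = beta_breed, beta_sex = beta_sex,
      censor_rate = censor_rate, visit_interval = visit_interval,
      max_followup = max_followup, seed = as.integer(seed)
    ),
    class = "sim_truth"
  )
}

#' Default synthetic-cohort ground truth
#'
#' A 15-marker canine-like configuration: the ten clock analytes carry the
#' published per-unit coefficients as their true hazard weights, plus five
#' null markers (zero coefficient) for selection tests. Baseline means and
#' SDs sit at typical adult canine values; ln-flagged markers are
#' parameterised on the log scale.
#'
#' @inheritParams sim_truth
#' @return A `sim_truth` object.
#' @export
default_sim_truth <- function(seed = 1L, gamma = 0.25, beta_breed = 0.4,
                              beta_sex = 0.2, censor_rate = 0.15,
                              visit_interval = 1, max_followup = 15) {
  markers <- dplyr::tribble(
    ~marker,           ~mean, ~sd,  ~age_slope, ~rho, ~coef,    ~log_scale,
    "wbc",             9.5,   2.2,  0.05,       0.5,  0.0919,   FALSE,
    "hgb",             15.5,  1.4,  -0.03,      0.5,  -0.00913, FALSE,
    "mcv",             68,    3.5,  0.05,       0.5,  -0.00749, FALSE,
    "hct",             46,    4.2,  -0.10,      0.5,  -0.0184,  FALSE,
    "mch",             22.5,  1.1,  0,          0.5,  -0.128,   FALSE,
    "glucose",         92,    9,    0.2,        0.5,  0.00917,  FALSE,
    "globulin",        3.1,   0.45, 0.02,       0.5,  0.133,    FALSE,
    "creatine_kinase", 4.8,   0.45, 0,          0.5,  0.333,    TRUE,
    "albumin",         3.4,   0.28, -0.01,      0.5,  -0.744,   FALSE,
    "alp",             4.1,   0.55, 0.03,       0.5,  0.263,    TRUE,
    "creatinine",      0.0,   0.22, 0.01,       0.5,  0,        TRUE,
    "urea_nitrogen",   2.7,   0.30, 0.01,       0.5,  0,        TRUE,
    "sodium",          146,   2.5,  0,          0.5,  0,        FALSE,
    "mchc",            33.8,  0.9,  0,          0.5,  0,        FALSE,
    "plt",             300,   55,   -1.0,       0.5,  0,        FALSE
  )
  sim_truth(markers, gamma = gamma, beta_breed = beta_breed,
            beta_sex = beta_sex, censor_rate = censor_rate,
            visit_interval = visit_interval, max_followup = max_followup,
            seed = seed)
}

#' Cohort-level simulation configuration
#'
#' @param n_animals Number of animals (>= 2).
#' @param truth A [sim_truth()] object.
#' @param frac_medium_large Proportion of medium/large animals.
#' @param frac_male Proportion of males.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_animals, truth = default_sim_truth(),
                       frac_medium_large = 0.5, frac_male = 0.5) {
  stopifnot(n_animals >= 2, inherits(truth, "sim_truth"),
            frac_medium_large >= 0, frac_medium_large <= 1,
            frac_male >= 0, frac_male <= 1)
  structure(
    list(n_animals = as.integer(n_animals), truth = truth,
         frac_medium_large = frac_medium_large, frac_male = frac_male),
    class = "sim_config"
  )
}

# deterministic animal metadata shared by the marker and event stages
animal_attributes <- function(config, seed_offset = 1L) {
  truth <- config$truth
  n <- config$n_animals
  with_seed(derive_seed(truth$seed, seed_offset), {
    breed_size <- ifelse(runif(n) < config$frac_medium_large,
                         "medium_large", "small")
    sex <- ifelse(runif(n) < config$frac_male, "male", "female")
    tibble(
      animal_id = sprintf("d%05d", seq_len(n)),
      species = "dog",
      breed = ifelse(breed_size == "small", "beagle", "labrador_retriever"),
      breed_size = breed_size,
      sex = sex
    )
  })
}

# visit-grid boundaries 0 = t0 < t1 < ... <= max_followup; draws occur at
# t1..tK; the final partial interval (tK, max_followup] reuses the tK draw
visit_grid <- function(truth) {
  k <- floor(truth$max_followup / truth$visit_interval - 1e-9)
  truth$visit_interval * seq_len(max(k, 1))
}

#' Simulate longitudinal marker panels
#'
#' Draws marker trajectories for every animal on the scheduled visit grid
#' (`visit_interval, 2 * visit_interval, ...` up to `max_followup`). Each
#' marker follows an AR(1) process with stationary standard deviation `sd`
#' around `mean + age_slope * age`; lag-1 autocorrelation is `rho`.
#' Trajectories cover the whole grid — [simulate_cohort()] truncates them at
#' each animal's simulated end of follow-up.
#'
#' @param config A [sim_config()] object.
#' @return Wide measurement tibble (`animal_id`, `age_at_draw`, marker
#'   columns in native units; ln-flagged markers are exponentiated).
#' @export
simulate_markers <- function(config) {
  truth <- config$truth
  attrs <- animal_attributes(config)
  ages <- visit_grid(truth)
  n <- config$n_animals
  k <- length(ages)
  sims <- with_seed(derive_seed(truth$seed, 2L), {
    lapply(seq_len(nrow(truth$markers)), function(i) {
      m <- truth$markers[i, ]
      e <- matrix(0, n, k)
      z <- matrix(rnorm(n * k), n, k)
      e[, 1] <- m$sd * z[, 1]
      if (k > 1) {
        scale_innov <- sqrt(1 - m$rho^2) * m$sd
        for (j in 2:k) e[, j] <- m$rho * e[, j - 1] + scale_innov * z[, j]
      }
      sweep(e, 2, m$mean + m$age_slope * ages, "+")
    })
  })
  panel <- tibble(
    animal_id = rep(attrs$animal_id, each = k),
    age_at_draw = rep(ages, times = n)
  )
  for (i in seq_len(nrow(truth$markers))) {
    m <- truth$markers[i, ]
    vals <- as.vector(t(sims[[i]]))
    panel[[m$marker]] <- if (m$log_scale) exp(vals) else vals
  }
  panel
}

# per-interval linear predictor matrix (n_animals x n_intervals) on the
# hazard scale; interval j = (t_{j-1}, t_j] uses the draw at t_{j-1}
# (backward-extended to the t_1 draw for the first interval)
sim_xb_matrix <- function(config, panel, attrs) {
  truth <- config$truth
  ages <- visit_grid(truth)
  k <- length(ages)
  n <- config$n_animals
  panel <- panel |> arrange(.data$animal_id, .data$age_at_draw)
  xb <- matrix(truth$beta0, n, k)
  for (i in seq_len(nrow(truth$markers))) {
    m <- truth$markers[i, ]
    v <- matrix(panel[[m$marker]], nrow = k)  # k x n, visits within animal
    if (m$log_scale) v <- log(v)
    xb <- xb + m$coef * t(v)
  }
  xb <- xb + truth$beta_breed * encode_breed(attrs$breed_size) +
    truth$beta_sex * encode_sex(attrs$sex)
  xb
}

#' Simulate event and censoring ages for a cohort
#'
#' The event law is a Gompertz proportional-hazards model with the markers as
#' piecewise-constant time-dependent covariates: within each inter-visit
#' interval the linear predictor `xb` is fixed at its interval-start value,
#' the cumulative hazard over `(a, b]` is `exp(xb) * (exp(gamma*b) -
#' exp(gamma*a)) / gamma`, and the event age is found by inverting the
#' piecewise cumulative hazard against a unit-exponential draw. Adoption
#' censoring is an independent exponential age; follow-up stops
#' administratively at `max_followup`. `end_age` is the minimum of the three
#' and `status` is 1 exactly when the event age is the strict minimum.
#'
#' @param config A [sim_config()] object.
#' @param panel Output of [simulate_markers()] (full-grid trajectories).
#' @return Animal-record tibble (`animal_id`, `species`, `breed`,
#'   `breed_size`, `sex`, `status`, `end_age`).
#' @export
simulate_events <- function(config, panel) {
  truth <- config$truth
  attrs <- animal_attributes(config)
  ages <- visit_grid(truth)
  bounds <- c(0, ages, truth$max_followup)
  bounds <- unique(bounds[bounds <= truth$max_followup + 1e-12])
  n <- config$n_animals
  xb <- sim_xb_matrix(config, panel, attrs)
  # interval j = (bounds[j], bounds[j+1]] uses the draw at bounds[j]
  # (first interval uses the first draw); map interval -> xb column
  n_int <- length(bounds) - 1
  col_for_interval <- pmin(pmax(seq_len(n_int) - 1, 1), ncol(xb))

  gam <- truth$gamma
  inc <- matrix(0, n, n_int)
  for (j in seq_len(n_int)) {
    a <- bounds[j]
    b <- bounds[j + 1]
    inc[, j] <- exp(xb[, col_for_interval[j]]) * (exp(gam * b) - exp(gam * a)) / gam
  }
  cum <- inc
  if (n_int > 1) {
    for (j in 2:n_int) cum[, j] <- cum[, j - 1] + inc[, j]
  }

  draws <- with_seed(derive_seed(truth$seed, 3L), {
    list(
      e = rexp(n),
      c = if (truth$censor_rate > 0) rexp(n, truth$censor_rate) else rep(Inf, n)
    )
  })
  # first interval whose cumulative hazard reaches the exponential draw,
  # then closed-form inversion within that interval
  j_hit <- rowSums(cum < draws$e) + 1L
  t_event <- rep(Inf, n)
  hit <- j_hit <= n_int
  if (any(hit)) {
    i_hit <- which(hit)
    jh <- j_hit[i_hit]
    prev <- ifelse(jh == 1, 0, cum[cbind(i_hit, pmax(jh - 1L, 1L))])
    xbij <- xb[cbind(i_hit, col_for_interval[jh])]
    t_event[i_hit] <- log(exp(gam * bounds[jh]) +
                            gam * (draws$e[i_hit] - prev) * exp(-xbij)) / gam
  }
  end_age <- pmin(t_event, draws$c, truth$max_followup)
  status <- as.integer(t_event < pmin(draws$c, truth$max_followup))
  attrs |> mutate(status = status, end_age = end_age)
}

#' Simulate a complete cohort with known ground truth
#'
#' Runs [simulate_markers()] and [simulate_events()], truncates each animal's
#' draws to ages strictly before its end of follow-up, and returns the pieces
#' a pipeline needs plus the generating truth for parameter-recovery checks.
#' Identical configurations give byte-identical output.
#'
#' @param config A [sim_config()] object.
#' @return List with `animals`, `panel` and `truth`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(50, default_sim_truth(seed = 7)))
#' dplyr::count(cohort$animals, status)
simulate_cohort <- function(config) {
  panel_full <- simulate_markers(config)
  animals <- simulate_events(config, panel_full)
  panel <- panel_full |>
    inner_join(animals |> select(all_of(c("animal_id", "end_age"))),
               by = "animal_id") |>
    filter(.data$age_at_draw < .data$end_age) |>
    select(-all_of("end_age"))
  list(animals = animals, panel = panel, truth = config$truth)
}

#' Simulate a paired calorie-restriction trial
#'
#' Emulates a pair-fed design: animals are generated in matched pairs sharing
#' every random draw (marker innovations, event and censoring exponentials,
#' breed size and sex), one arm per pair assigned to `control` and one to
#' `restricted`. After `effect_onset_age` the restricted arm's marker means
#' shift by `diet_effects` (on each marker's simulation scale, i.e. ln units
#' for ln-flagged markers). The event law is unchanged in form, so diet acts
#' on survival only through the markers.
#'
#' @param config A [sim_config()] object; `n_animals` must be even (pairs).
#' @param diet_effects Named numeric vector, marker -> additive shift applied
#'   to the restricted arm after onset.
#' @param effect_onset_age Age in years at which the shift begins.
#' @return List with `animals`, `panel`, `diet` (tibble `animal_id`, `pair`,
#'   `diet`) and `truth`.
#' @export
simulate_cr_trial <- function(config, diet_effects, effect_onset_age = 7) {
  truth <- config$truth
  if (config$n_animals %% 2 != 0) {
    abort("n_animals must be even for the paired design")
  }
  unknown <- setdiff(names(diet_effects), truth$markers$marker)
  if (length(unknown) > 0) {
    abort(sprintf("diet_effects name unknown marker(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  n_pairs <- config$n_animals / 2
  ages <- visit_grid(truth)

  arm_cfg <- sim_config(n_pairs, truth,
                        frac_medium_large = config$frac_medium_large,
                        frac_male = config$frac_male)
  control <- simulate_cohort(arm_cfg)

  # restricted arm: identical draws, shifted means after onset
  shifted <- truth
  shift_panel <- simulate_markers(arm_cfg)
  for (m in names(diet_effects)) {
    idx <- which(shift_panel$age_at_draw > effect_onset_age)
    is_log <- truth$markers$log_scale[truth$markers$marker == m]
    if (is_log) {
      shift_panel[[m]][idx] <- shift_panel[[m]][idx] * exp(diet_effects[[m]])
    } else {
      shift_panel[[m]][idx] <- shift_panel[[m]][idx] + diet_effects[[m]]
    }
  }
  animals_r <- simulate_events(arm_cfg, shift_panel)
  panel_r <- shift_panel |>
    inner_join(animals_r |> select(all_of(c("animal_id", "end_age"))),
               by = "animal_id") |>
    filter(.data$age_at_draw < .data$end_age) |>
    select(-all_of("end_age"))

  relabel <- function(df, suffix) {
    df |> mutate(animal_id = paste0(.data$animal_id, suffix))
  }
  animals <- bind_rows(relabel(control$animals, "_C"),
                       relabel(animals_r, "_R"))
  panel <- bind_rows(relabel(control$panel, "_C"), relabel(panel_r, "_R"))
  diet <- bind_rows(
    tibble(animal_id = paste0(control$animals$animal_id, "_C"),
           pair = seq_len(n_pairs), diet = "control"),
    tibble(animal_id = paste0(animals_r$animal_id, "_R"),
           pair = seq_len(n_pairs), diet = "restricted")
  )
  list(animals = animals, panel = panel, diet = diet, truth = truth)
}
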