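test_that("the degenerate clock returns biological age equal to age", {
  rows <- sim_rows(250, tiny_truth(seed = 61))
  clock <- identity_clock(rows, c("m1", "m2"))
  data <- tibble::tibble(
    m1 = c(8, 12, 10), m2 = c(4, 6, 5), age = c(2, 7.5, 12),
    breed_size = c("small", "medium_large", "small"),
    sex = c("female", "male", "male")
  )
  bioage <- biological_age(clock, data)
  expect_equal(bioage, data$age, tolerance = 1e-10)
  expect_equal(age_dev(bioage, data$age), rep(0, 3), tolerance = 1e-10)
})

test_that("the closed form agrees with bisection inversion of the reference model", {
  rows <- sim_rows(400, tiny_truth(seed = 62))
  clock <- train_clock(rows, c("m1", "m2"))
  set.seed(63)
  for (i in 1:25) {
    d <- tibble::tibble(
      m1 = runif(1, 4, 16), m2 = runif(1, 2, 8), age = runif(1, 0.5, 15),
      breed_size = sample(c("small", "medium_large"), 1),
      sex = sample(c("male", "female"), 1)
    )
    expect_equal(biological_age(clock, d), oracle_bioage(clock, d),
                 tolerance = 1e-8)
  }
})

test_that("linear predictor moves exactly by published per-unit coefficients", {
  rows <- sim_rows(250, tiny_truth(seed = 64))
  clock <- train_clock(rows, c("m1", "m2"))
  # impose the published albumin / ln-ALP weights on the two slots
  pub <- dog_clock_coefficients()
  clock$full$coefficients[["m1"]] <- pub$coefficient[pub$marker == "albumin"]
  clock$full$coefficients[["m2"]] <- pub$coefficient[pub$marker == "alp"]

  base <- tibble::tibble(m1 = 3.0, m2 = log(80), age = 7,
                         breed_size = "small", sex = "female")
  up_alb <- base |> dplyr::mutate(m1 = m1 + 1)
  up_alp <- base |> dplyr::mutate(m2 = log(80 * exp(1)))
  expect_equal(linear_predictor(clock, up_alb) - linear_predictor(clock, base),
               -0.744, tolerance = 1e-12)
  expect_equal(linear_predictor(clock, up_alp) - linear_predictor(clock, base),
               0.263, tolerance = 1e-12)
})

test_that("biological age is monotone in each marker with the coefficient's sign", {
  rows <- sim_rows(400, tiny_truth(seed = 65))
  clock <- train_clock(rows, c("m1", "m2"))
  set.seed(66)
  for (i in 1:20) {
    d <- tibble::tibble(
      m1 = runif(1, 4, 16), m2 = runif(1, 2, 8), age = runif(1, 1, 14),
      breed_size = sample(c("small", "medium_large"), 1),
      sex = sample(c("male", "female"), 1)
    )
    for (m in c("m1", "m2")) {
      bumped <- d
      bumped[[m]] <- bumped[[m]] + 0.5
      delta <- biological_age(clock, bumped) - biological_age(clock, d)
      expect_equal(sign(delta), sign(clock$full$coefficients[[m]]))
    }
  }
})

test_that("scoring a cohort needs every clock marker", {
  rows <- sim_rows(200, tiny_truth(seed = 67))
  clock <- train_clock(rows, c("m1", "m2"))
  cohort <- simulate_cohort(sim_config(30, tiny_truth(seed = 68)))
  panel <- cohort$panel
  panel$m2 <- NULL
  expect_error(score_cohort(panel, cohort$animals, clock), "m2")
  expect_error(
    biological_age(clock, tibble::tibble(m1 = 1, m2 = 1, age = -1,
                                         breed_size = "small", sex = "male")),
    "positive"
  )
})

test_that("refitting the full marker set reproduces the original clock", {
  rows <- sim_rows(400, tiny_truth(seed = 69))
  clock <- train_clock(rows, c("m1", "m2"))
  re <- refit_subset(rows, clock, c("m1", "m2"))
  expect_equal(re$full$coefficients, clock$full$coefficients, tolerance = 1e-6)
  expect_equal(re$full$gamma, clock$full$gamma, tolerance = 1e-6)
  expect_error(refit_subset(rows, clock, character(0)), "empty")
  expect_error(refit_subset(rows, clock, "nope"), "nope")
})

test_that("dropping null markers barely changes AgeDev; dropping a strong one costs fit", {
  truth <- sim_truth(
    tibble::tibble(
      marker = c("s1", "s2", "n1", "n2"),
      mean = c(10, 5, 0, 0), sd = c(1.5, 1, 1, 1), age_slope = 0, rho = 0.5,
      coef = c(0.5, -0.6, 0, 0), log_scale = FALSE
    ),
    seed = 70
  )
  train_rows <- sim_rows(500, truth)
  test_cohort <- simulate_cohort(sim_config(200, sim_truth(
    truth$markers, seed = 71
  )))
  clock <- train_clock(train_rows, c("s1", "s2", "n1", "n2"))
  sub_null <- refit_subset(train_rows, clock, c("s1", "s2"))

  sc_full <- score_cohort(test_cohort$panel, test_cohort$animals, clock)
  sc_sub <- score_cohort(test_cohort$panel, test_cohort$animals, sub_null)
  expect_gt(cor(sc_full$agedev, sc_sub$agedev), 0.99)

  # dropping a strongly weighted marker cannot improve held-out likelihood
  sub_weak <- refit_subset(train_rows, clock, c("s2", "n1", "n2"))
  test_rows <- suppressWarnings(
    to_counting_process(test_cohort$animals, test_cohort$panel)
  )
  ll_at <- function(m) {
    gompertz_loglik(test_rows, list(gamma = m$full$gamma, beta0 = m$full$beta0,
                                    coefs = m$full$coefficients))
  }
  expect_gt(ll_at(clock), ll_at(sub_weak))
})
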