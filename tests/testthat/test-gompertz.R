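test_that("the likelihood matches hand computation on tiny fixtures", {
  # single row (0, 1], event, xb = 0, gamma = 1:
  # log h(1) = 0 + 1; H(1) - H(0) = (e - 1); total = 2 - e
  rows <- tibble::tibble(tstart = 0, tstop = 1, event = 1L)
  ll <- gompertz_loglik(rows, list(gamma = 1, beta0 = 0))
  expect_equal(ll, 2 - exp(1), tolerance = 1e-10)

  # three-row fixture with a covariate, hand-summed term by term
  rows3 <- tibble::tibble(
    tstart = c(1, 2, 0.5), tstop = c(2, 3.5, 4), event = c(0L, 1L, 1L),
    x = c(0.7, -0.2, 1.1)
  )
  gam <- 0.3
  b0 <- -2
  bx <- 0.5
  xb <- b0 + bx * rows3$x
  hand <- sum(
    rows3$event * (xb + gam * rows3$tstop) -
      exp(xb) * (exp(gam * rows3$tstop) - exp(gam * rows3$tstart)) / gam
  )
  ll3 <- gompertz_loglik(rows3, list(gamma = gam, beta0 = b0, coefs = c(x = bx)))
  expect_equal(ll3, hand, tolerance = 1e-10)
})

test_that("the gamma -> 0 limit matches the exponential model", {
  rows <- tibble::tibble(
    tstart = c(0, 1, 2), tstop = c(1, 2, 5), event = c(0L, 0L, 1L),
    x = c(1, 2, 0.5)
  )
  b0 <- -1.2
  bx <- 0.4
  xb <- b0 + bx * rows$x
  exp_ll <- sum(rows$event * xb - exp(xb) * (rows$tstop - rows$tstart))
  ll <- gompertz_loglik(rows, list(gamma = 1e-10, beta0 = b0, coefs = c(x = bx)))
  expect_equal(ll, exp_ll, tolerance = 1e-6)
})

test_that("splitting an event-free interval leaves the likelihood unchanged", {
  params <- list(gamma = 0.35, beta0 = -3, coefs = c(x = 0.6))
  whole <- tibble::tibble(tstart = 1.2, tstop = 6.8, event = 0L, x = 0.9)
  split2 <- tibble::tibble(tstart = c(1.2, 4.1), tstop = c(4.1, 6.8),
                           event = c(0L, 0L), x = 0.9)
  expect_equal(gompertz_loglik(whole, params), gompertz_loglik(split2, params),
               tolerance = 1e-12)
})

test_that("NaN covariates fail naming the offending row", {
  rows <- tibble::tibble(tstart = 0, tstop = 1, event = 1L, x = NaN)
  expect_error(gompertz_loglik(rows, list(gamma = 1, beta0 = 0, coefs = c(x = 1))),
               "row")
})

test_that("a covariate-free fit matches a brute-force grid maximizer", {
  truth <- sim_truth(
    tibble::tibble(marker = "m", mean = 0, sd = 1, age_slope = 0, rho = 0,
                   coef = 0, log_scale = FALSE),
    gamma = 0.3, beta0 = -3.5, beta_breed = 0, beta_sex = 0,
    censor_rate = 0, visit_interval = 1, max_followup = 60, seed = 51
  )
  rows <- sim_rows(150, truth)
  fit <- fit_gompertz_ph(rows)

  ll <- function(gam, b0) {
    gompertz_loglik(rows, list(gamma = gam, beta0 = b0))
  }
  # nested grid refinement around a broad window
  g_rng <- c(0.05, 1)
  b_rng <- c(-6, -1)
  for (pass in 1:4) {
    gs <- seq(g_rng[1], g_rng[2], length.out = 31)
    bs <- seq(b_rng[1], b_rng[2], length.out = 31)
    vals <- outer(gs, bs, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    gw <- diff(g_rng) / 30
    bw <- diff(b_rng) / 30
    g_rng <- gs[best[1]] + c(-1, 1) * gw
    b_rng <- bs[best[2]] + c(-1, 1) * bw
  }
  expect_equal(fit$gamma, mean(g_rng), tolerance = 1e-3)
  expect_equal(fit$beta0, mean(b_rng), tolerance = 1e-3)
  expect_lt(fit$gradient_norm, 1e-6)
})

test_that("a duplicated covariate triggers a singular-information error", {
  rows <- sim_rows(80, tiny_truth(seed = 52))
  rows$m1_copy <- rows$m1
  expect_error(fit_gompertz_ph(rows, c("m1", "m1_copy")), "singular")
})

test_that("all-censored data cannot be fitted", {
  rows <- sim_rows(30, tiny_truth(seed = 53))
  rows$event <- 0L
  expect_error(fit_gompertz_ph(rows), "no events")
})

test_that("a single fit recovers simulated truth within sampling error", {
  truth <- tiny_truth(seed = 54)
  rows <- sim_rows(800, truth)
  fit <- fit_gompertz_ph(rows, c("m1", "m2", "breed_size", "sex"))
  td <- tidy(fit)
  ci <- function(term) unlist(td[td$term == term, c("conf.low", "conf.high")])
  expect_true(dplyr::between(0.25, ci("gamma")[1], ci("gamma")[2]))
  expect_true(dplyr::between(0.30, ci("m1")[1], ci("m1")[2]))
  expect_true(dplyr::between(-0.50, ci("m2")[1], ci("m2")[2]))
  expect_equal(glance(fit)$n_events, sum(rows$event))
})

test_that("conditional survival predictions behave like a PH model", {
  truth <- tiny_truth(seed = 55)
  rows <- sim_rows(300, truth)
  scores_like <- rows |> dplyr::mutate(agedev = m1 - 10)
  fit <- fit_gompertz_ph(scores_like, c("agedev", "breed_size", "sex"))

  nd <- function(a) tibble::tibble(agedev = a, breed_size = "small",
                                   sex = "male")
  grid <- seq(7, 14, by = 0.5)
  s0 <- predict_survival(fit, nd(0), current_age = 7, grid = grid)
  s2 <- predict_survival(fit, nd(2), current_age = 7, grid = grid)
  expect_equal(s0$survival[1], 1)
  expect_true(all(diff(s0$survival) <= 0))
  expect_true(all(s0$conf.low <= s0$survival & s0$survival <= s0$conf.high))
  if (fit$coefficients[["agedev"]] > 0) {
    expect_true(all(s2$survival[-1] < s0$survival[-1]))
  }

  # a zero AgeDev coefficient gives identical curves across AgeDev values
  fit0 <- fit
  fit0$coefficients[["agedev"]] <- 0
  fit0$par[["agedev"]] <- 0
  a <- predict_survival(fit0, nd(-2), current_age = 7, grid = grid)
  b <- predict_survival(fit0, nd(2), current_age = 7, grid = grid)
  expect_equal(a$survival, b$survival, tolerance = 1e-12)

  expect_error(predict_survival(fit, nd(0), current_age = 7, grid = c(5, 8)),
               "grid")
})

test_that("the fitter agrees with an independent parametric survival fit", {
  # plain right-censored Gompertz data (entry at 0, no covariates) is the
  # case an off-the-shelf parametric fitter handles; parameterizations map
  # as shape = gamma, log(rate) = beta0
  set.seed(56)
  n <- 500
  u <- runif(n)
  gam <- 0.3
  b0 <- -3
  t_ev <- log(1 - gam * log(u) / exp(b0)) / gam
  cens <- runif(n, 2, 25)
  rows <- tibble::tibble(
    tstart = 0,
    tstop = pmin(t_ev, cens),
    event = as.integer(t_ev <= cens)
  )
  fit <- fit_gompertz_ph(rows)
  ref <- flexsurv::flexsurvreg(
    survival::Surv(tstop, event) ~ 1, data = rows, dist = "gompertz"
  )
  expect_equal(fit$gamma, unname(ref$res["shape", "est"]), tolerance = 1e-4)
  expect_equal(fit$beta0, log(unname(ref$res["rate", "est"])),
               tolerance = 1e-4)
})
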