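# broom-style methods for fitted objects

#' Tidy a Gompertz PH fit
#'
#' One row per parameter: the shape `gamma` (natural scale; its confidence
#' interval is computed on the log scale and exponentiated), the intercept
#' `beta0`, and each covariate coefficient with Wald statistics.
#'
#' @param x A `gompertz_ph` object.
#' @param conf.level Confidence level for the intervals.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy gompertz_ph
#' @export
tidy.gompertz_ph <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - conf.level) / 2)
  est <- x$par
  out <- tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(est / se)),
    conf.low = unname(est - z * se),
    conf.high = unname(est + z * se)
  )
  g <- out$term == "log_gamma"
  out$term[g] <- "gamma"
  out$estimate[g] <- exp(est[["log_gamma"]])
  out$conf.low[g] <- exp(out$conf.low[g])
  out$conf.high[g] <- exp(out$conf.high[g])
  out
}

#' @rdname tidy.gompertz_ph
#' @method glance gompertz_ph
#' @export
glance.gompertz_ph <- function(x, ...) {
  tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * length(x$par),
    gamma = x$gamma,
    nobs = x$n_rows,
    n_events = x$n_events,
    n_animals = x$n_animals
  )
}

#' Tidy a biological age clock
#'
#' Stacks the tidied full and reference models with a `model` column.
#'
#' @param x A `phenoclock` object.
#' @param ... Passed to [tidy.gompertz_ph()].
#' @return A tibble.
#' @method tidy phenoclock
#' @export
tidy.phenoclock <- function(x, ...) {
  bind_rows(
    tidy(x$full, ...) |> mutate(model = "full"),
    tidy(x$ref, ...) |> mutate(model = "reference")
  ) |> relocate("model")
}

#' @rdname tidy.phenoclock
#' @method glance phenoclock
#' @export
glance.phenoclock <- function(x, ...) {
  tibble(
    n_markers = length(x$markers),
    gamma_full = x$full$gamma,
    gamma_ref = x$ref$gamma,
    logLik_full = x$full$loglik,
    logLik_ref = x$ref$loglik,
    nobs = x$full$n_rows,
    n_events = x$full$n_events
  )
}

#' Tidy a LASSO-Cox selection path
#'
#' @param x A `lasso_path` object.
#' @param ... Unused.
#' @return The per-lambda CV tibble (`lambda`, `deviance`, `se`, `nonzero`).
#' @method tidy lasso_path
#' @export
tidy.lasso_path <- function(x, ...) x$cv

#' @rdname tidy.lasso_path
#' @method glance lasso_path
#' @export
glance.lasso_path <- function(x, ...) {
  tibble(
    lambda_selected = x$lambda_selected,
    log_lambda_selected = log(x$lambda_selected),
    n_nonzero = length(x$nonzero_selected),
    n_lambdas = length(x$lambdas)
  )
}
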