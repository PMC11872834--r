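# internal helpers shared across modules

# binary encodings used by every model: reference category is a small female
encode_breed <- function(breed_size) as.numeric(breed_size == "medium_large")
encode_sex <- function(sex) as.numeric(sex == "male")

BREED_LEVELS <- c("small", "medium_large")
SEX_LEVELS <- c("male", "female")

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# model matrix for a set of covariate names: marker columns pass through,
# breed_size/sex are encoded as indicators
covariate_matrix <- function(rows, covariate_names) {
  cols <- lapply(covariate_names, function(nm) {
    if (nm == "breed_size") {
      encode_breed(rows$breed_size)
    } else if (nm == "sex") {
      encode_sex(rows$sex)
    } else {
      as.numeric(rows[[nm]])
    }
  })
  x <- do.call(cbind, cols)
  colnames(x) <- covariate_names
  if (anyNA(x)) {
    bad <- which(rowSums(is.na(x)) > 0)
    abort(sprintf(
      "NA covariate values in row(s): %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  x
}

# log(exp(a) - exp(b)) for a > b, stable for large a
log_diff_exp <- function(a, b) {
  a + log1p(-exp(b - a))
}

# log(1 + exp(x)) without overflow
log1p_exp <- function(x) {
  out <- ifelse(x > 33, x, log1p(exp(pmin(x, 33))))
  out
}

# deterministic integer sub-seeds below 2^31 derived from a base seed
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1013904223L + k * 69069L) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
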