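#' Rate functions for birth-death models
#'
#' A `rate_function` bundles speciation and extinction rates
#' \eqn{\lambda(t), \mu(t)} (t in Myr before present) under one of the
#' supported model families:
#'
#' * `M1` — constant \eqn{\lambda}, constant \eqn{\mu};
#' * `M2.1` — \eqn{\lambda = \alpha + \beta v(t)}, constant \eqn{\mu};
#' * `M2.2` — \eqn{\lambda = \alpha e^{\beta v(t)}}, constant \eqn{\mu};
#' * `M3.1`, `M3.2` — the same linear/exponential dependence on \eqn{\mu},
#'   constant \eqn{\lambda};
#' * `M4.1`, `M4.2` — both rates depend on v(t) with separate
#'   \eqn{(\alpha_1, \beta_1)} and \eqn{(\alpha_2, \beta_2)};
#' * `SHIFT(k)` — piecewise-constant rates with k change points.
#'
#' v(t) is an [env_series()] (e.g. patch counts or habitat area through
#' time).
#'
#' @param lambda,mu constant speciation/extinction rates (events/lineage/Myr);
#'   `lambda > 0`, `mu >= 0`.
#' @name rate_function
NULL

#' @rdname rate_function
#' @export
constant_rates <- function(lambda, mu) {
  if (lambda <= 0) stop("`lambda` must be positive")
  if (mu < 0) stop("`mu` must be non-negative")
  structure(list(model_id = "M1", type = "constant",
                 par = c(lambda = lambda, mu = mu)),
            class = "rate_function")
}

#' @rdname rate_function
#' @param shift_times change points in Myr before present, strictly
#'   increasing and positive. Interval 1 is the most recent,
#'   \eqn{[0, s_1)}; interval i covers \eqn{[s_{i-1}, s_i)}; rates are
#'   right-continuous in age at the change points.
#' @export
shift_rates <- function(shift_times, lambda, mu) {
  k <- length(shift_times)
  if (k > 0 && (any(shift_times <= 0) || any(diff(shift_times) <= 0)))
    stop("`shift_times` must be positive and strictly increasing")
  if (length(lambda) != k + 1 || length(mu) != k + 1)
    stop("`lambda` and `mu` need one value per interval (k + 1)")
  if (any(lambda <= 0)) stop("all interval `lambda` must be positive")
  if (any(mu < 0)) stop("all interval `mu` must be non-negative")
  structure(list(model_id = sprintf("SHIFT(%d)", k), type = "shift",
                 shift_times = as.numeric(shift_times),
                 lambda = as.numeric(lambda), mu = as.numeric(mu)),
            class = "rate_function")
}

#' @rdname rate_function
#' @param model_id one of `"M2.1"`, `"M2.2"`, `"M3.1"`, `"M3.2"`, `"M4.1"`,
#'   `"M4.2"`.
#' @param par named parameter vector: `alpha`, `beta` plus the constant
#'   `mu` (M2.x) or `lambda` (M3.x); `alpha1`, `beta1`, `alpha2`, `beta2`
#'   for M4.x.
#' @param env an [env_series()] supplying v(t).
#' @export
env_rates <- function(model_id, par, env) {
  if (!model_id %in% c("M2.1", "M2.2", "M3.1", "M3.2", "M4.1", "M4.2"))
    stop("unknown environmental model id: ", model_id)
  if (!inherits(env, "env_series")) stop("`env` must be an env_series")
  need <- switch(substr(model_id, 1, 2),
                 M2 = c("alpha", "beta", "mu"),
                 M3 = c("alpha", "beta", "lambda"),
                 M4 = c("alpha1", "beta1", "alpha2", "beta2"))
  if (!all(need %in% names(par)))
    stop("`par` must contain: ", paste(need, collapse = ", "))
  structure(list(model_id = model_id, type = "env",
                 par = par[need], env = env),
            class = "rate_function")
}

#' @export
print.rate_function <- function(x, ...) {
  cat("rate_function", x$model_id, "\n")
  if (x$type == "shift") {
    cat("  shifts at:", paste(format(x$shift_times), collapse = ", "), "\n")
    cat("  lambda:", paste(format(x$lambda), collapse = ", "), "\n")
    cat("  mu:    ", paste(format(x$mu), collapse = ", "), "\n")
  } else {
    cat(" ", paste(names(x$par), format(unname(x$par)), sep = " = ",
                   collapse = ", "), "\n")
  }
  invisible(x)
}

# piecewise-constant interval index for ages t (right-continuous in age)
.shift_interval <- function(rate, t) {
  findInterval(t, c(0, rate$shift_times)) # t in [s_{i-1}, s_i) -> i
}

#' Evaluate the speciation rate
#' @param rate a [rate_function][constant_rates].
#' @param t ages in Myr before present.
#' @return \eqn{\lambda(t)} as a numeric vector.
#' @export
rate_lambda <- function(rate, t) {
  switch(rate$type,
    constant = rep(rate$par[["lambda"]], length(t)),
    shift = rate$lambda[.shift_interval(rate, t)],
    env = {
      p <- rate$par
      v <- env_eval(rate$env, t)
      switch(rate$model_id,
        "M2.1" = p[["alpha"]] + p[["beta"]] * v,
        "M2.2" = p[["alpha"]] * exp(p[["beta"]] * v),
        "M3.1" = rep(p[["lambda"]], length(t)),
        "M3.2" = rep(p[["lambda"]], length(t)),
        "M4.1" = p[["alpha1"]] + p[["beta1"]] * v,
        "M4.2" = p[["alpha1"]] * exp(p[["beta1"]] * v))
    })
}

#' Evaluate the extinction rate
#' @inheritParams rate_lambda
#' @return \eqn{\mu(t)} as a numeric vector.
#' @export
rate_mu <- function(rate, t) {
  switch(rate$type,
    constant = rep(rate$par[["mu"]], length(t)),
    shift = rate$mu[.shift_interval(rate, t)],
    env = {
      p <- rate$par
      v <- env_eval(rate$env, t)
      switch(rate$model_id,
        "M2.1" = rep(p[["mu"]], length(t)),
        "M2.2" = rep(p[["mu"]], length(t)),
        "M3.1" = p[["alpha"]] + p[["beta"]] * v,
        "M3.2" = p[["alpha"]] * exp(p[["beta"]] * v),
        "M4.1" = p[["alpha2"]] + p[["beta2"]] * v,
        "M4.2" = p[["alpha2"]] * exp(p[["beta2"]] * v))
    })
}

# ages at which the rate functions are non-smooth, within (0, t_max)
.rate_breakpoints <- function(rate, t_max) {
  b <- switch(rate$type,
              constant = numeric(0),
              shift = rate$shift_times,
              env = rate$env$age)
  b[b > 0 & b < t_max]
}

# TRUE if rates are piecewise constant (closed-form integrals apply)
.is_piecewise_constant <- function(rate) {
  rate$type %in% c("constant", "shift")
}

#' Number of free parameters of a model family
#'
#' M1 has 2; one-sided environmental models (M2.x, M3.x) 3; two-sided
#' (M4.x) 4. A shift model with m change points counts its estimated shift
#' times as free parameters: k = 2(m + 1) + m = 3m + 2.
#'
#' @param model_id model identifier (e.g. `"M2.1"`, `"SHIFT(2)"`).
#' @return Integer parameter count.
#' @export
model_k_params <- function(model_id) {
  if (grepl("^SHIFT\\((\\d+)\\)$", model_id)) {
    m <- as.integer(sub("^SHIFT\\((\\d+)\\)$", "\\1", model_id))
    return(3L * m + 2L)
  }
  switch(model_id,
         "M1" = 2L,
         "M2.1" = , "M2.2" = , "M3.1" = , "M3.2" = 3L,
         "M4.1" = , "M4.2" = 4L,
         stop("unknown model id: ", model_id))
}

#' Dependence class of a model
#'
#' Aggregation used in posterior frequency tables: `cst` (M1), `lambda`
#' (M2.x: speciation depends on v), `mu` (M3.x), `lambda_mu` (M4.x),
#' `shift` for SHIFT(k).
#'
#' @param model_id model identifier(s).
#' @return Character vector of classes.
#' @export
model_class <- function(model_id) {
  vapply(model_id, function(m) {
    if (grepl("^SHIFT", m)) return("shift")
    switch(substr(m, 1, 2),
           M1 = "cst", M2 = "lambda", M3 = "mu", M4 = "lambda_mu",
           stop("unknown model id: ", m))
  }, character(1), USE.NAMES = FALSE)
}
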