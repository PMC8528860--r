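# Model-specific optimization setup: parameter transform (optimizer scale
# -> rate_function), base start, jitter scales, and natural-scale names.
# Positive parameters are optimized on the log scale; beta coefficients are
# unconstrained but internally measured against v(t)/v_scale so the simplex
# sees O(1) coordinates whatever the units of v (patch counts vs km^2).
.fit_setup <- function(chronogram, model_id, env, shift_times) {
  n <- chronogram$n_tips
  t_c <- chronogram$crown_age
  TL <- sum(chronogram$phy$edge.length)
  lam0 <- max(n - 2, 1) / TL
  mu0 <- lam0 / 5
  is_shift <- grepl("^SHIFT", model_id)
  is_env <- model_id %in% c("M2.1", "M2.2", "M3.1", "M3.2", "M4.1", "M4.2")
  if (is_env) {
    if (is.null(env)) stop(model_id, " requires an `env` series")
    v <- env_eval(env, seq(0, t_c, length.out = 256))
    v_scale <- max(abs(v), 1e-12)
  } else v_scale <- 1
  if (model_id == "M1") {
    list(
      start = c(log(lam0), log(mu0)),
      jitter_sd = c(0.7, 0.7),
      to_rate = function(th) constant_rates(exp(th[1]), exp(th[2])),
      to_par = function(th) c(lambda = exp(th[1]), mu = exp(th[2])))
  } else if (is_shift) {
    m <- length(shift_times)
    list(
      start = c(rep(log(lam0), m + 1), rep(log(mu0), m + 1)),
      jitter_sd = rep(0.7, 2 * (m + 1)),
      to_rate = function(th)
        shift_rates(shift_times, exp(th[seq_len(m + 1)]),
                    exp(th[m + 1 + seq_len(m + 1)])),
      to_par = function(th)
        setNames(c(exp(th[seq_len(m + 1)]), exp(th[m + 1 + seq_len(m + 1)])),
                 c(paste0("lambda_", seq_len(m + 1)),
                   paste0("mu_", seq_len(m + 1)))))
  } else if (model_id %in% c("M2.1", "M2.2")) {
    lin <- model_id == "M2.1"
    list(
      start = c(log(lam0), 0, log(mu0)),
      jitter_sd = c(0.7, 0.5, 0.7),
      to_rate = function(th)
        env_rates(model_id, c(alpha = exp(th[1]), beta = th[2] / v_scale,
                              mu = exp(th[3])), env),
      to_par = function(th)
        c(alpha = exp(th[1]), beta = th[2] / v_scale, mu = exp(th[3])),
      env_funs = function(th) list(
        lam = if (lin) function(v) exp(th[1]) + (th[2] / v_scale) * v
              else function(v) exp(th[1]) * exp((th[2] / v_scale) * v),
        mu = function(v) exp(th[3]) + 0 * v))
  } else if (model_id %in% c("M3.1", "M3.2")) {
    lin <- model_id == "M3.1"
    list(
      start = c(log(mu0), 0, log(lam0)),
      jitter_sd = c(0.7, 0.5, 0.7),
      to_rate = function(th)
        env_rates(model_id, c(alpha = exp(th[1]), beta = th[2] / v_scale,
                              lambda = exp(th[3])), env),
      to_par = function(th)
        c(alpha = exp(th[1]), beta = th[2] / v_scale, lambda = exp(th[3])),
      env_funs = function(th) list(
        lam = function(v) exp(th[3]) + 0 * v,
        mu = if (lin) function(v) exp(th[1]) + (th[2] / v_scale) * v
             else function(v) exp(th[1]) * exp((th[2] / v_scale) * v)))
  } else if (model_id %in% c("M4.1", "M4.2")) {
    lin <- model_id == "M4.1"
    list(
      start = c(log(lam0), 0, log(mu0), 0),
      jitter_sd = c(0.7, 0.5, 0.7, 0.5),
      to_rate = function(th)
        env_rates(model_id, c(alpha1 = exp(th[1]), beta1 = th[2] / v_scale,
                              alpha2 = exp(th[3]), beta2 = th[4] / v_scale),
                  env),
      to_par = function(th)
        c(alpha1 = exp(th[1]), beta1 = th[2] / v_scale,
          alpha2 = exp(th[3]), beta2 = th[4] / v_scale),
      env_funs = function(th) list(
        lam = if (lin) function(v) exp(th[1]) + (th[2] / v_scale) * v
              else function(v) exp(th[1]) * exp((th[2] / v_scale) * v),
        mu = if (lin) function(v) exp(th[3]) + (th[4] / v_scale) * v
             else function(v) exp(th[3]) * exp((th[4] / v_scale) * v)))
  } else stop("unknown model id: ", model_id)
}

#' Maximum-likelihood fit of one birth-death model
#'
#' Fits `M1`, one of the six environmental models (`M2.1` ... `M4.2`, which
#' need an [env_series()]), or a birth-death-shift model at fixed change
#' points (`model_id = "SHIFT"` with `shift_times`; rates per interval are
#' estimated, and the change points are counted as free parameters in k,
#' since [shift_scan()] profiles over them).
#'
#' Optimization is seeded multi-start Nelder-Mead: positive parameters on
#' the log scale, environmental slopes unconstrained (internally scaled by
#' the magnitude of v so all coordinates are O(1)). Restart 1 starts from a
#' Yule-flavoured guess (lambda ~ (n-2)/total branch length); later
#' restarts jitter it. Deterministic given `seed`.
#'
#' @param chronogram a [parse_chronogram()] object.
#' @param model_id `"M1"`, `"M2.1"`, `"M2.2"`, `"M3.1"`, `"M3.2"`,
#'   `"M4.1"`, `"M4.2"`, or `"SHIFT"`.
#' @param env [env_series()], required for M2-M4.
#' @param f sampling fraction; defaults to the chronogram's.
#' @param shift_times fixed change points for `"SHIFT"`.
#' @param n_restarts number of optimizer starts (default 10).
#' @param seed RNG seed for the restart jitters.
#' @param maxit,reltol Nelder-Mead control.
#' @return Object of class `bd_fit`: `model_id`, natural-scale `par`,
#'   `logL`, `k`, `n` (number of branching times), `AICc`, the fitted
#'   `rate` function, `crown_age`, `f`, `shift_times` (if any), and
#'   `convergence` diagnostics (best restart index, optim code, restart
#'   logLs).
#' @export
fit_model <- function(chronogram, model_id, env = NULL,
                      f = chronogram$sampling_fraction,
                      shift_times = NULL, n_restarts = 10, seed = 1L,
                      maxit = 500, reltol = 1e-8) {
  if (identical(model_id, "SHIFT") || grepl("^SHIFT\\(", model_id)) {
    if (is.null(shift_times)) shift_times <- numeric(0)
    model_id <- sprintf("SHIFT(%d)", length(shift_times))
  }
  setup <- .fit_setup(chronogram, model_id, env, shift_times)
  npar <- length(setup$start)
  k <- model_k_params(model_id)
  nobs <- length(chronogram$branching_times)
  if (nobs <= k + 1)
    stop(sprintf("%s too rich for this tree (k = %d, n = %d branching times)",
                 model_id, k, nobs))
  obj <- if (is.null(setup$env_funs)) {
    function(th) {
      rate <- tryCatch(setup$to_rate(th), error = function(e) NULL)
      if (is.null(rate)) return(1e10)
      ll <- tree_loglik(chronogram, rate, f = f)
      if (!is.finite(ll)) 1e10 else -ll
    }
  } else {
    # environmental models: v(t) at all quadrature nodes is cached once,
    # so each simplex step is pure arithmetic
    cache <- .env_loglik_cache(chronogram, env, f)
    function(th) {
      fn <- setup$env_funs(th)
      ll <- .env_loglik_eval(cache, fn$lam, fn$mu)
      if (!is.finite(ll)) 1e10 else -ll
    }
  }
  set.seed(seed)
  jit <- matrix(rnorm(n_restarts * npar), n_restarts, npar)
  jit[1, ] <- 0
  best <- NULL; best_val <- Inf; restart_ll <- rep(NA_real_, n_restarts)
  for (r in seq_len(n_restarts)) {
    th0 <- setup$start + jit[r, ] * setup$jitter_sd
    opt <- tryCatch(
      optim(th0, obj, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    restart_ll[r] <- -opt$value
    if (opt$value < best_val) {
      best_val <- opt$value; best <- opt; best[["restart"]] <- r
    }
  }
  if (is.null(best) || !is.finite(best_val) || best_val >= 1e10)
    stop(sprintf(
      "fit_model(%s): no restart reached a finite likelihood (%d attempted)",
      model_id, n_restarts))
  logL <- -best$value
  structure(list(
    model_id = model_id,
    par = setup$to_par(best$par),
    shift_times = if (grepl("^SHIFT", model_id)) shift_times else NULL,
    logL = logL, k = k, n = nobs,
    AICc = aicc(logL, k, nobs),
    rate = setup$to_rate(best$par),
    crown_age = chronogram$crown_age, f = f,
    convergence = list(n_restarts = n_restarts, best_restart = best$restart,
                       optim_code = best$convergence,
                       restart_logL = restart_ll)),
    class = "bd_fit")
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf("bd_fit %s: logL = %.4f, k = %d, AICc = %.4f\n",
              x$model_id, x$logL, x$k, x$AICc))
  if (!is.null(x$shift_times) && length(x$shift_times))
    cat("  shift times:", paste(format(x$shift_times), collapse = ", "), "\n")
  cat(" ", paste(names(x$par), format(unname(x$par), digits = 4),
                 sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
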