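#' Rate-through-time curve of a fitted model
#'
#' Evaluates the fitted speciation, extinction and net diversification
#' rates on a time grid. Shift models are right-continuous in age: for
#' t in \[s_i, s_{i+1}) the value is interval i's rate. Grid points older
#' than the tree's crown age get `NA` (that tree carries no information
#' there).
#'
#' @param fit a [fit_model()] result.
#' @param t_grid ages in Myr (default every 0.1 Myr up to the crown age).
#' @return `data.frame` with columns `time_Ma`, `lambda`, `mu`, `net`.
#' @export
rate_curve <- function(fit, t_grid = NULL) {
  if (!inherits(fit, "bd_fit")) stop("`fit` must be a bd_fit")
  if (is.null(t_grid)) t_grid <- seq(0, fit$crown_age, by = 0.1)
  ok <- t_grid <= fit$crown_age + 1e-9
  lam <- mu <- rep(NA_real_, length(t_grid))
  lam[ok] <- rate_lambda(fit$rate, t_grid[ok])
  mu[ok] <- rate_mu(fit$rate, t_grid[ok])
  data.frame(time_Ma = t_grid, lambda = lam, mu = mu, net = lam - mu)
}

#' Posterior summary of rate-through-time curves
#'
#' Pointwise median and 1st/9th deciles of the net diversification rate
#' across a sample of per-tree curves (each from that tree's own best
#' model). Trees younger than a grid time contribute nothing there (`NA`
#' in their curve); the number of contributing trees is recorded per grid
#' point. Quantiles use the inclusive linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param curves list of [rate_curve()] data.frames sharing `t_grid`.
#' @param t_grid ages in Myr; defaults to the grid of the first curve.
#' @return `data.frame` (class `rtt_summary`) with columns `time_Ma`,
#'   `n_trees`, `q10`, `median`, `q90`.
#' @export
summarize_sample <- function(curves, t_grid = NULL) {
  if (!length(curves)) stop("need at least one curve")
  if (is.null(t_grid)) t_grid <- curves[[1]]$time_Ma
  mat <- vapply(curves, function(cv) {
    if (!isTRUE(all.equal(cv$time_Ma, t_grid)))
      cv$net[match(round(t_grid, 6), round(cv$time_Ma, 6))]
    else cv$net
  }, numeric(length(t_grid)))
  mat <- matrix(mat, nrow = length(t_grid))
  n_trees <- rowSums(!is.na(mat))
  qs <- t(apply(mat, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    quantile(x, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
  }))
  out <- data.frame(time_Ma = t_grid, n_trees = n_trees,
                    q10 = qs[, 1], median = qs[, 2], q90 = qs[, 3])
  class(out) <- c("rtt_summary", "data.frame")
  out
}
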