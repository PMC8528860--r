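#' Corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k + 1)/(n - k - 1)`, with n the number of
#' observations. Throughout the package n is the number of branching times
#' (`n_tips - 1`), the count of events the likelihood factorizes over.
#'
#' @param logL log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(logL, k, n) {
  if (n <= k + 1)
    stop(sprintf("AICc undefined: n = %d observations for k = %d parameters",
                 n, k))
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank fitted models by AICc
#'
#' The model with the lowest AICc is best; models within `delta` AICc units
#' of it form the supported set, models beyond are considered significantly
#' less explicative. Exact ties break deterministically: fewer parameters
#' first, then lexicographic model id. Non-finite AICc values are excluded
#' with a warning.
#'
#' @param fits list of [fit_model()] results (at least 2).
#' @param delta AICc window for the supported set (default 2).
#' @return A `data.frame` (class `model_selection`) ordered best-first with
#'   columns `model_id`, `logL`, `k`, `AICc`, `delta_AICc`, `within`;
#'   attributes `best` (model id) and `within` (ids of the supported set).
#' @export
select_models <- function(fits, delta = 2) {
  if (length(fits) < 2) stop("need at least two fitted models to compare")
  tb <- data.frame(
    model_id = vapply(fits, `[[`, character(1), "model_id"),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    stringsAsFactors = FALSE)
  bad <- !is.finite(tb$AICc)
  if (any(bad)) {
    warning("excluding models with non-finite AICc: ",
            paste(tb$model_id[bad], collapse = ", "))
    tb <- tb[!bad, , drop = FALSE]
  }
  if (!nrow(tb)) stop("no model reached a finite AICc")
  tb <- tb[order(tb$AICc, tb$k, tb$model_id), , drop = FALSE]
  rownames(tb) <- NULL
  tb$delta_AICc <- tb$AICc - tb$AICc[1]
  tb$within <- tb$delta_AICc <= delta
  structure(tb, best = tb$model_id[1], within = tb$model_id[tb$within],
            class = c("model_selection", "data.frame"))
}

# candidate shift-time combinations for m shifts; exhaustive for m <= 2,
# greedy forward addition from the best (m-1)-set above that
.shift_combos <- function(candidates, m, greedy_base = NULL) {
  if (m == 0) return(list(numeric(0)))
  if (m <= 2 || is.null(greedy_base)) {
    if (length(candidates) < m) return(list())
    cmb <- combn(candidates, m, simplify = FALSE)
    return(cmb)
  }
  extra <- setdiff(candidates, greedy_base)
  lapply(extra, function(s) sort(c(greedy_base, s)))
}

# every inter-shift interval must contain at least one branching event
.combo_feasible <- function(shift_times, bt, t_c) {
  bounds <- c(0, shift_times, t_c + 1e-9)
  counts <- tabulate(findInterval(bt, bounds), nbins = length(bounds) - 1)
  all(counts > 0)
}

#' Scan for diversification-rate shifts
#'
#' Places candidate change points on a regular grid (every `grid_step` Myr,
#' strictly inside the crown age), fits a birth-death-shift model for every
#' feasible combination of m candidates (m = 0 ... `max_shifts`), and
#' selects the number of shifts by AICc. The search is exhaustive for
#' m <= 2 and greedy (forward addition to the best smaller set) beyond,
#' where the combinatorics explode. Combinations leaving any interval
#' without a branching event are skipped, as are m too rich for the tree.
#'
#' @param chronogram a [parse_chronogram()] object.
#' @param f sampling fraction; defaults to the chronogram's.
#' @param grid_step candidate spacing in Myr (default 5).
#' @param max_shifts largest number of shifts tried (default 4).
#' @param delta AICc window reported in the summary table.
#' @param n_restarts,seed,maxit,reltol passed to [fit_model()].
#' @return Object of class `shift_scan`: `best_m`, `best_fit`, a list
#'   `fits` (best fit per m), and `table` with one row per m
#'   (`m`, `shift_times`, `logL`, `k`, `AICc`, `delta_AICc`).
#' @export
shift_scan <- function(chronogram, f = chronogram$sampling_fraction,
                       grid_step = 5, max_shifts = 4, delta = 2,
                       n_restarts = 10, seed = 1L, maxit = 500,
                       reltol = 1e-8) {
  t_c <- chronogram$crown_age
  if (grid_step <= 0) stop("`grid_step` must be positive")
  candidates <- if (t_c > grid_step) seq(grid_step, t_c, by = grid_step)
                else numeric(0)
  candidates <- candidates[candidates < t_c - 1e-9]
  bt <- chronogram$branching_times
  nobs <- length(bt)
  fits <- list()
  greedy_base <- NULL
  for (m in 0:max_shifts) {
    k <- 3L * m + 2L
    if (nobs <= k + 1) break   # model too rich for this tree
    if (m > length(candidates)) break
    combos <- .shift_combos(candidates, m, greedy_base)
    combos <- Filter(function(s) .combo_feasible(s, bt, t_c), combos)
    if (!length(combos)) {
      warning(sprintf("shift_scan: no feasible candidate set for m = %d", m))
      next
    }
    best_m_fit <- NULL
    for (s in combos) {
      ft <- tryCatch(
        fit_model(chronogram, "SHIFT", f = f, shift_times = s,
                  n_restarts = n_restarts, seed = seed, maxit = maxit,
                  reltol = reltol),
        error = function(e) NULL)
      if (is.null(ft)) next
      if (is.null(best_m_fit) || ft$logL > best_m_fit$logL) best_m_fit <- ft
    }
    if (is.null(best_m_fit)) next
    fits[[as.character(m)]] <- best_m_fit
    if (m >= 2) greedy_base <- best_m_fit$shift_times
  }
  if (!length(fits)) stop("shift_scan: no model could be fitted")
  ms <- as.integer(names(fits))
  tb <- data.frame(
    m = ms,
    shift_times = vapply(fits, function(x)
      paste(format(x$shift_times), collapse = ","), character(1)),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    stringsAsFactors = FALSE, row.names = NULL)
  tb$delta_AICc <- tb$AICc - min(tb$AICc)
  # deterministic tie-break: fewer shifts first
  best_i <- order(tb$AICc, tb$m)[1]
  structure(list(best_m = tb$m[best_i],
                 best_fit = fits[[as.character(tb$m[best_i])]],
                 fits = fits, table = tb, delta = delta),
            class = "shift_scan")
}

#' @export
print.shift_scan <- function(x, ...) {
  cat(sprintf("shift_scan: best m = %d\n", x$best_m))
  print(x$table)
  invisible(x)
}

#' Model-selection frequencies over a posterior tree sample
#'
#' Fits a set of models to every tree of a posterior sample, selects per
#' tree by AICc, and tabulates (i) how often each model is the best, (ii)
#' how often each dependence class — `cst` (M1), `lambda` (M2.x), `mu`
#' (M3.x), `lambda_mu` (M4.x) — is the best, and (iii) class frequencies
#' counting membership of the within-`delta` set. The frequency with which
#' M1 is absent from the within-`delta` set is reported as
#' `m1_rejection_freq` (the "constant model rejected" summary). Trees
#' failing all fits are dropped and counted; frequencies are over the
#' successful trees.
#'
#' @param sample a [load_tree_sample()] object (or list of chronograms).
#' @param models character vector of model ids (default M1 plus the six
#'   environmental models).
#' @param env [env_series()] shared by the environmental models.
#' @param f sampling fraction; defaults to the sample's.
#' @param delta AICc window (default 2).
#' @param n_restarts,seed,maxit,reltol passed to [fit_model()].
#' @return Object of class `selection_table`: `per_tree` data.frame (tree,
#'   best model, best class, within-set ids), `model_freq`, `class_freq`,
#'   `within_class_freq`, `m1_rejection_freq`, `n_trees`, `n_failed`.
#' @export
posterior_frequencies <- function(sample,
                                  models = c("M1", "M2.1", "M2.2", "M3.1",
                                             "M3.2", "M4.1", "M4.2"),
                                  env = NULL,
                                  f = NULL, delta = 2, n_restarts = 10,
                                  seed = 1L, maxit = 500, reltol = 1e-8) {
  trees <- if (inherits(sample, "tree_sample")) sample$trees else sample
  if (is.null(f))
    f <- if (inherits(sample, "tree_sample")) sample$sampling_fraction
         else trees[[1]]$sampling_fraction
  if (length(models) < 2) stop("need at least two candidate models")
  per <- list(); nfail <- 0L
  for (i in seq_along(trees)) {
    sel <- tryCatch({
      fits <- lapply(models, function(m)
        fit_model(trees[[i]], m, env = env, f = f, n_restarts = n_restarts,
                  seed = seed + i, maxit = maxit, reltol = reltol))
      select_models(fits, delta = delta)
    }, error = function(e) NULL)
    if (is.null(sel)) { nfail <- nfail + 1L; next }
    within <- attr(sel, "within")
    per[[length(per) + 1L]] <- data.frame(
      tree = i, best_model = attr(sel, "best"),
      best_class = model_class(attr(sel, "best")),
      within = paste(within, collapse = ";"),
      m1_rejected = !("M1" %in% within),
      stringsAsFactors = FALSE)
  }
  if (!length(per)) stop("no tree could be fitted for >= 2 models")
  if (nfail > 0)
    message(sprintf("posterior_frequencies: dropped %d failed trees", nfail))
  per <- do.call(rbind, per)
  classes <- c("cst", "lambda", "mu", "lambda_mu")
  model_freq <- vapply(models, function(m) mean(per$best_model == m),
                       numeric(1))
  class_freq <- vapply(classes, function(cl) mean(per$best_class == cl),
                       numeric(1))
  within_class_freq <- vapply(classes, function(cl) {
    mean(vapply(strsplit(per$within, ";"), function(w)
      cl %in% model_class(w), logical(1)))
  }, numeric(1))
  structure(list(per_tree = per,
                 model_freq = model_freq,
                 class_freq = class_freq,
                 within_class_freq = within_class_freq,
                 m1_rejection_freq = mean(per$m1_rejected),
                 n_trees = nrow(per), n_failed = nfail, delta = delta),
            class = "selection_table")
}

#' @export
print.selection_table <- function(x, ...) {
  cat(sprintf("selection_table over %d trees (%d failed)\n",
              x$n_trees, x$n_failed))
  cat("best-model class frequencies:\n")
  print(round(x$class_freq, 3))
  cat(sprintf("M1 rejected (absent from within-%g set): %.3f\n",
              x$delta, x$m1_rejection_freq))
  invisible(x)
}
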