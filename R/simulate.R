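#' Simulate a reconstructed chronogram under time-varying rates
#'
#' Forward continuous-time simulation from two crown lineages at
#' `crown_age`, with time-varying hazards \eqn{\lambda(t), \mu(t)} drawn by
#' thinning (rejection against a global upper bound on
#' \eqn{\lambda + \mu}), which is exact — no time discretization. Extinct
#' lineages are pruned, each surviving tip is retained independently with
#' probability `f`, and the result is conditioned by rejection on >= 2
#' sampled tips with both crown lineages represented — matching the crown
#' conditioning of [tree_loglik()].
#'
#' Instead of `crown_age` a `target_tips` count may be given; the crown age
#' is then solved from the branching-process expectation
#' \eqn{E[n] = 2 f e^{R(T)}}.
#'
#' @param rate a [rate_function][constant_rates] (true generating model).
#' @param f sampling fraction in (0, 1].
#' @param crown_age crown age T in Myr.
#' @param target_tips expected sampled tip count (alternative to
#'   `crown_age`).
#' @param seed RNG seed (fixed seed reproduces the tree exactly).
#' @param max_lineages guard against explosive parameter choices.
#' @param max_tries rejection cap; fewer than 1 acceptance per 1000 tries
#'   is an error advising a parameter change.
#' @return A [parse_chronogram()] object carrying `f`.
#' @export
simulate_tree <- function(rate, f = 1, crown_age = NULL, target_tips = NULL,
                          seed = NULL, max_lineages = 1e5, max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  if (f <= 0 || f > 1) stop("`f` must lie in (0, 1]")
  if (is.null(crown_age)) {
    if (is.null(target_tips))
      stop("give either `crown_age` or `target_tips`")
    g <- function(T) 2 * f * exp(.bd_RJ(rate, T, T)$R) - target_tips
    if (g(500) < 0)
      stop("`target_tips` unreachable within 500 Myr under these rates")
    crown_age <- stats::uniroot(g, c(1e-3, 500), tol = 1e-6)$root
  }
  T <- crown_age
  tg <- sort(unique(c(seq(0, T, length.out = 1001),
                      .rate_breakpoints(rate, T))))
  lam_g <- rate_lambda(rate, tg); mu_g <- rate_mu(rate, tg)
  if (min(lam_g) <= 0 || min(mu_g) < 0)
    stop("true rates must satisfy lambda > 0 and mu >= 0 on [0, crown_age]")
  B <- max(lam_g + mu_g)
  st <- new.env()
  fmt <- function(x) sprintf("%.12g", x)
  sim_node <- function(tau0) {
    tau <- tau0
    repeat {
      tau <- tau + rexp(1, B)
      if (tau >= T) {
        st$tip <- st$tip + 1L
        return(paste0("t", st$tip, ":", fmt(T - tau0)))
      }
      age <- T - tau
      tot <- rate_lambda(rate, age) + rate_mu(rate, age)
      if (runif(1) < tot / B) {
        if (runif(1) < rate_lambda(rate, age) / tot) {
          st$nlin <- st$nlin + 1L
          if (st$nlin > max_lineages)
            stop("lineage explosion; lower lambda or the crown age")
          left <- sim_node(tau)
          right <- sim_node(tau)
          return(sprintf("(%s,%s):%s", left, right, fmt(tau - tau0)))
        } else {
          st$tip <- st$tip + 1L
          return(paste0("x", st$tip, ":", fmt(tau - tau0)))
        }
      }
    }
  }
  for (try in seq_len(max_tries)) {
    st$nlin <- 2L; st$tip <- 0L
    nwk <- sprintf("(%s,%s);", sim_node(0), sim_node(0))
    phy <- read.tree(text = nwk)
    extant <- phy$tip.label[startsWith(phy$tip.label, "t")]
    if (length(extant) < 2) next
    kept <- extant[runif(length(extant)) <= f]
    if (length(kept) < 2) next
    pruned <- drop.tip(phy, setdiff(phy$tip.label, kept))
    if (is.null(pruned) || Ntip(pruned) < 2) next
    # both crown lineages must have sampled descendants: pruned crown == T
    if (abs(max(node.depth.edgelength(pruned)) - T) > 1e-6 * T) next
    return(parse_chronogram(pruned, sampling_fraction = f))
  }
  stop(sprintf(
    "simulate_tree: no acceptance in %d tries (rate < 1e-3); change parameters",
    max_tries))
}

#' Simulate a habitat raster stack with known fragmentation
#'
#' Builds one 0/1 slice per age containing exactly `k[i]` disjoint
#' 8-connected square blobs (side `2 * blob_halfwidth + 1`), separated by
#' at least 2 cells of sea even across the date line, so the true patch
#' count is `k[i]` under either connectivity, with or without longitude
#' wrap. The returned truth table lists the per-slice patch count and the
#' exact total blob area from [cell_areas()].
#'
#' @param n_slices number of time slices.
#' @param k true patch counts, recycled to `n_slices`.
#' @param n_lat,n_lon lattice size in cells (defaults give uniform
#'   2-degree cells on a full 360-degree tropical ring, so slices can be
#'   round-tripped through the ESRI ASCII dialect and wrap at the date
#'   line).
#' @param lat_range,lon_range lattice extent in degrees.
#' @param blob_halfwidth blob half-width in cells (default 1: 3x3 blobs).
#' @param ages slice ages in Myr (default 0, 1, 2, ...).
#' @param seed RNG seed.
#' @param max_place_tries rejection cap per blob placement.
#' @return List with `stack` (a [habitat_stack()]) and `truth`
#'   (`data.frame` with `age_Ma`, `n_patches`, `total_area_km2`).
#' @export
simulate_habitat_stack <- function(n_slices, k, n_lat = 20, n_lon = 180,
                                   lat_range = c(-20, 20),
                                   lon_range = c(-180, 180),
                                   blob_halfwidth = 1, ages = NULL,
                                   seed = 1L, max_place_tries = 2000) {
  set.seed(seed)
  if (is.null(ages)) ages <- seq(0, n_slices - 1)
  if (length(ages) != n_slices) stop("one age per slice required")
  k <- rep_len(k, n_slices)
  h <- blob_halfwidth
  lat_edges <- seq(lat_range[1], lat_range[2], length.out = n_lat + 1)
  lon_edges <- seq(lon_range[1], lon_range[2], length.out = n_lon + 1)
  areas <- cell_areas(lat_edges, lon_edges)
  min_sep <- 2 * h + 3   # centre Chebyshev distance giving a >= 2-cell gap
  slices <- vector("list", n_slices)
  truth <- data.frame(age_Ma = ages, n_patches = as.integer(round(k)),
                      total_area_km2 = NA_real_)
  for (s in seq_len(n_slices)) {
    g <- matrix(0, n_lat, n_lon)
    centres <- matrix(numeric(0), 0, 2)
    for (b in seq_len(k[s])) {
      placed <- FALSE
      for (tr in seq_len(max_place_tries)) {
        ci <- sample((h + 1):(n_lat - h), 1)
        cj <- sample(seq_len(n_lon), 1)
        ok <- TRUE
        if (nrow(centres)) {
          dr <- abs(centres[, 1] - ci)
          dc <- abs(centres[, 2] - cj)
          dc <- pmin(dc, n_lon - dc)  # circular in longitude
          ok <- all(pmax(dr, dc) >= min_sep)
        }
        if (ok) {
          rows <- (ci - h):(ci + h)
          cols <- (((cj - h):(cj + h) - 1) %% n_lon) + 1
          g[rows, cols] <- 1
          centres <- rbind(centres, c(ci, cj))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("simulate_habitat_stack: blob placement cap exceeded; ",
             "reduce k or the blob size")
    }
    slices[[s]] <- habitat_slice(g, lat_edges, lon_edges, ages[s])
    truth$total_area_km2[s] <- sum(areas[g == 1])
  }
  list(stack = habitat_stack(slices), truth = truth)
}

#' Parameter-recovery and model-selection experiment
#'
#' For each configuration (a true generating model with its parameters,
#' sampling fraction and crown age), simulates `n_rep` reconstructed
#' trees, fits the candidate `models` to each, selects by AICc, and
#' tabulates selection frequencies plus bias/RMSE of the parameters of the
#' true model family. Failed replicates are dropped and counted.
#'
#' @param configs list of configurations; each a list with `label`, `rate`
#'   (a [rate_function][constant_rates]), `f`, and `crown_age`.
#' @param n_rep replicates per configuration.
#' @param models candidate model ids for [fit_model()].
#' @param env [env_series()] for environmental candidates.
#' @param seed base RNG seed; replicate r of configuration c uses
#'   `seed + 1000 * c + r`.
#' @param n_restarts,maxit passed to [fit_model()].
#' @return List with `per_replicate` (one row per replicate: label, rep,
#'   best model/class, true-model parameter estimates) and `summary` (per
#'   configuration: class frequencies, parameter bias and RMSE).
#' @export
recovery_experiment <- function(configs, n_rep = 10,
                                models = c("M1", "M2.1", "M2.2", "M3.1",
                                           "M3.2", "M4.1", "M4.2"),
                                env = NULL, seed = 1L, n_restarts = 5,
                                maxit = 500) {
  rows <- list(); summaries <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    true_id <- cfg$rate$model_id
    true_par <- if (true_id == "M1") cfg$rate$par else
      if (cfg$rate$type == "env") cfg$rate$par else NULL
    est <- list(); classes <- character(0); nfail <- 0L
    for (r in seq_len(n_rep)) {
      res <- tryCatch({
        ch <- simulate_tree(cfg$rate, f = cfg$f, crown_age = cfg$crown_age,
                            seed = seed + 1000L * ci + r)
        fits <- lapply(models, function(m)
          fit_model(ch, m, env = env, f = cfg$f, n_restarts = n_restarts,
                    seed = seed + r, maxit = maxit))
        sel <- select_models(fits)
        truth_fit <- if (true_id %in% models)
          fits[[match(true_id, models)]] else NULL
        list(best = attr(sel, "best"),
             par = if (!is.null(truth_fit)) truth_fit$par else NULL)
      }, error = function(e) NULL)
      if (is.null(res)) { nfail <- nfail + 1L; next }
      classes <- c(classes, model_class(res$best))
      if (!is.null(res$par)) est[[length(est) + 1L]] <- res$par
      rows[[length(rows) + 1L]] <- data.frame(
        label = cfg$label, rep = r, best_model = res$best,
        best_class = model_class(res$best), stringsAsFactors = FALSE)
    }
    freq <- vapply(c("cst", "lambda", "mu", "lambda_mu", "shift"),
                   function(cl) mean(classes == cl), numeric(1))
    sm <- list(label = cfg$label, n_ok = length(classes), n_failed = nfail,
               class_freq = freq)
    if (length(est) && !is.null(true_par)) {
      em <- do.call(rbind, est)
      common <- intersect(colnames(em), names(true_par))
      if (length(common)) {
        tp <- unlist(true_par[common])
        sm$bias <- colMeans(em[, common, drop = FALSE]) - tp
        sm$rmse <- sqrt(colMeans(
          (em[, common, drop = FALSE] - rep(tp, each = nrow(em)))^2))
        sm$median_est <- apply(em[, common, drop = FALSE], 2, median)
      }
    }
    summaries[[ci]] <- sm
  }
  list(per_replicate = do.call(rbind, rows), summary = summaries)
}
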