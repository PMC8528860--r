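#' Validate a time-calibrated tree as a chronogram
#'
#' Wraps an ultrametric `phylo` tree (or Newick text/file) together with its
#' sampling fraction, crown age and branching times. Time runs backwards
#' from the present: tips sit at t = 0 and the crown node at
#' `crown_age` Myr. Polytomies are resolved with zero-length branches, so
#' ties in branching times are allowed and survive to the likelihood.
#'
#' Ultrametricity is enforced to a relative tolerance of 1e-4 of the crown
#' age (published chronograms carry rounding error); beyond that the call
#' fails naming the worst tip rather than silently fitting a
#' non-ultrametric tree.
#'
#' @param tree a `phylo` object, Newick string, or path to a Newick file.
#' @param sampling_fraction probability f in (0, 1] that an extant species
#'   is present in the tree (assumed homogeneous across lineages).
#' @return An object of class `chronogram`: list with `phy`, `n_tips`,
#'   `sampling_fraction`, `crown_age`, and `branching_times` (Myr before
#'   present, sorted decreasing; `n_tips - 1` entries, the first equal to
#'   the crown age).
#' @export
parse_chronogram <- function(tree, sampling_fraction = 1) {
  f <- sampling_fraction
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f <= 0 || f > 1)
    stop("`sampling_fraction` must lie in (0, 1]")
  if (is.character(tree)) {
    phy <- if (grepl("\\(", tree[1])) read.tree(text = tree)
           else read.tree(tree)
    if (is.null(phy)) stop("could not parse Newick input")
  } else phy <- tree
  if (!inherits(phy, "phylo")) stop("`tree` must be a phylo object or Newick")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (Ntip(phy) < 2) stop("a chronogram needs at least 2 tips")
  if (!is.binary(phy)) phy <- multi2di(phy, random = FALSE)
  depth <- node.depth.edgelength(phy)
  tip_depth <- depth[seq_len(Ntip(phy))]
  crown <- max(tip_depth)
  if (crown <= 0) stop("tree has zero depth")
  dev <- abs(tip_depth - crown)
  if (max(dev) > 1e-4 * crown)
    stop(sprintf(
      "tree is not ultrametric: tip '%s' deviates by %.6g Myr (tolerance %.3g)",
      phy$tip.label[which.max(dev)], max(dev), 1e-4 * crown))
  bt <- sort(unname(branching.times(phy)), decreasing = TRUE)
  bt[1] <- crown  # guard against rounding in branching.times
  structure(list(phy = phy, n_tips = Ntip(phy), sampling_fraction = f,
                 crown_age = crown, branching_times = bt),
            class = "chronogram")
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("chronogram: %d tips, crown age %.4g Myr, f = %.3g\n",
              x$n_tips, x$crown_age, x$sampling_fraction))
  invisible(x)
}

#' Load a posterior sample of chronograms
#'
#' Reads a file of Newick trees (one per line) or a NEXUS trees block and
#' returns up to `max_trees` validated chronograms sharing one sampling
#' fraction. By default the first `max_trees` are taken; `select =
#' "random"` draws a seeded random subset instead.
#'
#' @param path tree file.
#' @param sampling_fraction shared f in (0, 1].
#' @param max_trees cap on the number of trees returned (default 1000).
#' @param select `"first"` (default) or `"random"`.
#' @param seed RNG seed used when `select = "random"`.
#' @return An object of class `tree_sample`: list with `trees` (list of
#'   [parse_chronogram()] results) and `sampling_fraction`. Trees failing
#'   validation are dropped with a message; zero usable trees is an error.
#' @export
load_tree_sample <- function(path, sampling_fraction = 1, max_trees = 1000,
                             select = c("first", "random"), seed = 1L) {
  select <- match.arg(select)
  if (!file.exists(path)) stop("cannot read tree file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty tree file: ", path)
  first_line <- lines[1]
  trees <- if (grepl("^#NEXUS", first_line, ignore.case = TRUE))
    read.nexus(path) else read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no parseable trees in ", path)
  if (length(trees) > max_trees) {
    idx <- if (select == "random") {
      set.seed(seed); sort(sample.int(length(trees), max_trees))
    } else seq_len(max_trees)
    trees <- trees[idx]
  } else if (length(trees) < max_trees) {
    warning(sprintf("%s: only %d trees available (requested up to %d)",
                    basename(path), length(trees), max_trees))
  }
  out <- list(); nfail <- 0L
  for (tr in trees) {
    ch <- tryCatch(parse_chronogram(tr, sampling_fraction),
                   error = function(e) NULL)
    if (is.null(ch)) nfail <- nfail + 1L else out[[length(out) + 1L]] <- ch
  }
  if (!length(out)) stop("zero valid chronograms in ", path)
  if (nfail > 0)
    message(sprintf("load_tree_sample: dropped %d invalid trees", nfail))
  structure(list(trees = out, sampling_fraction = sampling_fraction),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("tree_sample: %d chronograms, f = %.3g\n",
              length(x$trees), x$sampling_fraction))
  invisible(x)
}

#' Check a clade's phylogenetic sampling against a threshold
#'
#' Clades pass when their sampling fraction is strictly higher than the
#' threshold (default 50%): likelihood surfaces at >= 50% sampling differ
#' little from complete-tree surfaces. Failure is flagged, not fatal, so
#' users can override deliberately.
#'
#' @param f sampling fraction in (0, 1].
#' @param threshold strict lower bound (default 0.5).
#' @return `TRUE`/`FALSE`; a warning is emitted on failure.
#' @export
check_sampling_threshold <- function(f, threshold = 0.5) {
  if (!is.numeric(f) || any(f <= 0) || any(f > 1))
    stop("`f` must lie in (0, 1]")
  ok <- f > threshold
  if (any(!ok))
    warning(sprintf("sampling fraction %s not above %.2g; fits may be biased",
                    paste(format(f[!ok]), collapse = ", "), threshold))
  ok
}
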