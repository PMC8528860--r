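#' A single dated paleo-habitat map
#'
#' Bundles a 0/1 occupancy grid on a regular latitude-longitude lattice with
#' its age in Myr before present. Rows of `grid` run south to north
#' (matching `lat_edges`, which are strictly increasing), columns west to
#' east.
#'
#' @param grid numeric matrix of 0/1 occupancy, `length(lat_edges) - 1` rows
#'   and `length(lon_edges) - 1` columns.
#' @param lat_edges,lon_edges cell boundary coordinates in degrees;
#'   strictly increasing; latitudes within \[-90, 90\], longitudes spanning
#'   at most 360 degrees.
#' @param age non-negative age of the map, Myr before present.
#' @return An object of class `habitat_slice`.
#' @seealso [count_patches()], [total_area()], [habitat_stack()]
#' @export
habitat_slice <- function(grid, lat_edges, lon_edges, age) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  storage.mode(grid) <- "double"
  lat_edges <- as.numeric(lat_edges)
  lon_edges <- as.numeric(lon_edges)
  if (length(lat_edges) < 2 || any(diff(lat_edges) <= 0))
    stop("`lat_edges` must be strictly increasing")
  if (length(lon_edges) < 2 || any(diff(lon_edges) <= 0))
    stop("`lon_edges` must be strictly increasing")
  if (lat_edges[1] < -90 - 1e-9 || lat_edges[length(lat_edges)] > 90 + 1e-9)
    stop("`lat_edges` must lie within [-90, 90]")
  if (diff(range(lon_edges)) > 360 + 1e-9)
    stop("`lon_edges` must span at most 360 degrees")
  if (nrow(grid) != length(lat_edges) - 1L ||
      ncol(grid) != length(lon_edges) - 1L)
    stop("grid shape does not match the number of cell edges")
  if (anyNA(grid) || !all(grid == 0 | grid == 1))
    stop("grid values must all be 0 or 1 (coerce on load)")
  age <- as.numeric(age)
  if (length(age) != 1 || is.na(age) || age < 0)
    stop("`age` must be a single non-negative Myr value")
  structure(list(grid = grid, lat_edges = lat_edges, lon_edges = lon_edges,
                 age = age),
            class = "habitat_slice")
}

#' @export
print.habitat_slice <- function(x, ...) {
  cat(sprintf("habitat_slice: %d x %d cells, age %.6g Ma, %d habitat cells\n",
              nrow(x$grid), ncol(x$grid), x$age, sum(x$grid)))
  invisible(x)
}

#' A time-ordered stack of habitat maps on a shared lattice
#'
#' @param slices list of [habitat_slice()] objects sharing an identical
#'   lattice, with unique ages. Slices are sorted by increasing age.
#' @return An object of class `habitat_stack` with elements `slices`,
#'   `ages`, `lat_edges`, `lon_edges`.
#' @export
habitat_stack <- function(slices) {
  if (!length(slices)) stop("empty habitat stack")
  if (!all(vapply(slices, inherits, logical(1), "habitat_slice")))
    stop("all elements must be habitat_slice objects")
  ref <- slices[[1]]
  for (s in slices) {
    if (!isTRUE(all.equal(s$lat_edges, ref$lat_edges, tolerance = 1e-9)) ||
        !isTRUE(all.equal(s$lon_edges, ref$lon_edges, tolerance = 1e-9)))
      stop("all slices must share an identical lattice")
  }
  ages <- unname(vapply(slices, `[[`, numeric(1), "age"))
  if (anyDuplicated(ages)) stop("slice ages must be unique")
  ord <- order(ages)
  structure(list(slices = slices[ord], ages = ages[ord],
                 lat_edges = ref$lat_edges, lon_edges = ref$lon_edges),
            class = "habitat_stack")
}

#' @export
print.habitat_stack <- function(x, ...) {
  cat(sprintf("habitat_stack: %d slices, ages %.6g-%.6g Ma, %d x %d cells\n",
              length(x$slices), min(x$ages), max(x$ages),
              nrow(x$slices[[1]]$grid), ncol(x$slices[[1]]$grid)))
  invisible(x)
}

#' Read one ESRI ASCII grid
#'
#' Parses the `ncols/nrows/xllcorner/yllcorner/cellsize[/NODATA_value]`
#' header followed by row-major values, the first file row being the
#' northernmost band. Missing-data and non-\{0,1\} cells are coerced to 0
#' (non-habitat); the number of coerced cells is attached as attribute
#' `n_coerced` and a warning is raised.
#'
#' @param path file path.
#' @param age age in Myr to stamp on the slice.
#' @return A [habitat_slice()].
#' @export
read_ascii_grid <- function(path, age) {
  if (!file.exists(path)) stop("cannot read raster file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("file too short for an ASCII grid: ", path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  bad <- is.na(m) | !(m == 0 | m == 1)
  n_coerced <- sum(bad)
  if (n_coerced > 0) {
    m[bad] <- 0
    warning(sprintf("%s: %d non-{0,1}/missing cells coerced to 0",
                    basename(path), n_coerced))
  }
  # file rows run north -> south; flip to the internal south -> north order
  m <- m[nr:1, , drop = FALSE]
  sl <- habitat_slice(
    m,
    lat_edges = hdr$yllcorner + hdr$cellsize * (0:nr),
    lon_edges = hdr$xllcorner + hdr$cellsize * (0:nc),
    age = age)
  attr(sl, "n_coerced") <- n_coerced
  sl
}

#' Write a habitat slice as an ESRI ASCII grid
#'
#' Requires a uniform cell size in both directions (the dialect cannot
#' express anything else).
#'
#' @param slice a [habitat_slice()].
#' @param path output file path.
#' @export
write_ascii_grid <- function(slice, path) {
  dlat <- diff(slice$lat_edges); dlon <- diff(slice$lon_edges)
  cs <- dlat[1]
  if (max(abs(c(dlat, dlon) - cs)) > 1e-9 * abs(cs))
    stop("ASCII grid output requires a uniform cell size")
  g <- slice$grid
  g <- g[nrow(g):1, , drop = FALSE]  # back to north-first file order
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", slice$lon_edges[1]),
    sprintf("yllcorner %.10g", slice$lat_edges[1]),
    sprintf("cellsize %.10g", cs),
    "NODATA_value -9999"), con)
  writeLines(apply(g, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Load a stack of habitat rasters
#'
#' Either give `paths` (+ optional `ages`, otherwise ages are parsed from
#' filenames of the form `habitat_<age>Ma.asc`) or a `manifest` TSV with
#' columns `path` and `age_Ma` (paths resolved relative to the manifest).
#'
#' @param paths character vector of ESRI ASCII grid files.
#' @param ages numeric ages (Myr), one per file.
#' @param manifest path to a manifest TSV.
#' @return A [habitat_stack()]. The total number of coerced cells across
#'   files is reported in a single message.
#' @export
load_habitat_stack <- function(paths = NULL, ages = NULL, manifest = NULL) {
  if (!is.null(manifest)) {
    tb <- read.delim(manifest, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("path", "age_Ma") %in% names(tb)))
      stop("manifest must have columns `path` and `age_Ma`")
    paths <- ifelse(file.exists(tb$path), tb$path,
                    file.path(dirname(manifest), tb$path))
    ages <- tb$age_Ma
  }
  if (is.null(paths) || !length(paths)) stop("no raster files given")
  if (is.null(ages)) {
    m <- regmatches(basename(paths),
                    regexec("habitat_([0-9]+\\.?[0-9]*)Ma", basename(paths)))
    ages <- suppressWarnings(as.numeric(vapply(m, function(x)
      if (length(x) == 2) x[2] else NA_character_, character(1))))
    if (anyNA(ages))
      stop("cannot parse ages from filenames; supply `ages` or a manifest")
  }
  if (length(ages) != length(paths)) stop("one age per file required")
  slices <- mapply(read_ascii_grid, paths, ages, SIMPLIFY = FALSE)
  ncoerced <- sum(vapply(slices, function(s) {
    v <- attr(s, "n_coerced"); if (is.null(v)) 0L else v
  }, numeric(1)))
  if (ncoerced > 0)
    message(sprintf("load_habitat_stack: %d cells coerced to 0 in total",
                    ncoerced))
  habitat_stack(slices)
}

#' Spherical cell areas of a latitude-longitude lattice
#'
#' Area of the cell spanning latitudes \[phi1, phi2\] and longitudes
#' \[theta1, theta2\] on a sphere of radius `radius_km`:
#' `R^2 (theta2 - theta1) (sin phi2 - sin phi1)` with angles in radians.
#' This is exactly the area any cylindrical equal-area (e.g. Behrmann)
#' projection preserves, so no projection step is needed; the result does
#' not depend on longitude.
#'
#' @param lat_edges,lon_edges strictly increasing cell boundaries, degrees.
#' @param radius_km sphere radius (default 6371, the Earth mean radius).
#' @return Matrix of cell areas in km^2, rows = latitude bands (south to
#'   north), columns = longitude bands.
#' @export
cell_areas <- function(lat_edges, lon_edges, radius_km = 6371) {
  if (any(diff(lat_edges) <= 0) || any(diff(lon_edges) <= 0))
    stop("cell edges must be strictly increasing (no zero-width cells)")
  if (radius_km <= 0) stop("`radius_km` must be positive")
  dsin <- diff(sin(lat_edges * pi / 180))
  dth <- diff(lon_edges) * pi / 180
  radius_km^2 * outer(dsin, dth)
}

# Matrix of neighbour vertex ids shifted by (di, dj), NA outside;
# columns wrap when `wrap` is TRUE.
.shifted_ids <- function(id, di, dj, wrap) {
  nr <- nrow(id); nc <- ncol(id)
  out <- matrix(NA_integer_, nr, nc)
  rows <- seq_len(nr) + di
  ok_r <- rows >= 1 & rows <= nr
  cols <- seq_len(nc) + dj
  if (wrap) {
    cols <- ((cols - 1) %% nc) + 1
    out[ok_r, ] <- id[rows[ok_r], cols, drop = FALSE]
  } else {
    ok_c <- cols >= 1 & cols <= nc
    out[ok_r, ok_c] <- id[rows[ok_r], cols[ok_c], drop = FALSE]
  }
  out
}

.spans_globe <- function(lon_edges) {
  abs(diff(range(lon_edges)) - 360) < 1e-6
}

#' Count habitat patches in a slice
#'
#' Number of connected components of habitat (value 1) cells under 4- or
#' 8-connectivity. With `wrap_longitude = TRUE` and a lattice spanning the
#' full 360 degrees, the first and last columns are adjacent, so reef
#' tracts are not split at the antimeridian. There is no wrap across the
#' poles.
#'
#' @param slice a [habitat_slice()].
#' @param connectivity 4 (rook) or 8 (queen, the default).
#' @param wrap_longitude join the date line when the grid spans 360 degrees
#'   (default `TRUE`).
#' @return Integer patch count (0 for an all-sea map).
#' @export
count_patches <- function(slice, connectivity = 8, wrap_longitude = TRUE) {
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8")
  g <- slice$grid
  hab <- which(g == 1)
  nhab <- length(hab)
  if (nhab == 0L) return(0L)
  wrap <- isTRUE(wrap_longitude) && .spans_globe(slice$lon_edges) &&
    ncol(g) > 1L
  id <- matrix(NA_integer_, nrow(g), ncol(g))
  id[hab] <- seq_len(nhab)
  dirs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) dirs <- c(dirs, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (d in dirs) {
    nb <- .shifted_ids(id, d[1], d[2], wrap)
    sel <- !is.na(id) & !is.na(nb)
    from <- c(from, id[sel]); to <- c(to, nb[sel])
  }
  keep <- from != to  # guard against 1-column wrapped self-edges
  gr <- igraph::make_graph(rbind(from[keep], to[keep]), n = nhab,
                           directed = FALSE)
  as.integer(igraph::components(gr)$no)
}

#' Total habitat area of a slice
#'
#' @param slice a [habitat_slice()].
#' @param areas per-cell areas conforming to the slice lattice, from
#'   [cell_areas()]; computed from the slice edges when omitted.
#' @param radius_km sphere radius used when `areas` is omitted.
#' @return Total habitat area in km^2.
#' @export
total_area <- function(slice, areas = NULL, radius_km = 6371) {
  if (is.null(areas))
    areas <- cell_areas(slice$lat_edges, slice$lon_edges, radius_km)
  if (!identical(dim(areas), dim(slice$grid)))
    stop("`areas` shape does not match the slice grid")
  sum(areas[slice$grid == 1])
}

#' Interpolable environmental time series v(t)
#'
#' Holds (age, value) knots and an interpolation rule. Evaluation outside
#' the knot range is constant (the nearest knot value); the smoothing
#' spline option is clamped at 0 so habitat metrics stay non-negative.
#'
#' @param age strictly increasing knot ages (Myr before present).
#' @param value non-negative knot values.
#' @param kind `"patch_count"` or `"total_area_km2"` (free-form allowed).
#' @param interpolation `"linear"` (default; monotone segments, no
#'   overshoot) or `"spline"` (smoothing spline).
#' @param spline_df degrees of freedom for the smoothing spline; default
#'   `min(10, n knots)`.
#' @return An object of class `env_series`.
#' @export
env_series <- function(age, value, kind = "env",
                       interpolation = c("linear", "spline"),
                       spline_df = NULL) {
  interpolation <- match.arg(interpolation)
  age <- as.numeric(age); value <- as.numeric(value)
  if (length(age) != length(value) || !length(age))
    stop("`age` and `value` must be non-empty and of equal length")
  ord <- order(age)
  age <- age[ord]; value <- value[ord]
  if (any(diff(age) <= 0)) stop("knot ages must be strictly increasing")
  if (any(value < 0)) stop("knot values must be non-negative")
  obj <- structure(list(age = age, value = value, kind = kind,
                        interpolation = interpolation,
                        spline_df = spline_df),
                   class = "env_series")
  if (interpolation == "spline") {
    if (length(age) < 4) stop("spline interpolation needs >= 4 knots")
    df <- if (is.null(spline_df)) min(10, length(age)) else spline_df
    obj$spline <- smooth.spline(age, value, df = df)
    obj$spline_df <- df
  }
  obj
}

#' @export
print.env_series <- function(x, ...) {
  cat(sprintf("env_series (%s, %s): %d knots over %.6g-%.6g Ma\n",
              x$kind, x$interpolation, length(x$age), min(x$age), max(x$age)))
  invisible(x)
}

#' Evaluate an environmental series
#'
#' @param series an [env_series()].
#' @param t ages (Myr); clamped to the knot range (constant extrapolation).
#' @return Numeric vector of v(t).
#' @export
env_eval <- function(series, t) {
  t <- pmin(pmax(t, series$age[1]), series$age[length(series$age)])
  if (series$interpolation == "linear") {
    if (length(series$age) == 1) return(rep(series$value, length(t)))
    approx(series$age, series$value, xout = t, rule = 2)$y
  } else {
    pmax(0, predict(series$spline, t)$y)
  }
}

#' @export
as.data.frame.env_series <- function(x, ...) {
  data.frame(age_Ma = x$age, value = x$value)
}

#' Fragmentation / area time series from a habitat stack
#'
#' Computes one knot per slice: the patch count (fragmentation) or total
#' habitat area at that slice's age.
#'
#' @param stack a [habitat_stack()].
#' @param metric `"patch_count"` or `"total_area_km2"`.
#' @param connectivity,wrap_longitude passed to [count_patches()].
#' @param interpolation,spline_df passed to [env_series()].
#' @param radius_km sphere radius for areas.
#' @return An [env_series()]; `as.data.frame()` yields the (age, value)
#'   table.
#' @export
build_env_series <- function(stack,
                             metric = c("patch_count", "total_area_km2"),
                             connectivity = 8, wrap_longitude = TRUE,
                             interpolation = c("linear", "spline"),
                             spline_df = NULL, radius_km = 6371) {
  metric <- match.arg(metric)
  interpolation <- match.arg(interpolation)
  if (!inherits(stack, "habitat_stack")) stop("`stack` must be a habitat_stack")
  if (metric == "patch_count") {
    vals <- vapply(stack$slices, count_patches, numeric(1),
                   connectivity = connectivity,
                   wrap_longitude = wrap_longitude)
  } else {
    ar <- cell_areas(stack$lat_edges, stack$lon_edges, radius_km)
    vals <- vapply(stack$slices, total_area, numeric(1), areas = ar)
  }
  env_series(stack$ages, vals, kind = metric,
             interpolation = interpolation, spline_df = spline_df)
}
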