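#' Analysis grids and environmental covariate stacks
#'
#' The landscape is a stack of raster layers on one shared analysis grid
#' (default 30 m cells, projected meters, origin at the top-left corner).
#' Static layers: `wetland`, `water`, `road`, `fence_or_trail`, `ditch`
#' (binary) and `tree_canopy` (fraction 0-1). Dynamic layers have one
#' raster per calendar day: `ndvi` and `food` (gridded) and the daily
#' weather summaries `tmax`, `tmin`, `prcp`, `rhum`, `vp` (spatially
#' constant per day, stored as scalars).
#'
#' @name env-stack
NULL

STATIC_LAYERS <- c("wetland", "water", "road", "fence_or_trail", "ditch",
                   "tree_canopy")
DYNAMIC_LAYERS <- c("ndvi", "food", "tmax", "tmin", "prcp", "rhum", "vp")
BINARY_LAYERS <- c("wetland", "water", "road", "fence_or_trail", "ditch",
                   "food")
CONTINUOUS_LAYERS <- setdiff(c(STATIC_LAYERS, DYNAMIC_LAYERS), BINARY_LAYERS)

#' Define an analysis grid
#'
#' @param nrow,ncol grid dimensions
#' @param cell cell size in meters
#' @param xmin,ymax projected coordinates of the top-left corner
#' @return an `env_grid`
#' @export
env_grid <- function(nrow, ncol, cell, xmin = 0, ymax = nrow * cell) {
  assert_that(nrow >= 1 && ncol >= 1 && cell > 0, "invalid_argument",
              "grid dimensions and cell size must be positive")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cell = cell, xmin = xmin, ymax = ymax),
            class = "env_grid")
}

#' Locate points on the grid
#'
#' Cells are half-open in both coordinates: a point exactly on a cell's
#' right or bottom edge belongs to the neighbouring cell (row-major,
#' origin top-left).
#'
#' @param grid an [env_grid()]
#' @param x,y projected coordinates
#' @return data.frame with `row`, `col` (NA outside the grid)
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$cell) + 1
  row <- floor((grid$ymax - y) / grid$cell) + 1
  bad <- col < 1 | col > grid$ncol | row < 1 | row > grid$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

cell_center <- function(grid, row, col) {
  data.frame(x = grid$xmin + (col - 0.5) * grid$cell,
             y = grid$ymax - (row - 0.5) * grid$cell)
}

new_env_stack <- function(grid, static, dynamic, dates) {
  for (nm in names(static))
    stopifnot(identical(dim(static[[nm]]), c(grid$nrow, grid$ncol)))
  for (nm in intersect(names(static), BINARY_LAYERS))
    stopifnot(all(static[[nm]] %in% c(0, 1)))
  for (nm in names(dynamic))
    stopifnot(length(dynamic[[nm]]) == length(dates))
  structure(list(grid = grid, static = static, dynamic = dynamic,
                 dates = dates,
                 layers = c(names(static), names(dynamic))),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack %dx%d @ %gm, %d days, layers: %s>\n",
              x$grid$nrow, x$grid$ncol, x$grid$cell, length(x$dates),
              paste(x$layers, collapse = ", ")))
  invisible(x)
}

# mark all cells crossed by the segment (x0,y0)-(x1,y1); dense parametric
# sampling at cell/3 steps gives 1-cell-wide rasterized polylines
rasterize_segment <- function(mask, grid, x0, y0, x1, y1) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  tt <- seq(0, 1, length.out = max(2, ceiling(len / (grid$cell / 3))))
  ci <- cell_index(grid, x0 + tt * (x1 - x0), y0 + tt * (y1 - y0))
  ok <- !is.na(ci$row)
  mask[cbind(ci$row[ok], ci$col[ok])] <- 1
  mask
}

disk_mask <- function(grid, cx, cy, radius_m) {
  cc <- cell_center(grid, rep(seq_len(grid$nrow), grid$ncol),
                    rep(seq_len(grid$ncol), each = grid$nrow))
  m <- matrix(as.numeric((cc$x - cx)^2 + (cc$y - cy)^2 <= radius_m^2),
              grid$nrow, grid$ncol)
  m
}

smooth_field <- function(grid, n_bumps, scale_m, seed_offset = 0) {
  # sum of Gaussian bumps, rescaled to [0, 1]
  f <- matrix(0, grid$nrow, grid$ncol)
  cc <- cell_center(grid, rep(seq_len(grid$nrow), grid$ncol),
                    rep(seq_len(grid$ncol), each = grid$nrow))
  w <- grid$ncol * grid$cell; h <- grid$nrow * grid$cell
  for (i in seq_len(n_bumps)) {
    bx <- runif(1, grid$xmin, grid$xmin + w)
    by <- runif(1, grid$ymax - h, grid$ymax)
    s <- runif(1, scale_m / 2, scale_m)
    f <- f + matrix(exp(-((cc$x - bx)^2 + (cc$y - by)^2) / (2 * s^2)),
                    grid$nrow, grid$ncol)
  }
  rng <- range(f)
  if (diff(rng) == 0) return(f * 0)
  (f - rng[1]) / diff(rng)
}

#' Generate a synthetic landscape covariate stack
#'
#' Builds all layers of the standard stack on a square grid: wetland and
#' water patches (disks), 1-cell-wide linear features (road,
#' fence-or-trail, ditch) rasterized from random polylines, a smooth tree
#' canopy fraction, a daily NDVI field (smooth base plus a seasonal trend
#' and day-to-day noise), a daily binary artificial-food layer whose site
#' cells can switch on and off by day, and spatially constant daily
#' weather layers. Food sites are placed in the central third of the
#' extent, the interface zone between social-group territories, so that
#' steered between-group co-locations have resource cells to target.
#'
#' @param extent_m side length of the square landscape in meters; must be
#'   divisible by `cell_size_m`
#' @param cell_size_m cell size (default 30 m)
#' @param n_days number of calendar days of dynamic layers
#' @param n_food_sites number of artificial food sites (0 allowed)
#' @param seed integer seed; identical seeds give identical stacks
#' @param start_date first calendar day
#' @param food_on_prob daily probability a food site is provisioned
#' @return an `env_stack`
#' @export
gen_landscape <- function(extent_m, cell_size_m = 30, n_days = 14,
                          n_food_sites = 6, seed = 1,
                          start_date = as.Date("2020-01-01"),
                          food_on_prob = 0.9) {
  assert_that(extent_m > 0 && cell_size_m > 0, "invalid_argument",
              "extent and cell size must be positive")
  assert_that(extent_m %% cell_size_m == 0, "invalid_argument",
              "extent must be divisible by cell size")
  assert_that(n_days >= 1, "invalid_argument", "n_days must be >= 1")
  set.seed(seed)
  nside <- as.integer(extent_m / cell_size_m)
  grid <- env_grid(nside, nside, cell_size_m, xmin = 0, ymax = extent_m)
  w <- extent_m

  rand_pt <- function(lo = 0.05, hi = 0.95)
    c(runif(1, lo * w, hi * w), runif(1, lo * w, hi * w))

  wetland <- matrix(0, nside, nside)
  for (i in 1:3) {
    p <- rand_pt()
    wetland <- pmax(wetland, disk_mask(grid, p[1], p[2], runif(1, 4, 8) * cell_size_m))
  }
  water <- matrix(0, nside, nside)
  for (i in 1:2) {
    p <- rand_pt(0.2, 0.8)
    water <- pmax(water, disk_mask(grid, p[1], p[2], runif(1, 1, 2.5) * cell_size_m))
  }

  road <- matrix(0, nside, nside)
  rx <- runif(1, 0.2 * w, 0.8 * w)
  road <- rasterize_segment(road, grid, rx, 0, rx + runif(1, -0.1, 0.1) * w, w)
  ry <- runif(1, 0.2 * w, 0.8 * w)
  road <- rasterize_segment(road, grid, 0, ry, w, ry + runif(1, -0.1, 0.1) * w)

  fence <- matrix(0, nside, nside)
  for (i in 1:2) {
    p1 <- rand_pt(0, 1); p2 <- rand_pt(0, 1)
    fence <- rasterize_segment(fence, grid, p1[1], p1[2], p2[1], p2[2])
  }
  ditch <- matrix(0, nside, nside)
  p1 <- c(0, runif(1, 0.1 * w, 0.9 * w)); p2 <- c(w, runif(1, 0.1 * w, 0.9 * w))
  ditch <- rasterize_segment(ditch, grid, p1[1], p1[2], p2[1], p2[2])

  canopy <- smooth_field(grid, 6, w / 4)

  # food sites in the central third (between-territory interface)
  food_sites <- NULL
  if (n_food_sites > 0) {
    fx <- runif(n_food_sites, w / 3, 2 * w / 3)
    fy <- runif(n_food_sites, w / 3, 2 * w / 3)
    ci <- cell_index(grid, fx, fy)
    food_sites <- unique(data.frame(row = ci$row, col = ci$col))
  }

  dates <- seq(start_date, by = "day", length.out = n_days)
  doy <- as.integer(format(dates, "%j"))
  ndvi_base <- smooth_field(grid, 8, w / 5)
  ndvi <- lapply(seq_len(n_days), function(d) {
    v <- 0.25 + 0.5 * ndvi_base + 0.1 * sin(2 * pi * doy[d] / 365) +
      matrix(rnorm(nside * nside, 0, 0.02), nside, nside)
    pmin(pmax(v, 0), 1)
  })
  food <- lapply(seq_len(n_days), function(d) {
    m <- matrix(0, nside, nside)
    if (!is.null(food_sites) && nrow(food_sites)) {
      on <- runif(nrow(food_sites)) < food_on_prob
      if (any(on)) m[cbind(food_sites$row[on], food_sites$col[on])] <- 1
    }
    m
  })
  tmax <- as.list(25 + 8 * sin(2 * pi * (doy - 30) / 365) + rnorm(n_days, 0, 2))
  tmin <- lapply(seq_len(n_days), function(d) tmax[[d]] - runif(1, 5, 12))
  prcp <- as.list(round(rexp(n_days, 1 / 3) * rbinom(n_days, 1, 0.3), 2))
  rhum <- as.list(pmin(pmax(70 + rnorm(n_days, 0, 8), 20), 100))
  vp <- as.list(pmax(1.2 + rnorm(n_days, 0, 0.3), 0.1))

  env <- new_env_stack(
    grid,
    static = list(wetland = wetland, water = water, road = road,
                  fence_or_trail = fence, ditch = ditch,
                  tree_canopy = canopy),
    dynamic = list(ndvi = ndvi, food = food, tmax = tmax, tmin = tmin,
                   prcp = prcp, rhum = rhum, vp = vp),
    dates = dates)
  attr(env, "food_sites") <- food_sites
  attr(env, "seed") <- seed
  env
}

layer_on_date <- function(env, layer, date) {
  i <- match(as.Date(date), env$dates)
  if (is.na(i))
    crsf_stop("missing_data",
              sprintf("no %s raster for date %s", layer, as.character(date)))
  env$dynamic[[layer]][[i]]
}

#' Extract covariate values at points
#'
#' Static layers are sampled at the cell containing each point (half-open
#' cells, origin top-left); dynamic layers are sampled from the raster for
#' the point's own date.
#'
#' @param points data.frame with `x`, `y` and `date` (Date)
#' @param env an `env_stack`
#' @param layers layer names (default: all layers in the stack)
#' @return data.frame of covariate values, one row per point
#' @export
extract_covariates <- function(points, env, layers = env$layers) {
  assert_that(all(c("x", "y", "date") %in% names(points)),
              "invalid_argument", "points need x, y, date columns")
  bad <- setdiff(layers, env$layers)
  assert_that(length(bad) == 0, "invalid_argument",
              paste("unknown layers:", paste(bad, collapse = ", ")))
  ci <- cell_index(env$grid, points$x, points$y)
  assert_that(!anyNA(ci$row), "invalid_argument",
              "some points fall outside the environmental grid")
  dates <- as.Date(points$date)
  di <- match(dates, env$dates)
  if (anyNA(di))
    crsf_stop("missing_data",
              sprintf("no rasters for date(s): %s",
                      paste(unique(as.character(dates[is.na(di)])), collapse = ", ")))
  idx <- cbind(ci$row, ci$col)
  out <- lapply(layers, function(nm) {
    if (nm %in% names(env$static)) return(env$static[[nm]][idx])
    v <- numeric(nrow(points))
    for (d in unique(di)) {
      sel <- di == d
      lay <- env$dynamic[[nm]][[d]]
      v[sel] <- if (length(lay) == 1) as.numeric(lay) else
        lay[idx[sel, , drop = FALSE]]
    }
    v
  })
  names(out) <- layers
  as.data.frame(out)
}

# ---- plain-text raster interchange (ESRI ASCII grid) ---------------------

write_asc <- function(mat, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.6f", grid$xmin),
    sprintf("yllcorner %.6f", grid$ymax - grid$nrow * grid$cell),
    sprintf("cellsize %.6f", grid$cell),
    "NODATA_value -9999"), con)
  write.table(mat, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- lapply(strsplit(hdr, "\\s+"), function(p) as.numeric(p[2]))
  names(kv) <- vapply(strsplit(hdr, "\\s+"), `[`, "", 1)
  m <- as.matrix(read.table(path, skip = 6))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  grid <- env_grid(kv$nrows, kv$ncols, kv$cellsize, xmin = kv$xllcorner,
                   ymax = kv$yllcorner + kv$nrows * kv$cellsize)
  list(mat = m, grid = grid)
}

#' Write / read an environmental stack as text rasters plus a manifest
#'
#' One ESRI ASCII grid per static layer and per gridded layer-day;
#' spatially constant daily layers are stored in the JSON manifest itself.
#'
#' @param env an `env_stack`
#' @param dir output directory
#' @export
write_env_stack <- function(env, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(cell = env$grid$cell, nrow = env$grid$nrow,
                   ncol = env$grid$ncol, xmin = env$grid$xmin,
                   ymax = env$grid$ymax,
                   dates = as.character(env$dates),
                   static = list(), dynamic = list(), constants = list())
  for (nm in names(env$static)) {
    f <- paste0(nm, ".asc")
    write_asc(env$static[[nm]], env$grid, file.path(dir, f))
    manifest$static[[nm]] <- f
  }
  for (nm in names(env$dynamic)) {
    vals <- env$dynamic[[nm]]
    if (all(vapply(vals, length, 0L) == 1)) {
      manifest$constants[[nm]] <- as.numeric(unlist(vals))
    } else {
      files <- sprintf("%s_%s.asc", nm, as.character(env$dates))
      for (i in seq_along(vals))
        write_asc(vals[[i]], env$grid, file.path(dir, files[i]))
      manifest$dynamic[[nm]] <- files
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_env_stack
#' @export
read_env_stack <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  grid <- env_grid(man$nrow, man$ncol, man$cell, xmin = man$xmin,
                   ymax = man$ymax)
  dates <- as.Date(man$dates)
  static <- lapply(man$static, function(f) read_asc(file.path(dir, f))$mat)
  dynamic <- lapply(man$dynamic, function(fs)
    lapply(fs, function(f) read_asc(file.path(dir, f))$mat))
  for (nm in names(man$constants))
    dynamic[[nm]] <- as.list(man$constants[[nm]])
  new_env_stack(grid, static, dynamic, dates)
}
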