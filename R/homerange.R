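#' Kernel-density home range on the analysis grid
#'
#' Gaussian-kernel utilization distribution evaluated at the cell centers
#' of the analysis grid, renormalized so the density integrates to 1 over
#' the grid. Isopleths are defined by cumulative probability mass of
#' ranked cells: the level-q region is the smallest set of highest-density
#' cells whose mass reaches q, which makes isopleths deterministic and
#' nested by construction. The reference (Silverman) bandwidth per
#' coordinate is `sd * n^(-1/6)` unless overridden.
#'
#' @param points data.frame with `x`, `y` (>= 30 points for the default
#'   bandwidth rule)
#' @param grid an [env_grid()]
#' @param isopleth_levels utilization-mass levels (default 95% range and
#'   50% core)
#' @param bandwidth `"reference"` or a numeric length-2 bandwidth in meters
#' @param animal_id carried into the result
#' @return a `home_range`: density surface (per m^2), isopleth cell masks
#'   keyed by level, bandwidth used
#' @export
kde_homerange <- function(points, grid, isopleth_levels = c(0.95, 0.50),
                          bandwidth = "reference", animal_id = NA_character_) {
  n <- nrow(points)
  assert_that(n >= 2, "insufficient_data", "need at least 2 points")
  if (identical(bandwidth, "reference")) {
    assert_that(n >= 30, "insufficient_data",
                "reference bandwidth needs >= 30 points")
    h <- c(sd(points$x), sd(points$y)) * n^(-1 / 6)
  } else h <- rep_len(as.numeric(bandwidth), 2)
  if (any(h <= 0))
    crsf_stop("degenerate_input", "zero bandwidth (all points identical?)")

  xs <- grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cell
  ys <- grid$ymax - (seq_len(grid$nrow) - 0.5) * grid$cell
  kx <- dnorm(outer(xs, points$x, "-") / h[1]) / h[1]   # ncol x n
  ky <- dnorm(outer(ys, points$y, "-") / h[2]) / h[2]   # nrow x n
  dens <- (ky %*% t(kx)) / n
  tot <- sum(dens) * grid$cell^2
  if (tot <= 0) crsf_stop("degenerate_input", "no density mass on the grid")
  dens <- dens / tot

  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(dens[ord]) * grid$cell^2
  isopleths <- list()
  for (q in sort(isopleth_levels)) {
    k <- which(cum >= q)[1]
    if (is.na(k)) k <- length(ord)
    m <- matrix(FALSE, grid$nrow, grid$ncol)
    m[ord[seq_len(k)]] <- TRUE
    isopleths[[sprintf("%g", q)]] <- m
  }
  hr <- structure(list(animal_id = animal_id, grid = grid, density = dens,
                       isopleths = isopleths, bandwidth = h, n = n),
                  class = "home_range")
  stopifnot(abs(sum(dens) * grid$cell^2 - 1) < 1e-3)
  hr
}

#' @export
print.home_range <- function(x, ...) {
  lv <- names(x$isopleths)
  ar <- vapply(lv, function(l) hr_area(x, as.numeric(l)), 0)
  cat(sprintf("<home_range %s: n=%d, h=(%.1f, %.1f) m, %s>\n",
              x$animal_id, x$n, x$bandwidth[1], x$bandwidth[2],
              paste(sprintf("%s%%: %.3f km2", as.numeric(lv) * 100,
                            ar / 1e6), collapse = ", ")))
  invisible(x)
}

level_key <- function(hr, level) {
  key <- sprintf("%g", level)
  assert_that(key %in% names(hr$isopleths), "invalid_argument",
              sprintf("isopleth level %g not present", level))
  key
}

#' Isopleth area in square meters
#' @param hr a `home_range`
#' @param level isopleth level
#' @export
hr_area <- function(hr, level = 0.95) {
  sum(hr$isopleths[[level_key(hr, level)]]) * hr$grid$cell^2
}

new_grid_region <- function(grid, mask) {
  structure(list(grid = grid, mask = mask), class = "grid_region")
}

#' Isopleth region of a home range
#' @inheritParams hr_area
#' @return a `grid_region` (cell mask on the analysis grid)
#' @export
hr_region <- function(hr, level = 0.95) {
  new_grid_region(hr$grid, hr$isopleths[[level_key(hr, level)]])
}

#' Dyadic home-range overlap region
#'
#' Geometric intersection of two level-isopleth regions; possibly empty.
#' Both ranges must be computed on the identical grid.
#'
#' @param hr_a,hr_b `home_range` objects on the same grid
#' @param level isopleth level present in both
#' @return a `grid_region`
#' @export
overlap_region <- function(hr_a, hr_b, level = 0.95) {
  assert_that(identical(hr_a$grid, hr_b$grid), "invalid_argument",
              "home ranges are on incompatible grids")
  ka <- level_key(hr_a, level); kb <- level_key(hr_b, level)
  new_grid_region(hr_a$grid, hr_a$isopleths[[ka]] & hr_b$isopleths[[kb]])
}

#' Bounded overlap index of two home-range cores
#'
#' `area(A intersect B) / min(area(A), area(B))`, in `[0, 1]`.
#' @inheritParams overlap_region
#' @export
overlap_index <- function(hr_a, hr_b, level = 0.50) {
  inter <- sum(overlap_region(hr_a, hr_b, level)$mask)
  amin <- min(sum(hr_a$isopleths[[level_key(hr_a, level)]]),
              sum(hr_b$isopleths[[level_key(hr_b, level)]]))
  if (amin == 0) return(0)
  inter / amin
}

region_area <- function(region) sum(region$mask) * region$grid$cell^2

region_is_empty <- function(region) !any(region$mask)

#' Point-in-region test
#' @param region a `grid_region`
#' @param x,y coordinates
#' @export
region_contains <- function(region, x, y) {
  ci <- cell_index(region$grid, x, y)
  ok <- !is.na(ci$row)
  out <- logical(length(x))
  out[ok] <- region$mask[cbind(ci$row[ok], ci$col[ok])]
  out
}

#' Uniform points inside a region (rejection from the bounding box)
#' @param region a `grid_region`
#' @param n number of points
#' @return data.frame with `x`, `y`
#' @export
sample_region <- function(region, n) {
  assert_that(!region_is_empty(region), "degenerate_input", "empty region")
  g <- region$grid
  w <- which(region$mask, arr.ind = TRUE)
  rr <- range(w[, 1]); cc <- range(w[, 2])
  xlo <- g$xmin + (cc[1] - 1) * g$cell; xhi <- g$xmin + cc[2] * g$cell
  yhi <- g$ymax - (rr[1] - 1) * g$cell; ylo <- g$ymax - rr[2] * g$cell
  out_x <- numeric(0); out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- max(2 * (n - length(out_x)), 100)
    px <- runif(m, xlo, xhi); py <- runif(m, ylo, yhi)
    keep <- region_contains(region, px, py)
    out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
  }
  data.frame(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Export a region as a GeoJSON MultiPolygon of grid cells
#' @param region a `grid_region`
#' @param path output path
#' @export
write_region_geojson <- function(region, path) {
  g <- region$grid
  w <- which(region$mask, arr.ind = TRUE)
  polys <- lapply(seq_len(nrow(w)), function(i) {
    r <- w[i, 1]; c <- w[i, 2]
    x0 <- g$xmin + (c - 1) * g$cell; x1 <- x0 + g$cell
    y1 <- g$ymax - (r - 1) * g$cell; y0 <- y1 - g$cell
    list(list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))))
  })
  gj <- list(type = "Feature", properties = list(cell = g$cell),
             geometry = list(type = "MultiPolygon", coordinates = polys))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
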