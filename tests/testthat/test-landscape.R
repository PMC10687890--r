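test_that("landscape generation is deterministic and obeys layer invariants", {
  e1 <- gen_landscape(900, 30, n_days = 3, n_food_sites = 4, seed = 42)
  e2 <- gen_landscape(900, 30, n_days = 3, n_food_sites = 4, seed = 42)
  expect_identical(e1$static, e2$static)
  expect_identical(e1$dynamic, e2$dynamic)
  expect_equal(e1$grid$cell, 30)
  expect_equal(e1$grid$nrow, 30)
  for (nm in c("wetland", "water", "road", "fence_or_trail", "ditch"))
    expect_true(all(e1$static[[nm]] %in% c(0, 1)), label = nm)
  expect_true(all(e1$static$tree_canopy >= 0 & e1$static$tree_canopy <= 1))
  for (nm in names(e1$dynamic))
    expect_length(e1$dynamic[[nm]], 3)
})

test_that("zero food sites give an all-zero food layer every day", {
  e <- gen_landscape(600, 30, n_days = 2, n_food_sites = 0, seed = 1)
  for (d in 1:2) expect_true(all(e$dynamic$food[[d]] == 0))
})

test_that("invalid landscape arguments are rejected", {
  expect_error(gen_landscape(-300, 30, 2, 1, 1), class = "invalid_argument")
  expect_error(gen_landscape(1000, 30, 2, 1, 1), class = "invalid_argument")
  expect_error(gen_landscape(900, 30, 0, 1, 1), class = "invalid_argument")
})

test_that("cell lookup uses half-open cells with top-left origin", {
  g <- env_grid(10, 10, 10, xmin = 0, ymax = 100)
  # interior point
  expect_equal(cell_index(g, 5, 95), data.frame(row = 1L, col = 1L))
  # point exactly on a right/bottom cell edge belongs to the next cell
  expect_equal(cell_index(g, 10, 95)$col, 2L)
  expect_equal(cell_index(g, 5, 90)$row, 2L)
  # outside
  expect_true(is.na(cell_index(g, 101, 50)$col))
  expect_true(is.na(cell_index(g, 50, -0.001)$row))
})

test_that("covariate extraction honors static and dynamic semantics", {
  env <- tiny_env()
  g <- env$grid
  road_pt <- contactRSF:::cell_center(g, 5, 3)
  pts <- data.frame(x = road_pt$x, y = road_pt$y,
                    date = as.Date("2020-01-01"))
  expect_equal(extract_covariates(pts, env, "road")$road, 1)
  # dynamic layer differs by date at the same location
  fd <- contactRSF:::cell_center(g, 2, 2)
  p2 <- data.frame(x = rep(fd$x, 2), y = rep(fd$y, 2),
                   date = as.Date(c("2020-01-01", "2020-01-02")))
  expect_equal(extract_covariates(p2, env, "food")$food, c(1, 0))
  # spatially constant daily layers
  expect_equal(extract_covariates(p2, env, "tmax")$tmax, c(21, 22))
  # date outside the stack names the date
  p3 <- data.frame(x = fd$x, y = fd$y, date = as.Date("2021-06-01"))
  expect_error(extract_covariates(p3, env, "food"),
               "2021-06-01", class = "missing_data")
  # point outside the grid
  p4 <- data.frame(x = 1e6, y = 0, date = as.Date("2020-01-01"))
  expect_error(extract_covariates(p4, env, "road"),
               class = "invalid_argument")
})

test_that("environmental stacks round-trip through text rasters", {
  e <- gen_landscape(600, 30, n_days = 2, n_food_sites = 3, seed = 9)
  d <- tempfile()
  write_env_stack(e, d)
  e2 <- read_env_stack(d)
  expect_equal(e2$grid, e$grid)
  expect_equal(e2$dates, e$dates)
  # values identical after one serialization cycle
  expect_equal(e2$static$tree_canopy, e$static$tree_canopy,
               tolerance = 1e-12)
  expect_identical(e2$static$road, e$static$road)
  expect_equal(e2$dynamic$ndvi[[2]], e$dynamic$ndvi[[2]], tolerance = 1e-12)
  expect_equal(unlist(e2$dynamic$tmax), unlist(e$dynamic$tmax))
  unlink(d, recursive = TRUE)
})
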