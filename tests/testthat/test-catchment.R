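test_that("fill_depressions raises pits to spill level and is idempotent", {
  # drained DEM: untouched
  plane <- mp_raster(outer(1:5, 1:5, function(r, c) r + c))
  expect_equal(fill_depressions(plane)$values, plane$values)

  # 5x5 with an interior pit at 1 ringed by 5s; outer edge at 3
  m <- matrix(3, 5, 5)
  m[2:4, 2:4] <- 5
  m[3, 3] <- 1
  filled <- fill_depressions(mp_raster(m))
  expect_equal(filled$values[3, 3], 5)  # raised to the ring spill level
  expect_true(all(filled$values >= m))
  expect_equal(fill_depressions(filled)$values, filled$values)

  expect_error(fill_depressions(mp_raster(matrix(NA_real_, 3, 3))),
               "nodata")
})

test_that("every cell drains to the edge after filling (random DEMs)", {
  for (seed in 1:3) expect_monotone_path_to_edge(random_dem(7, seed))
})

test_that("d8 picks the steepest descent with fixed tie-breaking", {
  # uniform east-sloping plane: interior cells all point east (code 1)
  plane <- mp_raster(outer(1:4, 4:1, function(r, c) c + 0))
  dir <- d8_flow_direction(plane)
  expect_true(all(dir$values[, 1:3] == 1))
  expect_true(all(dir$values[, 4] == 0))  # east edge: outlets

  # centre 5 with neighbours E,SE,S,SW,W,NW,N,NE = 4,3,2,6,7,8,9,1
  m <- matrix(0, 3, 3)
  m[2, 2] <- 5
  m[2, 3] <- 4; m[3, 3] <- 3; m[3, 2] <- 2; m[3, 1] <- 6
  m[2, 1] <- 7; m[1, 1] <- 8; m[1, 2] <- 9; m[1, 3] <- 1
  dir <- d8_flow_direction(mp_raster(m))
  # steepest drop/distance: S (drop 3 / 1 = 3) beats NE (drop 4 / sqrt 2)
  expect_equal(dir$values[2, 2], 4L)

  # symmetric tie: equal drops E and S -> first in ordering (E)
  m2 <- matrix(5, 3, 3)
  m2[2, 3] <- 1; m2[3, 2] <- 1
  dir2 <- d8_flow_direction(mp_raster(m2))
  expect_equal(dir2$values[2, 2], 1L)
  # determinism
  expect_identical(dir2$values, d8_flow_direction(mp_raster(m2))$values)
})

test_that("flow accumulation matches hand traces and conserves mass", {
  # single-file west-to-east chain
  chain <- mp_raster(matrix(5:1, 1, 5))
  dir <- d8_flow_direction(chain)
  acc <- flow_accumulation(dir)
  expect_equal(acc$values[1, ], c(1, 2, 3, 4, 5))

  # all independent outlets: flat single row is resolved to drain, so use
  # nodata-separated cells
  m <- matrix(c(1, NA, 1, NA, 1), 1, 5)
  dirs <- d8_flow_direction(mp_raster(m))
  accs <- flow_accumulation(dirs)
  expect_equal(accs$values[1, c(1, 3, 5)], c(1, 1, 1))

  # fully convergent basin: outlet accumulation = cell count
  land <- gen_toy_landscape(15, seed = 4)
  dir <- d8_flow_direction(fill_depressions(land$dem))
  acc <- flow_accumulation(dir)
  outlets <- which(dir$values == 0, arr.ind = TRUE)
  expect_equal(sum(acc$values[outlets]), sum(!is.na(dir$values)))

  # cycle detection
  cyc <- mp_raster(matrix(1, 1, 2))
  dirbad <- d8_flow_direction(cyc)
  dirbad$values <- matrix(c(1L, 16L), 1, 2)  # E and W: two-cell cycle
  expect_error(flow_accumulation(dirbad), "cycle")
})

test_that("flow accumulation equals the path-tracing oracle on random DEMs", {
  for (seed in 1:5) {
    dem <- random_dem(8, seed)
    dir <- d8_flow_direction(fill_depressions(dem))
    acc <- flow_accumulation(dir)
    expect_equal(acc$values, accumulation_oracle(dir$values))
  }
})

test_that("pour point takes the accumulation argmax with buffer and ties", {
  chain <- mp_raster(matrix(5:1, 1, 5))
  acc <- flow_accumulation(d8_flow_direction(chain))
  mask_last <- mp_raster(matrix(c(0, 0, 0, 0, 1), 1, 5))
  expect_equal(find_pour_point(acc, mask_last), c(1L, 5L))

  # mask covering cell 3 only; buffer 1 reaches the higher-accumulation cell 4
  mask_mid <- mp_raster(matrix(c(0, 0, 1, 0, 0), 1, 5))
  expect_equal(find_pour_point(acc, mask_mid), c(1L, 3L))
  expect_equal(find_pour_point(acc, mask_mid, buffer_px = 1), c(1L, 4L))

  # two equal maxima: first in row-major order
  acc2 <- mp_raster(matrix(c(1, 7, 3, 7), 2, 2, byrow = TRUE))
  mask_all <- mp_raster(matrix(1, 2, 2))
  expect_equal(find_pour_point(acc2, mask_all), c(1L, 2L))

  expect_error(find_pour_point(acc, mp_raster(matrix(0, 1, 5))), "empty")
})

test_that("watershed equals the path-tracing oracle, nests and is disjoint", {
  # fully convergent toy DEM: watershed of the outlet is the whole grid
  land <- gen_toy_landscape(11, seed = 9)
  dir <- d8_flow_direction(fill_depressions(land$dem))
  outlet <- which(dir$values == 0, arr.ind = TRUE)[1, ]
  ws <- delineate_watershed(dir, outlet)
  expect_true(all(ws$values == 1))

  # ridge-top cell with nothing upstream
  acc <- flow_accumulation(dir)
  ridge <- which(acc$values == 1, arr.ind = TRUE)[1, ]
  ws_ridge <- delineate_watershed(dir, ridge)
  expect_equal(sum(ws_ridge$values), 1)

  for (seed in 6:8) {
    dem <- random_dem(8, seed)
    dir <- d8_flow_direction(fill_depressions(dem))
    # oracle agreement at an arbitrary interior cell
    ws <- delineate_watershed(dir, c(4, 4))
    expect_equal(ws$values, watershed_oracle(dir$values, c(4, 4)))
    # nesting: watershed of a cell's target contains the cell's watershed
    code <- dir$values[4, 4]
    if (!is.na(code) && code != 0) {
      k <- match(code, d8_offsets$code)
      down <- c(4 + d8_offsets$dr[k], 4 + d8_offsets$dc[k])
      ws_down <- delineate_watershed(dir, down)
      expect_true(all(ws_down$values[ws$values == 1] == 1))
    }
    # disjointness of distinct outlet watersheds and mass conservation
    outlets <- which(dir$values == 0, arr.ind = TRUE)
    total <- matrix(0, 8, 8)
    for (i in seq_len(nrow(outlets)))
      total <- total + delineate_watershed(dir, outlets[i, ])$values
    expect_true(all(total <= 1))
    expect_equal(sum(total), sum(!is.na(dir$values)))
  }
})

test_that("land-cover proportions count pixels and exclude nodata", {
  lc <- mp_raster(matrix(c(1, 1, 1, 2, 2, 3, 3, 3, NA, 3), 2, 5))
  mask <- mp_raster(matrix(1, 2, 5))
  s <- summarize_landcover(lc, mask, c(`1` = "forest", `2` = "urban"))
  expect_equal(s$forest_prop, 3 / 9)
  expect_equal(s$urban_prop, 2 / 9)

  all_forest <- summarize_landcover(mp_raster(matrix(1, 2, 2)),
                                    mp_raster(matrix(1, 2, 2)),
                                    c(`1` = "forest"))
  expect_equal(all_forest$forest_prop, 1)
  expect_error(summarize_landcover(lc, mp_raster(matrix(0, 2, 5)),
                                   c(`1` = "forest")), "empty")
})

test_that("wastewater loads sum over plants falling inside the mask", {
  mask <- mp_raster(matrix(c(1, 0, 0, 1), 2, 2), cell_size_m = 10)
  # mask cells: (1,1) covers x 0-10, y 10-20; (2,2) covers x 10-20, y 0-10
  pts <- data.frame(x = c(5, 15, 15), y = c(15, 15, 5),
                    load_pe = c(1000, 99, 2500))
  expect_equal(sum_wwtw_load(pts, mask), 3500)
  expect_equal(sum_wwtw_load(pts[2, ], mask), 0)
  expect_equal(sum_wwtw_load(NULL, mask), 0)
  # boundary point belongs to the half-open cell containing it
  expect_equal(sum_wwtw_load(data.frame(x = 10, y = 0, load_pe = 7), mask), 7)
})
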