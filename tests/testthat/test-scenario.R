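test_that("minimal hand-written scenario loads and cross-references resolve", {
  dir <- withr::local_tempdir()
  write_minimal_scenario(dir)
  b <- load_scenario(dir)
  expect_s3_class(b, "scenario_bundle")
  expect_equal(nrow(b$network$reaches), 2)
  expect_equal(length(b$orchards), 1)
  expect_equal(b$network$reaches$strahler_order, c(1L, 1L))
  expect_equal(length(b$discharge), 8760)
  expect_equal(b$discharge[1], 0.1 * 3600)
})

test_that("schema violations are reported by field name", {
  dir <- withr::local_tempdir()
  write_minimal_scenario(dir, drop_field = "manning_n")
  expect_error(load_scenario(dir), "manning_n")
})

test_that("topology errors are caught: cycles, dangling ids, multiple outlets", {
  base <- data.frame(
    id = c("a", "b", "c"), length = 100, bottom_width = 1, bank_slope = 1,
    manning_n = 0.035, longitudinal_slope = 0.002,
    downstream_id = c("b", "a", NA), drainage_area = c(1e5, 1e5, 3e5),
    drift_surface_width = 1, stringsAsFactors = FALSE
  )
  expect_error(reach_network(base), "cycle")
  base$downstream_id <- c(NA, "zz", NA)
  expect_error(reach_network(base), "outlet|dangling")
  base$downstream_id <- c("c", "c", NA)
  base$drainage_area <- c(1e5, 1e5, 3e5)
  expect_s3_class(reach_network(base), "reach_network")
})

test_that("drainage area must not decrease downstream", {
  df <- data.frame(
    id = c("up", "down"), length = 100, bottom_width = 1, bank_slope = 1,
    manning_n = 0.035, longitudinal_slope = 0.002,
    downstream_id = c("down", NA), drainage_area = c(2e5, 1e5),
    drift_surface_width = 1, stringsAsFactors = FALSE
  )
  expect_error(reach_network(df), "drainage_area")
})

test_that("temperature preprocessing is a trailing 3-day mean with padding", {
  x <- c(10, 12, 14, 16)
  out <- trailing_3day_mean(x)
  expect_equal(out[4], 12) # mean of days 1-3
  expect_equal(out[1:3], rep(12, 3)) # padded with first available mean
  # brute force on a longer random series
  set.seed(42)
  y <- rnorm(50, 10, 4)
  out <- trailing_3day_mean(y)
  for (t in 4:50) expect_equal(out[t], mean(y[(t - 3):(t - 1)]))
})

test_that("Strahler: chains stay order 1 and equal-order junctions increment", {
  chain <- make_chain_network(5)
  expect_equal(chain$reaches$strahler_order, rep(1L, 5))
  # two order-1 branches joining -> order 2 downstream
  df <- data.frame(
    id = c("out", "l", "r"), length = 100, bottom_width = 1, bank_slope = 1,
    manning_n = 0.035, longitudinal_slope = 0.002,
    downstream_id = c(NA, "out", "out"), drainage_area = c(2e5, 1e5, 1e5),
    drift_surface_width = 1, stringsAsFactors = FALSE
  )
  net <- reach_network(df)
  expect_equal(net$reaches$strahler_order[net$reaches$id == "out"], 2L)
})

test_that("Strahler orders match a recursive brute-force oracle on random trees", {
  set.seed(101)
  for (k in 1:50) {
    n <- sample(2:40, 1)
    parent <- random_parent_tree(n)
    net <- network_from_parents(parent)
    expect_equal(net$reaches$strahler_order, strahler_oracle(parent))
  }
})

test_that("geometry lookup by Strahler order sets attributes and errors on gaps", {
  df <- data.frame(
    id = c("out", "l", "r"), length = c(50, 100, 100), bottom_width = 1,
    bank_slope = 1, manning_n = 0.035, longitudinal_slope = 0.002,
    downstream_id = c(NA, "out", "out"), drainage_area = c(2e5, 1e5, 1e5),
    drift_surface_width = 1, stringsAsFactors = FALSE
  )
  net <- reach_network(df)
  lookup <- data.frame(order = 1:2, bottom_width = c(1, 2), bank_slope = 1,
                       manning_n = 0.03, drift_surface_width = c(1, 2))
  out <- assign_geometry_by_strahler(net, lookup)
  expect_equal(out$reaches$bottom_width[out$reaches$id == "out"], 2)
  expect_equal(out$reaches$bottom_width[out$reaches$id == "l"], 1)
  expect_equal(out$reaches$length, df$length) # untouched
  expect_error(assign_geometry_by_strahler(net, lookup[1, ]),
               "missing Strahler order")
  # identity lookup leaves the network uniform
  uni <- assign_geometry_by_strahler(net, data.frame(
    order = 1:2, bottom_width = 3, bank_slope = 1, manning_n = 0.03,
    drift_surface_width = 2))
  expect_true(all(uni$reaches$bottom_width == 3))
})

test_that("synthetic generator: single reach, valid networks, length bounds", {
  b1 <- generate_synthetic_catchment(1, seed = 3,
                                     period = simulation_period(0, 1))
  expect_equal(nrow(b1$network$reaches), 1)
  expect_true(is.na(b1$network$reaches$downstream_id))
  b <- generate_synthetic_catchment(120, seed = 11,
                                    period = simulation_period(0, 1))
  expect_silent(validate_network(b$network))
  r <- b$network$reaches
  expect_true(all(r$length >= 5 & r$length <= 110))
  expect_equal(median(r$length), 100, tolerance = 0.1)
  expect_equal(sum(is.na(r$downstream_id)), 1)
})

test_that("synthetic generator is deterministic: same seed, identical serialization", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- generate_synthetic_catchment(30, seed = 5, period = simulation_period(0, 1))
  b2 <- generate_synthetic_catchment(30, seed = 5, period = simulation_period(0, 1))
  write_scenario(b1, d1); write_scenario(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  b3 <- generate_synthetic_catchment(30, seed = 6, period = simulation_period(0, 1))
  expect_false(identical(b1$network$reaches$length, b3$network$reaches$length))
})

test_that("headwater (order-1) share is near the configured landscape composition", {
  shares <- vapply(1:5, function(s) {
    b <- generate_synthetic_catchment(200, seed = s,
                                      period = simulation_period(0, 1))
    mean(b$network$reaches$strahler_order == 1)
  }, numeric(1))
  expect_gt(mean(shares), 0.45)
  expect_lt(mean(shares), 0.65)
})

test_that("scenario serialization round-trips through load_scenario", {
  dir <- withr::local_tempdir()
  b <- generate_synthetic_catchment(15, seed = 9, period = simulation_period(0, 1))
  write_scenario(b, dir)
  b2 <- load_scenario(dir)
  expect_equal(b2$network$reaches$strahler_order, b$network$reaches$strahler_order)
  expect_equal(b2$network$reaches$drainage_area, b$network$reaches$drainage_area,
               tolerance = 1e-6)
  expect_equal(length(b2$orchards), length(b$orchards))
  expect_equal(b2$discharge, b$discharge, tolerance = 1e-5)
  expect_equal(b2$substance$koc, b$substance$koc)
})

test_that("wind rose validation rejects bad probability vectors", {
  expect_error(wind_rose(c(0, 180), c(180, 360), c(0.5, 0.4)), "sum to 1")
  expect_error(wind_rose(c(0, 180), c(180, 360), c(-0.1, 1.1)), ">= 0")
  expect_error(wind_rose(c(0, 90), c(90, 270), c(0.5, 0.5)), "partition")
})
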