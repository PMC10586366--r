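test_that("dissolved fraction follows two-phase equilibrium", {
  s <- inert_substance(koc = 1000, suspended_solids = 0)
  expect_equal(dissolved_fraction(s), 1) # no sorbent
  s2 <- substance_properties(koc = 1.024e6, dt50_water = 1000,
                             dt50_sediment = 43.9, foc_suspended = 0.1,
                             suspended_solids = 1.5e-5)
  expect_equal(dissolved_fraction(s2), 1 / (1 + 1.536))
  s3 <- substance_properties(koc = 1e15, dt50_water = 1, dt50_sediment = 1)
  expect_lt(dissolved_fraction(s3), 1e-6) # koc -> Inf limit
})

test_that("degradation halves mass over one half-life and obeys Arrhenius", {
  s <- substance_properties(koc = 1000, dt50_water = 43.9, dt50_sediment = 43.9,
                            ref_temp = 20)
  expect_equal(degrade(100, 43.9, 20, s, dt = 43.9 * 24), 50)
  expect_equal(degrade(100, 1000, 20, s, dt = 1000 * 24), 50)
  # zero activation energy: temperature has no effect
  s0 <- substance_properties(koc = 1000, dt50_water = 10, dt50_sediment = 10,
                             molar_activation_energy = 0)
  expect_equal(degrade(100, 10, 5, s0, 24), degrade(100, 10, 30, s0, 24))
  # warmer water degrades faster with positive activation energy
  expect_lt(degrade(100, 10, 25, s, 24), degrade(100, 10, 15, s, 24))
})

test_that("step_reach: no input and no initial mass leaves state unchanged", {
  s <- inert_substance()
  reach <- make_chain_network(1)$reaches[1, ]
  out <- step_reach(list(water_mass = 0, sediment_mass = 0), 0, 0,
                    list(discharge = 100, volume = 50), s, 15, reach)
  expect_equal(out$state$water_mass, 0)
  expect_equal(out$state$sediment_mass, 0)
  expect_equal(out$cw_avg, 0)
})

test_that("single-reach pulse follows the CSTR closed form", {
  net <- make_chain_network(1, length = 100)
  b <- make_bundle(net, q_outlet_m3h = 360, assess = 1)
  M0 <- 1000 # ug
  h0 <- 1000L
  res <- route_network(b, pulse_drift("r1", h0, M0))
  # analytic: V from the same Manning geometry at constant Q
  V <- channel_area(solve_depth_manning(360, net$reaches[1, ]), 1, 1) * 100
  a <- 360 / V # 1/h
  k <- 0:400
  # hourly average of (M0/V) exp(-a t) over [k, k+1] after the pulse, ug/L
  analytic <- M0 / V / 1000 * (exp(-a * k) - exp(-a * (k + 1))) / a
  got <- res$field$cw[1, (h0 + 1):(h0 + 401)]
  expect_equal(got, analytic, tolerance = 1e-3)
  expect_true(all(res$field$cw[1, 1:h0] == 0))
  # and the pulse is (eventually) fully exported at the outlet
  expect_equal(res$ledger$exported_at_outlet + res$ledger$stored, M0,
               tolerance = 1e-9 * M0)
})

test_that("water-sediment exchange conserves mass and relaxes to equilibrium partitioning", {
  net <- make_chain_network(1, length = 100)
  s <- substance_properties(koc = 100, dt50_water = 1e9, dt50_sediment = 1e9,
                            molar_activation_energy = 1e-9,
                            sed_exchange_velocity = 1, # fast exchange, m/d
                            suspended_solids = 0)
  b <- make_bundle(net, q_outlet_m3h = 0, assess = 1, substance = s)
  M0 <- 500
  res <- route_network(b, pulse_drift("r1", 0L, M0), keep_sediment = TRUE)
  # advection and volatilization off: no mass leaves the reach system
  expect_equal(res$ledger$exported_at_outlet, 0)
  expect_equal(res$ledger$volatilized, 0)
  expect_lt(ledger_closure_error(res$ledger), 1e-9)
  expect_equal(res$ledger$stored, M0, tolerance = 1e-6) # dt50 quasi-infinite
  # equilibrium split: fd * W / cap_w = S / cap_sed
  r <- net$reaches[1, ]
  V <- channel_area(0.01, r$bottom_width, r$bank_slope) * r$length # floor depth
  cap_w <- V * 1000
  v_sed <- r$bottom_width * r$length * s$sediment_depth
  cap_sed <- 1000 * v_sed * (s$sediment_porosity +
                               s$sediment_bulk_density * s$koc * s$foc_sediment)
  ratio_expected <- cap_sed / cap_w # fd = 1
  # recover final masses from the kernel outputs
  lastW <- res$field$cw[1, ncol(res$field$cw)] * cap_w # approx end-state
  expect_gt(res$field$csed[1, ncol(res$field$csed)], 0)
  # exact end-state from the returned ledger components is stored only in
  # aggregate; check the relaxation via the last-hour concentrations
  S_over_W <- unname(res$field$csed[1, 8760] * s$sediment_bulk_density *
                       1000 * v_sed / lastW)
  expect_equal(S_over_W, ratio_expected, tolerance = 1e-3)
})

test_that("network routing: chain pulse exports fully; reachability determines exposure", {
  # 3-reach chain, pulse at the headwater, no losses
  net <- make_chain_network(3)
  b <- make_bundle(net, q_outlet_m3h = 720, assess = 1)
  M0 <- 2000
  res <- route_network(b, pulse_drift("r3", 100L, M0))
  expect_equal(res$ledger$exported_at_outlet + res$ledger$stored, M0,
               tolerance = 1e-9 * M0)
  expect_lt(res$ledger$stored, 1e-6 * M0) # flushed by year end
  # all reaches downstream of the pulse see mass; a Y-network branch does not
  df <- data.frame(
    id = c("out", "mid", "left", "right"), length = 100, bottom_width = 1,
    bank_slope = 1, manning_n = 0.035, longitudinal_slope = 0.002,
    downstream_id = c(NA, "out", "mid", "mid"),
    drainage_area = c(4e5, 3e5, 1e5, 1e5),
    drift_surface_width = 1, stringsAsFactors = FALSE
  )
  netY <- reach_network(df)
  bY <- make_bundle(netY, q_outlet_m3h = 500, assess = 1)
  resY <- route_network(bY, pulse_drift("left", 50L, 100))
  tot <- rowSums(resY$field$cw)
  expect_gt(tot[["left"]], 0)
  expect_gt(tot[["mid"]], 0)
  expect_gt(tot[["out"]], 0)
  expect_identical(tot[["right"]], 0) # not downstream of the source
})

test_that("zero drift gives a zero field and an all-zero ledger", {
  net <- make_chain_network(2)
  b <- make_bundle(net, assess = 1)
  res <- route_network(b, pulse_drift(character(0), integer(0), numeric(0)))
  expect_true(all(res$field$cw == 0))
  expect_equal(ledger_closure_error(res$ledger), 0)
  expect_equal(res$ledger$input, 0)
})

test_that("mass ledger closes with all processes active", {
  b <- generate_synthetic_catchment(30, seed = 17,
                                    period = simulation_period(1, 2))
  d <- generate_drift_series(b, seed = 17)
  expect_gt(nrow(d), 0)
  res <- route_network(b, d)
  expect_lt(ledger_closure_error(res$ledger), 1e-6)
  expect_true(all(res$field$cw >= 0))
})

test_that("fate is linear: scaling drift scales every concentration", {
  b <- generate_synthetic_catchment(25, seed = 19,
                                    period = simulation_period(0, 1))
  d <- generate_drift_series(b, seed = 19)
  res1 <- route_network(b, d)
  d2 <- d; d2$mass_ug <- 2 * d$mass_ug
  res2 <- route_network(b, d2)
  nz <- res1$field$cw > 0
  expect_true(any(nz))
  expect_equal(res2$field$cw[nz] / res1$field$cw[nz], rep(2, sum(nz)),
               tolerance = 1e-9)
  expect_identical(res2$field$cw[!nz], res1$field$cw[!nz])
})

test_that("peak concentration does not increase downstream of a single pulse", {
  net <- make_chain_network(5)
  b <- make_bundle(net, q_outlet_m3h = 900, assess = 1)
  res <- route_network(b, pulse_drift("r5", 200L, 1000))
  peaks <- apply(res$field$cw, 1, max)
  # downstream order: r5 (dosed) -> r4 -> ... -> r1
  expect_true(all(diff(peaks[c("r5", "r4", "r3", "r2", "r1")]) <= 1e-12))
})

test_that("concentration pulses are peaky and short relative to residence time", {
  net <- make_chain_network(1)
  b <- make_bundle(net, q_outlet_m3h = 600, assess = 1)
  res <- route_network(b, pulse_drift("r1", 500L, 1000))
  cw <- res$field$cw[1, ]
  peak <- max(cw)
  t_above <- sum(cw > 0.5 * peak) # hours
  V <- channel_area(solve_depth_manning(600, net$reaches[1, ]), 1, 1) * 100
  rt_hours <- residence_time(V, 600) / 60
  expect_lte(t_above, max(1, 10 * rt_hours))
})

test_that("step_reach agrees with the routing kernel on a single reach-hour", {
  s <- substance_properties(koc = 5e4, dt50_water = 30, dt50_sediment = 100,
                            sed_exchange_velocity = 0.05)
  net <- make_chain_network(1)
  b <- make_bundle(net, q_outlet_m3h = 360, assess = 1, substance = s,
                   temp = 15)
  res <- route_network(b, pulse_drift("r1", 0L, 100))
  r <- net$reaches[1, ]
  d <- solve_depth_manning(360, r)
  V <- channel_area(d, r$bottom_width, r$bank_slope) * r$length
  one <- step_reach(list(water_mass = 0, sediment_mass = 0),
                    upstream_inflow_mass = 0, drift_mass = 100,
                    hydro = list(discharge = 360, volume = V),
                    substance = s, temperature = 15, reach = r)
  expect_equal(unname(res$field$cw[1, 1]), one$cw_avg, tolerance = 1e-10)
})
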