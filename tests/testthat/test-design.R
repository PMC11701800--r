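test_that("physiological ranges validate their windows", {
  r <- physiological_ranges()
  expect_equal(r$velocity_window, c(0.1e-6, 5e-6))
  expect_equal(r$wss_window, c(0.1e-3, 10e-3))
  expect_error(physiological_ranges(velocity_window = c(5e-6, 1e-7)),
               "lower < upper")
  expect_error(physiological_ranges(wss_window = c(-1, 1)), "lower < upper")
})

test_that("sweep reproduces the operating-point selection narrative", {
  sw <- get_default_sweep()
  tab <- sw$table
  expect_equal(tab$Q_uL_min, c(1, 3, 5, 10))
  # Q = 1 uL/min: shear stimulus below the 0.1 mPa floor
  expect_false(tab$wss_ok[tab$Q_uL_min == 1])
  expect_lt(tab$wss_stat_mPa[tab$Q_uL_min == 1], 0.1)
  # Q = 10 uL/min: interstitial velocity above the restrictive window
  expect_false(tab$velocity_ok[tab$Q_uL_min == 10])
  expect_gt(tab$max_top_velocity_um_s[tab$Q_uL_min == 10], 5)
  # intermediate rates feasible; recommendation is the largest feasible
  expect_true(all(tab$feasible[tab$Q_uL_min %in% c(3, 5)]))
  expect_true(sw$recommendation$feasible)
  expect_equal(sw$recommendation$Q_uL_min, 5)
})

test_that("feasibility transitions are monotone across the sweep", {
  tab <- get_default_sweep()$table
  # velocity and WSS metrics increase strictly with Q (Stokes linearity)
  expect_true(all(diff(tab$max_top_velocity_um_s) > 0))
  expect_true(all(diff(tab$wss_stat_mPa) > 0))
  # velocity_ok switches true -> false at most once going up in Q
  v <- tab$velocity_ok
  expect_lte(sum(diff(as.integer(v)) != 0), 1)
  # sub-floor WSS failure occurs only at the low end
  w <- tab$wss_ok
  expect_true(all(which(!w) <= min(which(w))))
  # oxygen drop decreases with Q (shorter residence time)
  expect_true(all(diff(tab$drop_array_pts) < 0))
  expect_true(all(diff(tab$drop_flat_pts) < 0))
})

test_that("recommendation rules and the no-feasible case behave as
          documented", {
  sw <- get_default_sweep()
  expect_equal(recommend_flow_rate(sw, "largest")$Q_uL_min, 5)
  expect_equal(recommend_flow_rate(sw, "smallest")$Q_uL_min, 3)
  sw_none <- sw
  sw_none$table$feasible <- FALSE
  rec <- recommend_flow_rate(sw_none)
  expect_false(rec$feasible)
  expect_true(is.na(rec$Q))
  expect_match(rec$message, "no feasible")
})

test_that("report tables are complete, unit-labelled and linear in Q", {
  sw <- get_default_sweep()
  tabs <- generate_report_tables(sw)
  expect_named(tabs, c("velocity_sweep", "wss_sweep", "probe_velocity",
                       "beam_wss", "oxygen_summary"))
  expect_equal(nrow(tabs$velocity_sweep), 4)
  expect_equal(nrow(tabs$probe_velocity), 27)
  expect_equal(nrow(tabs$beam_wss), 27)
  expect_true(all(vapply(tabs, function(t)
    !is.null(attr(t, "config_hash")), logical(1))))
  # velocity sweep values scale with Q
  v <- tabs$velocity_sweep$max_top_velocity_um_s
  q <- tabs$velocity_sweep$Q_uL_min
  expect_equal(v / q, rep(v[1] / q[1], 4), tolerance = 1e-6)
})

test_that("evaluating a single rate agrees with its sweep entry", {
  sw <- get_default_sweep()
  op <- evaluate_operating_point("5 uL/min", cfg = sw$cfg, base = sw$base)
  row <- sw$table[sw$table$Q_uL_min == 5, ]
  expect_equal(op$max_top_velocity * 1e6, row$max_top_velocity_um_s)
  expect_equal(op$wss_stat * 1e3, row$wss_stat_mPa)
  expect_equal(op$drops$array_points, row$drop_array_pts)
  expect_true(op$feasible)
})
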