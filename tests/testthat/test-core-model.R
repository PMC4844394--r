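p0 <- model_parameters()

test_that("parameter validation enforces the physical domain", {
  expect_s3_class(p0, "ca_params")
  expect_error(model_parameters(p_ipx = -1), "> 0")
  expect_error(model_parameters(c1 = 0), "c1")
  expect_error(model_parameters(c1 = 1.5), "c1")
  expect_error(model_parameters(h0 = 1.2), "h0")
  expect_error(model_parameters(j_in = -0.1), "j_in")
  # ci0 may not exceed the zero-gradient concentration c0/(1+c1)
  expect_error(model_parameters(ci0 = 7), "ci0")
})

test_that("parameters round-trip through YAML and JSON", {
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_parameters(p0, path)
    p2 <- read_parameters(path)
    expect_equal(unclass(p2), unclass(p0))
  }
})

test_that("open probability obeys its limits and half-saturation value", {
  # saturation of all three binding factors
  expect_equal(open_probability(1e9, 1e9, 1, p0), 1, tolerance = 1e-6)
  expect_identical(open_probability(0, 2, 0.5, p0), 0)
  # both dissociation factors at their half points: (1/2)^3 * (1/2)^3
  expect_equal(open_probability(p0$d_ipx, p0$d_act, 1, p0), 1 / 64)
  expect_error(open_probability(-1, 1, 0.5, p0), ">= 0")
  expect_error(open_probability(1, 1, 1.5, p0), "\\[0, 1\\]")
})

test_that("open probability increases in each argument when others are positive", {
  grid <- c(0.01, 0.1, 0.5, 2, 10)
  for (v in list(list(ipx = grid, ci = 1, h = 0.5),
                 list(ipx = 1, ci = grid, h = 0.5),
                 list(ipx = 1, ci = 1, h = seq(0.1, 1, by = 0.2)))) {
    o <- open_probability(v$ipx, v$ci, v$h, p0)
    expect_true(all(diff(o) > 0))
    expect_true(all(o >= 0 & o <= 1))
  }
})

test_that("pump flux follows the Hill form", {
  expect_identical(flux_pump(0, p0), 0)
  expect_equal(flux_pump(p0$k_store, p0), p0$v_store / 2)
  expect_equal(flux_pump(2, p0), 0.480769230769231, tolerance = 1e-12)
  ci <- seq(0, 10, by = 0.25)
  expect_true(all(diff(flux_pump(ci, p0)) > 0))
  expect_true(all(flux_pump(ci, p0) < p0$v_store))
  expect_error(flux_pump(-0.1, p0), ">= 0")
})

test_that("leak flux vanishes exactly at the zero-gradient concentration", {
  expect_equal(flux_leak(p0$c0 / (1 + p0$c1), p0), 0)
  expect_equal(flux_leak(0, p0), 0.375)
  expect_equal(flux_leak(2, p0), 0.265)
})

test_that("channel flux composes open probability and the store gradient", {
  expect_identical(flux_chan(0, 2, 0.5, p0), 0)
  expect_equal(flux_chan(5, p0$c0 / (1 + p0$c1), 0.5, p0), 0)
  # frozen arithmetic: 140 * (1/1.1)^3 * (2/2.02)^3 * 0.1562^3 * (7.5 - 2.2)
  expect_equal(flux_chan(1, 2, 0.1562, p0), 2.06207670962, tolerance = 1e-10)
})

test_that("gate steady state is the inhibition Michaelis form", {
  expect_identical(h_steady_state(0, p0), 1)
  expect_equal(h_steady_state(p0$d_inh, p0), 0.5)
  expect_equal(h_steady_state(2, p0), 0.04 / 2.04, tolerance = 1e-12)
  expect_true(all(diff(h_steady_state(seq(0, 5, 0.5), p0)) < 0))
})

test_that("derivatives match the flux sum and the gate equilibrium", {
  stim0 <- stimulus_protocol(numeric(0), numeric(0), numeric(0))
  # dh/dt = 0 when h is at its steady state
  d <- ca_derivatives(0, c(ci = 2, h = h_steady_state(2, p0)), stim0, p0)
  expect_equal(unname(d["dh"]), 0)
  # frozen sum of the flux oracles: 0.265 - 0.480769... + 0.1
  d2 <- ca_derivatives(0, c(ci = 2, h = 0.1562), stim0, p0,
                       include_jin = TRUE)
  expect_equal(unname(d2["dci"]), -0.115769230769231, tolerance = 1e-12)
  # omitting j_in removes exactly the influx term
  d3 <- ca_derivatives(0, c(ci = 2, h = 0.1562), stim0, p0,
                       include_jin = FALSE)
  expect_equal(unname(d2["dci"] - d3["dci"]), p0$j_in)
  # unstimulated rest point found by an independent 1-D bracketing oracle
  root <- uniroot(function(ci) flux_leak(ci, p0) - flux_pump(ci, p0) + p0$j_in,
                  c(0.1, 6), tol = 1e-12)$root
  d4 <- ca_derivatives(0, c(ci = root, h = 0.3), stim0, p0)
  expect_equal(unname(d4["dci"]), 0, tolerance = 1e-10)
  expect_error(ca_derivatives(0, c(ci = NaN, h = 0.5), stim0, p0),
               "non-finite")
})

test_that("an unstimulated run produces no transient", {
  stim0 <- stimulus_protocol(numeric(0), numeric(0), numeric(0))
  traj <- simulate_transient(p0, stim0, t_span = c(0, 420))
  expect_lte(max(traj$ci), p0$ci0)
})

test_that("simulated trajectories respect the model invariants", {
  traj <- simulate_transient(p0, default_stim(), t_span = c(0, 600),
                             include_jin = FALSE, dt = 0.5)
  expect_true(all(traj$h >= -1e-6 & traj$h <= 1 + 1e-6))
  expect_true(all(traj$ci >= -1e-9))
  expect_true(all(traj$ci <= p0$c0 / (1 + p0$c1) * (1 + 1e-3)))
  # store consistency: cer = (c0 - ci)/c1 and non-negative
  expect_equal(traj$cer, (p0$c0 - traj$ci) / p0$c1)
  expect_true(all(traj$cer >= 0))
  # flux balance: centered finite differences of ci match the flux sum
  # away from the stimulus edges
  mid <- 2:(nrow(traj) - 1)
  dnum <- (traj$ci[mid + 1] - traj$ci[mid - 1]) /
    (traj$time[mid + 1] - traj$time[mid - 1])
  dflx <- (traj$j_chan + traj$j_leak - traj$j_pump + traj$j_in)[mid]
  edge_free <- abs(traj$time[mid] - 60) > 2 & abs(traj$time[mid] - 480) > 2
  expect_lt(max(abs(dnum - dflx)[edge_free]) / max(abs(dflx)), 0.05)
})

test_that("equilibrated runs start at a genuine rest point", {
  y <- elicitCa:::equilibrate_state(p0, include_jin = TRUE)
  stim0 <- stimulus_protocol(numeric(0), numeric(0), numeric(0))
  d <- ca_derivatives(0, y, stim0, p0)
  expect_lt(max(abs(d)), 1e-6)
})

test_that("two-pulse refractory run reproduces the frozen suppression ratio", {
  mr <- model_refractory()
  expect_lte(mr$ratio, 0.10)
  # regression value recorded from the first verified run of this protocol
  expect_equal(mr$ratio, 0.0823, tolerance = 0.01)
})

test_that("trajectories round-trip through CSV with their provenance sidecar", {
  path <- withr::local_tempfile(fileext = ".csv")
  traj <- simulate_transient(p0, default_stim(), t_span = c(0, 120))
  write_trajectory(traj, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_trajectory(path)
  expect_equal(back$ci, traj$ci, tolerance = 1e-12)
  expect_equal(back$time, traj$time)
  expect_equal(unclass(attr(back, "params")), unclass(p0))
  expect_equal(attr(back, "stimulus")$pulses, default_stim()$pulses)
})
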