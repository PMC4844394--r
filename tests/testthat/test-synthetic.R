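cfg <- noisefree_config()
cc <- calibration_constants()

test_that("dose-amplitude curve is anchored, saturating and monotone", {
  expect_identical(dose_amplitude(0, cfg), 0)
  expect_equal(dose_amplitude(480, cfg), cfg$peak_at_max_dose)
  # half the asymptotic amplitude at the half-maximal dose, by the Hill form
  a_max <- cfg$peak_at_max_dose /
    (480^cfg$dose_hill / (480^cfg$dose_hill + cfg$dose_ec50^cfg$dose_hill))
  expect_equal(dose_amplitude(cfg$dose_ec50, cfg), a_max / 2)
  doses <- c(0, 10^seq(-5, 3, length.out = 50))
  expect_true(all(diff(dose_amplitude(doses, cfg)) > 0))
})

test_that("kernel peak location matches the closed-form argmax", {
  ts <- transient_peak_time(cfg$rise_tau, cfg$decay_tau)
  expect_equal(ts, log(cfg$decay_tau / cfg$rise_tau) * cfg$rise_tau *
                 cfg$decay_tau / (cfg$decay_tau - cfg$rise_tau))
  # numeric argmax of the kernel on a fine grid agrees
  s <- seq(0, 400, by = 0.01)
  k <- elicitCa:::transient_kernel(s, cfg$rise_tau, cfg$decay_tau)
  expect_equal(s[which.max(k)], ts, tolerance = 0.02)
  expect_equal(max(k), 1, tolerance = 1e-6)
  # other shape parameters obey the same closed form
  expect_equal({
    s2 <- seq(0, 200, by = 0.005)
    s2[which.max(elicitCa:::transient_kernel(s2, 10, 40))]
  }, transient_peak_time(10, 40), tolerance = 0.01)
})

test_that("generated transients have the emulated morphology", {
  tr <- make_transient(480, config = cfg)
  expect_s3_class(tr, "ca_trace")
  # flat baseline before onset + lag
  pre <- tr$times <= cfg$onset + cfg$lag
  expect_equal(tr$ca[pre], rep(cfg$baseline_ca, sum(pre)))
  ttp <- tr$times[which.max(tr$ca)] - cfg$onset
  expect_lte(ttp, 120)
  expect_gte(ttp, 60)
  # back below the return threshold (10% of peak) by 420 s after elicitation
  i420 <- which(tr$times >= cfg$onset + 420)[1]
  expect_lt(tr$ca[i420] - cfg$baseline_ca,
            0.10 * max(tr$ca - cfg$baseline_ca))
  # zero dose gives a flat trace
  flat <- make_transient(0, config = cfg)
  expect_equal(flat$ca, rep(cfg$baseline_ca, length(flat$ca)))
  # rise faster than decay: time from onset to peak shorter than peak to return
  f <- extract_features(tr, cfg$onset)
  expect_lt(f$time_to_peak - f$lag, f$duration - f$time_to_peak)
})

test_that("desensitization multiplier suppresses after strong first doses", {
  expect_identical(desensitize(0, cfg), 1)
  expect_lte(desensitize(480, cfg), 0.1)
  doses <- 10^seq(-5, log10(480), length.out = 30)
  expect_true(all(diff(desensitize(doses, cfg)) < 0))
})

test_that("forward luminescence model depletes the pool consistently", {
  tr <- make_transient(480, config = cfg, t_end = 400)
  lum <- ca_to_luminescence(tr, cc, cfg, noise = FALSE)
  expect_equal(lum$l_tot, cfg$aequorin_pool)
  expect_lt(sum(lum$counts), lum$l_tot)
  # expected counts reproduce lmax as the running pool
  expect_true(all(lmax_series(lum) > 0))
  # an all-zero trace emits nothing: the whole pool goes to the discharge
  zero <- ca_trace(0:59, rep(0, 60))
  lum0 <- ca_to_luminescence(zero, cc, cfg, noise = FALSE)
  expect_equal(lum0$counts, rep(0, 60))
  expect_equal(lum0$l_tot, cfg$aequorin_pool)
})

test_that("Poisson sampling is reproducible for a fixed seed", {
  tr <- make_transient(480, config = cfg, t_end = 200)
  set.seed(7)
  a <- ca_to_luminescence(tr, cc, cfg, noise = TRUE)
  set.seed(7)
  b <- ca_to_luminescence(tr, cc, cfg, noise = TRUE)
  expect_identical(a$counts, b$counts)
  set.seed(8)
  c_ <- ca_to_luminescence(tr, cc, cfg, noise = TRUE)
  expect_false(identical(a$counts, c_$counts))
})

test_that("experiments are deterministic given (design, config, seed)", {
  des <- design_dose_series(c(0.48, 480))
  e1 <- generate_experiment(des, synthetic_config(seed = 11))
  e2 <- generate_experiment(des, synthetic_config(seed = 11))
  expect_identical(e1$traces, e2$traces)
  expect_identical(e1$seeds, e2$seeds)
  e3 <- generate_experiment(des, synthetic_config(seed = 12))
  expect_false(identical(e1$traces, e3$traces))
})

test_that("dose-series experiments show monotone peak means", {
  exp <- generate_experiment(design_dose_series(), cfg)
  peaks <- vapply(seq_len(nrow(exp$design)), function(i) {
    ca <- luminescence_to_ca(exp$traces[[i]][[1]], cc)
    extract_features(ca, cfg$onset)$peak
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("double-elicitation experiments encode over-proportional inhibition", {
  exp <- generate_experiment(design_double_elicitation(), cfg)
  firsts <- vapply(exp$truth, function(tr) tr$features$peak, numeric(1))
  seconds <- vapply(exp$truth, function(tr) tr$features2$peak, numeric(1))
  expect_true(all(diff(firsts) > 0))     # first response rises with dose1
  expect_true(all(diff(seconds) < 0))    # second response falls with dose1
  # the two curves do not sum to a constant: inhibition is over-proportional
  expect_gt(diff(range(firsts + seconds)), 0.5)
})

test_that("generator ground truth matches the extracted pipeline features", {
  exp <- generate_experiment(design_dose_series(480), cfg)
  ca <- luminescence_to_ca(exp$traces[[1]][[1]], cc)
  f <- extract_features(ca, cfg$onset)
  truth <- exp$truth[[1]]$features
  expect_lte(abs(f$lag - truth$lag), cfg$dt)           # within one sample
  expect_equal(f$peak, truth$peak, tolerance = 1e-3)   # 0.1%
  expect_lte(abs(f$time_to_peak - truth$time_to_peak), cfg$dt)
  expect_lte(abs(f$duration - truth$duration), cfg$dt)
})

test_that("degenerate designs are handled explicitly", {
  empty <- generate_experiment(design_dose_series(numeric(0)), cfg)
  expect_length(empty$traces, 0)
  bad <- data.frame(dose1 = 480, dose2 = 240, interval = -10)
  expect_error(generate_experiment(bad, cfg), "interval")
})

test_that("experiments serialize to luminometer CSVs with a manifest", {
  dir <- withr::local_tempdir()
  exp <- generate_experiment(design_dose_series(c(0.48, 480)),
                             synthetic_config(seed = 3, replicates = 2))
  mpath <- write_experiment(exp, dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  expect_equal(nrow(man$files), 4L)
  back <- read_luminometer_csv(file.path(dir, "row1_rep1.csv"))
  expect_equal(back$counts, exp$traces[[1]][[1]]$counts)
  expect_equal(back$l_tot, exp$traces[[1]][[1]]$l_tot)
})
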