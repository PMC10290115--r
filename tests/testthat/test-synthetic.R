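test_that("two-state switch model follows the first-order closed form", {
  k <- switch_kinetics(tau_uv = 0.5, tau_vis = 0.5)
  # one UV interval at full intensity: rate k = 1/tau_uv = 2/s, plateau 0.1
  s <- illum_schedule(0, 3, "UV")
  st <- simulate_switch_state(s, k, dt = 0.01, start = 1, pss_uv = 0.1)
  rate <- 1 / 0.5
  expect_equal(st$e_fraction, 0.1 + (1 - 0.1) * exp(-rate * st$time),
               tolerance = 1e-12)
  # at t = ln2 / k the gap to the plateau is halved
  at <- 0.1 + 0.9 * exp(-rate * log(2) / rate)
  expect_equal(at - 0.1, 0.9 / 2)
  # constant VIS forever: monotone saturation toward the plateau from below
  sv <- illum_schedule(0, 10, "VIS")
  stv <- simulate_switch_state(sv, k, dt = 0.05, start = 0, pss_vis = 0.9)
  expect_true(all(diff(stv$e_fraction) >= 0))
  expect_true(all(stv$e_fraction <= 0.9 + 1e-12))
  # empty schedule gives an empty series
  empty <- illum_schedule(numeric(0), numeric(0), character(0))
  expect_equal(nrow(simulate_switch_state(empty, k, dt = 0.1)), 0)
})

test_that("dark intervals relax slowly toward the E isomer", {
  k <- switch_kinetics(thermal_halflife = 64)
  s <- illum_schedule(0, 3600, "dark")
  st <- simulate_switch_state(s, k, dt = 600, start = 0.1)
  expect_true(all(diff(st$e_fraction) > 0))
  # after one hour of a 64 h half-life, still below 2% recovery
  expect_lt(max(st$e_fraction), 0.12)
})

test_that("noise-free tongue trace equals the piecewise exponential model", {
  k <- switch_kinetics()
  s <- std_schedule(10)
  tr <- simulate_tongue_trace(s, k, noise_sd = 0, seed = 1)
  # within the first UV phase: a + b exp(-t/tau_uv) from the VIS plateau
  ph1 <- tr[tr$time_s < 1.95, ]
  model <- 6 + (6 + k$amplitude - 6) * exp(-ph1$time_s / k$tau_uv)
  expect_lt(max(abs(ph1$position_um - model)), 1e-12)
  # truth attribute matches the returned noise-free positions
  expect_equal(attr(tr, "truth_um"), tr$position_um)
  # amplitude 0 gives a constant trace
  tr0 <- simulate_tongue_trace(s, switch_kinetics(amplitude = 0),
                               noise_sd = 0, seed = 1)
  expect_equal(diff(range(tr0$position_um)), 0)
  expect_error(simulate_tongue_trace(s, k, noise_sd = -1), "noise_sd")
})

test_that("generators are bit-identical under a fixed seed", {
  s <- std_schedule(2)
  k <- switch_kinetics()
  t1 <- simulate_tongue_trace(s, k, noise_sd = 0.05, seed = 42)
  t2 <- simulate_tongue_trace(s, k, noise_sd = 0.05, seed = 42)
  expect_identical(t1$position_um, t2$position_um)
  cfg <- aspiration_scene_config(seed = 7)
  tr <- simulate_tongue_trace(s, k, noise_sd = 0, seed = 1)
  expect_identical(render_aspiration_stack(tr, cfg)$frames,
                   render_aspiration_stack(tr, cfg)$frames)
  m1 <- render_rbc_morphology("echinocyte", morphology_config(seed = 3))
  m2 <- render_rbc_morphology("echinocyte", morphology_config(seed = 3))
  expect_identical(m1, m2)
  sf1 <- simulate_shake_flask(0.88, noise_sd = 0.01, seed = 5)
  sf2 <- simulate_shake_flask(0.88, noise_sd = 0.01, seed = 5)
  expect_identical(sf1, sf2)
})

test_that("aspiration renderer places the interface at the ground truth", {
  # noise-free, blur-free: the erf edge midpoint sits at the trace position
  s <- illum_schedule(0, 0.75, "UV")
  tr <- simulate_tongue_trace(s, switch_kinetics(amplitude = 0),
                              noise_sd = 0, seed = 1, baseline = 6)
  cfg <- aspiration_scene_config(noise_sd = 0, psf_sigma = 0,
                                 edge_width = 0.8)
  stk <- render_aspiration_stack(tr, cfg)
  fr <- stk$frames[, , 1]
  axial <- fr[20, ]  # on the pipette axis
  # midpoint intensity (bright+dark)/2 at column 60 = 6 um / 0.1 um/px
  expect_equal(axial[60], (1000 + 200) / 2, tolerance = 1e-6)
  expect_gt(axial[50], axial[70])  # bright before, dark after
  # pure lateral drift: frame 11 equals frame 1 shifted by 5 rows
  cfg2 <- aspiration_scene_config(noise_sd = 0, drift_per_frame = 0.5)
  tr2 <- simulate_tongue_trace(illum_schedule(0, 1.2, "UV"),
                               switch_kinetics(amplitude = 0),
                               noise_sd = 0, seed = 1)
  stk2 <- render_aspiration_stack(tr2, cfg2)
  f1 <- stk2$frames[, , 1]
  f11 <- stk2$frames[, , 11]
  expect_equal(f11[6:40, ], f1[1:35, ], tolerance = 1e-9)
  # positions outside the field are rejected
  trbad <- tr
  trbad$position_um <- trbad$position_um + 100
  expect_error(render_aspiration_stack(trbad, cfg), "outside")
})

test_that("morphology renderer: spicule amplitude controls the phenotype", {
  cfg0 <- morphology_config(spicule_amplitude = 0, seed = 2)
  expect_identical(render_rbc_morphology("echinocyte", cfg0),
                   render_rbc_morphology("discocyte", cfg0))
  cfg <- morphology_config(cell_radius = 0)
  img <- render_rbc_morphology("discocyte", cfg)
  expect_equal(stats::sd(img), 0)
  expect_error(morphology_config(spicule_amplitude = 1), "spicule_amplitude")
})

test_that("shake-flask simulator conserves mass and encodes the ratio", {
  # logP 0: equal volumes give equal expected absorbances
  sf <- simulate_shake_flask(0, volume_pairs = data.frame(v_oct = 5, v_aq = 5))
  expect_equal(sf$A_oct, sf$A_aq)
  # noise-free round trip through the estimator returns exactly logP_true
  sf2 <- simulate_shake_flask(0.88)
  c_oct <- concentration_from_absorbance(sf2$A_oct, calibration(0.01))
  c_aq <- concentration_from_absorbance(sf2$A_aq, calibration(0.01))
  res <- aggregate_partition(data.frame(sample = sf2$sample,
                                        c_oct = c_oct, c_aq = c_aq))
  expect_equal(res$mean_logP, 0.88, tolerance = 1e-12)
  expect_equal(res$sd_logP, 0)
  # mass balance: concentrations recombine to the stock amount
  expect_equal(sf2$c_oct_true * sf2$v_oct + sf2$c_aq_true * sf2$v_aq,
               200 * (sf2$v_oct + sf2$v_aq), tolerance = 1e-9)
})

test_that("shake-flask Monte Carlo recovers the true logP within 0.1", {
  ests <- vapply(1:100, function(s) {
    sf <- simulate_shake_flask(0.88, noise_sd = 0.005, seed = s)
    co <- concentration_from_absorbance(sf$A_oct, calibration(0.01))
    ca <- concentration_from_absorbance(sf$A_aq, calibration(0.01))
    aggregate_partition(data.frame(sample = sf$sample, c_oct = co,
                                   c_aq = ca))$mean_logP
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.88), 0.1)
})
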