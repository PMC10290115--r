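test_that("reduce_roi averages across the pipette width", {
  fr <- matrix(7, 20, 30)
  roi <- roi_spec(5, 3, 10, 4)
  expect_equal(reduce_roi(fr, roi), rep(7, 10))
  # width 1 returns the raw row
  fr2 <- matrix(seq_len(600), 20, 30)
  roi1 <- roi_spec(6, 2, 12, 1)
  expect_equal(reduce_roi(fr2, roi1), fr2[6, 2:13])
  # two-row ROI is the elementwise mean of the rows
  roi2 <- roi_spec(6, 2, 12, 2)
  expect_equal(reduce_roi(fr2, roi2), (fr2[6, 2:13] + fr2[7, 2:13]) / 2)
  expect_error(reduce_roi(fr, roi_spec(18, 1, 10, 5)), "bounds")
})

test_that("quadratic vertex interpolates the derivative extremum", {
  # profile whose first difference is (6,5,2,0,1,4,6): symmetric triple
  # (2,0,1) around the minimum gives vertex at i + 1/6
  d <- c(6, 5, 2, 0, 1, 4, 6)
  profile <- cumsum(c(500, d))
  stk <- image_stack(array(rep(profile, each = 3),
                           c(3, length(profile), 1)), 1, 0.075)
  roi <- roi_spec(1, 1, length(profile), 3)
  tr <- track_interface(stk, roi, polarity = "min", smooth_sigma = 0)
  # min of d at index 4; vertex 4 + 1/6; diff midpoint offset +0.5
  expect_equal(tr$position_px, 4 + 1 / 6 + 0.5, tolerance = 1e-9)
  # symmetric triple (1,0,1) puts the vertex exactly on the sample
  d2 <- c(6, 5, 1, 0, 1, 4, 6)
  p2 <- cumsum(c(500, d2))
  stk2 <- image_stack(array(rep(p2, each = 3), c(3, length(p2), 1)),
                      1, 0.075)
  tr2 <- track_interface(stk2, roi, smooth_sigma = 0)
  expect_equal(tr2$position_px, 4 + 0.5, tolerance = 1e-12)
})

test_that("degenerate profiles are flagged, not guessed", {
  # extremum on the boundary
  profile <- seq(100, 50, length.out = 20)  # monotone, min diff at end? flat
  profile <- c(100, 90, seq(90, 100, length.out = 18))
  stk <- image_stack(array(rep(profile, each = 3), c(3, 20, 1)), 1, 0.075)
  tr <- track_interface(stk, roi_spec(1, 1, 20, 3), smooth_sigma = 0)
  expect_false(tr$ok[1])
  expect_true(is.na(tr$position_px[1]))
  # zero curvature (flat derivative) is flagged too
  flat <- image_stack(array(1000, c(3, 20, 1)), 1, 0.075)
  trf <- track_interface(flat, roi_spec(1, 1, 20, 3), smooth_sigma = 0)
  expect_false(trf$ok[1])
})

test_that("tracker recovers synthetic ground truth to sub-pixel accuracy", {
  sch <- std_schedule(4)
  tr <- simulate_tongue_trace(sch, switch_kinetics(), noise_sd = 0, seed = 1)
  roi <- roi_spec(16, 30, 70, 10)
  # noise-free: RMS below 0.05 px
  stk0 <- render_aspiration_stack(tr, aspiration_scene_config(noise_sd = 0))
  t0 <- track_interface(stk0, roi)
  expect_true(all(t0$ok))
  err0 <- t0$position_px - attr(stk0, "truth_px")
  expect_lt(sqrt(mean(err0^2)), 0.05)
  # noise-free sigmoid edge at a specific sub-pixel position
  one <- simulate_tongue_trace(illum_schedule(0, 0.15, "UV"),
                               switch_kinetics(amplitude = 0), noise_sd = 0,
                               seed = 1, baseline = 1.730)
  stk1 <- render_aspiration_stack(one, aspiration_scene_config(noise_sd = 0))
  t1 <- track_interface(stk1, roi_spec(16, 5, 40, 10))
  expect_lt(max(abs(t1$position_px - 17.30)), 0.05)
})

test_that("tracking is invariant to affine intensity rescaling", {
  sch <- std_schedule(2)
  tr <- simulate_tongue_trace(sch, switch_kinetics(), noise_sd = 0, seed = 1)
  stk <- render_aspiration_stack(tr, aspiration_scene_config(noise_sd = 5,
                                                             seed = 2))
  roi <- roi_spec(16, 30, 70, 10)
  t1 <- track_interface(stk, roi)
  stk2 <- image_stack(3.7 * stk$frames + 123, stk$pixel_size,
                      stk$frame_interval)
  t2 <- track_interface(stk2, roi)
  expect_equal(t2$position_px, t1$position_px, tolerance = 1e-9)
})

test_that("integer scene translation shifts tracked positions exactly", {
  sch <- std_schedule(2)
  tr <- simulate_tongue_trace(sch, switch_kinetics(), noise_sd = 0, seed = 1)
  stk <- render_aspiration_stack(tr, aspiration_scene_config(noise_sd = 0))
  k <- 4
  nc <- dim(stk$frames)[2]
  shifted <- stk$frames
  for (i in seq_len(dim(shifted)[3])) {
    shifted[, (k + 1):nc, i] <- stk$frames[, 1:(nc - k), i]
    shifted[, 1:k, i] <- stk$frames[, 1, i]
  }
  stk_s <- image_stack(shifted, stk$pixel_size, stk$frame_interval)
  roi <- roi_spec(16, 30, 80, 10)
  t1 <- track_interface(stk, roi)
  t2 <- track_interface(stk_s, roi)
  expect_equal(t2$position_px, t1$position_px + k, tolerance = 1e-6)
})

test_that("stabilization recovers known integer shifts", {
  set.seed(11)
  f1 <- matrix(stats::rnorm(60 * 80), 60, 80)
  f2 <- matrix(0, 60, 80)
  f2[4:60, 1:78] <- f1[1:57, 3:80]  # scene shifted by (+3, -2)
  stk <- image_stack(array(c(f1, f2), c(60, 80, 2)), 0.1, 0.075)
  st <- stabilize_stack(stk)
  expect_equal(unname(st$shifts[2, ]), c(-3, 2))
  # restored interior matches the reference
  expect_equal(st$stack$frames[10:50, 10:70, 2], f1[10:50, 10:70])
  # already-aligned stack: all shifts zero
  stk0 <- image_stack(array(rep(f1, 3), c(60, 80, 3)), 0.1, 0.075)
  expect_true(all(stabilize_stack(stk0)$shifts == 0))
  # featureless frames warn and get zero shift
  stku <- image_stack(array(c(f1, matrix(5, 60, 80)), c(60, 80, 2)),
                      0.1, 0.075)
  expect_warning(stu <- stabilize_stack(stku), "featureless")
  expect_true(all(stu$shifts == 0))
})

test_that("stabilization removes a slow uniform drift", {
  tr <- simulate_tongue_trace(illum_schedule(0, 3.7, "UV"),
                              switch_kinetics(), noise_sd = 0, seed = 1)
  cfg <- aspiration_scene_config(n_rows = 100, pipette_axis = 30,
                                 noise_sd = 8, drift_per_frame = 0.5,
                                 seed = 4)
  stk <- render_aspiration_stack(tr[1:50, ], cfg)
  st <- stabilize_stack(stk)
  residual <- attr(stk, "drift_rows") + st$shifts[, "row"]
  expect_lt(max(abs(residual)), 1)
})
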