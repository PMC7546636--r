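test_that("Laplacian pyramid reconstructs perfectly and sizes correctly", {
  withr::local_seed(1)
  fr <- matrix(runif(64 * 64), 64, 64)
  pyr <- build_pyramid(fr, "auto")
  expect_length(pyr$levels, 4)            # floor(log2(64)) - 2
  expect_lt(max(abs(collapse_pyramid(pyr) - fr)), 1e-6)

  # odd sizes reconstruct too
  fr2 <- matrix(runif(37 * 51), 37, 51)
  expect_lt(max(abs(collapse_pyramid(build_pyramid(fr2, 3)) - fr2)), 1e-12)

  cpyr <- build_pyramid(matrix(0.4, 32, 32), 2)
  expect_lt(max(abs(cpyr$levels[[1]])), 1e-12)
  expect_equal(mean(cpyr$residual), 0.4, tolerance = 1e-9)

  expect_error(build_pyramid(matrix(0, 8, 8), 4),
               class = "rubeoscan_error_geometry")
})

test_that("temporal band filter passes the pulse band and rejects DC and 10 Hz", {
  cfg <- magnifier_config(fps = 50)
  expect_lt(max(abs(temporal_bandpass(rep(3, 500), cfg))), 1e-9)

  tt <- seq_len(1500) / 50
  a1 <- interior_amp(temporal_bandpass(sin(2 * pi * 1 * tt), cfg))
  expect_gte(a1, 0.9)
  expect_lte(a1, 1.0)
  a10 <- interior_amp(temporal_bandpass(sin(2 * pi * 10 * tt), cfg))
  expect_lte(a10, 0.1)

  # matrix input filters every row identically
  X <- rbind(sin(2 * pi * 1 * tt), sin(2 * pi * 1 * tt))
  Y <- temporal_bandpass(X, cfg)
  expect_equal(Y[1, ], Y[2, ])

  expect_error(magnifier_config(fps = 50, high_cut_hz = 30),
               class = "rubeoscan_error_config")
  expect_error(temporal_bandpass(c(1, 2), cfg),
               class = "rubeoscan_error_input")
})

test_that("band_gain matches the measured filter response", {
  cfg <- magnifier_config(fps = 50)
  tt <- seq_len(2000) / 50
  for (f in c(0.7, 1.32, 2.6)) {
    g_meas <- interior_amp(temporal_bandpass(sin(2 * pi * f * tt), cfg))
    expect_equal(g_meas, band_gain(cfg, f), tolerance = 0.02)
  }
})

test_that("magnification amplifies in-band content by 1 + alpha * gain", {
  cfg <- magnifier_config(alpha = 50, color_constancy = FALSE)
  stk <- sinusoid_stack(freq_hz = 1, amp = 0.004)
  mag <- magnify(stk, cfg)
  sig <- mag$frames[6, 6, 1, ] - 0.5
  expected <- (1 + 50 * band_gain(cfg, 1)) * 0.004
  expect_equal(interior_amp(sig), expected, tolerance = 0.03 * expected)

  # out-of-band (10 Hz) content is amplified by at most 1.1x in steady
  # state (measured away from the boundary transients)
  stk10 <- sinusoid_stack(freq_hz = 10, amp = 0.004, T_len = 1200)
  sig10 <- magnify(stk10, cfg)$frames[6, 6, 1, ] - 0.5
  expect_lte(max(abs(sig10[500:700])), 1.1 * 0.004)
})

test_that("alpha = 0 is the identity and magnification is linear", {
  cfg0 <- magnifier_config(alpha = 0, color_constancy = FALSE)
  stk <- sinusoid_stack(freq_hz = 1.5, amp = 0.003)
  expect_lt(max(abs(magnify(stk, cfg0)$frames - stk$frames)), 1e-9)

  cfg <- magnifier_config(alpha = 20, color_constancy = FALSE)
  m1 <- magnify(stk, cfg)
  stk3 <- frame_stack(3 * stk$frames, fps = stk$fps)
  m3 <- magnify(stk3, cfg)
  expect_equal(m3$frames, 3 * m1$frames, tolerance = 1e-10)

  expect_error(magnify(frame_stack(array(0.5, c(8, 8, 3, 10)), fps = 50)),
               class = "rubeoscan_error_input")  # < 2 s of frames
})

test_that("pyramid and direct per-pixel magnification agree", {
  stk <- sinusoid_stack(freq_hz = 2, amp = 0.005, h = 24, w = 20, T_len = 250)
  cfg <- magnifier_config(alpha = 50, color_constancy = FALSE)
  m_pyr <- magnify(stk, cfg, use_pyramid = TRUE)
  m_fast <- magnify(stk, cfg, use_pyramid = FALSE)
  expect_lt(max(abs(m_pyr$frames - m_fast$frames)), 1e-8)
})

test_that("magnified cheek signal shows the 19-frame inter-beat spacing at 50 fps", {
  lay <- grid_layout()
  sch <- segment_schedule(fps = 50, segment_lengths = 400)
  vid <- render_video(lay, sch, group = "DM", seed = 4)
  mag <- magnify(vid$stacks[[1]], use_pyramid = FALSE)
  ps <- extract_patches(mag, vid$manifest)
  cheek <- ps$means[, which(ps$roles == "cheek")[1]]
  cheek <- cheek - mean(cheek)
  n <- length(cheek)
  peaks <- which(cheek > c(-Inf, head(cheek, -1)) &
                   cheek > c(tail(cheek, -1), Inf) &
                   cheek > 0.5 * max(cheek))
  spacing <- median(diff(peaks))
  expect_equal(spacing, 19, tolerance = 0.1)   # 0.38 s between beats
})
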