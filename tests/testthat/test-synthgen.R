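test_that("segment ESD sampling recovers its generating family", {
  s <- sample_segment_esd("gamma", c(beta = 5.449, theta = 0.022), 1e4, seed = 1)
  expect_true(all(s$values > 0))
  refit <- fit_gamma(s)
  expect_lt(abs(refit$beta - 5.449) / 5.449, 0.05)

  # Pareto median closed form: exponent magnitude 2, x_min 1 -> median 2
  p <- sample_segment_esd("power_law", c(exponent = 2, x_min = 1), 2e5, seed = 2)
  expect_lt(abs(median(p$values) - 2), 0.05)

  gp <- sample_segment_esd("gp", c(k = 0.3, sigma = 1), 1e4, seed = 3)
  expect_true(all(gp$values > 0))

  expect_error(sample_segment_esd("gamma", c(beta = 5, theta = 0.02), 0, 1),
               class = "rubeoscan_error_param")
  expect_error(sample_segment_esd("gamma", c(beta = -1, theta = 0.02), 10, 1),
               class = "rubeoscan_error_param")
})

test_that("sampling is reproducible and its ECDF converges to the family CDF", {
  a <- sample_segment_esd("gamma", c(beta = 2, theta = 1), 1000, seed = 9)
  b <- sample_segment_esd("gamma", c(beta = 2, theta = 1), 1000, seed = 9)
  expect_identical(a$values, b$values)

  ks_at <- function(n, seed) {
    x <- sort(sample_segment_esd("gamma", c(beta = 2, theta = 1), n, seed)$values)
    max(abs(pgamma(x, 2, 1) - seq_len(n) / n))
  }
  expect_lt(ks_at(20000, 5), ks_at(200, 5))
  expect_lt(ks_at(20000, 5), 0.02)
})

test_that("cohort generation honours sizes, families, mixture and seed", {
  spec0 <- cohort_spec(mixture = 0, seed = 3)
  feats <- generate_cohort_features(spec0)
  seg <- dplyr::distinct(feats, subject, group, atypical, segment, family)
  expect_equal(length(unique(seg$subject)), 27)
  expect_equal(nrow(seg), 162)
  expect_true(all(seg$family[seg$group == "DM"] == "gamma"))
  expect_true(all(seg$family[seg$group == "C"] == "gp"))
  expect_false(any(seg$atypical))

  spec <- cohort_spec(seed = 3)  # default mixture: 3/18 DM, 2/9 C atypical
  seg2 <- dplyr::distinct(generate_cohort_features(spec),
                          subject, group, atypical)
  expect_equal(sum(seg2$atypical & seg2$group == "DM"), 3)
  expect_equal(sum(seg2$atypical & seg2$group == "C"), 2)

  expect_identical(generate_cohort_features(spec),
                   generate_cohort_features(cohort_spec(seed = 3)))

  expect_error(cohort_spec(mixture = 1.2), class = "rubeoscan_error_param")
  expect_error(cohort_spec(dm_tail_params = data.frame()),
               class = "rubeoscan_error_config")
  expect_error(cohort_spec(n_dm = 0), class = "rubeoscan_error_param")
})

test_that("rendered segments follow the trimming schedule exactly", {
  lay <- scene_layout(frame_size = c(16, 34), arrangement = "grid",
                      patch_size = 5)
  vid <- render_video(lay, segment_schedule(), group = "C", seed = 1)
  expect_equal(vapply(vid$stacks, n_frames, integer(1)),
               c(5901L, 4851L, 6251L, 5901L, 4851L, 6251L))
  expect_equal(vid$stacks[[1]]$fps, 50)
  expect_equal(nrow(vid$manifest), 8)
  rm(vid); gc(verbose = FALSE)
})

test_that("zero modulation and zero noise give constant frames", {
  lay <- scene_layout(frame_size = c(68, 136), arrangement = "grid",
                      modulation_amp = 0, noise_sd = 0)
  vid <- render_video(lay, segment_schedule(fps = 25, segment_lengths = 80),
                      group = "DM", seed = 1)
  fr <- vid$stacks[[1]]$frames
  expect_equal(max(fr) - min(fr), diff(range(lay$base_rgb)))  # bases only
  expect_equal(sd(fr[, , 1, ]), 0)
})

test_that("layout validation rejects overlap and out-of-bounds patches", {
  expect_error(scene_layout(frame_size = c(40, 60), arrangement = "face"),
               class = "rubeoscan_error_layout")
  expect_error(scene_layout(frame_size = c(30, 136), arrangement = "grid"),
               class = "rubeoscan_error_layout")
  expect_silent(scene_layout())  # default face layout is valid
})

test_that("patch manifests survive a JSON round trip", {
  lay <- grid_layout()
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(lay$patch_boxes, path)
  back <- read_manifest(path)
  expect_equal(as.data.frame(back), as.data.frame(lay$patch_boxes))
})

test_that("group regimes keep the modulation sub-visible before magnification", {
  lay <- scene_layout()
  reg <- rubeoscan:::group_regimes(lay)
  expect_lt(reg$DM$pulse_amp, 1 / 255)
  expect_lt(reg$C$pulse_amp, 1 / 255)
})
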