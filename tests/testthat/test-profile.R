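const_stack <- function(v, h = 68, w = 136, T_len = 12) {
  frames <- array(0.3, c(h, w, 3, T_len))
  frames[, , 1, ] <- v
  frame_stack(frames, fps = 50)
}

test_that("patch extraction returns red-channel pixels and means", {
  lay <- grid_layout()
  ps <- extract_patches(const_stack(0.61), lay$patch_boxes)
  expect_length(ps$pixels, 8)
  expect_equal(dim(ps$pixels[[1]]), c(961, 12))
  expect_true(all(abs(ps$means - 0.61) < 1e-12))

  tidy_means <- patch_means(ps)
  expect_equal(nrow(tidy_means), 12 * 8)
  expect_setequal(unique(tidy_means$role),
                  c("cheek", "forehead", "nose", "philtrum"))

  bad <- lay$patch_boxes
  bad$x[1] <- 1000
  expect_error(extract_patches(const_stack(0.5), bad),
               class = "rubeoscan_error_geometry")
  expect_error(extract_patches(const_stack(0.5), lay$patch_boxes[1:5, ]),
               class = "rubeoscan_error_manifest")
})

test_that("tensor profile picks extreme patches and standardizes rows", {
  lay <- grid_layout()
  stk <- const_stack(0.5, T_len = 60)
  # patch 1 brightest with temporal structure, patch 4 dimmest
  b <- lay$patch_boxes
  withr::local_seed(7)
  sig <- 0.2 + 0.01 * sin(seq_len(60) / 3)
  stk$frames[(b$y[1] + 1):(b$y[1] + 31), (b$x[1] + 1):(b$x[1] + 31), 1, ] <-
    0.5 + rep(sig, each = 961) + rnorm(961 * 60, sd = 0.001)
  stk$frames[(b$y[4] + 1):(b$y[4] + 31), (b$x[4] + 1):(b$x[4] + 31), 1, ] <- 0.3

  ps <- extract_patches(stk, b)
  tp <- tensor_profile(ps)
  expect_equal(tp$hi, 1)
  expect_equal(tp$lo, 4)
  ok <- !tp$degenerate
  expect_true(any(ok))
  expect_lt(max(abs(rowMeans(tp$P[ok, , drop = FALSE]))), 1e-9)
  expect_lt(max(abs(apply(tp$P[ok, , drop = FALSE], 1, sd) - 1)), 1e-9)

  # permuting the manifest leaves the profile unchanged
  perm <- sample(8)
  tp2 <- tensor_profile(extract_patches(stk, b[perm, ]))
  expect_equal(tp2$P, tp$P)
  expect_equal(tp2$mean_abs_diff, tp$mean_abs_diff)

  # adding a constant to every pixel of every frame leaves the raw
  # difference (and hence the profile) unchanged
  stk_shift <- frame_stack(stk$frames + 0.05, fps = stk$fps)
  tp3 <- tensor_profile(extract_patches(stk_shift, b))
  expect_equal(tp3$mean_abs_diff, tp$mean_abs_diff, tolerance = 1e-12)
  expect_equal(tp3$P, tp$P, tolerance = 1e-9)
})

test_that("constant patches yield a degenerate-zero normalized profile", {
  lay <- grid_layout()
  stk <- const_stack(0.35, T_len = 10)   # base red between the two extremes
  b <- lay$patch_boxes
  stk$frames[(b$y[1] + 1):(b$y[1] + 31), (b$x[1] + 1):(b$x[1] + 31), 1, ] <- 100 / 255
  stk$frames[(b$y[2] + 1):(b$y[2] + 31), (b$x[2] + 1):(b$x[2] + 31), 1, ] <- 80 / 255
  ps <- extract_patches(stk, b)
  expect_warning(tp <- tensor_profile(ps), "degenerate")
  expect_equal(tp$mean_abs_diff, 20 / 255, tolerance = 1e-12)
  expect_true(all(tp$degenerate))
  expect_true(all(tp$P == 0))

  expect_error(tensor_profile(extract_patches(const_stack(0.5), b)),
               class = "rubeoscan_error_input")
})

test_that("synthetic DM cheeks fluctuate more than background patches", {
  lay <- grid_layout()
  sch <- segment_schedule(fps = 25, segment_lengths = 300)
  vid <- render_video(lay, sch, group = "DM", seed = 6)
  ps <- extract_patches(magnify(vid$stacks[[1]], use_pyramid = FALSE),
                        vid$manifest)
  v <- apply(ps$means, 2, var)
  expect_gt(min(v[ps$roles == "cheek"]), max(v[ps$roles != "cheek"]))
})

test_that("magnified DM/C mean patch-difference contrast is about 22-fold", {
  ratios <- vapply(1:5, function(s) {
    rendered_profile("DM", s)$mean_abs_diff /
      rendered_profile("C", s)$mean_abs_diff
  }, numeric(1))
  expect_gt(median(ratios), 14)
  expect_lt(median(ratios), 30)
})

test_that("tensor profiles survive the CSV round trip", {
  tp <- rendered_profile("C", 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(tp, path)
  back <- read_profile_csv(path)
  expect_equal(back$P, tp$P, tolerance = 1e-6)
  expect_equal(back$mean_abs_diff, tp$mean_abs_diff, tolerance = 1e-9)
})
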