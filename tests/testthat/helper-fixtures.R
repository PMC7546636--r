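# Shared fixtures, built in code and cached for the session.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

# compact 2x4 patch grid that fits desk-scale frames
grid_layout <- function(...) {
  scene_layout(frame_size = c(68, 136), arrangement = "grid", ...)
}

# desk-scale analysis settings for rendered video: 25 fps segments with the
# covariance window spanning ~1.6 beats so scale-free beat-to-beat
# variability is visible in the window eigenvalues
video_cfg <- list(fps = 25, T = 1000, window = 15, stride = 3,
                  q = 0.6, n_pixels = 250)

# one rendered + magnified segment per group (expensive; cached)
rendered_profile <- function(group, seed, T_len = 750) {
  cached(paste("prof", group, seed, T_len), {
    lay <- grid_layout()
    sch <- segment_schedule(fps = video_cfg$fps, segment_lengths = T_len)
    v <- render_video(lay, sch, group = group, seed = seed)
    m <- magnify(v$stacks[[1]], use_pyramid = FALSE)
    tensor_profile(extract_patches(m, v$manifest))
  })
}

# small clean feature-level cohort and its tail fits (cached)
small_clean_tails <- function() {
  cached("small_clean_tails", {
    spec <- cohort_spec(n_dm = 6, n_c = 4, esd_samples_per_segment = 400,
                        mixture = 0, seed = 42)
    tails <- fit_cohort_tails(generate_cohort_features(spec))
    tails$label <- as.character(tails$group)
    tails
  })
}

# a frame stack holding a pure sinusoid at freq_hz in one pixel block
sinusoid_stack <- function(freq_hz, amp = 0.01, fps = 50, T_len = 400,
                           h = 16, w = 16, base = 0.5) {
  tt <- seq_len(T_len) / fps
  frames <- array(base, c(h, w, 3, T_len))
  sig <- amp * sin(2 * pi * freq_hz * tt)
  frames[5:8, 5:8, 1, ] <- base + rep(sig, each = 16)
  frame_stack(frames, fps = fps)
}

# amplitude of an interior stretch of a series (avoids edge transients)
interior_amp <- function(x) {
  n <- length(x)
  max(abs(x[round(n * 0.25):round(n * 0.75)]))
}
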