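# Synthetic-data generation. The study's patient videos are not publicly
# deposited, so validation inputs are generated at two levels: (a)
# feature-level eigenvalue samples drawn from the reference tail-parameter
# families reported for the two groups, and (b) video-level synthetic face
# frame stacks with pulse-modulated patch coloration.

#' Reference tail-parameter families for the two groups
#'
#' Per-segment tail parameters reported for three subjects per group (three
#' video segments each): generalized Pareto `(k, sigma)` pairs — positive
#' `k` with small scales for controls, negative `k` with larger scales for
#' the diabetic group — plus power-law exponents `gamma` for controls and
#' Gamma `(beta, theta)` (shape, rate) pairs for the diabetic group. These
#' families parameterise the synthetic cohort generator.
#'
#' @param group `"C"` (control) or `"DM"` (diabetic).
#' @return A tibble with columns `subject`, `segment`, `k`, `sigma`, and
#'   `gamma` (C) or `beta`, `theta` (DM).
#' @export
reference_tail_params <- function(group = c("C", "DM")) {
  group <- match.arg(group)
  if (group == "C") {
    tibble(
      subject = rep(paste0("C", 1:3), each = 3),
      segment = rep(1:3, times = 3),
      k = c(0.0869, 0.1013, 0.1697, 0.5628, 0.4382, 1.0249,
            1.1599, 0.0897, 0.4650),
      sigma = c(0.0001, 0.0001, 0.0001, 0.0030, 0.0033, 0.0020,
                0.0004, 0.0031, 0.0016),
      gamma = c(-1.53, -1.52, -1.45, -1.20, -1.20, -1.21,
                -1.30, -1.21, -1.23)
    )
  } else {
    tibble(
      subject = rep(paste0("DM", 1:3), each = 3),
      segment = rep(1:3, times = 3),
      k = c(-0.378, -0.334, -0.361, -0.455, -0.135, -0.172,
            -0.745, -0.811, -0.565),
      sigma = c(0.156, 0.131, 0.127, 0.724, 0.665, 0.758,
                0.713, 0.916, 0.748),
      beta = c(5.449, 4.935, 4.344, 4.948, 2.283, 1.783,
               3.310, 5.450, 3.615),
      theta = c(0.022, 0.021, 0.023, 0.006, 0.008, 0.015,
                0.183, 0.146, 0.133)
    )
  }
}

#' Cohort specification for feature-level synthesis
#'
#' Defines a synthetic cohort whose per-segment eigenvalue samples are
#' drawn from the group tail families: Gamma (Tracy-Widom surrogate) for
#' typical diabetic (DM) segments, generalized Pareto with positive shape
#' for typical control (C) segments. A `mixture` fraction of subjects per
#' group is "atypical": all their segments are drawn from the opposite
#' group's family, emulating the minority of subjects whose tail type does
#' not match their clinical group (default 3/18 of DM and 2/9 of C).
#'
#' @param n_dm,n_c Number of DM / C subjects (>= 1).
#' @param segments_per_subject Segments per subject (default 6).
#' @param esd_samples_per_segment Eigenvalues per segment sample
#'   (default 500).
#' @param dm_tail_params Tibble (or list) of Gamma `(beta, theta)` pairs;
#'   default [reference_tail_params("DM")].
#' @param c_tail_params Tibble (or list) of GP `(k, sigma)` pairs; default
#'   [reference_tail_params("C")].
#' @param mixture Fraction of atypical subjects, either one number for
#'   both groups or a named pair `c(dm = ..., c = ...)`; each in `[0, 1]`.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_dm = 18, n_c = 9, segments_per_subject = 6,
                        esd_samples_per_segment = 500,
                        dm_tail_params = reference_tail_params("DM"),
                        c_tail_params = reference_tail_params("C"),
                        mixture = c(dm = 3 / 18, c = 2 / 9), seed = 1) {
  check_number(n_dm, "n_dm", lower = 1, integerish = TRUE)
  check_number(n_c, "n_c", lower = 1, integerish = TRUE)
  check_number(segments_per_subject, "segments_per_subject", lower = 1,
               integerish = TRUE)
  check_number(esd_samples_per_segment, "esd_samples_per_segment", lower = 1,
               integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  if (length(mixture) == 1) mixture <- c(dm = mixture, c = mixture)
  if (any(mixture < 0 | mixture > 1)) {
    stop_rube("`mixture` fractions must lie in [0, 1].", "param")
  }
  dm_tail_params <- as_tibble(dm_tail_params)
  c_tail_params <- as_tibble(c_tail_params)
  if (nrow(dm_tail_params) == 0 || nrow(c_tail_params) == 0) {
    stop_rube("Tail-parameter families must be non-empty.", "config")
  }
  if (!all(c("beta", "theta") %in% names(dm_tail_params)) ||
      any(dm_tail_params$beta <= 0) || any(dm_tail_params$theta <= 0)) {
    stop_rube("DM family needs positive Gamma `beta`, `theta` columns.", "config")
  }
  if (!all(c("k", "sigma") %in% names(c_tail_params)) ||
      any(c_tail_params$sigma <= 0)) {
    stop_rube("C family needs `k` and positive `sigma` columns.", "config")
  }
  structure(
    list(n_dm = n_dm, n_c = n_c,
         segments_per_subject = segments_per_subject,
         esd_samples_per_segment = esd_samples_per_segment,
         dm_tail_params = dm_tail_params, c_tail_params = c_tail_params,
         mixture = mixture, seed = seed),
    class = "cohort_spec"
  )
}

#' Sample a per-segment eigenvalue collection from a tail family
#'
#' Draws `n` positive values from one of the tail families used to emulate
#' a segment's largest-eigenvalue sample: `"gamma"` (shape/rate; the
#' Tracy-Widom surrogate typical of the DM group), `"power_law"`
#' (continuous Pareto via inverse CDF, with decay-exponent magnitude
#' `params$exponent` and cutoff `params$x_min`), or `"gp"` (generalized
#' Pareto with location 0; positive `params$k` gives the polynomial tail
#' typical of controls).
#'
#' @param tail_type One of `"gamma"`, `"power_law"`, `"gp"`.
#' @param params Named list or vector of parameters for the family:
#'   `beta`/`theta`, `exponent`/`x_min`, or `k`/`sigma`.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed (reproducible).
#' @return An [eigen_sample] of `n` positive values.
#' @export
#' @examples
#' s <- sample_segment_esd("gamma", c(beta = 5.449, theta = 0.022), 1000, 1)
#' fit_gamma(s)
sample_segment_esd <- function(tail_type = c("gamma", "power_law", "gp"),
                               params, n, seed = 1) {
  tail_type <- match.arg(tail_type)
  check_number(n, "n", lower = 1, integerish = TRUE)
  p <- as.list(params)
  vals <- with_seed_(seed, switch(
    tail_type,
    gamma = {
      if (p$beta <= 0 || p$theta <= 0) {
        stop_rube("Gamma parameters must be positive.", "param")
      }
      rgamma(n, shape = p$beta, rate = p$theta)
    },
    power_law = rplaw(n, exponent = abs(p$exponent), x_min = p$x_min %||% 1),
    gp = rgp(n, mu = 0, k = p$k, sigma = p$sigma)
  ))
  eigen_sample(vals)
}

#' Generate a feature-level synthetic cohort
#'
#' Produces per-segment eigenvalue samples for every subject of a
#' [cohort_spec()]: typical DM segments from the Gamma family, typical C
#' segments from the generalized-Pareto family, and the first
#' `round(mixture * n)` subjects of each group (after a seeded shuffle)
#' from the opposite family. Each segment's family parameters are drawn
#' uniformly from the group's parameter table.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `cohort_features` in long form with columns
#'   `subject`, `group` (`"C"`/`"DM"`), `atypical`, `segment`, `family`,
#'   `value`; `attr(, "spec")` carries the generating spec.
#' @export
generate_cohort_features <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- list(
    DM = list(n = spec$n_dm, own = "gamma", other = "gp",
              own_par = spec$dm_tail_params, other_par = spec$c_tail_params,
              mix = unname(spec$mixture["dm"])),
    C = list(n = spec$n_c, own = "gp", other = "gamma",
             own_par = spec$c_tail_params, other_par = spec$dm_tail_params,
             mix = unname(spec$mixture["c"]))
  )
  rows <- purrr::imap(groups, function(g, gname) {
    n_atyp <- round(g$mix * g$n)
    atyp_idx <- with_seed_(
      derive_seed(spec$seed, paste0("atypical-", gname)),
      sample.int(g$n, n_atyp)
    )
    purrr::map(seq_len(g$n), function(i) {
      subject <- sprintf("%s%02d", gname, i)
      atypical <- i %in% atyp_idx
      family <- if (atypical) g$other else g$own
      par_tab <- if (atypical) g$other_par else g$own_par
      purrr::map(seq_len(spec$segments_per_subject), function(s) {
        seg_seed <- derive_seed(spec$seed, paste(subject, s))
        j <- with_seed_(seg_seed + 1L, sample.int(nrow(par_tab), 1))
        pars <- if (family == "gamma") {
          c(beta = par_tab$beta[j], theta = par_tab$theta[j])
        } else {
          c(k = par_tab$k[j], sigma = par_tab$sigma[j])
        }
        vals <- sample_segment_esd(family, pars,
                                   spec$esd_samples_per_segment, seg_seed)
        tibble(subject = subject, group = gname, atypical = atypical,
               segment = s, family = family, value = vals$values)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(rows)
  out$group <- factor(out$group, levels = c("C", "DM"))
  attr(out, "spec") <- spec
  class(out) <- c("cohort_features", class(out))
  out
}

#' Segment trimming schedule
#'
#' The recording protocol yields six usable video segments per subject
#' (about two minutes each at 50 fps) after trimming breaks; the default
#' frame counts follow that schedule.
#'
#' @param fps Frames per second (default 50).
#' @param segment_lengths Ordered frame counts per segment.
#' @return A list of class `segment_schedule`.
#' @export
segment_schedule <- function(fps = 50,
                             segment_lengths = c(5901, 4851, 6251,
                                                 5901, 4851, 6251)) {
  check_number(fps, "fps", lower = 0, strict_lower = TRUE)
  if (length(segment_lengths) < 1 || any(segment_lengths <= 0)) {
    stop_rube("All segment lengths must be positive.", "param")
  }
  structure(list(fps = fps, segment_lengths = as.integer(segment_lengths)),
            class = "segment_schedule")
}

# fractional box anchors for the face arrangement (of a 320x180 frame)
face_anchor_fracs <- function() {
  tibble(
    role = c("cheek", "cheek", "forehead", "forehead",
             "nose", "nose", "philtrum", "philtrum"),
    fx = c(0.1875, 0.71875, 0.3125, 0.59375, 0.4531, 0.4531, 0.34375, 0.5625),
    fy = c(0.5278, 0.5278, 0.0556, 0.0556, 0.3056, 0.5, 0.7778, 0.7778)
  )
}

#' Scene layout for synthetic face videos
#'
#' Geometry and photometric parameters of the synthetic scene: frame size,
#' the eight 31x31 facial patches (2 cheek patches, which rubeosis faciei
#' reddens, and 6 background patches on forehead, nose and philtrum), base
#' skin color, pulse frequency, Red-channel modulation amplitude and
#' sensor noise. Patch boxes must be pairwise disjoint and inside the
#' frame.
#'
#' Two arrangements are available: `"face"` scatters the patches over a
#' face-like geometry (requires roughly >= 160x90 frames); `"grid"` packs
#' them into a tight 2x4 grid for small desk-scale frames.
#'
#' @param frame_size `(height, width)` in pixels; default `c(180, 320)`
#'   (a scaled-down layout; pass `c(720, 1280)` for full size).
#' @param arrangement `"face"` or `"grid"`.
#' @param patch_size Side of the square patches (default 31).
#' @param pulse_hz Pulse frequency in Hz; default 50/19 (about 2.63 Hz, a
#'   19-frame beat period — 0.38 s between beats — at 50 fps). Must lie in
#'   the (0.4, 4) Hz pass band.
#' @param base_rgb Base skin color (length-3, in `[0, 1]`).
#' @param modulation_amp Red-channel pulse amplitude for the control
#'   group's cheeks, in intensity units (sub-visible: well below 1/255).
#' @param noise_sd Per-pixel sensor noise standard deviation.
#' @return A list of class `scene_layout` with a `patch_boxes` tibble in
#'   0-based coordinates.
#' @export
scene_layout <- function(frame_size = c(180, 320),
                         arrangement = c("face", "grid"),
                         patch_size = 31, pulse_hz = 50 / 19,
                         base_rgb = c(0.78, 0.58, 0.50),
                         modulation_amp = 1.6e-4, noise_sd = 5e-5) {
  arrangement <- match.arg(arrangement)
  h <- frame_size[1]; w <- frame_size[2]
  check_number(h, "frame height", lower = 2, integerish = TRUE)
  check_number(w, "frame width", lower = 2, integerish = TRUE)
  check_number(pulse_hz, "pulse_hz", lower = 0.4, upper = 4, strict_lower = TRUE)
  check_number(modulation_amp, "modulation_amp", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  ps <- as.integer(patch_size)
  boxes <- if (arrangement == "face") {
    a <- face_anchor_fracs()
    tibble(role = a$role,
           x = as.integer(round(a$fx * w)), y = as.integer(round(a$fy * h)),
           w = ps, h = ps)
  } else {
    roles <- c("cheek", "cheek", "forehead", "forehead",
               "nose", "nose", "philtrum", "philtrum")
    m <- 2L
    tibble(role = roles,
           x = rep(m + (0:3) * (ps + m), 2),
           y = rep(c(m, 2L * m + ps), each = 4),
           w = ps, h = ps)
  }
  validate_boxes(boxes, h, w)
  structure(
    list(frame_size = c(h = h, w = w), patch_boxes = boxes,
         pulse_hz = pulse_hz, base_rgb = base_rgb,
         modulation_amp = modulation_amp, noise_sd = noise_sd),
    class = "scene_layout"
  )
}

validate_boxes <- function(boxes, h, w) {
  if (nrow(boxes) != 8) {
    stop_rube("Exactly 8 patch boxes are required.", "layout")
  }
  if (any(boxes$x < 0 | boxes$y < 0 |
          boxes$x + boxes$w > w | boxes$y + boxes$h > h)) {
    stop_rube("Patch boxes fall outside the frame bounds.", "layout")
  }
  for (i in seq_len(nrow(boxes) - 1)) {
    for (j in (i + 1):nrow(boxes)) {
      overlap_x <- boxes$x[i] < boxes$x[j] + boxes$w[j] &&
        boxes$x[j] < boxes$x[i] + boxes$w[i]
      overlap_y <- boxes$y[i] < boxes$y[j] + boxes$h[j] &&
        boxes$y[j] < boxes$y[i] + boxes$h[i]
      if (overlap_x && overlap_y) {
        stop_rube("Patch boxes overlap.", "layout")
      }
    }
  }
  invisible(boxes)
}

# Group-specific cheek modulation regimes. Amplitudes are in intensity
# units before magnification; they stay below one 8-bit step and are
# calibrated so that after alpha = 50 magnification the mean absolute
# patch-difference of the DM group is ~22x the control group's.
group_regimes <- function(layout) {
  amp <- layout$modulation_amp
  list(
    # C: every heart beat carries a power-law-distributed amplitude
    # (avalanche analogy) -> scale-free, heavy-tailed window eigenvalues.
    C = list(pulse_amp = amp, beat_exponent = 3, gauss_sd = 0,
             redness_offset = amp),
    # DM: larger, temporally unstructured modulation -> concentrated
    # (Tracy-Widom-like) window eigenvalues.
    DM = list(pulse_amp = 18 * amp, beat_exponent = NA,
              gauss_sd = 11 * amp,               # white, unstructured
              redness_offset = 18 * amp)
  )
}

# Per-beat amplitude multipliers: each pulse beat draws its amplitude
# from a continuous Pareto (density exponent `exponent`), rescaled to
# unit mean — the scale-invariant "avalanche size" analogy. Returns a
# piecewise-constant multiplier series m(t) with E[m] = 1.
beat_amplitudes <- function(T_len, fps, pulse_hz, exponent) {
  beat_len <- fps / pulse_hz
  beat_of_t <- floor((seq_len(T_len) - 1) / beat_len) + 1
  n_beats <- max(beat_of_t)
  a <- exponent - 1                      # survival tail index
  amps <- rplaw(n_beats, exponent = exponent, x_min = 1) * (a - 1) / a
  amps[beat_of_t]
}

#' Render a synthetic face video for one group
#'
#' Generates one frame stack per schedule entry plus the patch manifest.
#' All patches share the base skin color; cheek patches carry a small
#' constant redness offset (facial erythema, much larger for DM) and a
#' Red-channel pulse modulation whose temporal structure depends on the
#' group: controls get a modest pulse whose per-beat amplitude is drawn
#' from a power law (scale-free beat-to-beat variability, producing
#' heavy-tailed window eigenvalues); the DM group gets a larger-amplitude
#' constant pulse plus unstructured white Gaussian fluctuation (producing
#' Tracy-Widom-like eigenvalue edges).
#' Modulation amplitudes are sub-visible (below one 8-bit intensity step)
#' before magnification and supra-threshold after `alpha = 50`
#' magnification. Per-pixel Gaussian sensor noise is added everywhere.
#'
#' @param layout A [scene_layout()].
#' @param schedule A [segment_schedule()].
#' @param group `"DM"` or `"C"`.
#' @param seed Integer seed; output is a deterministic function of
#'   (layout, schedule, group, seed).
#' @return A list of class `rendered_video` with elements `stacks` (list
#'   of [frame_stack], one per segment) and `manifest` (patch-box tibble).
#' @export
render_video <- function(layout = scene_layout(), schedule = segment_schedule(),
                         group = c("DM", "C"), seed = 1) {
  stopifnot(inherits(layout, "scene_layout"),
            inherits(schedule, "segment_schedule"))
  group <- match.arg(group)
  regime <- group_regimes(layout)[[group]]
  h <- layout$frame_size[["h"]]; w <- layout$frame_size[["w"]]
  fps <- schedule$fps
  base <- array(rep(layout$base_rgb, each = h * w), c(h, w, 3))
  stacks <- purrr::imap(as.list(schedule$segment_lengths), function(T_len, i) {
    seg_seed <- derive_seed(seed, paste0("render-", group, "-", i))
    with_seed_(seg_seed, {
      frames <- array(base, c(h, w, 3, T_len))
      tt <- seq_len(T_len) / fps
      pulse <- sin(2 * pi * layout$pulse_hz * tt)
      beat_amp <- if (is.finite(regime$beat_exponent)) {
        beat_amplitudes(T_len, fps, layout$pulse_hz, regime$beat_exponent)
      } else {
        1
      }
      cheek_sig <- regime$redness_offset +
        regime$pulse_amp * beat_amp * pulse
      if (regime$gauss_sd > 0) {
        cheek_sig <- cheek_sig + rnorm(T_len, sd = regime$gauss_sd)
      }
      # faint common pulse on background patches (shared physiology)
      bg_sig <- 0.2 * layout$modulation_amp * pulse
      for (b in seq_len(nrow(layout$patch_boxes))) {
        bx <- layout$patch_boxes[b, ]
        rows <- (bx$y + 1):(bx$y + bx$h)
        cols <- (bx$x + 1):(bx$x + bx$w)
        sig <- if (bx$role == "cheek") cheek_sig else bg_sig
        frames[rows, cols, 1, ] <- frames[rows, cols, 1, ] +
          rep(sig, each = length(rows) * length(cols))
      }
      if (layout$noise_sd > 0) {
        frames <- frames + rnorm(length(frames), sd = layout$noise_sd)
      }
      frame_stack(frames, fps = fps, segment = i)
    })
  })
  structure(list(stacks = stacks, manifest = layout$patch_boxes,
                 group = group, seed = seed),
            class = "rendered_video")
}
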