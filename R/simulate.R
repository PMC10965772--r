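#' Scenario configuration for the ventilation simulator
#'
#' Defaults reproduce the study conditions of spontaneously breathing
#' isoflurane-anaesthetised chickens: 2-min recordings at 48 frames/s from
#' a 32-electrode belt driving 5 mA (the 192 kHz carrier is metadata only
#' -- the forward model is quasi-static), respiratory rate 10/min and heart
#' rate 240/min (mid-range of the observed physiology), cardiac flutter at
#' 3% of the tidal conductivity swing ("minuscule" but spectrally
#' detectable), and a tidal air-sac conductivity swing of 15% about a
#' 0.3 S/m baseline (absolute conductivity is immaterial for difference
#' imaging).
#'
#' @param recumbency one of `"dorsal"`, `"ventral"`, `"right_lateral"`,
#'   `"left_lateral"`; selects the axis along which an imposed shift acts.
#' @param rr respiratory rate, breaths/min.
#' @param hr heart rate, beats/min; must exceed four times the respiratory
#'   rate so the bands are separable.
#' @param brp generating breathing pattern, 1..4.
#' @param tiv_scale fractional air-sac conductivity swing (alpha).
#' @param cardiac_frac cardiac amplitude as a fraction of the tidal swing,
#'   in `[0, 0.2]`.
#' @param shift signed fraction in `[-1, 1]`; positive biases ventilation
#'   toward the non-dependent side/aspect of the chosen recumbency.
#' @param noise_sd channel noise as a fraction of the mean absolute voltage
#'   difference.
#' @param duration_s,fps recording length and frame rate.
#' @param seed integer root seed; waveform jitter and channel noise use
#'   independent sub-streams so that adding noise never perturbs breath
#'   timing.
#' @param current_A drive current.
#' @param sigma_base baseline conductivity, S/m.
#' @param carrier_hz carrier frequency (metadata).
#' @return a list of class `eit_scenario`.
#' @export
scenario_config <- function(recumbency = c("dorsal", "ventral",
                                           "right_lateral", "left_lateral"),
                            rr = 10, hr = 240, brp = 1L, tiv_scale = 0.15,
                            cardiac_frac = 0.03, shift = 0, noise_sd = 0.02,
                            duration_s = 120, fps = 48, seed = 1L,
                            current_A = 5e-3, sigma_base = 0.3,
                            carrier_hz = 192000) {
  recumbency <- match.arg(recumbency)
  if (rr <= 0 || hr <= 0) stop("rr and hr must be positive")
  if (hr <= 4 * rr) stop("hr must exceed 4 x rr for band separability")
  if (cardiac_frac < 0 || cardiac_frac > 0.2)
    stop("cardiac_frac must be in [0, 0.2]")
  if (abs(shift) > 1) stop("shift must be in [-1, 1]")
  if (!brp %in% 1:4) stop("brp must be 1, 2, 3 or 4")
  structure(list(recumbency = recumbency, rr = rr, hr = hr, brp = as.integer(brp),
                 tiv_scale = tiv_scale, cardiac_frac = cardiac_frac,
                 shift = shift, noise_sd = noise_sd, duration_s = duration_s,
                 fps = fps, seed = as.integer(seed), current_A = current_A,
                 sigma_base = sigma_base, carrier_hz = carrier_hz),
            class = "eit_scenario")
}

# expiratory shape functions on normalised time, value 1 -> 0
brp_shape <- function(brp) {
  switch(brp,
    function(tau) 1 - tau^2,                                   # BrP1 concave
    function(tau) (1 - tau)^2,                                 # BrP2 convex
    function(tau) piecewise_pause(tau, level = 0.6,            # BrP3 early pause
                                  t1 = 0.25, t2 = 0.40),
    function(tau) piecewise_pause(tau, level = 0.4,            # BrP4 late pause
                                  t1 = 0.45, t2 = 0.60))
}

piecewise_pause <- function(tau, level, t1, t2) {
  ifelse(tau < t1, 1 - (1 - level) * tau / t1,
         ifelse(tau < t2, level, level * (1 - (tau - t2) / (1 - t2))))
}

#' Generate a BrP-shaped air-sac volume waveform
#'
#' Normalised air-sac filling per frame in `[0, 1]`: half-cosine
#' inspiration over an inspiratory fraction drawn around 0.4 (sd 0.05),
#' expiration following the chosen BrP morphology (BrP3/BrP4 include a
#' plateau of 0.15 of the expiratory time at level 0.6 / 0.4), and a seeded
#' per-breath period jitter of +/- 5%.
#'
#' @inheritParams scenario_config
#' @param brp breathing pattern 1..4.
#' @return list with `v` (per-frame filling), `breaths` (frame indices of
#'   start-/end-inspiration and end-expiration for every complete breath),
#'   `brp`, `fps`.
#' @export
breathing_waveform <- function(brp, rr, duration_s, fps = 48, seed = 1L) {
  n <- round(duration_s * fps)
  T0 <- 60 / rr
  if (duration_s < T0) stop("duration shorter than one breath period")
  shape <- brp_shape(brp)
  sched <- with_seed(seed, {
    t0 <- 0; rows <- list()
    while (t0 < duration_s - 1e-9) {
      Tb <- T0 * stats::runif(1L, 0.95, 1.05)
      fi <- min(0.55, max(0.25, stats::rnorm(1L, 0.4, 0.05)))
      rows[[length(rows) + 1L]] <- c(t0, t0 + fi * Tb, t0 + Tb)
      t0 <- t0 + Tb
    }
    do.call(rbind, rows)
  })
  tt <- (seq_len(n) - 1L) / fps
  v <- numeric(n)
  for (k in seq_len(nrow(sched))) {
    s <- sched[k, ]
    ins <- tt >= s[1L] & tt < s[2L]
    v[ins] <- (1 - cos(pi * (tt[ins] - s[1L]) / (s[2L] - s[1L]))) / 2
    ex <- tt >= s[2L] & tt < s[3L]
    v[ex] <- shape(pmin(1, (tt[ex] - s[2L]) / (s[3L] - s[2L])))
  }
  frame_of <- function(t) pmin(n, pmax(1L, round(t * fps) + 1L))
  br <- data.frame(i_start_insp = frame_of(sched[, 1L]),
                   i_end_insp = frame_of(sched[, 2L]),
                   i_end_exp = frame_of(sched[, 3L]))
  br <- br[sched[, 3L] <= duration_s + 1e-9, , drop = FALSE]   # complete breaths
  list(v = v, breaths = br, brp = brp, fps = fps)
}

# axis coordinate in [0, 1] toward the non-dependent side for a recumbency
nondependent_coord <- function(cent, recumbency) {
  a <- switch(recumbency,
              dorsal = -cent[, 2L],          # on the back: non-dependent = ventral
              ventral = cent[, 2L],          # on the keel: non-dependent = dorsal
              right_lateral = cent[, 1L],    # right side down: non-dependent = left
              left_lateral = -cent[, 1L])
  if (diff(range(a)) == 0) return(rep(0.5, length(a)))
  (a - min(a)) / (max(a) - min(a))
}

#' Render a volume waveform to per-frame element conductivities
#'
#' Air-sac elements lose conductivity in proportion to filling (air is an
#' insulator): `sigma_e(t) = sigma_base (1 - alpha v(t) g_e)` with a
#' spatial gain `g_e` in `[1 - |shift|, 1 + |shift|]` increasing toward the
#' non-dependent side of the configured recumbency. Lung elements stay
#' constant (the parabronchial lung is non-compliant and isovolumetric);
#' cardiac elements carry a small heart-rate-synchronous flutter;
#' background is constant.
#'
#' @param p an `eit_phantom` with `airsac`/`cardiac` labels.
#' @param wf waveform from [breathing_waveform()].
#' @param cfg an `eit_scenario`.
#' @return matrix elements x frames of conductivities, S/m.
#' @export
conductivity_movie <- function(p, wf, cfg) {
  if (!any(p$element_labels == "airsac"))
    stop("phantom has no airsac-labelled elements")
  alpha <- cfg$tiv_scale
  if (alpha * (1 + abs(cfg$shift)) >= 1)
    stop("tiv_scale x (1 + |shift|) must be < 1 (conductivity would be <= 0)")
  n <- length(wf$v)
  ne <- nrow(p$elements)
  g <- rep(1, ne)
  air <- p$element_labels == "airsac"
  xi <- nondependent_coord(p$element_centroids[air, , drop = FALSE], cfg$recumbency)
  g_air <- 1 + cfg$shift * (2 * xi - 1)
  tt <- (seq_len(n) - 1L) / cfg$fps
  card_wave <- alpha * cfg$cardiac_frac * (1 + sin(2 * pi * (cfg$hr / 60) * tt)) / 2
  sig <- matrix(cfg$sigma_base, ne, n)
  sig[air, ] <- cfg$sigma_base * (1 - alpha * outer(g_air, wf$v))
  card <- p$element_labels == "cardiac"
  if (any(card))
    sig[card, ] <- cfg$sigma_base * (1 - matrix(card_wave, sum(card), n, byrow = TRUE))
  sig
}

#' Simulate a full EIT recording with ground truth
#'
#' Generates the waveform, renders conductivities, solves the forward
#' problem frame by frame, and adds seeded Gaussian channel noise with
#' standard deviation `noise_sd` times the mean absolute voltage deviation
#' from the reference frame (the first end-expiration frame, i.e. frame 1,
#' where filling is zero).
#'
#' @param p an `eit_phantom`.
#' @param cfg an `eit_scenario`.
#' @param pat an `eit_pattern` (default adjacent 32-electrode).
#' @return an object of class `eit_recording`: `voltages` (channels x
#'   frames), `time`, `fps`, `pattern`, `ref_frame`, acquisition metadata,
#'   and `truth` (volume curve, breath boundaries, BrP, shift).
#' @export
simulate_recording <- function(p, cfg, pat = make_pattern(32L, 0L)) {
  seeds <- with_seed(cfg$seed, sample.int(2^31 - 1L, 2L))
  wf <- breathing_waveform(cfg$brp, cfg$rr, cfg$duration_s, cfg$fps,
                           seed = seeds[1L])
  sig <- conductivity_movie(p, wf, cfg)
  V <- solve_forward_frames(p, sig, pat, cfg$current_A)
  ref <- 1L
  if (cfg$noise_sd > 0) {
    dv <- V - V[, ref]
    sd_n <- cfg$noise_sd * mean(abs(dv))
    V <- V + with_seed(seeds[2L],
                       matrix(stats::rnorm(length(V), 0, sd_n), nrow(V)))
  }
  structure(list(voltages = V,
                 time = (seq_len(ncol(V)) - 1L) / cfg$fps,
                 fps = cfg$fps, pattern = pat, ref_frame = ref,
                 current_A = cfg$current_A, carrier_hz = cfg$carrier_hz,
                 n_electrodes = pat$n_electrodes, skip = pat$skip,
                 scenario = cfg,
                 truth = list(volume = wf$v, breaths = wf$breaths,
                              brp = wf$brp, shift = cfg$shift)),
            class = "eit_recording")
}

#' @export
print.eit_recording <- function(x, ...) {
  cat(sprintf("<eit_recording: %d frames x %d channels at %g fps (%s, BrP%d, shift %+.2f)>\n",
              ncol(x$voltages), nrow(x$voltages), x$fps,
              x$scenario$recumbency, x$truth$brp, x$truth$shift))
  invisible(x)
}
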