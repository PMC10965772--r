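#' Extract and normalise the expiratory limb of a breath
#'
#' The segment from end-inspiration to end-expiration, normalised to
#' amplitude 1 at end-inspiration and 0 at end-expiration, on a normalised
#' time axis tau in `[0, 1]`. All breathing-pattern classification operates
#' on this representation, which makes it invariant to amplitude scaling
#' and breath duration.
#'
#' @param c an `eit_global_curve` (cardiac-filtered).
#' @param b one row of the breath table.
#' @return an object of class `eit_expiration`: `z_norm`, `tau`, `fs`.
#' @export
extract_expiration <- function(c, b) {
  stopifnot(inherits(c, "eit_global_curve"))
  i1 <- b$i_end_insp[1L]; i2 <- b$i_end_exp[1L]
  seg <- c$z[i1:i2]
  if (length(seg) < 5L) stop("expiration too short: ", length(seg), " frames")
  amp <- seg[1L] - seg[length(seg)]
  if (amp <= 0) stop("expiration has non-positive amplitude")
  z_norm <- (seg - seg[length(seg)]) / amp
  tau <- (seq_along(seg) - 1L) / (length(seg) - 1L)
  structure(list(z_norm = z_norm, tau = tau, fs = c$fps),
            class = "eit_expiration")
}

#' Detect an expiratory impedance pause (plateau)
#'
#' A pause is a momentary plateau in the expiratory impedance signal,
#' marked by a distinct inflexion point. Operationally: slopes are
#' estimated over a short window (`smooth_s`, robust to residual flutter
#' and channel noise); a plateau core is the longest run with absolute
#' slope below `slope_frac` times the mean absolute expiratory slope,
#' extended in both directions while the slope stays below four times
#' that threshold (hysteresis, recovering plateau shoulders rounded by the
#' anti-cardiac filter). A candidate is rejected when it touches the start
#' of expiration (the smooth end-inspiratory turn is not a pause), when it
#' starts in the final 5% of expiration or below `min_level` (the terminal
#' baseline is not a pause), or when it is shorter than `min_pause_s`.
#'
#' @param e an `eit_expiration`.
#' @param min_pause_s minimum plateau duration, seconds.
#' @param slope_frac core slope threshold as a fraction of the mean
#'   absolute slope of the normalised expiration.
#' @param smooth_s slope-estimation half-window, seconds.
#' @param min_level lowest normalised impedance at which a plateau onset
#'   still counts as a pause rather than the terminal baseline.
#' @return `NULL` if no pause, else a list with `onset_level` (normalised
#'   impedance at plateau onset), `tau_start`, `tau_end`, `duration_s`.
#' @export
detect_pause <- function(e, min_pause_s = 0.3, slope_frac = 0.1,
                         smooth_s = 0.08, min_level = 0.1) {
  stopifnot(inherits(e, "eit_expiration"))
  n <- length(e$z_norm)
  w <- max(1L, round(smooth_s * e$fs))
  lo <- pmax(1L, seq_len(n) - w); hi <- pmin(n, seq_len(n) + w)
  sl <- (e$z_norm[hi] - e$z_norm[lo]) / (e$tau[hi] - e$tau[lo])
  thr <- slope_frac * mean(abs(diff(e$z_norm) / diff(e$tau)))
  core <- abs(sl) <= thr & e$tau <= 0.95
  if (!any(core)) return(NULL)
  ext <- abs(sl) <= 4 * thr
  r <- rle(core)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  best <- NULL
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    while (i0 > 1L && ext[i0 - 1L]) i0 <- i0 - 1L
    while (i1 < n && ext[i1 + 1L]) i1 <- i1 + 1L
    if (i0 == 1L) next                       # touches start of expiration
    if (e$tau[i0] > 0.95 || e$z_norm[i0] < min_level) next
    if (is.null(best) || (i1 - i0) > (best[2L] - best[1L])) best <- c(i0, i1)
  }
  if (is.null(best)) return(NULL)
  duration_s <- (best[2L] - best[1L]) / e$fs
  if (duration_s < min_pause_s) return(NULL)
  list(onset_level = e$z_norm[best[1L]], tau_start = e$tau[best[1L]],
       tau_end = e$tau[best[2L]], duration_s = duration_s)
}

#' Classify one breath's expiratory morphology (BrP1-4)
#'
#' With a pause: BrP3 when the plateau onset is in the early phase of
#' expiration (remaining impedance change > 50%), BrP4 when late
#' (<= 50%). Without a pause the curve is compared with the straight chord
#' `1 - tau`: signed area at or above the chord means a concave-linear
#' expiration (BrP1), below means convex-linear (BrP2). The `A >= 0` tie
#' break assigns near-linear curves to BrP1, whose definition embraces the
#' linear shape.
#'
#' @param e an `eit_expiration`.
#' @param pause result of [detect_pause()] (or `NULL`).
#' @return list with `label` (one of `"BrP1".."BrP4"`) and `pause_level`
#'   (`NA` unless BrP3/BrP4).
#' @export
classify_breath <- function(e, pause = detect_pause(e)) {
  stopifnot(inherits(e, "eit_expiration"))
  if (!is.null(pause)) {
    lab <- if (pause$onset_level > 0.5) "BrP3" else "BrP4"
    return(list(label = lab, pause_level = pause$onset_level))
  }
  dev <- e$z_norm - (1 - e$tau)
  a <- pracma::trapz(e$tau, dev)
  list(label = if (a >= 0) "BrP1" else "BrP2", pause_level = NA_real_)
}

#' Per-recording breathing-pattern label
#'
#' A recording is assigned a breathing pattern only when at least 95% of
#' the analysed breaths fall into a single category; otherwise it is
#' labelled `"mixed"`.
#'
#' @param labels character vector of per-breath labels (`"BrP1".."BrP4"`).
#' @param min_share uniformity threshold (default 0.95).
#' @return a single label string.
#' @export
classify_recording <- function(labels, min_share = 0.95) {
  if (!length(labels)) stop("no breath labels to classify")
  tab <- table(labels)
  modal <- names(tab)[which.max(tab)]
  if (max(tab) / length(labels) >= min_share) modal else "mixed"
}
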