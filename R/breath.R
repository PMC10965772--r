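#' Global impedance-time curve of an image stream
#'
#' The conventional global ventilation signal: the per-frame sum of all
#' in-mask pixel values (out-of-mask pixels are zero by construction).
#'
#' @param images an `eit_image_stream`.
#' @return an object of class `eit_global_curve`: `z` (per-frame sum, AU),
#'   `fps`, `filtered`.
#' @export
global_curve <- function(images) {
  stopifnot(inherits(images, "eit_image_stream"))
  nt <- dim(images$frames)[3L]
  if (nt < 1L) stop("empty image stream")
  z <- apply(images$frames, 3L, sum)
  structure(list(z = z, fps = images$fps, filtered = FALSE),
            class = "eit_global_curve")
}

#' @export
print.eit_global_curve <- function(x, ...) {
  cat(sprintf("<eit_global_curve: %d frames at %g fps%s>\n",
              length(x$z), x$fps, if (x$filtered) ", filtered" else ""))
  invisible(x)
}

#' Remove cardiac flutter from the global curve
#'
#' Heart-rate-synchronous flutter (>= ~3.3 Hz at 200 beats/min) sits well
#' above the respiratory band (< 0.5 Hz at 12 breaths/min or less), so a
#' zero-phase low-pass filter separates the two without shifting breath
#' timing. A 4th-order Butterworth applied forward-backward
#' ([signal::filtfilt()]) gives > 60 dB attenuation at typical chicken
#' heart rates with a flat respiratory passband.
#'
#' @param c an `eit_global_curve`.
#' @param cutoff low-pass corner frequency, Hz (between the respiratory and
#'   cardiac bands).
#' @param order Butterworth order (effective order doubles under
#'   forward-backward filtering).
#' @return the filtered `eit_global_curve`.
#' @export
remove_cardiac <- function(c, cutoff = 1.5, order = 4L) {
  stopifnot(inherits(c, "eit_global_curve"))
  if (cutoff >= c$fps / 2) stop("cutoff must be below the Nyquist frequency ",
                                c$fps / 2, " Hz")
  if (cutoff <= 0) stop("cutoff must be positive")
  bf <- signal::butter(order, cutoff / (c$fps / 2), type = "low")
  zf <- signal::filtfilt(bf, c$z - c$z[1L]) + c$z[1L]   # avoid edge step
  structure(list(z = zf, fps = c$fps, filtered = TRUE),
            class = "eit_global_curve")
}

# Alternating local extrema of a curve, pruned so that every min->max or
# max->min excursion has prominence >= prom_frac x median excursion.
# Returns data.frame(index, type) with type "min"/"max", strictly
# alternating, starting and ending arbitrarily.
alternating_extrema <- function(z, prom_frac = 0.2) {
  n <- length(z)
  dz <- diff(z)
  s <- sign(dz)
  s[s == 0] <- NA
  s <- zoo_fill(s)                      # carry direction through flats
  if (all(is.na(s))) return(data.frame(index = integer(), type = character()))
  # interior turning points only: a recording cut mid-swing must not start
  # or end a breath at its first or last frame
  idx <- which(diff(s) != 0) + 1L
  if (!length(idx)) return(data.frame(index = integer(), type = character()))
  type <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    type[k] <- if (z[i] >= max(z[lo], z[hi])) "max" else "min"
  }
  ex <- data.frame(index = idx, type = type)
  ex <- collapse_alternating(ex, z)
  # prominence pruning: drop the weakest adjacent extremum pair until all
  # excursions clear the threshold (median recomputed as noise is removed)
  repeat {
    if (nrow(ex) < 3L) break
    exc <- abs(diff(z[ex$index]))
    thr <- prom_frac * stats::median(exc)
    weak <- which(exc < thr)
    if (!length(weak)) break
    k <- weak[which.min(exc[weak])]
    # a sub-threshold excursion marks both of its endpoints as noise (e.g.
    # a wiggle on an expiratory plateau); removing only one would leave a
    # false breath boundary behind
    ex <- ex[-c(k, k + 1L), , drop = FALSE]
    ex <- collapse_alternating(ex, z)
  }
  ex
}

# forward-fill NAs (direction through flat samples)
zoo_fill <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cumsum(ok)
  filled <- c(NA, x[ok])[idx + 1L]
  # leading NAs: back-fill from first direction
  filled[is.na(filled)] <- x[ok][1L]
  filled
}

# merge runs of same-type extrema, keeping the most extreme one
collapse_alternating <- function(ex, z) {
  if (nrow(ex) < 2L) return(ex)
  keep <- rep(TRUE, nrow(ex))
  k <- 1L
  while (k < nrow(ex)) {
    j <- k + 1L
    while (j <= nrow(ex) && ex$type[j] == ex$type[k]) j <- j + 1L
    if (j - k > 1L) {
      grp <- k:(j - 1L)
      best <- if (ex$type[k] == "max") grp[which.max(z[ex$index[grp]])]
              else grp[which.min(z[ex$index[grp]])]
      keep[setdiff(grp, best)] <- FALSE
    }
    k <- j
  }
  ex[keep, , drop = FALSE]
}

#' Segment breaths on the (filtered) global curve
#'
#' Breaths are spans minimum -> maximum -> next minimum of the global
#' curve: start-inspiration, end-inspiration, end-expiration. Candidate
#' extrema are pruned by prominence (default: excursions below 20% of the
#' median peak-to-trough excursion are treated as noise). Tidal impedance
#' variation is `TIV = z[end-inspiration] - z[start-inspiration]` (the
#' conventional non-negative tidal variation), and the inspiratory time is
#' the duration from start- to end-inspiration.
#'
#' @param c an `eit_global_curve` (filter first with [remove_cardiac()]).
#' @param prom_frac prominence threshold as a fraction of the median
#'   excursion.
#' @return data.frame with one row per complete breath: `i_start_insp`,
#'   `i_end_insp`, `i_end_exp` (frame indices), `tiv` (AU), `t_insp` (s).
#' @export
detect_breaths <- function(c, prom_frac = 0.2) {
  stopifnot(inherits(c, "eit_global_curve"))
  ex <- alternating_extrema(c$z, prom_frac)
  empty <- data.frame(i_start_insp = integer(), i_end_insp = integer(),
                      i_end_exp = integer(), tiv = numeric(), t_insp = numeric())
  if (nrow(ex) < 3L) { warning("no complete breath cycles found"); return(empty) }
  if (ex$type[1L] == "max") ex <- ex[-1L, , drop = FALSE]
  if (nrow(ex) < 3L) { warning("no complete breath cycles found"); return(empty) }
  nb <- (nrow(ex) - 1L) %/% 2L
  out <- empty
  for (k in seq_len(nb)) {
    i0 <- ex$index[2L * k - 1L]; i1 <- ex$index[2L * k]; i2 <- ex$index[2L * k + 1L]
    out[k, ] <- list(i0, i1, i2, c$z[i1] - c$z[i0], (i1 - i0) / c$fps)
  }
  out
}

#' Select consecutive artefact-free breaths
#'
#' Returns the longest run of consecutive breaths whose TIV and total
#' duration both lie within `tol` (default 50%) of the respective medians
#' over all detected breaths; apnoeic gaps longer than `max_gap_s` break a
#' run. The earliest longest run is preferred and truncated to its first
#' `max_n` breaths.
#'
#' @param breaths data.frame from [detect_breaths()], in time order.
#' @param fps frames per second (needed for the gap rule).
#' @param min_n,max_n minimum acceptable / maximum analysed run length.
#' @param tol fractional deviation from the median that still counts as
#'   artefact-free.
#' @param max_gap_s apnoea gap that terminates a run, seconds.
#' @return the selected subset of `breaths` (row-bound, in time order).
#' @export
select_artefact_free <- function(breaths, fps, min_n = 6L, max_n = 10L,
                                 tol = 0.5, max_gap_s = 10) {
  if (nrow(breaths) < min_n)
    stop("insufficient artefact-free breaths: ", nrow(breaths), " detected, ",
         min_n, " required")
  dur <- (breaths$i_end_exp - breaths$i_start_insp) / fps
  med_tiv <- stats::median(breaths$tiv)
  med_dur <- stats::median(dur)
  ok <- abs(breaths$tiv - med_tiv) <= tol * med_tiv &
        abs(dur - med_dur) <= tol * med_dur
  gap_break <- c(FALSE, (breaths$i_start_insp[-1L] -
                         breaths$i_end_exp[-nrow(breaths)]) / fps > max_gap_s)
  run_id <- cumsum(!ok | gap_break)
  runs <- split(which(ok), run_id[ok])
  if (!length(runs)) stop("insufficient artefact-free breaths")
  lens <- lengths(runs)
  best <- runs[[which.max(lens)]]       # earliest on ties (split preserves order)
  if (length(best) < min_n)
    stop("insufficient artefact-free breaths: best run has ", length(best),
         ", ", min_n, " required")
  breaths[best[seq_len(min(length(best), max_n))], , drop = FALSE]
}
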