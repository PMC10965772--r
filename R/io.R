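#' Write / read a voltage recording
#'
#' Plain-text serialisation: `<path>` holds the voltages as CSV, one row
#' per frame with channels in pattern order at full double precision, and
#' `<path without extension>.json` carries the acquisition metadata
#' (fps, electrode count, skip, drive current, carrier), the stimulation
#' pattern, the reference frame and -- for simulated recordings -- the
#' ground truth. The round trip is lossless to better than 1e-12.
#'
#' @param rec an `eit_recording`.
#' @param path CSV file path; the JSON sidecar is derived from it.
#' @return `read_recording` returns an `eit_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eit_recording"))
  V <- rec$voltages
  lines <- apply(V, 2L, function(col) paste(sprintf("%.17g", col), collapse = ","))
  writeLines(lines, path)
  meta <- list(
    schema = "avianEIT-recording-1",
    fps = rec$fps, n_electrodes = rec$n_electrodes, skip = rec$skip,
    current_A = rec$current_A, carrier_hz = rec$carrier_hz,
    ref_frame = rec$ref_frame,
    pattern = list(injections = unname(rec$pattern$injections),
                   channels = rec$pattern$channels),
    scenario = if (!is.null(rec$scenario)) unclass(rec$scenario),
    truth = if (!is.null(rec$truth))
      list(volume = rec$truth$volume, breaths = rec$truth$breaths,
           brp = rec$truth$brp, shift = rec$truth$shift))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".json")

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("metadata sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$pattern)) stop("pattern not found in ", side)
  for (k in c("fps", "n_electrodes", "skip", "current_A"))
    if (is.null(meta[[k]])) stop("required attribute '", k, "' not found in ", side)
  V <- t(as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                     colClasses = "numeric")))
  dimnames(V) <- NULL
  pat <- make_pattern(meta$n_electrodes, meta$skip)
  if (pat$n_channels != nrow(V))
    stop("voltage CSV has ", nrow(V), " channels but the pattern implies ",
         pat$n_channels)
  truth <- NULL
  if (!is.null(meta$truth))
    truth <- list(volume = meta$truth$volume,
                  breaths = as.data.frame(meta$truth$breaths),
                  brp = meta$truth$brp, shift = meta$truth$shift)
  cfg <- NULL
  if (!is.null(meta$scenario))
    cfg <- structure(meta$scenario, class = "eit_scenario")
  structure(list(voltages = V,
                 time = (seq_len(ncol(V)) - 1L) / meta$fps,
                 fps = meta$fps, pattern = pat,
                 ref_frame = if (is.null(meta$ref_frame)) 1L else meta$ref_frame,
                 current_A = meta$current_A, carrier_hz = meta$carrier_hz,
                 n_electrodes = meta$n_electrodes, skip = meta$skip,
                 scenario = cfg, truth = truth),
            class = "eit_recording")
}
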