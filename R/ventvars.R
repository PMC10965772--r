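#' Per-breath functional (tidal) image
#'
#' Pixel-wise difference between the end-inspiration and start-inspiration
#' frames of one breath. Negative pixels (out-of-phase artefacts) are
#' retained in the raw image; every distribution metric clamps them to zero
#' so they can never contribute negative "ventilation".
#'
#' @param images an `eit_image_stream`.
#' @param b one row of the breath table from [detect_breaths()].
#' @return an object of class `eit_func_image`: `pixels` (32 x 32), `mask`.
#' @export
tidal_image <- function(images, b) {
  stopifnot(inherits(images, "eit_image_stream"))
  nt <- dim(images$frames)[3L]
  i0 <- b$i_start_insp[1L]; i1 <- b$i_end_insp[1L]
  if (i0 < 1L || i1 < 1L || i0 > nt || i1 > nt)
    stop("breath frame indices out of range (stream has ", nt, " frames)")
  structure(list(pixels = images$frames[, , i1] - images$frames[, , i0],
                 mask = images$mask),
            class = "eit_func_image")
}

#' Construct a functional image directly from pixel values
#'
#' @param pixels 32 x 32 matrix (row 1 dorsal, column 1 subject's right).
#' @param mask 32 x 32 logical in-body mask; pixels outside are zeroed.
#' @return an `eit_func_image`.
#' @export
functional_image <- function(pixels, mask) {
  pixels <- as.matrix(pixels)
  stopifnot(all(dim(pixels) == dim(mask)))
  pixels[!mask] <- 0
  structure(list(pixels = pixels, mask = mask), class = "eit_func_image")
}

clamped <- function(f) {
  w <- pmax(f$pixels, 0)
  w[!f$mask] <- 0
  w
}

mask_bbox <- function(mask) {
  rs <- range(which(apply(mask, 1L, any)))
  cs <- range(which(apply(mask, 2L, any)))
  list(rmin = rs[1L], rmax = rs[2L], cmin = cs[1L], cmax = cs[2L])
}

#' Centre of ventilation along the right-left or ventral-dorsal axis
#'
#' The ventilation-weighted mean pixel position along the chosen axis,
#' normalised to the bounding box of the body mask and expressed in
#' percent. Conventions: `CoV_RL` runs 0% at the subject's right edge to
#' 100% at the left edge; `CoV_VD` runs 0% at the ventral edge to 100% at
#' the dorsal edge. So 0% CoV_RL means ventilation confined to the right
#' coelom, 0% CoV_VD means ventilation confined ventrally.
#'
#' @param f an `eit_func_image`.
#' @param axis `"RL"` or `"VD"`.
#' @return percentage in `[0, 100]`.
#' @export
centre_of_ventilation <- function(f, axis = c("RL", "VD")) {
  axis <- match.arg(axis)
  w <- clamped(f)
  tot <- sum(w)
  if (tot <= 0) stop("no ventilation signal: functional image is non-positive")
  bb <- mask_bbox(f$mask)
  n <- nrow(w)
  if (axis == "RL") {
    # column 1 = subject's right; u = 0 right edge -> 1 left edge
    u <- if (bb$cmax > bb$cmin) (seq_len(n) - bb$cmin) / (bb$cmax - bb$cmin)
         else rep(0.5, n)
    uw <- matrix(u, n, n, byrow = TRUE)
  } else {
    # row 1 = dorsal; u = 0 ventral edge -> 1 dorsal edge
    u <- if (bb$rmax > bb$rmin) (bb$rmax - seq_len(n)) / (bb$rmax - bb$rmin)
         else rep(0.5, n)
    uw <- matrix(u, n, n)
  }
  100 * sum(w * uw) / tot
}

# per-column weight on the right side of the mask-bounding-box midline
# (columns straddling the midline split half-half)
right_side_weight <- function(n, bb) {
  mid <- (bb$cmin + bb$cmax) / 2
  w <- as.numeric(seq_len(n) < mid)
  w[seq_len(n) == mid] <- 0.5
  w
}

#' Right-to-left ventilation ratio
#'
#' Sum of clamped pixel values on the subject's right of the mask midline
#' divided by the sum on the left; the midline is the vertical through the
#' centre of the mask bounding box, and a pixel column straddling it is
#' split half-half.
#'
#' @param f an `eit_func_image`.
#' @return positive ratio `sum(right) / sum(left)`.
#' @export
rl_ratio <- function(f) {
  w <- clamped(f)
  n <- nrow(w)
  rw <- right_side_weight(n, mask_bbox(f$mask))
  colsum <- colSums(w)
  right <- sum(colsum * rw)
  left <- sum(colsum * (1 - rw))
  if (left <= 0) stop("undefined RL ratio: left-side ventilation sum is zero")
  right / left
}

#' Eight-region ventilation distribution
#'
#' The mask bounding box is split into four equal-height horizontal bands
#' (dorsal, central-dorsal, central-ventral, ventral) and each band into a
#' right and left half at the bounding-box midline; each region's clamped
#' pixel sum is expressed as a percentage of the total, so the eight values
#' sum to 100. Pixel rows straddling a band edge are split in proportion to
#' their overlap.
#'
#' @param f an `eit_func_image`.
#' @return named numeric vector `R_D, R_CD, R_CV, R_V, L_D, L_CD, L_CV,
#'   L_V`, in percent.
#' @export
regional_distribution <- function(f) {
  w <- clamped(f)
  tot <- sum(w)
  if (tot <= 0) stop("no ventilation signal: functional image is non-positive")
  n <- nrow(w)
  bb <- mask_bbox(f$mask)
  H <- bb$rmax - bb$rmin + 1
  # row r spans [r - rmin, r - rmin + 1] in band units [0, H], dorsal at 0
  lo <- seq_len(n) - bb$rmin
  hi <- lo + 1
  band_w <- sapply(1:4, function(k) {
    pmax(0, pmin(hi, k * H / 4) - pmax(lo, (k - 1) * H / 4))
  })                                    # n x 4 row weights
  rw <- right_side_weight(n, bb)
  out <- numeric(8L)
  for (k in 1:4) {
    wk <- w * band_w[, k]
    cs <- colSums(wk)
    out[k] <- sum(cs * rw)              # right side
    out[k + 4L] <- sum(cs * (1 - rw))   # left side
  }
  names(out) <- c("R_D", "R_CD", "R_CV", "R_V", "L_D", "L_CD", "L_CV", "L_V")
  100 * out / tot
}

#' Ventilation variables for a set of breaths
#'
#' Computes, for each breath, the tidal image and the full set of
#' distribution variables (CoV_RL, CoV_VD, RL ratio, eight regional
#' percentages), carrying over TIV and inspiratory time from the breath
#' table, plus the arithmetic means over the selected breaths.
#'
#' @param images an `eit_image_stream`.
#' @param breaths breath table (typically from [select_artefact_free()]).
#' @return list with `per_breath` (data.frame, one row per breath) and
#'   `means` (named numeric vector of column means).
#' @export
variables_for_breaths <- function(images, breaths) {
  if (nrow(breaths) < 1L) stop("need at least one breath")
  rows <- lapply(seq_len(nrow(breaths)), function(k) {
    b <- breaths[k, , drop = FALSE]
    f <- tidal_image(images, b)
    reg <- regional_distribution(f)
    data.frame(breath = k,
               tiv = b$tiv, t_insp = b$t_insp,
               cov_rl = centre_of_ventilation(f, "RL"),
               cov_vd = centre_of_ventilation(f, "VD"),
               rl_ratio = rl_ratio(f),
               as.list(reg))
  })
  per_breath <- do.call(rbind, rows)
  means <- colMeans(per_breath[, -1L, drop = FALSE])
  list(per_breath = per_breath, means = means)
}
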