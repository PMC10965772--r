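## GREIT: linear reconstruction matrix trained on simulated point targets
## with a desired-image criterion, regularised to a prescribed noise figure.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Train a GREIT reconstruction matrix for a phantom
#'
#' Implements the Graz consensus linear reconstruction: small circular
#' conductivity-decrease targets are scattered over the body cross-section,
#' their (normalised) boundary-voltage signatures `Y` are computed from the
#' sensitivity matrix, and the reconstruction matrix `R` minimises
#' `||R Y - D||^2 + lambda^2 ||R||^2` where `D` holds the desired blob
#' images on the 32 x 32 grid. `lambda` is calibrated by bisection so the
#' image-domain noise amplification matches `noise_figure`.
#'
#' The sign convention is fixed here: targets are conductivity decreases
#' (air filling), and their desired images are positive, so inspiration
#' reconstructs as positive pixels.
#'
#' @param p an `eit_phantom`.
#' @param pat an `eit_pattern`.
#' @param n_targets number of training targets (>= 50).
#' @param target_radius target radius as a fraction of the mask diameter.
#' @param noise_figure desired ratio of image noise amplification to the
#'   amplification of a central reference target.
#' @param seed integer seed for target placement.
#' @param sigma0 baseline conductivity, S/m.
#' @param current drive current, A.
#' @param blob_factor desired-image blob radius as a multiple of the target
#'   radius.
#' @return an object of class `eit_recon_model`.
#' @export
train_greit <- function(p, pat, n_targets = 1000L, target_radius = 0.05,
                        noise_figure = 0.5, seed = 1L, sigma0 = 0.3,
                        current = 5e-3, blob_factor = 2) {
  if (n_targets < 50L) stop("n_targets < 50: undertrained reconstruction model")
  pm <- p$pixel_mask
  diam <- max(diff(pm$xlim), diff(pm$ylim))
  r_t <- target_radius * diam
  r_blob <- blob_factor * r_t

  sig0 <- rep(sigma0, nrow(p$elements))
  v0 <- solve_forward(p, sig0, pat, current)
  J <- jacobian(p, sig0, pat, current)

  ## Targets are sampled uniformly over the cross-section and mirrored
  ## about the body midline so the trained matrix respects the phantom's
  ## right-left symmetry (half sampled, half reflected).
  pts <- p$outer$points
  n_half <- ceiling(n_targets / 2)
  xmid <- mean(pm$xlim)
  tgt <- with_seed(seed, {
    out <- matrix(0, n_half, 2L)
    got <- 0L
    while (got < n_half) {
      cand <- cbind(stats::runif(4L * n_half, pm$xlim[1L], pm$xlim[2L]),
                    stats::runif(4L * n_half, pm$ylim[1L], pm$ylim[2L]))
      ok <- pracma::inpolygon(cand[, 1L], cand[, 2L], pts[, 1L], pts[, 2L])
      # keep the whole target (and its mirror image) inside the boundary
      for (sgn in c(1, -1)) {
        cx <- xmid + sgn * (cand[, 1L] - xmid)
        ok <- ok & pracma::inpolygon(cx + r_t, cand[, 2L], pts[, 1L], pts[, 2L]) &
              pracma::inpolygon(cx - r_t, cand[, 2L], pts[, 1L], pts[, 2L]) &
              pracma::inpolygon(cx, cand[, 2L] + r_t, pts[, 1L], pts[, 2L]) &
              pracma::inpolygon(cx, cand[, 2L] - r_t, pts[, 1L], pts[, 2L])
      }
      take <- min(sum(ok), n_half - got)
      if (take > 0L) {
        out[(got + 1L):(got + take), ] <- cand[ok, , drop = FALSE][seq_len(take), ]
        got <- got + take
      }
    }
    out
  })
  tgt <- rbind(tgt, cbind(2 * xmid - tgt[, 1L], tgt[, 2L]))[seq_len(2 * n_half), , drop = FALSE]
  n_targets <- nrow(tgt)

  cent <- p$element_centroids
  dsig_amp <- -0.1 * sigma0                       # conductivity decrease
  Y <- matrix(0, pat$n_channels, n_targets)
  inmask_idx <- which(as.vector(t(pm$mask)))      # row-major pixel indices
  pxv <- as.vector(t(pm$px))[inmask_idx]
  pyv <- as.vector(t(pm$py))[inmask_idx]
  D <- matrix(0, length(inmask_idx), n_targets)
  for (t in seq_len(n_targets)) {
    d2 <- (cent[, 1L] - tgt[t, 1L])^2 + (cent[, 2L] - tgt[t, 2L])^2
    hit <- which(d2 <= r_t^2)
    if (!length(hit)) hit <- which.min(d2)
    dsig <- numeric(nrow(cent)); dsig[hit] <- dsig_amp
    Y[, t] <- (J %*% dsig) / v0
    D[, t] <- as.numeric((pxv - tgt[t, 1L])^2 + (pyv - tgt[t, 2L])^2 <= r_blob^2)
  }

  ## R(lambda) = D Y' (Y Y' + lambda^2 I)^-1 via eigendecomposition of Y Y'
  E <- eigen(tcrossprod(Y), symmetric = TRUE)
  M <- D %*% crossprod(Y, E$vectors)              # npix_in x channels
  d_eig <- pmax(E$values, 0)

  ctr_t <- which.min((tgt[, 1L] - mean(pm$xlim))^2 + (tgt[, 2L] - mean(pm$ylim))^2)
  yc <- crossprod(E$vectors, Y[, ctr_t])          # V' y_c
  mean_abs_yc <- mean(abs(Y[, ctr_t]))

  nf_of <- function(log_l2) {
    g <- 1 / (d_eig + 10^log_l2)
    noise_amp <- mean(sqrt(rowSums(sweep(M, 2L, g, "*")^2)))
    sig_amp <- mean(abs(M %*% (g * yc))) / mean_abs_yc
    noise_amp / sig_amp
  }
  lo <- -14; hi <- 10
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (nf_of(mid) > noise_figure) lo <- mid else hi <- mid
  }
  lam2 <- 10^((lo + hi) / 2)
  R_in <- M %*% (t(E$vectors) * (1 / (d_eig + lam2)))

  R <- matrix(0, pm$n * pm$n, pat$n_channels)
  R[inmask_idx, ] <- R_in
  structure(list(R = R, pixel_mask = pm, n_channels = pat$n_channels,
                 fps = 48,
                 training_meta = list(n_targets = n_targets,
                                      target_radius = target_radius,
                                      blob_factor = blob_factor,
                                      noise_figure = noise_figure,
                                      achieved_nf = nf_of(log10(lam2)),
                                      lambda2 = lam2, seed = seed,
                                      sigma0 = sigma0, current = current),
                 v_baseline = v0),
            class = "eit_recon_model")
}

#' @export
print.eit_recon_model <- function(x, ...) {
  cat(sprintf("<eit_recon_model: %d channels -> %d in-mask pixels, NF %.2f, lambda^2 %.3g>\n",
              x$n_channels, sum(x$pixel_mask$mask),
              x$training_meta$achieved_nf, x$training_meta$lambda2))
  invisible(x)
}

#' Reconstruct a difference-image stream from voltage frames
#'
#' Per frame, the normalised voltage difference
#' `dv = (v - v_ref) / v_ref` is mapped through the reconstruction matrix.
#' Positive pixels mean conductivity decrease relative to the reference
#' frame, i.e. air filling during inspiration.
#'
#' @param model an `eit_recon_model`.
#' @param v_ref reference-frame voltages (length = channels), conventionally
#'   an end-expiration frame.
#' @param frames matrix channels x frames (or a single frame vector).
#' @param fps frame rate, frames per second.
#' @return an object of class `eit_image_stream`: `frames` (32 x 32 x T
#'   array, out-of-mask pixels exactly zero), `fps`, `mask`.
#' @export
reconstruct <- function(model, v_ref, frames, fps = 48) {
  stopifnot(inherits(model, "eit_recon_model"))
  if (is.vector(frames)) frames <- matrix(frames, ncol = 1L)
  if (length(v_ref) != model$n_channels || nrow(frames) != model$n_channels)
    stop("channel count mismatch: model has ", model$n_channels, " channels")
  zero <- which(v_ref == 0)
  if (length(zero))
    stop("zero reference voltage on channel ", zero[1L])
  dv <- (frames - v_ref) / v_ref
  X <- model$R %*% dv                              # row-major pixels x T
  n <- model$pixel_mask$n
  nt <- ncol(X)
  arr <- array(0, c(n, n, nt))
  for (t in seq_len(nt)) arr[, , t] <- matrix(X[, t], n, n, byrow = TRUE)
  structure(list(frames = arr, fps = fps, mask = model$pixel_mask$mask),
            class = "eit_image_stream")
}

#' @export
print.eit_image_stream <- function(x, ...) {
  cat(sprintf("<eit_image_stream: %d frames of %dx%d at %g fps>\n",
              dim(x$frames)[3L], dim(x$frames)[1L], dim(x$frames)[2L], x$fps))
  invisible(x)
}
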