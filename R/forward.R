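#' Rotating stimulation/measurement pattern
#'
#' Current is driven between electrode pairs `(i, i+1+skip)` in a rotating
#' sequence; for each injection, differential voltages are measured between
#' all pairs with the same offset that do not involve a driven electrode
#' (the standard convention for belt EIT; `skip = 0` is the adjacent
#' pattern used as the GREIT reference configuration). With 32 electrodes
#' and `skip = 0` this yields 32 injections x 29 measurements = 928
#' channels.
#'
#' @param n_electrodes electrode count.
#' @param skip electrodes skipped between the two driven electrodes
#'   (0 = adjacent pair).
#' @return an object of class `eit_pattern`: `injections` (n x 2 electrode
#'   indices), `channels` (data.frame with `inj`, `mp`, `mm`, `meas_inj` --
#'   the injection whose drive pair coincides with the measurement pair),
#'   `n_electrodes`, `skip`, `n_channels`.
#' @export
make_pattern <- function(n_electrodes = 32L, skip = 0L) {
  n <- as.integer(n_electrodes); skip <- as.integer(skip)
  if (n < 4L) stop("need at least 4 electrodes")
  if (skip < 0L || skip > n - 2L) stop("invalid skip: must be in 0..", n - 2L)
  off <- 1L + skip
  snk <- function(i) ((i - 1L + off) %% n) + 1L
  inj <- cbind(src = seq_len(n), snk = snk(seq_len(n)))
  ch <- do.call(rbind, lapply(seq_len(n), function(d) {
    mp <- seq_len(n); mm <- snk(mp)
    keep <- mp != inj[d, 1L] & mp != inj[d, 2L] & mm != inj[d, 1L] & mm != inj[d, 2L]
    data.frame(inj = d, mp = mp[keep], mm = mm[keep], meas_inj = mp[keep])
  }))
  structure(list(injections = inj, channels = ch, n_electrodes = n,
                 skip = skip, n_channels = nrow(ch)),
            class = "eit_pattern")
}

#' @export
print.eit_pattern <- function(x, ...) {
  cat(sprintf("<eit_pattern: %d electrodes, skip %d, %d injections x ~%d measurements = %d channels>\n",
              x$n_electrodes, x$skip, nrow(x$injections),
              x$n_channels %/% nrow(x$injections), x$n_channels))
  invisible(x)
}

# Precompute P1 element geometry for stiffness assembly and gradients.
# b, c are the usual shape-function coefficient triples; elements are CCW
# so areas are positive.
fem_precompute <- function(p) {
  tri <- p$elements; nodes <- p$nodes
  x1 <- nodes[tri[, 1L], 1L]; y1 <- nodes[tri[, 1L], 2L]
  x2 <- nodes[tri[, 2L], 1L]; y2 <- nodes[tri[, 2L], 2L]
  x3 <- nodes[tri[, 3L], 1L]; y3 <- nodes[tri[, 3L], 2L]
  area <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  if (any(area <= 0)) stop("mesh contains non-positively-oriented elements")
  b <- cbind(y2 - y3, y3 - y1, y1 - y2)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1)
  ne <- nrow(tri)
  ii <- jj <- integer(9L * ne)
  coef <- matrix(0, ne, 9L)
  k <- 1L
  for (a in 1:3) for (bb in 1:3) {
    ii[((k - 1L) * ne + 1L):(k * ne)] <- tri[, a]
    jj[((k - 1L) * ne + 1L):(k * ne)] <- tri[, bb]
    coef[, k] <- (b[, a] * b[, bb] + cc[, a] * cc[, bb]) / (4 * area)
    k <- k + 1L
  }
  out <- list(area = area, b = b, c = cc, ii = ii, jj = jj, coef = coef,
              n_nodes = nrow(nodes))

  # fast per-frame assembly: the grounded (node 1 removed) upper-triangular
  # stiffness pattern is fixed, so triplets are mapped once onto the slots
  # of a symmetric sparse template and only the x-vector changes per frame
  m <- nrow(nodes) - 1L
  keep <- which(ii > 1L & jj > 1L & ii <= jj)
  ri <- ii[keep] - 1L; rj <- jj[keep] - 1L
  key <- (rj - 1L) * m + ri                    # CSC order: by column, then row
  ord <- order(key)
  ks <- key[ord]
  newgrp <- c(TRUE, ks[-1L] != ks[-length(ks)])
  ukey <- ks[newgrp]
  ends <- c(which(newgrp)[-1L] - 1L, length(ks))
  ucol <- (ukey - 1L) %/% m + 1L
  urow <- (ukey - 1L) %% m + 1L
  tmpl <- Matrix::sparseMatrix(i = urow, j = ucol, x = numeric(length(ukey)),
                               dims = c(m, m), symmetric = TRUE)
  out$asm <- list(keep = keep, ord = ord, ends = ends, template = tmpl)
  out
}

# grounded symmetric stiffness (node 1 removed) for one conductivity frame
assemble_reduced <- function(p, sigma) {
  f <- p$fem
  v <- as.vector(f$coef * sigma)[f$asm$keep][f$asm$ord]
  cs <- cumsum(v)
  K <- f$asm$template
  K@x <- diff(c(0, cs[f$asm$ends]))
  K
}

assemble_stiffness <- function(p, sigma) {
  f <- p$fem
  Matrix::sparseMatrix(i = f$ii, j = f$jj, x = as.vector(f$coef * sigma),
                       dims = c(f$n_nodes, f$n_nodes))
}

injection_rhs <- function(p, pat, current) {
  B <- matrix(0, nrow(p$nodes), nrow(pat$injections))
  en <- p$electrode_nodes
  for (d in seq_len(nrow(pat$injections))) {
    B[en[pat$injections[d, 1L]], d] <- current
    B[en[pat$injections[d, 2L]], d] <- -current
  }
  B
}

# Nodal potentials for every injection: n_nodes x n_injections.
# Node 1 (the centre node) is used as the linear-algebra ground; each
# solution is then re-referenced to zero mean over the electrode nodes.
solve_fields <- function(p, sigma, pat, current, chol_cache = NULL,
                         Br = NULL) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("conductivity must be strictly positive and finite")
  Kr <- assemble_reduced(p, sigma)
  Ch <- if (is.null(chol_cache)) Matrix::Cholesky(Kr, LDL = FALSE, perm = TRUE)
        else Matrix::update(chol_cache, Kr)
  if (is.null(Br)) Br <- injection_rhs(p, pat, current)[-1L, , drop = FALSE]
  Ur <- as.matrix(Matrix::solve(Ch, Br))
  U <- rbind(0, Ur)
  U <- sweep(U, 2L, colMeans(U[p$electrode_nodes, , drop = FALSE]))
  list(U = U, chol = Ch)
}

channel_voltages <- function(p, pat, U) {
  en <- p$electrode_nodes
  ch <- pat$channels
  U[en[ch$mp] + (ch$inj - 1L) * nrow(U)] - U[en[ch$mm] + (ch$inj - 1L) * nrow(U)]
}

#' Solve the forward problem for one conductivity field
#'
#' Quasi-static 2-D point-electrode FEM: for each injection the Laplace
#' problem div(sigma grad u) = 0 is solved with +/- `current` nodal sources
#' at the driven electrodes, grounded by a zero-mean potential constraint
#' over the electrodes.
#'
#' @param p an `eit_phantom`.
#' @param sigma per-element conductivity, S/m, strictly positive.
#' @param pat an `eit_pattern`.
#' @param current drive current amplitude, amperes (default 5 mA).
#' @return numeric vector of differential channel voltages, volts, in
#'   pattern order.
#' @export
solve_forward <- function(p, sigma, pat, current = 5e-3) {
  sol <- solve_fields(p, sigma, pat, current)
  channel_voltages(p, pat, sol$U)
}

#' Solve the forward problem for a sequence of conductivity frames
#'
#' The sparse Cholesky symbolic factorisation is computed once and reused
#' across frames (only the numeric factorisation is updated), which is what
#' makes full-length 48 frames/s recordings tractable.
#'
#' @param sigma_frames matrix, elements x frames.
#' @inheritParams solve_forward
#' @return matrix channels x frames.
#' @export
solve_forward_frames <- function(p, sigma_frames, pat, current = 5e-3) {
  nt <- ncol(sigma_frames)
  out <- matrix(0, pat$n_channels, nt)
  cache <- NULL
  Br <- injection_rhs(p, pat, current)[-1L, , drop = FALSE]
  for (t in seq_len(nt)) {
    sol <- solve_fields(p, sigma_frames[, t], pat, current,
                        chol_cache = cache, Br = Br)
    cache <- sol$chol
    out[, t] <- channel_voltages(p, pat, sol$U)
  }
  out
}

# Per-element solution gradients for all injections:
# list(gx, gy), each elements x injections.
element_gradients <- function(p, U) {
  f <- p$fem; tri <- p$elements
  u1 <- U[tri[, 1L], , drop = FALSE]
  u2 <- U[tri[, 2L], , drop = FALSE]
  u3 <- U[tri[, 3L], , drop = FALSE]
  gx <- (f$b[, 1L] * u1 + f$b[, 2L] * u2 + f$b[, 3L] * u3) / (2 * f$area)
  gy <- (f$c[, 1L] * u1 + f$c[, 2L] * u2 + f$c[, 3L] * u3) / (2 * f$area)
  list(gx = gx, gy = gy)
}

#' Sensitivity (Jacobian) of channel voltages to element conductivities
#'
#' Computed by the adjoint-field product: because measurement pairs share
#' the drive-pair offset, the adjoint field of a measurement pair is the
#' drive field of the corresponding injection divided by the drive current,
#' so a single set of forward solves yields every row as
#' `J[ch, e] = -(area_e / I) grad(u_drive) . grad(u_meas)`.
#'
#' @inheritParams solve_forward
#' @param sigma0 baseline conductivity about which to linearise.
#' @return dense matrix, channels x elements, dV/dsigma.
#' @export
jacobian <- function(p, sigma0, pat, current = 5e-3) {
  sol <- solve_fields(p, sigma0, pat, current)
  g <- element_gradients(p, sol$U)
  ch <- pat$channels
  f <- p$fem
  J <- matrix(0, nrow(ch), length(f$area))
  for (k in seq_len(nrow(ch))) {
    d <- ch$inj[k]; m <- ch$meas_inj[k]
    J[k, ] <- -(f$area / current) * (g$gx[, d] * g$gx[, m] + g$gy[, d] * g$gy[, m])
  }
  J
}
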