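#' Build a finite-element phantom from a contour set
#'
#' Constructs the 2-D model used for both forward simulation and GREIT
#' training: a triangular mesh of the body cross-section, 32 electrodes
#' equidistant in arc length along the outer boundary (numbered
#' counter-clockwise starting at the ventral midline), an element label per
#' region, and the 32 x 32 reconstruction pixel mask.
#'
#' The mesh is a structured radial triangulation: the outer contour is
#' resampled to `n_boundary` arc-length-equidistant vertices (a multiple of
#' `n_electrodes`) and concentric rings are scaled towards the area
#' centroid. Interior region boundaries (lungs, cardiac silhouette) are
#' honoured at mesh resolution by labelling each element from its centroid;
#' region edges are therefore resolved to about one element, which is ample
#' for difference imaging on a 32 x 32 grid.
#'
#' Element labels: `lung_r`, `lung_l`, `cardiac` from the respective
#' contours; `airsac` for elements ventral to the lungs' ventral-most extent
#' that are not cardiac (the cranial-air-sac territory, used only as
#' simulation ground truth -- reconstruction uses the outer contour alone);
#' `background` otherwise.
#'
#' @param cs an `eit_contour_set`, or a single `eit_contour` taken as the
#'   outer boundary of a region-free phantom.
#' @param mesh_size target element edge length, mm.
#' @param n_electrodes number of boundary electrodes (default 32).
#' @return an object of class `eit_phantom`.
#' @export
build_phantom <- function(cs, mesh_size = 3, n_electrodes = 32L) {
  if (mesh_size <= 0) stop("mesh_size must be positive")
  if (inherits(cs, "eit_contour")) {
    outer <- cs
    rois <- list()
  } else {
    stopifnot(inherits(cs, "eit_contour_set"))
    outer <- cs$outer
    rois <- cs[c("lung_r", "lung_l", "cardiac")]
    check_roi_overlap(rois)
  }

  per <- polygon_perimeter(outer$points)
  nb <- max(2L, round(per / mesh_size / n_electrodes)) * n_electrodes
  bnd <- resample_contour(outer, nb)$points      # ventral start, CCW
  ctr <- polygon_centroid(outer$points)
  mean_r <- mean(sqrt(rowSums(sweep(bnd, 2L, ctr)^2)))
  nr <- max(3L, round(mean_r / mesh_size))

  nodes <- matrix(ctr, nrow = 1L)
  for (i in seq_len(nr))
    nodes <- rbind(nodes, sweep(sweep(bnd, 2L, ctr) * (i / nr), 2L, ctr, "+"))
  idx <- function(i, j) 1L + (i - 1L) * nb + ((j - 1L) %% nb) + 1L

  tri <- matrix(0L, nb + 2L * nb * (nr - 1L), 3L)
  row <- 1L
  for (j in seq_len(nb)) {                       # fan around the centre
    tri[row, ] <- c(1L, idx(1L, j), idx(1L, j + 1L)); row <- row + 1L
  }
  # quad diagonals mirrored about the ventral-dorsal axis so that a
  # symmetric contour yields a mirror-symmetric mesh
  if (nr > 1L) for (i in seq_len(nr - 1L)) for (j in seq_len(nb)) {
    a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
    if (j <= nb %/% 2L) {
      tri[row, ] <- c(a, b, d); tri[row + 1L, ] <- c(a, d, cc)
    } else {
      tri[row, ] <- c(a, b, cc); tri[row + 1L, ] <- c(b, d, cc)
    }
    row <- row + 2L
  }

  # orient all elements counter-clockwise
  sa <- tri_signed_area(nodes, tri)
  flip <- sa < 0
  if (any(flip)) tri[flip, 2:3] <- tri[flip, 3:2, drop = FALSE]

  electrode_nodes <- 1L + (nr - 1L) * nb + 1L + (seq_len(n_electrodes) - 1L) * (nb / n_electrodes)
  electrode_arc <- (seq_len(n_electrodes) - 1L) * per / n_electrodes

  cent <- (nodes[tri[, 1L], ] + nodes[tri[, 2L], ] + nodes[tri[, 3L], ]) / 3
  labels <- rep("background", nrow(tri))
  if (length(rois)) {
    for (nm in c("lung_r", "lung_l", "cardiac")) {
      pp <- rois[[nm]]$points
      inside <- pracma::inpolygon(cent[, 1L], cent[, 2L], pp[, 1L], pp[, 2L])
      labels[inside] <- nm
    }
    lung_ventral <- min(rois$lung_r$points[, 2L], rois$lung_l$points[, 2L])
    labels[labels == "background" & cent[, 2L] < lung_ventral] <- "airsac"
  }

  p <- structure(list(
    nodes = nodes, elements = tri,
    electrode_nodes = electrode_nodes, electrode_arc = electrode_arc,
    element_labels = labels, element_centroids = cent,
    outer = outer, rois = rois, mesh_size = mesh_size,
    n_boundary = nb, n_rings = nr, perimeter = per),
    class = "eit_phantom")
  p$fem <- fem_precompute(p)
  p$pixel_mask <- make_pixel_mask(p)
  p
}

#' @export
print.eit_phantom <- function(x, ...) {
  cat(sprintf("<eit_phantom: %d nodes, %d elements, %d electrodes>\n",
              nrow(x$nodes), nrow(x$elements), length(x$electrode_nodes)))
  print(table(x$element_labels))
  invisible(x)
}

check_roi_overlap <- function(rois) {
  nms <- names(rois)
  for (i in seq_along(rois)[-length(rois)]) for (j in seq.int(i + 1L, length(rois))) {
    a <- rois[[i]]$points; b <- rois[[j]]$points
    if (any(pracma::inpolygon(a[, 1L], a[, 2L], b[, 1L], b[, 2L])) ||
        any(pracma::inpolygon(b[, 1L], b[, 2L], a[, 1L], a[, 2L])))
      stop("ROI contours overlap: ", nms[i], " and ", nms[j])
  }
  invisible(TRUE)
}

tri_signed_area <- function(nodes, tri) {
  x1 <- nodes[tri[, 1L], 1L]; y1 <- nodes[tri[, 1L], 2L]
  x2 <- nodes[tri[, 2L], 1L]; y2 <- nodes[tri[, 2L], 2L]
  x3 <- nodes[tri[, 3L], 1L]; y3 <- nodes[tri[, 3L], 2L]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' The default chicken phantom
#'
#' Convenience constructor: the synthetic chicken cross-section of
#' [chicken_contours()] meshed at `mesh_size` (default 2.3 mm, about 4500
#' elements -- the resolution used for full-scale simulation runs).
#'
#' @inheritParams build_phantom
#' @param ... passed to [chicken_contours()].
#' @return an `eit_phantom`.
#' @export
chicken_phantom <- function(mesh_size = 2.3, ...) {
  build_phantom(chicken_contours(...), mesh_size = mesh_size)
}

#' Ground-truth ROI pixel masks of a phantom
#'
#' Pixel-level masks of the lung contours, the cardiac contour and the
#' air-sac territory (in-body pixels ventral to the lungs' ventral-most
#' extent, excluding cardiac pixels), used to verify regional properties
#' such as the absence of ventilation signal over the isovolumetric lungs.
#'
#' @param p an `eit_phantom` built from a full contour set.
#' @return list of 32 x 32 logical masks: `lung`, `cardiac`, `airsac`.
#' @export
roi_pixel_masks <- function(p) {
  if (!length(p$rois)) stop("phantom has no interior ROI contours")
  pm <- p$pixel_mask
  lung <- pixels_in_contour(pm, p$rois$lung_r) |
          pixels_in_contour(pm, p$rois$lung_l)
  cardiac <- pixels_in_contour(pm, p$rois$cardiac)
  lung_ventral <- min(p$rois$lung_r$points[, 2L], p$rois$lung_l$points[, 2L])
  airsac <- pm$mask & !cardiac & !lung & pm$py < lung_ventral
  list(lung = lung, cardiac = cardiac, airsac = airsac)
}

#' Reconstruction pixel grid of a phantom
#'
#' Lays a 32 x 32 pixel grid over the bounding box of the outer contour.
#' Display convention is radiological: row 1 is the dorsal-most row, column
#' 1 the subject's right. A pixel is in-mask when its centre falls inside
#' the outer contour; each in-mask pixel is mapped to the elements whose
#' centroid it contains (or to the nearest element if none).
#'
#' @param p an `eit_phantom`.
#' @param n grid resolution per side (default 32).
#' @return a list with `mask` (n x n logical), `px`, `py` (n x n physical
#'   pixel-centre coordinates, y up), `elems` (list of element index vectors,
#'   row-major over the grid), and the bounding box.
#' @export
make_pixel_mask <- function(p, n = 32L) {
  pts <- p$outer$points
  xr <- range(pts[, 1L]); yr <- range(pts[, 2L])
  dx <- diff(xr) / n; dy <- diff(yr) / n
  cx <- xr[1L] + (seq_len(n) - 0.5) * dx            # columns: right -> left
  cy <- yr[2L] - (seq_len(n) - 0.5) * dy            # rows: dorsal -> ventral
  px <- matrix(cx, n, n, byrow = TRUE)
  py <- matrix(cy, n, n)
  mask <- matrix(pracma::inpolygon(as.vector(px), as.vector(py),
                                   pts[, 1L], pts[, 2L]), n, n)

  cent <- p$element_centroids
  col_of <- pmin(pmax(ceiling((cent[, 1L] - xr[1L]) / dx), 1L), n)
  row_of <- pmin(pmax(ceiling((yr[2L] - cent[, 2L]) / dy), 1L), n)
  key <- (row_of - 1L) * n + col_of
  elems <- split(seq_len(nrow(cent)), factor(key, levels = seq_len(n * n)))
  names(elems) <- NULL
  for (k in which(as.vector(t(mask)))) {            # row-major in-mask pixels
    if (length(elems[[k]]) == 0L) {
      r <- (k - 1L) %/% n + 1L; cc <- (k - 1L) %% n + 1L
      d2 <- (cent[, 1L] - px[r, cc])^2 + (cent[, 2L] - py[r, cc])^2
      elems[[k]] <- which.min(d2)
    }
  }
  list(mask = mask, px = px, py = py, elems = elems,
       xlim = xr, ylim = yr, n = n)
}

#' Pixels inside a contour, on a phantom's reconstruction grid
#'
#' @param pm pixel mask as returned by [make_pixel_mask()].
#' @param k an `eit_contour`.
#' @return n x n logical matrix.
#' @export
pixels_in_contour <- function(pm, k) {
  matrix(pracma::inpolygon(as.vector(pm$px), as.vector(pm$py),
                           k$points[, 1L], k$points[, 2L]),
         pm$n, pm$n) & pm$mask
}
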