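#' Closed 2-D contours of the coelomic cross-section
#'
#' A `contour` is an ordered set of (x, y) vertices in millimetres describing
#' a closed simple polygon (the first vertex is not repeated at the end).
#' The coordinate convention throughout the package is anatomical with y up:
#' x increases from the subject's right towards the left, y increases from
#' ventral to dorsal. Contours are normalised to counter-clockwise
#' orientation on construction.
#'
#' @param points numeric matrix (n x 2) or data.frame of vertex coordinates, mm.
#' @param name label, e.g. `"outer"`, `"lung_r"`, `"lung_l"`, `"cardiac"`.
#' @return an object of class `eit_contour` with elements `points` (matrix)
#'   and `name`.
#' @export
contour <- function(points, name = "contour") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("contour points must be an n x 2 matrix")
  if (nrow(points) < 3L) stop("a contour needs at least 3 points")
  if (any(!is.finite(points))) stop("contour points must be finite")
  # drop a duplicated closing vertex if present
  if (isTRUE(all.equal(points[1L, ], points[nrow(points), ], check.attributes = FALSE)))
    points <- points[-nrow(points), , drop = FALSE]
  if (abs(polygon_area(points)) < .Machine$double.eps * 100)
    stop("degenerate contour: zero area")
  if (polygon_area(points) < 0)          # enforce counter-clockwise
    points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  if (nrow(points) <= 400L && !is_simple_polygon(points))
    stop("contour '", name, "' is self-intersecting")
  structure(list(points = points, name = as.character(name)),
            class = "eit_contour")
}

#' @export
print.eit_contour <- function(x, ...) {
  cat(sprintf("<eit_contour '%s': %d vertices, area %.1f mm^2, perimeter %.1f mm>\n",
              x$name, nrow(x$points), polygon_area(x$points),
              polygon_perimeter(x$points)))
  invisible(x)
}

# Shoelace signed area; positive for counter-clockwise vertex order.
polygon_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(pts) {
  d <- pts[c(seq_len(nrow(pts))[-1L], 1L), , drop = FALSE] - pts
  sum(sqrt(rowSums(d^2)))
}

# Area centroid of a simple polygon (not the vertex mean).
polygon_centroid <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# O(n^2) segment-intersection test for polygon simplicity (small n only).
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  seg <- cbind(pts, pts[c(2:n, 1L), , drop = FALSE])
  ccw <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      d1 <- ccw(a[1], a[2], b[1], b[2], c[1], c[2])
      d2 <- ccw(a[1], a[2], b[1], b[2], d[1], d[2])
      d3 <- ccw(c[1], c[2], d[1], d[2], a[1], a[2])
      d4 <- ccw(c[1], c[2], d[1], d[2], b[1], b[2])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

# Index of the vertex whose direction from the centroid is closest to
# straight ventral (-y). Defines the common start point for resampling so
# that contours from different subjects are averaged vertex-by-vertex.
ventral_start_index <- function(pts) {
  ctr <- polygon_centroid(pts)
  ang <- atan2(pts[, 2L] - ctr[2L], pts[, 1L] - ctr[1L])
  # angular distance to -pi/2 (ventral), wrapped to [-pi, pi]
  d <- abs(((ang + pi / 2 + pi) %% (2 * pi)) - pi)
  which.min(d)
}

#' Resample a contour to n points equally spaced in arc length
#'
#' The resampled contour starts at the vertex closest (in direction from the
#' contour centroid) to the ventral midline, so that resampled contours from
#' different subjects are index-aligned for averaging. Orientation
#' (counter-clockwise) is preserved.
#'
#' @param c an `eit_contour`.
#' @param n number of output points (>= 3).
#' @return an `eit_contour` with exactly `n` vertices.
#' @export
resample_contour <- function(c, n) {
  stopifnot(inherits(c, "eit_contour"))
  if (n < 3L) stop("n must be >= 3")
  pts <- c$points
  start <- ventral_start_index(pts)
  pts <- pts[c(start:nrow(pts), seq_len(start - 1L)), , drop = FALSE]
  pts_cl <- rbind(pts, pts[1L, ])               # explicit closure
  seglen <- sqrt(rowSums(diff(pts_cl)^2))
  if (sum(seglen) <= 0) stop("degenerate contour: zero perimeter")
  s <- c(0, cumsum(seglen))                     # arc length at each vertex
  per <- s[length(s)]
  target <- (seq_len(n) - 1L) * per / n
  xs <- stats::approx(s, pts_cl[, 1L], xout = target, ties = "ordered")$y
  ys <- stats::approx(s, pts_cl[, 2L], xout = target, ties = "ordered")$y
  contour(cbind(xs, ys), name = c$name)
}

#' Pointwise mean of a set of contours
#'
#' Each contour is resampled to `n` arc-length-equidistant points with the
#' common ventral start-point rule, translated so its area centroid sits at
#' the origin, averaged vertex-by-vertex, and the result is placed at the
#' mean of the original centroids. No rotation or scaling is applied:
#' subjects are imaged in a fixed posture, and scaling would distort
#' absolute size.
#'
#' @param contours list of `eit_contour` objects.
#' @param n number of points of the result.
#' @return an `eit_contour`.
#' @export
mean_contour <- function(contours, n = 128L) {
  if (length(contours) < 1L) stop("need at least one contour")
  rs <- lapply(contours, resample_contour, n = n)
  ctrs <- t(vapply(rs, function(k) polygon_centroid(k$points), numeric(2)))
  acc <- matrix(0, n, 2L)
  for (i in seq_along(rs))
    acc <- acc + sweep(rs[[i]]$points, 2L, ctrs[i, ])
  avg <- acc / length(rs)
  avg <- sweep(avg, 2L, -colMeans(ctrs))
  contour(avg, name = rs[[1L]]$name)
}

#' A subject's set of cross-sectional contours
#'
#' @param outer,lung_r,lung_l,cardiac `eit_contour` objects. Interior
#'   contours must lie strictly inside the outer contour.
#' @param subject_id identifier string.
#' @return an object of class `eit_contour_set`.
#' @export
contour_set <- function(outer, lung_r, lung_l, cardiac,
                        subject_id = "subject") {
  for (k in list(outer, lung_r, lung_l, cardiac))
    stopifnot(inherits(k, "eit_contour"))
  for (inner in list(lung_r, lung_l, cardiac)) {
    inside <- pracma::inpolygon(inner$points[, 1L], inner$points[, 2L],
                                outer$points[, 1L], outer$points[, 2L],
                                boundary = FALSE)
    if (!all(inside))
      stop("contour '", inner$name, "' is not strictly inside the outer contour")
  }
  structure(list(outer = outer, lung_r = lung_r, lung_l = lung_l,
                 cardiac = cardiac, subject_id = as.character(subject_id)),
            class = "eit_contour_set")
}

#' @export
print.eit_contour_set <- function(x, ...) {
  cat(sprintf("<eit_contour_set '%s'>\n", x$subject_id))
  for (nm in c("outer", "lung_r", "lung_l", "cardiac")) print(x[[nm]])
  invisible(x)
}

ellipse_points <- function(cx, cy, a, b, n = 64L, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + a * cos(th), cy + b * sin(th))
}

#' Synthetic chicken cross-section at the belt plane
#'
#' A parameterised stand-in for CT-derived contours of an adult chicken at
#' the level of an electrode belt placed just caudal to the shoulder joints:
#' an elliptical outer body contour, two dorso-lateral lung lobes and a
#' central-ventral cardiac silhouette. The cranial air sacs (clavicular and
#' cranial thoracic) occupy the ventral region between the heart and the
#' body wall; they cannot be delineated as a contour of their own and are
#' handled as a derived region label by [build_phantom()].
#'
#' @param subject_id identifier; small per-subject shape jitter is derived
#'   deterministically from the `jitter` argument.
#' @param jitter fractional perturbation of the axis lengths (0 gives the
#'   canonical geometry); used to emulate inter-subject variation.
#' @param n points per contour.
#' @return an `eit_contour_set`.
#' @export
chicken_contours <- function(subject_id = "synthetic-chicken-01",
                             jitter = 0, n = 96L) {
  j <- function(k) 1 + jitter * k
  outer <- contour(ellipse_points(0, 0, 45 * j(1), 40 * j(-0.5), n), "outer")
  # subject's right = negative x (x runs right -> left)
  lung_r <- contour(ellipse_points(-18, 15, 13 * j(0.8), 12 * j(0.3), n), "lung_r")
  lung_l <- contour(ellipse_points(18, 15, 13 * j(-0.6), 12 * j(0.5), n), "lung_l")
  cardiac <- contour(ellipse_points(0, -12, 10 * j(0.4), 10 * j(-0.2), n), "cardiac")
  contour_set(outer, lung_r, lung_l, cardiac, subject_id = subject_id)
}

#' Read / write contour sets as JSON
#'
#' Format: `{"subject_id": str, "units": "mm",
#' "contours": {"outer": [[x,y],...], "lung_r": ..., "lung_l": ...,
#' "cardiac": ...}}`.
#'
#' @param path file path.
#' @return `read_contours` returns an `eit_contour_set`.
#' @export
read_contours <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("outer", "lung_r", "lung_l", "cardiac")
  miss <- setdiff(need, names(obj$contours))
  if (length(miss)) stop("contour file missing: ", paste(miss, collapse = ", "))
  ks <- lapply(need, function(nm) contour(obj$contours[[nm]], nm))
  names(ks) <- need
  contour_set(ks$outer, ks$lung_r, ks$lung_l, ks$cardiac,
              subject_id = if (is.null(obj$subject_id)) "unknown" else obj$subject_id)
}

#' @rdname read_contours
#' @param cs an `eit_contour_set`.
#' @export
write_contours <- function(cs, path) {
  stopifnot(inherits(cs, "eit_contour_set"))
  obj <- list(
    subject_id = cs$subject_id,
    units = "mm",
    contours = lapply(cs[c("outer", "lung_r", "lung_l", "cardiac")],
                      function(k) unname(k$points)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
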