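#' Convert eccentricity to aspect ratio
#'
#' For an ellipse, `aspect_ratio = major/minor = 1/sqrt(1 - e^2)`.
#'
#' @param e eccentricity, in \[0, 1).
#' @return aspect ratio (>= 1).
#' @export
eccentricity_to_aspect_ratio <- function(e) {
  if (any(!is.finite(e)) || any(e < 0) || any(e >= 1))
    stop("eccentricity must lie in [0, 1)")
  1 / sqrt(1 - e^2)
}

#' Convert aspect ratio to eccentricity
#'
#' Inverse of [eccentricity_to_aspect_ratio()]: `e = sqrt(1 - 1/ar^2)`.
#'
#' @param ar aspect ratio (>= 1).
#' @return eccentricity in \[0, 1).
#' @export
aspect_ratio_to_eccentricity <- function(ar) {
  if (any(!is.finite(ar)) || any(ar < 1))
    stop("aspect ratio must be >= 1")
  sqrt(1 - 1 / ar^2)
}

#' Fit the moment-equivalent ellipse to a binary mask
#'
#' Computes the ellipse with the same second central moments as the foreground
#' pixel set (the same convention as standard region-properties routines).
#' Pixel centres are taken at 0-based integer coordinates with `x` along
#' columns and `y` along rows; the orientation is measured in degrees
#' counter-clockwise from the image x-axis, axially (modulo 180).
#'
#' @param mask a logical or 0/1 matrix with at least 8 foreground pixels
#'   forming a single connected component.
#' @return object of class `ellipse_fit`: `centroid` (x, y in pixels),
#'   `major_axis_len`, `minor_axis_len` (pixels), `orientation` (degrees in
#'   \[0,180)), `eccentricity`, `aspect_ratio`, `n_pixels`.
#' @export
fit_ellipse_to_mask <- function(mask) {
  m <- (as.matrix(mask) != 0) * 1
  if (sum(m) < 8) stop("mask must contain at least 8 foreground pixels")
  lab <- EBImage::bwlabel(m)
  if (max(lab) != 1) stop("mask must be a single connected component")
  px <- which(m == 1, arr.ind = TRUE)
  x <- px[, "col"] - 1
  y <- px[, "row"] - 1
  cx <- mean(x); cy <- mean(y)
  mxx <- mean((x - cx)^2)
  myy <- mean((y - cy)^2)
  mxy <- mean((x - cx) * (y - cy))
  common <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- (mxx + myy) / 2 + common
  l2 <- (mxx + myy) / 2 - common
  l2 <- max(l2, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  orient <- (0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi) %% 180
  if (minor <= 0) stop("degenerate mask: zero minor axis")
  structure(list(centroid = c(x = cx, y = cy),
                 major_axis_len = major, minor_axis_len = minor,
                 orientation = orient,
                 eccentricity = sqrt(max(0, 1 - (minor / major)^2)),
                 aspect_ratio = major / minor,
                 n_pixels = nrow(px)),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(paste0("Ellipse fit: centre (%.1f, %.1f) px, axes %.1f x %.1f px,",
                     " orientation %.1f deg, e = %.3f (AR %.2f)\n"),
              x$centroid[1], x$centroid[2], x$major_axis_len,
              x$minor_axis_len, x$orientation, x$eccentricity,
              x$aspect_ratio))
  invisible(x)
}

#' Build a 2D simulation domain for a cell of given width and eccentricity
#'
#' The domain represents the sub-apical plane of one epithelial cell.  The
#' short dimension (`width_nm`) is fixed and the long axis is scaled to match
#' the requested eccentricity: `length = width / sqrt(1 - e^2)` (the aspect
#' ratio of the moment-equivalent ellipse).  The long axis lies along x.
#' The default shape is a rectangle; an isosceles trapezoid variant with the
#' same area (two parallel long sides of lengths in ratio `taper`) is
#' available to mimic the tapered apical outline of epithelial cells.
#'
#' @param width_nm shortest cell dimension, nm (> 0).
#' @param eccentricity dimensionless, in \[0, 1).
#' @param shape_kind `"rectangle"` (default) or `"trapezoid"`.
#' @param taper trapezoid only: ratio of the shorter to the longer parallel
#'   side, in (0, 1\].
#' @return object of class `cell_domain`: `vertices` (counter-clockwise
#'   polygon, nm, not closed), `width`, `length`, `eccentricity`,
#'   `shape_kind`, `area`, `perimeter`, `orientation` (long-axis direction,
#'   0 degrees).
#' @export
build_cell_domain <- function(width_nm, eccentricity,
                              shape_kind = c("rectangle", "trapezoid"),
                              taper = 0.7) {
  shape_kind <- match.arg(shape_kind)
  if (!is.finite(width_nm) || width_nm <= 0) stop("width_nm must be > 0")
  if (!is.finite(eccentricity) || eccentricity < 0 || eccentricity >= 1)
    stop("eccentricity must lie in [0, 1)")
  len <- width_nm / sqrt(1 - eccentricity^2)
  if (shape_kind == "rectangle") {
    v <- rbind(c(0, 0), c(len, 0), c(len, width_nm), c(0, width_nm))
  } else {
    if (taper <= 0 || taper > 1) stop("taper must lie in (0, 1]")
    lb <- 2 * len / (1 + taper)   # longer parallel side (bottom)
    lt <- taper * lb              # shorter parallel side (top)
    v <- rbind(c(0, 0), c(lb, 0),
               c((lb + lt) / 2, width_nm), c((lb - lt) / 2, width_nm))
  }
  e <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]) - v
  elen <- sqrt(rowSums(e^2))
  structure(list(vertices = v, width = width_nm, length = len,
                 eccentricity = eccentricity, shape_kind = shape_kind,
                 area = abs(sum(v[, 1] * c(v[-1, 2], v[1, 2]) -
                                c(v[-1, 1], v[1, 1]) * v[, 2])) / 2,
                 perimeter = sum(elen), orientation = 0),
            class = "cell_domain")
}

#' @export
print.cell_domain <- function(x, ...) {
  cat(sprintf(paste0("Cell domain (%s): width %.0f nm, length %.0f nm,",
                     " e = %.3f, area %.3f um^2\n"),
              x$shape_kind, x$width, x$length, x$eccentricity,
              x$area / 1e6))
  invisible(x)
}

#' Place MT seed sites uniformly along the domain perimeter
#'
#' Seeds (MT minus-ends) are placed at equal arc-length spacing along the
#' boundary polygon.  Placement is deterministic: site `i` sits at arc length
#' `(i - 1 + phase) * perimeter / n` from the first vertex.
#'
#' @param domain a [build_cell_domain()] object.
#' @param n number of seeds (>= 1); 220 reproduces the default simulation
#'   conditions.
#' @param phase offset as a fraction of one inter-seed gap, in \[0, 1);
#'   the default 0.5 centres seeds within gaps (4 seeds on a square sit at
#'   the side midpoints).
#' @param inset_nm small inward offset of the seed position (default 0.5 nm,
#'   a sixteenth of a dimer) keeping nucleation sites numerically strictly
#'   inside the boundary so that a wall-parallel MT is never exactly
#'   collinear with the wall.
#' @return data frame with one row per seed: `x`, `y` (nm), `tx`, `ty`
#'   (unit wall tangent) and `nx`, `ny` (unit inward normal).
#' @export
place_seeds <- function(domain, n, phase = 0.5, inset_nm = 0.5) {
  if (!inherits(domain, "cell_domain")) stop("domain must be a cell_domain")
  if (n < 1) stop("n must be >= 1")
  if (phase < 0 || phase >= 1) stop("phase must lie in [0, 1)")
  v <- domain$vertices
  nv <- nrow(v)
  edges <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]) - v
  elen <- sqrt(rowSums(edges^2))
  cum <- c(0, cumsum(elen))
  gap <- domain$perimeter / n
  s <- (seq_len(n) - 1 + phase) * gap
  out <- data.frame(x = numeric(n), y = numeric(n), tx = numeric(n),
                    ty = numeric(n), nx = numeric(n), ny = numeric(n))
  for (i in seq_len(n)) {
    j <- findInterval(s[i], cum, rightmost.closed = TRUE)
    j <- min(j, nv)
    t <- (s[i] - cum[j]) / elen[j]
    tan <- edges[j, ] / elen[j]
    out$x[i] <- v[j, 1] + t * edges[j, 1] - tan[2] * inset_nm
    out$y[i] <- v[j, 2] + t * edges[j, 2] + tan[1] * inset_nm
    out$tx[i] <- tan[1]; out$ty[i] <- tan[2]
    # counter-clockwise polygon: interior lies to the left of each edge
    out$nx[i] <- -tan[2]; out$ny[i] <- tan[1]
  }
  out
}
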