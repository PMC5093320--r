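# shared fixture builders (all fixtures are generated in code)

# filled axis-aligned rectangle mask, optionally rotated about its centre
rect_mask <- function(nrow_px, ncol_px, h, w, angle_deg = 0) {
  cx <- (ncol_px - 1) / 2
  cy <- (nrow_px - 1) / 2
  xs <- matrix(seq_len(ncol_px) - 1, nrow_px, ncol_px, byrow = TRUE) - cx
  ys <- matrix(seq_len(nrow_px) - 1, nrow_px, ncol_px) - cy
  th <- -angle_deg * pi / 180
  xr <- xs * cos(th) - ys * sin(th)
  yr <- xs * sin(th) + ys * cos(th)
  (abs(xr) <= w / 2 & abs(yr) <= h / 2) * 1
}

disc_mask <- function(size_px, radius) {
  c0 <- (size_px - 1) / 2
  xs <- matrix(seq_len(size_px) - 1, size_px, size_px, byrow = TRUE) - c0
  ys <- matrix(seq_len(size_px) - 1, size_px, size_px) - c0
  (xs^2 + ys^2 <= radius^2) * 1
}

# brute-force second-central-moment ellipse over all foreground pixels:
# the independent oracle for fit_ellipse_to_mask
moment_oracle <- function(mask) {
  px <- which(mask != 0, arr.ind = TRUE)
  x <- px[, "col"] - 1
  y <- px[, "row"] - 1
  mxx <- mean((x - mean(x))^2)
  myy <- mean((y - mean(y))^2)
  mxy <- mean((x - mean(x)) * (y - mean(y)))
  common <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- (mxx + myy) / 2 + common
  l2 <- max((mxx + myy) / 2 - common, 0)
  list(aspect_ratio = sqrt(l1 / l2),
       eccentricity = sqrt(1 - l2 / l1),
       orientation = (0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi) %% 180)
}

# acute axial difference in degrees
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# do two segments properly cross at an interior point?
segments_cross <- function(p1, p2, q1, q2, eps = 1e-6) {
  r <- p2 - p1
  s <- q2 - q1
  den <- r[1] * s[2] - r[2] * s[1]
  if (abs(den) < 1e-12) return(FALSE)
  t <- ((q1[1] - p1[1]) * s[2] - (q1[2] - p1[2]) * s[1]) / den
  u <- ((q1[1] - p1[1]) * r[2] - (q1[2] - p1[2]) * r[1]) / den
  t > eps && t < 1 - eps && u > eps && u < 1 - eps
}

# small fast simulation settings for module-level tests
small_params <- function(...) {
  sim_params(n_seeds = 60, t_end = 3, avg_window = 1, series_window = 1, ...)
}
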