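#' Generate a synthetic filament image with known angular statistics
#'
#' Renders straight lines (emulating MTs) through anchor points drawn
#' uniformly inside an elliptical cell, at angles sampled from a normal
#' distribution with the given s.d. and wrapped to \[0, 180).  Each line is
#' the full chord of the cell through its anchor at the drawn angle (a
#' fixed-length option is available).  A matching one-label mask and the
#' machine-readable ground truth are returned, so quantifier error is always
#' computable.
#'
#' @param eccentricity cell eccentricity, in \[0, 1); the validation designs
#'   use 0.7, 0.8, 0.92 and 0.98.
#' @param sigma_deg generating angular s.d., degrees (>= 0); the validation
#'   designs use 22, 30 and 40.
#' @param n_lines number of lines (default 100).
#' @param mean_angle mean line direction, degrees (default: the cell
#'   orientation).
#' @param img_size image side in pixels (default 256).
#' @param cell_orientation cell long-axis direction, degrees (default 0).
#' @param line_length line length in pixels: a number, `"chord"` for the
#'   full chord of the cell through each anchor, or `NULL` (default) for the
#'   geometric mean of the semi-axes.  A fixed length keeps line length
#'   uncorrelated
#'   with angle, so the length-weighted ground truth is an unbiased estimate
#'   of the generating s.d.; chords in an elongated cell are longer along
#'   the long axis, which narrows the length-weighted distribution.
#' @param noise_sd s.d. of additive Gaussian read noise (default 0).
#' @param rng_seed integer seed, or `NULL` to use the current RNG state.
#' @return list of class `synthetic_lines`: `image` (matrix), `mask`
#'   (integer matrix, cell = 1), `lines` (data frame: `x`, `y`, `angle`,
#'   `length`, `intensity`), `eccentricity`, `sigma_deg`, `mean_angle`,
#'   `cell_orientation`, `rng_seed`.
#' @export
generate_line_image <- function(eccentricity, sigma_deg, n_lines = 100,
                                mean_angle = cell_orientation,
                                img_size = 256, cell_orientation = 0,
                                line_length = NULL, noise_sd = 0,
                                rng_seed = NULL) {
  if (sigma_deg < 0) stop("sigma_deg must be >= 0")
  if (n_lines < 1) stop("n_lines must be >= 1")
  if (eccentricity < 0 || eccentricity >= 1)
    stop("eccentricity must lie in [0, 1)")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  a <- 0.45 * img_size
  b <- a * sqrt(1 - eccentricity^2)
  chord <- identical(line_length, "chord") ||
    (is.numeric(line_length) && !is.finite(line_length))
  if (is.null(line_length)) line_length <- sqrt(a * b)
  c0 <- img_size / 2
  phi <- cell_orientation * pi / 180
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)

  # anchors uniform inside the ellipse
  rr <- sqrt(stats::runif(n_lines))
  tt <- stats::runif(n_lines, 0, 2 * pi)
  pts <- cbind(a * rr * cos(tt), b * rr * sin(tt)) %*% t(rot)
  ax <- pts[, 1] + c0
  ay <- pts[, 2] + c0
  angles <- (stats::rnorm(n_lines, mean_angle, sigma_deg)) %% 180

  img <- matrix(0, img_size, img_size)
  lens <- numeric(n_lines)
  for (i in seq_len(n_lines)) {
    th <- angles[i] * pi / 180
    d <- c(cos(th), sin(th))
    # chord of the ellipse through the anchor: solve in the ellipse frame
    pe <- t(rot) %*% c(ax[i] - c0, ay[i] - c0)
    de <- t(rot) %*% d
    A <- (de[1] / a)^2 + (de[2] / b)^2
    B <- 2 * (pe[1] * de[1] / a^2 + pe[2] * de[2] / b^2)
    C <- (pe[1] / a)^2 + (pe[2] / b)^2 - 1
    disc <- B^2 - 4 * A * C
    if (disc <= 0) next
    t1 <- (-B - sqrt(disc)) / (2 * A)
    t2 <- (-B + sqrt(disc)) / (2 * A)
    if (!chord) {
      t1 <- max(t1, -line_length / 2)
      t2 <- min(t2, line_length / 2)
    }
    lens[i] <- t2 - t1
    img <- .splat_segment(img, ax[i] + t1 * d[1], ay[i] + t1 * d[2],
                          ax[i] + t2 * d[1], ay[i] + t2 * d[2], 1)
  }
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow(img), ncol(img))
  img[img < 0] <- 0

  xs <- matrix(seq_len(img_size) - 1, img_size, img_size, byrow = TRUE) - c0
  ys <- matrix(seq_len(img_size) - 1, img_size, img_size) - c0
  xe <- xs * cos(phi) + ys * sin(phi)
  ye <- -xs * sin(phi) + ys * cos(phi)
  mask <- matrix(as.integer((xe / a)^2 + (ye / b)^2 <= 1),
                 img_size, img_size)

  structure(list(image = img, mask = mask,
                 lines = data.frame(x = ax, y = ay, angle = angles,
                                    length = lens, intensity = 1),
                 eccentricity = eccentricity, sigma_deg = sigma_deg,
                 mean_angle = mean_angle,
                 cell_orientation = cell_orientation,
                 rng_seed = if (is.null(rng_seed)) NA_integer_ else rng_seed),
            class = "synthetic_lines")
}

# additive anti-aliased line rasterization by bilinear splatting;
# img is [row = y, col = x] with 0-based pixel centres
.splat_segment <- function(img, x0, y0, x1, y1, intensity, step = 0.5) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len <= 0) return(img)
  n <- max(2L, ceiling(len / step) + 1L)
  tt <- seq(0, 1, length.out = n)
  w <- intensity * len / n
  xs <- x0 + tt * (x1 - x0)
  ys <- y0 + tt * (y1 - y0)
  nr <- nrow(img); nc <- ncol(img)
  ix <- floor(xs); iy <- floor(ys)
  fx <- xs - ix; fy <- ys - iy
  for (dxy in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    cx <- ix + dxy[1]; cy <- iy + dxy[2]
    ww <- w * (if (dxy[1] == 0) 1 - fx else fx) *
      (if (dxy[2] == 0) 1 - fy else fy)
    ok <- cx >= 0 & cx < nc & cy >= 0 & cy < nr
    if (any(ok)) {
      idx <- cy[ok] + 1L + nr * cx[ok]
      acc <- tapply(ww[ok], idx, sum)
      img[as.integer(names(acc))] <- img[as.integer(names(acc))] + acc
    }
  }
  img
}

#' Ground-truth MTSD of a synthetic line set
#'
#' Builds the length-weighted axial histogram of the true line angles
#' (1-degree bins) and fits the axial Von Mises distribution — the oracle
#' against which the image pipeline is judged.
#'
#' @param lines a [generate_line_image()] result, or its `lines` data frame.
#' @return MTSD in degrees.
#' @export
ground_truth_mtsd <- function(lines) {
  if (inherits(lines, "synthetic_lines")) lines <- lines$lines
  lines <- lines[lines$length > 0, , drop = FALSE]
  if (nrow(lines) < 2) stop("need at least 2 rendered lines")
  h <- bin_directions(lines$angle, weights = lines$length, bin_width = 1)
  fit_axial_von_mises(h)$sigma
}

#' Rasterize a simulation result to an image
#'
#' Renders the final MT polylines at the given scale with additive
#' intensity, so bundled (overlapping) MTs appear proportionally brighter,
#' together with the domain mask.  Closes the simulate-then-quantify loop.
#'
#' @param result a [run_simulation()] result.
#' @param nm_per_px raster scale (the cell width must span >= 3 px).
#' @param pad_px margin around the domain (default 8 px).
#' @param psf_sigma s.d. of the Gaussian point-spread function applied to
#'   the raster, in pixels (default 1; 0 disables).  Besides emulating
#'   microscope optics it suppresses the axis-ward rasterization aliasing
#'   of thin lines.
#' @param saturation detector saturation, in units of single-MT brightness:
#'   rendered intensity is proportional to bundle occupancy up to this
#'   level, mimicking the limited dynamic range of fluorescence imaging.
#'   The default `"auto"` exposes to the 90th percentile of occupied-pixel
#'   intensity (an auto-exposure rule); a number fixes the level; `Inf`
#'   gives strictly proportional output (the quantifier's relative
#'   magnitude threshold then sees only the brightest bundles).
#' @return list with `image`, `mask` (cell interior = 1) and `nm_per_px`.
#' @export
render_simulation <- function(result, nm_per_px = 4, pad_px = 8,
                              psf_sigma = 1, saturation = "auto") {
  if (!inherits(result, "sim_result")) stop("result must be a sim_result")
  if (result$domain$width / nm_per_px < 3)
    stop("nm_per_px too coarse: fewer than 3 px across the cell width")
  v <- result$domain$vertices / nm_per_px
  w <- ceiling(max(v[, 1])) + 2 * pad_px
  h <- ceiling(max(v[, 2])) + 2 * pad_px
  img <- matrix(0, h, w)
  segs <- result$final_segments
  if (nrow(segs) > 0) {
    for (i in seq_len(nrow(segs))) {
      L <- segs[i, "len_dimers"] * result$params$dimer_len
      if (L <= 0) next
      x0 <- segs[i, "x0"] / nm_per_px + pad_px
      y0 <- segs[i, "y0"] / nm_per_px + pad_px
      img <- .splat_segment(img, x0, y0,
                            x0 + segs[i, "dx"] * L / nm_per_px,
                            y0 + segs[i, "dy"] * L / nm_per_px, 1)
    }
  }
  if (psf_sigma > 0 && max(img) > 0)
    img <- EBImage::gblur(img, sigma = psf_sigma)
  if (identical(saturation, "auto")) {
    occ <- img[img > 0.5]
    saturation <- if (length(occ)) stats::quantile(occ, 0.9, names = FALSE)
    else Inf
  }
  img <- pmin(img, saturation)
  xs <- matrix(seq_len(w) - 1, h, w, byrow = TRUE) - pad_px
  ys <- matrix(seq_len(h) - 1, h, w) - pad_px
  mask <- matrix(as.integer(.in_convex_polygon(xs, ys, v)), h, w)
  list(image = img, mask = mask, nm_per_px = nm_per_px)
}

# point-in-convex-polygon (vertices counter-clockwise): non-negative cross
# products for every edge
.in_convex_polygon <- function(xs, ys, v) {
  inside <- TRUE
  nv <- nrow(v)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cr <- (v[j, 1] - v[i, 1]) * (ys - v[i, 2]) -
      (v[j, 2] - v[i, 2]) * (xs - v[i, 1])
    inside <- inside & (cr >= -1e-9)
  }
  inside
}

#' Generate a synthetic field of cells
#'
#' Tiles `n_cells` elliptical cells on a grid, each with its own line set.
#' The spread of cell long-axis orientations is controlled by
#' `orientation_sd`: 0 emulates a late-stage field of co-aligned cells,
#' large values a younger field whose long axes are dispersed (where
#' whole-field MTSD exceeds the cell-by-cell mean).
#'
#' @param n_cells number of cells (>= 1).
#' @param ecc_range range from which per-cell eccentricities are drawn.
#' @param orientation_sd s.d. of cell orientations, degrees.
#' @param sigma_deg per-cell angular s.d. of the lines, degrees.
#' @param lines_per_cell lines rendered per cell (default 60).
#' @param cell_size_px tile side in pixels (default 96).
#' @param rng_seed integer seed, or `NULL`.
#' @return list with `image`, `labels` (integer mask, one label per cell)
#'   and `cells` (data frame of per-cell ground truth).
#' @export
generate_cell_field <- function(n_cells, ecc_range = c(0.75, 0.92),
                                orientation_sd = 0, sigma_deg = 25,
                                lines_per_cell = 60, cell_size_px = 96,
                                rng_seed = NULL) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  W <- ncol_grid * cell_size_px
  H <- nrow_grid * cell_size_px
  img <- matrix(0, H, W)
  labels <- matrix(0L, H, W)
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    gx <- (i - 1) %% ncol_grid
    gy <- (i - 1) %/% ncol_grid
    e <- stats::runif(1, ecc_range[1], ecc_range[2])
    ori <- if (orientation_sd > 0)
      stats::rnorm(1, 0, orientation_sd) %% 180 else 0
    sl <- generate_line_image(e, sigma_deg, n_lines = lines_per_cell,
                              img_size = cell_size_px,
                              cell_orientation = ori)
    r0 <- gy * cell_size_px; c0 <- gx * cell_size_px
    rows <- r0 + seq_len(cell_size_px)
    cols <- c0 + seq_len(cell_size_px)
    img[rows, cols] <- img[rows, cols] + sl$image * (sl$mask > 0)
    labels[rows, cols][sl$mask > 0] <- i
    cells[[i]] <- data.frame(cell_id = i, eccentricity = e,
                             orientation = ori, sigma_deg = sigma_deg,
                             gt_mtsd = ground_truth_mtsd(sl))
  }
  list(image = img, labels = labels, cells = do.call(rbind, cells))
}
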