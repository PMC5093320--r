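#' Maximum-intensity projection of an image stack
#'
#' @param stack a 2D matrix (returned unchanged) or a 3D array with slices
#'   along the third dimension.
#' @return 2D matrix of pixelwise maxima.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3)
    stop("stack must be a 2D matrix or a 3D array")
  apply(stack, c(1, 2), max)
}

#' Percentile contrast stretch
#'
#' Remaps intensities so that the lowest `clip` fraction of pixel values is
#' set to 0 (black) and the highest `clip` fraction to 1 (white), linear in
#' between.  A constant image is returned unchanged with the attribute
#' `constant = TRUE`.
#'
#' @param img numeric matrix.
#' @param clip fraction clipped at each end (default 0.005, i.e. 0.5%).
#' @return matrix in \[0, 1\].
#' @export
stretch_contrast <- function(img, clip = 0.005) {
  if (!is.matrix(img) || length(img) == 0) stop("img must be a non-empty matrix")
  if (clip < 0 || clip >= 0.5) stop("clip must lie in [0, 0.5)")
  lo <- stats::quantile(img, clip, names = FALSE)
  hi <- stats::quantile(img, 1 - clip, names = FALSE)
  if (hi <= lo) {
    attr(img, "constant") <- TRUE
    return(img)
  }
  out <- (img - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# separable 5x5 Sobel kernels: smoothing [1,4,6,4,1] x derivative [-1,-2,0,2,1]
.sobel5_kernels <- function() {
  smooth <- c(1, 4, 6, 4, 1)
  deriv <- c(-1, -2, 0, 2, 1)
  # matrices are indexed [row = y, col = x]
  list(kx = outer(smooth, deriv),   # d/dx: derivative across columns
       ky = outer(deriv, smooth))   # d/dy: derivative across rows
}

#' 5x5 Sobel gradient field
#'
#' Convolves the image with two separable 5x5 Sobel operators (smoothing
#' `[1,4,6,4,1]` crossed with derivative `[-1,-2,0,2,1]`) to obtain the
#' signal gradient along x (columns) and y (rows), combined into the
#' gradient magnitude `M = sqrt(Gx^2 + Gy^2)` and gradient direction
#' `D = atan2(Gy, Gx)` reduced modulo 180 degrees.
#'
#' @param img numeric matrix, at least 5x5 (rows = y, columns = x).
#' @return object of class `gradient_field` with matrices `Gx`, `Gy`, `M`,
#'   `D` (degrees in \[0,180); `NA` where `M = 0`).
#' @export
sobel_5x5 <- function(img) {
  if (!is.matrix(img) || any(dim(img) < 5)) stop("image must be at least 5x5")
  k <- .sobel5_kernels()
  gx <- EBImage::filter2(img, k$kx, boundary = "replicate")
  gy <- EBImage::filter2(img, k$ky, boundary = "replicate")
  m <- sqrt(gx^2 + gy^2)
  d <- (atan2(gy, gx) * 180 / pi) %% 180
  d[m == 0] <- NA_real_
  structure(list(Gx = gx, Gy = gy, M = m, D = d), class = "gradient_field")
}

#' Per-cell gradient direction histogram
#'
#' Restricts the gradient field to the cell mask eroded by the kernel
#' half-width (2 px), discards pixels whose magnitude is below `mag_thresh`
#' of the maximum magnitude within the cell, applies the 90-degree
#' correction that rotates gradient directions into signal (filament)
#' directions, and bins the surviving directions at `bin_deg`, weighting
#' each pixel by its gradient magnitude.  The histogram is normalized to
#' the total retained magnitude.
#'
#' @param field a [sobel_5x5()] result.
#' @param mask logical/0-1 matrix of the same size.
#' @param bin_deg bin width in degrees (default 4).
#' @param mag_thresh relative magnitude threshold (default 0.22).
#' @param erode_px erosion radius in pixels (default 2; 0 disables).
#' @return an [angular_histogram()]; all-zero (with attribute `n_pixels = 0`)
#'   if no pixels survive, in which case the downstream MTSD is 90.
#' @export
cell_direction_histogram <- function(field, mask, bin_deg = 4,
                                     mag_thresh = 0.22, erode_px = 2) {
  if (!inherits(field, "gradient_field")) stop("field must be a gradient_field")
  m <- (as.matrix(mask) != 0) * 1
  if (!all(dim(m) == dim(field$M))) stop("mask and field dimensions differ")
  if (erode_px > 0 && sum(m) > 0)
    m <- EBImage::erode(m, EBImage::makeBrush(2 * erode_px + 1, "box"))
  sel <- m != 0
  empty <- function() {
    h <- angular_histogram(numeric(round(180 / bin_deg)), bin_width = bin_deg,
                           normalized = TRUE)
    attr(h, "n_pixels") <- 0L
    h
  }
  if (!any(sel)) return(empty())
  mag <- field$M[sel]
  dir <- field$D[sel]
  keep <- mag >= mag_thresh * max(mag) & !is.na(dir)
  if (!any(keep)) return(empty())
  h <- bin_directions((dir[keep] + 90) %% 180, weights = mag[keep],
                      bin_width = bin_deg, normalized = TRUE)
  attr(h, "n_pixels") <- sum(keep)
  h
}

#' Quantify cell shape and MT organization cell by cell
#'
#' The full automated pipeline: the image is contrast-stretched, the 5x5
#' Sobel gradient field is computed once on the full frame, and every
#' labelled cell is measured: its moment-equivalent ellipse (eccentricity,
#' aspect ratio, orientation), the magnitude-weighted gradient direction
#' histogram inside the (eroded) cell mask, the axial Von Mises fit giving
#' the MT main direction and MTSD, and the MTDEV (acute angle between MT
#' main direction and the cell long axis).
#'
#' @param img grayscale image: 2D matrix or 3D stack (max-projected first).
#' @param labels integer label mask of identical 2D size (0 = background).
#' @param bin_deg,mag_thresh,clip,erode_px pipeline parameters (defaults:
#'   4 degrees, 0.22, 0.005, 2 px).
#' @param min_pixels cells with fewer usable gradient pixels are flagged
#'   (default 50) and should be excluded from summaries.
#' @return data frame with one row per label: `cell_id`, `centroid_x`,
#'   `centroid_y`, `area_px`, `eccentricity`, `aspect_ratio`,
#'   `orientation_deg`, `mt_main_direction_deg`, `mtsd_deg`, `mtdev_deg`,
#'   `n_pixels_used`, `flagged`.
#' @export
quantify_cells <- function(img, labels, bin_deg = 4, mag_thresh = 0.22,
                           clip = 0.005, erode_px = 2, min_pixels = 50) {
  img <- max_project(img)
  labels <- as.matrix(labels)
  if (!all(dim(img) == dim(labels)))
    stop("image and label mask dimensions differ")
  field <- sobel_5x5(stretch_contrast(img, clip))
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  rows <- lapply(ids, function(id) {
    mask <- labels == id
    ell <- tryCatch(fit_ellipse_to_mask(mask), error = function(e) NULL)
    h <- cell_direction_histogram(field, mask, bin_deg = bin_deg,
                                  mag_thresh = mag_thresh,
                                  erode_px = erode_px)
    fit <- fit_axial_von_mises(h)
    np <- attr(h, "n_pixels")
    data.frame(
      cell_id = id,
      centroid_x = if (is.null(ell)) NA_real_ else ell$centroid[["x"]],
      centroid_y = if (is.null(ell)) NA_real_ else ell$centroid[["y"]],
      area_px = sum(mask),
      eccentricity = if (is.null(ell)) NA_real_ else ell$eccentricity,
      aspect_ratio = if (is.null(ell)) NA_real_ else ell$aspect_ratio,
      orientation_deg = if (is.null(ell)) NA_real_ else ell$orientation,
      mt_main_direction_deg = fit$mu,
      mtsd_deg = fit$sigma,
      mtdev_deg = if (is.null(ell) || is.na(fit$mu)) NA_real_ else
        mtdev(fit$mu, ell$orientation),
      flagged = is.null(ell) || np < min_pixels,
      n_pixels_used = np)
  })
  out <- do.call(rbind, rows)
  out[c("cell_id", "centroid_x", "centroid_y", "area_px", "eccentricity",
        "aspect_ratio", "orientation_deg", "mt_main_direction_deg",
        "mtsd_deg", "mtdev_deg", "n_pixels_used", "flagged")]
}

#' Quantify MT alignment over a whole field
#'
#' Runs the same pipeline with the entire frame (or a provided region) as a
#' single mask; the magnitude threshold is then relative to the field
#' maximum.
#'
#' @param img grayscale image (2D matrix or 3D stack).
#' @param mask optional region mask; defaults to the whole frame.
#' @inheritParams quantify_cells
#' @return one-row data frame with the same columns as [quantify_cells()]
#'   (`cell_id = 0`).
#' @export
quantify_field <- function(img, mask = NULL, bin_deg = 4, mag_thresh = 0.22,
                           clip = 0.005, erode_px = 2, min_pixels = 50) {
  img <- max_project(img)
  if (is.null(mask)) mask <- matrix(1L, nrow(img), ncol(img))
  labels <- matrix(0L, nrow(img), ncol(img))
  labels[as.matrix(mask) != 0] <- 1L
  out <- quantify_cells(img, labels, bin_deg = bin_deg,
                        mag_thresh = mag_thresh, clip = clip,
                        erode_px = erode_px, min_pixels = min_pixels)
  out$cell_id <- 0L
  out
}

#' Quantify an EB1-style time-lapse frame by frame
#'
#' Applies [quantify_cells()] independently to each frame (no tracking),
#' mirroring the per-time-point analysis of EB1 comet trajectory images.
#'
#' @param frames list of 2D matrices, or a 3D array with time along the
#'   third dimension.
#' @param labels label mask shared by all frames.
#' @param ... passed to [quantify_cells()].
#' @return data frame with a leading `frame` column.
#' @export
quantify_timelapse <- function(frames, labels, ...) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  out <- lapply(seq_along(frames), function(i) {
    q <- quantify_cells(frames[[i]], labels, ...)
    cbind(frame = i, q)
  })
  do.call(rbind, out)
}

#' Fourier-spectrum directionality histogram
#'
#' Independent cross-check of the Sobel pipeline: the image is Hann-windowed,
#' its 2D power spectrum computed, and spectral energy binned by orientation.
#' Spectral orientation is perpendicular to real-space filament direction,
#' so a 90-degree rotation is applied; only frequencies inside the inscribed
#' circle of the spectrum (and away from DC) contribute, which keeps the
#' histogram isotropic for white noise.
#'
#' @param img numeric matrix, at least 32x32.
#' @param bin_deg bin width in degrees (default 4).
#' @param r_min minimum spectral radius in cycles (default 2, excludes the
#'   DC peak and large-scale illumination).
#' @return a normalized [angular_histogram()] of filament direction.
#' @export
fourier_directionality <- function(img, bin_deg = 4, r_min = 2) {
  if (!is.matrix(img) || any(dim(img) < 32)) stop("image must be >= 32x32")
  nr <- nrow(img); nc <- ncol(img)
  wy <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
  wx <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
  z <- (img - mean(img)) * outer(wy, wx)
  P <- Mod(stats::fft(z))^2
  ky <- seq_len(nr) - 1; ky[ky > nr / 2] <- ky[ky > nr / 2] - nr
  kx <- seq_len(nc) - 1; kx[kx > nc / 2] <- kx[kx > nc / 2] - nc
  KY <- matrix(ky, nr, nc)
  KX <- matrix(kx, nr, nc, byrow = TRUE)
  r <- sqrt(KX^2 + KY^2)
  keep <- r >= r_min & r <= min(nr, nc) / 2
  # spectral orientation is perpendicular to the stripes that produce it
  ang <- (atan2(KY[keep], KX[keep]) * 180 / pi + 90) %% 180
  bin_directions(ang, weights = P[keep], bin_width = bin_deg,
                 normalized = TRUE)
}

#' Read a grayscale image (TIFF or PNG)
#'
#' Multi-channel images are averaged to one channel; multi-slice TIFFs are
#' returned as a 3D array suitable for [max_project()].
#'
#' @param path file path; format chosen by extension.
#' @return a numeric matrix or 3D array (values in \[0, 1\]).
#' @export
read_grayscale_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, all = TRUE)
    x <- lapply(x, .collapse_channels)
    if (length(x) == 1) return(x[[1]])
    return(array(unlist(x), dim = c(dim(x[[1]]), length(x))))
  }
  if (ext == "png") return(.collapse_channels(png::readPNG(path)))
  stop("unsupported image format: ", ext)
}

.collapse_channels <- function(x) {
  if (length(dim(x)) == 3) x <- apply(x, c(1, 2), mean)
  x
}

#' Read an integer label mask (TIFF or PNG)
#'
#' TIFF masks are read with their native integer values; 8-bit PNG masks are
#' rescaled from \[0, 1\] back to 0..255.
#'
#' @param path file path.
#' @return an integer matrix (0 = background).
#' @export
read_label_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(x)) == 3) x <- x[, , 1]
    return(matrix(as.integer(round(x)), nrow(x), ncol(x)))
  }
  if (ext == "png") {
    x <- .collapse_channels(png::readPNG(path))
    return(matrix(as.integer(round(x * 255)), nrow(x), ncol(x)))
  }
  stop("unsupported mask format: ", ext)
}
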