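#' Axial direction histogram
#'
#' Builds the weighted axial (180-degree periodic) direction histogram that is
#' the common currency of the simulator and the image pipeline.  Bin edges
#' cover \[0, 180) with a uniform width that must divide 180 exactly
#' (1 degree for simulated MT length histograms, 4 degrees for image gradient
#' histograms).
#'
#' @param weights numeric vector of non-negative bin weights, one per bin.
#' @param bin_width bin width in degrees; must divide 180 exactly.
#' @param normalized logical; if `TRUE` the weights are rescaled to sum to 1
#'   (a no-op for an all-zero histogram).
#' @return an object of class `angular_histogram` with elements `weights`,
#'   `breaks`, `mids`, `bin_width` and `normalized`.
#' @seealso [bin_directions()] to build one from raw angles,
#'   [fit_axial_von_mises()] to fit it.
#' @export
angular_histogram <- function(weights, bin_width = 180 / length(weights),
                              normalized = FALSE) {
  nb <- round(180 / bin_width)
  if (abs(nb * bin_width - 180) > 1e-9)
    stop("bin_width must divide 180 exactly")
  if (length(weights) != nb)
    stop("length(weights) does not match 180/bin_width bins")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  tot <- sum(weights)
  if (normalized && tot > 0) weights <- weights / tot
  structure(list(weights = as.numeric(weights),
                 breaks = seq(0, 180, by = bin_width),
                 mids = seq(bin_width / 2, 180 - bin_width / 2, by = bin_width),
                 bin_width = bin_width,
                 normalized = normalized),
            class = "angular_histogram")
}

#' @export
print.angular_histogram <- function(x, ...) {
  cat(sprintf("Axial direction histogram: %d bins of %g deg, total weight %g\n",
              length(x$weights), x$bin_width, sum(x$weights)))
  invisible(x)
}

#' Bin axial directions into a weighted histogram
#'
#' @param angles directions in degrees; reduced modulo 180.
#' @param weights per-angle weights (e.g. MT length in dimers, or gradient
#'   magnitude); defaults to 1.
#' @param bin_width bin width in degrees.
#' @param normalized passed to [angular_histogram()].
#' @return an `angular_histogram`.
#' @export
bin_directions <- function(angles, weights = rep(1, length(angles)),
                           bin_width = 1, normalized = FALSE) {
  if (length(angles) != length(weights))
    stop("angles and weights differ in length")
  nb <- round(180 / bin_width)
  a <- angles %% 180
  idx <- pmin(floor(a / bin_width) + 1L, nb)
  w <- numeric(nb)
  if (length(a)) {
    tab <- tapply(weights, factor(idx, levels = seq_len(nb)), sum)
    w <- as.numeric(ifelse(is.na(tab), 0, tab))
  }
  angular_histogram(w, bin_width = bin_width, normalized = normalized)
}

#' Fit an axial Von Mises distribution to a direction histogram
#'
#' MT directions are axial (a filament has no head or tail), so angles are
#' doubled to map the 180-degree-periodic data onto the circle, the weighted
#' circular moments are computed over the bin centres, and the fit is read off
#' in closed form: the mean direction `mu` is half the circular mean of the
#' doubled angles, and the angular standard deviation `sigma` (the MTSD) is
#' half the circular s.d., `sigma = (90/pi) * sqrt(-2 log Rbar)`, capped at 90.
#' This moment estimator exactly inverts a wrapped-normal generator: data
#' drawn with angular s.d. `s` return `sigma == s` in expectation.
#'
#' An empty histogram (or one with vanishing resultant length) is reported
#' with `mu = NA` and `sigma = 90`, the "completely unaligned" convention.
#'
#' @param hist an [angular_histogram()], or a bare numeric vector of bin
#'   weights over \[0, 180).
#' @return an object of class `von_mises_fit` with fields `mu` (degrees in
#'   \[0,180)), `sigma` (degrees in \[0,90\], the MTSD), `kappa`
#'   (concentration of the doubled-angle Von Mises) and `resultant_length`.
#' @export
fit_axial_von_mises <- function(hist) {
  if (is.numeric(hist)) hist <- angular_histogram(hist)
  if (!inherits(hist, "angular_histogram"))
    stop("hist must be an angular_histogram or numeric weights")
  w <- hist$weights
  if (any(w < 0)) stop("negative weights")
  tot <- sum(w)
  unaligned <- function() {
    structure(list(mu = NA_real_, sigma = 90, kappa = 0,
                   resultant_length = 0),
              class = "von_mises_fit")
  }
  if (tot <= 0) return(unaligned())
  th2 <- 2 * hist$mids * pi / 180
  C <- sum(w * cos(th2)) / tot
  S <- sum(w * sin(th2)) / tot
  rbar <- sqrt(C^2 + S^2)
  if (rbar < 1e-12) return(unaligned())
  mu <- (atan2(S, C) * 180 / pi / 2) %% 180
  sigma <- min(90, (90 / pi) * sqrt(-2 * log(rbar)))
  structure(list(mu = mu, sigma = sigma, kappa = .a1inv(rbar),
                 resultant_length = rbar),
            class = "von_mises_fit")
}

# Moment inverse of A1(kappa) = I1/I0 (Best & Fisher approximation).
.a1inv <- function(r) {
  if (r >= 1) return(Inf)
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' @export
print.von_mises_fit <- function(x, ...) {
  cat(sprintf(
    "Axial Von Mises fit: mu = %s deg, sigma (MTSD) = %.2f deg, kappa = %.3f\n",
    if (is.na(x$mu)) "NA" else sprintf("%.2f", x$mu), x$sigma, x$kappa))
  invisible(x)
}

#' MT deviation from the cell long axis (MTDEV)
#'
#' The acute axial difference between the MT main direction and the cell
#' orientation, both defined modulo 180 degrees.
#'
#' @param mu MT main direction, degrees.
#' @param cell_orientation cell long-axis orientation, degrees.
#' @return degrees in \[0, 90\] (`NA` if either input is `NA`).
#' @export
mtdev <- function(mu, cell_orientation) {
  d <- abs(mu - cell_orientation) %% 180
  pmin(d, 180 - d)
}

#' Compare linear fits across datasets (shared vs separate lines)
#'
#' Extra-sum-of-squares F test of one shared straight line for all datasets
#' against one line per dataset, the standard test for asking whether two
#' MTSD-versus-eccentricity relationships follow the same equation.
#'
#' @param datasets a list of data frames, each with columns `x` and `y` and
#'   at least 3 rows.
#' @return list with `F`, `p_value`, `shared_intercept`, `shared_slope`,
#'   `ss_shared`, `ss_separate`, `df_shared`, `df_separate`.
#' @export
compare_linear_fits <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2)
    stop("need a list of at least two datasets")
  datasets <- lapply(datasets, function(d) {
    d <- as.data.frame(d)
    if (!all(c("x", "y") %in% names(d))) stop("datasets need columns x and y")
    if (nrow(d) < 3) stop("each dataset needs at least 3 points")
    if (stats::var(d$x) == 0) stop("degenerate dataset: x has zero variance")
    d[c("x", "y")]
  })
  pooled <- do.call(rbind, datasets)
  fit_sh <- stats::lm(y ~ x, data = pooled)
  ss_sh <- sum(stats::resid(fit_sh)^2)
  ss_sep <- sum(vapply(datasets, function(d)
    sum(stats::resid(stats::lm(y ~ x, data = d))^2), numeric(1)))
  n <- nrow(pooled)
  k <- length(datasets)
  df_sh <- n - 2
  df_sep <- n - 2 * k
  if (df_sep <= 0) stop("too few points for the separate-fits model")
  # guard against numerically-zero residuals (exactly collinear data)
  eps <- 1e-10 * (sum(pooled$y^2) + 1)
  num <- (ss_sh - ss_sep) / (df_sh - df_sep)
  den <- ss_sep / df_sep
  Fstat <- if (ss_sep <= eps) {
    if (ss_sh - ss_sep <= eps) 0 else Inf
  } else max(0, num / den)
  p <- stats::pf(Fstat, df_sh - df_sep, df_sep, lower.tail = FALSE)
  co <- stats::coef(fit_sh)
  list(F = Fstat, p_value = p,
       shared_intercept = unname(co[1]), shared_slope = unname(co[2]),
       ss_shared = ss_sh, ss_separate = ss_sep,
       df_shared = df_sh, df_separate = df_sep)
}

#' One-phase exponential decay fit
#'
#' Least-squares fit of `y = (y0 - plateau) * exp(-k * x) + plateau`, the
#' model used for the MTDEV-versus-eccentricity relationship.
#'
#' @param x,y numeric vectors (>= 4 points).
#' @return list with `y0`, `plateau`, `k`, `rss`, `converged` and `flag`
#'   (a message for degenerate or non-converged fits; `NA` otherwise).
#' @export
fit_one_phase_decay <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    stop("need at least 4 (x, y) points")
  if (stats::var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    return(list(y0 = mean(y), plateau = mean(y), k = NA_real_,
                rss = sum((y - mean(y))^2), converged = FALSE,
                flag = "constant y: decay rate unidentifiable, plateau = mean"))
  }
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  start <- list(y0 = ys[1], plateau = ys[length(ys)],
                k = 1 / max(diff(range(xs)), .Machine$double.eps))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ (y0 - plateau) * exp(-k * x) + plateau,
                      data = data.frame(x = x, y = y),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(y0 = start$y0, plateau = start$plateau, k = start$k,
                rss = NA_real_, converged = FALSE,
                flag = paste("fit failed:", conditionMessage(fit))))
  }
  co <- stats::coef(fit)
  list(y0 = unname(co["y0"]), plateau = unname(co["plateau"]),
       k = unname(co["k"]), rss = sum(stats::resid(fit)^2),
       converged = TRUE, flag = NA_character_)
}
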