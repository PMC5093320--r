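#' Simulation parameters for the MT dynamic-instability model
#'
#' Each MT is a one-dimensional polymer of 8.2-nm tubulin dimers evolving as
#' a continuous-time Markov chain.  A growing MT of length n (state A_n) adds
#' a dimer at rate `alpha` or switches to shrinking at the catastrophe rate
#' `beta_prime`; a shrinking MT (state B_n) loses a dimer at rate `beta` or
#' is rescued at rate `alpha_prime`.  Rates are non-dimensional; multiplying
#' by the dimensional factor R (see [dimensionalize()]) recovers per-second
#' rates.
#'
#' @param alpha polymerization rate (default 1000).
#' @param beta depolymerization rate (default 3500).
#' @param alpha_prime rescue rate (default 4).
#' @param beta_prime catastrophe rate (default 1).
#' @param growth_speed_um_s observed MT growth speed used to fix the
#'   dimensional factor R (default 0.15 um/s).
#' @param dimer_len tubulin dimer length, nm (default 8.2).
#' @param p_cat catastrophe probability on steep collisions (default 0.01).
#' @param theta_critical critical collision angle, degrees (default 30).
#' @param n_seeds number of MT seeds on the cell periphery (default 220).
#' @param rule_set collision rule set: `"angle_dependent"` (full model;
#'   default), `"stabilize_no_cross"` (MT-MT catastrophe + boundary
#'   stabilization), `"cross_stabilize"` (MT-MT crossover + boundary
#'   stabilization) or `"cross_boundary_cat"` (MT-MT crossover + boundary
#'   catastrophe).
#' @param t_end simulated non-dimensional time (default 10, about 550 s).
#' @param sample_dt sampling interval for the angle histogram (default 0.01).
#' @param avg_window trailing window, in non-dimensional time, over which the
#'   final statistics are averaged (default 2.5, i.e. 250 samples).
#' @param series_window trailing window, in non-dimensional time, over which
#'   histograms are pooled when computing the MTSD *time series* (default
#'   2.5, matching `avg_window` so the series tracks the same windowed
#'   statistic that defines the reported final MTSD).  A single 0.01-unit
#'   snapshot is a noisy estimate of the array state; set `series_window =
#'   sample_dt` for raw per-sample values.
#' @param frozen_pause if `TRUE`, MTs stabilized at the boundary are fully
#'   frozen; by default they remain subject to spontaneous catastrophe.
#' @param rng_seed integer seed for the run.
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(alpha = 1000, beta = 3500, alpha_prime = 4,
                       beta_prime = 1, growth_speed_um_s = 0.15,
                       dimer_len = 8.2, p_cat = 0.01, theta_critical = 30,
                       n_seeds = 220,
                       rule_set = c("angle_dependent", "stabilize_no_cross",
                                    "cross_stabilize", "cross_boundary_cat"),
                       t_end = 10, sample_dt = 0.01, avg_window = 2.5,
                       series_window = 2.5, frozen_pause = FALSE,
                       rng_seed = 1L) {
  rule_set <- match.arg(rule_set)
  p <- list(alpha = alpha, beta = beta, alpha_prime = alpha_prime,
            beta_prime = beta_prime, growth_speed_um_s = growth_speed_um_s,
            dimer_len = dimer_len, p_cat = p_cat,
            theta_critical = theta_critical, n_seeds = as.integer(n_seeds),
            rule_set = rule_set, t_end = t_end, sample_dt = sample_dt,
            avg_window = avg_window, series_window = series_window,
            frozen_pause = isTRUE(frozen_pause),
            rng_seed = as.integer(rng_seed))
  with(p, {
    if (any(c(alpha, beta, alpha_prime, beta_prime) <= 0))
      stop("all transition rates must be > 0")
    if (p_cat < 0 || p_cat > 1) stop("p_cat must lie in [0, 1]")
    if (theta_critical <= 0 || theta_critical > 90)
      stop("theta_critical must lie in (0, 90]")
    if (n_seeds < 1) stop("n_seeds must be >= 1")
    if (t_end < 0 || sample_dt <= 0) stop("invalid t_end/sample_dt")
    if (avg_window > t_end && t_end > 0)
      stop("avg_window must not exceed t_end")
    if (series_window < sample_dt)
      stop("series_window must be at least sample_dt")
    if (dimer_len <= 0) stop("dimer_len must be > 0")
  })
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("MT simulation parameters: alpha=%g beta=%g alpha'=%g ",
                     "beta'=%g, %d seeds, rule '%s', t_end=%g\n"),
              x$alpha, x$beta, x$alpha_prime, x$beta_prime, x$n_seeds,
              x$rule_set, x$t_end))
  invisible(x)
}

.rule_code <- function(rule_set) {
  match(rule_set, c("stabilize_no_cross", "cross_stabilize",
                    "cross_boundary_cat", "angle_dependent"))
}

#' Dimensionalize the non-dimensional CTMC rates
#'
#' The dimensional factor R (per second) is fixed by equating the model
#' growth speed `alpha * dimer_len * R` to the observed MT growth speed.
#' Each dimensional rate is then `rate * R`, and a non-dimensional time `t`
#' corresponds to `t / R` seconds.
#'
#' @param params a [sim_params()] object.
#' @return a list with `R` (s^-1), a data frame `rates` (non-dimensional and
#'   per-second values for alpha, beta, alpha', beta') and `seconds`, a
#'   function converting non-dimensional time to seconds.
#' @examples
#' d <- dimensionalize(sim_params())
#' d$R            # 0.01829 s^-1
#' d$seconds(10)  # about 547 s
#' @export
dimensionalize <- function(params = sim_params()) {
  if (params$growth_speed_um_s <= 0) stop("growth speed must be > 0")
  R <- params$growth_speed_um_s * 1000 / (params$alpha * params$dimer_len)
  nd <- c(alpha = params$alpha, beta = params$beta,
          alpha_prime = params$alpha_prime, beta_prime = params$beta_prime)
  list(R = R,
       rates = data.frame(rate = names(nd), non_dimensional = unname(nd),
                          per_second = unname(nd) * R),
       seconds = function(t) t / R)
}

#' Resolve a collision into an outcome
#'
#' Pure function of the collision angle, the target, the rule set and a
#' uniform random draw.  Under the full angle-dependent rules: for a
#' collision at acute angle `theta` below `theta_critical` the MT undergoes
#' catastrophe with probability `P = theta / theta_critical * p_cat` and
#' otherwise zips along the target; at or above `theta_critical` an MT-MT
#' collision ends in catastrophe with probability `p_cat` and otherwise
#' crosses, while a boundary collision always ends in catastrophe.  The
#' other rule sets are deterministic: `stabilize_no_cross` (MT-MT
#' catastrophe, boundary stabilization), `cross_stabilize` (MT-MT crossover,
#' boundary stabilization), `cross_boundary_cat` (MT-MT crossover, boundary
#' catastrophe).
#'
#' @param angle acute collision angle in degrees, in (0, 90\]; vectorized.
#' @param target `"boundary"` or `"microtubule"`.
#' @param rule_set one of the four rule sets (see [sim_params()]).
#' @param u uniform draws in \[0, 1); recycled against `angle`.
#' @param p_cat,theta_critical rule parameters.
#' @return character vector of outcomes:
#'   `"zip"`, `"cross"`, `"catastrophe"` or `"stabilize"`.
#' @export
resolve_collision <- function(angle, target = c("microtubule", "boundary"),
                              rule_set = c("angle_dependent",
                                           "stabilize_no_cross",
                                           "cross_stabilize",
                                           "cross_boundary_cat"),
                              u = stats::runif(length(angle)),
                              p_cat = 0.01, theta_critical = 30) {
  target <- match.arg(target)
  rule_set <- match.arg(rule_set)
  if (any(angle <= 0 | angle > 90))
    stop("collision angle out of (0, 90]: collision detection bug")
  n <- max(length(angle), length(u))
  angle <- rep_len(angle, n); u <- rep_len(u, n)
  boundary <- target == "boundary"
  if (rule_set == "stabilize_no_cross")
    return(rep(if (boundary) "stabilize" else "catastrophe", n))
  if (rule_set == "cross_stabilize")
    return(rep(if (boundary) "stabilize" else "cross", n))
  if (rule_set == "cross_boundary_cat")
    return(rep(if (boundary) "catastrophe" else "cross", n))
  out <- character(n)
  shallow <- angle < theta_critical
  P <- angle / theta_critical * p_cat
  out[shallow] <- ifelse(u[shallow] < P[shallow], "catastrophe", "zip")
  if (boundary) {
    out[!shallow] <- "catastrophe"
  } else {
    out[!shallow] <- ifelse(u[!shallow] < p_cat, "catastrophe", "cross")
  }
  out
}

#' Run one MT self-organization simulation
#'
#' Places `n_seeds` seeds on the domain boundary, starts all MT lengths at
#' zero, and evolves the system by an exact Gillespie algorithm until
#' `t_end`, resolving every MT-MT and MT-boundary collision under the chosen
#' rule set.  The length-weighted axial direction histogram (1-degree bins)
#' is sampled every `sample_dt`; the final MTSD is the Von Mises sigma of
#' the histogram averaged over the trailing `avg_window`.
#'
#' @param domain a [build_cell_domain()] object.
#' @param params a [sim_params()] object.
#' @return an object of class `sim_result`: `params`, `domain`, `times`
#'   (non-dimensional sample times), `seconds`, `hist` (samples x 180 bins,
#'   dimers), `mtsd_series` (degrees per sample), `mtsd` (final MTSD,
#'   degrees, from the histogram averaged over the trailing `avg_window`),
#'   `mtsd_frame` (MTSD of the final snapshot alone, the quantity a
#'   rendered image of the final state measures),
#'   `mt_main_direction` (degrees, `NA` if unaligned), `mtdev`
#'   (degrees vs the domain long axis), `events` (collision log),
#'   `final_segments`, `convergence_s` (see [detect_convergence()]).
#' @export
run_simulation <- function(domain, params = sim_params()) {
  if (!inherits(domain, "cell_domain")) stop("domain must be a cell_domain")
  if (!inherits(params, "sim_params")) stop("params must be sim_params")
  seeds <- place_seeds(domain, params$n_seeds)
  cpar <- list(alpha = params$alpha, beta = params$beta,
               alpha_prime = params$alpha_prime,
               beta_prime = params$beta_prime, p_cat = params$p_cat,
               theta_critical = params$theta_critical,
               dimer_len = params$dimer_len, t_end = params$t_end,
               sample_dt = params$sample_dt,
               rule_code = .rule_code(params$rule_set),
               frozen_pause = params$frozen_pause)
  set.seed(params$rng_seed)
  raw <- .sim_run_cpp(domain$vertices, as.matrix(seeds), cpar)

  nsamp <- nrow(raw$hist)
  times <- params$sample_dt * seq_len(nsamp)
  dim_fac <- dimensionalize(params)
  wlen <- max(1L, min(nsamp, round(params$series_window / params$sample_dt)))
  mtsd_series <- .mtsd_from_hist_rows(.rolling_row_mean(raw$hist, wlen))

  nwin <- max(1L, min(nsamp, round(params$avg_window / params$sample_dt)))
  if (nsamp > 0) {
    avg_hist <- colMeans(raw$hist[seq(nsamp - nwin + 1, nsamp), , drop = FALSE])
    fit <- fit_axial_von_mises(angular_histogram(avg_hist, bin_width = 1))
  } else {
    fit <- fit_axial_von_mises(angular_histogram(numeric(180), bin_width = 1))
  }
  conv <- if (nsamp > 0) {
    detect_convergence(mtsd_series, dim_fac$seconds(times),
                       window_s = dim_fac$seconds(params$avg_window))
  } else NA_real_
  frame_fit <- if (nsamp > 0)
    fit_axial_von_mises(angular_histogram(raw$hist[nsamp, ], bin_width = 1))
  else fit

  events <- data.frame(
    t = raw$event_t,
    mt = raw$event_mt,
    target = c("boundary", "microtubule")[raw$event_target + 1L],
    angle = raw$event_angle,
    outcome = c("zip", "cross", "catastrophe", "stabilize")[raw$event_outcome + 1L],
    stringsAsFactors = FALSE)
  segs <- raw$final_segments
  colnames(segs) <- c("mt", "x0", "y0", "dx", "dy", "len_dimers")
  structure(list(params = params, domain = domain, times = times,
                 seconds = dim_fac$seconds(times), hist = raw$hist,
                 mtsd_series = mtsd_series, mtsd = fit$sigma,
                 mtsd_frame = frame_fit$sigma,
                 mt_main_direction = fit$mu,
                 mtdev = if (is.na(fit$mu)) NA_real_ else
                   mtdev(fit$mu, domain$orientation),
                 events = events, final_segments = segs,
                 convergence_s = conv),
            class = "sim_result")
}

# trailing rolling mean over rows (window w), growing window at the start
.rolling_row_mean <- function(h, w) {
  if (w <= 1L || nrow(h) == 0) return(h)
  cs <- apply(h, 2, cumsum)
  n <- nrow(h)
  lag <- rbind(matrix(0, min(w, n), ncol(h)),
               cs[seq_len(max(0, n - w)), , drop = FALSE])
  (cs - lag) / pmin(seq_len(n), w)
}

# vectorized per-row axial Von Mises sigma for a samples x 180 histogram
.mtsd_from_hist_rows <- function(h) {
  mids <- seq(0.5, 179.5, by = 1) * pi / 90   # doubled angles, radians
  W <- rowSums(h)
  C <- as.numeric(h %*% cos(mids))
  S <- as.numeric(h %*% sin(mids))
  rbar <- ifelse(W > 0, sqrt(C^2 + S^2) / W, 0)
  ifelse(rbar < 1e-12, 90, pmin(90, (90 / pi) * sqrt(-2 * log(rbar))))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("MT simulation (rule '%s', e = %.2f, width %.0f nm): ",
                     "MTSD %.1f deg, main direction %s deg, MTDEV %s deg\n"),
              x$params$rule_set, x$domain$eccentricity, x$domain$width,
              x$mtsd,
              if (is.na(x$mt_main_direction)) "NA"
              else sprintf("%.1f", x$mt_main_direction),
              if (is.na(x$mtdev)) "NA" else sprintf("%.1f", x$mtdev)))
  cat(sprintf("  %d collision events; convergence at %s s\n",
              nrow(x$events),
              if (is.na(x$convergence_s)) "NA (not converged)"
              else sprintf("%.0f", x$convergence_s)))
  invisible(x)
}

#' Time for the MTSD series to converge
#'
#' Returns the first time after which the MTSD stays within a relative
#' tolerance band of its long-run stable value, defined as the mean of the
#' series over the trailing averaging window.  A series inside the band from
#' the start converges at 0; a series still outside the band at the end
#' returns `NA` (not converged).
#'
#' @param mtsd_series MTSD values, degrees.
#' @param times_s sample times in seconds (same length).
#' @param window_s trailing window over which the stable value is taken,
#'   seconds (default: the final 2.5 non-dimensional time units of a default
#'   run, about 137 s).
#' @param tol relative tolerance (default 0.10).
#' @return convergence time in seconds, or `NA_real_`.
#' @export
detect_convergence <- function(mtsd_series, times_s,
                               window_s = 2.5 / 0.01829, tol = 0.10) {
  n <- length(mtsd_series)
  if (n == 0 || n != length(times_s)) stop("invalid series")
  t_end <- times_s[n]
  in_win <- times_s > t_end - window_s
  stable <- mean(mtsd_series[in_win])
  ok <- abs(mtsd_series - stable) <= tol * stable
  bad <- which(!ok)
  if (length(bad) == 0) return(0)
  if (max(bad) == n) return(NA_real_)
  times_s[max(bad) + 1L]
}

#' Sweep eccentricities (and cell widths) and tabulate MTSD
#'
#' Runs `runs_per_point` independent simulations for every width x
#' eccentricity combination and reports per-run and summary MTSD.  When two
#' or more widths are given, the mean-MTSD-versus-eccentricity relationships
#' are additionally compared with the shared-versus-separate linear fit test
#' ([compare_linear_fits()]).
#'
#' @param widths cell widths in nm (default 492, the 60-dimer cell).
#' @param eccs eccentricities (default 0.7 to 0.95 in steps of 0.05).
#' @param params base [sim_params()]; each run gets a deterministic seed
#'   offset from `params$rng_seed`.
#' @param runs_per_point independent runs per point (default 3).
#' @return object of class `mt_sweep`: `runs` (one row per run: `width_nm`,
#'   `eccentricity`, `run`, `rng_seed`, `mtsd_deg`, `mtdev_deg`,
#'   `convergence_s`), `summary` (mean and s.e.m. per point) and
#'   `fit_comparison` (or `NULL` for a single width).
#' @export
sweep_eccentricity <- function(widths = 492,
                               eccs = seq(0.7, 0.95, by = 0.05),
                               params = sim_params(), runs_per_point = 3) {
  if (runs_per_point < 1) stop("runs_per_point must be >= 1")
  rows <- list()
  i <- 0L
  for (w in widths) for (e in eccs) for (r in seq_len(runs_per_point)) {
    i <- i + 1L
    seed_i <- params$rng_seed + 7919L * i
    p <- params
    p$rng_seed <- seed_i
    res <- run_simulation(build_cell_domain(w, e), p)
    rows[[i]] <- data.frame(width_nm = w, eccentricity = e, run = r,
                            rng_seed = seed_i, mtsd_deg = res$mtsd,
                            mtdev_deg = res$mtdev,
                            convergence_s = res$convergence_s)
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, list(runs$width_nm,
                                                runs$eccentricity),
                                     drop = TRUE), function(d) {
    data.frame(width_nm = d$width_nm[1], eccentricity = d$eccentricity[1],
               mean_mtsd = mean(d$mtsd_deg),
               sem_mtsd = stats::sd(d$mtsd_deg) / sqrt(nrow(d)),
               n_runs = nrow(d))
  }))
  agg <- agg[order(agg$width_nm, agg$eccentricity), ]
  rownames(agg) <- NULL
  cmpfit <- NULL
  if (length(widths) >= 2 && length(eccs) >= 3) {
    # compared at run level so the test sees the run-to-run variance
    ds <- lapply(split(runs, runs$width_nm), function(d)
      data.frame(x = d$eccentricity, y = d$mtsd_deg))
    cmpfit <- compare_linear_fits(ds)
  }
  structure(list(runs = runs, summary = agg, fit_comparison = cmpfit),
            class = "mt_sweep")
}

#' @export
print.mt_sweep <- function(x, ...) {
  cat("MTSD versus eccentricity sweep\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$fit_comparison))
    cat(sprintf("Shared vs separate linear fits across widths: F = %.3f, p = %.3f\n",
                x$fit_comparison$F, x$fit_comparison$p_value))
  invisible(x)
}

#' Tabulate collision outcomes by angle category
#'
#' Events are placed in the angle categories 10-30, 31-60 and 61-90 degrees
#' (collisions shallower than 10 degrees are not categorized, matching the
#' angular resolution of live-imaging collision calls), separately for
#' boundary and MT targets, and outcome frequencies are normalized within
#' each category.
#'
#' @param events the `events` data frame of a [run_simulation()] result.
#' @return data frame with columns `target`, `category`, `outcome`,
#'   `n`, `frequency`; empty if no events fall in the categories.
#' @export
collision_angle_summary <- function(events) {
  if (is.null(events) || nrow(events) == 0)
    return(data.frame(target = character(), category = character(),
                      outcome = character(), n = integer(),
                      frequency = numeric()))
  ev <- events[events$angle >= 10, , drop = FALSE]
  if (nrow(ev) == 0)
    return(data.frame(target = character(), category = character(),
                      outcome = character(), n = integer(),
                      frequency = numeric()))
  ev$category <- cut(ev$angle, breaks = c(10, 30, 60, 90),
                     labels = c("10-30", "31-60", "61-90"),
                     include.lowest = TRUE)
  out <- do.call(rbind, lapply(split(ev, list(ev$target, ev$category),
                                     drop = TRUE), function(d) {
    tab <- table(d$outcome)
    data.frame(target = d$target[1], category = as.character(d$category[1]),
               outcome = names(tab), n = as.integer(tab),
               frequency = as.numeric(tab) / nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$target, out$category, out$outcome), ]
}
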