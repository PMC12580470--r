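# Disturbance-stratified subset scheme and circular (von Mises kernel)
# activity density estimation with bootstrap envelopes.

# Subsets with fewer than this many independent events are dropped from
# activity estimation (robustness floor for circular KDE).
MIN_EVENTS_ACTIVITY <- 10

#' Median split of trail cameras by recreation RAI
#'
#' Within each effort window, trail cameras at or above the median
#' recreation RAI are labelled `"high"` recreational activity, those
#' below the median `"low"` (ties at the median go to high, so 60
#' distinct values split 30/30). Each forest camera inherits the label of
#' its paired trail camera; cameras without a pair are excluded with a
#' message. Splitting is per window, so the two high-effort periods are
#' classified separately before any later pooling.
#'
#' @param rec_rai Output of [recreation_rai_per_camera()].
#' @param deployments Deployment table with `camera_id`, `location_id`,
#'   `placement`.
#' @return Data frame `camera_id`, `window`, `recreation` in
#'   `{"low","high"}` covering trail and forest cameras.
#' @export
median_split_recreation <- function(rec_rai, deployments) {
  dep <- deployments[, c("camera_id", "location_id", "placement")]
  trail <- dep[dep$placement == "trail", ]
  forest <- dep[dep$placement == "forest", ]
  out <- list()
  for (w in unique(rec_rai$window)) {
    rw <- rec_rai[rec_rai$window == w & !is.na(rec_rai$rai), ]
    if (nrow(rw) == 0) next
    med <- stats::median(rw$rai)
    lab <- ifelse(rw$rai >= med, "high", "low")
    trail_lab <- data.frame(
      camera_id = rw$camera_id, window = w,
      recreation = lab, stringsAsFactors = FALSE
    )
    # forest partner inherits the trail camera's label
    loc <- trail$location_id[match(rw$camera_id, trail$camera_id)]
    fmatch <- match(loc, forest$location_id)
    paired <- !is.na(fmatch)
    if (any(!paired)) {
      message(sum(!paired), " trail camera(s) without a forest pair in ",
        w, ": pair label not assigned")
    }
    forest_lab <- data.frame(
      camera_id = forest$camera_id[fmatch[paired]], window = w,
      recreation = lab[paired], stringsAsFactors = FALSE
    )
    out[[w]] <- rbind(trail_lab, forest_lab)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the disturbance-stratified activity subsets
#'
#' Splits one species' events into the 24-cell grid of effort stratum (3)
#' x placement (2) x recreational activity on the nearby trail (2) x
#' hunting-zone membership (2). Events in the two high-effort windows
#' carry their own window's recreation label and are pooled into the one
#' high stratum. Subsets with fewer than `min_events` events are dropped
#' (and reported in the summary); kept subsets carry the solar-radian
#' event times.
#'
#' @param events One species' independent events with `camera_id`,
#'   `event_time` and a `solar` column of solar radian times (see
#'   [to_solar_radians()]).
#' @param deployments Deployment table.
#' @param splits Output of [median_split_recreation()].
#' @param calendar An `effort_calendar`.
#' @param min_events Drop threshold (default 10).
#' @return List of class `activity_subsets`: `times` (named list of
#'   solar-radian vectors for kept subsets), `summary` (data frame of all
#'   24 keys with `n_events` and `kept`).
#' @export
build_subsets <- function(events, deployments, splits, calendar,
                          min_events = MIN_EVENTS_ACTIVITY) {
  stopifnot("solar" %in% names(events))
  dep <- deployments[, c("camera_id", "placement", "in_hunting_zone")]
  dates <- as.Date(format(events$event_time, tz = DIEL_REF_TZ, "%Y-%m-%d"))
  ev <- data.frame(
    camera_id = events$camera_id, solar = events$solar,
    stratum = effort_of_date(calendar, dates, "stratum"),
    window = effort_of_date(calendar, dates, "window"),
    stringsAsFactors = FALSE
  )
  ev <- merge(ev, dep, by = "camera_id")
  m <- match(
    paste(ev$camera_id, ev$window),
    paste(splits$camera_id, splits$window)
  )
  ev$recreation <- splits$recreation[m]
  ev <- ev[!is.na(ev$stratum) & !is.na(ev$recreation), , drop = FALSE]
  ev$zone <- ifelse(ev$in_hunting_zone, "hunting", "non-hunting")

  keys <- expand.grid(
    stratum = c("high", "medium", "low"),
    placement = c("trail", "forest"),
    recreation = c("low", "high"),
    zone = c("hunting", "non-hunting"),
    stringsAsFactors = FALSE
  )
  key_of <- function(df) {
    paste(df$stratum, df$placement, df$recreation, df$zone, sep = ".")
  }
  groups <- split(ev$solar, factor(key_of(ev), levels = key_of(keys)))
  keys$n_events <- vapply(groups, length, integer(1))
  keys$kept <- keys$n_events >= min_events
  times <- groups[keys$kept]
  structure(list(times = times, summary = keys), class = "activity_subsets")
}

# --- circular kernel machinery -------------------------------------------

# Mean resultant length of a von Mises distribution, A1(kappa).
.vm_A1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

# Inverse of A1 (Fisher's piecewise approximation, refined by one
# Newton step through uniroot where it matters).
.vm_A1inv <- function(r) {
  if (r >= 1) {
    return(1e8)
  }
  if (r <= 0) {
    return(1e-8)
  }
  k <- if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
  max(k, 1e-8)
}

# Plug-in concentration: kernel circular SD matched to the linear
# normal-reference rule 1.06 * sigma_hat * n^(-1/5), with
# sigma_hat = sqrt(-2 log Rbar) the circular SD of the sample.
.vm_bandwidth_kappa <- function(times, adjust = 1) {
  n <- length(times)
  rbar <- Mod(mean(exp(1i * times)))
  rbar <- min(max(rbar, 1e-12), 1 - 1e-12)
  sigma <- sqrt(-2 * log(rbar))
  h <- 1.06 * sigma * n^(-1 / 5) * adjust
  .vm_A1inv(exp(-h^2 / 2))
}

# Von Mises kernel mixture density on a grid (overflow-safe via
# exponentially scaled Bessel).
.vm_kde <- function(grid, times, kappa) {
  logc <- log(2 * pi) + log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  d <- outer(grid, times, function(g, t) exp(kappa * cos(g - t) - logc))
  rowMeans(d)
}

# Trapezoidal integral of a periodic density sampled on a half-open
# uniform grid over [0, 2*pi).
.circ_trapz <- function(grid, f) {
  step <- grid[2] - grid[1]
  sum(f) * step # uniform periodic grid: trapezoid == rectangle rule
}

#' Circular activity density with bootstrap envelope
#'
#' Von Mises kernel density of solar-radian event times on a 512-point
#' grid over `[0, 2*pi)`, with the kernel concentration chosen by a
#' plug-in rule (kernel circular SD matched to `1.06 * sigma * n^(-1/5)`)
#' and pointwise percentile envelopes from resampling the event times
#' with replacement.
#'
#' @param times_radians Event times in solar radians, `[0, 2*pi)`; at
#'   least 10 (the subset floor).
#' @param bandwidth_adjust Multiplier on the plug-in kernel SD.
#' @param B Bootstrap resamples for the envelope (0 to skip).
#' @param seed Optional seed.
#' @param n_grid Grid size.
#' @return Object of class `activity_curve`: `grid`, `density`, `ci_low`,
#'   `ci_high`, `n_events`, `kappa_bw`.
#' @export
fit_activity_kde <- function(times_radians, bandwidth_adjust = 1, B = 1000,
                             seed = NULL, n_grid = 512) {
  n <- length(times_radians)
  if (n < MIN_EVENTS_ACTIVITY) {
    stop(
      "activity density needs at least ", MIN_EVENTS_ACTIVITY,
      " events; got ", n
    )
  }
  times <- times_radians %% (2 * pi)
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[seq_len(n_grid)]
  kappa <- .vm_bandwidth_kappa(times, bandwidth_adjust)
  dens <- .vm_kde(grid, times, kappa)
  dens <- dens / .circ_trapz(grid, dens)
  ci_low <- ci_high <- rep(NA_real_, n_grid)
  if (B > 0) {
    if (!is.null(seed)) set.seed(seed)
    reps <- matrix(NA_real_, nrow = B, ncol = n_grid)
    for (b in seq_len(B)) {
      ts <- sample(times, n, replace = TRUE)
      kb <- .vm_bandwidth_kappa(ts, bandwidth_adjust)
      db <- .vm_kde(grid, ts, kb)
      reps[b, ] <- db / .circ_trapz(grid, db)
    }
    ci <- apply(reps, 2, stats::quantile,
      probs = c(0.025, 0.975),
      names = FALSE
    )
    ci_low <- ci[1, ]
    ci_high <- ci[2, ]
  }
  structure(
    list(
      grid = grid, density = dens, ci_low = ci_low, ci_high = ci_high,
      n_events = n, kappa_bw = kappa
    ),
    class = "activity_curve"
  )
}

#' @export
print.activity_curve <- function(x, ...) {
  cat(sprintf(
    "Activity curve: %d events, kernel kappa %.2f, peak density %.3f\n",
    x$n_events, x$kappa_bw, max(x$density)
  ))
  invisible(x)
}

#' Plot an activity density curve
#'
#' Base-graphics plot of the density with its bootstrap envelope; x axis
#' in solar radians (sunrise at pi/2, sunset at 3*pi/2).
#'
#' @param x An `activity_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.activity_curve <- function(x, ...) {
  graphics::plot(x$grid, x$density,
    type = "l", xlab = "solar time (rad)",
    ylab = "density", xaxt = "n", ...
  )
  graphics::axis(1,
    at = c(0, pi / 2, pi, 3 * pi / 2, 2 * pi),
    labels = c("0", "sunrise", "noon", "sunset", "2π")
  )
  if (!anyNA(x$ci_low)) {
    graphics::lines(x$grid, x$ci_low, lty = 3)
    graphics::lines(x$grid, x$ci_high, lty = 3)
  }
  invisible(x)
}

#' Coefficient of overlap between two activity curves
#'
#' Integral of the pointwise minimum of two densities on a common grid
#' (trapezoid); 1 for identical curves, 0 for disjoint support.
#'
#' @param curve_a,curve_b `activity_curve` objects on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
overlap_area <- function(curve_a, curve_b) {
  if (length(curve_a$grid) != length(curve_b$grid) ||
    max(abs(curve_a$grid - curve_b$grid)) > 1e-12) {
    stop("activity curves are on different grids")
  }
  .circ_trapz(curve_a$grid, pmin(curve_a$density, curve_b$density))
}
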