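# Relative abundance index, trail-use index, and nonparametric bootstrap
# over camera-trap locations (paired trail + forest cameras resampled
# together).

#' Relative abundance index
#'
#' Independent events per 100 trap-days: `100 * n_events / trap_days`.
#'
#' @param n_events Non-negative event count(s).
#' @param trap_days Positive trap-day total(s).
#' @return Numeric RAI; `NA` with a warning where `trap_days` is 0.
#' @export
rai <- function(n_events, trap_days) {
  stopifnot(all(n_events >= 0), all(trap_days >= 0))
  out <- ifelse(trap_days > 0, 100 * n_events / trap_days, NA_real_)
  if (anyNA(out)) {
    warning("RAI undefined for ", sum(is.na(out)),
      " stratum/camera(s) with zero trap days",
      call. = FALSE
    )
  }
  out
}

#' Trail-use index
#'
#' `log((rai_trail + 1) / (rai_forest + 1))` with the natural log.
#' Positive values mean the species was recorded relatively more on
#' trails, negative relatively more in the forest; 0 means parity.
#'
#' @param rai_trail,rai_forest Non-negative RAI values.
#' @return Numeric index.
#' @export
trail_index <- function(rai_trail, rai_forest) {
  if (any(rai_trail < 0) || any(rai_forest < 0)) {
    stop("RAI inputs to trail_index must be non-negative")
  }
  log((rai_trail + 1) / (rai_forest + 1))
}

#' Nonparametric bootstrap over camera-trap locations
#'
#' Resamples location ids with replacement `B` times; each replicate
#' passes the resampled per-location rows (paired trail and forest
#' cameras of a location always move together) to `statistic`, which
#' must return a named or unnamed numeric vector computed from the pooled
#' multiset. Cross-stratum contrasts stay paired when computed inside one
#' `statistic`, since all components of a replicate share the same
#' location draw.
#'
#' @param loc_stats Data frame with a `location_id` column and whatever
#'   per-location columns `statistic` needs; one row per location.
#' @param statistic Function of a resampled `loc_stats` data frame
#'   returning a numeric vector (constant length).
#' @param B Number of bootstrap replicates.
#' @param seed Optional integer seed for reproducibility.
#' @param ci_level Confidence level for the percentile interval.
#' @return Object of class `location_boot`: list with `point` (statistic
#'   on the full data), `replicates` (B x k matrix, NA rows where the
#'   statistic was undefined), `ci_low`, `ci_high`, `n_dropped`, `B`.
#' @export
bootstrap_locations <- function(loc_stats, statistic, B = 1000, seed = NULL,
                                ci_level = 0.95) {
  stopifnot("location_id" %in% names(loc_stats), B >= 1)
  locs <- unique(loc_stats$location_id)
  if (length(locs) < 1) stop("no locations to resample")
  if (!is.null(seed)) set.seed(seed)
  point <- statistic(loc_stats)
  k <- length(point)
  reps <- matrix(NA_real_, nrow = B, ncol = k)
  colnames(reps) <- names(point)
  idx_by_loc <- split(seq_len(nrow(loc_stats)), loc_stats$location_id)
  for (b in seq_len(B)) {
    draw <- sample(locs, length(locs), replace = TRUE)
    rows <- unlist(idx_by_loc[as.character(draw)], use.names = FALSE)
    val <- tryCatch(statistic(loc_stats[rows, , drop = FALSE]),
      error = function(e) rep(NA_real_, k)
    )
    if (length(val) == k && all(is.finite(val))) reps[b, ] <- val
  }
  ok <- stats::complete.cases(reps)
  alpha <- (1 - ci_level) / 2
  ci <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
    probs = c(alpha, 1 - alpha), names = FALSE
  )
  structure(
    list(
      point = point, replicates = reps,
      ci_low = ci[1, ], ci_high = ci[2, ],
      n_dropped = sum(!ok), B = B, ci_level = ci_level
    ),
    class = "location_boot"
  )
}

#' @export
print.location_boot <- function(x, ...) {
  cat(
    "Location-level bootstrap (", x$B, " replicates, ",
    x$n_dropped, " dropped)\n",
    sep = ""
  )
  print(data.frame(
    estimate = x$point, ci_low = x$ci_low,
    ci_high = x$ci_high
  ))
  invisible(x)
}

#' Bootstrap difference with percentile CI
#'
#' Difference `a - b` of two statistics with a percentile CI from the
#' replicate-wise differences. The two replicate vectors must come from
#' the same bootstrap draws (e.g. two components of one
#' [bootstrap_locations()] call) so the differences are paired.
#'
#' @param replicates_a,replicates_b Replicate vectors of equal length.
#' @param point_a,point_b Point estimates; default to the replicate
#'   medians if omitted.
#' @param ci_level Confidence level.
#' @param label Optional label for printing.
#' @return List of class `boot_difference`: `difference`, `ci_low`,
#'   `ci_high`, `significant` (CI excludes 0), `label`.
#' @export
difference_with_ci <- function(replicates_a, replicates_b,
                               point_a = NULL, point_b = NULL,
                               ci_level = 0.95, label = "") {
  if (length(replicates_a) != length(replicates_b)) {
    stop("replicate vectors must have the same length")
  }
  if (is.null(point_a)) point_a <- stats::median(replicates_a, na.rm = TRUE)
  if (is.null(point_b)) point_b <- stats::median(replicates_b, na.rm = TRUE)
  d <- replicates_a - replicates_b
  d <- d[is.finite(d)]
  alpha <- (1 - ci_level) / 2
  ci <- stats::quantile(d, probs = c(alpha, 1 - alpha), names = FALSE)
  structure(
    list(
      label = label, difference = point_a - point_b,
      ci_low = ci[1], ci_high = ci[2],
      significant = ci[1] > 0 || ci[2] < 0
    ),
    class = "boot_difference"
  )
}

#' @export
print.boot_difference <- function(x, ...) {
  cat(sprintf(
    "%s: difference %.3f [%.3f, %.3f]%s\n",
    if (nzchar(x$label)) x$label else "contrast",
    x$difference, x$ci_low, x$ci_high,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Recreation RAI per trail camera and effort window
#'
#' One RAI (events per 100 trap-days) per trail camera per effort
#' *window* — the two high-effort periods are kept separate here because
#' the recreation median split is done per window; pooling happens
#' afterwards where needed.
#'
#' @param events Independent recreation events (trail cameras), with
#'   `camera_id`, `event_time`.
#' @param trapdays Output of [compute_trap_days()] restricted to trail
#'   cameras.
#' @param calendar An `effort_calendar`.
#' @return Data frame `camera_id`, `window`, `stratum`, `n_events`,
#'   `n_active_days`, `rai` (`NA` where a camera has no active days in a
#'   window).
#' @export
recreation_rai_per_camera <- function(events, trapdays, calendar) {
  ev_win <- effort_of_date(
    calendar,
    as.Date(format(events$event_time, tz = DIEL_REF_TZ, "%Y-%m-%d")),
    "window"
  )
  counts <- stats::aggregate(
    list(n_events = rep(1L, nrow(events))),
    by = list(camera_id = events$camera_id, window = ev_win), FUN = sum
  )
  out <- merge(trapdays, counts,
    by = c("camera_id", "window"), all.x = TRUE
  )
  out$n_events[is.na(out$n_events)] <- 0L
  suppressWarnings(out$rai <- rai(out$n_events, out$n_active_days))
  if (anyNA(out$rai)) {
    message(
      sum(is.na(out$rai)),
      " camera-window(s) with zero trap days: recreation RAI missing"
    )
  }
  out[order(out$camera_id, out$window), c(
    "camera_id", "window", "stratum",
    "n_events", "n_active_days", "rai"
  )]
}

#' Pooled RAI, trail index and contrasts per species and stratum
#'
#' The full abundance analysis: for one species, pools events and trap
#' days over trail and forest cameras per effort stratum, computes RAI
#' for each placement and the trail index, and bootstraps camera
#' locations (paired) to attach percentile CIs. All strata and
#' placements are computed inside one statistic so every cross-stratum
#' or trail-vs-forest contrast is paired on the same location draws.
#'
#' @param events Independent events of one species, annotated with
#'   `camera_id`, `event_time`.
#' @param trapdays [compute_trap_days()] output for all cameras.
#' @param deployments Deployment table (for placement and pairing).
#' @param calendar An `effort_calendar`.
#' @param B,seed,ci_level Bootstrap settings.
#' @return List of class `abundance_fit` with elements `estimates` (data
#'   frame: stratum, placement RAIs and CIs, trail index and CI),
#'   `differences` (trail-vs-forest per stratum and trail-index stratum
#'   contrasts with CIs and significance), and the underlying
#'   `location_boot` object.
#' @export
abundance_analysis <- function(events, trapdays, deployments, calendar,
                               B = 1000, seed = NULL, ci_level = 0.95) {
  strata <- intersect(c("high", "medium", "low"), unique(calendar$stratum))
  dep <- deployments[, c("camera_id", "location_id", "placement")]
  ev_str <- effort_of_date(
    calendar,
    as.Date(format(events$event_time, tz = DIEL_REF_TZ, "%Y-%m-%d")),
    "stratum"
  )
  ev <- data.frame(camera_id = events$camera_id, stratum = ev_str)
  ev <- merge(ev, dep, by = "camera_id")
  td <- merge(trapdays, dep, by = "camera_id")

  # per location x stratum x placement: events and trap days
  ev_agg <- stats::aggregate(
    list(n_events = rep(1L, nrow(ev))),
    by = ev[, c("location_id", "stratum", "placement")], FUN = sum
  )
  td_agg <- stats::aggregate(list(days = td$n_active_days),
    by = td[, c("location_id", "stratum", "placement")], FUN = sum
  )
  cell <- merge(td_agg, ev_agg,
    by = c("location_id", "stratum", "placement"), all.x = TRUE
  )
  cell$n_events[is.na(cell$n_events)] <- 0L

  # wide per-location table: one row per location
  locs <- sort(unique(dep$location_id))
  wide <- data.frame(location_id = locs)
  for (s in strata) {
    for (p in c("trail", "forest")) {
      sel <- cell$stratum == s & cell$placement == p
      m <- match(locs, cell$location_id[sel])
      wide[[paste("ev", p, s, sep = "_")]] <-
        ifelse(is.na(m), 0, cell$n_events[sel][m])
      wide[[paste("td", p, s, sep = "_")]] <-
        ifelse(is.na(m), 0, cell$days[sel][m])
    }
  }

  stat <- function(df) {
    out <- c()
    for (s in strata) {
      rt <- 100 * sum(df[[paste0("ev_trail_", s)]]) /
        sum(df[[paste0("td_trail_", s)]])
      rf <- 100 * sum(df[[paste0("ev_forest_", s)]]) /
        sum(df[[paste0("td_forest_", s)]])
      out <- c(out, stats::setNames(
        c(rt, rf, trail_index(rt, rf)),
        paste0(c("rai_trail.", "rai_forest.", "trail_index."), s)
      ))
    }
    out
  }
  boot <- bootstrap_locations(wide, stat,
    B = B, seed = seed,
    ci_level = ci_level
  )

  est <- data.frame(
    stratum = strata,
    rai_trail = boot$point[paste0("rai_trail.", strata)],
    rai_trail_lo = boot$ci_low[paste0("rai_trail.", strata)],
    rai_trail_hi = boot$ci_high[paste0("rai_trail.", strata)],
    rai_forest = boot$point[paste0("rai_forest.", strata)],
    rai_forest_lo = boot$ci_low[paste0("rai_forest.", strata)],
    rai_forest_hi = boot$ci_high[paste0("rai_forest.", strata)],
    trail_index = boot$point[paste0("trail_index.", strata)],
    trail_index_lo = boot$ci_low[paste0("trail_index.", strata)],
    trail_index_hi = boot$ci_high[paste0("trail_index.", strata)],
    row.names = NULL
  )

  diffs <- list()
  for (s in strata) {
    diffs[[paste0("rai_forest_vs_trail.", s)]] <- difference_with_ci(
      boot$replicates[, paste0("rai_forest.", s)],
      boot$replicates[, paste0("rai_trail.", s)],
      point_a = boot$point[[paste0("rai_forest.", s)]],
      point_b = boot$point[[paste0("rai_trail.", s)]],
      ci_level = ci_level,
      label = paste0("RAI forest vs trail, ", s, " effort")
    )
  }
  pairs <- utils::combn(strata, 2, simplify = FALSE)
  for (pr in pairs) {
    nm <- paste0("trail_index.", pr[1], "_vs_", pr[2])
    diffs[[nm]] <- difference_with_ci(
      boot$replicates[, paste0("trail_index.", pr[1])],
      boot$replicates[, paste0("trail_index.", pr[2])],
      point_a = boot$point[[paste0("trail_index.", pr[1])]],
      point_b = boot$point[[paste0("trail_index.", pr[2])]],
      ci_level = ci_level,
      label = paste0("trail index, ", pr[1], " vs ", pr[2])
    )
  }
  structure(list(estimates = est, differences = diffs, boot = boot),
    class = "abundance_fit"
  )
}
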