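# Synthetic camera-trap study generator: paired trail/forest deployments,
# a seasonal hunting calendar, diurnal recreation streams with trigger
# bursts, and species detection streams whose circadian density follows a
# known day/night ground-truth model, so every downstream stage runs and
# parameter recovery is checkable without field data.

#' Simulation configuration
#'
#' Defaults describe the emulated study: 61 paired trail/forest locations
#' monitored for about 13 months across a mid-European mountain park,
#' monthly hunting weights that produce low (<5\%), medium (5\%-10\%) and
#' high (>10\%) effort strata, diurnal recreation concentrated on trails,
#' and five species with distinct circadian mixtures and nocturnality
#' coefficients.
#'
#' @param n_location_pairs Number of paired trail/forest locations.
#' @param study_start,study_end Study window dates.
#' @param latitude_band,longitude_band Ranges deployments are scattered
#'   over (degrees).
#' @param frac_in_hunting_zone Proportion of locations inside the hunting
#'   zone (distance 0 m).
#' @param max_distance_to_zone_m Maximum distance to the hunting-zone
#'   border for outside locations.
#' @param monthly_hunt_weights 12 non-negative weights (Jan..Dec) shaping
#'   the hunting calendar.
#' @param total_hunt_events Total successful hunting events distributed
#'   over the calendar.
#' @param species_params Named list of [circadian_truth()] objects.
#' @param recreation_mean_rate Mean recreation events per trail camera
#'   per day (per-camera rates are lognormal around this).
#' @param recreation_burst_prob Probability a recreation event is a burst
#'   of extra triggers within seconds (exercises the 8 s filter).
#' @param outage_prob_per_day Daily probability a camera is out
#'   (independent Bernoulli; runs become exclusion intervals).
#' @param seed Integer seed: identical config + seed gives identical
#'   output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_location_pairs = 61,
                       study_start = as.Date("2020-11-15"),
                       study_end = as.Date("2021-12-05"),
                       latitude_band = c(48.9, 49.1),
                       longitude_band = c(13.2, 13.6),
                       frac_in_hunting_zone = 0.3,
                       max_distance_to_zone_m = 3933,
                       monthly_hunt_weights = c(
                         15, 3, 3, 3, 3, 7, 7, 7, 7, 15, 15, 15
                       ),
                       total_hunt_events = 500,
                       species_params = default_species_params(),
                       recreation_mean_rate = 8,
                       recreation_burst_prob = 0.3,
                       outage_prob_per_day = 0.02,
                       seed = 1L) {
  stopifnot(
    n_location_pairs >= 2,
    length(monthly_hunt_weights) == 12,
    all(monthly_hunt_weights >= 0),
    sum(monthly_hunt_weights) > 0,
    frac_in_hunting_zone >= 0, frac_in_hunting_zone <= 1,
    recreation_mean_rate >= 0, outage_prob_per_day >= 0,
    outage_prob_per_day < 1
  )
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  n_months <- length(unique(format(
    seq(study_start, study_end, by = "day"),
    "%Y-%m"
  )))
  if (n_months < 3) stop("study interval must span at least 3 months")
  structure(
    list(
      n_location_pairs = as.integer(n_location_pairs),
      study_start = study_start, study_end = study_end,
      latitude_band = latitude_band, longitude_band = longitude_band,
      frac_in_hunting_zone = frac_in_hunting_zone,
      max_distance_to_zone_m = max_distance_to_zone_m,
      monthly_hunt_weights = monthly_hunt_weights,
      total_hunt_events = total_hunt_events,
      species_params = species_params,
      recreation_mean_rate = recreation_mean_rate,
      recreation_burst_prob = recreation_burst_prob,
      outage_prob_per_day = outage_prob_per_day,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Circadian ground truth for one species
#'
#' A von Mises mixture over clock time (radians, `2*pi` = 24 h) plus
#' Poisson event rates per camera-day and a nocturnality linear predictor
#' on named design-matrix columns (see [build_design()] naming:
#' `(Intercept)`, `effortmedium`, `effortlow`, `placementforest`,
#' `dist_hunting_zone_m_s`, `recreation_rai_s`, `visibility_s` and their
#' interactions). The simulated night share at a camera is the
#' inverse-logit of this predictor, so the beta-binomial model is
#' correctly specified under the generator.
#'
#' @param mixture_weights Simplex weights.
#' @param mixture_means Clock-radian means in `[0, 2*pi)`.
#' @param mixture_kappas Concentrations (>= 0).
#' @param base_rate_trail,base_rate_forest Expected events per camera-day.
#' @param nocturnality_coefs Named numeric vector on design columns;
#'   unnamed columns default to 0.
#' @return List of class `circadian_truth`.
#' @export
circadian_truth <- function(mixture_weights = c(0.5, 0.5),
                            mixture_means = c(5, 19) * 2 * pi / 24,
                            mixture_kappas = c(2, 2),
                            base_rate_trail = 0.05,
                            base_rate_forest = 0.05,
                            nocturnality_coefs = c("(Intercept)" = 0)) {
  stopifnot(
    length(mixture_weights) == length(mixture_means),
    length(mixture_means) == length(mixture_kappas),
    all(mixture_weights >= 0), sum(mixture_weights) > 0,
    all(mixture_kappas >= 0),
    base_rate_trail >= 0, base_rate_forest >= 0
  )
  structure(
    list(
      mixture_weights = mixture_weights / sum(mixture_weights),
      mixture_means = mixture_means %% (2 * pi),
      mixture_kappas = mixture_kappas,
      base_rate_trail = base_rate_trail,
      base_rate_forest = base_rate_forest,
      nocturnality_coefs = nocturnality_coefs
    ),
    class = "circadian_truth"
  )
}

#' Default species parameters
#'
#' Five emulated species spanning the guilds of a central-European
#' montane mammal community: a crepuscular hunted deer responsive to
#' effort and distance, a nocturnal hunted suid, a diurnal-leaning
#' unhunted deer, and two trail-favouring carnivores (one strongly
#' nocturnal). Base rates are on the order of a few events per 100
#' camera-days, matching typical trail-camera RAIs.
#'
#' @return Named list of [circadian_truth()] objects.
#' @export
default_species_params <- function() {
  h <- function(x) x * 2 * pi / 24
  list(
    red_deer = circadian_truth(
      mixture_weights = c(0.45, 0.45, 0.10),
      mixture_means = h(c(5, 19, 12)), mixture_kappas = c(2.5, 2.5, 0.5),
      base_rate_trail = 0.065, base_rate_forest = 0.068,
      nocturnality_coefs = c(
        "(Intercept)" = 0.6, effortmedium = -0.5, effortlow = -1.0,
        placementforest = -0.5, dist_hunting_zone_m_s = -0.4,
        recreation_rai_s = 0.25, visibility_s = 0.1
      )
    ),
    wild_boar = circadian_truth(
      mixture_weights = c(0.8, 0.2),
      mixture_means = h(c(1, 22)), mixture_kappas = c(1.5, 2),
      base_rate_trail = 0.018, base_rate_forest = 0.05,
      nocturnality_coefs = c(
        "(Intercept)" = 1.6, effortmedium = -0.5,
        placementforest = -0.3
      )
    ),
    roe_deer = circadian_truth(
      mixture_weights = c(0.4, 0.4, 0.2),
      mixture_means = h(c(7, 17, 12)), mixture_kappas = c(2, 2, 0.8),
      base_rate_trail = 0.027, base_rate_forest = 0.055,
      nocturnality_coefs = c(
        "(Intercept)" = -0.3, effortmedium = -0.6, effortlow = -0.7,
        recreation_rai_s = 0.2
      )
    ),
    red_fox = circadian_truth(
      mixture_weights = c(0.7, 0.3),
      mixture_means = h(c(0, 20)), mixture_kappas = c(1.2, 1.5),
      base_rate_trail = 0.045, base_rate_forest = 0.007,
      nocturnality_coefs = c(
        "(Intercept)" = 1.2, effortmedium = -0.5, effortlow = -0.6,
        placementforest = -0.7, recreation_rai_s = 0.2
      )
    ),
    lynx = circadian_truth(
      mixture_weights = c(0.6, 0.4),
      mixture_means = h(c(23, 4)), mixture_kappas = c(1.5, 1.5),
      base_rate_trail = 0.013, base_rate_forest = 0.0015,
      nocturnality_coefs = c("(Intercept)" = 1.5)
    )
  )
}

# Collapse Bernoulli outage days into "a/b;c/d" exclusion interval spec.
.days_to_spec <- function(days) {
  if (length(days) == 0) {
    return("")
  }
  days <- sort(days)
  brk <- c(0, which(diff(days) > 1), length(days))
  parts <- vapply(seq_len(length(brk) - 1), function(i) {
    a <- days[brk[i] + 1]
    b <- days[brk[i + 1]]
    paste(format(a), format(b), sep = "/")
  }, character(1))
  paste(parts, collapse = ";")
}

#' Generate the deployment table
#'
#' One trail and one forest camera per location. Locations inside the
#' hunting zone have distance 0 m to its border; outside locations draw
#' a truncated-exponential distance (mean 1000 m, capped at the
#' configured maximum), giving the right-skewed distance distribution of
#' a border-hugging hunting zone. Visibility covariates are uniform
#' within realistic understorey ranges; a latent per-camera recreation
#' rate (lognormal around the configured mean, trail only; the pair
#' value is shared) drives the recreation generator and the ground-truth
#' nocturnality predictor. Independent daily Bernoulli outages become
#' exclusion intervals.
#'
#' @param config A [sim_config()].
#' @return Data frame, 2 rows per location: `camera_id`, `location_id`,
#'   `placement`, `lat`, `lon`, `in_hunting_zone`,
#'   `dist_hunting_zone_m`, `vis50`, `vis70`, `vis140`,
#'   `recreation_rate`, `start`, `end`, `exclusions`.
#' @export
generate_deployments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_location_pairs
  loc_id <- sprintf("L%03d", seq_len(n))
  in_zone <- stats::runif(n) < config$frac_in_hunting_zone
  dist <- ifelse(in_zone, 0, pmin(
    stats::rexp(n, 1 / 1000) + 1,
    config$max_distance_to_zone_m
  ))
  lat <- stats::runif(n, config$latitude_band[1], config$latitude_band[2])
  lon <- stats::runif(n, config$longitude_band[1], config$longitude_band[2])
  rec_rate <- stats::rlnorm(
    n, log(max(config$recreation_mean_rate, 1e-12)) - 0.5, 1
  )
  if (config$recreation_mean_rate == 0) rec_rate <- rep(0, n)
  all_days <- seq(config$study_start, config$study_end, by = "day")
  rows <- list()
  for (p in c("trail", "forest")) {
    for (i in seq_len(n)) {
      out_days <- all_days[
        stats::runif(length(all_days)) < config$outage_prob_per_day
      ]
      rows[[paste(p, i)]] <- data.frame(
        camera_id = paste0(loc_id[i], if (p == "trail") "T" else "F"),
        location_id = loc_id[i], placement = p,
        lat = lat[i], lon = lon[i],
        in_hunting_zone = in_zone[i], dist_hunting_zone_m = dist[i],
        vis50 = stats::runif(1, 0.38, 0.65),
        vis70 = stats::runif(1, 0.67, 0.96),
        vis140 = stats::runif(1, 0.71, 0.97),
        recreation_rate = rec_rate[i],
        start = config$study_start, end = config$study_end,
        exclusions = .days_to_spec(out_days),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$location_id, out$placement, decreasing = FALSE), ]
  rownames(out) <- NULL
  out
}

#' Generate the monthly hunting calendar
#'
#' Deterministically allocates the configured total of successful
#' hunting events over the study months proportionally to each month's
#' weight (by month of year), then classifies effort strata with
#' [classify_effort()]. The default weights make Feb-May fall below 5\%,
#' Jun-Sep within 5\%-10\% and Oct-Jan above 10\% of all events.
#'
#' @param config A [sim_config()].
#' @return An `effort_calendar` (see [classify_effort()]).
#' @export
generate_hunting_calendar <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  months <- unique(format(
    seq(config$study_start, config$study_end, by = "day"), "%Y-%m"
  ))
  moy <- as.integer(substr(months, 6, 7))
  w <- config$monthly_hunt_weights[moy]
  counts <- round(config$total_hunt_events * w / sum(w))
  classify_effort(data.frame(month = months, count = counts))
}

# Active (non-excluded) days of one deployment row.
.active_days <- function(dep_row) {
  days <- seq(as.Date(dep_row$start), as.Date(dep_row$end), by = "day")
  excl <- .expand_exclusions(dep_row$exclusions)
  days[!days %in% excl]
}

# Sample one clock time (radians) from the truth mixture.
.sample_mixture <- function(truth) {
  k <- sample.int(length(truth$mixture_weights), 1,
    prob = truth$mixture_weights
  )
  kappa <- truth$mixture_kappas[k]
  mu <- truth$mixture_means[k]
  if (kappa < 1e-8) {
    return(stats::runif(1, 0, 2 * pi))
  }
  # Best-Fisher von Mises sampler
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      return((mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi))
    }
  }
}

# Night interval (clock hours) of a date at the reference location.
.night_hours <- function(date, tz = DIEL_REF_TZ) {
  st <- .sun_times_cached(DIEL_REF_LAT, DIEL_REF_LON, date, tz)
  hr <- function(t) {
    lt <- as.POSIXlt(t, tz = tz)
    lt$hour + lt$min / 60 + lt$sec / 3600
  }
  c(dawn_end = hr(st$nautical_dawn_end), dusk_start = hr(st$nautical_dusk_start))
}

# Draw a clock hour from the mixture restricted to night or day.
.sample_hour_conditional <- function(truth, night, bounds, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    h <- .sample_mixture(truth) * 24 / (2 * pi)
    is_n <- h < bounds["dawn_end"] | h >= bounds["dusk_start"]
    if (is_n == night) {
      return(h)
    }
  }
  # mixture mass in the segment is negligible: fall back to uniform
  if (night) {
    span <- bounds["dawn_end"] + 24 - bounds["dusk_start"]
    (bounds["dusk_start"] + stats::runif(1, 0, span)) %% 24
  } else {
    stats::runif(1, bounds["dawn_end"], bounds["dusk_start"])
  }
}

# Linear predictor of the truth's nocturnality coefficients for one
# camera x effort cell, given pre-scaled covariates.
.truth_lp <- function(coefs, effort, placement, dist_s, rec_s, vis_s) {
  vals <- c(
    "(Intercept)" = 1,
    effortmedium = as.numeric(effort == "medium"),
    effortlow = as.numeric(effort == "low"),
    placementforest = as.numeric(placement == "forest"),
    dist_hunting_zone_m_s = dist_s,
    recreation_rai_s = rec_s,
    visibility_s = vis_s
  )
  # interactions: products of any named components joined by ":"
  lp <- 0
  for (nm in names(coefs)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% names(vals))) {
      stop("unknown term in nocturnality_coefs: ", nm)
    }
    lp <- lp + coefs[[nm]] * prod(vals[parts])
  }
  lp
}

#' True night-share per camera and effort stratum
#'
#' The inverse-logit of the ground-truth linear predictor, evaluated for
#' every camera x stratum cell — the quantity the beta-binomial model
#' estimates, exposed for parameter-recovery checks.
#'
#' @param deployments Deployment table from [generate_deployments()].
#' @param truth A [circadian_truth()].
#' @param strata Stratum labels to evaluate.
#' @return Data frame `camera_id`, `effort`, `p_night`.
#' @export
true_night_share <- function(deployments, truth,
                             strata = c("high", "medium", "low")) {
  z <- function(x) as.numeric(scale(x))
  dep <- deployments
  dep$dist_s <- z(dep$dist_hunting_zone_m)
  dep$rec_s <- z(100 * dep$recreation_rate)
  dep$vis_s <- z(dep$vis140)
  out <- list()
  for (s in strata) {
    p <- vapply(seq_len(nrow(dep)), function(i) {
      stats::plogis(.truth_lp(
        truth$nocturnality_coefs, s, dep$placement[i],
        dep$dist_s[i], dep$rec_s[i], dep$vis_s[i]
      ))
    }, numeric(1))
    out[[s]] <- data.frame(
      camera_id = dep$camera_id, effort = s,
      p_night = p, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate one species' detection stream
#'
#' Per camera active day, the event count is Poisson with the placement's
#' base rate; each event is night with probability given by the
#' ground-truth nocturnality predictor for that camera x effort cell,
#' and its clock time is drawn from the circadian mixture restricted to
#' the night or day segment of that date (nautical twilight at the
#' study-area reference). Timestamps land only on active days. Each
#' event emits 1-3 trigger rows within a few seconds, mimicking a
#' multi-shot camera; the 5-min filter collapses them back to one event.
#'
#' @param deployments Deployment table.
#' @param truth A [circadian_truth()].
#' @param calendar An `effort_calendar`.
#' @param seed Integer seed.
#' @param class_label Label written into the detection rows.
#' @param tz Civil timezone of the emitted timestamps.
#' @return Detection data frame: `camera_id`, `timestamp`, `class_label`.
#' @export
simulate_species_events <- function(deployments, truth, calendar, seed,
                                    class_label = "species",
                                    tz = DIEL_REF_TZ) {
  stopifnot(inherits(truth, "circadian_truth"))
  set.seed(seed)
  pnight <- true_night_share(deployments, truth)
  key <- paste(pnight$camera_id, pnight$effort)
  out <- list()
  for (i in seq_len(nrow(deployments))) {
    dep <- deployments[i, ]
    rate <- if (dep$placement == "trail") {
      truth$base_rate_trail
    } else {
      truth$base_rate_forest
    }
    if (rate == 0) next
    days <- .active_days(dep)
    if (length(days) == 0) next
    n_ev <- stats::rpois(length(days), rate)
    ev_days <- rep(days, n_ev)
    if (length(ev_days) == 0) next
    strata <- effort_of_date(calendar, ev_days, "stratum")
    p <- pnight$p_night[match(paste(dep$camera_id, strata), key)]
    p[is.na(p)] <- 0.5 # events outside the calendar (should not occur)
    ts <- numeric(length(ev_days))
    for (j in seq_along(ev_days)) {
      bounds <- .night_hours(ev_days[j], tz)
      night <- stats::runif(1) < p[j]
      h <- .sample_hour_conditional(truth, night, bounds)
      ts[j] <- as.numeric(as.POSIXct(paste(ev_days[j], "00:00:00"),
        tz = tz
      )) + h * 3600
    }
    n_trig <- sample(1:3, length(ts), replace = TRUE)
    trig_ts <- unlist(lapply(seq_along(ts), function(j) {
      ts[j] + c(0, cumsum(stats::runif(n_trig[j] - 1, 0.5, 2)))
    }))
    out[[dep$camera_id]] <- data.frame(
      camera_id = dep$camera_id,
      timestamp = as.POSIXct(trig_ts, origin = "1970-01-01", tz = tz),
      class_label = class_label, stringsAsFactors = FALSE
    )
  }
  res <- if (length(out) > 0) {
    do.call(rbind, out)
  } else {
    data.frame(
      camera_id = character(),
      timestamp = .POSIXct(numeric(0), tz = tz),
      class_label = character()
    )
  }
  res <- res[order(res$camera_id, res$timestamp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate the recreation detection stream
#'
#' Trail cameras only. Daily event counts are Poisson with the camera's
#' latent recreation rate; clock times follow a unimodal midday peak
#' (normal around 13:00, SD 2.5 h, wrapped into daylight hours). A
#' configurable fraction of events are bursts: several triggers a few
#' seconds apart, as successive groups pass — deliberately exercising
#' the 8-second independence rule.
#'
#' @param deployments Deployment table.
#' @param seed Integer seed.
#' @param rates Optional per-camera rates overriding
#'   `deployments$recreation_rate`.
#' @param burst_prob Probability an event is a multi-trigger burst.
#' @param class_label Label for the rows.
#' @param tz Civil timezone of the emitted timestamps.
#' @return Detection data frame: `camera_id`, `timestamp`, `class_label`.
#' @export
simulate_recreation_events <- function(deployments, seed, rates = NULL,
                                       burst_prob = 0.3,
                                       class_label = "human",
                                       tz = DIEL_REF_TZ) {
  set.seed(seed)
  trail <- deployments[deployments$placement == "trail", , drop = FALSE]
  if (is.null(rates)) rates <- trail$recreation_rate
  stopifnot(all(rates >= 0), length(rates) == nrow(trail))
  out <- list()
  for (i in seq_len(nrow(trail))) {
    dep <- trail[i, ]
    if (rates[i] == 0) next
    days <- .active_days(dep)
    n_ev <- stats::rpois(length(days), rates[i])
    ev_days <- rep(days, n_ev)
    if (length(ev_days) == 0) next
    h <- stats::rnorm(length(ev_days), 13, 2.5) %% 24
    ts <- as.numeric(as.POSIXct(paste(ev_days, "00:00:00"), tz = tz)) +
      h * 3600
    burst <- stats::runif(length(ts)) < burst_prob
    extra <- lapply(which(burst), function(j) {
      k <- 1 + stats::rpois(1, 1.5)
      ts[j] + cumsum(stats::runif(k, 1, 6))
    })
    all_ts <- c(ts, unlist(extra))
    out[[dep$camera_id]] <- data.frame(
      camera_id = dep$camera_id,
      timestamp = as.POSIXct(all_ts, origin = "1970-01-01", tz = tz),
      class_label = class_label, stringsAsFactors = FALSE
    )
  }
  res <- if (length(out) > 0) {
    do.call(rbind, out)
  } else {
    data.frame(
      camera_id = character(),
      timestamp = .POSIXct(numeric(0), tz = tz),
      class_label = character()
    )
  }
  res <- res[order(res$camera_id, res$timestamp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a full synthetic study to disk
#'
#' Emits the three delimited inputs the pipeline reads — detections
#' (species + recreation), deployments, hunting calendar — into a
#' directory, with the seed recorded in header comments.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths.
#' @export
write_synthetic_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dep <- generate_deployments(config)
  cal <- generate_hunting_calendar(config)
  streams <- list(simulate_recreation_events(
    dep,
    seed = config$seed + 1000L,
    burst_prob = config$recreation_burst_prob
  ))
  sp <- names(config$species_params)
  for (k in seq_along(sp)) {
    streams[[k + 1]] <- simulate_species_events(
      dep, config$species_params[[sp[k]]], cal,
      seed = config$seed + 2000L + k, class_label = sp[k]
    )
  }
  det <- do.call(rbind, streams)
  det <- det[order(det$camera_id, det$class_label, det$timestamp), ]
  paths <- list(
    detections = file.path(dir, "detections.csv"),
    deployments = file.path(dir, "deployments.csv"),
    hunting = file.path(dir, "hunting_calendar.csv")
  )
  write_detections(det, paths$detections,
    comments = paste("seed:", config$seed)
  )
  dep_out <- dep
  dep_out$start <- format(dep_out$start)
  dep_out$end <- format(dep_out$end)
  con <- file(paths$deployments, "w")
  writeLines(paste("# seed:", config$seed), con)
  utils::write.csv(dep_out, con, row.names = FALSE)
  close(con)
  con <- file(paths$hunting, "w")
  writeLines(paste("# seed:", config$seed), con)
  utils::write.csv(
    data.frame(month = format(cal$month, "%Y-%m"), count = cal$count),
    con,
    row.names = FALSE
  )
  close(con)
  invisible(paths)
}

#' Read a deployment table written by [write_synthetic_study()]
#'
#' @param path Path to the deployments CSV.
#' @return Deployment data frame with parsed dates.
#' @export
read_deployments <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c(
    "camera_id", "location_id", "placement", "lat", "lon",
    "in_hunting_zone", "dist_hunting_zone_m", "start", "end"
  )
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop("deployment file missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  d$start <- as.Date(d$start)
  d$end <- as.Date(d$end)
  d$in_hunting_zone <- as.logical(d$in_hunting_zone)
  if (!"exclusions" %in% names(d)) d$exclusions <- ""
  d$exclusions[is.na(d$exclusions)] <- ""
  d
}

#' Read a monthly hunting calendar file
#'
#' @param path CSV with columns `month` (`YYYY-MM`) and `count`.
#' @return An `effort_calendar`.
#' @export
read_hunting_calendar <- function(path) {
  classify_effort(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  )
}
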