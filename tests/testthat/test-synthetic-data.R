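test_that("deployments are paired, bounded and deterministic", {
  cfg <- sim_config(seed = 3) # full 61-pair study design
  dep <- generate_deployments(cfg)
  expect_equal(nrow(dep), 122)
  expect_equal(sum(dep$placement == "trail"), 61)
  expect_equal(sum(dep$placement == "forest"), 61)
  # each location has exactly one camera of each placement
  tab <- table(dep$location_id, dep$placement)
  expect_true(all(tab == 1))
  # zone cameras sit at distance zero; others within the cap
  expect_true(all(dep$dist_hunting_zone_m[dep$in_hunting_zone] == 0))
  out <- dep[!dep$in_hunting_zone, ]
  expect_true(all(out$dist_hunting_zone_m > 0 &
    out$dist_hunting_zone_m <= cfg$max_distance_to_zone_m))
  # visibility covariates within their understorey ranges
  expect_true(all(dep$vis50 >= 0.38 & dep$vis50 <= 0.65))
  expect_true(all(dep$vis140 >= 0.71 & dep$vis140 <= 0.97))
  # determinism under the seed
  expect_identical(dep, generate_deployments(sim_config(seed = 3)))
  # zone fraction 1 forces all distances to zero
  dep1 <- generate_deployments(sim_config(
    n_location_pairs = 10,
    frac_in_hunting_zone = 1, seed = 1
  ))
  expect_true(all(dep1$dist_hunting_zone_m == 0))
  expect_error(sim_config(n_location_pairs = 1), "n_location_pairs")
})

test_that("default hunting weights reproduce the seasonal effort strata", {
  cal <- generate_hunting_calendar(sim_config(seed = 1))
  moy <- as.integer(format(cal$month, "%m"))
  expect_true(all(cal$stratum[moy %in% c(10, 11, 12, 1)] == "high"))
  expect_true(all(cal$stratum[moy %in% 2:5] == "low"))
  expect_true(all(cal$stratum[moy %in% 6:9] == "medium"))
  # uniform weights: every month lands in the medium band
  cal_u <- generate_hunting_calendar(
    sim_config(monthly_hunt_weights = rep(1, 12), seed = 1)
  )
  expect_true(all(cal_u$stratum == "medium"))
})

test_that("species streams respect rates, calendars and active days", {
  cfg <- small_config()
  dep <- fix$dep
  cal <- fix$cal
  truth0 <- circadian_truth(base_rate_trail = 0, base_rate_forest = 0)
  expect_equal(
    nrow(simulate_species_events(dep, truth0, cal, seed = 1)), 0
  )
  det <- simulate_species_events(dep, cfg$species_params$red_deer, cal,
    seed = 8, class_label = "red_deer"
  )
  expect_identical(
    det,
    simulate_species_events(dep, cfg$species_params$red_deer, cal,
      seed = 8, class_label = "red_deer"
    )
  )
  # no timestamp on an excluded day
  for (cam in unique(det$camera_id)) {
    dep_row <- dep[dep$camera_id == cam, ]
    excl <- dielshift:::.expand_exclusions(dep_row$exclusions)
    days <- as.Date(format(det$timestamp[det$camera_id == cam],
      tz = "Etc/GMT-1", "%Y-%m-%d"
    ))
    expect_false(any(days %in% excl))
    expect_true(all(days >= dep_row$start & days <= dep_row$end))
  }
})

test_that("simulated night shares track the ground-truth inverse-logit", {
  # flat truth: intercept 0 gives a 0.5 night share
  dep <- fix$dep
  cal <- fix$cal
  flat <- circadian_truth(
    mixture_weights = 1, mixture_means = 0, mixture_kappas = 0,
    base_rate_trail = 2, base_rate_forest = 2,
    nocturnality_coefs = c("(Intercept)" = 0)
  )
  det <- simulate_species_events(dep, flat, cal, seed = 12)
  night <- is_night(det$timestamp)
  n <- length(night)
  expect_gt(n, 1e4)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(night) - 0.5), 3 * se)

  # strong positive high-effort contrast: high-stratum night share
  # exceeds the low stratum
  shifted <- circadian_truth(
    mixture_weights = 1, mixture_means = 0, mixture_kappas = 0,
    base_rate_trail = 2, base_rate_forest = 2,
    nocturnality_coefs = c("(Intercept)" = 1.2, effortlow = -2.4)
  )
  det2 <- simulate_species_events(dep, shifted, cal, seed = 13)
  night2 <- is_night(det2$timestamp)
  stratum <- effort_of_date(
    cal, as.Date(format(det2$timestamp, tz = "Etc/GMT-1", "%Y-%m-%d")),
    "stratum"
  )
  p_high <- mean(night2[stratum == "high"])
  p_low <- mean(night2[stratum == "low"])
  expect_gt(p_high, p_low)
  expect_equal(p_high, plogis(1.2),
    tolerance = 3 * sqrt(0.25 / sum(stratum == "high")) + 0.02
  )
  expect_equal(p_low, plogis(-1.2),
    tolerance = 3 * sqrt(0.25 / sum(stratum == "low")) + 0.02
  )
})

test_that("recreation streams are diurnal, trail-only and exercise bursts", {
  dep <- fix$dep
  rec <- simulate_recreation_events(dep, seed = 6)
  trail_ids <- dep$camera_id[dep$placement == "trail"]
  expect_true(all(rec$camera_id %in% trail_ids))
  hours <- as.integer(format(rec$timestamp, tz = "Etc/GMT-1", "%H"))
  expect_gt(mean(hours >= 8 & hours <= 18), 0.9)
  # bursts create sub-8-second gaps that the filter collapses
  ev <- filter_independent(rec, 8)
  expect_lt(nrow(ev), nrow(rec))
  # zero rates give an empty stream
  expect_equal(nrow(simulate_recreation_events(dep,
    seed = 6,
    rates = rep(0, sum(dep$placement == "trail"))
  )), 0)
})

test_that("doubling recreation rates doubles expected event counts", {
  dep <- generate_deployments(sim_config(
    n_location_pairs = 3, seed = 2,
    study_start = "2021-06-01", study_end = "2021-08-31"
  ))
  base_rates <- rep(2, 3)
  n1 <- n2 <- numeric(100)
  for (r in 1:100) {
    n1[r] <- nrow(simulate_recreation_events(dep,
      seed = r, rates = base_rates, burst_prob = 0
    ))
    n2[r] <- nrow(simulate_recreation_events(dep,
      seed = 1000 + r, rates = 2 * base_rates, burst_prob = 0
    ))
  }
  ratio <- mean(n2) / mean(n1)
  # Poisson scaling: ratio 2 within sampling error
  se <- ratio * sqrt(var(n1) / (100 * mean(n1)^2) +
    var(n2) / (100 * mean(n2)^2))
  expect_lt(abs(ratio - 2), 4 * se + 0.05)
})

test_that("a written study round-trips through the readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(
    n_location_pairs = 3, seed = 5,
    species_params = default_species_params()["lynx"],
    recreation_mean_rate = 1, study_start = "2021-01-01",
    study_end = "2021-06-30"
  )
  paths <- write_synthetic_study(cfg, dir)
  det <- read_detections(paths$detections)
  dep <- read_deployments(paths$deployments)
  cal <- read_hunting_calendar(paths$hunting)
  expect_equal(nrow(dep), 6)
  expect_s3_class(cal, "effort_calendar")
  expect_true(all(det$class_label %in% c("human", "lynx")))
  expect_equal(nrow(attr(det, "rejected")), 0)
})
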