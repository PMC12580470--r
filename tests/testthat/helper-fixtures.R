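# Shared fixtures: one small synthetic study reused across test files.

small_config <- function(seed = 42, ...) {
  sim_config(
    n_location_pairs = 8, seed = seed,
    species_params = default_species_params()[c("red_deer", "red_fox")],
    recreation_mean_rate = 3, ...
  )
}

# Built once per test run; deterministic under the fixed seed.
fix <- local({
  cfg <- small_config()
  dep <- generate_deployments(cfg)
  cal <- generate_hunting_calendar(cfg)
  list(cfg = cfg, dep = dep, cal = cal)
})

# Independence-filter oracle: plain per-stream scan over sorted times.
brute_force_filter <- function(records, threshold) {
  out <- list()
  for (cam in unique(records$camera_id)) {
    for (cl in unique(records$class_label)) {
      r <- records[records$camera_id == cam & records$class_label == cl, ]
      if (nrow(r) == 0) next
      ts <- sort(as.numeric(r$timestamp))
      prev <- -Inf
      for (t in ts) {
        if (t - prev >= threshold) {
          out[[length(out) + 1]] <- data.frame(
            camera_id = cam, class_label = cl, event_time = t
          )
        }
        prev <- t
      }
    }
  }
  ev <- do.call(rbind, out)
  ev[order(ev$camera_id, ev$class_label, ev$event_time), , drop = FALSE]
}

# Random trigger stream over a handful of cameras and classes.
random_stream <- function(n, seed) {
  set.seed(seed)
  origin <- as.POSIXct("2021-05-01 00:00:00", tz = "Etc/GMT-1")
  data.frame(
    camera_id = sample(c("A", "B", "C"), n, replace = TRUE),
    timestamp = origin + stats::runif(n, 0, 3600),
    class_label = sample(c("red_deer", "human"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Simulated beta-binomial dataset on the effort x placement x covariate
# design (used for recovery and cross-check tests).
simulate_bb <- function(n, beta, phi, seed) {
  set.seed(seed)
  rows <- data.frame(
    effort = sample(c("high", "medium", "low"), n, replace = TRUE),
    placement = sample(c("trail", "forest"), n, replace = TRUE),
    dist_hunting_zone_m = rnorm(n)
  )
  des <- build_design(rows, covariates = "dist_hunting_zone_m")
  stopifnot(ncol(des$X) == length(beta))
  mu <- plogis(drop(des$X %*% beta))
  tot <- rpois(n, 50) + 1
  p <- rbeta(n, mu * phi, (1 - mu) * phi)
  list(des = des, n_night = rbinom(n, tot, p), n_total = tot)
}

# Exact von Mises density (for KDE oracles).
dvonmises <- function(theta, mu, kappa) {
  exp(kappa * cos(theta - mu) - kappa) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}
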