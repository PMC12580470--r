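test_that("day/night aggregation matches a per-event altitude oracle", {
  cfg <- fix$cfg
  dep <- fix$dep
  cal <- fix$cal
  det <- simulate_species_events(dep, cfg$species_params$red_deer, cal,
    seed = 31, class_label = "red_deer"
  )
  ev <- filter_independent(det, 300)
  td <- suppressWarnings(compute_trap_days(dep, cal))
  rec_ev <- filter_independent(simulate_recreation_events(dep, seed = 32), 8)
  rr <- recreation_rai_per_camera(
    rec_ev, td[td$camera_id %in% dep$camera_id[dep$placement == "trail"], ],
    cal
  )
  rows <- aggregate_day_night(ev, dep, cal, rr, visibility_layer = "vis140")
  expect_true(all(rows$n_night + rows$n_day >= 1))
  expect_true(all(rows$dist_hunting_zone_m[dep$in_hunting_zone[
    match(rows$camera_id, dep$camera_id)
  ]] == 0))
  # oracle: classify every event by the sign of (altitude + 12)
  alt <- sun_altitude(49, 13.4, ev$event_time)
  clear <- abs(alt + 12) > 0.05
  oracle_night <- alt < -12
  ev_str <- effort_of_date(
    cal, as.Date(format(ev$event_time, tz = "Etc/GMT-1", "%Y-%m-%d")),
    "stratum"
  )
  agg <- aggregate(
    list(n = oracle_night[clear]),
    by = list(camera_id = ev$camera_id[clear], effort = ev_str[clear]),
    FUN = sum
  )
  m <- merge(rows, agg, by = c("camera_id", "effort"))
  # altitude oracle and twilight-interval classification agree closely
  expect_true(all(abs(m$n_night - m$n) <= pmax(1, 0.02 * (m$n_night + m$n_day))))
})

test_that("design expansion enumerates the factorial interaction columns", {
  rows <- expand.grid(
    effort = c("high", "low"), placement = c("trail", "forest"),
    x = c(-1, 0, 1, 2)
  )
  names(rows)[3] <- "dist_hunting_zone_m"
  des <- build_design(rows, covariates = "dist_hunting_zone_m")
  # intercept, effort, placement, x, effort:placement, effort:x,
  # placement:x, effort:placement:x
  expect_equal(ncol(des$X), 8)
  xs <- des$X[, "dist_hunting_zone_m_s"]
  expect_equal(mean(xs), 0, tolerance = 1e-10)
  expect_equal(sd(xs), 1, tolerance = 1e-10)
  # reference levels: high effort and trail placement absorb the intercept
  expect_false(any(grepl("efforthigh|placementtrail", colnames(des$X))))
  # a quadratic transform adds one more scaled term to the expansion
  des2 <- build_design(rows,
    covariates = "dist_hunting_zone_m",
    transforms = list(dist_hunting_zone_m = "quadratic")
  )
  expect_equal(ncol(des2$X), 12)
  # stored scaling constants allow exact back-transformation
  sc <- des$scaling["dist_hunting_zone_m_s", ]
  expect_equal(
    xs * sc["sd"] + sc["center"],
    rows$dist_hunting_zone_m,
    ignore_attr = TRUE
  )
})

test_that("beta-binomial likelihood reduces to known special cases", {
  X <- matrix(1, 1, 1)
  # Bernoulli reduction: n_total = 1, mu = 0.5, any phi
  for (phi in c(0.5, 2, 50)) {
    expect_equal(betabinom_loglik(0, phi, X, 1, 1), log(0.5))
    expect_equal(betabinom_loglik(0, phi, X, 0, 1), log(0.5))
  }
  # large-phi limit approaches the binomial likelihood
  set.seed(2)
  n <- 8
  Xn <- cbind(1, rnorm(n))
  beta <- c(0.3, -0.8)
  tot <- rpois(n, 30) + 1
  k <- rbinom(n, tot, plogis(Xn %*% beta))
  ll_bb <- betabinom_loglik(beta, 1e6, Xn, k, tot)
  ll_bin <- sum(dbinom(k, tot, plogis(Xn %*% beta), log = TRUE))
  expect_equal(ll_bb, ll_bin, tolerance = 1e-4)
})

test_that("beta-binomial likelihood matches brute-force pmf integration", {
  # oracle: P(k | n, a, b) = C(n,k) * Int theta^k (1-theta)^(n-k) dBeta
  pmf_oracle <- function(k, n, a, b) {
    choose(n, k) * integrate(
      function(th) th^k * (1 - th)^(n - k) * dbeta(th, a, b),
      0, 1,
      rel.tol = 1e-12
    )$value
  }
  set.seed(7)
  X <- cbind(1, rnorm(6))
  beta <- c(-0.2, 0.5)
  phi <- 3.7
  tot <- sample(5:20, 6)
  k <- sapply(tot, function(n) sample(0:n, 1))
  mu <- plogis(drop(X %*% beta))
  oracle <- sum(log(mapply(
    pmf_oracle, k, tot,
    mu * phi, (1 - mu) * phi
  )))
  expect_equal(betabinom_loglik(beta, phi, X, k, tot), oracle,
    tolerance = 1e-8
  )
})

test_that("the ML fit is permutation invariant and recovers a null model", {
  b_true <- c(0.4, rep(0, 11))
  sim <- simulate_bb(150, b_true, 10, seed = 44)
  fit <- fit_betabinom(sim$des,
    n_night = sim$n_night,
    n_total = sim$n_total
  )
  expect_true(fit$converged)
  # null slopes: every non-intercept coefficient within 3 SE of zero
  nz <- abs(fit$coefficients[-1]) / fit$se[-1]
  expect_lt(max(nz), 3.5)
  expect_lt(abs(fit$coefficients[1] - 0.4) / fit$se[1], 3)
  # permutation invariance
  perm <- sample(seq_along(sim$n_night))
  fit2 <- fit_betabinom(sim$des$X[perm, ],
    n_night = sim$n_night[perm],
    n_total = sim$n_total[perm]
  )
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-6)
})

test_that("the ML fit agrees with an independent beta-binomial implementation", {
  skip_if_not_installed("glmmTMB")
  beta <- c(0.5, -0.6, -1.0, -0.4, 0.3, 0.2, 0, 0, 0, 0, 0, 0)
  sim <- simulate_bb(250, beta, 8, seed = 77)
  fit <- fit_betabinom(sim$des, n_night = sim$n_night, n_total = sim$n_total)
  df <- as.data.frame(sim$des$X[, -1])
  names(df) <- make.names(colnames(sim$des$X)[-1])
  preds <- names(df)
  df$k <- sim$n_night
  df$m <- sim$n_total - sim$n_night
  g <- glmmTMB::glmmTMB(
    stats::reformulate(preds, response = quote(cbind(k, m))),
    data = df, family = glmmTMB::betabinomial()
  )
  expect_equal(unname(fit$coefficients),
    unname(glmmTMB::fixef(g)$cond),
    tolerance = 0.02
  )
  expect_equal(fit$phi, glmmTMB::sigma(g), tolerance = 0.05)
})

test_that("predicted nocturnality is the inverse-logit of the linear predictor", {
  sim <- simulate_bb(120, c(0.2, rep(0, 11)), 10, seed = 5)
  fit <- fit_betabinom(sim$des, n_night = sim$n_night, n_total = sim$n_total)
  X3 <- sim$des$X[1:3, , drop = FALSE]
  pred <- predict_nocturnality(fit, X3)
  expect_equal(pred$index, unname(plogis(drop(X3 %*% fit$coefficients))))
  expect_true(all(pred$ci_low <= pred$index & pred$index <= pred$ci_high))
  # index crosses 0.5 exactly where the linear predictor crosses 0
  Xz <- matrix(0, 1, ncol(X3))
  colnames(Xz) <- colnames(X3)
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(predict_nocturnality(fit0, Xz)$index, 0.5)
  expect_error(predict_nocturnality(fit, X3[, 1:4]), "columns")
})

test_that("the posterior sampler stays near the ML solution", {
  sim <- simulate_bb(100, c(0.5, rep(0, 11)), 10, seed = 21)
  fit <- fit_betabinom(sim$des, n_night = sim$n_night, n_total = sim$n_total)
  draws <- sample_betabinom_posterior(fit,
    n_iter = 1500, burn = 500,
    thin = 5, seed = 1
  )
  expect_equal(ncol(draws), length(fit$coefficients) + 1)
  post_mean <- colMeans(draws)[1]
  expect_lt(abs(post_mean - fit$coefficients[1]), 4 * fit$se[1] + 0.2)
})
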