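# Day/night aggregation and the overdispersed beta-binomial nocturnality
# regression with effort x placement x covariate three-way interactions.

#' Aggregate events into day/night counts per camera and effort stratum
#'
#' Classifies each event as night or day by nautical twilight (see
#' [is_night()]), counts per camera x (pooled) effort stratum, and joins
#' the model covariates: placement, distance to the hunting zone, the
#' paired-trail recreation RAI (high-effort windows combined by pooling
#' events and trap days), and the species-appropriate visibility layer.
#' Camera x stratum cells with no events are absent from the result.
#'
#' @param events One species' independent events (`camera_id`,
#'   `event_time`).
#' @param deployments Deployment table.
#' @param calendar An `effort_calendar`.
#' @param rec_rai Output of [recreation_rai_per_camera()] (per window).
#' @param visibility_layer Which visibility covariate to carry:
#'   `"vis140"`, `"vis70"` or `"vis50"` (approximate species eye level).
#' @param lat,lon,tz Sun-geometry reference (defaults: study area).
#' @return Data frame with `camera_id`, `location_id`, `effort`,
#'   `placement`, `n_night`, `n_day`, `dist_hunting_zone_m`,
#'   `recreation_rai`, `visibility`.
#' @export
aggregate_day_night <- function(events, deployments, calendar, rec_rai,
                                visibility_layer = c("vis140", "vis70", "vis50"),
                                lat = DIEL_REF_LAT, lon = DIEL_REF_LON,
                                tz = DIEL_REF_TZ) {
  visibility_layer <- match.arg(visibility_layer)
  dates <- as.Date(format(events$event_time, tz = tz, "%Y-%m-%d"))
  stratum <- effort_of_date(calendar, dates, "stratum")
  if (anyNA(stratum)) {
    stop(sum(is.na(stratum)), " event(s) fall outside the effort calendar")
  }
  night <- is_night(events$event_time, lat, lon, tz)
  agg <- stats::aggregate(
    list(n_night = as.integer(night), n_day = as.integer(!night)),
    by = list(camera_id = events$camera_id, effort = stratum), FUN = sum
  )

  dep <- deployments[, c(
    "camera_id", "location_id", "placement",
    "dist_hunting_zone_m", "vis50", "vis70", "vis140"
  )]
  agg <- merge(agg, dep, by = "camera_id")

  # paired-trail recreation RAI per stratum, high windows pooled:
  # pooled RAI = 100 * sum(events) / sum(days) over the stratum's windows
  rr <- rec_rai[!is.na(rec_rai$rai), ]
  pooled <- stats::aggregate(
    rr[, c("n_events", "n_active_days")],
    by = list(camera_id = rr$camera_id, effort = rr$stratum), FUN = sum
  )
  suppressWarnings(
    pooled$recreation_rai <- rai(pooled$n_events, pooled$n_active_days)
  )
  trail_of_loc <- dep[dep$placement == "trail", c("camera_id", "location_id")]
  names(trail_of_loc)[1] <- "trail_camera_id"
  agg <- merge(agg, trail_of_loc, by = "location_id")
  agg <- merge(agg,
    pooled[, c("camera_id", "effort", "recreation_rai")],
    by.x = c("trail_camera_id", "effort"), by.y = c("camera_id", "effort"),
    all.x = TRUE
  )
  agg$visibility <- agg[[visibility_layer]]
  out <- agg[, c(
    "camera_id", "location_id", "effort", "placement",
    "n_night", "n_day", "dist_hunting_zone_m", "recreation_rai",
    "visibility"
  )]
  drop <- !stats::complete.cases(out)
  if (any(drop)) {
    message(sum(drop), " camera-stratum row(s) dropped (missing covariates)")
    out <- out[!drop, , drop = FALSE]
  }
  out[order(out$camera_id, out$effort), ]
}

#' Build the nocturnality design matrix
#'
#' Treatment-codes effort (reference `"high"`) and placement (reference
#' `"trail"`), applies optional per-covariate transforms
#' (`"log1p"`, `"sqrt"`, `"quadratic"`), z-scores every continuous
#' covariate (storing the constants for back-transformation), and
#' expands the full effort x placement x covariate interaction per the
#' model formula.
#'
#' @param rows Output of [aggregate_day_night()] (or any data frame with
#'   `effort`, `placement` and the covariates).
#' @param covariates Character vector of continuous covariate columns.
#' @param transforms Named list mapping covariate names to a transform
#'   (`"identity"`, `"log1p"`, `"sqrt"`, `"quadratic"`). A quadratic adds
#'   a separately scaled squared term that joins the interaction
#'   expansion.
#' @return List of class `noct_design`: `X` (design matrix), `response`
#'   (matrix of `n_night`, `n_total` if present in `rows`), `scaling`
#'   (data frame of centers/SDs), `terms_formula`.
#' @export
build_design <- function(rows,
                         covariates = c(
                           "dist_hunting_zone_m", "recreation_rai",
                           "visibility"
                         ),
                         transforms = list()) {
  stopifnot(all(c("effort", "placement") %in% names(rows)))
  rows$effort <- stats::relevel(
    factor(rows$effort, levels = intersect(
      c("high", "medium", "low"),
      unique(rows$effort)
    )),
    ref = "high"
  )
  rows$placement <- stats::relevel(factor(rows$placement), ref = "trail")

  sc <- list()
  cov_terms <- character()
  for (v in covariates) {
    x <- rows[[v]]
    if (is.null(x)) stop("covariate not found: ", v)
    tr <- if (!is.null(transforms[[v]])) transforms[[v]] else "identity"
    x <- switch(tr,
      identity = x,
      log1p = log1p(x),
      sqrt = sqrt(x),
      quadratic = x,
      stop("unknown transform: ", tr)
    )
    if (stats::sd(x) == 0) {
      warning("constant covariate dropped: ", v, call. = FALSE)
      next
    }
    nm <- paste0(v, "_s")
    rows[[nm]] <- as.numeric(scale(x))
    sc[[nm]] <- c(center = mean(x), sd = stats::sd(x))
    cov_terms <- c(cov_terms, nm)
    if (tr == "quadratic") {
      nm2 <- paste0(v, "_sq_s")
      rows[[nm2]] <- as.numeric(scale(x^2))
      sc[[nm2]] <- c(center = mean(x^2), sd = stats::sd(x^2))
      cov_terms <- c(cov_terms, nm2)
    }
  }
  rhs <- if (length(cov_terms) > 0) {
    paste0(
      "effort * placement * (",
      paste(cov_terms, collapse = " + "), ")"
    )
  } else {
    "effort * placement"
  }
  fml <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(fml, data = rows)
  qr_rank <- qr(X)$rank
  if (qr_rank < ncol(X)) {
    warning("design matrix rank deficient: rank ", qr_rank, " < ",
      ncol(X), " columns",
      call. = FALSE
    )
  }
  response <- NULL
  if (all(c("n_night", "n_day") %in% names(rows))) {
    response <- cbind(
      n_night = rows$n_night,
      n_total = rows$n_night + rows$n_day
    )
  }
  structure(
    list(
      X = X, response = response,
      scaling = do.call(rbind, sc), terms_formula = fml
    ),
    class = "noct_design"
  )
}

#' Beta-binomial log-likelihood (mean-precision parameterization)
#'
#' `n_night ~ BetaBinomial(n_total, alpha = mu * phi,
#' beta = (1 - mu) * phi)` with `mu = plogis(X beta)`; computed through
#' log-gamma arithmetic so large counts do not overflow. As
#' `phi -> Inf` the likelihood approaches the plain binomial.
#'
#' @param beta Coefficient vector (length `ncol(design)`).
#' @param phi Positive precision.
#' @param design Design matrix.
#' @param n_night,n_total Count vectors.
#' @return Scalar log-likelihood.
#' @export
betabinom_loglik <- function(beta, phi, design, n_night, n_total) {
  stopifnot(phi > 0, length(beta) == ncol(design))
  eta <- drop(design %*% beta)
  mu <- stats::plogis(eta)
  a <- mu * phi
  b <- (1 - mu) * phi
  ll <- lchoose(n_total, n_night) +
    lbeta(n_night + a, n_total - n_night + b) - lbeta(a, b)
  if (any(!is.finite(ll))) {
    stop(
      "non-finite beta-binomial log-likelihood at row(s) ",
      paste(utils::head(which(!is.finite(ll)), 5), collapse = ", ")
    )
  }
  sum(ll)
}

#' Fit the beta-binomial nocturnality model
#'
#' Maximum (optionally ridge-penalized) likelihood over
#' `(beta, log phi)` by BFGS, standard errors from the inverse observed
#' information at the optimum. A weak Gaussian penalty
#' (`beta ~ N(0, penalty_sd^2)` on the scaled coefficients) stabilizes
#' the heavily parameterized three-way-interaction designs; set
#' `penalty_sd = Inf` for plain ML.
#'
#' @param design A `noct_design` (or bare design matrix, in which case
#'   `n_night`/`n_total` must be given).
#' @param n_night,n_total Optional response vectors overriding the
#'   design's.
#' @param penalty_sd Prior SD of the Gaussian ridge penalty on the
#'   coefficients (default `Inf` = unpenalized).
#' @param init Optional initial coefficient vector.
#' @param maxit Optimizer iteration cap.
#' @return Object of class `noct_fit`: `coefficients`, `se`, `phi`,
#'   `phi_se_log`, `loglik`, `vcov`, `converged`, `scaling`, `design`.
#' @export
fit_betabinom <- function(design, n_night = NULL, n_total = NULL,
                          penalty_sd = Inf, init = NULL, maxit = 2000) {
  if (inherits(design, "noct_design")) {
    X <- design$X
    if (is.null(n_night)) n_night <- design$response[, "n_night"]
    if (is.null(n_total)) n_total <- design$response[, "n_total"]
    scaling <- design$scaling
  } else {
    X <- design
    scaling <- NULL
  }
  stopifnot(!is.null(n_night), !is.null(n_total), all(n_total >= 1))
  p <- ncol(X)
  if (is.null(init)) {
    # moment start: empirical logit of the pooled night share
    p0 <- (sum(n_night) + 0.5) / (sum(n_total) + 1)
    init <- c(stats::qlogis(p0), rep(0, p - 1))
  }
  par0 <- c(init, log_phi = log(10))
  negll <- function(par) {
    beta <- par[seq_len(p)]
    phi <- exp(par[p + 1])
    ll <- tryCatch(
      betabinom_loglik(beta, phi, X, n_night, n_total),
      error = function(e) -Inf
    )
    pen <- if (is.finite(penalty_sd)) {
      sum(beta^2) / (2 * penalty_sd^2)
    } else {
      0
    }
    if (!is.finite(ll)) {
      return(1e10)
    }
    -ll + pen
  }
  opt <- stats::optim(par0, negll,
    method = "BFGS",
    control = list(maxit = maxit, reltol = 1e-12)
  )
  H <- stats::optimHess(opt$par, negll)
  V <- tryCatch(solve(H), error = function(e) {
    warning("observed information singular; SEs unavailable",
      call. = FALSE
    )
    matrix(NA_real_, p + 1, p + 1)
  })
  beta <- stats::setNames(opt$par[seq_len(p)], colnames(X))
  se <- sqrt(pmax(diag(V)[seq_len(p)], 0))
  names(se) <- colnames(X)
  structure(
    list(
      coefficients = beta, se = se,
      phi = unname(exp(opt$par[p + 1])),
      phi_se_log = sqrt(max(diag(V)[p + 1], 0)),
      loglik = betabinom_loglik(
        beta, exp(opt$par[p + 1]), X, n_night,
        n_total
      ),
      vcov = V[seq_len(p), seq_len(p), drop = FALSE],
      converged = opt$convergence == 0,
      scaling = scaling, X = X,
      n_night = n_night, n_total = n_total,
      penalty_sd = penalty_sd
    ),
    class = "noct_fit"
  )
}

#' @export
print.noct_fit <- function(x, ...) {
  cat("Beta-binomial nocturnality fit",
    if (!x$converged) "(NOT converged)" else "", "\n",
    sep = " "
  )
  cat(sprintf(
    "  log-likelihood %.2f, precision phi %.2f, %d rows\n",
    x$loglik, x$phi, length(x$n_night)
  ))
  print(round(data.frame(
    estimate = x$coefficients, se = x$se,
    z = x$coefficients / x$se
  ), 4))
  invisible(x)
}

#' Coefficient table of a nocturnality fit
#'
#' @param object A `noct_fit`.
#' @param ci_level Wald interval level.
#' @param ... Unused.
#' @return Data frame with term, estimate, SE and Wald CI.
#' @export
summary.noct_fit <- function(object, ci_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  data.frame(
    term = names(object$coefficients),
    estimate = unname(object$coefficients),
    se = unname(object$se),
    ci_low = unname(object$coefficients - z * object$se),
    ci_high = unname(object$coefficients + z * object$se),
    row.names = NULL
  )
}

#' Predicted nocturnality index over a covariate grid
#'
#' Inverse-logit of the linear predictor per grid row, with a normal
#' approximation interval on the linear-predictor scale. 0.5 means equal
#' night and day activity; the index crosses 0.5 exactly where the
#' linear predictor crosses 0.
#'
#' @param fit A `noct_fit`.
#' @param newX Design matrix rows matching the fit's coefficients (build
#'   with the same [build_design()] scaling).
#' @param ci_level Interval level.
#' @return Data frame `index`, `ci_low`, `ci_high`.
#' @export
predict_nocturnality <- function(fit, newX, ci_level = 0.95) {
  newX <- as.matrix(newX)
  if (ncol(newX) != length(fit$coefficients)) {
    stop(
      "newX has ", ncol(newX), " columns; fit has ",
      length(fit$coefficients), " coefficients"
    )
  }
  if (!is.null(colnames(newX)) &&
    !identical(colnames(newX), names(fit$coefficients))) {
    stop("newX column names do not match fitted coefficient names")
  }
  eta <- as.numeric(newX %*% fit$coefficients)
  se_eta <- as.numeric(sqrt(pmax(rowSums((newX %*% fit$vcov) * newX), 0)))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  data.frame(
    index = stats::plogis(eta),
    ci_low = stats::plogis(eta - z * se_eta),
    ci_high = stats::plogis(eta + z * se_eta)
  )
}

#' Random-walk Metropolis sampler for the nocturnality posterior
#'
#' Optional Bayesian companion to [fit_betabinom()]: samples
#' `(beta, log phi)` under weak `N(0, 2.5^2)` priors on the scaled
#' coefficients and a half-normal(5) prior on `log phi`, with a
#' Gaussian random-walk proposal scaled from the ML covariance.
#'
#' @param fit A converged `noct_fit` (supplies data and the proposal).
#' @param n_iter Total iterations.
#' @param burn Burn-in discarded from the front.
#' @param thin Keep every `thin`-th draw.
#' @param seed Optional seed.
#' @param prior_sd Prior SD on coefficients.
#' @return Matrix of posterior draws (columns: coefficients, `log_phi`).
#' @export
sample_betabinom_posterior <- function(fit, n_iter = 5000, burn = 1000,
                                       thin = 5, seed = NULL,
                                       prior_sd = 2.5) {
  if (!is.null(seed)) set.seed(seed)
  X <- fit$X
  p <- ncol(X)
  logpost <- function(par) {
    beta <- par[seq_len(p)]
    phi <- exp(par[p + 1])
    ll <- tryCatch(
      betabinom_loglik(beta, phi, X, fit$n_night, fit$n_total),
      error = function(e) -Inf
    )
    ll + sum(stats::dnorm(beta, 0, prior_sd, log = TRUE)) +
      stats::dnorm(par[p + 1], 0, 5, log = TRUE)
  }
  cur <- c(fit$coefficients, log(fit$phi))
  step <- 2.4 / sqrt(p + 1) *
    sqrt(pmax(c(diag(fit$vcov), fit$phi_se_log^2), 1e-4))
  lp_cur <- logpost(cur)
  keep <- matrix(NA_real_, nrow = 0, ncol = p + 1)
  draws <- matrix(NA_real_, nrow = n_iter, ncol = p + 1)
  for (i in seq_len(n_iter)) {
    prop <- cur + stats::rnorm(p + 1, 0, step)
    lp_prop <- logpost(prop)
    if (log(stats::runif(1)) < lp_prop - lp_cur) {
      cur <- prop
      lp_cur <- lp_prop
    }
    draws[i, ] <- cur
  }
  out <- draws[seq(burn + 1, n_iter, by = thin), , drop = FALSE]
  colnames(out) <- c(names(fit$coefficients), "log_phi")
  out
}
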