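# Detection ingest, independence filtering, trap-day accounting and
# hunting-effort stratification.

# Independence thresholds: 8 s for human/recreation bursts, 5 min for
# wildlife, following the dominant camera-trap convention.
THRESHOLD_RECREATION_S <- 8
THRESHOLD_WILDLIFE_S <- 300

#' Read a detection table
#'
#' Reads a delimited detection file with columns `camera_id`, `timestamp`
#' (ISO-8601 with UTC offset, e.g. `2021-03-01T14:22:05+0100`) and
#' `class_label`. Lines starting with `#` are treated as comments. Rows
#' with unparseable timestamps are dropped and reported; missing columns
#' are a hard error.
#'
#' @param path Path to a CSV file.
#' @param tz Timezone the parsed instants are represented in.
#' @return A `data.frame` with columns `camera_id`, `timestamp`
#'   (`POSIXct`), `class_label`, sorted by camera, label and time. The
#'   attribute `"rejected"` holds a data.frame of rejected line numbers
#'   and reasons.
#' @export
read_detections <- function(path, tz = DIEL_REF_TZ) {
  if (!file.exists(path)) stop("detection file not found: ", path)
  raw <- utils::read.csv(path,
    comment.char = "#", stringsAsFactors = FALSE,
    colClasses = "character"
  )
  required <- c("camera_id", "timestamp", "class_label")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("detection file ", path, " is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  ts <- parse_iso_instant(raw$timestamp, tz = tz)
  bad <- which(is.na(ts))
  rejected <- data.frame(
    line = bad, timestamp = raw$timestamp[bad],
    reason = rep("unparseable timestamp", length(bad)),
    stringsAsFactors = FALSE
  )
  if (length(bad) > 0) {
    warning(length(bad), " row(s) with unparseable timestamps dropped from ",
      path,
      call. = FALSE
    )
    raw <- raw[-bad, , drop = FALSE]
    ts <- ts[-bad]
  }
  out <- data.frame(
    camera_id = raw$camera_id, timestamp = ts,
    class_label = raw$class_label, stringsAsFactors = FALSE
  )
  out <- out[order(out$camera_id, out$class_label, out$timestamp), ,
    drop = FALSE
  ]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

# ISO-8601 with numeric offset ("+0100" or "+01:00") or trailing "Z";
# bare local timestamps are interpreted in tz.
parse_iso_instant <- function(x, tz = DIEL_REF_TZ) {
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", x)
  has_offset <- grepl("[+-]\\d{4}$", x)
  out <- .POSIXct(rep(NA_real_, length(x)), tz = tz)
  if (any(has_offset)) {
    p <- as.POSIXct(x[has_offset],
      format = "%Y-%m-%dT%H:%M:%S%z", tz = tz
    )
    out[has_offset] <- p
  }
  if (any(!has_offset)) {
    p <- as.POSIXct(x[!has_offset], format = "%Y-%m-%dT%H:%M:%S", tz = tz)
    out[!has_offset] <- p
  }
  out
}

#' Write a detection table
#'
#' Writes the delimited format [read_detections()] reads, with ISO-8601
#' offset timestamps and optional `#` header comments (used by the
#' synthetic generator to record its seed).
#'
#' @param detections Data frame with `camera_id`, `timestamp`,
#'   `class_label`.
#' @param path Output path.
#' @param comments Character vector of header comment lines (without
#'   leading `#`).
#' @export
write_detections <- function(detections, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste("#", cm), con)
  out <- data.frame(
    camera_id = detections$camera_id,
    timestamp = format(detections$timestamp, "%Y-%m-%dT%H:%M:%S%z"),
    class_label = detections$class_label
  )
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse detections into independent events
#'
#' Within each `camera_id` x `class_label` stream (sorted by time), a
#' record extends the current event when its gap to the immediately
#' preceding record is below the threshold (record-to-record chaining); a
#' gap of at least `threshold_seconds` starts a new event. The event time
#' is the first trigger's time.
#'
#' @param records Data frame with `camera_id`, `timestamp`, `class_label`.
#' @param threshold_seconds Positive separation threshold in seconds
#'   (8 for recreation, 300 for wildlife).
#' @return Data frame of independent events: `camera_id`, `class_label`,
#'   `event_time`, `n_triggers`, sorted by (camera, label, time).
#' @export
filter_independent <- function(records, threshold_seconds) {
  stopifnot(threshold_seconds > 0)
  if (nrow(records) == 0) {
    return(data.frame(
      camera_id = character(), class_label = character(),
      event_time = .POSIXct(numeric(0), tz = DIEL_REF_TZ),
      n_triggers = integer()
    ))
  }
  ord <- order(records$camera_id, records$class_label, records$timestamp)
  r <- records[ord, , drop = FALSE]
  key <- paste(r$camera_id, r$class_label, sep = "\r")
  tsec <- as.numeric(r$timestamp)
  new_key <- c(TRUE, key[-1] != key[-length(key)])
  gap <- c(Inf, diff(tsec))
  new_event <- new_key | gap >= threshold_seconds
  event_id <- cumsum(new_event)
  first <- which(new_event)
  data.frame(
    camera_id = r$camera_id[first],
    class_label = r$class_label[first],
    event_time = r$timestamp[first],
    n_triggers = as.integer(tabulate(event_id)),
    stringsAsFactors = FALSE
  )
}

#' Classify hunting-effort strata from a monthly cull calendar
#'
#' Each month's share of all hunting events over the study window assigns
#' it to a stratum: below 5\% is low, 5\%-10\% inclusive is medium, above
#' 10\% is high. Consecutive months in the same stratum form a window;
#' windows of the same stratum (e.g. the two high-effort periods spanning
#' the turn of the year) are pooled into one stratum but keep distinct
#' window ids for steps that need them (the per-window recreation split).
#'
#' @param monthly_counts Data frame with columns `month` (first-of-month
#'   `Date` or `"YYYY-MM"` string) and `count` (non-negative hunt events).
#' @return An object of class `effort_calendar`: a data.frame with
#'   `month`, `count`, `share`, `stratum`, `window`.
#' @export
classify_effort <- function(monthly_counts) {
  stopifnot(all(c("month", "count") %in% names(monthly_counts)))
  m <- monthly_counts
  if (is.character(m$month)) m$month <- as.Date(paste0(m$month, "-01"))
  m <- m[order(m$month), , drop = FALSE]
  if (any(m$count < 0)) stop("negative hunt counts")
  total <- sum(m$count)
  if (total == 0) stop("all-zero hunting calendar: cannot classify effort")
  m$share <- m$count / total
  m$stratum <- ifelse(m$share < 0.05, "low",
    ifelse(m$share <= 0.10, "medium", "high")
  )
  # window id: stratum + run index over consecutive months
  run <- cumsum(c(TRUE, m$stratum[-1] != m$stratum[-nrow(m)]))
  m$window <- paste0(m$stratum, ".", ave(run, m$stratum, FUN = function(x) {
    match(x, unique(x))
  }))
  rownames(m) <- NULL
  class(m) <- c("effort_calendar", "data.frame")
  m
}

#' Map dates to effort strata / windows
#'
#' @param calendar An `effort_calendar` from [classify_effort()].
#' @param dates `Date` vector.
#' @param what `"stratum"` (pooled) or `"window"` (per contiguous run).
#' @return Character vector; `NA` for dates outside the calendar.
#' @export
effort_of_date <- function(calendar, dates, what = c("stratum", "window")) {
  what <- match.arg(what)
  key <- format(as.Date(dates), "%Y-%m")
  calendar[[what]][match(key, format(calendar$month, "%Y-%m"))]
}

# Expand one camera's exclusion spec ("YYYY-MM-DD/YYYY-MM-DD;...") into a
# vector of excluded Dates (union of intervals).
.expand_exclusions <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) {
    return(as.Date(character()))
  }
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  days <- lapply(parts, function(p) {
    ab <- strsplit(p, "/", fixed = TRUE)[[1]]
    seq(as.Date(ab[1]), as.Date(ab[length(ab)]), by = "day")
  })
  unique(do.call(c, days))
}

#' Trap days per camera and effort stratum
#'
#' Counts, for every camera and effort window/stratum, the whole calendar
#' days on which the camera was deployed and not excluded (outage,
#' obstruction). Overlapping exclusion intervals are unioned; exclusions
#' outside the deployment window are clipped with a warning.
#'
#' @param deployments Deployment table (see [generate_deployments()] for
#'   the columns): needs `camera_id`, `start`, `end`, `exclusions`.
#' @param calendar An `effort_calendar`.
#' @return Data frame: `camera_id`, `stratum`, `window`, `n_active_days`,
#'   one row per camera x window (windows with zero overlap included with
#'   0 days).
#' @export
compute_trap_days <- function(deployments, calendar) {
  windows <- unique(calendar[, c("stratum", "window")])
  out <- vector("list", nrow(deployments))
  for (i in seq_len(nrow(deployments))) {
    d <- deployments[i, ]
    dep_days <- seq(as.Date(d$start), as.Date(d$end), by = "day")
    excl <- .expand_exclusions(d$exclusions)
    outside <- excl[!excl %in% dep_days]
    if (length(outside) > 0) {
      warning("camera ", d$camera_id, ": ", length(outside),
        " excluded day(s) outside deployment window, clipped",
        call. = FALSE
      )
    }
    active <- dep_days[!dep_days %in% excl]
    win <- effort_of_date(calendar, active, "window")
    tab <- table(factor(win, levels = windows$window))
    out[[i]] <- data.frame(
      camera_id = d$camera_id,
      stratum = windows$stratum,
      window = windows$window,
      n_active_days = as.numeric(tab[windows$window]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
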