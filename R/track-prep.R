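#' Resample a track to a regular fix interval
#'
#' Greedy forward selection: the first fix is kept; thereafter the earliest
#' fix whose gap from the last kept fix lies within
#' `interval +/- tolerance` is kept. A fix that can only be reached with a
#' larger gap still gets kept but opens a new burst, so bursts are maximal
#' runs of regularly spaced fixes.
#'
#' @param track data.frame with `animal_id`, `timestamp` (POSIXct UTC),
#'   `x`, `y`; time-sorted and deduplicated.
#' @param interval target fix interval in hours (default 3, the common
#'   denominator across collar programmes).
#' @param tolerance accepted deviation in minutes (default 3).
#' @return the kept fixes with a `burst_id` column.
#' @export
resample_track <- function(track, interval = 3, tolerance = 3) {
  if (nrow(track) == 0L) {
    warn2("empty track: nothing to resample")
    track$burst_id <- integer(0)
    return(track)
  }
  t <- as.numeric(as_utc(track$timestamp))
  if (is.unsorted(t, strictly = TRUE))
    stop2("track timestamps must be strictly increasing")
  lo <- interval * 3600 - tolerance * 60
  hi <- interval * 3600 + tolerance * 60
  n <- length(t)
  keep <- integer(n); burst <- integer(n)
  keep[1] <- 1L; burst[1] <- 1L
  m <- 1L
  i <- 1L
  repeat {
    gaps <- t - t[keep[m]]
    nxt <- which(gaps >= lo)          # earliest fix at or beyond the window
    if (!length(nxt)) break
    j <- nxt[1]
    m <- m + 1L
    keep[m] <- j
    burst[m] <- burst[m - 1L] + (gaps[j] > hi)
  }
  out <- track[keep[seq_len(m)], , drop = FALSE]
  out$burst_id <- burst[seq_len(m)]
  rownames(out) <- NULL
  out
}

#' Trim the capture and collar-removal windows
#'
#' Drops the first `head_days` x 24 h after the first fix (capture stress)
#' and the last `tail_days` calendar days (UTC) spanned by the track
#' (collar removal). Retention is half-open:
#' `[first + head_days*24h, start of the last tail_days calendar days)`.
#'
#' @param track data.frame with a `timestamp` column.
#' @param head_days days removed from the start (default 3).
#' @param tail_days calendar days removed from the end (default 1).
#' @return the trimmed track (empty with a warning if nothing survives).
#' @export
trim_capture_window <- function(track, head_days = 3, tail_days = 1) {
  if (nrow(track) == 0L) return(track)
  ts <- as_utc(track$timestamp)
  lo <- min(ts) + head_days * 86400
  last_day <- as.Date(max(ts), tz = "UTC")
  hi <- as.POSIXct(paste(last_day - (tail_days - 1)), tz = "UTC")
  if (tail_days == 0) hi <- max(ts) + 1
  keep <- ts >= lo & ts < hi
  if (!any(keep)) warn2("capture-window trim removed every fix")
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen gross positional errors (two-stage median / spike filter)
#'
#' Stage R1 flags a fix whose distance to the coordinate-wise median of its
#' neighbours (up to `median_window` fixes before and after within the same
#' burst, excluding the fix itself) exceeds `distance_limit`. Stage R2 then
#' looks at R1-clean fixes only and flags the out-and-back spike signature:
#' geometric mean of incoming and outgoing speed above `speed_limit`
#' together with a turning-angle cosine below `cos_angle_limit`. Flagged
#' fixes are retained in the table (columns `r1_outlier`, `r2_spike`) and
#' excluded from analysis sets downstream.
#'
#' @param track resampled track (needs `burst_id`).
#' @param median_window fixes on each side entering the running median.
#' @param distance_limit meters; R1 threshold.
#' @param speed_limit meters per hour; R2 speed threshold.
#' @param cos_angle_limit R2 cosine threshold (near -1 catches only sharp
#'   out-and-back spikes).
#' @return the track with logical columns `r1_outlier` and `r2_spike`.
#' @export
screen_gross_errors <- function(track, median_window = 10,
                                distance_limit = 1e5, speed_limit = 1e4,
                                cos_angle_limit = -0.97) {
  if (is.null(track$burst_id)) track$burst_id <- 1L
  track$r1_outlier <- FALSE
  track$r2_spike <- FALSE
  for (b in unique(track$burst_id)) {
    idx <- which(track$burst_id == b)
    n <- length(idx)
    if (n < 2L) next
    x <- track$x[idx]; y <- track$y[idx]
    tt <- as.numeric(as_utc(track$timestamp[idx]))
    # R1: distance to local median (window shrinks at burst edges)
    r1 <- vapply(seq_len(n), function(i) {
      w <- setdiff(max(1, i - median_window):min(n, i + median_window), i)
      if (!length(w)) return(FALSE)
      sqrt((x[i] - stats::median(x[w]))^2 + (y[i] - stats::median(y[w]))^2) >
        distance_limit
    }, logical(1))
    # R2 on R1-clean fixes: re-index the burst without flagged positions
    clean <- which(!r1)
    r2 <- rep(FALSE, n)
    if (length(clean) >= 3L) {
      cx <- x[clean]; cy <- y[clean]; ct <- tt[clean]
      m <- length(clean)
      dx <- diff(cx); dy <- diff(cy)
      d <- sqrt(dx^2 + dy^2)
      dt <- diff(ct) / 3600
      sp <- d / dt
      for (i in 2:(m - 1L)) {
        spd <- sqrt(sp[i - 1L] * sp[i])
        costa <- sum(c(dx[i - 1L], dy[i - 1L]) * c(dx[i], dy[i])) /
          (d[i - 1L] * d[i])
        if (is.finite(spd) && is.finite(costa) &&
            spd > speed_limit && costa < cos_angle_limit)
          r2[clean[i]] <- TRUE
      }
    }
    track$r1_outlier[idx] <- r1
    track$r2_spike[idx] <- r2
  }
  track
}

#' Per-month fix-rate filter
#'
#' For every calendar month (UTC) a track touches, the achieved fix rate is
#' the number of unflagged kept fixes divided by the number expected
#' (`expected_per_day` times the days of that month covered by the track
#' span). Months at or above `min_rate` are retained; analyses drop the
#' others.
#'
#' @param track screened track.
#' @param expected_per_day expected fixes per day (8 for a 3-h schedule).
#' @param min_rate minimum acceptable rate (default 0.8).
#' @return data.frame `animal_id`, `month` ("YYYY-MM"), `n_fixes`,
#'   `n_expected`, `rate`, `retain`.
#' @export
monthly_fix_filter <- function(track, expected_per_day = 8, min_rate = 0.8) {
  if (nrow(track) == 0L)
    return(data.frame(animal_id = character(), month = character(),
                      n_fixes = integer(), n_expected = numeric(),
                      rate = numeric(), retain = logical()))
  ts <- as_utc(track$timestamp)
  flagged <- (track$r1_outlier %||% rep(FALSE, nrow(track))) |
    (track$r2_spike %||% rep(FALSE, nrow(track)))
  days <- seq(as.Date(min(ts), tz = "UTC"), as.Date(max(ts), tz = "UTC"), by = "day")
  cov_days <- table(format(days, "%Y-%m"))
  fix_month <- format(ts, "%Y-%m", tz = "UTC")
  res <- lapply(names(cov_days), function(m) {
    nf <- sum(fix_month == m & !flagged)
    ne <- expected_per_day * as.numeric(cov_days[[m]])
    data.frame(animal_id = track$animal_id[1], month = m,
               n_fixes = nf, n_expected = ne, rate = nf / ne,
               retain = nf / ne >= min_rate)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Annotate fixes with their diel class
#'
#' Adds a `diel` column (`"day"` / `"night"`) using the shared solar
#' classifier at the supplied reference coordinates.
#'
#' @param track data.frame with `timestamp`.
#' @param latitude,longitude degrees.
#' @return the track with a `diel` column.
#' @export
annotate_diel <- function(track, latitude, longitude) {
  track$diel <- classify_day_night(as_utc(track$timestamp), latitude, longitude)
  track
}

#' Remove flagged fixes before step construction
#'
#' Drops fixes carrying an R1/R2 screening flag and splits bursts where
#' the removal (or any pre-existing gap) breaks the regular spacing, so
#' steps are only ever formed between genuinely consecutive fixes.
#'
#' @param track screened track.
#' @param interval,tolerance the fix schedule (hours, minutes).
#' @return the unflagged fixes with a recomputed `burst_id`.
#' @export
drop_flagged <- function(track, interval = 3, tolerance = 3) {
  flagged <- (track$r1_outlier %||% rep(FALSE, nrow(track))) |
    (track$r2_spike %||% rep(FALSE, nrow(track)))
  out <- track[!flagged, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  t <- as.numeric(as_utc(out$timestamp))
  hi <- interval * 3600 + tolerance * 60
  lo <- interval * 3600 - tolerance * 60
  gap_bad <- c(FALSE, diff(t) > hi | diff(t) < lo)
  out$burst_id <- cumsum(gap_bad) + 1L
  rownames(out) <- NULL
  out
}
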