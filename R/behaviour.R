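# Sleep scoring, average daily activity profiles, double-plotted actograms
# and morning/evening peak-phase estimation.

#' Score sleep by the 5-minute immobility rule
#'
#' A minute is immobile iff its beam count is zero; a maximal run of at
#' least `min_bout` immobile minutes is a sleep bout, shorter runs count as
#' wake (the standard single-beam DAM convention).
#'
#' @param series A [beam_count_series()] with 1-min bins.
#' @param min_bout Minimum bout length in minutes (default 5).
#' @return An object of class `sleep_series`: list with `asleep`
#'   (per-minute logical), `bouts` (data frame `start`, `duration`), and
#'   the identity/start of the input series.
#' @examples
#' s <- beam_count_series("f", "M", 1, as.POSIXct("2024-01-01", tz = "UTC"),
#'                        c(1, 0, 0, 0, 0, 0, 1))
#' sum(annotate_sleep(s)$asleep) # 5
#' @export
annotate_sleep <- function(series, min_bout = 5L) {
  stopifnot(inherits(series, "beam_count_series"))
  immobile <- series$counts == 0L
  r <- rle(immobile)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout
  asleep <- rep(FALSE, length(immobile))
  for (i in which(keep)) asleep[starts[i]:ends[i]] <- TRUE
  bouts <- data.frame(start = starts[keep], duration = r$lengths[keep])
  structure(list(fly_id = series$fly_id, start = series$start,
                 asleep = asleep, bouts = bouts),
            class = "sleep_series")
}

#' @export
print.sleep_series <- function(x, ...) {
  cat(sprintf("Sleep series '%s': %d/%d min asleep in %d bout(s)\n",
              x$fly_id, sum(x$asleep), length(x$asleep), nrow(x$bouts)))
  invisible(x)
}

#' Light-phase sleep in hours per day
#'
#' Mean, over the analysed days, of the hours spent asleep while the lights
#' are on.  The input must contain a light phase (an LD segment); a pure DD
#' segment is an error.
#'
#' @param series A [beam_count_series()] (an LD segment, see
#'   [split_ld_dd()]).
#' @param schedule A [light_schedule()].
#' @param min_bout Minimum sleep-bout length (minutes).
#' @return Hours of light-phase sleep per day (numeric scalar).
#' @export
light_phase_sleep <- function(series, schedule, min_bout = 5L) {
  sl <- annotate_sleep(series, min_bout = min_bout)
  zi <- zeitgeber_index(series, schedule)
  if (!any(zi$lights_on))
    stop("segment contains no light phase (DD input?)")
  n_days <- length(unique(zi$day[zi$lights_on]))
  sum(sl$asleep & zi$lights_on) / 60 / n_days
}

#' Average daily activity profile of a cohort
#'
#' The single-fly activity is first averaged over the analysed LD days
#' (1440 one-minute ZT bins), then averaged across flies, then smoothed
#' with a centred moving-average filter over 11 one-minute values with
#' circular wrap (the profile is a daily cycle).
#'
#' @param cohort A [beam_count_series()] or list of them (LD segments).
#' @param schedule A [light_schedule()].
#' @param window Moving-average window in minutes (odd, default 11).
#' @return An object of class `activity_profile`: list with `bin_zt`
#'   (1440 bin-centre ZT hours), `mean_activity`, `smoothed`, and
#'   `n_flies`.
#' @export
mean_daily_profile <- function(cohort, schedule, window = 11L) {
  if (inherits(cohort, "beam_count_series")) cohort <- list(cohort)
  if (length(cohort) == 0L) stop("empty cohort")
  per_fly <- vapply(cohort, function(s) {
    zi <- zeitgeber_index(s, schedule)
    bin <- (as.integer(round(zi$zt * 60)) %% 1440L) + 1L   # 1..1440
    means <- tapply(s$counts, bin, mean)
    out <- rep(NA_real_, 1440L)
    out[as.integer(names(means))] <- as.numeric(means)
    out
  }, numeric(1440L))
  if (anyNA(per_fly)) stop("cohort does not cover all 1440 daily minutes")
  mean_activity <- rowMeans(per_fly)
  structure(list(bin_zt = (seq_len(1440L) - 0.5) / 60,
                 mean_activity = mean_activity,
                 smoothed = moving_average_circular(mean_activity, window),
                 n_flies = length(cohort)),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("Activity profile of %d fly/flies: mean %.2f counts/min (peak %.2f at ZT%.2f)\n",
              x$n_flies, mean(x$mean_activity), max(x$smoothed),
              x$bin_zt[which.max(x$smoothed)]))
  invisible(x)
}

#' @export
plot.activity_profile <- function(x, ...) {
  graphics::plot(x$bin_zt, x$mean_activity, type = "h", col = "grey70",
                 xlab = "ZT (h)", ylab = "activity (counts/min)", ...)
  graphics::lines(x$bin_zt, x$smoothed, lwd = 2)
  invisible(x)
}

## Local maxima of `y` under an 11-point rolling-maximum envelope:
## indices where y equals rollingmax(y) within tol; contiguous runs of hits
## merge to their (rounded) midpoint.
envelope_peaks <- function(y, k = 11L, tol = 1e-9) {
  hit <- abs(y - rolling_max(y, k)) <= tol
  if (!any(hit)) return(integer(0))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  as.integer(round((starts[idx] + ends[idx]) / 2))
}

#' Estimate morning and evening activity peaks
#'
#' Implements the double-plot peak algorithm: (1) the 1440-bin daily
#' profile is duplicated to 2880 bins; (2) smoothed by local regression
#' (loess, degree 2) with a 0.02 span; (3) a rolling maximum over 11
#' points of the smoothed curve defines its envelope; (4) candidate peaks
#' are the points where the smoothed curve meets the envelope (contiguous
#' hits merged to their midpoint); (5) the morning peak is the candidate
#' nearest lights-on inside the morning window and the evening peak the
#' candidate nearest lights-off inside the evening window, ties broken by
#' greater smoothed height and then earlier time.
#'
#' If the winning evening candidate lies within 15 min *after* lights-off
#' it is treated as a lights-off startle artefact: the estimate is flagged
#' `masked` and the evening peak reported as absent.
#'
#' @param profile An [mean_daily_profile()] result (LD days).
#' @param schedule A [light_schedule()].
#' @param span Loess span on the 2880-point double-plotted series.
#' @param window Rolling-maximum window (points).
#' @param morning_window,evening_window Assignment windows in hours
#'   relative to lights-on resp. lights-off.
#' @return An object of class `peak_estimate`: list with `m_peak_zt`,
#'   `e_peak_zt` (hours, `NA` when absent), `m_offset_from_lights_on` and
#'   `e_offset_to_lights_off` (minutes), `masked` (logical) and
#'   `candidates_zt`.
#' @export
detect_m_e_peaks <- function(profile, schedule, span = 0.02, window = 11L,
                             morning_window = c(-2, 6),
                             evening_window = c(-8, 1)) {
  stopifnot(inherits(profile, "activity_profile"),
            inherits(schedule, "light_schedule"))
  y <- rep(profile$mean_activity, 2L)            # double plot: 2880 bins
  xh <- (seq_along(y) - 0.5) / 60                # hours 0..48
  sm <- stats::predict(stats::loess(y ~ xh, span = span, degree = 2,
                                    family = "gaussian"))
  cand_idx <- envelope_peaks(sm, k = window)
  cand_zt <- xh[cand_idx]
  cand_h <- sm[cand_idx]

  pick <- function(anchor, win) {
    lo <- anchor + win[1]; hi <- anchor + win[2]
    in_win <- cand_zt >= lo & cand_zt <= hi
    if (!any(in_win)) return(NULL)
    zt <- cand_zt[in_win]; h <- cand_h[in_win]
    d <- abs(zt - anchor)
    best <- order(round(d * 60), -h, zt)[1]      # nearest; ties: higher, earlier
    list(zt = zt[best], height = h[best])
  }

  ## anchors on the doubled axis: use the second-day copy so windows that
  ## reach before ZT0 / after ZT24 stay inside the series
  l_on <- 24
  l_off <- 24 + schedule$light_hours
  m <- pick(l_on, morning_window)
  e <- pick(l_off, evening_window)

  masked <- FALSE
  e_zt <- NA_real_
  if (!is.null(e)) {
    after_off_min <- (e$zt - l_off) * 60
    if (after_off_min > 0 && after_off_min <= 15) {
      masked <- TRUE                              # lights-off startle occludes E
    } else {
      e_zt <- e$zt %% 24
    }
  }
  m_zt <- if (is.null(m)) NA_real_ else m$zt %% 24

  structure(list(
    m_peak_zt = m_zt,
    e_peak_zt = e_zt,
    m_offset_from_lights_on =
      if (is.na(m_zt)) NA_real_ else (m$zt - l_on) * 60,
    e_offset_to_lights_off =
      if (is.na(e_zt)) NA_real_ else (l_off - e$zt) * 60,
    masked = masked,
    candidates_zt = cand_zt %% 24),
    class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("Peaks: M at ZT%s (%s min after L_ON), E at ZT%s (%s min before L_OFF)%s\n",
              fmt_or_na(x$m_peak_zt), fmt_or_na(x$m_offset_from_lights_on),
              fmt_or_na(x$e_peak_zt), fmt_or_na(x$e_offset_to_lights_off),
              if (x$masked) " [E masked by lights-off startle]" else ""))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "--" else sprintf("%.2f", v)

#' Double-plotted actogram matrix
#'
#' Row d of the matrix is day d concatenated with day d + 1 (the
#' conventional double plot); the last row pads its right half with zeros.
#' Only complete ZT-aligned days are used.
#'
#' @param series A [beam_count_series()].
#' @param schedule A [light_schedule()].
#' @return A `days x 2880` numeric matrix with rownames `day<d>`.
#' @export
actogram_matrix <- function(series, schedule) {
  zi <- zeitgeber_index(series, schedule)
  tab <- table(zi$day)
  days <- as.integer(names(tab)[tab == 1440L])
  if (length(days) == 0L) stop("no complete day in the recording")
  rows <- lapply(seq_along(days), function(i) {
    d1 <- series$counts[zi$day == days[i]]
    d2 <- if (i < length(days) && days[i + 1L] == days[i] + 1L)
      series$counts[zi$day == days[i + 1L]] else rep(0L, 1440L)
    c(d1, d2)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("day", days)
  m
}
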