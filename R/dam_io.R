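# Reading/writing Trikinetics-style DAM monitor files and mapping wall-clock
# time to Zeitgeber time under a declared light schedule.

#' Construct a light schedule
#'
#' Describes the photoperiod an experiment was run under: how many hours of
#' light and darkness make up the 24 h day, the wall-clock time of lights-on
#' (which defines Zeitgeber time 0), and the first experiment day that is
#' spent entirely in constant darkness (DD).
#'
#' Days are delimited by lights-on (ZT0), not by midnight, so that "the last
#' 5 LD days" and "the first 9 DD days" are biologically aligned segments.
#'
#' @param light_hours Hours of light per day, in (0, 24).
#' @param dark_hours Hours of darkness; must satisfy
#'   `light_hours + dark_hours == 24`.
#' @param lights_on_clock Wall-clock time of lights-on, `"HH:MM"`.
#' @param dd_start_day Index (>= 1) of the first full day of constant
#'   darkness; days before it are light-dark (LD) days.
#' @param temperature_label Free-text label, e.g. `"20C"`.
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule(20, 4, dd_start_day = 11) # LD20:4, 10 LD days then DD
#' @export
light_schedule <- function(light_hours, dark_hours = 24 - light_hours,
                           lights_on_clock = "08:00", dd_start_day = 11L,
                           temperature_label = "20C") {
  stopifnot(is.numeric(light_hours), length(light_hours) == 1L)
  if (!isTRUE(all.equal(light_hours + dark_hours, 24)))
    stop("light_hours + dark_hours must equal 24")
  if (light_hours <= 0 || light_hours >= 24)
    stop("light_hours must be in (0, 24)")
  if (dd_start_day < 1) stop("dd_start_day must be >= 1")
  structure(
    list(light_hours = light_hours, dark_hours = dark_hours,
         lights_on_clock = lights_on_clock,
         dd_start_day = as.integer(dd_start_day),
         temperature_label = temperature_label),
    class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("Light schedule LD%g:%g, lights-on %s, DD from day %d (%s)\n",
              x$light_hours, x$dark_hours, x$lights_on_clock,
              x$dd_start_day, x$temperature_label))
  invisible(x)
}

#' Construct a beam-count series for one fly
#'
#' One fly's per-minute infrared beam-interruption counts, together with its
#' monitor/channel identity and the wall-clock start of the recording.
#'
#' @param fly_id Character label for the fly.
#' @param monitor Monitor name.
#' @param channel Channel number, 1--32.
#' @param start `POSIXct` timestamp (UTC recommended) of the first minute.
#' @param counts Non-negative integer vector, one value per minute.
#' @return An object of class `beam_count_series`.
#' @export
beam_count_series <- function(fly_id, monitor, channel, start, counts) {
  channel <- as.integer(channel)
  if (is.na(channel) || channel < 1L || channel > 32L)
    stop("channel must be in 1..32")
  if (!inherits(start, "POSIXct")) stop("start must be POSIXct")
  counts <- as.integer(round(counts))
  if (length(counts) < 1L) stop("counts must be non-empty")
  if (anyNA(counts) || any(counts < 0L)) stop("counts must be non-negative")
  structure(
    list(fly_id = as.character(fly_id), monitor = as.character(monitor),
         channel = channel, start = start, counts = counts),
    class = "beam_count_series")
}

#' @export
print.beam_count_series <- function(x, ...) {
  cat(sprintf("Beam-count series '%s' (%s ch %d): %d min from %s, %d counts\n",
              x$fly_id, x$monitor, x$channel, length(x$counts),
              format(x$start, "%Y-%m-%d %H:%M", tz = "UTC"),
              sum(x$counts)))
  invisible(x)
}

## Minute-resolution timestamps of a series.
series_times <- function(series) {
  series$start + 60 * (seq_along(series$counts) - 1L)
}

#' Map a beam-count series to Zeitgeber time
#'
#' Assigns each recorded minute a day index and a Zeitgeber time
#' (ZT, hours since lights-on, in \[0, 24)), plus a boolean saying whether
#' the lights are on at that minute.  ZT0 is the minute of lights-on; days
#' are delimited by lights-on, and day 1 is the ZT-day containing the first
#' sample.  Lights are on iff `zt < light_hours` and the day precedes
#' `dd_start_day` (in DD the lights never come on).
#'
#' @param series A [beam_count_series()].
#' @param schedule A [light_schedule()].
#' @return A data frame with one row per minute: `minute` (index), `day`,
#'   `zt` (hours) and `lights_on` (logical).
#' @examples
#' s <- beam_count_series("f1", "M1", 1,
#'        as.POSIXct("2024-01-01 09:00:00", tz = "UTC"), rep(1L, 120))
#' zi <- zeitgeber_index(s, light_schedule(12, 12, "08:00"))
#' zi$zt[1] # 1.0: one hour after lights-on
#' @export
zeitgeber_index <- function(series, schedule) {
  stopifnot(inherits(series, "beam_count_series"),
            inherits(schedule, "light_schedule"))
  n <- length(series$counts)
  lt <- as.POSIXlt(series$start, tz = attr(series$start, "tzone") %||% "UTC")
  start_clock_min <- lt$hour * 60 + lt$min + lt$sec / 60
  on_min <- parse_clock_minutes(schedule$lights_on_clock)
  zt0_min <- (start_clock_min - on_min) %% 1440
  minute_zt <- (zt0_min + (seq_len(n) - 1L)) %% 1440
  day <- 1L + (zt0_min + (seq_len(n) - 1L)) %/% 1440
  zt <- minute_zt / 60
  lights_on <- zt < schedule$light_hours & day < schedule$dd_start_day
  data.frame(minute = seq_len(n), day = as.integer(day), zt = zt,
             lights_on = lights_on)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a recording into its analysed LD and DD segments
#'
#' Entrained profiles are computed from the last `ld_days_used` complete
#' light-dark days and free-running rhythmicity from the first
#' `dd_days_used` complete days of constant darkness, following the usual
#' DAM recording design (about 10 LD days of which the last 5 are analysed,
#' then at least 9 DD days).
#'
#' @param series A [beam_count_series()].
#' @param schedule A [light_schedule()].
#' @param ld_days_used Number of trailing complete LD days to keep (default 5).
#' @param dd_days_used Number of leading complete DD days to keep (default 9).
#' @return A list with elements `ld` and `dd`, each a `beam_count_series`
#'   (or `NULL` when the recording contains no such segment and the
#'   corresponding `*_days_used` is 0).  Fewer complete days than requested
#'   triggers a warning and truncation; zero complete days is an error.
#' @export
split_ld_dd <- function(series, schedule, ld_days_used = 5L, dd_days_used = 9L) {
  zi <- zeitgeber_index(series, schedule)
  tab <- table(zi$day)
  complete <- as.integer(names(tab)[tab == 1440L])
  ld_days <- complete[complete < schedule$dd_start_day]
  dd_days <- complete[complete >= schedule$dd_start_day]

  take <- function(days, k, label) {
    if (k == 0L) return(NULL)
    if (length(days) == 0L)
      stop("no complete ", label, " day in the recording")
    if (length(days) < k) {
      warning(sprintf("only %d complete %s day(s) available, %d requested",
                      length(days), label, k))
      k <- length(days)
    }
    days
  }

  out <- list(ld = NULL, dd = NULL)
  if (!is.null(take(ld_days, ld_days_used, "LD"))) {
    keep <- utils::tail(ld_days, min(ld_days_used, length(ld_days)))
    idx <- zi$minute[zi$day %in% keep]
    out$ld <- beam_count_series(series$fly_id, series$monitor, series$channel,
                                series$start + 60 * (idx[1] - 1L),
                                series$counts[idx])
  }
  if (!is.null(take(dd_days, dd_days_used, "DD"))) {
    keep <- utils::head(dd_days, min(dd_days_used, length(dd_days)))
    idx <- zi$minute[zi$day %in% keep]
    out$dd <- beam_count_series(series$fly_id, series$monitor, series$channel,
                                series$start + 60 * (idx[1] - 1L),
                                series$counts[idx])
  }
  out
}

#' Write a cohort to a DAM2-style monitor file
#'
#' Writes the tab-separated layout produced by Trikinetics DAMSystem:
#' column 1 a record index, column 2 the date (`"1 Jan 24"`), column 3 the
#' time (`"HH:MM:SS"`), column 4 a status flag (1 = valid), columns 5--10
#' unused (zero), and columns 11--42 the counts of channels 1--32.
#'
#' All series must share the same start time, length and monitor name;
#' channels not present in the cohort are written as zero.
#'
#' @param cohort List of [beam_count_series()] from one monitor.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dam_monitor <- function(cohort, path) {
  stopifnot(length(cohort) >= 1L)
  starts <- unique(vapply(cohort, function(s) as.numeric(s$start), numeric(1)))
  lens <- unique(vapply(cohort, function(s) length(s$counts), integer(1)))
  if (length(starts) != 1L || length(lens) != 1L)
    stop("all series in a monitor file must share start time and length")
  chans <- vapply(cohort, function(s) s$channel, integer(1))
  if (anyDuplicated(chans)) stop("duplicate channels in cohort")
  n <- lens
  counts <- matrix(0L, nrow = n, ncol = 32L)
  for (s in cohort) counts[, s$channel] <- s$counts
  times <- cohort[[1]]$start + 60 * (seq_len(n) - 1L)
  dates <- sub("^0", "", format(times, "%d %b %y", tz = "UTC"))
  clock <- format(times, "%H:%M:%S", tz = "UTC")
  header <- cbind(seq_len(n), dates, clock, 1L,
                  matrix(0L, nrow = n, ncol = 6L))
  utils::write.table(cbind(header, counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DAM2-style monitor file
#'
#' Parses the 42-column tab-separated Trikinetics layout (see
#' [write_dam_monitor()]).  Timestamps must advance in strict 1-minute
#' steps; a gap or reversal is an error.  Rows whose status column is not 1
#' are kept but flagged (their indices are attached as attribute
#' `"flagged_rows"`, with a warning).  An optional finer recording bin is
#' aggregated to 1-minute bins by summation.
#'
#' @param path File path.
#' @param channel_map Named integer vector mapping fly labels to channel
#'   numbers, e.g. `c(fly1 = 1, fly2 = 2)`; unnamed channels get labels
#'   `"<monitor>_ch<channel>"`.
#' @param monitor Monitor label (default: file name without extension).
#' @param tz Time zone of the timestamps (default UTC).
#' @return A list of [beam_count_series()], one per requested channel.
#' @export
read_dam_monitor <- function(path, channel_map, monitor = NULL, tz = "UTC") {
  if (is.null(monitor)) monitor <- tools::file_path_sans_ext(basename(path))
  raw <- readLines(path)
  if (length(raw) == 0L) stop("empty DAM file: ", path)
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 42L)
  if (length(bad))
    stop(sprintf("malformed DAM row at line %d: %d columns (expected 42)",
                 bad[1], nf[bad[1]]))
  m <- do.call(rbind, fields)
  times <- as.POSIXct(paste(m[, 2], m[, 3]),
                      format = "%d %b %y %H:%M:%S", tz = tz)
  if (anyNA(times)) stop("unparseable date/time at line ", which(is.na(times))[1])
  step <- diff(as.numeric(times))
  if (any(step <= 0)) stop("non-monotonic timestamps at line ",
                           which(step <= 0)[1] + 1L)
  status <- as.integer(m[, 4])
  counts <- matrix(as.integer(m[, 11:42]), ncol = 32L)

  if (length(unique(step)) > 1L) stop("irregular timestamp spacing")
  bin <- if (length(step)) step[1] else 60
  if (bin < 60) {
    if (60 %% bin != 0) stop("recording bin does not divide 60 s")
    per <- 60 / bin
    if (nrow(counts) %% per != 0)
      counts <- counts[seq_len(per * (nrow(counts) %/% per)), , drop = FALSE]
    grp <- rep(seq_len(nrow(counts) / per), each = per)
    counts <- apply(counts, 2, function(col) tapply(col, grp, sum))
    times <- times[seq(1, length(grp), by = per)]
    status <- as.integer(tapply(status, grp, min))
  } else if (bin > 60) {
    stop("bins coarser than 1 min are not supported")
  }

  flagged <- which(status != 1L)
  if (length(flagged))
    warning(length(flagged), " row(s) with non-valid status flag")

  chans <- as.integer(channel_map)
  labels <- names(channel_map)
  if (is.null(labels)) labels <- sprintf("%s_ch%02d", monitor, chans)
  if (any(is.na(chans) | chans < 1L | chans > 32L))
    stop("unknown channel in channel_map")
  out <- vector("list", length(chans))
  for (i in seq_along(chans)) {
    s <- beam_count_series(labels[i], monitor, chans[i], times[1],
                           counts[, chans[i]])
    attr(s, "flagged_rows") <- flagged
    out[[i]] <- s
  }
  names(out) <- labels
  out
}

#' Drop flies that died during the recording
#'
#' A fly with zero beam crossings over the final 24 h of the analysed span
#' is treated as dead (common DAM practice) and excluded with a message.
#'
#' @param cohort List of [beam_count_series()].
#' @return The surviving subset of `cohort`.
#' @export
drop_dead_flies <- function(cohort) {
  dead <- vapply(cohort, function(s) {
    n <- length(s$counts)
    sum(s$counts[max(1L, n - 1439L):n]) == 0L
  }, logical(1))
  if (any(dead))
    message("excluding ", sum(dead), " dead fly/flies: ",
            paste(vapply(cohort[dead], `[[`, "", "fly_id"), collapse = ", "))
  cohort[!dead]
}
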