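# Seeded generators for the four input kinds of the pipeline, each with a
# ground-truth sidecar sufficient to score the downstream stage.
#
# The generative model is phenomenological: Poisson beam counts whose rate
# is a baseline modulated by Gaussian morning/evening bumps and a midday
# siesta suppression; in constant darkness rhythmic flies free-run with an
# exponentially damping amplitude, arrhythmic flies flatten out.

#' Simulation parameters for one fly strain
#'
#' Phenomenological description of a latitudinal strain: its photoperiodic
#' response (true critical night length, logistic steepness, asymptote) and
#' its locomotor phenotype (fraction of flies rhythmic in constant darkness,
#' free-running period, amplitude damping, morning/evening bump timing,
#' siesta depth).
#'
#' Defaults describe a robustly rhythmic mid-latitude strain: baseline
#' 2 counts/min, morning and evening bumps of 3x baseline amplitude and
#' 60 min SD anchored 10 min after lights-on / before lights-off, a 60%
#' siesta trough, free-running period 24.5 h with negligible damping.
#'
#' @param strain Strain label.
#' @param latitude Collection latitude, degrees N.
#' @param cnl_true True critical night length (h): night length at which
#'   half of the population enters diapause.
#' @param pprc_slope Logistic steepness of the photoperiodic response
#'   (per hour of night length).
#' @param pprc_asymptote Maximal diapause incidence, in (0, 1]; values
#'   below 1 emulate strains that never reach full diapause.
#' @param rhythmic_fraction Fraction of flies that stay rhythmic in DD.
#' @param free_run_period Endogenous period in DD (h).
#' @param damping_halflife Days over which the DD oscillation amplitude
#'   halves; large values mean a sustained rhythm.
#' @param m_offset Minutes after lights-on at which the morning activity
#'   bump is centred.
#' @param e_offset Minutes before lights-off at which the evening bump is
#'   centred.
#' @param m_amp,e_amp Bump amplitudes as multiples of the baseline rate.
#' @param siesta_depth Fractional midday suppression of activity, in [0,1].
#' @param loff_startle_amp Amplitude (multiples of baseline) of a sharp
#'   clock-independent startle spike just after lights-off; 0 disables it.
#'   Used to emulate strains whose evening peak is masked by the lights-off
#'   response.
#' @param baseline_rate Baseline beam-count rate (counts/min).
#' @param bump_sd_min SD of the morning/evening bumps (minutes).
#' @param seed Integer seed for this strain's generators.
#' @return An object of class `strain_sim_params`.
#' @export
strain_sim_params <- function(strain = "sim", latitude = 55,
                              cnl_true = 8, pprc_slope = 1.5,
                              pprc_asymptote = 1,
                              rhythmic_fraction = 0.8,
                              free_run_period = 24.5,
                              damping_halflife = 100,
                              m_offset = 10, e_offset = 10,
                              m_amp = 3, e_amp = 3,
                              siesta_depth = 0.6,
                              loff_startle_amp = 0,
                              baseline_rate = 2,
                              bump_sd_min = 60,
                              seed = 1L) {
  stopifnot(pprc_asymptote > 0, pprc_asymptote <= 1,
            cnl_true > 0, pprc_slope > 0,
            rhythmic_fraction >= 0, rhythmic_fraction <= 1,
            siesta_depth >= 0, siesta_depth <= 1,
            baseline_rate >= 0, m_amp >= 0, e_amp >= 0,
            loff_startle_amp >= 0,
            free_run_period > 0, damping_halflife > 0, bump_sd_min > 0)
  structure(as.list(environment()), class = "strain_sim_params")
}

#' @export
print.strain_sim_params <- function(x, ...) {
  cat(sprintf(
    "Strain '%s' (%.0f deg N): CNL %.1f h, slope %.2f, asymptote %.2f; %0.0f%% rhythmic, tau %.1f h\n",
    x$strain, x$latitude, x$cnl_true, x$pprc_slope, x$pprc_asymptote,
    100 * x$rhythmic_fraction, x$free_run_period))
  invisible(x)
}

## Daily activity shape (multiples of baseline) at Zeitgeber/circadian
## phase `zt` in hours.  `startle` adds the light-driven lights-off spike
## and is only applied under LD.
activity_shape <- function(zt, light_hours, params, startle = FALSE) {
  sd_h <- params$bump_sd_min / 60
  m_c <- params$m_offset / 60
  e_c <- light_hours - params$e_offset / 60
  s_c <- light_hours / 2
  s_sd <- light_hours / 5
  s <- params$m_amp * exp(-circular_diff(zt, m_c)^2 / (2 * sd_h^2)) +
    params$e_amp * exp(-circular_diff(zt, e_c)^2 / (2 * sd_h^2)) -
    params$siesta_depth * exp(-circular_diff(zt, s_c)^2 / (2 * s_sd^2))
  if (startle && params$loff_startle_amp > 0) {
    spike_c <- light_hours + 5 / 60   # startle peaks ~5 min after lights-off
    s <- s + params$loff_startle_amp *
      exp(-circular_diff(zt, spike_c)^2 / (2 * (5 / 60)^2))
  }
  s
}

#' Generate a cohort of synthetic DAM recordings
#'
#' Per-minute beam counts are drawn Poisson with rate
#' `baseline * (1 + shape)` where `shape` holds the morning/evening bumps
#' and siesta suppression of [strain_sim_params()].  During LD every fly is
#' entrained; in DD a fly drawn rhythmic (probability `rhythmic_fraction`)
#' free-runs at `free_run_period` with the shape amplitude halving every
#' `damping_halflife` days, while an arrhythmic fly has a flat rate.
#' Negative composed rates are clipped to zero (and counted in a message).
#'
#' @param params A [strain_sim_params()].
#' @param schedule A [light_schedule()]; `dd_start_day` must equal
#'   `n_ld_days + 1`.
#' @param n_flies Number of flies.
#' @param n_ld_days,n_dd_days Days of LD (>= 1) and DD (>= 0).
#' @param start Wall-clock start; defaults to lights-on so the recording
#'   begins at ZT0 of day 1.
#' @param seed Seed (default `params$seed`); identical seeds give
#'   bit-identical cohorts.
#' @return A list of [beam_count_series()] with a `"truth"` attribute: a
#'   data frame of per-fly ground truth (rhythmic flag, period, true peak
#'   offsets).
#' @export
gen_dam_cohort <- function(params, schedule, n_flies = 32L,
                           n_ld_days = 10L, n_dd_days = 9L,
                           start = NULL, seed = params$seed) {
  stopifnot(inherits(params, "strain_sim_params"),
            inherits(schedule, "light_schedule"))
  if (n_flies < 0) stop("n_flies must be >= 0")
  if (n_ld_days < 1 || n_dd_days < 0) stop("non-positive duration")
  if (schedule$dd_start_day != n_ld_days + 1L)
    stop("schedule$dd_start_day must be n_ld_days + 1")
  if (is.null(start)) {
    on_min <- parse_clock_minutes(schedule$lights_on_clock)
    start <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") + 60 * on_min
  }

  minutes_ld <- n_ld_days * 1440L
  minutes_dd <- n_dd_days * 1440L
  t_min <- seq_len(minutes_ld + minutes_dd) - 1L     # minutes since ZT0 day 1
  zt_h <- (t_min %% 1440) / 60
  in_dd <- t_min >= minutes_ld
  dd_elapsed_h <- pmax(0, (t_min - minutes_ld) / 60)

  shape_ld <- activity_shape(zt_h, schedule$light_hours, params,
                             startle = TRUE)
  ## circadian phase in DD: continues from ZT0 at DD start (whole LD days),
  ## advancing at 24 h of subjective time per free_run_period hours
  theta <- (dd_elapsed_h * 24 / params$free_run_period) %% 24
  shape_dd <- activity_shape(theta, schedule$light_hours, params,
                             startle = FALSE)
  damp <- 0.5^((dd_elapsed_h / 24) / params$damping_halflife)

  clipped <- 0L
  cohort <- with_seed(seed, {
    rhythmic <- stats::runif(n_flies) < params$rhythmic_fraction
    lapply(seq_len(n_flies), function(i) {
      lam <- numeric(length(t_min))
      lam[!in_dd] <- params$baseline_rate * (1 + shape_ld[!in_dd])
      lam[in_dd] <- if (rhythmic[i])
        params$baseline_rate * (1 + damp[in_dd] * shape_dd[in_dd])
      else params$baseline_rate
      neg <- lam < 0
      if (any(neg)) { clipped <<- clipped + sum(neg); lam[neg] <- 0 }
      s <- beam_count_series(sprintf("%s_f%02d", params$strain, i),
                             paste0("M_", params$strain),
                             ((i - 1L) %% 32L) + 1L, start,
                             stats::rpois(length(lam), lam))
      attr(s, "rhythmic_true") <- rhythmic[i]
      s
    })
  })
  if (clipped > 0)
    message("clipped ", clipped, " negative rate value(s) to 0")
  attr(cohort, "truth") <- data.frame(
    fly_id = vapply(cohort, `[[`, "", "fly_id"),
    rhythmic = vapply(cohort, attr, logical(1), "rhythmic_true"),
    free_run_period = params$free_run_period,
    m_offset_true_min = params$m_offset,
    e_offset_true_min = params$e_offset,
    stringsAsFactors = FALSE)
  cohort
}

#' Generate a photoperiodic diapause panel
#'
#' For each strain and night length NL, the number of diapausing flies is
#' drawn Binomial(`n_per_point`, P) with
#' `P(NL) = asymptote / (1 + exp(-slope * (NL - cnl_true)))`, the logistic
#' photoperiodic response of [strain_sim_params()].
#'
#' @param strains List of [strain_sim_params()].
#' @param night_lengths Night lengths tested (h), each in (0, 24).
#' @param n_per_point Flies tested per point (>= 1; at least 25 emulates
#'   the usual assay size).
#' @param seed Seed (default: the first strain's seed).
#' @return A data frame of class `diapause_assay` with columns `strain`,
#'   `latitude`, `night_length`, `n_diapause`, `n_total`, plus a `"truth"`
#'   attribute with the generating parameters per strain.
#' @export
gen_diapause_panel <- function(strains, night_lengths, n_per_point = 30L,
                               seed = NULL) {
  if (inherits(strains, "strain_sim_params")) strains <- list(strains)
  if (length(night_lengths) == 0L) stop("night_lengths must be non-empty")
  if (any(night_lengths <= 0 | night_lengths >= 24))
    stop("night lengths must be in (0, 24)")
  if (n_per_point < 1) stop("n_per_point must be >= 1")
  if (is.null(seed)) seed <- strains[[1]]$seed
  rows <- with_seed(seed, {
    do.call(rbind, lapply(strains, function(p) {
      prob <- p$pprc_asymptote /
        (1 + exp(-p$pprc_slope * (night_lengths - p$cnl_true)))
      data.frame(strain = p$strain, latitude = p$latitude,
                 night_length = night_lengths,
                 n_diapause = stats::rbinom(length(night_lengths),
                                            n_per_point, prob),
                 n_total = as.integer(n_per_point),
                 stringsAsFactors = FALSE)
    }))
  })
  class(rows) <- c("diapause_assay", "data.frame")
  attr(rows, "truth") <- data.frame(
    strain = vapply(strains, `[[`, "", "strain"),
    latitude = vapply(strains, `[[`, numeric(1), "latitude"),
    cnl_true = vapply(strains, `[[`, numeric(1), "cnl_true"),
    pprc_slope = vapply(strains, `[[`, numeric(1), "pprc_slope"),
    pprc_asymptote = vapply(strains, `[[`, numeric(1), "pprc_asymptote"),
    stringsAsFactors = FALSE)
  rows
}

#' Cosinor parameters for a synthetic staining time series
#'
#' The staining intensity of a neuron cluster is modelled as a mesor plus a
#' 24 h and a 12 h cosine component with Gaussian noise:
#' `value = mesor + amp24 cos(2 pi (t - phase24)/24) +
#' amp12 cos(2 pi (t - phase12)/12) + N(0, sigma)`.
#'
#' @param mesor Mean level (grey-value units).
#' @param amp24,amp12 Amplitudes of the 24 h and 12 h components (>= 0).
#' @param phase24,phase12 Peak times of the components (h).
#' @param sigma Gaussian noise SD (>= 0).
#' @param n_brains Brains per timepoint.
#' @param n_cells Cells measured per brain (raw ROIs before per-brain
#'   averaging); cell-level noise shares `sigma`.
#' @param timepoints Sampling times (h), typically every 3 h.
#' @param seed Integer seed.
#' @return An object of class `cosinor_params`.
#' @export
cosinor_params <- function(mesor = 100, amp24 = 20, amp12 = 0,
                           phase24 = 0, phase12 = 0, sigma = 10,
                           n_brains = 10L, n_cells = 1L,
                           timepoints = seq(1, 22, by = 3), seed = 1L) {
  stopifnot(sigma >= 0, amp24 >= 0, amp12 >= 0, n_brains >= 1, n_cells >= 1,
            length(timepoints) >= 1)
  structure(as.list(environment()), class = "cosinor_params")
}

#' Generate a synthetic staining time series
#'
#' Draws per-cell ROI intensities following the cosinor model of
#' [cosinor_params()]: each brain gets an independent Gaussian deviation,
#' and (when `n_cells > 1`) each cell an additional one, both with SD
#' `sigma`.
#'
#' @param params A [cosinor_params()].
#' @param cluster Neuron-cluster label attached to every sample.
#' @param seed Seed (default `params$seed`).
#' @return Data frame with columns `brain_id`, `cell_id`, `cluster`,
#'   `timepoint_h`, `value` and a `"truth"` attribute holding `params`.
#' @export
gen_staining_series <- function(params, cluster = "LNd", seed = params$seed) {
  stopifnot(inherits(params, "cosinor_params"))
  tp <- params$timepoints
  mu <- params$mesor +
    params$amp24 * cos(2 * pi * (tp - params$phase24) / 24) +
    params$amp12 * cos(2 * pi * (tp - params$phase12) / 12)
  grid <- expand.grid(cell = seq_len(params$n_cells),
                      brain = seq_len(params$n_brains),
                      t_idx = seq_along(tp))
  values <- with_seed(seed, {
    brain_dev <- matrix(stats::rnorm(params$n_brains * length(tp),
                                     sd = params$sigma),
                        nrow = params$n_brains)
    cell_dev <- if (params$n_cells > 1)
      stats::rnorm(nrow(grid), sd = params$sigma) else 0
    mu[grid$t_idx] + brain_dev[cbind(grid$brain, grid$t_idx)] + cell_dev
  })
  out <- data.frame(
    brain_id = sprintf("brain%02d_t%02d", grid$brain, grid$t_idx),
    cell_id = sprintf("c%02d", grid$cell),
    cluster = cluster,
    timepoint_h = tp[grid$t_idx],
    value = values,
    stringsAsFactors = FALSE)
  attr(out, "truth") <- params
  out
}

#' Generate a deterministic two-channel image fixture
#'
#' Builds a pair of z-stacks (arrays indexed `[z, y, x]`) containing
#' disc-shaped somata with a per-plane intensity profile, an optional
#' terminal pixel mask, and a constant background, plus a ground-truth
#' sidecar recording every quantity the imaging stage should recover.
#' Soma contributions are additive; overlapping somata therefore sum, with
#' a warning.
#'
#' @param shape Integer vector `c(z, y, x)`.
#' @param somata List of somata, each a list with elements `centre`
#'   (`c(y, x)`), `radius` (pixels), `intensity` (length-2: per channel),
#'   and optionally `z_profile` (per-plane multipliers, default all 1).
#' @param terminal_mask Logical `y x x` matrix (or NULL) marking terminal
#'   pixels.
#' @param terminal_intensity Length-2 intensity added on terminal pixels in
#'   every plane.
#' @param background Constant background grey value (both channels).
#' @param pixel_size Pixel edge length in micrometres (default 0.537).
#' @return List with elements `ch1`, `ch2` (arrays), `pixel_size` and
#'   `truth` (sidecar list).
#' @export
gen_image_fixture <- function(shape = c(4L, 64L, 64L), somata = list(),
                              terminal_mask = NULL,
                              terminal_intensity = c(0, 0),
                              background = 10, pixel_size = 0.537) {
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  ch1 <- array(background, dim = c(nz, ny, nx))
  ch2 <- array(background, dim = c(nz, ny, nx))
  covered <- matrix(0L, ny, nx)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)

  soma_truth <- list()
  for (i in seq_along(somata)) {
    s <- somata[[i]]
    stopifnot(length(s$centre) == 2L, s$radius >= 0)
    if (s$centre[1] - s$radius < 1 || s$centre[1] + s$radius > ny ||
        s$centre[2] - s$radius < 1 || s$centre[2] + s$radius > nx)
      stop("soma ", i, " extends beyond the image")
    zp <- s$z_profile %||% rep(1, nz)
    stopifnot(length(zp) == nz)
    disc <- (yy - s$centre[1])^2 + (xx - s$centre[2])^2 <= s$radius^2
    if (any(covered[disc] > 0L)) warning("overlapping somata: intensities sum")
    covered[disc] <- covered[disc] + 1L
    for (z in seq_len(nz)) {
      ch1[z, , ][disc] <- ch1[z, , ][disc] + s$intensity[1] * zp[z]
      ch2[z, , ][disc] <- ch2[z, , ][disc] + s$intensity[2] * zp[z]
    }
    soma_truth[[i]] <- list(
      centre = s$centre, radius = s$radius,
      mask = which(disc), area_px = sum(disc),
      area_um2 = sum(disc) * pixel_size^2,
      intensity = s$intensity,
      brightest_plane = which.max(zp),
      z_profile = zp)
  }

  term_truth <- NULL
  if (!is.null(terminal_mask)) {
    stopifnot(is.matrix(terminal_mask), all(dim(terminal_mask) == c(ny, nx)))
    for (z in seq_len(nz)) {
      ch1[z, , ][terminal_mask] <- ch1[z, , ][terminal_mask] + terminal_intensity[1]
      ch2[z, , ][terminal_mask] <- ch2[z, , ][terminal_mask] + terminal_intensity[2]
    }
    term_truth <- list(n_px = sum(terminal_mask),
                       intensity = terminal_intensity,
                       mass_ch1 = sum(terminal_mask) * terminal_intensity[1])
  }

  list(ch1 = ch1, ch2 = ch2, pixel_size = pixel_size,
       truth = list(background = background, shape = shape,
                    somata = soma_truth, terminal = term_truth))
}
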