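# End-to-end pipeline: a validated configuration, a simulate step writing
# all four synthetic data kinds with ground-truth sidecars, and an analyse
# step producing the per-strain result tables (rhythmicity, peaks, sleep,
# PPRC/CNL, cycling, latitude correlations).  Both steps are deterministic
# under the master seed; per-stage seeds are derived by fixed offsets.

#' Default panel of simulated latitudinal strains
#'
#' Nine strains at the latitudes of the classical European collection
#' sites (69 to 41 degrees N) whose true critical night length runs
#' linearly from 4 h at 69 N to 12 h at 41 N.  The circadian phenotype
#' follows the same cline: the fraction of DD-rhythmic flies, siesta depth
#' and the looseness of the morning/evening peaks all increase towards the
#' south.  One mid-latitude strain has an asymptote below 1 (it never
#' reaches full diapause) and the southernmost strain carries a prominent
#' lights-off startle spike that masks its evening peak.
#'
#' @param seed Master seed from which per-strain seeds derive.
#' @return List of [strain_sim_params()].
#' @export
default_strain_panel <- function(seed = 1L) {
  lat <- c(69, 68, 66, 62, 47, 46, 42, 41, 41)
  names_ <- c("north69", "north68", "north66", "north62", "mid47",
              "mid46", "south42", "south41a", "south41b")
  lapply(seq_along(lat), function(i) {
    l <- lat[i]
    f <- (69 - l) / 28                       # 0 at 69 N .. 1 at 41 N
    strain_sim_params(
      strain = names_[i], latitude = l,
      cnl_true = 4 + 8 * f,
      pprc_slope = 1.5,
      pprc_asymptote = if (names_[i] == "mid46") 0.8 else 1,
      rhythmic_fraction = 0.1 + 0.8 * f,
      free_run_period = 24.5,
      damping_halflife = 0.5 + 99.5 * f,
      m_offset = 10 + 80 * f, e_offset = 10 + 80 * f,
      siesta_depth = 0.2 + 0.6 * f,
      loff_startle_amp = if (names_[i] == "south41b") 8 else 0,
      seed = derive_seed(seed, 100 + i))
  })
}

#' Default staining simulation set
#'
#' Two simulated strains x three neuron clusters covering the qualitative
#' cycling regimes: a "south"-like strain with robust 24 h components and
#' a "north"-like strain whose long-photoperiod clusters cycle at 12 h
#' only (or not at all).
#'
#' @param seed Master seed.
#' @return Data-frame-driven list: each element has `strain`, `cluster`
#'   and a [cosinor_params()].
#' @export
default_staining_set <- function(seed = 1L) {
  spec <- list(
    list(strain = "south", cluster = "s-LNv",
         args = list(amp24 = 20, amp12 = 0, phase24 = 0)),
    list(strain = "south", cluster = "LNd",
         args = list(amp24 = 15, amp12 = 0, phase24 = 12)),
    list(strain = "south", cluster = "DN1",
         args = list(amp24 = 10, amp12 = 5, phase24 = 6)),
    list(strain = "north", cluster = "s-LNv",
         args = list(amp24 = 0, amp12 = 0)),
    list(strain = "north", cluster = "LNd",
         args = list(amp24 = 0, amp12 = 15, phase12 = 2)),
    list(strain = "north", cluster = "l-LNv",
         args = list(amp24 = 0, amp12 = 12, phase12 = 5)))
  lapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    s$params <- do.call(cosinor_params,
                        c(s$args, list(seed = derive_seed(seed, 200 + i))))
    s$args <- NULL
    s
  })
}

#' Pipeline configuration
#'
#' Validates and bundles every tunable of the simulate/analyse pipeline.
#'
#' @param seed Master seed; all stage seeds derive from it by fixed
#'   offsets, so a fixed seed makes the whole pipeline bit-reproducible.
#' @param strains List of [strain_sim_params()]
#'   (default [default_strain_panel()]).
#' @param staining List from [default_staining_set()].
#' @param n_flies Flies per strain for the DAM simulation.
#' @param n_ld_days,n_dd_days Recording design (days).
#' @param light_hours Photoperiod of the LD segment (h), default LD20:4.
#' @param lights_on_clock Wall-clock lights-on.
#' @param ld_days_used,dd_days_used Days analysed per segment.
#' @param alpha Significance level for rhythmicity and cycling calls.
#' @param period_range,period_step Lomb-Scargle period grid (h).
#' @param jtk_periods Reference periods for the cycling test (h).
#' @param night_lengths,n_per_point Diapause assay design.
#' @param n_boot Bootstrap replicates for CNL confidence intervals.
#' @param with_images Simulate/analyse the image fixture.
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            strains = default_strain_panel(seed),
                            staining = default_staining_set(seed),
                            n_flies = 30L, n_ld_days = 10L, n_dd_days = 9L,
                            light_hours = 20, lights_on_clock = "08:00",
                            ld_days_used = 5L, dd_days_used = 9L,
                            alpha = 0.05,
                            period_range = c(14, 34), period_step = 0.1,
                            jtk_periods = c(24, 12),
                            night_lengths = seq(4, 18, by = 2),
                            n_per_point = 30L, n_boot = 200L,
                            with_images = TRUE) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_flies < 1) stop("n_flies must be >= 1")
  if (n_ld_days < 1 || n_dd_days < 0) stop("invalid day counts")
  if (ld_days_used > n_ld_days || dd_days_used > n_dd_days)
    stop("analysed days exceed recorded days")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(night_lengths) < 3) stop("need >= 3 night lengths")
  for (s in strains) stopifnot(inherits(s, "strain_sim_params"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "Pipeline config: seed %d, %d strain(s) x %d flies, LD%g:%g (%d+%d days), %d night lengths\n",
    x$seed, length(x$strains), x$n_flies, x$light_hours,
    24 - x$light_hours, x$n_ld_days, x$n_dd_days, length(x$night_lengths)))
  invisible(x)
}

config_schedule <- function(config) {
  light_schedule(config$light_hours, 24 - config$light_hours,
                 config$lights_on_clock,
                 dd_start_day = config$n_ld_days + 1L)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Simulate a complete synthetic dataset
#'
#' Writes, under `out_dir`: DAM monitor files (one per strain, under
#' `dam/`), the diapause panel (`diapause.tsv`), the staining series
#' (`staining.tsv`), a two-channel image fixture (under `images/`), the
#' ground-truth sidecars (`truth_*.json`) and a `manifest.json`.  The
#' whole directory is a pure function of the configuration: the same
#' master seed gives byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; must be empty unless
#'   `overwrite`).
#' @param overwrite Allow writing into a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is not empty: ", out_dir)
  dir.create(file.path(out_dir, "dam"), recursive = TRUE,
             showWarnings = FALSE)
  schedule <- config_schedule(config)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("chronocline")),
                   kinds = character(0), files = character(0))
  add <- function(kind, files) {
    manifest$kinds <<- union(manifest$kinds, kind)
    manifest$files <<- c(manifest$files, files)
  }

  ## 1. DAM recordings
  truth_dam <- list()
  for (p in config$strains) {
    cohort <- gen_dam_cohort(p, schedule, n_flies = config$n_flies,
                             n_ld_days = config$n_ld_days,
                             n_dd_days = config$n_dd_days)
    f <- file.path("dam", paste0("M_", p$strain, ".txt"))
    write_dam_monitor(cohort, file.path(out_dir, f))
    tr <- attr(cohort, "truth")
    tr$strain <- p$strain
    tr$latitude <- p$latitude
    truth_dam[[p$strain]] <- tr
    add("dam", f)
  }
  write_json_file(truth_dam, file.path(out_dir, "truth_dam.json"))

  ## 2. diapause panel
  panel <- gen_diapause_panel(config$strains, config$night_lengths,
                              config$n_per_point,
                              seed = derive_seed(config$seed, 300))
  write_tsv(panel, file.path(out_dir, "diapause.tsv"))
  write_json_file(attr(panel, "truth"),
                  file.path(out_dir, "truth_diapause.json"))
  add("diapause", "diapause.tsv")

  ## 3. staining series
  staining <- do.call(rbind, lapply(config$staining, function(s) {
    df <- gen_staining_series(s$params, cluster = s$cluster)
    df$strain <- s$strain
    df
  }))
  write_tsv(staining, file.path(out_dir, "staining.tsv"))
  write_json_file(lapply(config$staining, function(s)
    c(list(strain = s$strain, cluster = s$cluster),
      s$params[c("mesor", "amp24", "amp12", "phase24", "phase12",
                 "sigma", "n_brains")])),
    file.path(out_dir, "truth_staining.json"))
  add("staining", "staining.tsv")

  ## 4. image fixture
  if (config$with_images) {
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
    fx <- gen_image_fixture(
      shape = c(8L, 64L, 64L),
      somata = list(
        list(centre = c(20, 20), radius = 5, intensity = c(90, 40),
             z_profile = c(0.2, 0.5, 1, 0.7, 0.4, 0.2, 0.1, 0.1)),
        list(centre = c(45, 40), radius = 4, intensity = c(60, 120),
             z_profile = rep(1, 8))),
      terminal_mask = {
        m <- matrix(FALSE, 64, 64); m[10:12, 50:57] <- TRUE; m
      },
      terminal_intensity = c(50, 0), background = 10)
    write_image_stack(fx$ch1, file.path(out_dir, "images", "ch1_pdf.txt"))
    write_image_stack(fx$ch2, file.path(out_dir, "images", "ch2_crz.txt"))
    write_json_file(list(background = fx$truth$background,
                         pixel_size = fx$pixel_size,
                         somata = lapply(fx$truth$somata, function(s)
                           s[c("centre", "radius", "area_px", "area_um2",
                               "intensity", "brightest_plane")]),
                         terminal = fx$truth$terminal),
                    file.path(out_dir, "truth_images.json"))
    add("images", c("images/ch1_pdf.txt", "images/ch2_crz.txt"))
  }

  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

provenance <- function(config) {
  data.frame(seed = config$seed,
             version = as.character(utils::packageVersion("chronocline")))
}

#' Analyse a simulated (or compatible) dataset directory
#'
#' Runs every pipeline stage whose inputs are present and writes one TSV
#' table per stage into `out_dir`: `rhythmicity.tsv` (percent rhythmic and
#' period per strain), `peaks.tsv`, `sleep.tsv`, `pprc_cnl.tsv`,
#' `jtk.tsv` (24 h and 12 h p-values per strain and cluster),
#' `imaging.tsv` and `latitude_correlation.tsv`.  Missing inputs skip
#' their stage with a message; other stages still run.  Every table
#' carries `seed` and `version` provenance columns; a fixed seed gives
#' bit-identical outputs.
#'
#' @param config The [pipeline_config()] the dataset was simulated with.
#' @param dataset_dir Directory written by [pipeline_simulate()].
#' @param out_dir Results directory (created).
#' @return Named list of the tables written, invisibly.
#' @export
pipeline_analyse <- function(config, dataset_dir, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  mpath <- file.path(dataset_dir, "manifest.json")
  if (!file.exists(mpath)) stop("dataset manifest not found: ", mpath)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- config_schedule(config)
  prov <- provenance(config)
  results <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      message("stage '", name, "' skipped: ", conditionMessage(e))
      NULL
    })
  }

  strain_lat <- vapply(config$strains, `[[`, numeric(1), "latitude")
  names(strain_lat) <- vapply(config$strains, `[[`, "", "strain")

  ## ---- behaviour + rhythmicity from DAM files -------------------------
  dam_files <- list.files(file.path(dataset_dir, "dam"), full.names = TRUE)
  if (length(dam_files)) {
    beh <- run_stage("behaviour", {
      rhythm_rows <- list(); peak_rows <- list(); sleep_rows <- list()
      for (f in dam_files) {
        strain <- sub("^M_", "", tools::file_path_sans_ext(basename(f)))
        chans <- seq_len(min(config$n_flies, 32L))
        names(chans) <- sprintf("%s_f%02d", strain, chans)
        cohort <- drop_dead_flies(read_dam_monitor(f, chans))
        segs <- lapply(cohort, split_ld_dd, schedule = schedule,
                       ld_days_used = config$ld_days_used,
                       dd_days_used = config$dd_days_used)
        ## rhythmicity in DD
        pgs <- lapply(segs, function(s)
          suppressWarnings(lomb_scargle(s$dd, config$period_range,
                                        config$period_step, config$alpha)))
        pr <- percent_rhythmic(pgs)
        periods <- vapply(pgs, `[[`, numeric(1), "best_period")
        rhythm_rows[[strain]] <- data.frame(
          strain = strain, latitude = unname(strain_lat[strain]),
          n = pr$n, n_rhythmic = pr$n_rhythmic,
          percent_rhythmic = pr$percent,
          ci_lower = 100 * pr$ci[["lower"]],
          ci_upper = 100 * pr$ci[["upper"]],
          mean_period_h = if (pr$n_rhythmic > 0)
            mean(periods[vapply(pgs, `[[`, logical(1), "rhythmic")])
          else NA_real_)
        ## peaks from the LD profile
        prof <- mean_daily_profile(lapply(segs, `[[`, "ld"), schedule)
        pk <- detect_m_e_peaks(prof, schedule)
        peak_rows[[strain]] <- data.frame(
          strain = strain, latitude = unname(strain_lat[strain]),
          m_peak_zt = pk$m_peak_zt, e_peak_zt = pk$e_peak_zt,
          m_offset_min = pk$m_offset_from_lights_on,
          e_offset_min = pk$e_offset_to_lights_off,
          masked = pk$masked)
        ## light-phase sleep
        lps <- vapply(segs, function(s)
          light_phase_sleep(s$ld, schedule), numeric(1))
        sleep_rows[[strain]] <- data.frame(
          strain = strain, latitude = unname(strain_lat[strain]),
          mean_light_sleep_h = mean(lps), sd_light_sleep_h = stats::sd(lps))
      }
      list(rhythm = do.call(rbind, rhythm_rows),
           peaks = do.call(rbind, peak_rows),
           sleep = do.call(rbind, sleep_rows))
    })
    if (!is.null(beh)) {
      results$rhythmicity <- write_table(beh$rhythm, prov, out_dir,
                                         "rhythmicity.tsv")
      results$peaks <- write_table(beh$peaks, prov, out_dir, "peaks.tsv")
      results$sleep <- write_table(beh$sleep, prov, out_dir, "sleep.tsv")
    }
  } else message("stage 'behaviour' skipped: no DAM files")

  ## ---- photoperiodism -------------------------------------------------
  dpath <- file.path(dataset_dir, "diapause.tsv")
  if (file.exists(dpath)) {
    pprc <- run_stage("photoperiodism", {
      panel <- utils::read.delim(dpath)
      rows <- lapply(split(panel, panel$strain), function(d) {
        fit <- fit_pprc(d)
        ci <- if (!is.na(fit$cnl))
          bootstrap_cnl_ci(fit, n_boot = config$n_boot,
                           seed = derive_seed(config$seed, 400))
        else c(NA_real_, NA_real_)
        data.frame(strain = d$strain[1], latitude = d$latitude[1],
                   asymptote = fit$coefficients[["asymptote"]],
                   slope = fit$coefficients[["slope"]],
                   ed50_h = fit$coefficients[["ed50"]],
                   cnl_h = fit$cnl, ci_lower = ci[[1]], ci_upper = ci[[2]],
                   separation = fit$separation)
      })
      do.call(rbind, rows)
    })
    if (!is.null(pprc))
      results$pprc_cnl <- write_table(pprc, prov, out_dir, "pprc_cnl.tsv")
  } else message("stage 'photoperiodism' skipped: no diapause table")

  ## ---- staining cycling -----------------------------------------------
  spath <- file.path(dataset_dir, "staining.tsv")
  if (file.exists(spath)) {
    jtk <- run_stage("cycling", {
      staining <- utils::read.delim(spath)
      combos <- unique(staining[, c("strain", "cluster")])
      rows <- lapply(seq_len(nrow(combos)), function(i) {
        d <- staining[staining$strain == combos$strain[i] &
                        staining$cluster == combos$cluster[i], ]
        avg <- per_brain_average(d)
        res <- lapply(config$jtk_periods, function(pd)
          jtk_cycle(avg, period = pd))
        out <- data.frame(strain = combos$strain[i],
                          cluster = combos$cluster[i])
        for (j in seq_along(config$jtk_periods)) {
          pd <- config$jtk_periods[j]
          out[[sprintf("p_value_%gh", pd)]] <- res[[j]]$p_value
          out[[sprintf("tau_%gh", pd)]] <- res[[j]]$tau
          out[[sprintf("lag_%gh", pd)]] <- res[[j]]$best_lag
        }
        out
      })
      do.call(rbind, rows)
    })
    if (!is.null(jtk))
      results$jtk <- write_table(jtk, prov, out_dir, "jtk.tsv")
  } else message("stage 'cycling' skipped: no staining table")

  ## ---- imaging --------------------------------------------------------
  ipath <- file.path(dataset_dir, "images")
  tpath <- file.path(dataset_dir, "truth_images.json")
  if (dir.exists(ipath) && file.exists(tpath)) {
    img <- run_stage("imaging", {
      ch1 <- read_image_stack(file.path(ipath, "ch1_pdf.txt"))
      ch2 <- read_image_stack(file.path(ipath, "ch2_crz.txt"))
      truth <- jsonlite::read_json(tpath, simplifyVector = FALSE)
      bg <- truth$background
      rows <- list()
      for (i in seq_along(truth$somata)) {
        s <- truth$somata[[i]]
        ctr <- unlist(s$centre)
        nuc <- nuclear_intensity(ch1, c(s$brightest_plane, ctr),
                                 background = bg)
        mask <- matrix(FALSE, dim(ch1)[2], dim(ch1)[3])
        yy <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
        xx <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask),
                     byrow = TRUE)
        mask[(yy - ctr[1])^2 + (xx - ctr[2])^2 <= s$radius^2] <- TRUE
        soma <- soma_intensity_area(ch1, mask, background = bg,
                                    pixel_size = truth$pixel_size)
        rows[[length(rows) + 1L]] <- data.frame(
          roi = sprintf("soma%d", i), kind = "nuclear3x3",
          value = nuc$value, area_um2 = NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          roi = sprintf("soma%d", i), kind = "soma",
          value = soma$value, area_um2 = soma$area)
      }
      proj <- subtract_crz_channel(max_project(ch1), max_project(ch2))
      wit <- whole_image_terminal_intensity(proj, background_estimate = 0)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = "terminals", kind = "whole_image", value = wit$value,
        area_um2 = NA_real_)
      do.call(rbind, rows)
    })
    if (!is.null(img))
      results$imaging <- write_table(img, prov, out_dir, "imaging.tsv")
  } else message("stage 'imaging' skipped: no image fixture")

  ## ---- latitude correlations ------------------------------------------
  corr <- run_stage("latitude_correlation", {
    rows <- list()
    add_corr <- function(metric_name, lat, val) {
      cw <- tryCatch(suppressMessages(correlate_with_latitude(lat, val)),
                     error = function(e) NULL)
      if (is.null(cw)) return()
      rows[[metric_name]] <<- data.frame(
        metric = metric_name, r = cw$r, p_value = cw$p_value,
        slope = cw$slope, intercept = cw$intercept, n = cw$n)
    }
    if (!is.null(results$pprc_cnl))
      add_corr("cnl_h", results$pprc_cnl$latitude, results$pprc_cnl$cnl_h)
    if (!is.null(results$rhythmicity))
      add_corr("percent_rhythmic", results$rhythmicity$latitude,
               results$rhythmicity$percent_rhythmic)
    if (!is.null(results$peaks)) {
      add_corr("m_offset_min", results$peaks$latitude,
               results$peaks$m_offset_min)
      add_corr("e_offset_min", results$peaks$latitude,
               results$peaks$e_offset_min)
    }
    if (!is.null(results$sleep))
      add_corr("light_sleep_h", results$sleep$latitude,
               results$sleep$mean_light_sleep_h)
    if (length(rows) == 0L) stop("no per-strain metrics available")
    do.call(rbind, rows)
  })
  if (!is.null(corr))
    results$latitude_correlation <-
      write_table(corr, prov, out_dir, "latitude_correlation.tsv")

  invisible(results)
}

write_table <- function(df, prov, out_dir, name) {
  df$seed <- prov$seed
  df$version <- prov$version
  row.names(df) <- NULL
  write_tsv(df, file.path(out_dir, name))
  df
}
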