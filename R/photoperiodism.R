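# Photoperiodic response curves: maximum-likelihood logistic dose-response
# fit, critical night length (CNL) extraction, parametric-bootstrap CNL
# confidence intervals and the latitude-cline correlation.

#' Fit a photoperiodic response curve (PPRC)
#'
#' Fits, by maximum binomial likelihood, the three-parameter logistic
#' dose-response model
#' \deqn{P(NL) = d / (1 + \exp(-b (NL - e)))}
#' to diapause incidence as a function of night length NL, where
#' `d` in (0, 1] is the upper asymptote (maximal diapause incidence),
#' `b > 0` the steepness and `e` the ED50 (the inflection point, i.e. the
#' night length at which the curve reaches half of its asymptote).  The
#' lower bound is fixed at 0 and the asymptote left free because some
#' low-latitude strains never reach 100% diapause.
#'
#' Optimisation uses bounded quasi-Newton (L-BFGS-B) with an analytic
#' gradient from multiple starts spanning the night-length range.
#' Complete separation (all-0 or all-1 responses, or a perfect step) is
#' reported via the `separation` flag; such fits sit on the parameter
#' boundary and their slope is not interpretable.
#'
#' @param assays Data frame with columns `night_length`, `n_diapause`,
#'   `n_total` for one strain (e.g. one strain's rows of
#'   [gen_diapause_panel()]); at least 3 distinct night lengths.
#' @param strain Optional strain label (default: taken from the data if
#'   present).
#' @param n_starts Number of multi-start ED50 values (default 5).
#' @param slope_max Upper box bound on the slope (default 50/h); a fitted
#'   slope at this bound is flagged as effectively infinite.
#' @return An object of class `pprc_fit` with components `coefficients`
#'   (`asymptote`, `slope`, `ed50`), `cnl` (see
#'   [critical_night_length()]), `loglik`, `fitted`, `data`, `converged`,
#'   `separation`, `ci_cnl` (filled by [bootstrap_cnl_ci()]).
#' @seealso [critical_night_length()], [bootstrap_cnl_ci()],
#'   [correlate_with_latitude()]
#' @examples
#' panel <- gen_diapause_panel(strain_sim_params(cnl_true = 9), seq(4, 18, 2))
#' fit <- fit_pprc(panel)
#' coef(fit)
#' @export
fit_pprc <- function(assays, strain = NULL, n_starts = 5L, slope_max = 50) {
  stopifnot(all(c("night_length", "n_diapause", "n_total") %in% names(assays)))
  nl <- assays$night_length
  y <- assays$n_diapause
  n <- assays$n_total
  if (any(y < 0 | y > n)) stop("n_diapause must lie in [0, n_total]")
  if (length(unique(nl)) < 3L) stop("need >= 3 distinct night lengths")
  if (any(n < 25))
    warning("fewer than 25 flies tested at some point(s)")
  if (is.null(strain))
    strain <- if ("strain" %in% names(assays)) as.character(assays$strain[1])
    else "unknown"

  eps <- 1e-12
  nll <- function(par) {
    p <- pmin(1 - eps, pmax(eps, par[1] * stats::plogis(par[2] * (nl - par[3]))))
    -sum(y * log(p) + (n - y) * log(1 - p))
  }
  gr <- function(par) {
    d <- par[1]; b <- par[2]; e <- par[3]
    s <- stats::plogis(b * (nl - e))
    p <- pmin(1 - eps, pmax(eps, d * s))
    w <- -(y / p - (n - y) / (1 - p))       # d(nll)/dP
    c(sum(w * s),
      sum(w * d * s * (1 - s) * (nl - e)),
      sum(w * d * s * (1 - s) * (-b)))
  }

  frac <- y / n
  d0 <- min(1, max(max(frac), 0.1))
  e_starts <- stats::quantile(nl, probs = seq(0.1, 0.9,
                                              length.out = n_starts))
  b_starts <- rep_len(c(1.5, 0.5, 5, 1.5, 0.5), n_starts)
  lower <- c(1e-4, 1e-3, min(nl) - 24)
  upper <- c(1, slope_max, max(nl) + 24)

  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(c(d0, b_starts[i], unname(e_starts[i])), nll, gr,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  if (best$convergence != 0L) {
    ## L-BFGS-B can stop with an abnormal line-search code at an active
    ## box bound (typically d = 1) although the optimum is reached; a
    ## restart from the candidate either confirms it or improves on it.
    polish <- tryCatch(
      stats::optim(best$par, nll, gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value + 1e-8) {
      polish$value <- min(polish$value, best$value)
      best <- polish
    }
    if (best$convergence != 0L) {
      ## KKT check: treat the candidate as converged when the projected
      ## gradient (feasible directions only) vanishes at the box bounds
      g <- gr(best$par)
      at_lo <- best$par <= lower + 1e-10
      at_hi <- best$par >= upper - 1e-10
      g[(at_lo & g > 0) | (at_hi & g < 0)] <- 0
      if (max(abs(g)) < 1e-3 * (1 + abs(best$value)))
        best$convergence <- 0L
    }
  }

  d <- best$par[1]; b <- best$par[2]; e <- best$par[3]
  all0 <- all(y == 0)
  all1 <- all(y == n)
  perfect_step <- !all0 && !all1 && all(frac %in% c(0, 1))
  separation <- all0 || all1 || perfect_step || b >= 0.999 * slope_max
  p_fit <- d * stats::plogis(b * (nl - e))

  out <- structure(list(
    coefficients = c(asymptote = d, slope = b, ed50 = e),
    loglik = -best$value,
    fitted = data.frame(night_length = nl, p_obs = frac, p_fit = p_fit,
                        n_total = n),
    data = assays[, c("night_length", "n_diapause", "n_total")],
    strain = strain,
    converged = best$convergence == 0L,
    separation = separation,
    ci_cnl = c(NA_real_, NA_real_),
    call = match.call()),
    class = "pprc_fit")
  out$cnl <- critical_night_length(out)
  out
}

#' Critical night length of a fitted response curve
#'
#' The CNL is the night length at which the fitted curve crosses an
#' absolute diapause incidence of 50% of the population.  It is found by
#' root-finding on the fitted curve and is undefined (`NA`) when the
#' asymptote `d` does not reach 0.5; when `d = 1` it coincides with the
#' ED50 (the inflection point).  For `d < 1` the inflection-point reading
#' (ED50, 50% *of the asymptote*) differs from the absolute crossing; both
#' are kept on the fit object and [print.pprc_fit()] flags the
#' discrepancy.
#'
#' @param fit A [fit_pprc()] object.
#' @return CNL in hours, or `NA_real_` when the curve never reaches 50%.
#' @export
critical_night_length <- function(fit) {
  stopifnot(inherits(fit, "pprc_fit"))
  cf <- fit$coefficients
  if (!is.finite(cf["asymptote"]) || cf["asymptote"] <= 0.5)
    return(NA_real_)
  curve_fun <- function(x)
    cf["asymptote"] * stats::plogis(cf["slope"] * (x - cf["ed50"])) - 0.5
  lo <- cf["ed50"] - 48; hi <- cf["ed50"] + 48
  if (curve_fun(lo) >= 0 || curve_fun(hi) <= 0) return(NA_real_)
  unname(stats::uniroot(curve_fun, c(lo, hi), tol = 1e-10)$root)
}

#' Parametric-bootstrap confidence interval for the CNL
#'
#' Resamples diapause counts Binomial(`n_total`, fitted P) at the observed
#' night lengths, refits the curve (warm-started at the original
#' estimates), and returns the percentile interval of the bootstrap CNLs.
#' If more than 20% of refits fail (non-convergence or undefined CNL) the
#' basic (reflected) interval is returned instead, with a warning.
#'
#' @param fit A converged [fit_pprc()].
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; same seed, same interval.
#' @return Length-2 numeric `c(lower, upper)` in hours, with the bootstrap
#'   draws attached as attribute `"draws"`.  Also stored in `fit$ci_cnl`
#'   when the result is re-assigned.
#' @export
bootstrap_cnl_ci <- function(fit, n_boot = 200L, level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "pprc_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (is.na(fit$cnl)) stop("CNL undefined for this fit")
  nl <- fit$data$night_length
  n <- fit$data$n_total
  p_fit <- fit$fitted$p_fit
  cf <- fit$coefficients

  eps <- 1e-12
  refit_cnl <- function(y) {
    nll <- function(par) {
      p <- pmin(1 - eps, pmax(eps,
                              par[1] * stats::plogis(par[2] * (nl - par[3]))))
      -sum(y * log(p) + (n - y) * log(1 - p))
    }
    gr <- function(par) {
      s <- stats::plogis(par[2] * (nl - par[3]))
      p <- pmin(1 - eps, pmax(eps, par[1] * s))
      w <- -(y / p - (n - y) / (1 - p))
      c(sum(w * s),
        sum(w * par[1] * s * (1 - s) * (nl - par[3])),
        sum(w * par[1] * s * (1 - s) * (-par[2])))
    }
    fitb <- tryCatch(
      stats::optim(unname(cf), nll, gr, method = "L-BFGS-B",
                   lower = c(1e-4, 1e-3, min(nl) - 24),
                   upper = c(1, 50, max(nl) + 24),
                   control = list(factr = 1e7, maxit = 300)),
      error = function(e) NULL)
    if (is.null(fitb) || fitb$convergence != 0L) return(NA_real_)
    d <- fitb$par[1]; b <- fitb$par[2]; e <- fitb$par[3]
    if (d <= 0.5) return(NA_real_)
    e - log(2 * d - 1) / b        # closed-form absolute 50% crossing
  }

  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      refit_cnl(stats::rbinom(length(nl), n, p_fit))
    }, numeric(1))
  })
  fail <- mean(is.na(draws))
  ok <- draws[!is.na(draws)]
  if (length(ok) < 2L) stop("bootstrap failed: too few successful refits")
  a <- (1 - level) / 2
  perc <- unname(stats::quantile(ok, c(a, 1 - a), type = 7))
  ci <- if (fail > 0.2) {
    warning(sprintf("%.0f%% of bootstrap refits failed: basic interval used",
                    100 * fail))
    sort(2 * fit$cnl - rev(perc))
  } else perc
  names(ci) <- c("lower", "upper")
  attr(ci, "draws") <- draws
  ci
}

#' Pearson correlation of a per-strain metric with latitude
#'
#' Strains with an undefined (non-finite) metric -- e.g. a CNL that never
#' crosses 50% -- are excluded with a message.
#'
#' @param latitude Numeric latitudes (degrees N).
#' @param metric Numeric per-strain values (e.g. CNL, percent rhythmic,
#'   peak offsets, light-phase sleep).
#' @return List with `r` (Pearson), `p_value` (two-sided, t-distributed),
#'   `slope`, `intercept` (least-squares line), `n`, `excluded`.
#' @export
correlate_with_latitude <- function(latitude, metric) {
  stopifnot(length(latitude) == length(metric))
  keep <- is.finite(latitude) & is.finite(metric)
  if (any(!keep))
    message("excluding ", sum(!keep), " strain(s) with undefined metric")
  latitude <- latitude[keep]; metric <- metric[keep]
  if (length(latitude) < 3L) stop("need >= 3 strains with finite metric")
  if (stats::sd(latitude) == 0 || stats::sd(metric) == 0)
    stop("zero variance in latitude or metric")
  ct <- stats::cor.test(latitude, metric, method = "pearson")
  fit <- stats::lm(metric ~ latitude)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(latitude), excluded = sum(!keep))
}

## ---- pprc_fit methods --------------------------------------------------

#' @export
print.pprc_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("Photoperiodic response curve fit ('%s')\n", x$strain))
  cat(sprintf("  asymptote d = %.3f, slope b = %.3f /h, ED50 = %.3f h\n",
              cf[1], cf[2], cf[3]))
  cat(sprintf("  CNL (absolute 50%% crossing) = %s h%s\n", fmt_or_na(x$cnl),
              if (!is.na(x$cnl) && abs(x$cnl - cf[3]) > 1e-6)
                sprintf(" [differs from ED50 = %.3f h since d < 1]", cf[3])
              else ""))
  if (!all(is.na(x$ci_cnl)))
    cat(sprintf("  95%% CI: [%.3f, %.3f] h\n", x$ci_cnl[1], x$ci_cnl[2]))
  if (x$separation)
    cat("  note: complete separation; slope effectively infinite\n")
  cat(sprintf("  log-likelihood %.3f on %d points\n", x$loglik,
              nrow(x$data)))
  invisible(x)
}

#' @export
summary.pprc_fit <- function(object, ...) {
  print(object)
  cat("\nFitted values:\n")
  print(object$fitted, row.names = FALSE)
  invisible(object)
}

#' @export
coef.pprc_fit <- function(object, ...) object$coefficients

#' @export
logLik.pprc_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, class = "logLik")
}

#' Predict diapause incidence from a fitted response curve
#'
#' @param object A [fit_pprc()] object.
#' @param newdata Optional data frame with a `night_length` column, or a
#'   numeric vector of night lengths; defaults to the fitted data.
#' @param ... Ignored.
#' @return Predicted diapause fractions.
#' @export
predict.pprc_fit <- function(object, newdata = NULL, ...) {
  nl <- if (is.null(newdata)) object$data$night_length
  else if (is.numeric(newdata)) newdata
  else newdata$night_length
  cf <- object$coefficients
  unname(cf["asymptote"] * stats::plogis(cf["slope"] * (nl - cf["ed50"])))
}

#' @export
residuals.pprc_fit <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  y <- object$data$n_diapause
  n <- object$data$n_total
  p <- pmin(1 - 1e-12, pmax(1e-12, object$fitted$p_fit))
  if (type == "pearson") {
    (y - n * p) / sqrt(n * p * (1 - p))
  } else {
    ll_sat <- ifelse(y == 0, 0, y * log(y / n)) +
      ifelse(y == n, 0, (n - y) * log(1 - y / n))
    ll_fit <- y * log(p) + (n - y) * log(1 - p)
    sign(y - n * p) * sqrt(pmax(0, 2 * (ll_sat - ll_fit)))
  }
}

#' @export
simulate.pprc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$data$n_total
  p <- object$fitted$p_fit
  draws <- with_seed(seed, {
    replicate(nsim, stats::rbinom(length(n), n, p), simplify = FALSE)
  })
  out <- as.data.frame(draws, col.names = paste0("sim_", seq_len(nsim)))
  row.names(out) <- NULL
  out
}

#' @export
plot.pprc_fit <- function(x, ...) {
  nl <- x$data$night_length
  grid <- seq(min(nl) - 1, max(nl) + 1, length.out = 200)
  graphics::plot(nl, x$fitted$p_obs, pch = 19, ylim = c(0, 1),
                 xlab = "night length (h)", ylab = "diapause incidence",
                 main = x$strain, ...)
  graphics::lines(grid, predict(x, grid))
  if (!is.na(x$cnl)) {
    graphics::abline(h = 0.5, lty = 3)
    graphics::abline(v = x$cnl, lty = 2)
  }
  invisible(x)
}
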