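#' Double-reference a sensorgram
#'
#' `corrected = (active - reference) - (blank_active - blank_reference)`.
#' When the blank cycles are absent, single referencing
#' (`active - reference`) is applied. All grids must be identical.
#'
#' @param active analyte injection over the protein surface (`sensorgram`)
#' @param reference same injection over the empty reference surface
#' @param blank_active,blank_reference optional buffer-blank cycles
#' @return the corrected `sensorgram`
#' @export
reference_blank_subtract <- function(active, reference,
                                     blank_active = NULL,
                                     blank_reference = NULL) {
  grids_match <- function(a, b) {
    !is.null(b) && length(a$time) == length(b$time) &&
      max(abs(a$time - b$time)) < 1e-9
  }
  if (!grids_match(active, reference)) {
    stop("active and reference time grids differ", call. = FALSE)
  }
  corrected <- active$response - reference$response
  if (!is.null(blank_active) || !is.null(blank_reference)) {
    if (!grids_match(active, blank_active) ||
        !grids_match(active, blank_reference)) {
      stop("blank time grids differ from the active grid", call. = FALSE)
    }
    corrected <- corrected - (blank_active$response - blank_reference$response)
  }
  sensorgram(active$cycle, active$conc, active$time, corrected,
             active$assoc_window, active$dissoc_window)
}

#' Extract the equilibrium response from a sensorgram
#'
#' `Req` is the mean response over the final `window` seconds of the
#' association phase. A least-squares slope over the same window checks that
#' the curve has actually plateaued; points failing `|slope| < slope_tol` are
#' flagged (`plateau_ok = FALSE`) but not dropped.
#'
#' @param sg a `sensorgram` with an association window
#' @param window averaging window length (s), default 5
#' @param slope_tol plateau slope tolerance (RU/s), default 0.05
#' @return list with `conc`, `req`, `plateau_ok`, `slope`
#' @export
extract_equilibrium <- function(sg, window = 5, slope_tol = 0.05) {
  stopifnot(inherits(sg, "sensorgram"))
  if (is.null(sg$assoc_window)) {
    stop("sensorgram has no association window", call. = FALSE)
  }
  dur <- diff(sg$assoc_window)
  if (window >= dur) {
    stop(sprintf("window (%g s) must be shorter than the association phase (%g s)",
                 window, dur), call. = FALSE)
  }
  sel <- sg$time >= (sg$assoc_window[2] - window) &
         sg$time <= sg$assoc_window[2] + 1e-9
  t_w <- sg$time[sel]
  r_w <- sg$response[sel]
  slope <- unname(stats::coef(stats::lm(r_w ~ t_w))[2L])
  list(conc = sg$conc, req = mean(r_w),
       plateau_ok = abs(slope) < slope_tol, slope = slope)
}

# Residual sum of squares of the 1:1 steady-state model; for fixed KD the
# optimal Rmax is linear, so the fit profiles over log10(KD).
ss_rss <- function(log10_kd, conc, req, rmax_max) {
  kd <- 10^log10_kd
  f <- conc / (conc + kd)
  rmax <- sum(req * f) / sum(f * f)
  rmax <- min(max(rmax, 1e-12), rmax_max)
  sum((req - rmax * f)^2)
}

ss_rmax_for_kd <- function(kd, conc, req, rmax_max) {
  f <- conc / (conc + kd)
  min(max(sum(req * f) / sum(f * f), 1e-12), rmax_max)
}

#' Fit the 1:1 steady-state affinity model
#'
#' Least-squares fit of `Req = C * Rmax / (C + KD)` to one equilibrium
#' series. `KD` is profiled on the log10 scale over `[1e-4, 1e4]` uM (for
#' fixed `KD` the optimal `Rmax` is available in closed form, bounded by
#' `10 * max(Req)`), initialized from `Rmax0 = max(Req)` and the
#' linearly-interpolated concentration at half-maximal response, with a 7x7
#' log-grid multi-start fallback. `saturation_flag` is set when the fitted
#' `KD` exceeds the highest tested concentration — the affinity then lies
#' outside the measured range and the estimate is less reliable.
#'
#' @param series a `steady_state_series`, or anything with numeric `conc`
#'   and `req` elements
#' @param kd_bounds log-uniform search bounds for KD (uM)
#' @return an `affinity_fit` object
#' @export
fit_steady_state <- function(series, kd_bounds = c(1e-4, 1e4)) {
  conc <- series$conc
  req <- series$req
  if (length(conc) < 4L) {
    stop("need >= 4 concentration points", call. = FALSE)
  }
  if (all(abs(req) < 1e-12)) {
    stop("all responses are zero; nothing to fit", call. = FALSE)
  }
  rmax_max <- 10 * max(req)
  lb <- log10(kd_bounds[1]); ub <- log10(kd_bounds[2])

  # initial KD: concentration at half-maximal response, linearly interpolated
  half <- max(req) / 2
  kd0 <- if (any(req >= half) && any(req < half)) {
    i <- which(req >= half)[1L]
    if (i == 1L) conc[1L]
    else conc[i - 1L] + (half - req[i - 1L]) *
      (conc[i] - conc[i - 1L]) / (req[i] - req[i - 1L])
  } else max(conc)
  kd0 <- min(max(kd0, kd_bounds[1]), kd_bounds[2])

  opt <- stats::optimize(ss_rss, c(lb, ub), conc = conc, req = req,
                         rmax_max = rmax_max, tol = 1e-10)
  # local refinement around the initial guess; keep whichever is better
  loc <- stats::optim(log10(kd0), ss_rss, method = "L-BFGS-B",
                      lower = lb, upper = ub,
                      conc = conc, req = req, rmax_max = rmax_max)
  best <- if (loc$value < opt$objective) {
    list(log10_kd = loc$par, rss = loc$value)
  } else {
    list(log10_kd = opt$minimum, rss = opt$objective)
  }
  # multi-start safety net: 7x7 grid over (KD, implicit Rmax) via KD starts
  starts <- seq(lb, ub, length.out = 7L)
  for (s in starts) {
    cand <- stats::optim(s, ss_rss, method = "L-BFGS-B",
                         lower = lb, upper = ub,
                         conc = conc, req = req, rmax_max = rmax_max)
    if (cand$value < best$rss - 1e-12) {
      best <- list(log10_kd = cand$par, rss = cand$value)
    }
  }
  kd <- 10^best$log10_kd
  rmax <- ss_rmax_for_kd(kd, conc, req, rmax_max)
  fitted <- rmax * conc / (conc + kd)
  structure(
    list(kd = kd, rmax = rmax,
         rmse = sqrt(mean((req - fitted)^2)),
         saturation_flag = kd > max(conc),
         conc = conc, req = req, fitted = fitted,
         kd_bounds = kd_bounds),
    class = "affinity_fit"
  )
}

#' @export
print.affinity_fit <- function(x, ...) {
  cat(sprintf("affinity_fit: KD = %.4g uM, Rmax = %.4g RU, RMSE = %.3g RU\n",
              x$kd, x$rmax, x$rmse))
  if (x$saturation_flag) {
    cat(sprintf(
      "  warning: fitted KD exceeds the highest tested concentration (%g uM);\n  the affinity lies outside the measured range and may be less accurate\n",
      max(x$conc)))
  }
  invisible(x)
}

#' @export
summary.affinity_fit <- function(object, ...) {
  cat(sprintf("Steady-state affinity fit (Req = C * Rmax / (C + KD))\n"))
  cat(sprintf("  KD   = %.4g uM\n  Rmax = %.4g RU\n", object$kd, object$rmax))
  cat(sprintf("  %d concentrations from %.4g to %.4g uM\n",
              length(object$conc), min(object$conc), max(object$conc)))
  cat(sprintf("  residual RMSE = %.4g RU\n", object$rmse))
  cat(sprintf("  saturation_flag = %s\n", object$saturation_flag))
  invisible(object)
}

#' @export
coef.affinity_fit <- function(object, ...) {
  c(KD = object$kd, Rmax = object$rmax)
}

#' @export
predict.affinity_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$conc
          else if (is.list(newdata)) newdata$conc
          else newdata
  object$rmax * conc / (conc + object$kd)
}

#' @export
residuals.affinity_fit <- function(object, ...) {
  object$req - object$fitted
}

#' @export
plot.affinity_fit <- function(x, ...) {
  graphics::plot(x$conc, x$req, log = "x",
                 xlab = "concentration (uM)", ylab = "Req (RU)",
                 main = sprintf("KD = %.3g uM", x$kd), ...)
  grid_c <- exp(seq(log(min(x$conc)), log(max(x$conc)), length.out = 200))
  graphics::lines(grid_c, predict(x, grid_c))
  graphics::abline(v = x$kd, lty = 2)
  invisible(x)
}

#' Fit replicate steady-state series and summarize KD
#'
#' Each replicate is fitted independently; the object reports the
#' per-replicate fits, the mean KD with its sample SD (the triplicate
#' convention for reporting affinities), a pooled fit over all points, and
#' the mean Rmax. Replicates that fail to fit are excluded with a warning;
#' fewer than two successful fits is an error.
#'
#' @param series_list list of `steady_state_series` (typically 3)
#' @param ... passed to [fit_steady_state()]
#' @return an `affinity_fit_set`: list with `fits`, `kd_mean`, `kd_sd`,
#'   `rmax_mean`, `pooled` (an `affinity_fit`), `saturation_flag`
#' @export
fit_triplicates <- function(series_list, ...) {
  fits <- list()
  for (i in seq_along(series_list)) {
    f <- tryCatch(fit_steady_state(series_list[[i]], ...),
                  error = function(e) e)
    if (inherits(f, "error")) {
      warning(sprintf("replicate %d failed to fit (%s); excluded",
                      i, conditionMessage(f)), call. = FALSE)
    } else {
      fits[[length(fits) + 1L]] <- f
    }
  }
  if (length(fits) < 2L) {
    stop("fewer than 2 replicates fitted successfully", call. = FALSE)
  }
  kds <- vapply(fits, `[[`, numeric(1), "kd")
  rmaxs <- vapply(fits, `[[`, numeric(1), "rmax")
  pooled <- fit_steady_state(list(
    conc = unlist(lapply(fits, `[[`, "conc")),
    req = unlist(lapply(fits, `[[`, "req"))), ...)
  structure(
    list(fits = fits, kd_mean = mean(kds), kd_sd = stats::sd(kds),
         kd_values = kds, rmax_mean = mean(rmaxs), pooled = pooled,
         saturation_flag = any(vapply(fits, `[[`, logical(1),
                                      "saturation_flag"))),
    class = "affinity_fit_set"
  )
}

#' @export
print.affinity_fit_set <- function(x, ...) {
  cat(sprintf("affinity_fit_set: %d replicates, KD = %.4g +/- %.2g uM, Rmax = %.4g RU\n",
              length(x$fits), x$kd_mean, x$kd_sd, x$rmax_mean))
  if (x$saturation_flag) {
    cat("  warning: at least one replicate fitted KD above the tested concentration range\n")
  }
  invisible(x)
}

#' @export
coef.affinity_fit_set <- function(object, ...) {
  c(KD = object$kd_mean, KD_sd = object$kd_sd, Rmax = object$rmax_mean)
}
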