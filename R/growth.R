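#' Logistic growth curve, closed form
#'
#' Density at time `t` under logistic growth:
#' `N(t) = K / (1 + ((K - N0)/N0) * exp(-r * t))`.
#'
#' @param t time, hours (vector).
#' @param K carrying capacity (same units as `N0`).
#' @param r intrinsic growth rate, per hour.
#' @param N0 initial density, `0 < N0 < K`.
#' @return density at each `t`, same units as `K`.
#' @export
#' @examples
#' logistic_od(0:24, K = 1, r = 0.5, N0 = 0.01)
logistic_od <- function(t, K, r, N0) {
  K / (1 + ((K - N0) / N0) * exp(-r * t))
}

#' Construct a growth curve from an optical-density time series
#'
#' Bundles one well's plate-reader readings with its identity. Times must be
#' strictly increasing and at least four points are required for a logistic
#' fit downstream.
#'
#' @param time time points, hours, strictly increasing.
#' @param od optical-density readings aligned to `time`; finite.
#' @param sample_id,strain_id identifiers carried through to fit tables.
#' @param media_id `"fresh"` or `"spent:<strain>"`.
#' @return an object of class `growth_curve` (a list with the validated
#'   fields).
#' @export
growth_curve <- function(time, od, sample_id = "sample", strain_id = NA_character_,
                         media_id = "fresh") {
  time <- as.numeric(time)
  od <- as.numeric(od)
  if (length(time) != length(od))
    stop("`time` and `od` must have the same length")
  if (length(time) < 4L)
    stop("a growth curve needs at least 4 time points, got ", length(time))
  if (any(!is.finite(time)) || any(!is.finite(od)))
    stop("`time` and `od` must be finite")
  if (any(diff(time) <= 0))
    stop("`time` must be strictly increasing")
  structure(list(time = time, od = od, sample_id = sample_id,
                 strain_id = strain_id, media_id = media_id),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("Growth curve", x$sample_id,
      sprintf("(strain %s, media %s): %d points over %.1f h, max OD %.3g\n",
              x$strain_id, x$media_id, length(x$time), max(x$time), max(x$od)))
  invisible(x)
}

#' Subtract a constant blank from OD readings
#'
#' Optional blank correction; corrected values are floored at `1e-6` so that
#' log-phase slopes stay defined.
#'
#' @param od optical-density readings (or a `growth_curve`).
#' @param blank constant blank OD to subtract.
#' @return corrected readings (or curve).
#' @export
blank_correct <- function(od, blank = 0) {
  if (inherits(od, "growth_curve")) {
    od$od <- pmax(od$od - blank, 1e-6)
    return(od)
  }
  pmax(od - blank, 1e-6)
}

#' Fit a logistic growth model to an OD time series
#'
#' Nonlinear least squares of `K / (1 + ((K - N0)/N0) exp(-r t))` against the
#' readings, via Levenberg-Marquardt with positivity bounds. Starting values:
#' `K` from the maximum OD, `N0` from the first positive reading, `r` from the
#' log-linear slope of the early phase. A flat or declining series, or a fit
#' with non-positive rate, is returned with `converged = FALSE` rather than
#' an error.
#'
#' @param curve a [growth_curve()] (or a list with `time` and `od`).
#' @param blank optional constant blank OD subtracted (floored at 1e-6)
#'   before fitting.
#' @return an object of class `logistic_fit`: estimates `K`, `r`, `N0`, the
#'   residual sum of squares `sse`, `converged`, a `reason` when not
#'   converged, `max_od`, and the data.
#' @seealso [coef.logistic_fit()], [predict.logistic_fit()],
#'   [plot.logistic_fit()]
#' @export
#' @examples
#' tt <- seq(0, 24, by = 1/6)
#' fit <- fit_logistic(growth_curve(tt, logistic_od(tt, 1, 0.5, 0.01)))
#' coef(fit)
fit_logistic <- function(curve, blank = 0) {
  if (!inherits(curve, "growth_curve"))
    curve <- growth_curve(curve$time, curve$od)
  if (blank != 0) curve <- blank_correct(curve, blank)
  tt <- curve$time
  od <- curve$od

  failed <- function(reason) {
    structure(list(K = NA_real_, r = NA_real_, N0 = NA_real_,
                   sse = NA_real_, converged = FALSE, reason = reason,
                   max_od = max(od), curve = curve, fitted = NULL),
              class = "logistic_fit")
  }

  # no-growth screen: series never rises appreciably above its start
  rng <- max(od) - min(od)
  slope <- unname(coef(lm(od ~ tt))[2])
  if (rng <= .Machine$double.eps * 10 || (max(od) - od[1]) <= 0 || slope <= 0)
    return(failed("no growth detected"))

  K0 <- max(od)
  N00 <- max(od[od > 0][1], 1e-6)
  # early-phase rate from log-OD slope over the first rise to ~half max
  early <- which(od > 0 & od <= (N00 + K0) / 2)
  if (length(early) < 3L) early <- seq_len(min(6L, length(tt)))
  r0 <- unname(coef(lm(log(od[early]) ~ tt[early]))[2])
  if (!is.finite(r0) || r0 <= 0) r0 <- 0.1

  fit <- tryCatch(
    minpack.lm::nlsLM(
      od ~ K / (1 + ((K - N0) / N0) * exp(-r * tt)),
      start = list(K = K0, r = r0, N0 = N00),
      lower = c(K = 1e-8, r = 1e-8, N0 = 1e-10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed("optimizer failed"))

  est <- coef(fit)
  if (!all(is.finite(est)) || est["r"] <= 0)
    return(failed("no growth detected"))
  if (est["N0"] >= est["K"])
    return(failed("degenerate fit (N0 >= K)"))

  fv <- logistic_od(tt, est["K"], est["r"], est["N0"])
  structure(list(K = unname(est["K"]), r = unname(est["r"]),
                 N0 = unname(est["N0"]), sse = sum((od - fv)^2),
                 converged = TRUE, reason = NULL,
                 max_od = max(od), curve = curve, fitted = fv),
            class = "logistic_fit")
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(K = object$K, r = object$r, N0 = object$N0)
}

#' @export
fitted.logistic_fit <- function(object, ...) object$fitted

#' @export
residuals.logistic_fit <- function(object, ...) {
  if (!object$converged) return(NULL)
  object$curve$od - object$fitted
}

#' Predict OD from a fitted logistic model
#'
#' @param object a `logistic_fit`.
#' @param times time points (hours); defaults to the observed times.
#' @param ... unused.
#' @return predicted OD values.
#' @export
predict.logistic_fit <- function(object, times = object$curve$time, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  logistic_od(times, object$K, object$r, object$N0)
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Logistic fit [%s]: K = %.4g, r = %.4g /h, N0 = %.4g (SSE %.3g)\n",
                x$curve$sample_id, x$K, x$r, x$N0, x$sse))
  } else {
    cat(sprintf("Logistic fit [%s]: not converged (%s); max OD %.4g\n",
                x$curve$sample_id, x$reason, x$max_od))
  }
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  print(object)
  if (object$converged) {
    res <- residuals(object)
    cat(sprintf("  %d points, residual SD %.3g, max OD %.4g\n",
                length(res), sd(res), object$max_od))
    cat(sprintf("  doubling time %.2f h at low density\n", log(2) / object$r))
  }
  invisible(object)
}

#' @export
plot.logistic_fit <- function(x, ...) {
  plot(x$curve$time, x$curve$od, xlab = "time (h)", ylab = "OD",
       main = x$curve$sample_id, pch = 16, cex = 0.5, ...)
  if (x$converged) {
    tt <- seq(min(x$curve$time), max(x$curve$time), length.out = 200)
    lines(tt, predict(x, tt), col = "red3", lwd = 2)
  }
  invisible(x)
}

#' Fit logistic models to every well of a plate
#'
#' @param plate long-form plate-reader table with columns `time_h`, `well`,
#'   `od` (see [read_plate_csv()]).
#' @param map plate map with columns `well`, `strain_id`, `media_id`,
#'   `replicate`.
#' @param blank constant blank OD subtracted before fitting.
#' @return a data frame with one row per well: `sample_id`, `strain_id`,
#'   `media_id`, `K_fit`, `r_fit`, `N0_fit`, `sse`, `converged`, `max_od`.
#' @export
fit_plate <- function(plate, map, blank = 0) {
  wells <- unique(plate$well)
  rows <- lapply(wells, function(w) {
    sub <- plate[plate$well == w, ]
    sub <- sub[order(sub$time_h), ]
    m <- map[map$well == w, , drop = FALSE]
    strain <- if (nrow(m)) m$strain_id[1] else NA_character_
    media <- if (nrow(m)) m$media_id[1] else NA_character_
    f <- fit_logistic(growth_curve(sub$time_h, sub$od, sample_id = w,
                                   strain_id = strain, media_id = media),
                      blank = blank)
    data.frame(sample_id = w, strain_id = strain, media_id = media,
               K_fit = f$K, r_fit = f$r, N0_fit = f$N0, sse = f$sse,
               converged = f$converged, max_od = f$max_od,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spent-media growth difference
#'
#' The resource-overlap metric used for spent-media assays: growth in spent
#' media divided by growth in unspent (fresh) media, minus 1. Zero means the
#' strain grows equally well in both; -1 means no growth in spent media;
#' positive values mean it grows better in spent media.
#'
#' @param growth_in_spent,growth_in_fresh the same growth metric (maximum OD
#'   by convention; fitted rate also meaningful) measured in spent and fresh
#'   media. `growth_in_fresh` must be positive.
#' @return `growth_in_spent / growth_in_fresh - 1`.
#' @export
#' @examples
#' spent_media_difference(0.4, 0.8)  # -0.5: halved growth in spent media
spent_media_difference <- function(growth_in_spent, growth_in_fresh) {
  if (any(growth_in_fresh <= 0))
    stop("`growth_in_fresh` must be positive")
  growth_in_spent / growth_in_fresh - 1
}

#' Summarise replicate growth rates for a strain
#'
#' @param strain_id strain identifier.
#' @param r_values fitted intrinsic growth rates (per hour) across
#'   replicates; at least 2 are needed for the standard deviation used by the
#'   outcome prediction rule.
#' @return an object of class `growth_rate_summary` with `mean_r`, `sd_r`,
#'   `n_replicates`.
#' @export
growth_rate_summary <- function(strain_id, r_values) {
  r_values <- r_values[is.finite(r_values)]
  n <- length(r_values)
  if (n < 1L) stop("no finite growth rates for ", strain_id)
  structure(list(strain_id = strain_id, mean_r = mean(r_values),
                 sd_r = if (n >= 2L) sd(r_values) else NA_real_,
                 n_replicates = n),
            class = "growth_rate_summary")
}

#' @export
print.growth_rate_summary <- function(x, ...) {
  cat(sprintf("%s: r = %.3g +/- %.3g /h (n = %d)\n",
              x$strain_id, x$mean_r, x$sd_r, x$n_replicates))
  invisible(x)
}

#' Predict a pairwise competition outcome from growth rates
#'
#' The one-standard-deviation rule: a competitor whose mean growth rate
#' exceeds the focal strain's mean by more than one (focal) standard
#' deviation is predicted to exclude it; the mirrored rule applies in the
#' other direction against the competitor's standard deviation; otherwise
#' the two strains are predicted to coexist. A difference of exactly one
#' standard deviation counts as "within", hence coexistence.
#'
#' @param competitor,focal [growth_rate_summary()] objects with at least two
#'   replicates each.
#' @return one of `"competitor_excludes_focal"`,
#'   `"focal_excludes_competitor"`, `"coexist"`.
#' @export
predict_pairwise_outcome <- function(competitor, focal) {
  for (s in list(competitor, focal)) {
    if (!inherits(s, "growth_rate_summary"))
      stop("arguments must be growth_rate_summary objects")
    if (s$n_replicates < 2L || !is.finite(s$sd_r))
      stop("sd_r undefined for ", s$strain_id, " (need >= 2 replicates)")
  }
  if (competitor$mean_r > focal$mean_r + focal$sd_r)
    return("competitor_excludes_focal")
  if (focal$mean_r > competitor$mean_r + competitor$sd_r)
    return("focal_excludes_competitor")
  "coexist"
}
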