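# Downstream ensemble machinery: empirical-quantile prediction bands,
# parameter correlations, trajectory features, and coverage statistics.

#' Empirical-quantile prediction band
#'
#' Pointwise-in-time band from an ensemble of trajectories: at each time the
#' ensemble mean and the (1 - level)/2 and 1 - (1 - level)/2 empirical
#' quantiles (linear interpolation between order statistics,
#' \code{stats::quantile} type 7). These are empirical quantiles of the
#' ensemble predictions, not Bayesian credible intervals.
#'
#' @param trajectories Numeric matrix, one row per ensemble member, one
#'   column per time point (>= 2 members).
#' @param times Optional time vector (defaults to column index).
#' @param level Band level in (0, 1), default 0.95.
#' @return A data.frame of class \code{"poets_band"} with columns
#'   \code{time}, \code{mean}, \code{lower}, \code{upper} and attribute
#'   \code{"level"}.
#' @export
prediction_band <- function(trajectories, times = NULL, level = 0.95) {
  X <- as.matrix(trajectories)
  if (nrow(X) < 2L) {
    stop("at least 2 ensemble members are required", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(times)) times <- seq_len(ncol(X))
  if (length(times) != ncol(X)) {
    stop("times length must match the trajectory grid", call. = FALSE)
  }
  p <- (1 - level) / 2
  out <- data.frame(time = as.numeric(times),
                    mean = colMeans(X),
                    lower = apply(X, 2, quantile, probs = p, names = FALSE),
                    upper = apply(X, 2, quantile, probs = 1 - p,
                                  names = FALSE))
  attr(out, "level") <- level
  class(out) <- c("poets_band", "data.frame")
  out
}

#' @export
plot.poets_band <- function(x, truth = NULL, xlab = "time", ylab = "value",
                            main = NULL, ...) {
  rng <- range(x$lower, x$upper, truth)
  plot(x$time, x$mean, type = "n", ylim = rng, xlab = xlab, ylab = ylab,
       main = main, ...)
  polygon(c(x$time, rev(x$time)), c(x$lower, rev(x$upper)),
          col = adjustcolor("steelblue", 0.3), border = NA)
  lines(x$time, x$mean, col = "steelblue", lwd = 2, lty = 2)
  if (!is.null(truth)) lines(x$time, truth, col = "black", lwd = 1.5)
  invisible(x)
}

#' Pairwise parameter correlations of an ensemble
#'
#' Pearson correlations across ensemble members, computed on the scale the
#' search operated on (log10 for log-space problems), since compensatory
#' couplings between rate constants are linear on that scale. Constant
#' columns have undefined correlation and are reported as \code{NA} (the
#' diagonal stays 1).
#'
#' @param params Numeric matrix, members x parameters (>= 3 members).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
parameter_correlations <- function(params) {
  P <- as.matrix(params)
  if (nrow(P) < 3L) stop("at least 3 ensemble members are required",
                         call. = FALSE)
  constant <- apply(P, 2, function(v) isTRUE(all.equal(min(v), max(v))) ||
                      sd(v) == 0)
  R <- suppressWarnings(cor(P))
  R[constant, ] <- NA_real_
  R[, constant] <- NA_real_
  diag(R) <- 1
  R
}

#' Trajectory features: lag time, peak, time to peak, AUC
#'
#' Summarises a non-negative trajectory by its onset, amplitude and total
#' exposure: \code{peak_value} is the maximum, \code{time_to_peak} the time
#' of its first attainment, \code{auc} the trapezoidal integral over the full
#' grid (the "endogenous potential" style area statistic), and
#' \code{lag_time} the first time the trajectory crosses
#' \code{lag_fraction * peak_value} (linear interpolation between samples).
#' The 5% default threshold is a package convention; it is exposed as a
#' parameter.
#'
#' @param times Strictly increasing time vector.
#' @param values Non-negative trajectory values on that grid.
#' @param lag_fraction Threshold fraction of the peak (default 0.05).
#' @return A list of class \code{"trajectory_features"} with elements
#'   \code{lag_time}, \code{peak_value}, \code{time_to_peak}, \code{auc};
#'   an all-zero trajectory yields all-zero features with attribute
#'   \code{"degenerate" = TRUE}.
#' @export
trajectory_features <- function(times, values, lag_fraction = 0.05) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values) || length(times) < 2L) {
    stop("times and values must have equal length >= 2", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) stop("values must be non-negative", call. = FALSE)
  out <- list(lag_time = 0, peak_value = 0, time_to_peak = 0, auc = 0)
  class(out) <- "trajectory_features"
  if (all(values == 0)) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  peak <- max(values)
  i_peak <- which.max(values)
  auc <- sum(diff(times) * (head(values, -1) + tail(values, -1)) / 2)
  thresh <- lag_fraction * peak
  lag <- times[1]
  if (values[1] < thresh) {
    i <- which(values >= thresh)[1]
    lag <- times[i - 1] + (thresh - values[i - 1]) /
      (values[i] - values[i - 1]) * (times[i] - times[i - 1])
  }
  out$lag_time <- lag
  out$peak_value <- peak
  out$time_to_peak <- times[i_peak]
  out$auc <- auc
  out
}

#' @export
print.trajectory_features <- function(x, ...) {
  cat(sprintf("lag_time = %g, peak_value = %g, time_to_peak = %g, auc = %g\n",
              x$lag_time, x$peak_value, x$time_to_peak, x$auc))
  invisible(x)
}

#' Band coverage of a truth trajectory
#'
#' Fraction of time points at which the truth lies inside the band
#' (inclusive bounds).
#'
#' @param band A \code{\link{prediction_band}} result.
#' @param truth Truth values on the same time grid.
#' @return A scalar in [0, 1].
#' @export
coverage_rate <- function(band, truth) {
  stopifnot(inherits(band, "poets_band"))
  truth <- as.numeric(truth)
  if (length(truth) != nrow(band)) {
    stop("truth must be on the band's time grid", call. = FALSE)
  }
  mean(band$lower <= truth & truth <= band$upper)
}

#' Interval membership of a scalar feature
#'
#' @param interval Length-2 numeric (lower, upper).
#' @param truth_value Scalar to test.
#' @return Logical: is the value inside the interval (inclusive)?
#' @export
feature_covered <- function(interval, truth_value) {
  interval <- as.numeric(interval)
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  interval[1] <= truth_value && truth_value <= interval[2]
}
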