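#' Fluorogenic folding-assay kinetic trace
#'
#' A time/intensity series from an OmpT-type fluorogenic folding assay
#' (fluorescence excitation 325 nm / emission 430 nm, typically read every
#' 10 s for up to 5 h). Times must be strictly increasing and the series
#' at least 10 points long.
#'
#' @param times Numeric vector of times in seconds, strictly increasing.
#' @param intensities Fluorescence intensities (arbitrary units).
#' @param label Condition label (e.g. `"WT"`, `"Q-MUT"`).
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, intensities, label = "") {
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities)) stop("times/intensities length mismatch")
  if (length(times) < 10) stop("trace too short (need >= 10 points)")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(times)) || !all(is.finite(intensities))) {
    stop("non-finite values in trace")
  }
  structure(list(times = times, intensities = intensities, label = label),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> '%s': %d points, t = %g..%g s, I = %.3g..%.3g\n",
              x$label, length(x$times), min(x$times), max(x$times),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Read kinetic traces from a delimited file
#'
#' Expects columns `time`, `intensity` and optionally `condition`; one
#' trace per condition value (or a single unlabelled trace).
#'
#' @param path CSV/TSV file path.
#' @param sep Field separator (default `,`).
#' @return List of [kinetic_trace()] objects.
#' @export
read_traces <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  if (!all(c("time", "intensity") %in% names(d))) {
    stop("trace file needs 'time' and 'intensity' columns")
  }
  if ("condition" %in% names(d)) {
    lapply(split(d, d$condition), function(g) {
      kinetic_trace(g$time, g$intensity, label = g$condition[1])
    })
  } else {
    list(kinetic_trace(d$time, d$intensity))
  }
}

#' Background-normalize a trace
#'
#' Subtracts the mean of the background traces' zero-time intensities from
#' every point of the trace; times are untouched.
#'
#' @param trace A [kinetic_trace()].
#' @param background_traces Non-empty list of background [kinetic_trace()]s
#'   (a single trace is also accepted).
#' @return Normalized [kinetic_trace()].
#' @export
normalize_trace <- function(trace, background_traces) {
  if (inherits(background_traces, "kinetic_trace")) {
    background_traces <- list(background_traces)
  }
  if (length(background_traces) == 0) stop("no background traces given")
  bg0 <- vapply(background_traces, function(b) b$intensities[1], numeric(1))
  kinetic_trace(trace$times, trace$intensities - mean(bg0),
                label = trace$label)
}

## least-squares slope of y on x, closed form
ls_slope <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  sum((x - xm) * (y - ym)) / sum((x - xm)^2)
}

#' Fit the plateau baseline of a trace
#'
#' The plateau is the longest trailing window of the trace whose
#' least-squares slope is statistically compatible with the tolerance
#' (|slope| at most `slope_tol` plus twice its standard error) and whose
#' length is at least `min_points`; a straight line is then fitted over
#' that window.
#' The default tolerance is 1 percent of the trace's maximum rise rate,
#' where the rise rate is estimated as the largest least-squares slope
#' over sliding windows of about a twentieth of the trace — a noise-robust
#' stand-in for the maximum pointwise rate (raw forward differences are
#' dominated by noise at realistic signal-to-noise).
#'
#' @param trace A [kinetic_trace()].
#' @param slope_tol Absolute slope tolerance (a.u./s); `NULL` for the
#'   default above.
#' @param min_points Minimum plateau length in samples (default 20).
#' @return List with `plateau_start_index`, `intercept`, `slope`,
#'   `slope_tol`, `max_rate`; class `plateau_fit`.
#' @export
fit_plateau_baseline <- function(trace, slope_tol = NULL, min_points = 20) {
  t <- trace$times; y <- trace$intensities
  n <- length(t)
  if (n < min_points) stop("trace shorter than min_points")
  max_rate <- max_rise_rate(t, y)
  if (is.null(slope_tol)) slope_tol <- 0.01 * max_rate
  ## trailing-window slopes via cumulative sums (window i..n); a window
  ## qualifies when its slope is statistically compatible with the
  ## tolerance (|b| <= tol + 2 se), so noisy short windows whose slope
  ## merely cannot be estimated below tol are not rejected
  cs_t <- rev(cumsum(rev(t))); cs_y <- rev(cumsum(rev(y)))
  cs_tt <- rev(cumsum(rev(t * t))); cs_ty <- rev(cumsum(rev(t * y)))
  cs_yy <- rev(cumsum(rev(y * y)))
  m <- n:1
  sxx <- cs_tt - cs_t^2 / m
  sxy <- cs_ty - cs_t * cs_y / m
  syy <- cs_yy - cs_y^2 / m
  slope_i <- sxy / sxx          # slope of window starting at i
  rss <- pmax(syy - slope_i * sxy, 0)
  se_i <- sqrt(rss / (pmax(m - 2, 1) * sxx))
  ok <- abs(slope_i) <= slope_tol + 2 * se_i & m >= min_points
  ok[!is.finite(slope_i)] <- FALSE
  if (!any(ok)) stop("no plateau detected (no trailing window with |slope| <= ",
                     signif(slope_tol, 3), " a.u./s)")
  i0 <- which(ok)[1]            # smallest start index = longest window
  idx <- i0:n
  b <- ls_slope(t[idx], y[idx])
  a <- mean(y[idx]) - b * mean(t[idx])
  structure(list(plateau_start_index = i0, intercept = a, slope = b,
                 slope_tol = slope_tol, max_rate = max_rate,
                 min_points = min_points),
            class = "plateau_fit")
}

## maximum rise rate: largest least-squares slope over sliding windows of
## ~n/20 samples (minimum 5); exact for noise-free monotone traces up to
## window smearing, robust to point noise otherwise
max_rise_rate <- function(t, y) {
  n <- length(t)
  w <- max(5, round(n / 20))
  if (w >= n) w <- n - 1
  ## windowed LS slopes via cumulative sums: window j..j+w-1
  cs <- function(v) c(0, cumsum(v))
  win <- function(cv, j) cv[j + w] - cv[j]
  j <- seq_len(n - w + 1)
  st <- cs(t); sy <- cs(y); stt <- cs(t * t); sty <- cs(t * y)
  sxx <- win(stt, j) - win(st, j)^2 / w
  sxy <- win(sty, j) - win(st, j) * win(sy, j) / w
  max(abs(sxy / sxx))
}

#' Half-time of a folding trace
#'
#' The plateau level is the fitted baseline evaluated at the centroid of
#' the plateau window — the minimum-variance point of the fit, robust to
#' noise spikes and much less biased by residual late rise than the
#' window edges. The half-time is the earliest time at which the trace
#' crosses half that level: the crossing is located on a lightly
#' median-smoothed copy of the trace and then refined by a local
#' least-squares line through the samples bracketing it, whose
#' intersection with the half level is reported (for symmetric noise this
#' estimate is unbiased, unlike the raw first sample-to-sample crossing,
#' which fires systematically early when the noise exceeds the per-sample
#' rise).
#'
#' @param trace A [kinetic_trace()] (normalized so the signal starts near
#'   zero).
#' @param fit A [fit_plateau_baseline()] result; computed with defaults
#'   when omitted.
#' @return An object of class `half_time_result`: list with `half_time`
#'   (s), `plateau_level` (a.u.), `baseline_slope` (a.u./s),
#'   `plateau_start_index`, `label`.
#' @export
half_time <- function(trace, fit = NULL) {
  if (is.null(fit)) fit <- fit_plateau_baseline(trace)
  t <- trace$times; y <- trace$intensities
  n <- length(t)
  idx <- fit$plateau_start_index:n
  plateau_level <- fit$intercept + fit$slope * mean(t[idx])
  target <- plateau_level / 2
  sm <- if (n >= 11) as.numeric(stats::runmed(y, 5, endrule = "median")) else y
  if (sm[1] >= target) stop("trace does not start below half-plateau")
  above <- which(sm >= target)
  if (length(above) == 0) stop("trace never reaches half-plateau")
  j <- above[1]
  ## refine with a local least-squares line about the crossing; the window
  ## is re-centred on each new estimate so the final fit brackets the true
  ## crossing even when the initial smoothed crossing fires early
  jc <- j
  th <- NA_real_
  for (it in 1:5) {
    w <- max(3, round(0.15 * jc))
    lo <- max(1, jc - w); hi <- min(n, jc + w)
    if (hi - lo < 2) break
    cf <- stats::lm.fit(cbind(1, t[lo:hi]), y[lo:hi])$coefficients
    if (!is.finite(cf[2]) || cf[2] <= 0) break
    th_new <- min(max((target - cf[1]) / cf[2], t[1]), t[n])
    jc_new <- which.min(abs(t - th_new))
    th <- th_new
    if (jc_new == jc) break
    jc <- jc_new
  }
  if (!is.finite(th)) {
    ## degenerate local fit: plain interpolation on the smoothed trace
    th <- if (j == 1) t[1] else {
      t[j - 1] + (target - sm[j - 1]) / (sm[j] - sm[j - 1]) *
        (t[j] - t[j - 1])
    }
  }
  structure(list(half_time = th, plateau_level = plateau_level,
                 baseline_slope = fit$slope,
                 plateau_start_index = fit$plateau_start_index,
                 label = trace$label),
            class = "half_time_result")
}

#' @export
print.half_time_result <- function(x, ...) {
  cat(sprintf("<half_time_result> '%s': t1/2 = %.1f s, plateau %.3g a.u. (slope %.2g a.u./s)\n",
              x$label, x$half_time, x$plateau_level, x$baseline_slope))
  invisible(x)
}

#' Summarize half-times by condition
#'
#' @param results List of [half_time()] results, or a data frame with
#'   `condition` and `half_time` columns.
#' @return Data frame with `condition`, `n`, `mean_half_time`, `sem`
#'   (sd/sqrt(n), `NA` for n = 1).
#' @export
summarize_conditions <- function(results) {
  if (is.data.frame(results)) {
    d <- results
  } else {
    d <- data.frame(
      condition = vapply(results, function(r) r$label, character(1)),
      half_time = vapply(results, function(r) r$half_time, numeric(1))
    )
  }
  groups <- split(d$half_time, d$condition)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (length(v) == 0) {
      warning("empty condition group '", g, "' skipped")
      return(NULL)
    }
    data.frame(condition = g, n = length(v), mean_half_time = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
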