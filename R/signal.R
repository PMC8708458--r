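# Conditioning of raw sensor maneuvers. Canonical order (enforced by
# conditionFrame): remove resonances -> zero-phase Butterworth low-pass ->
# linear detrend -> ambient-air correction -> landmark extraction.
# Conditioning never changes the number of samples or the time axis.

.frameFs <- function(frame) 1 / mean(diff(frame@time))

.applyChannels <- function(frame, fun, ambientToo = TRUE) {
  breath <- apply(frame@breath, 2, fun)
  ambient <- if (ambientToo) apply(frame@ambient, 2, fun) else frame@ambient
  dimnames(breath) <- dimnames(frame@breath)
  dimnames(ambient) <- dimnames(frame@ambient)
  initialize(frame, breath = breath, ambient = ambient)
}

#' Remove narrow resonance bands from all channels
#'
#' Attenuates the stated eigenfrequency bands with a zero-phase (two-pass)
#' order-2 Butterworth band-stop filter per frequency. Applied to breath and
#' ambient channels alike; length and time axis are unchanged.
#'
#' @param frame a [SensorFrame-class].
#' @param frequencies notch center frequencies in Hz (may be empty).
#' @param bandwidth full stop-band width in Hz.
#' @return the filtered [SensorFrame-class].
#' @export
removeResonances <- function(frame, frequencies, bandwidth = 0.1) {
  stopifnot(is(frame, "SensorFrame"), bandwidth > 0)
  if (length(frequencies) == 0L) return(frame)
  fs <- .frameFs(frame)
  nyq <- fs / 2
  bad <- frequencies[frequencies >= nyq]
  if (length(bad))
    stop(sprintf("notch frequency %.3g Hz is at or above the Nyquist frequency (%.3g Hz)",
                 bad[1], nyq))
  for (f in frequencies) {
    lo <- max(f - bandwidth / 2, 1e-6) / nyq
    hi <- min(f + bandwidth / 2, nyq * (1 - 1e-6)) / nyq
    filt <- signal::butter(2, c(lo, hi), type = "stop")
    frame <- .applyChannels(frame, function(x) .filtfiltDC(filt, x))
  }
  frame
}

# zero-phase filtering around the series mean: the filters used here have
# unit DC gain, so filtering the deviations and restoring the mean is
# exact for the passband while avoiding the edge transient a nonzero
# baseline would otherwise excite
.filtfiltDC <- function(filt, x) {
  m <- mean(x)
  signal::filtfilt(filt, x - m) + m
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass with the given cutoff in a
#' forward and a backward pass (zero phase), so landmark times are not
#' shifted. The effective magnitude response is the squared single-pass
#' response `|H(f)|^2 = 1 / (1 + (f/fc)^(2*order))`.
#'
#' @param frame a [SensorFrame-class].
#' @param cutoff half-power cutoff in Hz (single pass), `0 < cutoff < Nyquist`.
#' @param order filter order (>= 1).
#' @return the filtered [SensorFrame-class].
#' @export
lowpassFilter <- function(frame, cutoff = 0.5, order = 2) {
  stopifnot(is(frame, "SensorFrame"), order >= 1)
  fs <- .frameFs(frame)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop(sprintf("cutoff must lie in (0, %.3g) Hz", fs / 2))
  filt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  .applyChannels(frame, function(x) .filtfiltDC(filt, x))
}

# least-squares straight line over the whole series
.lsLine <- function(t, x) {
  tc <- t - mean(t)
  b <- sum(tc * x) / sum(tc * tc)
  a <- mean(x) - b * mean(t)
  a + b * t
}

#' Remove the linear trend from every channel
#'
#' Subtracts, per channel, the least-squares straight line fitted over the
#' whole maneuver.
#'
#' @param frame a [SensorFrame-class] (>= 2 samples).
#' @return the detrended [SensorFrame-class].
#' @export
detrendLinear <- function(frame) {
  stopifnot(is(frame, "SensorFrame"))
  t <- frame@time
  .applyChannels(frame, function(x) x - .lsLine(t, x))
}

# shift a series by `lag` samples (positive lag = take later samples),
# replicating edge values to keep the length
.shiftSeries <- function(x, lag) {
  n <- length(x)
  if (lag == 0) return(x)
  if (lag > 0) c(x[(1 + lag):n], rep(x[n], lag))
  else c(rep(x[1], -lag), x[1:(n + lag)])
}

#' Ambient-air correction by cross-correlation alignment
#'
#' For each sensor, finds the lag (over `-maxLag..+maxLag`, in whole
#' samples) that maximizes the cross-correlation between the breath and the
#' ambient series, aligns the ambient series at that lag and subtracts it
#' from the breath series. The result (breath minus aligned ambient) is the
#' working alveolar-gradient signal: the component of the response
#' attributable to exhaled rather than inspired air. A positive lag means
#' the ambient channel trails the breath channel.
#'
#' Channels where either series has zero variance fall back to lag 0 and are
#' flagged. Chosen lags (seconds) and flags are recorded in the returned
#' frame's metadata (`ambientLags`, `ambientFlags`).
#'
#' Lag estimation only (not the subtraction) uses copies of both series
#' passed through a zero-phase high-pass at `alignHighpass`: the slow
#' maneuver waveform carries no alignment information about the shared
#' ambient component and would otherwise bias the correlation peak, a
#' standard prewhitening step in time-delay estimation. Set
#' `alignHighpass = 0` to correlate the raw series.
#'
#' @param frame a [SensorFrame-class].
#' @param maxLag lag search half-window in seconds (< maneuver duration / 2).
#' @param alignHighpass high-pass cutoff (Hz) of the alignment prefilter.
#' @return a [SensorFrame-class] whose breath channels are ambient-corrected.
#' @export
ambientCorrect <- function(frame, maxLag = 2, alignHighpass = 0.15) {
  stopifnot(is(frame, "SensorFrame"))
  dur <- diff(range(frame@time))
  if (maxLag >= dur / 2) stop("maxLag must be below half the maneuver duration")
  fs <- .frameFs(frame)
  n0 <- length(frame@time)
  L <- min(round(maxLag * fs), floor((n0 - 2) / 2))
  lags <- -L:L
  n <- length(frame@time)
  corrected <- frame@breath
  chosen <- numeric(7)
  flags <- character(7)
  hp <- NULL
  if (alignHighpass > 0 && alignHighpass < fs / 2)
    hp <- signal::butter(2, alignHighpass / (fs / 2), type = "high")
  for (s in 1:7) {
    b <- frame@breath[, s]
    a <- frame@ambient[, s]
    balign <- if (is.null(hp)) b else signal::filtfilt(hp, b)
    aalign <- if (is.null(hp)) a else signal::filtfilt(hp, a)
    if (sd(b) == 0 || sd(a) == 0) {
      chosen[s] <- 0
      flags[s] <- "zero-variance channel; lag fixed at 0"
      corrected[, s] <- b - a
      next
    }
    # full-window correlation with the same edge-padded shift used for the
    # subtraction, so the scored alignment is exactly the one applied
    cc <- vapply(lags, function(l) {
      ai <- .shiftSeries(aalign, l)
      if (sd(ai) == 0) -Inf else cor(balign, ai)
    }, numeric(1))
    best <- lags[which.max(cc)]
    chosen[s] <- best / fs
    flags[s] <- ""
    corrected[, s] <- b - .shiftSeries(a, best)
    # shifting a detrended series reintroduces a linear component, so the
    # gradient signal is reported trend-free: the line is fitted on the
    # interior (excluding the lag window at each end, where shift padding
    # and filter transients live) and subtracted over the full window
    inner <- (L + 1):(n - L)
    tc <- frame@time[inner] - mean(frame@time[inner])
    slope <- sum(tc * corrected[inner, s]) / sum(tc * tc)
    level <- mean(corrected[inner, s]) - slope * mean(frame@time[inner])
    corrected[, s] <- corrected[, s] - (level + slope * frame@time)
  }
  md <- frame@metadata
  md$ambientLags <- setNames(chosen, colnames(frame@breath))
  md$ambientFlags <- setNames(flags, colnames(frame@breath))
  initialize(frame, breath = corrected, metadata = md)
}

.phaseWindow <- function(frame, phase) {
  ph <- frame@phases[frame@phases$phase == phase, , drop = FALSE]
  if (!nrow(ph)) stop("maneuver has no '", phase, "' phase")
  idx <- which(frame@time >= min(ph$t_start) - 1e-9 &
               frame@time <= max(ph$t_end) + 1e-9)
  if (!length(idx)) stop("no samples fall inside the '", phase, "' phase")
  idx
}

#' Locate the expiration peak and breath-hold trough per sensor
#'
#' The peak is the maximum of the (conditioned) breath signal within the
#' expiration phase; the trough is the minimum within the breath-hold
#' phase. Ties are broken by the earliest time. A sensor whose trough is
#' non-positive (no finite peak/trough ratio) is flagged and the subject is
#' marked non-evaluable.
#'
#' @param frame a conditioned [SensorFrame-class].
#' @return data.frame with one row per sensor: `sensor`, `peak_value`,
#'   `peak_time`, `trough_value`, `trough_time`, `evaluable`; attributes
#'   `subjectID` and `evaluable` (all sensors evaluable) are attached.
#' @export
findLandmarks <- function(frame) {
  stopifnot(is(frame, "SensorFrame"))
  iExp <- .phaseWindow(frame, "expiration")
  iHold <- .phaseWindow(frame, "breath_hold")
  res <- data.frame(sensor = 1:7, peak_value = NA_real_, peak_time = NA_real_,
                    trough_value = NA_real_, trough_time = NA_real_,
                    evaluable = TRUE)
  for (s in 1:7) {
    x <- frame@breath[, s]
    ip <- iExp[which.max(x[iExp])]
    it <- iHold[which.min(x[iHold])]
    res$peak_value[s] <- x[ip]
    res$peak_time[s] <- frame@time[ip]
    res$trough_value[s] <- x[it]
    res$trough_time[s] <- frame@time[it]
    if (x[it] <= 0) res$evaluable[s] <- FALSE
  }
  attr(res, "subjectID") <- frame@subjectID
  attr(res, "evaluable") <- all(res$evaluable)
  res
}

#' Condition one maneuver with the canonical pipeline
#'
#' Applies, in the fixed canonical order: resonance removal (if any notch
#' frequencies are configured), zero-phase Butterworth low-pass, linear
#' detrending and cross-correlation ambient correction.
#'
#' @param frame a raw [SensorFrame-class].
#' @param config a [pipelineConfig()] list (fields `notchFrequencies`,
#'   `notchBandwidth`, `lowpassCutoff`, `filterOrder`, `maxLag`).
#' @return the conditioned [SensorFrame-class].
#' @export
conditionFrame <- function(frame, config = pipelineConfig()) {
  frame <- removeResonances(frame, config$notchFrequencies,
                            config$notchBandwidth)
  frame <- lowpassFilter(frame, config$lowpassCutoff, config$filterOrder)
  frame <- detrendLinear(frame)
  ambientCorrect(frame, config$maxLag,
                 alignHighpass = config$alignHighpass)
}

#' Condition a list of maneuvers and collect a report
#'
#' @param frames list of raw [SensorFrame-class] objects.
#' @param config a [pipelineConfig()] list.
#' @return list with `frames` (conditioned), `landmarks` (list of landmark
#'   tables) and `report` (data.frame of chosen ambient lags and flags per
#'   subject and sensor).
#' @export
conditionCohort <- function(frames, config = pipelineConfig()) {
  conditioned <- lapply(frames, conditionFrame, config = config)
  landmarks <- lapply(conditioned, findLandmarks)
  report <- do.call(rbind, lapply(conditioned, function(f) {
    data.frame(subject_id = f@subjectID, sensor = 1:7,
               ambient_lag_s = unname(f@metadata$ambientLags),
               flag = unname(f@metadata$ambientFlags),
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  list(frames = conditioned, landmarks = landmarks, report = report)
}
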