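#' Construct a raw EMG trial
#'
#' Bundles multichannel EMG samples with the timing information needed to
#' process one gait cycle: the sampling rate, the heel-strike events bounding
#' the cycle, and the cycle period `t_f`.
#'
#' @param samples Numeric matrix, time x channels.
#' @param channel_names Character vector naming the columns of `samples`.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param cycle_events Numeric vector of at least two heel-strike times (s);
#'   the gait cycle runs from the first to the second event.
#' @param time Optional time vector (s) for the rows of `samples`; defaults to
#'   `0, 1/fs, 2/fs, ...`.
#' @return An object of class `"raw_emg_trial"`.
#' @export
raw_emg_trial <- function(samples, channel_names, sampling_rate, cycle_events,
                          time = NULL) {
  samples <- as.matrix(samples)
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    stopf("sampling_rate must be a positive number")
  if (length(cycle_events) < 2L || any(diff(cycle_events) <= 0))
    stopf("cycle_events must contain >= 2 increasing heel-strike times")
  if (is.null(time)) time <- (seq_len(nrow(samples)) - 1L) / sampling_rate
  if (length(time) != nrow(samples))
    stopf("time vector length (%d) != number of sample rows (%d)",
          length(time), nrow(samples))
  if (length(channel_names) != ncol(samples))
    stopf("channel_names length != number of sample columns")
  colnames(samples) <- channel_names
  t_f <- cycle_events[2] - cycle_events[1]
  if (cycle_events[1] < time[1] || cycle_events[2] > time[length(time)])
    stopf("gait cycle [%g, %g] s lies outside the recorded span [%g, %g] s",
          cycle_events[1], cycle_events[2], time[1], time[length(time)])
  # 100 ms of pre-cycle context is consumed by the electromechanical-delay
  # padding; require twice that so filtering edge effects stay clear of it.
  if (cycle_events[1] - time[1] < 0.2 - 1e-9)
    stopf("need >= 0.2 s of data before the cycle start (have %.3f s)",
          cycle_events[1] - time[1])
  structure(
    list(samples = samples, channel_names = channel_names,
         sampling_rate = sampling_rate, time = time,
         cycle_events = cycle_events[1:2], t_f = t_f),
    class = "raw_emg_trial")
}

#' @export
print.raw_emg_trial <- function(x, ...) {
  cat(sprintf("Raw EMG trial: %d channels x %d samples @ %g Hz, t_f = %.3f s\n",
              ncol(x$samples), nrow(x$samples), x$sampling_rate, x$t_f))
  invisible(x)
}

#' EMG envelope extraction
#'
#' Standard gait-EMG conditioning: per channel, zero-phase high-pass at
#' `hp_cutoff` Hz, demeaning, full-wave rectification, then a zero-phase
#' low-pass whose cutoff scales with the gait-cycle period (`lp_scale / t_f`
#' Hz), so slower cycles get proportionally smoother envelopes.  Both filters
#' are fourth-order zero-phase Butterworth (second-order applied
#' forward-backward).  Filter ringing can push the smoothed envelope slightly
#' negative; the result is clamped at zero.
#'
#' @param raw A [raw_emg_trial()].
#' @param hp_cutoff High-pass cutoff in Hz (default 40).
#' @param lp_scale Dimensionless low-pass scale; cutoff = `lp_scale / t_f` Hz
#'   (default 3.5).
#' @return Envelope matrix with the dimensions of `raw$samples`, all values
#'   >= 0.
#' @export
filter_envelope <- function(raw, hp_cutoff = 40, lp_scale = 3.5) {
  stopifnot(inherits(raw, "raw_emg_trial"))
  fs <- raw$sampling_rate
  nyq <- fs / 2
  lp_cutoff <- lp_scale / raw$t_f
  if (hp_cutoff >= nyq)
    stopf("high-pass cutoff %g Hz >= Nyquist %g Hz", hp_cutoff, nyq)
  if (lp_cutoff >= nyq)
    stopf("low-pass cutoff %g Hz >= Nyquist %g Hz", lp_cutoff, nyq)
  bhp <- signal::butter(2, hp_cutoff / nyq, type = "high")
  blp <- signal::butter(2, lp_cutoff / nyq, type = "low")
  env <- raw$samples
  for (j in seq_len(ncol(env))) {
    x <- env[, j]
    if (all(x == 0)) next  # zero channel passes through untouched
    x <- signal::filtfilt(bhp, x)
    x <- abs(x - mean(x))
    x <- signal::filtfilt(blp, x)
    env[, j] <- pmax(x, 0)
  }
  env
}

#' The five EMG magnitude-normalization schemes
#'
#' Character vector of the scheme tags accepted throughout the package:
#' `MaxOver`, `MaxPer`, `VarOver`, `VarPer`, `MagPer`.
#'
#' @export
NORMALIZATION_SCHEMES <- c("MaxOver", "MaxPer", "VarOver", "VarPer", "MagPer")

#' Normalize EMG envelopes across a set of trials
#'
#' Applies one of five magnitude-normalization schemes to a set of envelope
#' matrices sharing a channel layout:
#' \describe{
#'   \item{MaxOver}{divide each channel by its maximum over all trials}
#'   \item{MaxPer}{by its maximum within each trial}
#'   \item{VarOver}{by its standard deviation over all trials}
#'   \item{VarPer}{by its standard deviation within each trial}
#'   \item{MagPer}{by its Euclidean 2-norm within each trial}
#' }
#' "Over" constants are shared across the supplied trials (the caller decides
#' what constitutes "all trials", e.g. one leg's set); "Per" constants are
#' trial-specific.
#'
#' @param envelopes List of envelope matrices (rows = time, columns =
#'   channels), one per trial, all with identical column names.
#' @param scheme One of `"MaxOver"`, `"MaxPer"`, `"VarOver"`, `"VarPer"`,
#'   `"MagPer"`.
#' @return List with `trials` (normalized matrices), `constants` (named
#'   vector for Over schemes, list of named vectors for Per schemes) and
#'   `scheme`.
#' @export
normalize_emg <- function(envelopes, scheme = NORMALIZATION_SCHEMES) {
  scheme <- match.arg(scheme)
  if (!is.list(envelopes) || length(envelopes) == 0)
    stopf("envelopes must be a non-empty list of matrices")
  envelopes <- lapply(envelopes, as.matrix)
  cn <- colnames(envelopes[[1]])
  for (E in envelopes)
    if (!identical(colnames(E), cn))
      stopf("all trials must share the same channel set")
  check_const <- function(const, trial = NULL) {
    bad <- which(!is.finite(const) | const <= 0)
    if (length(bad)) {
      nm <- if (is.null(cn)) as.character(bad[1]) else cn[bad[1]]
      where <- if (is.null(trial)) "" else sprintf(" in trial %d", trial)
      stopf("degenerate channel '%s'%s: normalization constant is zero", nm, where)
    }
    const
  }
  if (scheme %in% c("MaxOver", "VarOver")) {
    stacked <- do.call(rbind, envelopes)
    const <- if (scheme == "MaxOver") apply(stacked, 2, max)
             else apply(stacked, 2, stats::sd)
    check_const(const)
    trials <- lapply(envelopes, function(E) sweep(E, 2, const, "/"))
    constants <- stats::setNames(const, cn)
  } else {
    constants <- vector("list", length(envelopes))
    trials <- vector("list", length(envelopes))
    for (i in seq_along(envelopes)) {
      E <- envelopes[[i]]
      const <- switch(scheme,
        MaxPer = apply(E, 2, max),
        VarPer = apply(E, 2, stats::sd),
        MagPer = sqrt(colSums(E^2)))
      check_const(const, i)
      constants[[i]] <- stats::setNames(const, cn)
      trials[[i]] <- sweep(E, 2, const, "/")
    }
  }
  list(trials = trials, constants = constants, scheme = scheme)
}

#' Resample an envelope onto the padded gait-cycle grid
#'
#' Cubic-spline resamples one trial's envelope to 101 frames spanning heel
#' strike to heel strike (0-100% of the gait cycle) plus `n_pad =
#' round(10 / t_f)` frames preceding the cycle (round-half-up), which supply
#' about 100 ms of history for the electromechanical delay.
#'
#' @param envelope Envelope matrix on the trial's raw time grid.
#' @param raw The [raw_emg_trial()] the envelope came from (supplies timing).
#' @param normalization Tag recording which scheme produced `envelope`
#'   (default `"none"`).
#' @return An object of class `"processed_emg_trial"` with fields
#'   `frames` ((101 + n_pad) x channels), `n_pad`, `percent_grid`, `t_f`.
#' @export
time_normalize <- function(envelope, raw, normalization = "none") {
  stopifnot(inherits(raw, "raw_emg_trial"))
  envelope <- as.matrix(envelope)
  t_f <- raw$t_f
  n_pad <- n_pad_frames(t_f)
  dt <- t_f / 100
  grid <- raw$cycle_events[1] + dt * seq(-n_pad, 100)
  if (grid[1] < raw$time[1] - 1e-9)
    stopf("insufficient pre-cycle data for padding: need %.3f s before heel strike",
          n_pad * dt)
  out <- matrix(NA_real_, length(grid), ncol(envelope))
  for (j in seq_len(ncol(envelope))) {
    sf <- stats::splinefun(raw$time, envelope[, j], method = "fmm")
    out[, j] <- sf(grid)
  }
  out <- pmax(out, 0)
  colnames(out) <- colnames(envelope)
  structure(
    list(channel_names = colnames(envelope), frames = out, n_pad = n_pad,
         normalization = normalization, t_f = t_f,
         percent_grid = seq(0, 100, length.out = 101)),
    class = "processed_emg_trial")
}

#' Number of padding frames before the gait cycle
#'
#' `round(10 / t_f)` with half-up rounding, i.e. roughly 100 ms expressed in
#' 1%-of-cycle frames.
#'
#' @param t_f Gait-cycle period in seconds.
#' @return Non-negative integer frame count.
#' @export
n_pad_frames <- function(t_f) {
  stopifnot(t_f > 0)
  as.integer(floor(10 / t_f + 0.5))
}

#' @export
print.processed_emg_trial <- function(x, ...) {
  cat(sprintf(
    "Processed EMG trial: %d channels, %d frames (101 cycle + %d pad), scheme %s\n",
    ncol(x$frames), nrow(x$frames), x$n_pad, x$normalization))
  invisible(x)
}

#' Full EMG processing chain for a set of trials
#'
#' Convenience pipeline: envelope extraction ([filter_envelope()]) for every
#' trial, magnitude normalization across the set ([normalize_emg()]), then
#' time normalization onto the padded gait-cycle grid ([time_normalize()]).
#' By default the normalization scheme operates on the envelopes directly;
#' `renormalize_from = "maxover"` first rescales each channel by its maximum
#' over all trials and applies the scheme to that already-normalized signal.
#'
#' @param raws List of [raw_emg_trial()] objects (e.g. all trials of one leg).
#' @param scheme Normalization scheme, see [normalize_emg()].
#' @param hp_cutoff,lp_scale Passed to [filter_envelope()].
#' @param renormalize_from `"envelope"` (default) or `"maxover"`.
#' @return List of `"processed_emg_trial"` objects with the applied constants
#'   attached as attribute `"constants"`.
#' @export
process_emg <- function(raws, scheme = "MaxOver", hp_cutoff = 40,
                        lp_scale = 3.5, renormalize_from = c("envelope", "maxover")) {
  renormalize_from <- match.arg(renormalize_from)
  stopifnot(length(raws) >= 1)
  envs <- lapply(raws, filter_envelope, hp_cutoff = hp_cutoff, lp_scale = lp_scale)
  if (renormalize_from == "maxover" && scheme != "MaxOver")
    envs <- normalize_emg(envs, "MaxOver")$trials
  nm <- normalize_emg(envs, scheme)
  out <- mapply(function(E, raw) time_normalize(E, raw, normalization = scheme),
                nm$trials, raws, SIMPLIFY = FALSE)
  attr(out, "constants") <- nm$constants
  out
}
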