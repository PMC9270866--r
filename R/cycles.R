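#' Detect R-wave peaks in an ECG trace
#'
#' Marks end-diastole candidates as the peaks of the R wave. The trace
#' is detrended by moving-median subtraction, thresholded at a fraction
#' of its 98th-percentile amplitude, and screened with a refractory
#' period; each surviving peak is refined by a parabolic fit through
#' its three-sample neighbourhood and rounded back to the nearest
#' sample. The detector constants are conventions of this package (the
#' acquisition itself fixes none) and are all tunable.
#'
#' @param ecg numeric ECG series (arbitrary units).
#' @param sample_rate sampling rate in Hz.
#' @param refractory minimum peak separation in seconds (default 0.2).
#' @param threshold_frac detection threshold as a fraction of the
#'   98th-percentile detrended amplitude (default 0.6).
#' @param detrend_window moving-median window in seconds (default 0.6).
#' @return integer vector of strictly increasing sample indices
#'   (1-based); empty, with a warning, when nothing crosses threshold.
#' @export
detect_r_peaks <- function(ecg, sample_rate, refractory = 0.2,
                           threshold_frac = 0.6, detrend_window = 0.6) {
  n <- length(ecg)
  if (n < 3 || any(!is.finite(ecg))) stopf("ecg must be finite, length >= 3")
  k <- max(3L, as.integer(round(detrend_window * sample_rate)))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (n %% 2 == 1) n else n - 1L)
  x <- ecg - stats::runmed(ecg, k)
  thr <- threshold_frac * stats::quantile(x, 0.98, names = FALSE)
  # strict local maxima above threshold
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] > x[cand + 1]]
  if (!length(cand) || thr <= 0) {
    warnf("no R peak above threshold")
    return(integer())
  }
  # refractory screening: keep the larger of any pair closer than the period
  refr <- refractory * sample_rate
  keep <- integer()
  for (i in cand[order(-x[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  # parabolic sub-sample refinement, rounded to the nearest sample
  refined <- vapply(keep, function(i) {
    y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
    den <- y1 - 2 * y2 + y3
    d <- if (den == 0) 0 else 0.5 * (y1 - y3) / den
    as.integer(round(i + max(-0.5, min(0.5, d))))
  }, integer(1))
  sort(unique(refined))
}

#' Time derivative of a pressure trace
#'
#' Central finite difference of the moving-average-smoothed pressure,
#' scaled to mmHg/s; the endpoints use one-sided differences. Used to
#' locate end-systole at the maximum negative LV dP/dt.
#'
#' @param pressure numeric series in mmHg.
#' @param sample_rate sampling rate in Hz.
#' @param smooth_window moving-average width in samples (odd; default 5,
#'   about 39 ms at 128 Hz). `1` disables smoothing.
#' @return numeric series of the same length, in mmHg/s.
#' @export
compute_dpdt <- function(pressure, sample_rate, smooth_window = 5) {
  n <- length(pressure)
  if (smooth_window < 1 || smooth_window > n)
    stopf("smooth_window must be in [1, %d]", n)
  p <- pressure
  if (smooth_window > 1) {
    w <- as.integer(smooth_window)
    if (w %% 2 == 0) w <- w + 1L
    h <- (w - 1L) %/% 2L
    padded <- c(rep(p[1], h), p, rep(p[n], h))
    p <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[(h + 1):(h + n)]
  }
  d <- numeric(n)
  d[1] <- (p[2] - p[1]) * sample_rate
  d[n] <- (p[n] - p[n - 1]) * sample_rate
  if (n > 2) d[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) * sample_rate / 2
  d
}

#' Segment a recording into cardiac cycles
#'
#' End-diastole (ED) is the R-wave peak on the ECG; end-systole (ES) is
#' the maximum negative dP/dt of LV pressure within the RR interval.
#' Two further phase landmarks are package conventions, not acquisition
#' definitions: end of isovolumic contraction (EIVC) at the maximum
#' positive LV dP/dt, and end of isovolumic relaxation (EIVR) at the
#' first sample after ES where LVP falls below its value at ED.
#'
#' A cycle whose ES candidate sits on the interval boundary is flagged
#' unusable rather than dropped.
#'
#' @param rec a `channel_recording`.
#' @param smooth_window passed to [compute_dpdt()].
#' @param ... passed to [detect_r_peaks()].
#' @return data.frame of class `cycle_landmarks` with one row per full
#'   RR interval: `ed`, `eivc`, `es`, `eivr`, `next_ed` (sample
#'   indices; `eivr` may be NA) and `usable`.
#' @export
segment_cycles <- function(rec, smooth_window = 5, ...) {
  peaks <- detect_r_peaks(rec$ecg, rec$sample_rate, ...)
  if (length(peaks) < 2)
    stopf("need >= 2 R peaks to segment cycles, found %d", length(peaks))
  dpdt <- compute_dpdt(rec$lvp, rec$sample_rate, smooth_window)
  out <- lapply(seq_len(length(peaks) - 1), function(k) {
    ed <- peaks[k]; next_ed <- peaks[k + 1]
    span <- (ed + 1):(next_ed - 1)
    es <- span[which.min(dpdt[span])]
    eivc <- span[which.max(dpdt[span])]
    after <- if (es < next_ed - 1) (es + 1):(next_ed - 1) else integer()
    below <- after[rec$lvp[after] < rec$lvp[ed]]
    eivr <- if (length(below)) below[1] else NA_integer_
    usable <- es > span[1] && es < span[length(span)]
    data.frame(ed = ed, eivc = eivc, es = es, eivr = eivr,
               next_ed = next_ed, usable = usable)
  })
  res <- do.call(rbind, out)
  class(res) <- c("cycle_landmarks", "data.frame")
  res
}

#' Average consecutive cardiac cycles on a normalized time grid
#'
#' Each selected cycle is linearly resampled from its ED to the next ED
#' onto a fixed 0-100 % grid, and all channels (crystal coordinates and
#' pressures/ECG) are averaged pointwise across cycles. Landmark phases
#' are averaged in normalized time. The default of 4 consecutive beats
#' matches routine practice for sinus-rhythm sonomicrometry data.
#'
#' The attribute `noise_gain` records, per grid point, the factor by
#' which the pipeline (linear interpolation + n-beat averaging)
#' attenuates iid per-sample noise: for noise of SD sigma the averaged
#' beat carries residual SD `sigma/sqrt(n) * noise_gain`. Linear
#' interpolation between two samples itself shrinks iid noise, so the
#' gain is at most 1; dividing observed residuals by it recovers the
#' sample-domain noise level.
#'
#' @param rec a `channel_recording`.
#' @param cycles a `cycle_landmarks` data.frame from [segment_cycles()].
#' @param n number of consecutive usable cycles to average (default 4).
#' @param grid_points number of points on the 0-100 % grid (default 101).
#' @param start index (within the usable cycles) of the first beat.
#' @return an object of class `averaged_beat`: `grid` (percent),
#'   per-crystal `grid_points x 3` matrices in `crystals`, averaged
#'   `lvp`/`rvp`/`cvp`/`ecg`, landmark phases `es_phase`, `eivc_phase`,
#'   `eivr_phase` (percent), `n_beats`, `state_tag`, and the source
#'   landmark rows.
#' @export
average_beats <- function(rec, cycles, n = 4, grid_points = 101, start = 1) {
  use <- cycles[cycles$usable, , drop = FALSE]
  if (nrow(use) < start + n - 1)
    stopf("need %d usable cycles from beat %d, only %d available",
          n, start, nrow(use))
  sel <- use[start:(start + n - 1), , drop = FALSE]
  grid <- seq(0, 100, length.out = grid_points)

  # per-beat fractional sample positions for each grid point
  pos <- lapply(seq_len(n), function(b)
    sel$ed[b] + grid / 100 * (sel$next_ed[b] - sel$ed[b]))
  resample <- function(x) {
    acc <- numeric(grid_points)
    for (b in seq_len(n)) {
      i0 <- floor(pos[[b]]); w <- pos[[b]] - i0
      i1 <- pmin(i0 + 1, length(x))
      acc <- acc + (1 - w) * x[i0] + w * x[i1]
    }
    acc / n
  }
  crystals <- lapply(rec$crystals, function(m)
    cbind(resample(m[, 1]), resample(m[, 2]), resample(m[, 3])))
  # iid-noise attenuation of interp + averaging, per grid point
  shrink <- rowMeans(vapply(seq_len(n), function(b) {
    w <- pos[[b]] - floor(pos[[b]])
    (1 - w)^2 + w^2
  }, numeric(grid_points)))
  phase_of <- function(idx) mean(100 * (idx - sel$ed) / (sel$next_ed - sel$ed))
  beat <- structure(
    list(grid = grid, crystals = crystals,
         lvp = resample(rec$lvp), rvp = resample(rec$rvp),
         cvp = resample(rec$cvp), ecg = resample(rec$ecg),
         n_beats = n, es_phase = phase_of(sel$es),
         eivc_phase = phase_of(sel$eivc),
         eivr_phase = if (anyNA(sel$eivr)) NA_real_ else phase_of(sel$eivr),
         state_tag = rec$state_tag, sample_rate = rec$sample_rate,
         source_landmarks = sel),
    class = "averaged_beat")
  attr(beat, "noise_gain") <- sqrt(shrink)
  beat
}

#' @export
print.averaged_beat <- function(x, ...) {
  cat(sprintf("Averaged beat [%s]: %d cycles, %d grid points; ES at %.1f%% of cycle\n",
              x$state_tag, x$n_beats, length(x$grid), x$es_phase))
  invisible(x)
}

# Resolve a timepoint spec ("ED", "ES" or percent of cycle) to a grid index.
beat_grid_index <- function(beat, timepoint) {
  phase <- if (is.numeric(timepoint)) timepoint
  else switch(toupper(timepoint),
              ED = 0, ES = beat$es_phase,
              stopf("unknown timepoint '%s'", timepoint))
  which.min(abs(beat$grid - phase))
}

# Crystal frame (labels x 3) of an averaged beat at a grid index.
beat_frame <- function(beat, labels, grid_index) {
  out <- matrix(NA_real_, length(labels), 3,
                dimnames = list(labels, c("x", "y", "z")))
  for (i in seq_along(labels)) out[i, ] <- beat$crystals[[labels[i]]][grid_index, ]
  out
}
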