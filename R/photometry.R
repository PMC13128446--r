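#' Construct a PhotometryRecording
#'
#' @param time seconds (uniform grid); may be omitted and derived from `fs`.
#' @param f465 biosensor channel (465 nm), arbitrary units.
#' @param f405 isosbestic channel (405 nm), arbitrary units.
#' @param fs sampling rate, Hz.
#' @param baselineWindow `[t0, t1]` seconds, preceding the injection.
#' @param injectionTime seconds.
#' @param animalId label used to persist per-animal thresholds.
#' @return a [PhotometryRecording-class].
#' @export
PhotometryRecording <- function(f465, f405, fs, time = NULL,
                                baselineWindow = NULL, injectionTime = NULL,
                                animalId = "animal1") {
  n <- length(f465)
  if (is.null(time)) time <- (seq_len(n) - 1) / fs
  if (is.null(injectionTime)) injectionTime <- time[n] + 1 / fs
  if (is.null(baselineWindow)) baselineWindow <- c(time[1], injectionTime)
  new("PhotometryRecording", time = time, f465 = f465, f405 = f405,
      fs = fs, baselineWindow = as.numeric(baselineWindow),
      injectionTime = as.numeric(injectionTime), animalId = animalId)
}

#' Anti-alias low-pass filter and decimate a recording
#'
#' Both channels are low-pass filtered (zero-phase Butterworth, default
#' 10 Hz cutoff, order 2 applied forward-backward) and then decimated by
#' the given factor. The sampling rate must be at least 20x the cutoff
#' before decimation, and the cutoff must stay below the post-decimation
#' Nyquist frequency.
#'
#' @param rec a [PhotometryRecording-class].
#' @param cutoffHz low-pass cutoff (default 10).
#' @param factor decimation factor (default 10).
#' @param order Butterworth order (default 2; applied zero-phase).
#' @return a decimated [PhotometryRecording-class].
#' @export
preprocessRecording <- function(rec, cutoffHz = 10, factor = 10L,
                                order = 2L) {
  stopifnot(is(rec, "PhotometryRecording"))
  if (rec@fs < 20 * cutoffHz)
    stop("sampling rate must be >= 20x the low-pass cutoff")
  newFs <- rec@fs / factor
  if (cutoffHz >= newFs / 2)
    stop("cutoff is above the Nyquist frequency after decimation")
  bf <- signal::butter(order, cutoffHz / (rec@fs / 2), type = "low")
  idx <- seq(1, length(rec@time), by = factor)
  # filter about the mean: the DC gain is 1, and zero-centring avoids
  # start-up edge transients on non-zero-mean traces
  lp <- function(v) {
    m <- mean(v)
    (signal::filtfilt(bf, v - m) + m)[idx]
  }
  new("PhotometryRecording", time = rec@time[idx], f465 = lp(rec@f465),
      f405 = lp(rec@f405), fs = newFs,
      baselineWindow = rec@baselineWindow,
      injectionTime = rec@injectionTime, animalId = rec@animalId)
}

# Asymmetric least-squares baseline (Eilers-Boelens), with p = 0.5 giving
# the symmetric-weights variant. Suppresses peaks when p is small.
alsBaseline <- function(y, lambda = 1e5, p = 0.05, maxit = 20L) {
  n <- length(y)
  if (n < 4) return(y)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(maxit)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    wNew <- ifelse(y > z, p, 1 - p)
    if (max(abs(wNew - w)) < 1e-12) break
    w <- wNew
  }
  z
}

#' Estimate the F0 baseline trace by isosbestic rescaling
#'
#' A polynomial map (default degree 1, i.e. affine) from the isosbestic
#' channel to the biosensor channel is estimated on the baseline window and
#' applied to the whole isosbestic channel, yielding the motion- and
#' bleach-tracking baseline F0. In `"baseline_als"` mode the biosensor
#' signal in the baseline window is first replaced by an asymmetric
#' least-squares baseline estimate (peak-suppressed), so transient peaks in
#' the baseline window do not bias the map; `"polynomial_rescale"` uses the
#' raw baseline-window signal.
#'
#' @param rec a [PhotometryRecording-class].
#' @param mode `"polynomial_rescale"` or `"baseline_als"`.
#' @param degree polynomial degree of the isosbestic-to-signal map
#'   (default 1).
#' @param lambda,p asymmetric least-squares parameters (mode
#'   `"baseline_als"`); `p = 0.5` gives symmetric weights.
#' @return numeric F0 trace, same length as the recording. A degenerate
#'   (constant) isosbestic channel with non-constant signal is an error.
#' @export
fitBaseline <- function(rec, mode = c("polynomial_rescale", "baseline_als"),
                        degree = 1L, lambda = 1e5, p = 0.05) {
  stopifnot(is(rec, "PhotometryRecording"))
  mode <- match.arg(mode)
  inBase <- rec@time >= rec@baselineWindow[1] &
    rec@time <= rec@baselineWindow[2]
  if (!any(inBase)) stop("baseline window contains no samples")
  iso <- rec@f405[inBase]
  sig <- rec@f465[inBase]
  if (sd(iso) < 1e-12 * max(1, abs(mean(iso)))) {
    if (sd(sig) > 1e-10 * max(1, abs(mean(sig))))
      stop("degenerate (constant) isosbestic channel with ",
           "non-constant signal")
    return(rep(mean(sig), length(rec@time)))
  }
  if (mode == "baseline_als") sig <- alsBaseline(sig, lambda = lambda,
                                                 p = p)
  # raw polynomial in the isosbestic value; degree 1 = affine rescale
  fitMap <- lm(sig ~ poly(iso, degree, raw = TRUE))
  as.numeric(predict(fitMap,
                     newdata = data.frame(iso = rec@f405)))
}

#' Fractional fluorescence change dF/F
#'
#' `dF/F = (F - F0) / F0` pointwise. Samples where `F0 <= 0` are masked to
#' `NA` with a warning.
#'
#' @param f fluorescence trace.
#' @param f0 baseline trace (same length).
#' @return dF/F trace, dimensionless.
#' @examples
#' computeDff(1.1, 1.0)  # 0.1
#' @export
computeDff <- function(f, f0) {
  stopifnot(length(f) == length(f0))
  bad <- !(f0 > 0)
  if (any(bad, na.rm = TRUE))
    warning(sum(bad, na.rm = TRUE),
            " sample(s) with F0 <= 0 masked to NA")
  dff <- (f - f0) / f0
  dff[bad] <- NA_real_
  dff
}

#' Set the per-animal transient prominence threshold
#'
#' `threshold = median(dff) + k * MAD(dff)` over the baseline-window dF/F,
#' with `k = 2.5` by default (MAD with the Gaussian consistency constant
#' 1.4826). The threshold is set once per animal on a baseline recording
#' and remains constant across all experimental conditions. Baselines
#' shorter than 60 s are refused.
#'
#' @param dffBaseline dF/F samples restricted to the baseline window.
#' @param fs sampling rate of the dF/F trace, Hz.
#' @param k MAD multiplier (default 2.5).
#' @return the threshold (scalar).
#' @export
setTransientThreshold <- function(dffBaseline, fs, k = 2.5) {
  dffBaseline <- dffBaseline[is.finite(dffBaseline)]
  if (length(dffBaseline) / fs < 60)
    stop("baseline must be at least 60 s long")
  median(dffBaseline) + k * mad(dffBaseline)
}

# Topographic prominence of each local maximum of v: peak height minus the
# higher of the two lowest valleys separating it from higher terrain (or
# the trace edge). Returns peaks with indices, prominences and the valley
# bounds used.
peakProminences <- function(v) {
  n <- length(v)
  # strict local maxima; plateaus take their first index
  isPk <- which(diff(sign(diff(v))) < 0) + 1L
  if (!length(isPk)) {
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric(), left = integer(),
                      right = integer()))
  }
  res <- lapply(isPk, function(i) {
    h <- v[i]
    # walk left to the nearest strictly higher sample (or edge)
    j <- i - 1L
    leftMin <- h; leftIdx <- i
    while (j >= 1L && v[j] <= h) {
      if (v[j] < leftMin) { leftMin <- v[j]; leftIdx <- j }
      j <- j - 1L
    }
    j <- i + 1L
    rightMin <- h; rightIdx <- i
    while (j <= n && v[j] <= h) {
      if (v[j] < rightMin) { rightMin <- v[j]; rightIdx <- j }
      j <- j + 1L
    }
    base <- max(leftMin, rightMin)
    data.frame(index = i, height = h, prominence = h - base,
               left = leftIdx, right = rightIdx)
  })
  do.call(rbind, res)
}

#' Detect fluorescence transients by prominence threshold
#'
#' Local maxima of the dF/F trace whose topographic prominence is at least
#' the fixed threshold. Amplitude is the prominence; duration is the full
#' width at half prominence (linear interpolation of the crossings within
#' the peak's base interval); frequency is events per minute over the
#' analysis window.
#'
#' @param dff dF/F trace.
#' @param time seconds (same length); or supply `fs` for a uniform grid.
#' @param threshold prominence threshold from [setTransientThreshold()].
#' @param fs sampling rate, used when `time` is missing.
#' @param window optional `[t0, t1]` analysis window; defaults to the full
#'   trace.
#' @return a [TransientSet-class].
#' @export
detectTransients <- function(dff, threshold, time = NULL, fs = NULL,
                             window = NULL) {
  if (is.null(time)) {
    if (is.null(fs)) stop("supply either time or fs")
    time <- (seq_along(dff) - 1) / fs
  }
  if (!length(dff)) stop("empty trace")
  if (is.null(window)) window <- range(time)
  keep <- time >= window[1] & time <= window[2] & is.finite(dff)
  v <- dff[keep]; tt <- time[keep]
  pk <- peakProminences(v)
  pk <- pk[pk$prominence >= threshold, , drop = FALSE]
  events <- if (nrow(pk)) {
    do.call(rbind, lapply(seq_len(nrow(pk)), function(r) {
      i <- pk$index[r]
      half <- pk$height[r] - pk$prominence[r] / 2
      # left crossing of the half-prominence level
      lseg <- seq(pk$left[r], i)
      below <- which(v[lseg] < half)
      tl <- if (length(below)) {
        j <- lseg[max(below)]
        approx(v[c(j, j + 1)], tt[c(j, j + 1)], xout = half)$y
      } else tt[pk$left[r]]
      rseg <- seq(i, pk$right[r])
      below <- which(v[rseg] < half)
      tr <- if (length(below)) {
        j <- rseg[min(below)]
        approx(v[c(j - 1, j)], tt[c(j - 1, j)], xout = half)$y
      } else tt[pk$right[r]]
      data.frame(peak_time_s = tt[i], amplitude = pk$prominence[r],
                 duration_s = max(tr - tl, .Machine$double.eps))
    }))
  } else {
    data.frame(peak_time_s = numeric(), amplitude = numeric(),
               duration_s = numeric())
  }
  minutes <- (window[2] - window[1]) / 60
  new("TransientSet", events = events, threshold = threshold,
      frequencyPerMin = if (minutes > 0) nrow(events) / minutes else
        NA_real_,
      window = as.numeric(window))
}

#' Slow-component AUC in 5-minute bins
#'
#' The dF/F trace is low-pass filtered with a zero-phase Butterworth filter
#' (default 0.1 Hz cutoff, 2nd order, forward-backward) and the trapezoidal
#' area under the curve is computed in consecutive bins (default 5 min)
#' whose edges are aligned to the injection time and snapped to sample
#' points, making AUC exactly additive over adjacent bins. Records shorter
#' than one bin yield a partial bin flagged in the output.
#'
#' @param dff dF/F trace.
#' @param time seconds, uniform grid.
#' @param fs sampling rate, Hz.
#' @param cutoffHz Butterworth cutoff (default 0.1).
#' @param binSec bin width in seconds (default 300).
#' @param injectionTime bin-alignment origin (default first sample).
#' @param order Butterworth order (default 2).
#' @return data.frame with `bin_start_s`, `bin_end_s`, `auc` (dimensionless
#'   x seconds) and `partial` (logical).
#' @export
slowAuc <- function(dff, fs, time = NULL, cutoffHz = 0.1, binSec = 300,
                    injectionTime = NULL, order = 2L) {
  if (is.null(time)) time <- (seq_along(dff) - 1) / fs
  if (cutoffHz >= fs / 2) stop("cutoff above Nyquist")
  bf <- signal::butter(order, cutoffHz / (fs / 2), type = "low")
  m <- mean(dff)
  low <- signal::filtfilt(bf, dff - m) + m
  if (is.null(injectionTime)) injectionTime <- time[1]
  # bin edges tiling the record, aligned to the injection time
  k0 <- floor((time[1] - injectionTime) / binSec)
  k1 <- ceiling((time[length(time)] - injectionTime) / binSec)
  edges <- injectionTime + seq(k0, k1) * binSec
  out <- list()
  for (b in seq_len(length(edges) - 1)) {
    lo <- edges[b]; hi <- edges[b + 1]
    idx <- which(time >= lo - 1e-9 & time <= hi + 1e-9)
    if (length(idx) < 2) next
    out[[length(out) + 1L]] <- data.frame(
      bin_start_s = lo, bin_end_s = hi,
      auc = trapezoid(time[idx], low[idx]),
      partial = time[idx[1]] - lo > 1 / fs ||
        hi - time[idx[length(idx)]] > 1 / fs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
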