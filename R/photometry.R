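#' Rolling z-score detrending
#'
#' Per-sample standardization `(x - mu_w) / sigma_w` using a centered
#' window of `window` samples, truncated at the series edges. The
#' standard deviation is the population SD over the window, floored at
#' 1e-12 so constant stretches map to zero rather than NaN.
#'
#' This removes slow drift (e.g. photobleaching) while leaving structure
#' much faster than the window untouched; the output is invariant to
#' positive affine transforms of the input.
#'
#' @param x Numeric series.
#' @param window Window length in samples (>= 2, <= length(x)).
#' @return Numeric series of the same length; attribute `constant` flags
#'   whether any window had (near-)zero variance.
#' @export
rolling_zscore <- function(x, window) {
  n <- length(x)
  if (window < 2 || window > n)
    stop("window must be in [2, length(x)]", call. = FALSE)
  xc <- x - mean(x)                       # improves cumsum conditioning
  cs <- cumsum(xc); cs2 <- cumsum(xc^2)
  i <- seq_len(n)
  lo <- pmax(1L, i - (ceiling(window / 2) - 1L))
  hi <- pmin(n, i + floor(window / 2))
  m <- hi - lo + 1
  cs0 <- c(0, cs); cs20 <- c(0, cs2)   # prefix sums with leading zero
  s <- cs0[hi + 1] - cs0[lo]
  s2 <- cs20[hi + 1] - cs20[lo]
  mu <- s / m
  v <- pmax(s2 / m - mu^2, 0)
  sd_w <- pmax(sqrt(v), 1e-12)
  out <- (xc - mu) / sd_w
  attr(out, "constant") <- any(v < 1e-20)
  out
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Raw photometry container
#'
#' Bundles a frequency-modulated photodetector trace with its sampling
#' rate and the carrier frequencies riding on it.
#'
#' @param samples Numeric voltage series.
#' @param fs Sampling rate, Hz (default 2000).
#' @param carriers Named or unnamed numeric vector of carrier
#'   frequencies, Hz (default `c(signal = 167, control = 223)`); all must
#'   be below the Nyquist frequency.
#' @return An object of class `raw_photometry`.
#' @export
raw_photometry <- function(samples, fs = 2000,
                           carriers = c(signal = 167, control = 223)) {
  if (any(carriers >= fs / 2))
    stop("carrier frequencies must be below the Nyquist frequency",
         call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs, carriers = carriers),
            class = "raw_photometry")
}

#' Demodulate a frequency-modulated photometry channel
#'
#' Short-time spectral (lock-in style) demodulation: the trace is cut
#' into Hamming-windowed frames of `win` samples advancing by `hop`
#' samples (216 and 108 at 2 kHz, giving a 54 ms frame period); in each
#' frame, spectral power is evaluated by direct complex-exponential
#' projection at 1 Hz-spaced frequencies across an 8 Hz band centered on
#' the carrier (9 frequencies; direct evaluation because the native
#' resolution fs/win is not 1 Hz), and the demodulated value is the mean
#' band power. Power is the squared magnitude of the projection
#' normalized by the window sum; only relative values matter because the
#' series is finally detrended with [rolling_zscore()] over a 1-minute
#' window (round(60 / 0.054) = 1111 frames).
#'
#' @param raw A [raw_photometry()] or numeric sample vector.
#' @param carrier Carrier frequency to demodulate, Hz (< Nyquist).
#' @param win,hop Frame length and advance in samples.
#' @param band Width of the averaged band, Hz (9 frequencies at 8 Hz).
#' @param zscore Apply the final rolling z-score (default TRUE).
#' @param zscore_window_s Width of that window in seconds.
#' @param detrend_raw Also rolling-z-score the raw modulated trace first
#'   (1-min window in samples) to strip bleaching before demodulation;
#'   off by default so that, pre-z-scoring, band power stays proportional
#'   to the squared modulation amplitude.
#' @return A `demod_signal`: list with `values`, `t` (frame-center times,
#'   seconds; frame k covers samples (k-1)*hop+1 .. (k-1)*hop+win and is
#'   assigned the centroid time k * hop/fs), `period` (hop/fs), and
#'   `carrier`.
#' @examples
#' t <- seq(0, 2, by = 1/2000)[-1]
#' d <- demodulate(sin(2 * pi * 167 * t), 167, zscore = FALSE)
#' @export
demodulate <- function(raw, carrier, win = 216, hop = 108, band = 8,
                       zscore = TRUE, zscore_window_s = 60,
                       detrend_raw = FALSE) {
  if (inherits(raw, "raw_photometry")) {
    x <- raw$samples; fs <- raw$fs
  } else {
    x <- as.numeric(raw); fs <- 2000
  }
  if (carrier >= fs / 2)
    stop("carrier must be below the Nyquist frequency", call. = FALSE)
  n <- length(x)
  if (n < win) stop("need at least ", win, " samples", call. = FALSE)
  if (detrend_raw)
    x <- as.numeric(rolling_zscore(x, min(n, zscore_window_s * fs)))

  n_frames <- floor((n - win) / hop) + 1
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1) * hop, `+`)
  w <- hamming_window(win)
  frames <- matrix(x[idx], nrow = win) * w

  freqs <- carrier + seq(-band / 2, band / 2, by = 1)
  tn <- (seq_len(win) - 1) / fs
  arg <- outer(tn, freqs, function(t, f) 2 * pi * f * t)
  re <- crossprod(frames, cos(arg))        # n_frames x n_freqs
  im <- crossprod(frames, sin(arg))
  power <- (re^2 + im^2) / sum(w)^2
  values <- rowMeans(power)

  period <- hop / fs
  if (zscore) {
    zw <- min(n_frames, round(zscore_window_s / period))
    values <- as.numeric(rolling_zscore(values, zw))
  }
  structure(list(values = values, t = seq_len(n_frames) * period,
                 period = period, carrier = carrier),
            class = "demod_signal")
}

#' @export
print.demod_signal <- function(x, ...) {
  cat(sprintf("<demod_signal> %d frames @ %.0f ms (carrier %g Hz), %.1f s\n",
              length(x$values), 1000 * x$period, x$carrier,
              length(x$values) * x$period))
  invisible(x)
}

# Nearest frame to time te on the hop grid (frame centers k*period),
# ties toward the earlier frame. Returns an index, possibly off-range.
nearest_frame <- function(te, period) {
  as.integer(ceiling(te / period - 0.5 - 1e-9))
}

#' Align a demodulated signal to behavioral events
#'
#' Cuts the signal into per-trial snippets centered on a named trial
#' event (CE, CX, SE, FL, SX), taking the frame whose center is nearest
#' the event time (ties toward the earlier frame). Rows are labeled by
#' choice direction relative to the recording hemisphere (ipsi/contra),
#' by outcome, and by previous-trial outcome. Trials whose window would
#' extend past the recording are dropped and counted.
#'
#' @param sig A `demod_signal`.
#' @param session A `session_table` on the same clock as the recording.
#' @param event One of `"CE"`, `"CX"`, `"SE"`, `"FL"`, `"SX"`.
#' @param pre,post Window extent in seconds before/after the event.
#' @param hemisphere Recording hemisphere (`"left"` or `"right"`):
#'   a choice on the same side is labeled ipsi.
#' @return A `peri_event_tensor`: list with `mat` (trials x frames),
#'   `time` (frame offsets, seconds, shared by all rows), `info`
#'   (per-trial labels: trial, choice, direction, rewarded,
#'   prev_rewarded, mouse_id), `event`, and `n_dropped`.
#' @export
align_events <- function(sig, session, event = "SE", pre = 2, post = 4,
                         hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(sig, "demod_signal"))
  col <- paste0("t_", event)
  if (!col %in% names(session)) stop("unknown event: ", event, call. = FALSE)
  te <- session[[col]]
  n_pre <- round(pre / sig$period)
  n_post <- round(post / sig$period)
  k <- nearest_frame(te, sig$period)
  ok <- !is.na(te) & (k - n_pre) >= 1 & (k + n_post) <= length(sig$values)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    warning(n_dropped, " trial(s) dropped: event outside the recording")
  if (!any(ok)) stop("no events fall within the recording", call. = FALSE)
  kk <- k[ok]
  offs <- -n_pre:n_post
  mat <- matrix(sig$values[outer(kk, offs, `+`)],
                nrow = length(kk), ncol = length(offs))
  prev_rew <- c(NA, session$rewarded[-nrow(session)])
  info <- data.frame(trial = session$trial[ok],
                     choice = session$choice[ok],
                     direction = ifelse(session$choice[ok] == hemisphere,
                                        "ipsi", "contra"),
                     rewarded = session$rewarded[ok],
                     prev_rewarded = prev_rew[ok],
                     mouse_id = session$mouse_id[ok],
                     stringsAsFactors = FALSE)
  structure(list(mat = mat, time = offs * sig$period, info = info,
                 event = event, n_dropped = n_dropped),
            class = "peri_event_tensor")
}

#' Post-event window means of a peri-event tensor
#'
#' Averages each trial's snippet over the frames whose centers fall in
#' `(window[1], window[2]]` seconds relative to the event (default the
#' 500 ms immediately following it, i.e. 9 frames at the 54 ms period),
#' then aggregates per mouse within each grouping label.
#'
#' @param tensor A `peri_event_tensor` from [align_events()].
#' @param window Two-element window in seconds, default `c(0, 0.5)`.
#' @param group Name of the label column in `tensor$info` used for
#'   grouping (default `"direction"`).
#' @return List with `trial` (per-trial means + labels), `mouse`
#'   (mouse x group means), and `n_frames` (frames averaged).
#' @export
window_mean <- function(tensor, window = c(0, 0.5), group = "direction") {
  sel <- tensor$time > window[1] + 1e-9 & tensor$time <= window[2] + 1e-9
  if (!any(sel))
    stop("tensor does not cover the requested window", call. = FALSE)
  per_trial <- rowMeans(tensor$mat[, sel, drop = FALSE])
  trial <- cbind(tensor$info, window_mean = per_trial)
  mouse <- stats::aggregate(trial$window_mean,
                            by = list(mouse_id = trial$mouse_id,
                                      group = trial[[group]]),
                            FUN = mean)
  names(mouse)[3] <- "window_mean"
  list(trial = trial, mouse = mouse, n_frames = sum(sel))
}
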