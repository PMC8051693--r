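#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth applied forward and backward (`signal::filtfilt`),
#' giving zero phase distortion and unit passband gain. Used both for the
#' band decomposition feeding symbolic transfer entropy and anywhere else
#' a band-limited signal is needed.
#'
#' @param x numeric signal.
#' @param band numeric length-2 `(f_lo, f_hi)` in Hz; `f_hi` must be
#'   below Nyquist.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 4).
#' @return filtered signal, same length as `x`.
#' @export
bandpass <- function(x, band, fs, order = 4L) {
  if (length(band) != 2L || band[1L] >= band[2L]) {
    stop("band must be (f_lo, f_hi) with f_lo < f_hi")
  }
  if (band[2L] >= fs / 2) stop("band extends to or beyond Nyquist")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Complexity pre-filter: low-pass 115 Hz with a 45-75 Hz stop band
#'
#' Zero-phase order-4 Butterworth low-pass at 115 Hz combined with an
#' order-4 band-stop over 45-75 Hz (the frequency range excluded from all
#' analyses), applied before the Hilbert-amplitude step of the complexity
#' pipeline.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz; must exceed 230 so the 115 Hz edge is
#'   below Nyquist.
#' @param f_lp low-pass edge (default 115 Hz).
#' @param f_stop band-stop edges (default `c(45, 75)`).
#' @return filtered signal.
#' @export
complexity_filter <- function(x, fs, f_lp = 115, f_stop = c(45, 75)) {
  if (fs <= 2 * f_lp) stop("fs must exceed twice the low-pass edge")
  lp <- signal::butter(4L, f_lp / (fs / 2), type = "low")
  bs <- signal::butter(4L, f_stop / (fs / 2), type = "stop")
  y <- as.numeric(signal::filtfilt(lp, x))
  as.numeric(signal::filtfilt(bs, y))
}

#' Local linear detrending
#'
#' Removes slow drift by subtracting a piecewise-local linear fit:
#' ordinary least-squares lines are fitted in sliding windows (1 s wide,
#' advancing by 0.5 s) and their midpoint values interpolated into a
#' smooth trend estimate, which is subtracted from the signal.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param window_s regression window length in seconds (default 1).
#' @param step_s window advance in seconds (default 0.5, i.e. 50%
#'   overlap).
#' @return detrended signal, same length as `x`.
#' @export
detrend_local <- function(x, fs, window_s = 1, step_s = 0.5) {
  n <- length(x)
  w <- as.integer(round(window_s * fs))
  s <- as.integer(round(step_s * fs))
  if (n < w) stop("signal shorter than the regression window")
  starts <- unique(c(seq(1L, max(1L, n - w + 1L), by = s), n - w + 1L))
  t_all <- seq_len(n)
  acc <- numeric(n)
  cnt <- numeric(n)
  for (st in starts) {
    sel <- st:(st + w - 1L)
    tt <- t_all[sel]
    fit <- stats::lm.fit(cbind(1, tt), x[sel])
    acc[sel] <- acc[sel] + fit$coefficients[1L] + fit$coefficients[2L] * tt
    cnt[sel] <- cnt[sel] + 1
  }
  x - acc / cnt
}

#' Instantaneous amplitude via the Hilbert transform
#'
#' Magnitude of the analytic signal, computed in the frequency domain
#' (positive frequencies doubled, negative zeroed).
#'
#' @param x numeric signal.
#' @return non-negative numeric vector, same length as `x`.
#' @export
instantaneous_amplitude <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}
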