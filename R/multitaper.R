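#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `K` DPSS tapers of length `n` with time-bandwidth
#' product `NW`, via the classical symmetric tridiagonal formulation: the
#' tapers are the top eigenvectors of the tridiagonal matrix with diagonal
#' `((n-1-2t)/2)^2 cos(2*pi*W)` and off-diagonal `t(n-t)/2`. The top
#' eigenvalues are found by Sturm-sequence bisection and the eigenvectors
#' by shifted tridiagonal inverse iteration, so no dense eigendecomposition
#' is formed. Tapers are unit-energy; results are cached per
#' `(n, NW, K)`.
#'
#' @param n taper length in samples.
#' @param NW time-(half-)bandwidth product (the spectral concentration
#'   half-width is `NW/n` in normalized frequency).
#' @param K number of tapers (usually `2*NW - 1`).
#' @return `n x K` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, NW = 2, K = 3) {
  key <- sprintf("n%d_NW%g_K%d", n, NW, K)
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)
  W <- NW / n
  t <- 0:(n - 1L)
  d <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  e <- (t * (n - t) / 2)[-1L]                 # off-diagonal, length n-1
  lams <- .trid_top_eigenvalues(d, e, K)
  V <- matrix(0, n, K)
  for (k in seq_len(K)) {
    V[, k] <- .trid_inverse_iter(d, e, lams[k], V[, seq_len(k - 1L), drop = FALSE])
  }
  # Sign convention: symmetric tapers have positive mean, antisymmetric
  # ones a positive initial slope.
  for (k in seq_len(K)) {
    s <- sum(V[, k])
    if (abs(s) > 1e-8) {
      if (s < 0) V[, k] <- -V[, k]
    } else if (sum(diff(V[, k])[1:2]) < 0) {
      V[, k] <- -V[, k]
    }
  }
  .taper_cache[[key]] <- V
  V
}

.taper_cache <- new.env(parent = emptyenv())

# Number of eigenvalues of the symmetric tridiagonal (d, e) below x,
# by the standard LDL^T Sturm count.
.sturm_count <- function(d, e, x) {
  n <- length(d)
  cnt <- 0L
  q <- d[1L] - x
  if (q < 0) cnt <- 1L
  for (i in 2:n) {
    q <- d[i] - x - e[i - 1L]^2 / if (q == 0) 1e-300 else q
    if (q < 0) cnt <- cnt + 1L
  }
  cnt
}

# The K largest eigenvalues of the symmetric tridiagonal (d, e),
# descending, by bisection on the Sturm count.
.trid_top_eigenvalues <- function(d, e, K) {
  n <- length(d)
  rad <- abs(d) + c(abs(e), 0) + c(0, abs(e))  # Gershgorin radii
  lo0 <- min(d - rad)
  hi0 <- max(d + rad)
  vapply(seq_len(K), function(k) {
    # k-th largest: count of eigenvalues below it is n - k
    lo <- lo0
    hi <- hi0
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (.sturm_count(d, e, mid) >= n - k + 1L) hi <- mid else lo <- mid
      if (hi - lo < 1e-10 * max(1, abs(hi))) break
    }
    (lo + hi) / 2
  }, numeric(1L))
}

# One eigenvector of (d, e) at eigenvalue lam by shifted inverse
# iteration with tridiagonal (Thomas) solves. The start vector must not
# sit in a symmetry class (DPSS eigenvectors alternate symmetric /
# antisymmetric), so a deterministic quasi-random start is used and the
# iterate is re-orthogonalized against the already-found vectors.
.trid_inverse_iter <- function(d, e, lam, prev) {
  n <- length(d)
  dd <- d - lam + 1e-10 * max(abs(d))
  v <- sin(seq_len(n) * 1.61803398875) + 0.3 * cos(seq_len(n) * 0.2357)
  v <- v / sqrt(sum(v^2))
  for (it in 1:6) {
    v <- .thomas_solve(dd, e, v)
    if (ncol(prev) > 0L) v <- v - prev %*% crossprod(prev, v)
    v <- v / sqrt(sum(v^2))
    # Rayleigh-quotient residual: stop once the eigenpair is tight.
    Tv <- d * v + c(e * v[-1L], 0) + c(0, e * v[-n])
    if (sqrt(sum((Tv - sum(v * Tv) * v)^2)) < 1e-8 * abs(lam)) break
  }
  as.numeric(v)
}

.thomas_solve <- function(d, e, b) {
  n <- length(d)
  cp <- numeric(n)
  bp <- numeric(n)
  denom <- d[1L]
  if (abs(denom) < 1e-300) denom <- 1e-300
  cp[1L] <- e[1L] / denom
  bp[1L] <- b[1L] / denom
  for (i in 2:n) {
    denom <- d[i] - e[i - 1L] * cp[i - 1L]
    if (abs(denom) < 1e-300) denom <- 1e-300
    if (i < n) cp[i] <- e[i] / denom
    bp[i] <- (b[i] - e[i - 1L] * bp[i - 1L]) / denom
  }
  x <- numeric(n)
  x[n] <- bp[n]
  for (i in (n - 1L):1L) x[i] <- bp[i] - cp[i] * x[i + 1L]
  x
}

#' Multitaper power spectral density of one window
#'
#' Averages the eigenspectra of `K` DPSS tapers (time-bandwidth product
#' `NW`), yielding a one-sided PSD on the natural FFT grid (`fs/n` Hz
#' resolution; 0.2 Hz for a 5-s window). Satisfies Parseval:
#' `sum(psd) * df` approximates the window variance.
#'
#' @param x numeric window (a single 5-s segment).
#' @param fs sampling rate in Hz.
#' @param NW,K multitaper parameters (defaults 2 and 3).
#' @return data.frame with `freq` (Hz) and `power` (units^2/Hz).
#' @export
multitaper_psd <- function(x, fs, NW = 2, K = 3) {
  n <- length(x)
  if (n < 8L) stop("window too short for spectral estimation")
  H <- dpss_tapers(n, NW, K)
  eig <- abs(fft_matrix(H * x))^2 / fs        # n x K two-sided eigenspectra
  S2 <- rowMeans(eig)
  .fold_onesided(S2, n, fs)
}

# Column-wise FFT of a matrix.
fft_matrix <- function(M) {
  apply(M, 2L, fft)
}

.fold_onesided <- function(S2, n, fs) {
  n_half <- n %/% 2L + 1L
  S <- S2[seq_len(n_half)]
  scale <- rep(2, n_half)
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[n_half] <- 1
  data.frame(freq = (seq_len(n_half) - 1L) * fs / n, power = S * scale)
}

#' Normalized band powers from a power spectrum
#'
#' Integrates the PSD over each band of the scheme (excluding the
#' scheme's gaps, e.g. 45-75 Hz) and divides by the summed power over
#' all bands, so the shares sum to 1. Shares are invariant to global
#' signal scaling.
#'
#' @param spec data.frame from [multitaper_psd()] (columns `freq`,
#'   `power`).
#' @param scheme a [band_scheme()].
#' @return data.frame with `band`, `power` (integrated, units^2) and
#'   `share`.
#' @export
band_powers <- function(spec, scheme = band_scheme()) {
  stopifnot(inherits(scheme, "band_scheme"))
  fmax <- max(spec$freq)
  if (any(scheme$bands$f_hi > fmax + 1e-9)) {
    stop("band extends beyond the spectrum's frequency support")
  }
  df <- spec$freq[2L] - spec$freq[1L]
  excl <- scheme$excluded
  keep <- rep(TRUE, nrow(spec))
  for (i in seq_len(nrow(excl))) {
    keep <- keep & !(spec$freq >= excl$f_lo[i] & spec$freq < excl$f_hi[i])
  }
  pow <- vapply(seq_len(nrow(scheme$bands)), function(i) {
    sel <- keep & spec$freq >= scheme$bands$f_lo[i] &
      spec$freq < scheme$bands$f_hi[i]
    sum(spec$power[sel]) * df
  }, numeric(1L))
  data.frame(band = scheme$bands$name, power = pow, share = pow / sum(pow))
}

#' Multitaper coherence spectrum between two channels
#'
#' Magnitude coherence from auto- and cross-spectra averaged over windows
#' and tapers, with the Fisher z-transform `atanh(C)` (C clipped at
#' 1 - 1e-6 so identical channels stay finite) and per-band mean z values
#' excluding the scheme's gaps.
#'
#' @param frontal_windows,occipital_windows lists of paired numeric
#'   windows (equal count, >= 2: coherence from a single window is
#'   degenerate and refused).
#' @param fs sampling rate in Hz.
#' @param NW,K multitaper parameters.
#' @param scheme a [band_scheme()] for the per-band summaries.
#' @return object of class `coherence_result`: list with `spectrum`
#'   (data.frame `freq`, `coherence`, `z`), `band_z` (data.frame `band`,
#'   `z`), `n_windows`.
#' @export
coherence_spectrum <- function(frontal_windows, occipital_windows, fs,
                               NW = 2, K = 3, scheme = band_scheme()) {
  nw <- length(frontal_windows)
  if (nw != length(occipital_windows)) stop("window lists must be paired")
  if (nw < 2L) stop("coherence needs at least 2 windows")
  n <- length(frontal_windows[[1L]])
  H <- dpss_tapers(n, NW, K)
  Sxx <- numeric(n)
  Syy <- numeric(n)
  Sxy <- complex(n)
  for (w in seq_len(nw)) {
    Fx <- fft_matrix(H * frontal_windows[[w]])
    Fy <- fft_matrix(H * occipital_windows[[w]])
    Sxx <- Sxx + rowSums(abs(Fx)^2)
    Syy <- Syy + rowSums(abs(Fy)^2)
    Sxy <- Sxy + rowSums(Fx * Conj(Fy))
  }
  C2 <- abs(Sxy) / sqrt(Sxx * Syy)
  n_half <- n %/% 2L + 1L
  freq <- (seq_len(n_half) - 1L) * fs / n
  C <- pmin(pmax(C2[seq_len(n_half)], 0), 1)
  z <- atanh(pmin(C, 1 - 1e-6))
  excl <- scheme$excluded
  keep <- rep(TRUE, n_half)
  for (i in seq_len(nrow(excl))) {
    keep <- keep & !(freq >= excl$f_lo[i] & freq < excl$f_hi[i])
  }
  band_z <- vapply(seq_len(nrow(scheme$bands)), function(i) {
    sel <- keep & freq >= scheme$bands$f_lo[i] & freq < scheme$bands$f_hi[i]
    mean(z[sel])
  }, numeric(1L))
  structure(
    list(
      spectrum = data.frame(freq = freq, coherence = C, z = z),
      band_z = data.frame(band = scheme$bands$name, z = band_z),
      n_windows = nw
    ),
    class = "coherence_result"
  )
}

#' Select artifact-free non-transition epochs
#'
#' An epoch is retained iff it is not an artifact and its state equals
#' that of both neighbors (the first and last epoch are compared to their
#' single neighbor) — the strictest reading of "non-transition". Spectral,
#' connectivity and complexity summaries all use this mask.
#'
#' @param h a [hypnogram()].
#' @return logical vector over epochs, with attribute `provenance`
#'   (`"artifact"`, `"transition"` or `"retained"` per epoch).
#' @export
select_epochs <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  lab <- h$labels
  n <- length(lab)
  if (n == 1L) {
    keep <- lab != "ARTIFACT"
  } else {
    prev_ok <- c(TRUE, lab[-1L] == lab[-n])     # equals left neighbor
    next_ok <- c(lab[-n] == lab[-1L], TRUE)     # equals right neighbor
    keep <- prev_ok & next_ok & lab != "ARTIFACT"
  }
  prov <- ifelse(lab == "ARTIFACT", "artifact",
                 ifelse(keep, "retained", "transition"))
  structure(keep, provenance = prov)
}

#' Per-state spectral power and coherence summary
#'
#' Computes, for each requested state over the retained (artifact-free,
#' non-transition) epochs: the mean multitaper PSD per channel, its
#' normalized band powers, and the frontal-occipital coherence with
#' per-band Fisher-z means. States with no retained epoch are reported
#' as missing (the REM-scarcity case); coherence additionally needs at
#' least 2 windows.
#'
#' @param session an [eeg_session()].
#' @param h the paired [hypnogram()].
#' @param scheme a [band_scheme()].
#' @param states states to summarize (default all three).
#' @param NW,K multitaper parameters.
#' @return named list per state: `NULL` for missing states, else a list
#'   with `n_windows`, `psd` (data.frame `freq`, `frontal`, `occipital`),
#'   `band_power` (data.frame `band`, `channel`, `power`, `share`) and
#'   `coherence` (a `coherence_result` or `NULL`).
#' @export
state_spectral_summary <- function(session, h, scheme = band_scheme(),
                                   states = STATES, NW = 2, K = 3) {
  mask <- select_epochs(h)
  wins <- epoch_windows(session, h, mask)
  out <- list()
  for (st in states) {
    sw <- Filter(function(w) w$state == st, wins)
    if (length(sw) == 0L) {
      out[[st]] <- NULL
      next
    }
    fw <- lapply(sw, `[[`, "frontal")
    ow <- lapply(sw, `[[`, "occipital")
    psd_f <- NULL
    psd_o <- NULL
    for (i in seq_along(fw)) {
      pf <- multitaper_psd(fw[[i]], session$fs, NW, K)
      po <- multitaper_psd(ow[[i]], session$fs, NW, K)
      if (is.null(psd_f)) {
        psd_f <- pf$power
        psd_o <- po$power
        freq <- pf$freq
      } else {
        psd_f <- psd_f + pf$power
        psd_o <- psd_o + po$power
      }
    }
    psd_f <- psd_f / length(fw)
    psd_o <- psd_o / length(fw)
    bp_f <- band_powers(data.frame(freq = freq, power = psd_f), scheme)
    bp_o <- band_powers(data.frame(freq = freq, power = psd_o), scheme)
    band_power <- rbind(
      cbind(channel = "frontal", bp_f),
      cbind(channel = "occipital", bp_o)
    )
    coh <- if (length(fw) >= 2L) {
      coherence_spectrum(fw, ow, session$fs, NW, K, scheme)
    } else {
      NULL
    }
    out[[st]] <- list(
      n_windows = length(fw),
      psd = data.frame(freq = freq, frontal = psd_f, occipital = psd_o),
      band_power = band_power,
      coherence = coh
    )
  }
  out
}
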