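#' Binarize an amplitude window at its mean
#'
#' 1 where the amplitude exceeds the window's own mean, 0 otherwise
#' (values equal to the mean map to 0, a deterministic tie rule that is
#' measure-zero for recorded data). The mean is computed per window,
#' never globally.
#'
#' @param window numeric vector (a 5-s instantaneous-amplitude segment).
#' @return integer vector of 0/1.
#' @export
binarize <- function(window) {
  if (length(window) == 0L) stop("cannot binarize an empty window")
  as.integer(window > mean(window))
}

#' Lempel-Ziv (LZ76) complexity of a binary sequence
#'
#' The number of distinct words in the exhaustive sequential parse of
#' the sequence: scanning left to right, a new word is registered
#' whenever the current phrase cannot be reproduced by copying from the
#' prior history; a final incomplete phrase counts as a word.
#'
#' @param b integer/logical vector of 0s and 1s (or a character string
#'   of `"0"`/`"1"`).
#' @return integer word count.
#' @examples
#' lz76(c(0, 0, 0, 1, 1, 0, 1, 0, 0, 1, 0, 0, 0, 1, 0, 1))  # 6
#' @export
lz76 <- function(b) {
  if (is.character(b) && length(b) == 1L) {
    b <- as.integer(strsplit(b, "")[[1L]])
  }
  b <- as.integer(b)
  if (length(b) == 0L) stop("cannot parse an empty sequence")
  if (!all(b %in% c(0L, 1L))) stop("sequence must be binary")
  .lz76_cpp(b)
}

# Phase-randomized surrogate: same magnitude spectrum, uniform random
# phases, conjugate-symmetric so the result is real.
.phase_surrogate <- function(x) {
  n <- length(x)
  X <- fft(x)
  mag <- Mod(X)
  half <- (n - 1L) %/% 2L                  # free phases excluding DC/Nyquist
  ph <- runif(half, 0, 2 * pi)
  phase <- numeric(n)
  if (half > 0L) {
    phase[2L:(half + 1L)] <- ph
    phase[n:(n - half + 1L)] <- -ph
  }
  Re(fft(mag * exp(1i * phase), inverse = TRUE) / n)
}

#' Surrogate-corrected Lempel-Ziv complexity of one window
#'
#' Raw LZc of the window (instantaneous amplitude, binarized at its
#' mean, LZ76-parsed) divided by the mean LZc of `n_surrogates`
#' phase-randomized surrogates. Each surrogate shares the window's
#' magnitude spectrum but has random phases, and is re-run through the
#' same amplitude-binarize-parse chain, so the correction removes what
#' is explainable by the linear spectral profile alone; values near 1
#' mean no complexity beyond the spectrum. Deterministic given `seed`.
#'
#' The window is expected to be already detrended and filtered (see
#' [detrend_local()] and [complexity_filter()]); [state_lzc()] performs
#' the whole chain.
#'
#' @param window numeric vector (band-limited signal segment).
#' @param n_surrogates number of phase-randomized surrogates (default 50).
#' @param seed integer seed.
#' @return list with `lzc` (corrected), `raw`, `surrogate_mean`; `lzc`
#'   is `NA` for a degenerate (constant) window.
#' @export
corrected_lzc <- function(window, n_surrogates = 50L, seed = NULL) {
  if (sd(window) == 0) {
    return(list(lzc = NA_real_, raw = NA_real_, surrogate_mean = NA_real_))
  }
  raw <- lz76(binarize(instantaneous_amplitude(window)))
  surr <- with_seed(seed, vapply(seq_len(n_surrogates), function(i) {
    s <- .phase_surrogate(window)
    lz76(binarize(instantaneous_amplitude(s)))
  }, numeric(1L)))
  sm <- mean(surr)
  if (sm == 0) {
    return(list(lzc = NA_real_, raw = raw, surrogate_mean = 0))
  }
  list(lzc = raw / sm, raw = raw, surrogate_mean = sm)
}

#' Per-state corrected Lempel-Ziv complexity
#'
#' Full complexity pipeline per channel: local-linear detrend, low-pass
#' at 115 Hz with the 45-75 Hz stop band, Hilbert instantaneous
#' amplitude, then per retained 5-s window binarize at the window mean,
#' LZ76 parse, and surrogate correction; window values are averaged per
#' state. Surrogates are drawn from the filtered signal window before
#' the Hilbert step, one independent set per window.
#'
#' @param session an [eeg_session()].
#' @param h the paired [hypnogram()].
#' @param channels channels to analyze (default frontal and occipital).
#' @param states states to analyze.
#' @param n_surrogates surrogates per window (default 50).
#' @param seed integer seed.
#' @return data.frame with `channel`, `state`, `lzc` (mean corrected),
#'   `raw` (mean), `surrogate_mean` (mean), `n_windows`; `NA` rows for
#'   states without retained windows.
#' @export
state_lzc <- function(session, h, channels = c("frontal", "occipital"),
                      states = STATES, n_surrogates = 50L, seed = NULL) {
  mask <- select_epochs(h)
  spe <- as.integer(round(h$epoch_s * session$fs))
  rows <- list()
  with_seed(seed, {
    for (ch in channels) {
      x <- session[[ch]]
      x <- detrend_local(x, session$fs)
      x <- complexity_filter(x, session$fs)
      filtered <- eeg_session(
        frontal = if (ch == "frontal") x else session$frontal,
        occipital = if (ch == "occipital") x else session$occipital,
        fs = session$fs, subject_id = session$subject_id,
        condition = session$condition
      )
      wins <- epoch_windows(filtered, h, mask)
      for (st in states) {
        sw <- Filter(function(w) w$state == st, wins)
        if (length(sw) == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            channel = ch, state = st, lzc = NA_real_, raw = NA_real_,
            surrogate_mean = NA_real_, n_windows = 0L
          )
          next
        }
        vals <- lapply(sw, function(w) {
          corrected_lzc(w[[ch]], n_surrogates = n_surrogates)
        })
        lzcs <- vapply(vals, `[[`, numeric(1L), "lzc")
        rows[[length(rows) + 1L]] <- data.frame(
          channel = ch, state = st,
          lzc = mean(lzcs, na.rm = TRUE),
          raw = mean(vapply(vals, `[[`, numeric(1L), "raw"), na.rm = TRUE),
          surrogate_mean = mean(
            vapply(vals, `[[`, numeric(1L), "surrogate_mean"), na.rm = TRUE),
          n_windows = sum(!is.na(lzcs))
        )
      }
    }
  })
  do.call(rbind, rows)
}
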