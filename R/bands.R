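#' Spectral band scheme
#'
#' Named frequency bands for power and coherence analysis, plus excluded
#' gaps removed from all spectral summaries. The default scheme covers
#' slow oscillations through high gamma with the 45-75 Hz range excluded
#' (a guard band around mains interference and its notch filters):
#' SO 0.5-1, delta 1-4, theta 4-9, sigma 9-15, beta 15-30, low gamma
#' 30-45, high gamma 75-115 Hz.
#'
#' @param bands data.frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @param excluded data.frame with columns `f_lo`, `f_hi`: frequency gaps
#'   dropped from every band integral.
#' @return object of class `band_scheme`.
#' @export
band_scheme <- function(bands = default_bands(), excluded = default_excluded()) {
  stopifnot(all(c("name", "f_lo", "f_hi") %in% names(bands)))
  if (any(bands$f_lo >= bands$f_hi)) stop("each band needs f_lo < f_hi")
  o <- order(bands$f_lo)
  bands <- bands[o, , drop = FALSE]
  if (nrow(bands) > 1L && any(bands$f_lo[-1L] < bands$f_hi[-nrow(bands)])) {
    stop("bands must not overlap")
  }
  structure(list(bands = bands, excluded = excluded), class = "band_scheme")
}

#' @rdname band_scheme
#' @export
default_bands <- function() {
  data.frame(
    name = c("SO", "delta", "theta", "sigma", "beta", "low_gamma", "high_gamma"),
    f_lo = c(0.5, 1, 4, 9, 15, 30, 75),
    f_hi = c(1, 4, 9, 15, 30, 45, 115)
  )
}

#' @rdname band_scheme
#' @export
default_excluded <- function() data.frame(f_lo = 45, f_hi = 75)

#' @export
print.band_scheme <- function(x, ...) {
  cat("<band_scheme>\n")
  for (i in seq_len(nrow(x$bands))) {
    cat(sprintf(
      "  %-10s %5.1f - %5.1f Hz\n",
      x$bands$name[i], x$bands$f_lo[i], x$bands$f_hi[i]
    ))
  }
  if (nrow(x$excluded) > 0L) {
    cat(sprintf(
      "  excluded:  %s\n",
      paste(sprintf("%g-%g Hz", x$excluded$f_lo, x$excluded$f_hi), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Band scheme for symbolic transfer entropy
#'
#' Each band carries the ordinal-pattern embedding delay `tau` (in samples
#' at 512 Hz) that tunes the symbolization to that band's timescale. The
#' default table is delta 0.5-4 Hz (tau 64), theta 4-9 (28), sigma 9-15
#' (17), beta 15-30 (9), low gamma 30-45 (6), high gamma 75-115 (2), with
#' embedding dimension 3 and a transfer-time search over 1-50 samples
#' (about 2-100 ms at 512 Hz).
#'
#' @param entries data.frame with columns `name`, `f_lo`, `f_hi`,
#'   `tau_samples`.
#' @param embedding_dimension ordinal-pattern length (default 3).
#' @param delta_search integer vector of candidate transfer times in
#'   samples.
#' @return object of class `nste_band_scheme`.
#' @export
nste_band_scheme <- function(entries = default_nste_bands(),
                             embedding_dimension = 3L,
                             delta_search = 1:50) {
  stopifnot(all(c("name", "f_lo", "f_hi", "tau_samples") %in% names(entries)))
  if (any(entries$tau_samples < 1)) stop("all tau values must be >= 1 sample")
  if (length(delta_search) == 0L) stop("delta_search must be non-empty")
  structure(
    list(
      entries = entries,
      embedding_dimension = as.integer(embedding_dimension),
      delta_search = as.integer(delta_search)
    ),
    class = "nste_band_scheme"
  )
}

#' @rdname nste_band_scheme
#' @export
default_nste_bands <- function() {
  data.frame(
    name = c("delta", "theta", "sigma", "beta", "low_gamma", "high_gamma"),
    f_lo = c(0.5, 4, 9, 15, 30, 75),
    f_hi = c(4, 9, 15, 30, 45, 115),
    tau_samples = c(64L, 28L, 17L, 9L, 6L, 2L)
  )
}

#' @export
print.nste_band_scheme <- function(x, ...) {
  cat(sprintf(
    "<nste_band_scheme> dE = %d, delta search %d-%d samples\n",
    x$embedding_dimension, min(x$delta_search), max(x$delta_search)
  ))
  for (i in seq_len(nrow(x$entries))) {
    cat(sprintf(
      "  %-10s %5.1f - %5.1f Hz  tau = %d\n",
      x$entries$name[i], x$entries$f_lo[i], x$entries$f_hi[i],
      x$entries$tau_samples[i]
    ))
  }
  invisible(x)
}
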