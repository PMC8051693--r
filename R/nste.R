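#' Ordinal-pattern symbolization of a time series
#'
#' Maps each time point to the rank permutation of the delayed triplet
#' `(x(t), x(t+tau), ..., x(t+(dE-1)tau))`. Ties are broken by temporal
#' order (the earlier sample ranks lower), so the map is deterministic
#' and the symbols are invariant under any strictly monotone transform
#' of the signal. With embedding dimension `dE` the alphabet has `dE!`
#' symbols, indexed 0 to `dE!-1` in lexicographic order of the rank
#' vector.
#'
#' @param x numeric series of length `> (dE-1)*tau`.
#' @param dE embedding dimension (default 3).
#' @param tau embedding delay in samples.
#' @return object of class `symbol_series`: list with `symbols`
#'   (integers in `[0, dE!-1]`), `dE`, `tau`, `source_length`.
#' @export
symbolize <- function(x, dE = 3L, tau) {
  dE <- as.integer(dE)
  tau <- as.integer(tau)
  n <- length(x)
  m <- n - (dE - 1L) * tau
  if (m < 1L) stop("series too short for this embedding")
  emb <- vapply(0:(dE - 1L), function(j) x[(1L + j * tau):(m + j * tau)],
                numeric(m))
  if (!is.matrix(emb)) emb <- matrix(emb, nrow = 1L)
  # Rank of each coordinate within its row; ties -> temporal order, which
  # base rank() delivers with ties.method = "first".
  ranks <- t(apply(emb, 1L, rank, ties.method = "first"))
  # Lexicographic index of the rank vector: treat (r1..rdE) as digits.
  sym <- integer(m)
  for (j in seq_len(dE)) sym <- sym * dE + (ranks[, j] - 1L)
  # Compress the dE^dE codes onto 0..dE!-1 via the table of valid codes.
  perms <- .permutation_codes(dE)
  structure(
    list(symbols = match(sym, perms) - 1L, dE = dE, tau = tau,
         source_length = n),
    class = "symbol_series"
  )
}

# Codes (base-dE digit encodings) of all dE! rank vectors, sorted.
.permutation_codes <- function(dE) {
  perm <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  codes <- vapply(perm(seq_len(dE)), function(p) {
    s <- 0L
    for (j in seq_len(dE)) s <- s * dE + (p[j] - 1L)
    s
  }, integer(1L))
  sort(codes)
}

#' Symbolic transfer entropy between two symbol series
#'
#' `TE(X -> Y) = H(Y_{t+delta} | Y_t) - H(Y_{t+delta} | Y_t, X_t)` in
#' bits, with all entropies from the empirical joint symbol frequencies
#' within the window (plug-in estimator). Non-negative up to estimator
#' noise.
#'
#' @param xs,ys [symbolize()]d source and target series of equal length.
#' @param delta transfer time in symbol-series samples.
#' @return list with `te` (bits), `h_cond` (`H(Y_future | Y_past)`,
#'   bits, the normalization ceiling), `n` (joint samples), and
#'   `small_sample` (`TRUE` when `n < dE!^2`).
#' @export
symbolic_te <- function(xs, ys, delta) {
  stopifnot(inherits(xs, "symbol_series"), inherits(ys, "symbol_series"))
  if (length(xs$symbols) != length(ys$symbols)) {
    stop("symbol series must be aligned (equal length)")
  }
  A <- factorial(xs$dE)
  m <- length(ys$symbols)
  if (delta >= m) stop("delta too large for these series")
  yf <- ys$symbols[(1L + delta):m]
  yp <- ys$symbols[1L:(m - delta)]
  xp <- xs$symbols[1L:(m - delta)]
  n <- length(yf)
  ent <- function(counts) {
    p <- counts[counts > 0] / n
    -sum(p * log2(p))
  }
  h_yf_yp <- ent(tabulate(1L + yf + A * yp, nbins = A * A))
  h_yp <- ent(tabulate(1L + yp, nbins = A))
  h_yp_xp <- ent(tabulate(1L + yp + A * xp, nbins = A * A))
  h_yf_yp_xp <- ent(tabulate(1L + yf + A * yp + A * A * xp, nbins = A^3))
  h_cond <- h_yf_yp - h_yp
  te <- h_yf_yp + h_yp_xp - h_yf_yp_xp - h_yp
  list(te = te, h_cond = h_cond, n = n, small_sample = n < A * A)
}

#' Normalized symbolic transfer entropy for one window pair
#'
#' For each direction independently, searches the transfer time over
#' `delta_search` and keeps the maximum of the normalized STE
#' `(TE - TE_shuffled) / H(Y_future | Y_past)`, clipped to `[0, 1]`,
#' where `TE_shuffled` is the mean STE over `n_shuffle` full random
#' permutations of the source symbol series (the shuffle estimates the
#' finite-sample bias; permuting the source destroys directed coupling
#' but preserves its symbol distribution). "Feedback" is the
#' frontal-to-occipital direction, "feedforward" occipital-to-frontal.
#'
#' @param frontal,occipital numeric windows (already band-limited).
#' @param band_entry one row of an [nste_band_scheme()] entries table
#'   (uses `tau_samples`), or a plain `tau` via the `tau` argument.
#' @param fs sampling rate in Hz (only used to report delta in ms).
#' @param dE embedding dimension.
#' @param delta_search integer vector of candidate transfer times.
#' @param n_shuffle surrogates for the bias term (default 20).
#' @param tau embedding delay in samples (overrides `band_entry`).
#' @param seed integer seed for the shuffles.
#' @return list with `feedback`, `feedforward` (each
#'   `list(nste, delta, te, te_shuffled, h_cond)`), or `NULL` entries for
#'   degenerate (constant) windows.
#' @export
nste_window <- function(frontal, occipital, band_entry = NULL, fs = 512,
                        dE = 3L, delta_search = 1:50, n_shuffle = 20L,
                        tau = NULL, seed = NULL) {
  if (is.null(tau)) {
    if (is.null(band_entry)) stop("give either band_entry or tau")
    tau <- band_entry$tau_samples
  }
  if (sd(frontal) == 0 || sd(occipital) == 0) {
    return(list(feedback = NULL, feedforward = NULL))
  }
  xf <- symbolize(frontal, dE, tau)
  xo <- symbolize(occipital, dE, tau)
  with_seed(seed, list(
    feedback = .nste_direction(xf, xo, delta_search, n_shuffle),
    feedforward = .nste_direction(xo, xf, delta_search, n_shuffle)
  ))
}

# Maximize normalized STE over the transfer-time search for one
# direction (xs -> ys). Shuffle surrogates are drawn once per window
# and reused across candidate deltas.
.nste_direction <- function(xs, ys, delta_search, n_shuffle) {
  shuffles <- lapply(seq_len(n_shuffle), function(i) {
    s <- xs
    s$symbols <- sample(s$symbols)
    s
  })
  best <- NULL
  for (delta in delta_search) {
    r <- symbolic_te(xs, ys, delta)
    if (r$h_cond <= 0) next
    te_sh <- mean(vapply(shuffles, function(s) symbolic_te(s, ys, delta)$te,
                         numeric(1L)))
    nste <- min(max((r$te - te_sh) / r$h_cond, 0), 1)
    if (is.null(best) || nste > best$nste) {
      best <- list(nste = nste, delta = delta, te = r$te,
                   te_shuffled = te_sh, h_cond = r$h_cond)
    }
  }
  best
}

#' Per-state band-specific NSTE summary
#'
#' Band-pass filters the session's cortical channels per NSTE band,
#' segments the filtered signals into the retained (artifact-free,
#' non-transition) 5-s windows of each state, runs the per-window
#' transfer-time search in both directions, and averages. States with no
#' retained window are reported as missing.
#'
#' @param session an [eeg_session()].
#' @param h the paired [hypnogram()].
#' @param scheme an [nste_band_scheme()].
#' @param states states to analyze.
#' @param n_shuffle shuffle surrogates per window.
#' @param seed integer seed.
#' @return data.frame with `state`, `band`, `direction`, `nste` (mean),
#'   `n_windows`, `mean_delta`.
#' @export
state_nste <- function(session, h, scheme = nste_band_scheme(),
                       states = STATES, n_shuffle = 20L, seed = NULL) {
  stopifnot(inherits(scheme, "nste_band_scheme"))
  mask <- select_epochs(h)
  rows <- list()
  with_seed(seed, {
    for (bi in seq_len(nrow(scheme$entries))) {
      entry <- scheme$entries[bi, ]
      filt <- eeg_session(
        frontal = bandpass(session$frontal, c(entry$f_lo, entry$f_hi),
                           session$fs),
        occipital = bandpass(session$occipital, c(entry$f_lo, entry$f_hi),
                             session$fs),
        fs = session$fs, subject_id = session$subject_id,
        condition = session$condition
      )
      wins <- epoch_windows(filt, h, mask)
      for (st in states) {
        sw <- Filter(function(w) w$state == st, wins)
        if (length(sw) == 0L) {
          for (dir in c("feedback", "feedforward")) {
            rows[[length(rows) + 1L]] <- data.frame(
              state = st, band = entry$name, direction = dir,
              nste = NA_real_, n_windows = 0L, mean_delta = NA_real_
            )
          }
          next
        }
        res <- lapply(sw, function(w) {
          nste_window(w$frontal, w$occipital, tau = entry$tau_samples,
                      fs = session$fs, dE = scheme$embedding_dimension,
                      delta_search = scheme$delta_search,
                      n_shuffle = n_shuffle)
        })
        for (dir in c("feedback", "feedforward")) {
          vals <- vapply(res, function(r) {
            if (is.null(r[[dir]])) NA_real_ else r[[dir]]$nste
          }, numeric(1L))
          deltas <- vapply(res, function(r) {
            if (is.null(r[[dir]])) NA_real_ else as.numeric(r[[dir]]$delta)
          }, numeric(1L))
          rows[[length(rows) + 1L]] <- data.frame(
            state = st, band = entry$name, direction = dir,
            nste = mean(vals, na.rm = TRUE),
            n_windows = sum(!is.na(vals)),
            mean_delta = mean(deltas, na.rm = TRUE)
          )
        }
      }
    }
  })
  do.call(rbind, rows)
}
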