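#' Construct an EEG session
#'
#' Holds the two cortical channels of a recording session (frontal and
#' occipital screw electrodes), an optional nuchal EMG channel, the sampling
#' rate, and pairing metadata. All channels must be the same length.
#'
#' @param frontal numeric vector, frontal EEG.
#' @param occipital numeric vector, occipital EEG.
#' @param emg optional numeric vector, EMG.
#' @param fs sampling rate in Hz.
#' @param subject_id subject identifier.
#' @param condition `"control"` or `"treatment"`.
#' @return An object of class `eeg_session`.
#' @export
eeg_session <- function(frontal, occipital, emg = NULL, fs,
                        subject_id = NA_character_,
                        condition = c("control", "treatment")) {
  condition <- match.arg(condition)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (length(frontal) != length(occipital)) {
    stop("frontal and occipital channels must have the same length")
  }
  if (!is.null(emg) && length(emg) != length(frontal)) {
    stop("emg channel must match the EEG channel length")
  }
  structure(
    list(
      frontal = as.numeric(frontal), occipital = as.numeric(occipital),
      emg = if (is.null(emg)) NULL else as.numeric(emg),
      fs = as.numeric(fs), subject_id = as.character(subject_id),
      condition = condition
    ),
    class = "eeg_session"
  )
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf(
    "<eeg_session> subject %s (%s): %d samples @ %g Hz (%.1f s)%s\n",
    x$subject_id, x$condition, length(x$frontal), x$fs,
    length(x$frontal) / x$fs, if (is.null(x$emg)) "" else " + EMG"
  ))
  invisible(x)
}

#' Read EEG channels from a delimited text file
#'
#' Expects columns named `frontal`, `occipital` and optionally `emg` (or,
#' unnamed, in that order). The sampling rate comes from `fs`, or from a
#' plain-text sidecar file `<path>.meta` containing a line `fs: <Hz>`.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz; if `NULL`, read from the sidecar.
#' @param subject_id,condition pairing metadata passed to [eeg_session()].
#' @return an [eeg_session()].
#' @export
read_signals <- function(path, fs = NULL, subject_id = NA_character_,
                         condition = "control") {
  if (!file.exists(path)) stop("signal file not found: ", path)
  if (is.null(fs)) {
    meta <- paste0(path, ".meta")
    if (!file.exists(meta)) {
      stop("sampling rate not given and no sidecar file found: ", meta)
    }
    lines <- readLines(meta, warn = FALSE)
    m <- regmatches(lines, regexec("^\\s*fs\\s*[:=]\\s*([0-9.]+)", lines))
    hit <- vapply(m, length, 1L) == 2L
    if (!any(hit)) stop("no 'fs:' entry in sidecar file ", meta)
    fs <- as.numeric(m[[which(hit)[1L]]][2L])
  }
  dat <- read.csv(path)
  nm <- tolower(names(dat))
  if (ncol(dat) < 2L) stop("signal file must contain at least 2 channels")
  pick <- function(name, fallback) {
    i <- match(name, nm)
    if (is.na(i)) i <- fallback
    dat[[i]]
  }
  emg <- if ("emg" %in% nm || ncol(dat) >= 3L) pick("emg", 3L) else NULL
  eeg_session(
    frontal = pick("frontal", 1L), occipital = pick("occipital", 2L),
    emg = emg, fs = fs, subject_id = subject_id, condition = condition
  )
}

#' Write EEG channels to CSV with a sampling-rate sidecar
#'
#' @param session an [eeg_session()].
#' @param path output CSV path; a sidecar `<path>.meta` records `fs`.
#' @return `path`, invisibly.
#' @export
write_signals <- function(session, path) {
  stopifnot(inherits(session, "eeg_session"))
  dat <- data.frame(frontal = session$frontal, occipital = session$occipital)
  if (!is.null(session$emg)) dat$emg <- session$emg
  write.csv(dat, path, row.names = FALSE)
  writeLines(sprintf("fs: %g", session$fs), paste0(path, ".meta"))
  invisible(path)
}

#' Downsample a session with anti-alias filtering
#'
#' Resamples every channel with the polyphase method (`signal::resample`),
#' which low-pass filters before decimating, and updates `fs`. The typical
#' use is the 1024 -> 512 Hz reduction applied before spectral analysis.
#'
#' @param session an [eeg_session()].
#' @param fs_out target sampling rate in Hz; must satisfy `0 < fs_out <= fs`.
#' @return an [eeg_session()] at `fs_out`.
#' @export
downsample <- function(session, fs_out) {
  stopifnot(inherits(session, "eeg_session"))
  if (!is.numeric(fs_out) || length(fs_out) != 1L || fs_out <= 0) {
    stop("fs_out must be a single positive number")
  }
  if (fs_out > session$fs) {
    stop("fs_out exceeds the session sampling rate (no upsampling)")
  }
  if (fs_out == session$fs) return(session)
  frac <- .rat_approx(fs_out / session$fs)
  res <- function(x) as.numeric(signal::resample(x, frac[1L], frac[2L]))
  eeg_session(
    frontal = res(session$frontal), occipital = res(session$occipital),
    emg = if (is.null(session$emg)) NULL else res(session$emg),
    fs = fs_out, subject_id = session$subject_id,
    condition = session$condition
  )
}

# Small-denominator rational approximation p/q of a ratio in (0, 1].
.rat_approx <- function(r, max_q = 1024L) {
  q <- seq_len(max_q)
  err <- abs(r * q - round(r * q))
  qq <- q[which(err < 1e-9)[1L]]
  if (is.na(qq)) qq <- q[which.min(err)]
  c(as.integer(round(r * qq)), qq)
}

#' Segment a session into per-epoch windows
#'
#' Epoch `k` (0-based) covers samples `[k * epoch_s * fs, (k+1) * epoch_s *
#' fs)`, a half-open partition with no overlap. Only epochs selected by
#' `mask` are returned; each element carries the epoch's state label and the
#' per-channel sample segments.
#'
#' @param session an [eeg_session()].
#' @param h the paired [hypnogram()]; session and hypnogram durations must
#'   agree to within one epoch.
#' @param mask logical vector over epochs (default: all epochs whose full
#'   window fits in the recording). See [select_epochs()] for the
#'   artifact-free non-transition mask.
#' @return list of entries `list(epoch, state, frontal, occipital, emg)`,
#'   with `epoch` the 1-based epoch index.
#' @export
epoch_windows <- function(session, h, mask = NULL) {
  stopifnot(inherits(session, "eeg_session"), inherits(h, "hypnogram"))
  spe <- h$epoch_s * session$fs
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch_s * fs must be an integer number of samples")
  }
  spe <- as.integer(round(spe))
  n_epochs <- length(h$labels)
  dur_diff <- abs(length(session$frontal) / session$fs - duration(h))
  if (dur_diff >= h$epoch_s) {
    stop("session and hypnogram misaligned by more than one epoch")
  }
  n_full <- min(n_epochs, length(session$frontal) %/% spe)
  if (is.null(mask)) mask <- seq_len(n_epochs) <= n_full
  if (length(mask) > n_epochs) stop("mask longer than the hypnogram")
  mask <- mask & (seq_along(mask) <= n_full)
  idx <- which(mask)
  lapply(idx, function(k) {
    sel <- ((k - 1L) * spe + 1L):(k * spe)
    list(
      epoch = k, state = h$labels[k],
      frontal = session$frontal[sel], occipital = session$occipital[sel],
      emg = if (is.null(session$emg)) NULL else session$emg[sel]
    )
  })
}
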