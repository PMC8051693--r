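#' Markov chain parameters for hypnogram simulation
#'
#' First-order Markov dynamics over (W, NREM, REM) at the scoring epoch
#' resolution: the distribution of the next epoch's state depends only on
#' the current state. Rows of `P` must be stochastic.
#'
#' @param P 3x3 row-stochastic matrix with rows/columns ordered
#'   (W, NREM, REM); `P[i, j]` is P(next = j | current = i).
#' @param initial_state starting state.
#' @param epoch_s epoch length in seconds.
#' @param n_epochs number of epochs (default 4320 = 6 h at 5 s).
#' @return object of class `chain_params`.
#' @export
chain_params <- function(P, initial_state = "W", epoch_s = 5,
                         n_epochs = 4320L) {
  P <- as.matrix(P)
  if (!all(dim(P) == c(3L, 3L))) stop("P must be a 3x3 matrix")
  if (any(P < 0)) stop("P entries must be non-negative")
  if (any(abs(rowSums(P) - 1) > 1e-12)) {
    stop("rows of P must sum to 1 (within 1e-12)")
  }
  dimnames(P) <- list(STATES, STATES)
  initial_state <- parse_state_labels(initial_state)
  if (initial_state == "ARTIFACT") stop("initial_state must be a true state")
  structure(
    list(P = P, initial_state = initial_state,
         epoch_s = as.numeric(epoch_s), n_epochs = as.integer(n_epochs)),
    class = "chain_params"
  )
}

#' Default transition matrices for the two treatment arms
#'
#' Row-stochastic 3x3 matrices built from published group-mean transition
#' probabilities in chemogenetically stimulated mice (treatment) and
#' vehicle controls, with each row renormalized to sum exactly to 1
#' (printed means do not). W never transitions directly to REM in either
#' arm. Note: the source reports the same control value (0.9621) for
#' remaining in NREM and remaining in REM, possibly a transcription
#' duplicate; it is used verbatim here.
#'
#' @param arm `"control"` (vehicle) or `"treatment"` (stimulation).
#' @return 3x3 row-stochastic matrix over (W, NREM, REM).
#' @export
default_transition_matrix <- function(arm = c("control", "treatment")) {
  arm <- match.arg(arm)
  P <- if (arm == "control") {
    rbind(
      W    = c(0.9205, 0.0790, 0),
      NREM = c(0.0310, 0.9621, 0.0072),
      REM  = c(0.0625, 0.0030, 0.9621)
    )
  } else {
    rbind(
      W    = c(0.8983, 0.1017, 0),
      NREM = c(0.0600, 0.9384, 0.0017),
      REM  = c(0.0833, 0.0110, 0.9052)
    )
  }
  P <- P / rowSums(P)
  dimnames(P) <- list(STATES, STATES)
  P
}

#' Simulate a hypnogram from a Markov chain
#'
#' @param params a [chain_params()].
#' @param seed integer seed; identical inputs and seed give identical
#'   output.
#' @return a [hypnogram()] whose first label is `initial_state`.
#' @examples
#' p <- chain_params(default_transition_matrix("control"), n_epochs = 720)
#' h <- simulate_hypnogram(p, seed = 1)
#' @export
simulate_hypnogram <- function(params, seed = NULL) {
  stopifnot(inherits(params, "chain_params"))
  with_seed(seed, {
    cum <- t(apply(params$P, 1L, cumsum))
    n <- params$n_epochs
    u <- runif(n - 1L)
    s <- integer(n)
    s[1L] <- match(params$initial_state, STATES)
    for (k in 2L:n) {
      r <- cum[s[k - 1L], ]
      s[k] <- 1L + (u[k - 1L] > r[1L]) + (u[k - 1L] > r[2L])
    }
    hypnogram(STATES[s], epoch_s = params$epoch_s)
  })
}

#' State-conditioned EEG synthesis parameters
#'
#' Describes, per vigilance state, a set of band-limited oscillators
#' (center frequency, amplitude, per-channel weights), a 1/f^alpha
#' background-noise process, an EMG tone level, and a directed linear
#' coupling between the cortical channels (the occipital channel receives
#' a delayed, scaled copy of the frontal one, or vice versa) whose
#' direction and lag are exactly known — the ground truth for directed
#' connectivity recovery.
#'
#' Defaults emulate the classic state signatures: high-amplitude slow
#' oscillations and delta with sigma-band spindles in NREM, a prominent
#' regular theta rhythm in REM, and low-amplitude broadband activity with
#' high EMG tone in wakefulness.
#'
#' @param states named list (W, NREM, REM) of per-state settings, each
#'   `list(oscillators = data.frame(freq, amp, w_frontal, w_occipital),
#'   noise_alpha =, noise_amp =, emg =)`.
#' @param coupling `list(direction = "frontal_to_occipital" |
#'   "occipital_to_frontal" | "none", lag_ms =, gain =)`.
#' @param fs sampling rate in Hz.
#' @return object of class `state_eeg_params`.
#' @export
state_eeg_params <- function(states = default_state_eeg(), coupling =
                               list(direction = "frontal_to_occipital",
                                    lag_ms = 20, gain = 0.8),
                             fs = 512) {
  for (st in STATES) {
    if (is.null(states[[st]])) stop("missing state settings for ", st)
    if (any(states[[st]]$oscillators$amp < 0)) stop("amplitudes must be >= 0")
  }
  if (coupling$lag_ms < 0) stop("coupling lag must be >= 0")
  if (fs <= 0) stop("fs must be positive")
  structure(list(states = states, coupling = coupling, fs = fs),
            class = "state_eeg_params")
}

#' @rdname state_eeg_params
#' @export
default_state_eeg <- function() {
  osc <- function(freq, amp, wf, wo) {
    data.frame(freq = freq, amp = amp, w_frontal = wf, w_occipital = wo)
  }
  list(
    W = list(
      oscillators = osc(c(7.5, 35), c(0.4, 0.15), c(0.8, 1), c(1, 0.9)),
      noise_alpha = 1.0, noise_amp = 1.0, emg = 1.0
    ),
    NREM = list(
      oscillators = osc(c(0.75, 2.5, 11), c(3.0, 1.0, 0.4),
                        c(1, 1, 0.9), c(0.8, 0.9, 1)),
      noise_alpha = 2.0, noise_amp = 0.5, emg = 0.2
    ),
    REM = list(
      oscillators = osc(7, 1.2, 0.7, 1),
      noise_alpha = 1.5, noise_amp = 0.5, emg = 0.05
    )
  )
}

# 1/f^(alpha/2)-shaped Gaussian noise of length n via spectral shaping.
.pink_noise <- function(n, alpha, fs) {
  if (n == 0L) return(numeric(0))
  if (alpha == 0) return(rnorm(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)                       # two-sided frequency magnitude
  g <- ifelse(f < fs / n, 1, (f / (fs / n))^(-alpha / 2))
  x <- Re(fft(W * g, inverse = TRUE)) / n
  x / sd(x)
}

#' Synthesize state-conditioned EEG for a hypnogram
#'
#' Each bout (maximal same-state run) is rendered with that state's
#' oscillators and 1/f background; oscillator phases are randomized per
#' bout, not per epoch, so no artificial periodicity at the epoch length
#' is introduced. The directed coupling then adds `gain` times the
#' lagged source channel into the target channel.
#'
#' @param h a [hypnogram()].
#' @param params a [state_eeg_params()].
#' @param seed integer seed.
#' @param subject_id,condition metadata for the returned session.
#' @return an [eeg_session()] of length `length(h) * epoch_s * fs` samples.
#' @export
synthesize_eeg <- function(h, params, seed = NULL,
                           subject_id = NA_character_,
                           condition = "control") {
  stopifnot(inherits(h, "hypnogram"), inherits(params, "state_eeg_params"))
  fs <- params$fs
  spe <- as.integer(round(h$epoch_s * fs))
  lag <- as.integer(round(params$coupling$lag_ms / 1000 * fs))
  if (lag >= spe) stop("coupling lag must be shorter than one epoch window")
  with_seed(seed, {
    bouts <- segment_bouts(h)
    n_total <- length(h$labels) * spe
    frontal <- numeric(n_total)
    occipital <- numeric(n_total)
    emg <- numeric(n_total)
    for (b in seq_len(nrow(bouts))) {
      st <- bouts$state[b]
      i0 <- as.integer(round(bouts$start_s[b] / h$epoch_s)) * spe
      len <- as.integer(round(bouts$duration_s[b] / h$epoch_s)) * spe
      idx <- (i0 + 1L):(i0 + len)
      tt <- (seq_len(len) - 1L) / fs
      sp <- if (st == "ARTIFACT") params$states[["W"]] else params$states[[st]]
      f_sig <- numeric(len)
      o_sig <- numeric(len)
      oscs <- sp$oscillators
      for (j in seq_len(nrow(oscs))) {
        ph <- runif(1L, 0, 2 * pi)
        wave <- oscs$amp[j] * sin(2 * pi * oscs$freq[j] * tt + ph)
        f_sig <- f_sig + oscs$w_frontal[j] * wave
        o_sig <- o_sig + oscs$w_occipital[j] * wave
      }
      if (sp$noise_amp > 0) {
        f_sig <- f_sig + sp$noise_amp * .pink_noise(len, sp$noise_alpha, fs)
        o_sig <- o_sig + sp$noise_amp * .pink_noise(len, sp$noise_alpha, fs)
      }
      if (st == "ARTIFACT") {                # saturating artifact segments
        f_sig <- f_sig + 10 * rnorm(len)
        o_sig <- o_sig + 10 * rnorm(len)
      }
      frontal[idx] <- f_sig
      occipital[idx] <- o_sig
      emg[idx] <- sp$emg * abs(rnorm(len))
    }
    cp <- params$coupling
    if (cp$direction == "frontal_to_occipital" && cp$gain != 0) {
      occipital <- occipital + cp$gain * .lagged(frontal, lag)
    } else if (cp$direction == "occipital_to_frontal" && cp$gain != 0) {
      frontal <- frontal + cp$gain * .lagged(occipital, lag)
    }
    eeg_session(frontal, occipital, emg = emg, fs = fs,
                subject_id = subject_id, condition = condition)
  })
}

.lagged <- function(x, lag) {
  if (lag == 0L) return(x)
  c(numeric(lag), x[seq_len(length(x) - lag)])
}

#' Simulate a paired cohort with known ground truth
#'
#' Generates `n_subjects` control/treatment session pairs from the given
#' chain and (optionally) EEG parameters, using per-subject seeds derived
#' from `seed`. Optional between-subject variability perturbs each
#' subject's transition matrix by adding Gaussian jitter to every row
#' (then clipping at 0 and renormalizing); structural zeros (entries that
#' are exactly 0, e.g. W to REM) are preserved.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param control,treatment per-arm `list(chain = chain_params, eeg =
#'   state_eeg_params or NULL)`. When `eeg` is `NULL`, only hypnograms are
#'   generated (the state-dynamics battery needs nothing else).
#' @param seed integer master seed.
#' @param jitter_sd standard deviation of the per-subject transition
#'   probability jitter (default 0: every subject uses the arm matrix
#'   verbatim).
#' @return a [paired_cohort()]; each arm entry is
#'   `list(hypnogram =, session =, chain =)`, where `chain` records the
#'   subject's realized generating parameters.
#' @export
make_cohort <- function(n_subjects, control, treatment, seed = NULL,
                        jitter_sd = 0) {
  stopifnot(n_subjects >= 1L)
  subjects <- with_seed(seed, {
    subj_seeds <- sample.int(2147483646L, n_subjects * 4L)
    out <- list()
    for (i in seq_len(n_subjects)) {
      id <- sprintf("S%02d", i)
      arms <- list()
      for (a in c("control", "treatment")) {
        arm <- if (a == "control") control else treatment
        k <- (i - 1L) * 4L + if (a == "control") 1L else 3L
        chain <- arm$chain
        if (jitter_sd > 0) {
          chain <- .jitter_chain(chain, jitter_sd, seed = subj_seeds[k + 1L])
        }
        hyp <- simulate_hypnogram(chain, seed = subj_seeds[k])
        sess <- if (!is.null(arm$eeg)) {
          synthesize_eeg(hyp, arm$eeg, seed = subj_seeds[k + 1L],
                         subject_id = id, condition = a)
        } else {
          NULL
        }
        arms[[a]] <- list(hypnogram = hyp, session = sess, chain = chain)
      }
      out[[id]] <- arms
    }
    out
  })
  paired_cohort(subjects)
}

.jitter_chain <- function(chain, sd, seed) {
  with_seed(seed, {
    P <- chain$P
    zero <- P == 0
    P <- pmax(P + matrix(rnorm(9L, 0, sd), 3L), 0)
    P[zero] <- 0
    P <- P / rowSums(P)
    chain_params(P, initial_state = chain$initial_state,
                 epoch_s = chain$epoch_s, n_epochs = chain$n_epochs)
  })
}
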