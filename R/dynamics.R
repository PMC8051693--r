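#' Segment a hypnogram into bouts
#'
#' A bout is a maximal run of consecutive epochs in the same state.
#' Artifact runs form their own bouts (downstream state statistics skip
#' them). Bouts tile the hypnogram without gaps or overlap.
#'
#' @param h a [hypnogram()].
#' @return data.frame with columns `state`, `start_s`, `duration_s`.
#' @examples
#' segment_bouts(hypnogram(c("W", "W", "NREM", "NREM", "NREM", "W")))
#' @export
segment_bouts <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  r <- rle(h$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(
    state = r$values,
    start_s = h$t0 + starts * h$epoch_s,
    duration_s = r$lengths * h$epoch_s
  )
}

#' Time spent in each state, total or per bin
#'
#' @param h a [hypnogram()].
#' @param bin_s bin width in seconds, or `NULL` for the whole recording.
#'   A final partial bin is kept and flagged via the `complete` column.
#' @return data.frame with columns `bin`, `bin_start_s`, `state`,
#'   `seconds`, `percent` (of the scored bin), `complete`. Artifact time
#'   is reported under state `ARTIFACT` but excluded from the percentage
#'   denominator.
#' @export
state_times <- function(h, bin_s = NULL) {
  stopifnot(inherits(h, "hypnogram"))
  if (!is.null(bin_s) && bin_s <= 0) stop("bin_s must be positive")
  n <- length(h$labels)
  if (is.null(bin_s)) {
    bin_of <- rep(1L, n)
    n_bins <- 1L
    epb <- n
  } else {
    epb <- bin_s / h$epoch_s
    if (abs(epb - round(epb)) > 1e-9) {
      stop("bin_s must be a whole number of epochs")
    }
    epb <- as.integer(round(epb))
    bin_of <- (seq_len(n) - 1L) %/% epb + 1L
    n_bins <- max(bin_of)
  }
  rows <- lapply(seq_len(n_bins), function(b) {
    lab <- h$labels[bin_of == b]
    tab <- table(factor(lab, levels = STATE_ALPHABET))
    secs <- as.numeric(tab) * h$epoch_s
    scored <- sum(secs[STATE_ALPHABET != "ARTIFACT"])
    data.frame(
      bin = b,
      bin_start_s = h$t0 + (b - 1L) * (if (is.null(bin_s)) duration(h) else bin_s),
      state = STATE_ALPHABET,
      seconds = secs,
      percent = if (scored > 0) {
        ifelse(STATE_ALPHABET == "ARTIFACT", NA_real_, 100 * secs / scored)
      } else {
        NA_real_
      },
      complete = length(lab) == epb
    )
  })
  do.call(rbind, rows)
}

#' Latency to first occurrence of a state
#'
#' Time from the session start to the first epoch scored as `state`. If
#' the state never occurs the latency is censored at the total recording
#' duration (e.g. 21600 s for a 6-h session), the convention used for
#' survival analysis of sleep-onset times.
#'
#' @param h a [hypnogram()].
#' @param state target state.
#' @return `list(latency_s, censored)`.
#' @export
latency <- function(h, state) {
  stopifnot(inherits(h, "hypnogram"))
  state <- parse_state_labels(state)
  i <- match(state, h$labels)
  if (is.na(i)) {
    list(latency_s = duration(h), censored = TRUE)
  } else {
    list(latency_s = (i - 1L) * h$epoch_s, censored = FALSE)
  }
}

# Adjacent epoch pairs eligible for transition counting: both members
# non-artifact and originally adjacent (pairs spanning an artifact are
# dropped, not spliced together).
.transition_pairs <- function(labels) {
  n <- length(labels)
  if (n < 2L) return(cbind(character(0), character(0)))
  a <- labels[-n]
  b <- labels[-1L]
  keep <- a != "ARTIFACT" & b != "ARTIFACT"
  cbind(a[keep], b[keep])
}

#' Count transitions between two states
#'
#' Number of adjacent epoch pairs (src, dst). With `bin_s`, counts are
#' reported per bin, a transition being assigned to the bin of its
#' destination epoch.
#'
#' @param h a [hypnogram()].
#' @param src,dst distinct source and destination states.
#' @param bin_s optional bin width in seconds.
#' @return integer count, or data.frame (`bin`, `count`) when binned.
#' @export
count_transitions <- function(h, src, dst, bin_s = NULL) {
  stopifnot(inherits(h, "hypnogram"))
  src <- parse_state_labels(src)
  dst <- parse_state_labels(dst)
  if (src == dst) stop("src and dst must differ")
  n <- length(h$labels)
  a <- h$labels[-n]
  b <- h$labels[-1L]
  hit <- a == src & b == dst
  if (is.null(bin_s)) return(sum(hit))
  epb <- as.integer(round(bin_s / h$epoch_s))
  dest_epoch <- which(hit) + 1L
  bin <- (dest_epoch - 1L) %/% epb + 1L
  n_bins <- (n - 1L) %/% epb + 1L
  data.frame(
    bin = seq_len(n_bins),
    count = as.integer(tabulate(bin, nbins = n_bins))
  )
}

#' Estimate the Markov transition matrix of a hypnogram
#'
#' Conditional transition probabilities P(X | Y): the number of times
#' state Y is followed by state X in the next epoch, divided by the
#' number of (successor-bearing) Y epochs. Marginal state probabilities
#' are label frequencies over all scored epochs. Pairs that span an
#' artifact epoch are not counted.
#'
#' @param h a [hypnogram()] with at least 2 epochs.
#' @return object of class `transition_matrix`: list with `counts` (3x3
#'   integer), `probs` (3x3 row-stochastic where defined, `NaN` rows for
#'   unobserved states), `state_probs` (length-3 marginal frequencies),
#'   `n_epochs`.
#' @examples
#' h <- hypnogram(c("W", "W", "NREM", "W", "NREM", "NREM",
#'                  "NREM", "REM", "REM", "W"))
#' transition_matrix(h)
#' @export
transition_matrix <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  if (length(h$labels) < 2L) stop("need at least 2 epochs")
  scored <- h$labels[h$labels != "ARTIFACT"]
  if (length(scored) == 0L) stop("all epochs are artifact")
  pairs <- .transition_pairs(h$labels)
  counts <- matrix(0L, 3L, 3L, dimnames = list(STATES, STATES))
  if (nrow(pairs) > 0L) {
    tab <- table(factor(pairs[, 1L], levels = STATES),
                 factor(pairs[, 2L], levels = STATES))
    counts[] <- as.integer(tab)
  }
  probs <- counts / rowSums(counts)          # NaN rows for unobserved states
  state_probs <- as.numeric(table(factor(scored, levels = STATES))) /
    length(scored)
  names(state_probs) <- STATES
  structure(
    list(counts = counts, probs = probs, state_probs = state_probs,
         n_epochs = length(h$labels)),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> P(column | row):\n")
  print(round(x$probs, 4))
  cat("state frequencies:",
      paste(sprintf("%s %.3f", STATES, x$state_probs), collapse = ", "), "\n")
  invisible(x)
}

#' Pool transition matrices across recordings
#'
#' Sums the raw transition counts of several [transition_matrix()]
#' estimates (e.g. one per subject) and re-normalizes — the efficient
#' pooled estimator of a shared generating matrix. For paired group
#' statistics, keep per-subject matrices instead and test the
#' probability values across subjects.
#'
#' @param tms list of [transition_matrix()] objects.
#' @return a [transition_matrix()] with pooled counts; `state_probs` is
#'   the epoch-weighted average.
#' @export
pool_transitions <- function(tms) {
  stopifnot(length(tms) >= 1L,
            all(vapply(tms, inherits, logical(1L), "transition_matrix")))
  counts <- Reduce(`+`, lapply(tms, `[[`, "counts"))
  n_epochs <- sum(vapply(tms, `[[`, numeric(1L), "n_epochs"))
  w <- vapply(tms, `[[`, numeric(1L), "n_epochs")
  state_probs <- colSums(
    t(vapply(tms, `[[`, numeric(3L), "state_probs")) * w / sum(w)
  )
  structure(
    list(counts = counts, probs = counts / rowSums(counts),
         state_probs = state_probs, n_epochs = n_epochs),
    class = "transition_matrix"
  )
}

#' Fragmentation index of a state
#'
#' FI = 1 - P(X | X), one minus the probability of remaining in state X
#' from one epoch to the next. FI = 0 for a perfectly consolidated state
#' and FI = 1 only when the state is completely fragmented (every
#' occurrence is immediately followed by a different state). For a state
#' with no observed successor the FI is undefined and returned as `NA`
#' (not 0) — e.g. REM after strong REM suppression.
#'
#' @param tm a [transition_matrix()] (or a [hypnogram()], from which one
#'   is computed).
#' @param state state of interest.
#' @return `list(state, value, n_source)` where `n_source` is the number
#'   of successor-bearing epochs of `state`.
#' @export
fragmentation_index <- function(tm, state) {
  if (inherits(tm, "hypnogram")) tm <- transition_matrix(tm)
  stopifnot(inherits(tm, "transition_matrix"))
  state <- parse_state_labels(state)
  n_src <- sum(tm$counts[state, ])
  value <- if (n_src == 0L) NA_real_ else 1 - tm$probs[state, state]
  list(state = state, value = unname(value), n_source = unname(n_src))
}

#' Hourly fragmentation index
#'
#' FI computed per 1-h block, each block contributing its own transition
#' matrix (transitions across block boundaries belong to neither block).
#'
#' @param h a [hypnogram()].
#' @param state state of interest.
#' @param block_s block length in seconds (default 3600).
#' @return data.frame with `block`, `start_s`, `value`, `n_source`.
#' @export
hourly_fi <- function(h, state, block_s = 3600) {
  stopifnot(inherits(h, "hypnogram"))
  epb <- as.integer(round(block_s / h$epoch_s))
  n_blocks <- length(h$labels) %/% epb
  if (n_blocks < 1L) stop("hypnogram shorter than one block")
  rows <- lapply(seq_len(n_blocks), function(b) {
    sel <- ((b - 1L) * epb + 1L):(b * epb)
    hb <- hypnogram(h$labels[sel], epoch_s = h$epoch_s,
                    t0 = h$t0 + (b - 1L) * block_s)
    fi <- fragmentation_index(transition_matrix(hb), state)
    data.frame(block = b, start_s = hb$t0, value = fi$value,
               n_source = fi$n_source)
  })
  do.call(rbind, rows)
}

#' Bout-duration probability histogram
#'
#' Bin counts of bout durations for one state, in fixed-width increments
#' (conventionally 10 s for wakefulness, 50 s for NREM sleep), normalized
#' to probabilities summing to 1. Bin k covers `[k*w, (k+1)*w)`.
#'
#' @param bt a bout table from [segment_bouts()].
#' @param state state of interest.
#' @param bin_width_s bin width in seconds; defaults to 10 for W and 50
#'   for NREM.
#' @return data.frame with `bin_lo_s`, `bin_hi_s`, `count`, `prob`; zero
#'   rows (with attribute `empty = TRUE`) when the state has no bouts.
#' @export
bout_histogram <- function(bt, state, bin_width_s = NULL) {
  state <- parse_state_labels(state)
  if (is.null(bin_width_s)) {
    bin_width_s <- switch(state, W = 10, NREM = 50, 10)
  }
  if (bin_width_s <= 0) stop("bin_width_s must be positive")
  d <- bt$duration_s[bt$state == state]
  if (length(d) == 0L) {
    out <- data.frame(bin_lo_s = numeric(0), bin_hi_s = numeric(0),
                      count = integer(0), prob = numeric(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  k <- floor(d / bin_width_s)
  n_bins <- max(k) + 1L
  counts <- tabulate(k + 1L, nbins = n_bins)
  data.frame(
    bin_lo_s = (seq_len(n_bins) - 1L) * bin_width_s,
    bin_hi_s = seq_len(n_bins) * bin_width_s,
    count = counts,
    prob = counts / sum(counts)
  )
}
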