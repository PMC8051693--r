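test_that("chain_params validates stochastic rows", {
  P <- default_transition_matrix("control")
  expect_equal(rowSums(P), c(W = 1, NREM = 1, REM = 1), tolerance = 1e-12)
  expect_equal(P["W", "REM"], 0)
  bad <- P
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(chain_params(bad), "sum to 1")
  bad2 <- P
  bad2[2, 1] <- -bad2[2, 1]
  expect_error(chain_params(bad2), "non-negative")
})

test_that("degenerate chains produce the exact deterministic hypnograms", {
  # absorbing identity chain stays in the initial state
  h <- simulate_hypnogram(chain_params(diag(3), initial_state = "W",
                                       n_epochs = 50), seed = 1)
  expect_equal(unique(h$labels), "W")

  # deterministic two-state cycle alternates strictly
  P <- matrix(0, 3, 3)
  P[1, 2] <- 1   # W -> NREM
  P[2, 1] <- 1   # NREM -> W
  P[3, 3] <- 1
  h2 <- simulate_hypnogram(chain_params(P, initial_state = "W",
                                        n_epochs = 40), seed = 1)
  expect_equal(h2$labels, rep(c("W", "NREM"), 20))
})

test_that("empirical self-transition matches the generating probability", {
  # Monte-Carlo oracle: mean empirical p(NREM->NREM) over 100 runs of a
  # 4320-epoch chain with p = 0.95 lands within +/- 0.005
  P <- rbind(c(0.9, 0.1, 0), c(0.05, 0.95, 0), c(0, 0, 1))
  cp <- chain_params(P, initial_state = "NREM", n_epochs = 4320)
  p_hat <- vapply(1:100, function(s) {
    transition_matrix(simulate_hypnogram(cp, seed = s))$probs["NREM", "NREM"]
  }, numeric(1))
  expect_equal(mean(p_hat), 0.95, tolerance = 0.005)
})

test_that("long-run state frequencies match the stationary distribution", {
  P <- default_transition_matrix("control")
  pi_stat <- Re(eigen(t(P))$vectors[, 1])
  pi_stat <- pi_stat / sum(pi_stat)
  cp <- chain_params(P, n_epochs = 4320)
  freqs <- rowMeans(vapply(1:20, function(s) {
    transition_matrix(simulate_hypnogram(cp, seed = s))$state_probs
  }, numeric(3)))
  expect_equal(unname(freqs), unname(pi_stat), tolerance = 0.03)
})

test_that("simulation is seed-deterministic", {
  cp <- chain_params(default_transition_matrix("treatment"), n_epochs = 500)
  expect_identical(simulate_hypnogram(cp, seed = 7)$labels,
                   simulate_hypnogram(cp, seed = 7)$labels)
  expect_false(identical(simulate_hypnogram(cp, seed = 7)$labels,
                         simulate_hypnogram(cp, seed = 8)$labels))

  h <- hypnogram(rep("NREM", 4))
  p <- state_eeg_params(fs = 256)
  expect_identical(synthesize_eeg(h, p, seed = 3)$frontal,
                   synthesize_eeg(h, p, seed = 3)$frontal)
})

test_that("synthesized EEG honors state content and coupling settings", {
  # a pure 0.75 Hz NREM oscillator concentrates power in the SO band
  h <- hypnogram(rep("NREM", 24))
  st <- default_state_eeg()
  st$NREM$oscillators <- data.frame(freq = 0.75, amp = 2,
                                    w_frontal = 1, w_occipital = 1)
  st$NREM$noise_amp <- 0.2
  p <- state_eeg_params(st, fs = 512)
  ses <- synthesize_eeg(h, p, seed = 3)
  bp <- subset(state_spectral_summary(ses, h)$NREM$band_power,
               channel == "frontal")
  expect_equal(bp$band[which.max(bp$share)], "SO")

  # zero amplitudes and zero noise give all-zero channels
  st0 <- default_state_eeg()
  for (s in names(st0)) {
    st0[[s]]$oscillators$amp <- 0
    st0[[s]]$noise_amp <- 0
    st0[[s]]$emg <- 0
  }
  p0 <- state_eeg_params(st0, coupling = list(direction = "none",
                                              lag_ms = 0, gain = 0),
                         fs = 256)
  z <- synthesize_eeg(hypnogram(rep("W", 3)), p0, seed = 1)
  expect_true(all(z$frontal == 0) && all(z$occipital == 0))

  # uncoupled channels stay incoherent; coupling raises coherence
  hh <- hypnogram(rep("W", 22))
  mk <- function(gain) {
    stw <- default_state_eeg()
    stw$W$oscillators$amp <- 0      # pure noise channels
    pp <- state_eeg_params(stw, coupling = list(
      direction = "frontal_to_occipital", lag_ms = 20, gain = gain
    ), fs = 256)
    ses <- synthesize_eeg(hh, pp, seed = 9)
    wins <- epoch_windows(ses, hh)
    coherence_spectrum(lapply(wins, `[[`, "frontal"),
                       lapply(wins, `[[`, "occipital"), 256,
                       scheme = band_scheme(data.frame(
                         name = "broad", f_lo = 1, f_hi = 45
                       ), data.frame(f_lo = numeric(0), f_hi = numeric(0))))
  }
  c0 <- mean(mk(0)$spectrum$coherence)
  c8 <- mean(mk(0.8)$spectrum$coherence)
  expect_lt(c0, 0.3)
  expect_gt(c8, c0 + 0.2)

  # a lag longer than the epoch window is refused
  pl <- state_eeg_params(coupling = list(direction = "frontal_to_occipital",
                                         lag_ms = 6000, gain = 0.5), fs = 256)
  expect_error(synthesize_eeg(hypnogram(rep("W", 2)), pl, seed = 1),
               "lag")
})

test_that("make_cohort builds aligned pairs with per-subject seeds", {
  ctrl <- list(chain = chain_params(default_transition_matrix("control"),
                                    n_epochs = 720), eeg = NULL)
  trt <- list(chain = chain_params(default_transition_matrix("treatment"),
                                   n_epochs = 720), eeg = NULL)
  coh <- make_cohort(3, ctrl, trt, seed = 5)
  expect_s3_class(coh, "paired_cohort")
  expect_length(coh$subjects, 3)
  expect_named(coh$subjects[[1]], c("control", "treatment"))
  # reproducible and arm-distinct
  coh2 <- make_cohort(3, ctrl, trt, seed = 5)
  expect_identical(coh$subjects$S01$control$hypnogram$labels,
                   coh2$subjects$S01$control$hypnogram$labels)
  expect_false(identical(coh$subjects$S01$control$hypnogram$labels,
                         coh$subjects$S02$control$hypnogram$labels))

  single <- make_cohort(1, ctrl, trt, seed = 1)
  expect_length(single$subjects, 1)

  # jitter perturbs per-subject matrices but preserves structural zeros
  cj <- make_cohort(4, ctrl, trt, seed = 2, jitter_sd = 0.01)
  Ps <- lapply(cj$subjects, function(s) s$control$chain$P)
  expect_false(identical(Ps[[1]], Ps[[2]]))
  expect_true(all(vapply(Ps, function(P) P["W", "REM"] == 0, logical(1))))
  expect_true(all(vapply(Ps, function(P) all(abs(rowSums(P) - 1) < 1e-12),
                         logical(1))))
})
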