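test_that("bout segmentation is exact run-length encoding", {
  bt <- segment_bouts(hyp("W", "W", "N", "N", "N", "W"))
  expect_equal(bt$state, c("W", "NREM", "W"))
  expect_equal(bt$start_s, c(0, 10, 25))
  expect_equal(bt$duration_s, c(10, 15, 5))

  expect_equal(nrow(segment_bouts(hyp("N"))), 1)
  expect_equal(segment_bouts(hyp("N"))$duration_s, 5)
  expect_equal(nrow(segment_bouts(hyp("W", "N", "W", "N"))), 4)

  # bouts tile the hypnogram: durations sum to total, adjacent differ
  h <- simulate_hypnogram(
    chain_params(default_transition_matrix("treatment"), n_epochs = 600),
    seed = 3
  )
  bt2 <- segment_bouts(h)
  expect_equal(sum(bt2$duration_s), duration(h))
  expect_true(all(head(bt2$state, -1) != tail(bt2$state, -1)))
  expect_equal(bt2$start_s[-1], head(bt2$start_s + bt2$duration_s, -1))
})

test_that("state times account for every second, totals and bins", {
  st <- state_times(hyp("W", "W", "N"))
  expect_equal(st$seconds[st$state == "W"], 10)
  expect_equal(st$seconds[st$state == "NREM"], 5)
  expect_equal(st$seconds[st$state == "REM"], 0)
  expect_equal(sum(st$percent, na.rm = TRUE), 100)

  h <- simulate_hypnogram(
    chain_params(default_transition_matrix("control"), n_epochs = 4320),
    seed = 1
  )
  hourly <- state_times(h, bin_s = 3600)
  expect_equal(max(hourly$bin), 6)
  expect_true(all(hourly$complete))
  per_bin <- tapply(hourly$percent, hourly$bin, sum, na.rm = TRUE)
  expect_equal(as.numeric(per_bin), rep(100, 6))
  expect_equal(sum(hourly$seconds), duration(h))
  expect_error(state_times(h, bin_s = -1), "positive")
})

test_that("latency handles onset, absence and censoring", {
  expect_equal(latency(hypnogram(c(rep("W", 120), "N")), "NREM"),
               list(latency_s = 600, censored = FALSE))
  expect_equal(latency(hypnogram(rep(c("W", "N"), 2160)), "REM"),
               list(latency_s = 21600, censored = TRUE))
  expect_equal(latency(hyp("N", "W"), "NREM")$latency_s, 0)
})

test_that("transition counts match hand enumeration", {
  expect_equal(count_transitions(hyp("N", "W", "N", "W"), "NREM", "W"), 2)
  expect_equal(count_transitions(hyp("W", "W", "W"), "NREM", "W"), 0)
  h <- hyp("W", "W", "N", "W", "N", "N", "N", "R", "R", "W")
  expect_equal(count_transitions(h, "NREM", "W"), 1)
  expect_equal(count_transitions(h, "W", "NREM"), 2)
  expect_error(count_transitions(h, "W", "W"), "differ")

  # binned counting assigns a transition to its destination epoch's bin
  binned <- count_transitions(h, "W", "NREM", bin_s = 25)
  expect_equal(binned$count, c(2, 0))   # destinations at epochs 3 and 5
  expect_equal(sum(binned$count), count_transitions(h, "W", "NREM"))
})

test_that("transition matrix reproduces the hand-counted example", {
  h <- hyp("W", "W", "N", "W", "N", "N", "N", "R", "R", "W")
  tm <- transition_matrix(h)
  expect_equal(tm$probs["W", "W"], 1 / 3)
  expect_equal(tm$probs["W", "NREM"], 2 / 3)
  expect_equal(tm$probs["NREM", "NREM"], 0.5)
  expect_equal(tm$probs["NREM", "W"], 0.25)
  expect_equal(tm$probs["NREM", "REM"], 0.25)
  expect_equal(tm$probs["REM", "REM"], 0.5)
  expect_equal(tm$probs["REM", "W"], 0.5)
  expect_equal(unname(tm$state_probs), c(0.4, 0.4, 0.2))
  expect_equal(sum(tm$counts), length(h$labels) - 1)

  # constant hypnogram: self-transition probability 1
  expect_equal(transition_matrix(hyp("N", "N", "N"))$probs["NREM", "NREM"], 1)

  expect_error(transition_matrix(hyp("A", "A")), "artifact")
  expect_error(transition_matrix(hyp("W")), "2 epochs")
})

test_that("artifact epochs break transition pairs instead of splicing", {
  # W A N: neither W->A nor A->N nor the spliced W->N pair is counted
  tm <- transition_matrix(hyp("W", "W", "A", "N", "N"))
  expect_equal(sum(tm$counts), 2)  # W->W and N->N only
  expect_equal(tm$counts["W", "NREM"], 0)
  # marginals ignore artifact epochs
  expect_equal(unname(tm$state_probs), c(0.5, 0.5, 0))
})

test_that("bout-boundary counts agree with off-diagonal transition counts", {
  h <- simulate_hypnogram(
    chain_params(default_transition_matrix("treatment"), n_epochs = 2000),
    seed = 11
  )
  tm <- transition_matrix(h)
  bt <- segment_bouts(h)
  for (src in c("W", "NREM", "REM")) {
    for (dst in setdiff(c("W", "NREM", "REM"), src)) {
      boundaries <- sum(head(bt$state, -1) == src & tail(bt$state, -1) == dst)
      expect_equal(tm$counts[src, dst], boundaries)
      expect_equal(count_transitions(h, src, dst), boundaries)
    }
  }
})

test_that("fragmentation index follows its definition and edge rules", {
  # complete fragmentation: every NREM epoch exits the state
  expect_equal(
    fragmentation_index(transition_matrix(hypnogram(rep(c("N", "W"), 20))),
                        "NREM")$value, 1)
  # perfect consolidation
  expect_equal(
    fragmentation_index(transition_matrix(hyp("N", "N", "N", "N")),
                        "NREM")$value, 0)
  # hand-counted p(N->N) = 0.5
  h <- hyp("W", "W", "N", "W", "N", "N", "N", "R", "R", "W")
  expect_equal(fragmentation_index(transition_matrix(h), "NREM")$value, 0.5)
  # unobserved state: missing, not zero
  expect_true(is.na(
    fragmentation_index(transition_matrix(hyp("W", "W", "N")), "REM")$value
  ))
  # FI always within [0, 1] on simulated chains
  for (s in 1:5) {
    h <- simulate_hypnogram(
      chain_params(default_transition_matrix("control"), n_epochs = 1000),
      seed = s
    )
    fi <- fragmentation_index(transition_matrix(h), "NREM")$value
    expect_true(fi >= 0 && fi <= 1)
  }
})

test_that("hourly FI tracks blockwise self-transition probabilities", {
  h6 <- simulate_hypnogram(
    chain_params(default_transition_matrix("control"), n_epochs = 4320),
    seed = 2
  )
  fi <- hourly_fi(h6, "NREM")
  expect_equal(nrow(fi), 6)
  expect_equal(fi$start_s, (0:5) * 3600)

  # constant-state block has FI exactly 0
  expect_equal(hourly_fi(hypnogram(rep("N", 720)), "NREM")$value, 0)

  # piecewise chain: consolidated first block, fragmented second
  P_cons <- rbind(c(0.9, 0.1, 0), c(0.02, 0.98, 0), c(0, 0, 1))
  P_frag <- rbind(c(0.6, 0.4, 0), c(0.4, 0.6, 0), c(0, 0, 1))
  h_cons <- simulate_hypnogram(
    chain_params(P_cons, "NREM", n_epochs = 720), seed = 4)
  h_frag <- simulate_hypnogram(
    chain_params(P_frag, "NREM", n_epochs = 720), seed = 4)
  h2 <- hypnogram(c(h_cons$labels, h_frag$labels))
  fi2 <- hourly_fi(h2, "NREM")
  # 3-sigma binomial envelopes around the generating 1 - p(N->N)
  expect_lt(abs(fi2$value[1] - 0.02), 0.016)
  expect_lt(abs(fi2$value[2] - 0.40), 0.08)
})

test_that("bout histograms bin and normalize correctly", {
  bt <- data.frame(state = "NREM", start_s = c(0, 30, 100),
                   duration_s = c(30, 70, 120))
  hist <- bout_histogram(bt, "NREM", bin_width_s = 50)
  expect_equal(hist$count[1:3], c(1, 1, 1))
  expect_equal(hist$prob[1:3], rep(1 / 3, 3))
  expect_equal(sum(hist$prob), 1)
  # bin edges are half-open [k*w, (k+1)*w)
  expect_equal(hist$bin_lo_s[1:3], c(0, 50, 100))

  single <- bout_histogram(data.frame(state = "W", duration_s = 25), "W")
  expect_equal(sum(single$prob), 1)
  expect_equal(single$prob[single$bin_lo_s == 20], 1)

  empty <- bout_histogram(bt, "REM")
  expect_equal(nrow(empty), 0)
  expect_true(attr(empty, "empty"))

  # default widths: 10 s for W, 50 s for NREM
  expect_equal(bout_histogram(bt, "NREM")$bin_hi_s[1], 50)
  expect_error(bout_histogram(bt, "NREM", bin_width_s = 0), "positive")
})

test_that("pooled transition counts recover a shared generating matrix", {
  P <- default_transition_matrix("control")
  cp <- chain_params(P, n_epochs = 4320)
  tms <- lapply(1:11, function(s) {
    transition_matrix(simulate_hypnogram(cp, seed = 100 + s))
  })
  pooled <- pool_transitions(tms)
  expect_equal(sum(pooled$counts), 11 * 4319)
  expect_lt(max(abs(pooled$probs - P)), 0.01)
})
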