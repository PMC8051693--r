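test_that("paired t matches the closed-form computation", {
  # differences (2, 1, 3): t = 2 / (1/sqrt(3)) = 3.4641, df 2
  s <- paired_sample(control = c(0, 0, 0), treatment = c(2, 1, 3))
  r <- paired_t(s, tails = "one", direction = "greater")
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(r$df, 2)
  expect_equal(r$p, pt(2 / (1 / sqrt(3)), df = 2, lower.tail = FALSE),
               tolerance = 1e-9)

  # sign-flip antisymmetry
  r_rev <- paired_t(paired_sample(c(2, 1, 3), c(0, 0, 0)))
  expect_equal(r_rev$t, -r$t, tolerance = 1e-9)

  # identical arms: zero variance refused
  expect_error(paired_t(paired_sample(1:4, 1:4)), "variance")
  # arms differing by a constant: t defined, two-tailed p = pt-based
  rc <- paired_t(paired_sample(c(1, 2, 3), c(2, 3, 4.5)))
  expect_gt(rc$p, 0)
  expect_error(paired_t(paired_sample(1, 2)), "2 complete pairs")
  # missing pairs dropped and counted
  s_na <- paired_sample(c(1, 2, NA, 4), c(2, 3, 5, 6))
  expect_equal(s_na$n_dropped, 1)
  expect_length(s_na$control, 3)
})

test_that("wilcoxon signed-rank gives exact small-sample p-values", {
  # 6 all-positive distinct differences, one-tailed: p = 1/2^6
  s <- paired_sample(rep(0, 6), c(1, 2, 3, 4, 5, 6))
  r <- wilcoxon_signed_rank(s, tails = "one", direction = "greater")
  expect_equal(r$p, 1 / 64, tolerance = 1e-12)
  expect_equal(r$V, 21)

  # exact distribution equals sign-pattern enumeration for n <= 10
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n), 2)
    while (any(d == 0) || any(duplicated(abs(d)))) d <- round(rnorm(n), 2)
    r1 <- wilcoxon_signed_rank(paired_sample(rep(0, n), d))
    # enumeration oracle: all 2^n sign assignments of the ranked |d|
    rk <- rank(abs(d))
    V_obs <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    V_all <- signs %*% rk
    p_exact <- min(1, mean(V_all >= max(V_obs, sum(rk) - V_obs)) +
                     mean(V_all <= min(V_obs, sum(rk) - V_obs)))
    expect_equal(r1$p, p_exact, tolerance = 1e-9)
  }

  # symmetric differences: two-tailed p near 1
  s2 <- paired_sample(c(0, 0, 0, 0, 0, 0), c(-3, 3, -2, 2, -1, 1))
  expect_gt(wilcoxon_signed_rank(s2)$p, 0.9)
  # zero differences dropped
  s3 <- paired_sample(c(1, 2, 3, 4, 5, 6, 7), c(1, 3, 4, 5, 6, 7, 8))
  expect_equal(wilcoxon_signed_rank(s3)$n_used, 6)
  expect_error(wilcoxon_signed_rank(paired_sample(1:3, 1:3)), "zero")
})

test_that("Benjamini-Hochberg step-up rejects per the i*q/m thresholds", {
  r <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_equal(r$p_adj, c(0.04, 0.04, 0.04, 0.04))

  expect_true(benjamini_hochberg(0.04, q = 0.05)$reject)
  expect_false(any(benjamini_hochberg(rep(1, 5))$reject))

  # step-up rescue: p = 0.049 sits at rank 3 threshold 3*q/3 = 0.05, so
  # every smaller p is rejected with it even above its own threshold
  r2 <- benjamini_hochberg(c(0.04, 0.049, 0.001), q = 0.05)
  expect_equal(r2$reject, c(TRUE, TRUE, TRUE))
  # without the rank-3 rescue only the smallest survives
  r3 <- benjamini_hochberg(c(0.04, 0.2, 0.001), q = 0.05)
  expect_equal(r3$reject, c(FALSE, FALSE, TRUE))
  # adjusted p monotone nondecreasing in rank order
  p <- c(0.001, 0.2, 0.01, 0.04, 0.8)
  adj <- benjamini_hochberg(p)$p_adj
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  # BH rejects at least as many as Bonferroni
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(20)^2
    bh <- sum(benjamini_hochberg(p, 0.05)$reject)
    bonf <- sum(p <= 0.05 / length(p))
    expect_gte(bh, bonf)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("KS two-sample statistic equals the brute-force CDF scan", {
  expect_equal(ks_two_sample(1:10, 1:10)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  set.seed(8)
  a <- rexp(40, 1 / 50)
  b <- rexp(60, 1 / 30)
  D_pkg <- ks_two_sample(a, b)$D
  grid <- sort(c(a, b))
  D_brute <- max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g),
                            numeric(1))))
  expect_equal(D_pkg, D_brute, tolerance = 1e-12)
  expect_error(ks_two_sample(numeric(0), 1:3), "nonempty")
})

test_that("Spearman correlation equals rank-then-Pearson", {
  x <- c(1, 5, 2, 8, 3)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  set.seed(4)
  a <- rnorm(30)
  b <- a + rnorm(30)
  expect_equal(spearman_cor(a, b)$rho, cor(rank(a), rank(b)),
               tolerance = 1e-12)
  expect_error(spearman_cor(1:3, 3:1), "4 observations")
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("Kaplan-Meier curves honor censoring and log-rank compares arms", {
  # distinct uncensored events: survival drops 1/n per event
  km <- km_logrank(time = c(10, 20, 30, 40), censored = rep(FALSE, 4),
                   arm = rep("a", 4))
  expect_equal(km$fit$surv, c(0.75, 0.5, 0.25, 0))
  expect_true(is.na(km$p))

  # identical arms: log-rank p near 1
  tim <- rep(c(5, 10, 15, 20, 30), 2)
  arm <- rep(c("veh", "cno"), each = 5)
  r <- km_logrank(tim, rep(FALSE, 10), arm)
  expect_gt(r$p, 0.95)

  # a fully censored arm never drops below 1
  r2 <- km_logrank(time = c(5, 10, 21600, 21600),
                   censored = c(FALSE, FALSE, TRUE, TRUE),
                   arm = c("veh", "veh", "cno", "cno"))
  surv_cno <- summary(r2$fit)$surv[summary(r2$fit)$strata == "arm=cno"]
  expect_true(length(surv_cno) == 0 || all(surv_cno == 1))
  expect_error(km_logrank(c(-1, 2), c(FALSE, FALSE), c("a", "b")),
               "non-negative")
})

test_that("compare_conditions runs the paired battery over tidy tables", {
  set.seed(6)
  df <- expand.grid(subject = sprintf("S%02d", 1:8),
                    condition = c("control", "treatment"),
                    band = c("delta", "theta"),
                    stringsAsFactors = FALSE)
  df$value <- rnorm(nrow(df)) +
    ifelse(df$condition == "treatment" & df$band == "delta", 3, 0)
  res <- compare_conditions(df, "band")
  expect_equal(nrow(res), 2)
  expect_equal(res$n_pairs, c(8, 8))
  delta_row <- res[res$band == "delta", ]
  theta_row <- res[res$band == "theta", ]
  expect_lt(delta_row$p_t, 0.01)
  expect_gt(theta_row$p_t, 0.05)
  expect_true(delta_row$reject_wilcoxon)
  expect_true(all(res$p_wilcoxon_adj >= res$p_wilcoxon - 1e-15))
})
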