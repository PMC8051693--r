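#' Subject-aligned paired sample
#'
#' Control/treatment value pairs aligned on subject. Pairs with a
#' missing side are excluded from every test and their count reported.
#'
#' @param control,treatment numeric vectors of equal length.
#' @param subject optional subject IDs.
#' @return object of class `paired_sample`.
#' @export
paired_sample <- function(control, treatment, subject = NULL) {
  if (length(control) != length(treatment)) {
    stop("control and treatment must be the same length")
  }
  if (is.null(subject)) subject <- seq_along(control)
  keep <- complete.cases(control, treatment)
  structure(
    list(control = control[keep], treatment = treatment[keep],
         subject = subject[keep], n_dropped = sum(!keep)),
    class = "paired_sample"
  )
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample> %d complete pairs (%d dropped)\n",
              length(x$control), x$n_dropped))
  invisible(x)
}

.check_pairs <- function(s, min_n = 2L) {
  stopifnot(inherits(s, "paired_sample"))
  if (length(s$control) < min_n) {
    stop("need at least ", min_n, " complete pairs")
  }
}

#' Paired t test
#'
#' Classical t test on within-subject differences (treatment - control).
#' One-tailed tests require an explicit pre-specified direction; the
#' direction is configuration, never inferred from the data.
#'
#' @param s a [paired_sample()].
#' @param tails `"one"` or `"two"`.
#' @param direction for one-tailed tests: `"greater"` (treatment >
#'   control) or `"less"`.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(s, tails = c("two", "one"),
                     direction = c("greater", "less")) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  .check_pairs(s)
  d <- s$treatment - s$control
  if (var(d) == 0) stop("zero variance of paired differences")
  alt <- if (tails == "two") "two.sided" else direction
  r <- t.test(s$treatment, s$control, paired = TRUE, alternative = alt)
  list(t = unname(r$statistic), df = unname(r$parameter),
       p = r$p.value, mean_diff = mean(d))
}

#' Wilcoxon signed-rank test
#'
#' Paired rank test on within-subject differences; zero differences are
#' dropped (standard practice). Exact p-values for n <= 25 without ties,
#' otherwise the normal approximation.
#'
#' @inheritParams paired_t
#' @return list with `V` (signed-rank statistic), `p`, `n_used`.
#' @export
wilcoxon_signed_rank <- function(s, tails = c("two", "one"),
                                 direction = c("greater", "less")) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  .check_pairs(s)
  d <- s$treatment - s$control
  d <- d[d != 0]
  if (length(d) == 0L) stop("all paired differences are zero")
  alt <- if (tails == "two") "two.sided" else direction
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  r <- suppressWarnings(
    wilcox.test(d, alternative = alt, exact = exact, correct = !exact)
  )
  list(V = unname(r$statistic), p = r$p.value, n_used = length(d))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at FDR level `q`: rejection flags from the largest
#' rank `i` with `p_(i) <= i*q/m`, plus the usual monotone adjusted
#' p-values (`p.adjust(method = "BH")`).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return data.frame with `p`, `p_adj`, `reject`, in the input order.
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  p_adj <- p.adjust(pvals, method = "BH")
  o <- order(pvals)
  thresh <- seq_len(m) * q / m
  ok <- which(pvals[o] <= thresh)
  reject <- rep(FALSE, m)
  if (length(ok) > 0L) reject[o[seq_len(max(ok))]] <- TRUE
  data.frame(p = pvals, p_adj = p_adj, reject = reject)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Sup-distance between the empirical CDFs of two duration samples
#' (e.g. bout-length distributions under the two treatments), with the
#' asymptotic p-value.
#'
#' @param a,b numeric samples.
#' @return list with `D`, `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be nonempty")
  r <- suppressWarnings(ks.test(a, b))
  list(D = unname(r$statistic), p = r$p.value)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties, e.g. for relating REM-sleep time
#' to the fragmentation index across subjects.
#'
#' @param x,y numeric vectors, `n >= 4`.
#' @return list with `rho`, `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length")
  if (length(x) < 4L) stop("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  r <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(r$estimate), p = r$p.value)
}

#' Kaplan-Meier curves and log-rank test for state-onset latencies
#'
#' Treats the latency to a state as a time-to-event outcome: subjects
#' who never reached the state within the recording are censored at the
#' recording duration. Curves report the probability of not yet having
#' entered the state versus time; arms are compared with the two-sample
#' log-rank test.
#'
#' @param time numeric event/censoring times in seconds.
#' @param censored logical, `TRUE` where the state never occurred.
#' @param arm factor/character arm labels (two levels for the test).
#' @return list with `fit` (a [survival::survfit] object; its `surv`
#'   component is the probability of no state onset), `chisq`, `p`
#'   (`NA` when only one arm is present).
#' @export
km_logrank <- function(time, censored, arm) {
  if (any(time < 0)) stop("times must be non-negative")
  event <- as.integer(!censored)
  arm <- factor(arm)
  fit <- survival::survfit(survival::Surv(time, event) ~ arm)
  if (nlevels(arm) < 2L) {
    return(list(fit = fit, chisq = NA_real_, p = NA_real_))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ arm)
  p <- stats::pchisq(sd_$chisq, df = nlevels(arm) - 1L, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd_$chisq), p = p)
}

#' Run the paired battery over a long-format results table
#'
#' Applies the paired t and Wilcoxon signed-rank tests to every
#' measurement group of a tidy table (e.g. one row per subject,
#' condition, state and band) and adjusts p-values across groups with
#' Benjamini-Hochberg.
#'
#' @param df data.frame with columns `subject`, `condition`
#'   (control/treatment), `value`, plus grouping columns.
#' @param group_cols character vector of grouping column names.
#' @param tails,direction passed to the tests.
#' @param q FDR level for the BH adjustment.
#' @return data.frame: one row per group with both tests' statistics,
#'   raw and BH-adjusted p-values, and rejection flags at `q`.
#' @export
compare_conditions <- function(df, group_cols, tails = "two",
                               direction = "greater", q = 0.05) {
  stopifnot(all(c("subject", "condition", "value") %in% names(df)))
  key <- if (length(group_cols) == 0L) {
    rep("all", nrow(df))
  } else {
    do.call(paste, c(df[group_cols], sep = "\r"))
  }
  groups <- split(df, key)
  rows <- lapply(groups, function(g) {
    s <- paired_from_summary(g)
    out <- g[1L, group_cols, drop = FALSE]
    res_t <- tryCatch(paired_t(s, tails, direction), error = function(e) NULL)
    res_w <- tryCatch(wilcoxon_signed_rank(s, tails, direction),
                      error = function(e) NULL)
    out$n_pairs <- length(s$control)
    out$mean_control <- mean(s$control)
    out$mean_treatment <- mean(s$treatment)
    out$t <- if (is.null(res_t)) NA_real_ else res_t$t
    out$p_t <- if (is.null(res_t)) NA_real_ else res_t$p
    out$V <- if (is.null(res_w)) NA_real_ else res_w$V
    out$p_wilcoxon <- if (is.null(res_w)) NA_real_ else res_w$p
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  ok <- !is.na(res$p_wilcoxon)
  res$p_wilcoxon_adj <- NA_real_
  res$reject_wilcoxon <- NA
  if (any(ok)) {
    bh <- benjamini_hochberg(res$p_wilcoxon[ok], q)
    res$p_wilcoxon_adj[ok] <- bh$p_adj
    res$reject_wilcoxon[ok] <- bh$reject
  }
  res
}
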