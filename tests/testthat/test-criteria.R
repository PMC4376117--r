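test_that("log-likelihood sums floored log densities over trials", {
  p <- dm_params(v = 1, a = 1, zr = 0.5, t0 = 0.3)
  d <- tibble::tibble(response = c(1L, 1L, 0L), rt = c(0.5, 0.7, 0.6))
  ll <- log_likelihood(d, p)
  by_hand <- sum(log(pmax(density_full(c(0.5, 0.7), p, "upper"), 1e-6))) +
    log(pmax(density_full(0.6, p, "lower"), 1e-6))
  expect_equal(ll, by_hand)
  # duplicating every trial doubles the log-likelihood exactly
  expect_equal(log_likelihood(dplyr::bind_rows(d, d), p), 2 * ll)
  # one response time far below t0 contributes exactly the floor
  d_out <- dplyr::bind_rows(d, tibble::tibble(response = 1L, rt = 0.05))
  expect_equal(log_likelihood(d_out, p), ll + log(1e-6))
  expect_error(log_likelihood(d[0, ], p), "empty")
})

test_that("the likelihood prefers the generating parameters at large n", {
  set.seed(91)
  p <- dm_params(v = 1.2, a = 1, zr = 0.5, t0 = 0.3)
  d <- sample_dataset(p, 5000, precision = 4)
  ll_true <- log_likelihood(d, p)
  for (dv in c(-0.5, 0.5)) {
    p2 <- dm_params(v = 1.2 + dv, a = 1, zr = 0.5, t0 = 0.3)
    expect_gt(ll_true, log_likelihood(d, p2))
  }
})

test_that("BIC follows the free-parameter and sample-size bookkeeping", {
  expect_equal(bic(-123.4, 0, 50), 246.8)
  expect_equal(bic(-500, 7, 200), 1037.0882, tolerance = 1e-6)
  expect_equal(bic(-500, 8, 200) - bic(-500, 7, 200), log(200))
})

test_that("quantile bins split response times as published", {
  rts <- seq(0.3, 1.2, length.out = 20)
  b <- cs_bins(rts)
  expect_length(b$edges, 5)
  expect_equal(b$counts, c(2, 4, 4, 4, 4, 2))
  expect_equal(sum(b$counts), 20)
  # degenerate edges still conserve the trial count
  b2 <- cs_bins(rep(0.5, 17))
  expect_equal(sum(b2$counts), 17)
  # quantile type 7 (linear interpolation between order statistics)
  expect_equal(b$edges, unname(quantile(rts, c(.1, .3, .5, .7, .9), type = 7)))
})

test_that("chi-square statistic honours the 12-trial exclusion rule", {
  set.seed(13)
  p <- dm_params(v = 1.8, a = 1, zr = 0.5, t0 = 0.3)
  d <- sample_dataset(p, 60, precision = 4)
  # force exactly 11 lower responses: below the cutoff, so they only enter
  # through the total trial count, never through their own bins
  d_low <- sample_dataset(dm_params(v = -1.8, a = 1, zr = 0.5, t0 = 0.3), 11,
                          precision = 4)
  d_low$response <- 0L
  d$response <- 1L
  base <- dplyr::bind_rows(d, d_low)
  cs1 <- cs_statistic(base, p, precision = 3)
  jig <- base
  jig$rt[jig$response == 0L] <- jig$rt[jig$response == 0L] + 0.123
  expect_equal(cs_statistic(jig, p, precision = 3), cs1)
  # but moving included (upper) response times changes the statistic
  jig2 <- base
  jig2$rt[jig2$response == 1L] <- jig2$rt[jig2$response == 1L] * 1.05
  expect_false(isTRUE(all.equal(cs_statistic(jig2, p, precision = 3), cs1)))
  # no includable threshold anywhere aborts
  tiny <- dplyr::bind_rows(d[1:11, ], d_low)
  expect_error(cs_statistic(tiny, p, precision = 3), "12 responses")
})

test_that("chi-square is blind to within-bin jitter, unlike ML and KS", {
  set.seed(29)
  p <- dm_params(v = 0.5, a = 1, zr = 0.5, t0 = 0.3)
  d <- sample_dataset(p, 80, precision = 4)
  stopifnot(min(table(d$response)) >= 12)
  jig <- d
  for (resp in 0:1) {
    idx <- which(jig$response == resp)
    rts <- jig$rt[idx]
    n <- length(rts)
    # order statistics adjacent to the five quantile edges must not move
    locked <- unique(c(floor(0.1 * (n - 1) + 1), ceiling(0.1 * (n - 1) + 1),
                       floor(0.3 * (n - 1) + 1), ceiling(0.3 * (n - 1) + 1),
                       floor(0.5 * (n - 1) + 1), ceiling(0.5 * (n - 1) + 1),
                       floor(0.7 * (n - 1) + 1), ceiling(0.7 * (n - 1) + 1),
                       floor(0.9 * (n - 1) + 1), ceiling(0.9 * (n - 1) + 1)))
    ord <- order(rts)
    srt <- sort(rts)
    for (k in seq_len(n)) {
      if (k %in% locked) next
      lo <- if (k == 1) srt[1] - 0.01 else srt[k - 1]
      hi <- if (k == n) srt[n] + 0.01 else srt[k + 1]
      srt[k] <- lo + 0.37 * (hi - lo)  # nudge strictly inside its gap
    }
    jig$rt[idx[ord]] <- srt
  }
  expect_equal(cs_statistic(jig, p, 3), cs_statistic(d, p, 3), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(log_likelihood(jig, p, 3),
                                log_likelihood(d, p, 3))))
  # KS depends on the exact location of the trial attaining the maximum
  # distance: nudging that trial moves the statistic
  dist <- combined_cdf(p, precision = 3)
  tau <- sort(signed_tau(d))
  n <- length(tau)
  pc <- predicted_cdf(dist, tau)
  gaps <- pmax(abs(seq_len(n) / n - pc), abs((seq_len(n) - 1) / n - pc))
  k <- which.max(gaps)
  d2 <- d
  at <- which(abs(d2$rt - abs(tau[k])) < 1e-12 &
                d2$response == as.integer(tau[k] > 0))[1]
  d2$rt[at] <- d2$rt[at] + 0.02
  expect_false(isTRUE(all.equal(ks_statistic(d2, p, 3),
                                ks_statistic(d, p, 3))))
})

test_that("chi-square degrees of freedom follow K(N-1) - P", {
  expect_equal(cs_df(1, 12, 7)$df, 4)
  expect_equal(cs_df(4, 12, 11)$df, 33)
  expect_true(cs_df(1, 12, 7)$testable)
  expect_false(cs_df(1, 12, 11)$testable)
})

test_that("KS distance and p-value behave as a one-sample test", {
  p <- dm_params(v = 0, a = 1, zr = 0.5, t0 = 0.3, d = 0)
  dist <- combined_cdf(p, precision = 3)
  # a single trial placed where the predicted CDF is one half gives D = 0.5
  one <- tibble::tibble(response = 1L, rt = 1e-6)
  expect_equal(ks_statistic(one, p, 3), 0.5, tolerance = 2e-3)
  # invariant under trial order
  set.seed(5)
  d <- sample_dataset(p, 50, precision = 4)
  expect_equal(ks_statistic(d, p, 3),
               ks_statistic(d[sample(nrow(d)), ], p, 3))
  # a deterministic quantile sample sits on the predicted CDF
  dq <- deterministic_dataset(p, 250, precision = 4)
  expect_lte(ks_statistic(dq, p, 4), 1 / 250 + 1e-3)

  expect_equal(ks_pvalue(0, 100), 1)
  ps <- vapply(seq(0.01, 0.5, by = 0.01), ks_pvalue, numeric(1), n = 100)
  expect_true(all(diff(ps) < 0))
  expect_equal(ks_pvalue(0.136, 100), 0.0448865, tolerance = 1e-5)
})

test_that("aggregation matches the per-criterion conventions", {
  agg <- aggregate_objective("ks", c(0.10, 0.35, 0.12, 0.60))
  expect_equal(agg$value, 0.00252)
  expect_equal(agg$minimized, -sum(log(c(0.10, 0.35, 0.12, 0.60))))
  expect_equal(aggregate_objective("ks", 0.37)$value, 0.37)
  expect_equal(aggregate_objective("ks", c(0.2, 0))$value, 0)
  expect_identical(aggregate_objective("ks", c(0.2, 0))$minimized, Inf)
  expect_equal(aggregate_objective("ml", c(-120.5, -80.25))$value, 200.75)
  expect_equal(aggregate_objective("cs", c(10, 20, 5))$value, 35)
  # penalized solutions are incomparably worse than any plain value
  pen <- aggregate_objective("ml", numeric(0), penalty = 0.4)
  expect_true(pen$penalized)
  expect_identical(pen$minimized, Inf)
  expect_equal(pen$penalty, 0.4)
})
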