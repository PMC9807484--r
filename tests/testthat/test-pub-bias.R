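# strictly concordant fixture: standardised deviates and variances rise together
concordant_effects <- function(k) {
  v <- seq(0.1, 1, length.out = k)
  y <- cumsum(seq_len(k))
  make_effects(y, v)
}

test_that("Begg exact test reproduces the small-k rank-correlation convention", {
  # fully concordant, no ties: tau = 1, two-sided exact p = 2/k!
  for (k in c(3, 4, 6)) {
    out <- begg_test(concordant_effects(k))
    expect_equal(out$begg_method, "exact")
    expect_equal(out$kendall_tau, 1, tolerance = 1e-12)
    expect_equal(out$p_begg, 2 / factorial(k), tolerance = 1e-10)
  }
})

test_that("Begg exact p equals full-enumeration and matches cor.test as oracle", {
  set.seed(91)
  for (i in 1:10) {
    k <- sample(4:6, 1)
    eff <- make_effects(rnorm(k), runif(k, 0.05, 1))
    out <- begg_test(eff)
    expect_equal(out$begg_method, "exact")
    # oracle: recompute the standardised deviates and use cor.test's exact
    # Kendall distribution
    w <- 1 / eff$v
    mu <- sum(w * eff$y) / sum(w)
    ystar <- (eff$y - mu) / sqrt(eff$v - 1 / sum(w))
    oracle <- stats::cor.test(ystar, eff$v, method = "kendall", exact = TRUE)
    expect_equal(out$kendall_tau, unname(oracle$estimate), tolerance = 1e-10)
    expect_equal(out$p_begg, oracle$p.value, tolerance = 1e-10)
  }
})

test_that("Begg falls back to the tie-corrected normal approximation", {
  # k > 8 forces the approximation
  set.seed(5)
  eff <- make_effects(rnorm(12), runif(12, 0.1, 1))
  out <- begg_test(eff)
  expect_equal(out$begg_method, "normal_approx")
  expect_gte(out$p_begg, 0)
  expect_lte(out$p_begg, 1)
  # tied variances at small k also force it
  eff2 <- make_effects(c(1, 2, 3, 4), c(0.2, 0.2, 0.5, 0.9))
  expect_equal(begg_test(eff2)$begg_method, "normal_approx")
})

test_that("Begg is not testable below 3 substudies or from a single parent study", {
  one_parent <- make_effects(c(1, 2, 3, 4), c(0.1, 0.2, 0.3, 0.4),
                             parent = rep("p01", 4))
  expect_equal(begg_test(one_parent)$begg_method, "not_testable")
  expect_equal(begg_test(make_effects(c(1, 2), c(0.1, 0.2)))$begg_method,
               "not_testable")
})

test_that("Egger regression recovers closed-form OLS and its edge cases", {
  # x = (1,2,3), t = (2,3,5): intercept 1/3, slope 3/2
  eff <- make_effects(c(2, 1.5, 5 / 3), c(1, 1 / 4, 1 / 9))
  out <- egger_test(eff)
  expect_equal(out$egger_intercept, 1 / 3, tolerance = 1e-10)
  expect_equal(out$egger_slope, 1.5, tolerance = 1e-10)
  expect_false(out$perfect_fit)

  # symmetric construction: intercept exactly 0
  sym <- make_effects(c(1, -1, 4, -4), c(1, 1, 4, 4))
  expect_equal(egger_test(sym)$egger_intercept, 0, tolerance = 1e-12)

  # exact line t = 1 + 2x: perfect fit flagged, intercept exact
  se <- 1 / c(1, 2, 4, 8)
  tvals <- 1 + 2 / se
  perf <- make_effects(tvals * se, se^2)
  outp <- egger_test(perf)
  expect_true(outp$perfect_fit)
  expect_equal(outp$egger_intercept, 1, tolerance = 1e-10)

  expect_error(egger_test(make_effects(c(1, 2, 3), c(1, 1, 1))), "degenerate")
})

test_that("Egger z-form agrees with metafor's regtest", {
  skip_if_not_installed("metafor")
  set.seed(12)
  y <- rnorm(8, 1, 1)
  v <- runif(8, 0.05, 0.8)
  out <- egger_test(make_effects(y, v))
  ref <- metafor::regtest(y, vi = v, model = "lm", predictor = "sei")
  expect_equal(out$egger_z, unname(ref$zval), tolerance = 1e-6)
  # metafor's lm-based regtest uses the t reference distribution
  out_t <- egger_test(make_effects(y, v), use_t = TRUE)
  expect_equal(out_t$p_egger, ref$pval, tolerance = 1e-6)
})

test_that("trim-and-fill reproduces the hand-executed L0 iteration", {
  eff <- make_effects(c(0, 3, 3.1, 3.2, 3.3), 1)
  tf <- trim_and_fill(eff, side = "right")
  expect_equal(tf$k0, 1L)
  expect_equal(tf$filled$y, 1.35, tolerance = 1e-12)
  expect_equal(tf$center, 2.325, tolerance = 1e-12)
  # filled points keep the original variances
  expect_equal(tf$filled$v, 1)
})

test_that("trim-and-fill leaves symmetric funnels alone and mirrors preserve the centre", {
  sym <- make_effects(c(-2, -1, 0, 1, 2), 1)
  tf <- trim_and_fill(sym, side = "auto")
  expect_equal(tf$k0, 0L)
  expect_equal(tf$mu_adjusted, 0, tolerance = 1e-12)

  # mirrored fill preserves the trimmed fixed-effect centre at equal variances
  skew <- make_effects(c(0, 0.2, 2.8, 3, 3.1, 3.2, 3.3), 1)
  tfs <- trim_and_fill(skew, side = "right")
  if (tfs$k0 > 0) {
    all_y <- c(skew$y, tfs$filled$y)
    expect_equal(mean(all_y), tfs$center, tolerance = 1e-12)
  }

  # left-censored data: imputation lands on the left
  left <- make_effects(c(-0.1, 2.9, 3.0, 3.1, 3.2), 1)
  mirror <- make_effects(-c(-0.1, 2.9, 3.0, 3.1, 3.2), 1)
  tf_r <- trim_and_fill(left, side = "right")
  tf_l <- trim_and_fill(mirror, side = "left")
  expect_equal(tf_l$k0, tf_r$k0)
  expect_equal(sort(tf_l$filled$y), sort(-tf_r$filled$y), tolerance = 1e-12)
})

test_that("trim-and-fill k0 matches metafor on seeded instances", {
  skip_if_not_installed("metafor")
  set.seed(33)
  for (i in 1:10) {
    k <- sample(6:12, 1)
    y <- rnorm(k, 1, 1.5)
    v <- runif(k, 0.05, 0.5)
    # suppress the lowest effects to induce right-excess asymmetry
    y <- sort(y)[ceiling(k / 3):k]
    v <- v[ceiling(k / 3):k]
    eff <- make_effects(y, v)
    tf <- trim_and_fill(eff, side = "right")
    ref <- suppressWarnings(
      metafor::trimfill(metafor::rma(yi = y, vi = v, method = "FE"),
                        side = "left", estimator = "L0")
    )
    expect_equal(tf$k0, unname(ref$k0))
  }
})

test_that("bias summary picks top-reported targets and respects the single-parent exclusion", {
  base <- dplyr::bind_rows(
    make_records("miR-1-3p", events_case = c(9, 8, 9, 8, 9), n_case = 12,
                 events_ctrl = c(2, 3, 2, 2, 3), n_ctrl = 12),
    make_records("miR-2-5p", events_case = c(2, 3, 2, 2), n_case = 12,
                 events_ctrl = c(9, 8, 9, 9), n_ctrl = 12),
    # all substudies share one parent study -> not testable
    make_records("miR-3-5p", events_case = c(8, 9, 8), n_case = 12,
                 events_ctrl = c(2, 2, 3), n_ctrl = 12,
                 parent = rep("solo", 3))
  )
  corpus <- mir_corpus(base)
  analysis <- run_meta(corpus, meta_config())
  rep <- bias_summary(analysis, corpus)
  expect_setequal(rep$mirna, c("miR-1-3p", "miR-2-5p", "miR-3-5p"))
  expect_equal(rep$begg_method[rep$mirna == "miR-3-5p"], "not_testable")
  expect_true(is.na(rep$k0[rep$mirna == "miR-3-5p"]))
  full <- rep[rep$mirna == "miR-1-3p", ]
  expect_false(is.na(full$p_begg))
  expect_false(is.na(full$p_egger))
  expect_true(full$p_begg >= 0 & full$p_begg <= 1)
  expect_true(abs(full$kendall_tau) <= 1)

  # absent targets are skipped with a message
  expect_message(bias_summary(analysis, corpus, targets = c("miR-1-3p", "miR-99-5p")),
                 "absent")
})

test_that("funnel data recomputes the fixed-effect centre", {
  eff <- make_effects(c(1, 2, 3), c(1, 0.5, 0.25))
  fd <- funnel_data(eff)
  expect_equal(fd$center, sum(eff$y / eff$v) / sum(1 / eff$v))
  expect_equal(fd$points$se, sqrt(eff$v))
  expect_s3_class(plot_funnel(fd), "ggplot")
})
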