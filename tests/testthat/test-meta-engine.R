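test_that("log odds ratios from 2x2 event counts, with continuity correction", {
  rec <- make_records("miR-1-3p",
                      events_case = c(8, 3, 5), n_case = 10,
                      events_ctrl = c(2, 3, 0), n_ctrl = 10)
  eff <- effect_from_counts(rec)
  expect_equal(eff$y[1], log(16), tolerance = 1e-12)
  expect_equal(eff$v[1], 1 / 8 + 1 / 2 + 1 / 2 + 1 / 8)
  expect_equal(eff$y[2], 0)
  # zero cell: +0.5 on all four cells, flagged
  expect_true(eff$corrected[3])
  expect_equal(eff$y[3], log((5.5 * 10.5) / (5.5 * 0.5)), tolerance = 1e-12)
  expect_equal(eff$v[3], 1 / 5.5 + 1 / 5.5 + 1 / 0.5 + 1 / 10.5, tolerance = 1e-12)
  expect_false(any(eff$corrected[1:2]))
})

test_that("both tau-squared estimators recover the balanced closed form", {
  eff <- make_effects(c(0.5, 1.0, 1.5), 0.1)
  # balanced design: tau2 = max(0, S2_y - v) = 0.25 - 0.10
  expect_equal(tau2_eb(eff), 0.15, tolerance = 1e-6)
  expect_equal(tau2_reml(eff), 0.15, tolerance = 1e-5)

  # no heterogeneity -> exactly zero
  flat <- make_effects(c(0.7, 0.7, 0.7), c(0.1, 0.2, 0.3))
  expect_identical(tau2_eb(flat), 0)
  expect_identical(tau2_reml(flat), 0)

  # two-point algebra: sum((y - 1)^2) / (1 + tau2) = 1 => tau2 = 1
  two <- make_effects(c(0, 2), 1)
  expect_equal(tau2_eb(two), 1, tolerance = 1e-6)

  expect_error(tau2_eb(make_effects(1, 0.1)), "not meta-analysable")
  expect_error(tau2_reml(make_effects(1, 0.1)), "not meta-analysable")
})

test_that("tau-squared estimators match metafor and a grid-search oracle", {
  skip_if_not_installed("metafor")
  set.seed(42)
  for (i in 1:20) {
    k <- sample(4:10, 1)
    y <- rnorm(k, 0.5, 1)
    v <- runif(k, 0.05, 0.5)
    eff <- make_effects(y, v)
    m_reml <- suppressWarnings(metafor::rma(yi = y, vi = v, method = "REML",
                                            control = list(tau2.max = 200)))
    m_eb <- suppressWarnings(metafor::rma(yi = y, vi = v, method = "EB",
                                          control = list(tau2.max = 200)))
    expect_equal(tau2_reml(eff), m_reml$tau2, tolerance = 1e-4)
    expect_equal(tau2_eb(eff), m_eb$tau2, tolerance = 1e-4)
    expect_equal(tau2_reml(eff), reml_grid_oracle(y, v), tolerance = 1e-5)
  }
})

test_that("random-effects pooling gives the closed-form balanced answer", {
  eff <- make_effects(c(0.5, 1.0, 1.5), 0.1)
  pooled <- pool_random_effects(eff, 0.15)
  expect_equal(pooled$mu, 1.0, tolerance = 1e-12)
  expect_equal(pooled$se, sqrt(0.25 / 3), tolerance = 1e-12)
  expect_equal(pooled$ci_low, 1 - qnorm(0.975) * pooled$se, tolerance = 1e-12)
  expect_equal(pooled$p_raw, 2 * pnorm(-1 / pooled$se), tolerance = 1e-12)

  # dominant-weight limit
  dom <- make_effects(c(1, 5), c(0.01, 100))
  expect_equal(pool_random_effects(dom, 0)$mu, (100 * 1 + 0.01 * 5) / 100.01,
               tolerance = 1e-12)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.001, 205), 0.205)
  expect_equal(bonferroni_adjust(0.5, 5), 1.0)
  expect_equal(bonferroni_adjust(0.01, 1), 0.01)
})

test_that("run_meta composes the estimators with per-run Bonferroni and both-estimator gate", {
  rec <- dplyr::bind_rows(
    make_records("miR-1-3p", events_case = c(9, 8, 9), n_case = 10,
                 events_ctrl = c(1, 2, 2), n_ctrl = 10),
    make_records("miR-2-5p", events_case = c(5, 6, 4), n_case = 10,
                 events_ctrl = c(5, 4, 6), n_ctrl = 10),
    make_records("miR-3-5p", events_case = 8, n_case = 10,
                 events_ctrl = 2, n_ctrl = 10)
  )
  corpus <- mir_corpus(rec)
  res <- suppressMessages(run_meta(corpus, meta_config()))
  # singleton excluded and logged
  expect_equal(nrow(res), 2)
  expect_equal(attr(res, "excluded")$mirna, "miR-3-5p")
  expect_equal(attr(res, "m_tests"), 2)
  expect_equal(res$p_adj_reml, pmin(1, 2 * res$p_raw_reml))
  strong <- res[res$mirna == "miR-1-3p", ]
  expect_true(strong$significant)
  expect_equal(strong$direction, "up")
  null_row <- res[res$mirna == "miR-2-5p", ]
  expect_false(null_row$significant)
  expect_error(run_meta(mir_corpus(rec[0, ]), meta_config()), "empty corpus")
})

test_that("pooled effects are antisymmetric under arm swap and permutation invariant", {
  set.seed(11)
  rec <- dplyr::bind_rows(purrr::map(1:3, function(i) {
    make_records(paste0("miR-", i, "-3p"),
                 events_case = rbinom(4, 30, 0.6), n_case = 30,
                 events_ctrl = rbinom(4, 25, 0.2), n_ctrl = 25)
  }))
  res <- run_meta(mir_corpus(rec), meta_config())

  swapped <- rec |>
    dplyr::rename(n_case = "n_ctrl", n_ctrl = "n_case",
                  events_case = "events_ctrl", events_ctrl = "events_case")
  res_swap <- run_meta(mir_corpus(swapped), meta_config())
  expect_equal(res_swap$mu_reml, -res$mu_reml, tolerance = 1e-10)
  expect_equal(res_swap$mu_eb, -res$mu_eb, tolerance = 1e-10)

  shuffled <- rec[sample(nrow(rec)), ]
  res_shuf <- run_meta(mir_corpus(shuffled), meta_config())
  expect_equal(res_shuf$mu_reml, res$mu_reml, tolerance = 1e-12)
  expect_equal(res_shuf$tau2_eb, res$tau2_eb, tolerance = 1e-12)
})

test_that("subgroup analysis partitions strata and flags cross-stratum direction flips", {
  up_serum <- make_records("miR-9-5p", events_case = c(9, 9, 8), n_case = 10,
                           events_ctrl = c(1, 2, 2), n_ctrl = 10,
                           tissue = "serum", fraction = "serum")
  down_plasma <- make_records("miR-9-5p", events_case = c(1, 2, 1), n_case = 10,
                              events_ctrl = c(9, 8, 9), n_ctrl = 10,
                              tissue = "plasma", fraction = "plasma",
                              parent = sprintf("q%02d", 1:3))
  down_plasma$substudy_id <- paste0("pl_", down_plasma$substudy_id)
  corpus <- mir_corpus(dplyr::bind_rows(up_serum, down_plasma))

  sg <- suppressMessages(run_subgroups(corpus, meta_config(), axis = "blood_fraction"))
  expect_setequal(names(sg$sets), c("subgroup:serum", "subgroup:plasma"))
  expect_equal(sg$inconsistent$mirna, "miR-9-5p")

  # nanostring-only records are skipped from the platform axis with a message
  ns <- make_records("miR-8-3p", events_case = c(5, 6), n_case = 10,
                     events_ctrl = c(5, 5), n_ctrl = 10, platform = "nanostring")
  corpus2 <- mir_corpus(dplyr::bind_rows(up_serum, ns))
  expect_message(run_subgroups(corpus2, meta_config(), axis = "platform"),
                 "nanostring")
  sg2 <- suppressMessages(run_subgroups(corpus2, meta_config(), axis = "platform"))
  expect_equal(names(sg2$sets), "subgroup:pcr")
})

test_that("sensitivity thresholds are inclusive and threshold 0 reproduces the overall run", {
  rec <- dplyr::bind_rows(
    make_records("miR-1-3p", events_case = c(9, 8, 9), n_case = c(12, 13, 20),
                 events_ctrl = c(1, 2, 2), n_ctrl = c(12, 12, 20)),
    make_records("miR-2-5p", events_case = c(8, 9), n_case = c(15, 30),
                 events_ctrl = c(2, 3), n_ctrl = c(15, 30))
  )
  corpus <- mir_corpus(rec)
  sens <- suppressMessages(run_sensitivity(corpus, meta_config(), thresholds = c(25, 50, 0)))
  # n = 24 excluded at t=25, n = 25 included
  k25 <- tibble::as_tibble(sens$sets[["sensitivity:n>=25"]])
  # total 24 dropped, total exactly 25 kept (inclusive bound), total 40 kept
  expect_equal(k25$k[k25$mirna == "miR-1-3p"], 2L)
  expect_equal(k25$k[k25$mirna == "miR-2-5p"], 2L)

  overall <- run_meta(corpus, meta_config())
  t0 <- tibble::as_tibble(sens$sets[["sensitivity:n>=0"]])
  expect_equal(t0$mu_reml, overall$mu_reml, tolerance = 1e-12)
})

test_that("direction consistency is vacuous where non-significant and strict elsewhere", {
  mk_set <- function(label, mirna, direction, significant) {
    res <- empty_set <- tibble::tibble(
      mirna = mirna, k = 3L, mu_reml = ifelse(direction == "up", 1, -1),
      mu_eb = ifelse(direction == "up", 1, -1), tau2_reml = 0, tau2_eb = 0,
      se_reml = 0.1, se_eb = 0.1, ci_low = 0, ci_high = 0,
      p_raw_reml = 0.001, p_raw_eb = 0.001, p_adj_reml = 0.002, p_adj_eb = 0.002,
      direction = direction, significant = significant
    )
    metamirna:::new_mir_analysis(res, label = label, m_tests = length(mirna),
                                 alpha = 0.05,
                                 excluded = tibble::tibble(mirna = character(), k = integer()))
  }
  sets <- list(
    mk_set("overall", c("a", "b", "c"), c("up", "up", "down"), c(TRUE, TRUE, FALSE)),
    mk_set("subgroup:serum", c("a", "b", "c"), c("up", "down", "down"),
           c(TRUE, TRUE, FALSE))
  )
  cons <- direction_consistency(sets)
  expect_equal(cons$status[cons$mirna == "a"], "consistent_up")
  expect_equal(cons$status[cons$mirna == "b"], "inconsistent")
  expect_equal(cons$status[cons$mirna == "c"], "never_significant")
})
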