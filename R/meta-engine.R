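#' Meta-analysis configuration
#'
#' @param min_substudies Minimum number of substudies for a microRNA to be
#'   meta-analysed (default 2; singletons are excluded and logged).
#' @param alpha Significance level applied to Bonferroni-adjusted p values.
#' @param m_tests Bonferroni divisor. `NULL` (default) means "set per analysis
#'   run" to the number of microRNAs actually meta-analysed in that run.
#' @param tau2_tol Convergence tolerance for both tau-squared estimators.
#' @param tau2_max_iter Iteration cap for the Paule-Mandel bisection.
#' @param ci_level Confidence level for Wald intervals (default 0.95).
#' @return A `mir_meta_config` list.
#' @export
meta_config <- function(min_substudies = 2, alpha = 0.05, m_tests = NULL,
                        tau2_tol = 1e-8, tau2_max_iter = 200, ci_level = 0.95) {
  stopifnot(min_substudies >= 2, alpha > 0, alpha < 1, ci_level > 0, ci_level < 1)
  structure(
    list(min_substudies = as.integer(min_substudies), alpha = alpha,
         m_tests = m_tests, tau2_tol = tau2_tol,
         tau2_max_iter = as.integer(tau2_max_iter), ci_level = ci_level),
    class = "mir_meta_config"
  )
}

#' Log odds ratios from dysregulation-event counts
#'
#' Converts each substudy's 2x2 table (dysregulation events vs non-events in
#' case and control arms) to a signed natural-log odds ratio `y` and its
#' within-substudy variance `v = 1/a + 1/b + 1/c + 1/d`. If any cell is zero
#' the Haldane-Anscombe continuity correction adds 0.5 to all four cells and
#' the record is flagged `corrected`. The sign convention is
#' case-vs-control, so `y > 0` means dysregulation events are more frequent
#' in the diabetic arm (upregulated dysregulation evidence).
#'
#' @param records A `mir_corpus` or its records tibble (must carry the event
#'   count columns plus `substudy_id`, `parent_study_id`, `mirna`).
#' @return A tibble of effect sizes: `substudy_id`, `parent_study_id`,
#'   `mirna`, `y`, `v`, `corrected`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   substudy_id = "s1", parent_study_id = "p1", mirna = "miR-1-3p",
#'   n_case = 10L, n_ctrl = 10L, events_case = 8L, events_ctrl = 2L
#' )
#' effect_from_counts(rec)
effect_from_counts <- function(records) {
  if (inherits(records, "mir_corpus")) records <- records$records
  records <- tibble::as_tibble(records)
  a <- as.numeric(records$events_case)
  b <- as.numeric(records$n_case) - a
  c_ <- as.numeric(records$events_ctrl)
  d <- as.numeric(records$n_ctrl) - c_
  stopifnot(all(a >= 0), all(b >= 0), all(c_ >= 0), all(d >= 0))
  corrected <- a == 0 | b == 0 | c_ == 0 | d == 0
  cc <- ifelse(corrected, 0.5, 0)
  a <- a + cc; b <- b + cc; c_ <- c_ + cc; d <- d + cc
  tibble::tibble(
    substudy_id = records$substudy_id,
    parent_study_id = records$parent_study_id,
    mirna = records$mirna,
    y = log((a * d) / (b * c_)),
    v = 1 / a + 1 / b + 1 / c_ + 1 / d,
    corrected = corrected
  )
}

#' Between-substudy variance: empirical-Bayes / Paule-Mandel estimator
#'
#' Solves the Paule-Mandel estimating equation
#' `sum(w_i (y_i - mu(t))^2) = k - 1` with `w_i = 1/(v_i + t)` and
#' `mu(t)` the weighted mean, by bisection; this fixed point coincides with
#' the empirical-Bayes estimator in standard implementations. Truncated at 0
#' when the equation has no positive root (no excess heterogeneity).
#'
#' @param effects Effect-size tibble from [effect_from_counts()] (needs `y`,
#'   `v`; `k >= 2` rows).
#' @param tol Bisection tolerance on tau-squared.
#' @param max_iter Iteration cap.
#' @return Non-negative scalar tau-squared.
#' @export
tau2_eb <- function(effects, tol = 1e-8, max_iter = 200) {
  y <- effects$y; v <- effects$v
  k <- length(y)
  if (k < 2) abort("not meta-analysable: fewer than 2 substudies")
  f <- function(t) {
    w <- 1 / (v + t)
    mu <- sum(w * y) / sum(w)
    sum(w * (y - mu)^2) - (k - 1)
  }
  if (f(0) <= 0) return(0)
  hi <- max(var(y), max(v), 1)
  it <- 0
  while (f(hi) > 0 && it < max_iter) {
    hi <- hi * 2
    it <- it + 1
  }
  lo <- 0
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Between-substudy variance: restricted maximum likelihood
#'
#' Maximises the restricted log-likelihood
#' `-1/2 [ sum(log(v_i + t)) + log(sum(w_i)) + sum(w_i (y_i - mu(t))^2) ]`
#' over `t` in `[0, cap]` by bounded 1-D optimisation, where
#' `cap = max(10, 100 * var(y))`. The boundary `t = 0` is checked explicitly
#' so homogeneous inputs return exactly zero.
#'
#' @inheritParams tau2_eb
#' @return Non-negative scalar tau-squared.
#' @export
tau2_reml <- function(effects, tol = 1e-8, max_iter = 200) {
  y <- effects$y; v <- effects$v
  k <- length(y)
  if (k < 2) abort("not meta-analysable: fewer than 2 substudies")
  ll <- function(t) {
    w <- 1 / (v + t)
    mu <- sum(w * y) / sum(w)
    -0.5 * (sum(log(v + t)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  cap <- max(10, 100 * var(y))
  opt <- optimize(ll, interval = c(0, cap), maximum = TRUE, tol = max(tol, 1e-10))
  if (ll(0) >= opt$objective) 0 else opt$maximum
}

#' Random-effects pooling at a given tau-squared
#'
#' Inverse-variance pooling with weights `1/(v_i + tau2)`; Wald standard
#' error, confidence interval and two-sided normal p value.
#'
#' @inheritParams tau2_eb
#' @param tau2 Between-substudy variance to pool under.
#' @param ci_level Confidence level.
#' @return One-row tibble: `mu`, `se`, `ci_low`, `ci_high`, `p_raw`.
#' @export
pool_random_effects <- function(effects, tau2, ci_level = 0.95) {
  y <- effects$y; v <- effects$v
  if (length(y) < 2) abort("not meta-analysable: fewer than 2 substudies")
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- z_quantile(ci_level)
  tibble::tibble(
    mu = mu, se = se,
    ci_low = mu - z * se, ci_high = mu + z * se,
    p_raw = 2 * pnorm(-abs(mu) / se)
  )
}

#' Bonferroni adjustment
#'
#' @param p_raw Raw p values.
#' @param m_tests Number of tests (the Bonferroni divisor), `>= 1`.
#' @return `pmin(1, m_tests * p_raw)`.
#' @export
bonferroni_adjust <- function(p_raw, m_tests) {
  stopifnot(m_tests >= 1)
  pmin(1, m_tests * p_raw)
}

meta_one_mirna <- function(eff, cfg) {
  t_reml <- tau2_reml(eff, tol = cfg$tau2_tol, max_iter = cfg$tau2_max_iter)
  t_eb <- tau2_eb(eff, tol = cfg$tau2_tol, max_iter = cfg$tau2_max_iter)
  p_reml <- pool_random_effects(eff, t_reml, cfg$ci_level)
  p_eb <- pool_random_effects(eff, t_eb, cfg$ci_level)
  tibble::tibble(
    k = nrow(eff),
    mu_reml = p_reml$mu, mu_eb = p_eb$mu,
    tau2_reml = t_reml, tau2_eb = t_eb,
    se_reml = p_reml$se, se_eb = p_eb$se,
    ci_low = p_reml$ci_low, ci_high = p_reml$ci_high,
    p_raw_reml = p_reml$p_raw, p_raw_eb = p_eb$p_raw
  )
}

#' Per-microRNA random-effects meta-analysis over a corpus
#'
#' Groups effects by canonical microRNA, drops microRNAs observed in fewer
#' than `min_substudies` substudies (recorded in the `excluded` attribute),
#' estimates tau-squared by both REML and empirical Bayes, pools under each,
#' Bonferroni-adjusts both raw p values with `m_tests` = the number of
#' microRNAs analysed in this run (unless fixed in the config), and flags a
#' microRNA significant only when *both* estimators give adjusted `p < alpha`
#' *and* agree on the sign of the pooled effect. Direction is the sign of the
#' REML pooled log odds ratio.
#'
#' @param corpus A `mir_corpus` (or an effects tibble from
#'   [effect_from_counts()]).
#' @param cfg A [meta_config()].
#' @param label Label for this analysis set (e.g. `"overall"`,
#'   `"subgroup:serum"`).
#' @return A `mir_analysis` object: tibble of per-microRNA results with
#'   attributes `label`, `m_tests`, `alpha`, `excluded`.
#' @export
run_meta <- function(corpus, cfg = meta_config(), label = "overall") {
  effects <- if (inherits(corpus, "mir_corpus")) effect_from_counts(corpus) else tibble::as_tibble(corpus)
  if (nrow(effects) == 0) abort("empty corpus: nothing to meta-analyse")

  counts <- dplyr::count(effects, .data$mirna, name = "k")
  excluded <- dplyr::filter(counts, .data$k < cfg$min_substudies)
  if (nrow(excluded)) {
    inform(paste0(nrow(excluded), " microRNA(s) excluded with k < ",
                  cfg$min_substudies, " in ", label))
  }
  keep <- dplyr::filter(counts, .data$k >= cfg$min_substudies)$mirna

  res <- if (length(keep)) {
    effects |>
      dplyr::filter(.data$mirna %in% keep) |>
      dplyr::group_by(.data$mirna) |>
      dplyr::group_modify(~ meta_one_mirna(.x, cfg)) |>
      dplyr::ungroup()
  } else {
    empty_meta_results()[, 1:12]
  }

  m_tests <- cfg$m_tests %||% nrow(res)
  if (nrow(res)) {
    res <- res |>
      dplyr::mutate(
        p_adj_reml = bonferroni_adjust(.data$p_raw_reml, max(1, m_tests)),
        p_adj_eb = bonferroni_adjust(.data$p_raw_eb, max(1, m_tests)),
        direction = dplyr::if_else(.data$mu_reml >= 0, "up", "down"),
        sign_agree = sign(.data$mu_reml) == sign(.data$mu_eb) |
          .data$mu_reml == 0 | .data$mu_eb == 0,
        significant = .data$p_adj_reml < cfg$alpha & .data$p_adj_eb < cfg$alpha &
          .data$sign_agree
      ) |>
      dplyr::select(-"sign_agree") |>
      dplyr::arrange(.data$mirna)
  } else {
    res <- empty_meta_results()
  }
  new_mir_analysis(res, label = label, m_tests = m_tests, alpha = cfg$alpha,
                   excluded = excluded)
}

empty_meta_results <- function() {
  tibble::tibble(
    mirna = character(), k = integer(), mu_reml = double(), mu_eb = double(),
    tau2_reml = double(), tau2_eb = double(), se_reml = double(),
    se_eb = double(), ci_low = double(), ci_high = double(),
    p_raw_reml = double(), p_raw_eb = double(), p_adj_reml = double(),
    p_adj_eb = double(), direction = character(), significant = logical()
  )
}

new_mir_analysis <- function(results, label, m_tests, alpha, excluded) {
  structure(results, class = c("mir_analysis", class(results)),
            label = label, m_tests = m_tests, alpha = alpha, excluded = excluded)
}

#' @export
print.mir_analysis <- function(x, ...) {
  cat("<mir_analysis> ", attr(x, "label"), ": ", nrow(x), " microRNAs (m = ",
      attr(x, "m_tests"), "), ", sum(x$significant), " significant at alpha = ",
      attr(x, "alpha"), "\n", sep = "")
  NextMethod()
}

#' @export
tidy.mir_analysis <- function(x, ...) {
  tibble::as_tibble(x) |> dplyr::mutate(label = attr(x, "label"), .before = 1)
}

#' @export
glance.mir_analysis <- function(x, ...) {
  tibble::tibble(
    label = attr(x, "label"), n_mirnas = nrow(x), m_tests = attr(x, "m_tests"),
    alpha = attr(x, "alpha"), n_significant = sum(x$significant),
    n_excluded = nrow(attr(x, "excluded"))
  )
}

#' Subgroup meta-analyses along one stratification axis
#'
#' Partitions the corpus by tissue class, blood fraction (within blood
#' records), or detection platform, and re-runs [run_meta()] per stratum with
#' a per-stratum Bonferroni divisor. For the platform axis only the PCR and
#' sequencing strata are analysed (other platforms are too sparse to form an
#' informative stratum and are skipped with a message). Also returns a
#' cross-stratum direction table flagging microRNAs significant with opposite
#' directions in different strata.
#'
#' @param corpus A `mir_corpus`.
#' @param cfg A [meta_config()].
#' @param axis One of `"tissue"`, `"blood_fraction"`, `"platform"`.
#' @return A `mir_subgroups` list: `sets` (named list of `mir_analysis`),
#'   `direction_table` (mirna x stratum direction of significant results) and
#'   `inconsistent` (microRNAs up in one stratum, down in another).
#' @export
run_subgroups <- function(corpus, cfg = meta_config(), axis = c("tissue", "blood_fraction", "platform")) {
  axis <- match.arg(axis)
  stopifnot(inherits(corpus, "mir_corpus"))
  rec <- corpus$records
  rec <- switch(axis,
    tissue = dplyr::mutate(rec, stratum = .data$tissue_class),
    blood_fraction = rec |>
      dplyr::filter(.data$tissue_class == "blood") |>
      dplyr::mutate(stratum = .data$blood_fraction),
    platform = {
      skip <- setdiff(unique(rec$platform), c("pcr", "seq"))
      if (length(skip)) {
        inform(paste0("platform stratum(s) skipped: ", paste(skip, collapse = ", ")))
      }
      rec |>
        dplyr::filter(.data$platform %in% c("pcr", "seq")) |>
        dplyr::mutate(stratum = .data$platform)
    }
  )
  strata <- sort(unique(rec$stratum))
  sets <- purrr::map(strata, function(s) {
    sub <- dplyr::filter(rec, .data$stratum == s)
    run_meta(effect_from_counts(sub), cfg, label = paste0("subgroup:", s))
  })
  names(sets) <- paste0("subgroup:", strata)
  sets <- purrr::keep(sets, ~ nrow(.x) > 0)

  dir_tab <- purrr::map_dfr(sets, function(s) {
    tibble::as_tibble(s) |>
      dplyr::filter(.data$significant) |>
      dplyr::transmute(.data$mirna, stratum = attr(s, "label"), .data$direction)
  })
  inconsistent <- dir_tab |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(n_directions = dplyr::n_distinct(.data$direction), .groups = "drop") |>
    dplyr::filter(.data$n_directions > 1)

  structure(list(sets = sets, direction_table = dir_tab, inconsistent = inconsistent,
                 axis = axis),
            class = "mir_subgroups")
}

#' Sample-size sensitivity analyses
#'
#' Repeats the overall meta-analysis keeping only substudies whose combined
#' sample size `n_case + n_ctrl` meets each threshold (inclusive).
#'
#' @param corpus A `mir_corpus`.
#' @param cfg A [meta_config()].
#' @param thresholds Integer thresholds (default `c(25, 50)`).
#' @return A `mir_sensitivity` list: `sets` (named list of `mir_analysis`
#'   labelled `sensitivity:n>=T`) and `summary` (threshold, substudies
#'   retained, microRNAs analysed, microRNAs significant).
#' @export
run_sensitivity <- function(corpus, cfg = meta_config(), thresholds = c(25, 50)) {
  stopifnot(inherits(corpus, "mir_corpus"), length(thresholds) >= 1)
  sets <- purrr::map(thresholds, function(t) {
    sub <- dplyr::filter(corpus$records, .data$n_case + .data$n_ctrl >= t)
    label <- paste0("sensitivity:n>=", t)
    if (nrow(sub) == 0) {
      return(new_mir_analysis(empty_meta_results(), label = label,
                              m_tests = 0, alpha = cfg$alpha,
                              excluded = tibble::tibble(mirna = character(), k = integer())))
    }
    run_meta(effect_from_counts(sub), cfg, label = label)
  })
  names(sets) <- paste0("sensitivity:n>=", thresholds)
  summary <- purrr::map2_dfr(sets, thresholds, function(s, t) {
    tibble::tibble(threshold = t,
                   n_substudies = sum(dplyr::filter(corpus$records,
                                                    .data$n_case + .data$n_ctrl >= t) |> nrow()),
                   n_mirnas = nrow(s), n_significant = sum(s$significant))
  })
  structure(list(sets = sets, summary = summary), class = "mir_sensitivity")
}

#' Cross-analysis direction consistency
#'
#' A microRNA is direction-consistent when every analysis set in which it is
#' significant agrees on the direction of dysregulation; sets where it is not
#' significant are vacuously consistent.
#'
#' @param sets A list of `mir_analysis` objects (overall, subgroups,
#'   sensitivity runs, ...).
#' @return A tibble `mirna`, `status` with status one of `consistent_up`,
#'   `consistent_down`, `inconsistent`, `never_significant`.
#' @export
direction_consistency <- function(sets) {
  stopifnot(length(sets) >= 1)
  all_res <- purrr::map_dfr(sets, ~ tibble::as_tibble(.x))
  sig <- dplyr::filter(all_res, .data$significant)
  all_res |>
    dplyr::distinct(.data$mirna) |>
    dplyr::left_join(
      sig |>
        dplyr::group_by(.data$mirna) |>
        dplyr::summarise(dirs = list(unique(.data$direction)), .groups = "drop"),
      by = "mirna"
    ) |>
    dplyr::mutate(status = purrr::map_chr(.data$dirs, function(d) {
      if (is.null(d)) "never_significant"
      else if (length(d) > 1) "inconsistent"
      else paste0("consistent_", d)
    })) |>
    dplyr::select("mirna", "status") |>
    dplyr::arrange(.data$mirna)
}
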