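#' Funnel-plot data for one microRNA
#'
#' Effect sizes against their standard errors, centred at the fixed-effect
#' (inverse-variance) pooled estimate, recomputed here rather than cached from
#' the random-effects run.
#'
#' @param effects Effect-size tibble (`y`, `v`, `substudy_id`).
#' @return A `mir_funnel` list: `points` tibble (`y`, `se`, `substudy_id`)
#'   and scalar `center`.
#' @export
funnel_data <- function(effects) {
  stopifnot(nrow(effects) >= 1)
  w <- 1 / effects$v
  structure(
    list(
      points = tibble::tibble(y = effects$y, se = sqrt(effects$v),
                              substudy_id = effects$substudy_id),
      center = sum(w * effects$y) / sum(w)
    ),
    class = "mir_funnel"
  )
}

kendall_stats <- function(x, y) {
  # S statistic, tau, and tie-corrected variance of S (normal approximation)
  n <- length(x)
  cmp <- function(v) sign(outer(v, v, "-"))
  sx <- cmp(x); sy <- cmp(y)
  s <- sum(sx[lower.tri(sx)] * sy[lower.tri(sy)])
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- s / sqrt((n0 - n1) * (n0 - n2))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
  } else 0
  list(s = s, tau = tau, var_s = (v0 - vt - vu) / 18 + v1 + v2,
       ties = n1 > 0 || n2 > 0)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

begg_exact_p <- function(x, y) {
  # two-sided exact permutation p for Kendall's tau, no ties assumed
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- kendall_stats(rx, ry)$tau
  perms <- all_permutations(n)
  sx <- sign(outer(rx, rx, "-")); lt <- lower.tri(sx)
  n0 <- n * (n - 1) / 2
  taus <- apply(perms, 1, function(p) {
    sy <- sign(outer(ry[p], ry[p], "-"))
    sum(sx[lt] * sy[lt]) / n0
  })
  mean(abs(taus) >= abs(obs) - 1e-12)
}

#' Begg-Mazumdar rank-correlation test for funnel asymmetry
#'
#' Correlates the variance-standardised deviates
#' `y*_i = (y_i - mu_FE) / sqrt(v_i - 1/sum(1/v_j))` with the sampling
#' variances `v_i` by Kendall's tau. The two-sided p value is computed by
#' exact permutation enumeration when `k <= exact_cutoff` and neither vector
#' has ties, and otherwise by the normal approximation with tie-corrected
#' variance of Kendall's S. Testing requires at least 3 substudies from at
#' least 2 parent studies; otherwise the microRNA is `not_testable` (the
#' model assumes independent studies).
#'
#' @param effects Effect-size tibble (`y`, `v`, `parent_study_id`).
#' @param exact_cutoff Largest k for which the exact enumeration is used
#'   (default 8; 8! = 40320 permutations).
#' @return One-row tibble: `kendall_tau`, `p_begg`, `begg_method`
#'   (`exact`, `normal_approx` or `not_testable`).
#' @export
begg_test <- function(effects, exact_cutoff = 8) {
  k <- nrow(effects)
  n_parent <- dplyr::n_distinct(effects$parent_study_id)
  if (k < 3 || n_parent < 2) {
    return(tibble::tibble(kendall_tau = NA_real_, p_begg = NA_real_,
                          begg_method = "not_testable"))
  }
  y <- effects$y; v <- effects$v
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  vstar <- v - 1 / sum(w)
  if (any(vstar <= 0)) {
    warn("non-positive standardised variance(s) clamped to 1e-12 in Begg test")
    vstar <- pmax(vstar, 1e-12)
  }
  ystar <- (y - mu_fe) / sqrt(vstar)
  ks <- kendall_stats(ystar, v)
  if (k <= exact_cutoff && !ks$ties) {
    tibble::tibble(kendall_tau = ks$tau, p_begg = begg_exact_p(ystar, v),
                   begg_method = "exact")
  } else {
    z <- ks$s / sqrt(ks$var_s)
    tibble::tibble(kendall_tau = ks$tau, p_begg = 2 * pnorm(-abs(z)),
                   begg_method = "normal_approx")
  }
}

#' Egger regression test for small-study asymmetry
#'
#' Ordinary least squares of the standardised effect `t_i = y_i / se_i` on
#' precision `x_i = 1/se_i` with intercept; a non-zero intercept indicates
#' asymmetry. The test statistic defaults to `z = intercept / SE(intercept)`
#' with a two-sided normal p value; a Student-t version on `k - 2` degrees of
#' freedom is available via `use_t`.
#'
#' @param effects Effect-size tibble (`y`, `v`, `parent_study_id`).
#' @param use_t Use the t reference distribution instead of normal.
#' @return One-row tibble: `egger_intercept`, `egger_slope`, `egger_z`,
#'   `p_egger`, `perfect_fit`.
#' @export
egger_test <- function(effects, use_t = FALSE) {
  k <- nrow(effects)
  if (k < 3) abort("Egger test needs at least 3 substudies")
  se <- sqrt(effects$v)
  x <- 1 / se
  tstat <- effects$y / se
  if (diff(range(x)) < 1e-12) abort("degenerate precision design: all precisions equal")
  fit <- lm(tstat ~ x)
  res_var <- sum(fit$residuals^2) / (k - 2)
  est <- coef(fit)[["(Intercept)"]]
  if (res_var < 1e-14) {
    return(tibble::tibble(egger_intercept = est, egger_slope = coef(fit)[["x"]],
                          egger_z = sign(est) * Inf, p_egger = 0, perfect_fit = TRUE))
  }
  se_int <- sqrt(diag(vcov(fit)))[["(Intercept)"]]
  z <- est / se_int
  p <- if (use_t) 2 * stats::pt(-abs(z), df = k - 2) else 2 * pnorm(-abs(z))
  tibble::tibble(egger_intercept = est, egger_slope = coef(fit)[["x"]],
                 egger_z = z, p_egger = p, perfect_fit = FALSE)
}

fe_center <- function(y, v) sum(y / v) / sum(1 / v)

trimfill_l0 <- function(y, v, k0) {
  # L0 estimator with center from the k0-trimmed set, ranks over all k
  k <- length(y)
  ord <- order(y)
  keep <- if (k0 > 0) ord[seq_len(k - k0)] else ord
  center <- fe_center(y[keep], v[keep])
  d <- y - center
  r <- rank(abs(d))
  t_n <- sum(r[d > 0])
  (4 * t_n - k * (k + 1)) / (2 * k - 1)
}

#' Duval-Tweedie trim-and-fill correction
#'
#' Estimates the number `k0` of substudies suppressed on one side of the
#' funnel by the iterative `L0` estimator: trim the `k0` most extreme effects
#' on the excess side, re-centre at the fixed-effect estimate of the trimmed
#' set, recompute signed-rank sums over all substudies, and iterate until
#' `k0` stabilises (cap 50 iterations). The `k0` trimmed effects are then
#' mirrored about the trimmed centre (keeping their variances) and the
#' observed-plus-filled set is pooled under the REML random-effects model.
#'
#' @param effects Effect-size tibble (`y`, `v`, `substudy_id`).
#' @param side Which side of the funnel carries the observed excess (i.e. the
#'   side to trim): `"auto"` (default) picks the side with the larger positive
#'   `L0`, breaking ties by the sign of the Egger intercept; `"right"` trims
#'   the largest effects, `"left"` the smallest.
#' @return A `mir_trimfill` list: `k0`, `side`, `filled` tibble (mirrored
#'   points), `mu_adjusted`, `p_adjusted`, `center`, `iterations`.
#' @export
trim_and_fill <- function(effects, side = c("auto", "left", "right")) {
  side <- match.arg(side)
  k <- nrow(effects)
  if (k < 3) abort("trim-and-fill needs at least 3 substudies")
  y <- effects$y; v <- effects$v

  if (side == "auto") {
    l_right <- trimfill_l0(y, v, 0)
    l_left <- trimfill_l0(-y, v, 0)
    side <- if (max(l_right, l_left) <= 0) "right" # no excess: k0 = 0 either way
            else if (l_right > l_left) "right"
            else if (l_left > l_right) "left"
            else {
      egger_int <- tryCatch(egger_test(effects)$egger_intercept, error = function(e) 0)
      if (egger_int >= 0) "right" else "left"
    }
  }
  flip <- if (side == "left") -1 else 1
  yy <- flip * y

  k0 <- 0L; prev <- -1L; it <- 0L; trace <- integer()
  while (k0 != prev && it < 50L) {
    prev <- k0
    l0 <- trimfill_l0(yy, v, k0)
    k0 <- max(0L, min(as.integer(round(l0)), k - 2L))
    trace <- c(trace, k0)
    it <- it + 1L
  }
  if (k0 != prev) {
    abort(paste0("trim-and-fill did not converge in 50 iterations; k0 trace: ",
                 paste(trace, collapse = " -> ")))
  }

  ord <- order(yy)
  keep <- if (k0 > 0) ord[seq_len(k - k0)] else ord
  center <- fe_center(yy[keep], v[keep])
  filled <- if (k0 > 0) {
    trim_idx <- ord[seq.int(k - k0 + 1L, k)]
    tibble::tibble(
      y = flip * (2 * center - yy[trim_idx]),
      v = v[trim_idx],
      substudy_id = paste0("fill_", seq_len(k0)),
      parent_study_id = paste0("fill_", seq_len(k0))
    )
  } else {
    tibble::tibble(y = double(), v = double(), substudy_id = character(),
                   parent_study_id = character())
  }

  combined <- dplyr::bind_rows(
    tibble::tibble(y = y, v = v,
                   substudy_id = effects$substudy_id,
                   parent_study_id = effects$parent_study_id),
    filled
  )
  pooled <- pool_random_effects(combined, tau2_reml(combined))
  structure(
    list(k0 = k0, side = side, filled = filled,
         mu_adjusted = pooled$mu, p_adjusted = pooled$p_raw,
         center = flip * center, iterations = it),
    class = "mir_trimfill"
  )
}

#' Publication-bias reports for selected microRNAs
#'
#' Runs the Begg, Egger and trim-and-fill analyses per target microRNA. The
#' default target selection mirrors common practice for reporting: the top
#' `n_top` most reported microRNAs overall plus the top `n_top` most reported
#' per direction of dysregulation (by substudy count, ties broken
#' alphabetically). MicroRNAs whose substudies all share one parent study, or
#' with fewer than 3 substudies, are reported `not_testable`.
#'
#' Post-correction significance asks whether the trim-and-fill corrected
#' pooled effect is itself significant (`p_adjusted < alpha`); the correction
#' is a single follow-up test per tested microRNA, so it is not folded into
#' the meta-analysis Bonferroni family.
#'
#' @param analysis A `mir_analysis` (used for target defaults and `m_tests`).
#' @param corpus The `mir_corpus` the analysis was run on.
#' @param targets Character vector of canonical microRNA names, or `NULL` for
#'   the default selection.
#' @param n_top Number of top-reported microRNAs per category (default 3).
#' @return A `mir_bias` tibble: one row per target with Begg, Egger and
#'   trim-and-fill fields plus `significant_after_correction`.
#' @export
bias_summary <- function(analysis, corpus, targets = NULL, n_top = 3) {
  stopifnot(inherits(analysis, "mir_analysis"), inherits(corpus, "mir_corpus"))
  effects <- effect_from_counts(corpus)
  res <- tibble::as_tibble(analysis)

  if (is.null(targets)) {
    counts <- res |> dplyr::arrange(dplyr::desc(.data$k), .data$mirna)
    top_overall <- head(counts$mirna, n_top)
    top_dir <- counts |>
      dplyr::group_by(.data$direction) |>
      dplyr::slice_head(n = n_top) |>
      dplyr::pull(.data$mirna)
    targets <- unique(c(top_overall, top_dir))
  }

  missing <- setdiff(targets, res$mirna)
  if (length(missing)) {
    inform(paste0("bias target(s) absent from analysis, skipped: ",
                  paste(missing, collapse = ", ")))
    targets <- setdiff(targets, missing)
  }

  alpha <- attr(analysis, "alpha")
  out <- purrr::map_dfr(targets, function(m) {
    eff <- dplyr::filter(effects, .data$mirna == m)
    k <- nrow(eff)
    n_parent <- dplyr::n_distinct(eff$parent_study_id)
    base <- tibble::tibble(mirna = m, k = k, n_parent_studies = n_parent)
    if (k < 3 || n_parent < 2) {
      return(dplyr::mutate(base, kendall_tau = NA_real_, p_begg = NA_real_,
                           begg_method = "not_testable", egger_intercept = NA_real_,
                           egger_z = NA_real_, p_egger = NA_real_, k0 = NA_integer_,
                           mu_adjusted = NA_real_, p_adjusted = NA_real_,
                           significant_after_correction = NA))
    }
    bg <- begg_test(eff)
    eg <- egger_test(eff)
    tf <- trim_and_fill(eff)
    dplyr::mutate(base,
      kendall_tau = bg$kendall_tau, p_begg = bg$p_begg, begg_method = bg$begg_method,
      egger_intercept = eg$egger_intercept, egger_z = eg$egger_z, p_egger = eg$p_egger,
      k0 = tf$k0, mu_adjusted = tf$mu_adjusted, p_adjusted = tf$p_adjusted,
      significant_after_correction = tf$p_adjusted < alpha
    )
  })
  structure(out, class = c("mir_bias", class(out)))
}

#' @export
tidy.mir_bias <- function(x, ...) tibble::as_tibble(x)
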