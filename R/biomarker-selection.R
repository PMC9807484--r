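#' Collect statistical and biological evidence per microRNA candidate
#'
#' Candidates are microRNAs that are (a) significant in at least one analysis
#' set *and* direction-consistent across every set in which they are
#' significant, and (b) present as measured perturbation inputs on the target
#' pathway, provided that pathway is itself significantly impacted
#' (`p_g_adj < alpha`). Blood detectability means significance in the blood
#' tissue subgroup or in at least one blood-fraction subgroup.
#' Post-bias-correction survival is recorded where bias tests were run and is
#' `NA` (untested) otherwise.
#'
#' @param sets List of `mir_analysis` objects (overall + subgroups +
#'   sensitivity).
#' @param consistency Output of [direction_consistency()] over the same sets.
#' @param impact A `mir_impact` result containing `target_pathway_id`.
#' @param bias A `mir_bias` report (may cover only a subset of microRNAs), or
#'   `NULL`.
#' @param target_pathway_id The disease pathway candidates must act on.
#' @param alpha Significance level for the pathway gate.
#' @return A `mir_profiles` tibble (one row per candidate) with an `excluded`
#'   attribute recording rejection reasons.
#' @export
collect_evidence <- function(sets, consistency, impact, bias = NULL,
                             target_pathway_id, alpha = 0.05) {
  stopifnot(length(sets) >= 1)
  imp <- tibble::as_tibble(impact)
  row <- dplyr::filter(imp, .data$pathway_id == target_pathway_id)
  if (nrow(row) != 1) {
    abort(paste0("target pathway absent from impact results: ", target_pathway_id))
  }
  pathway_significant <- row$p_g_adj < alpha
  pathway_inputs <- row$de_nodes[[1]]

  all_res <- purrr::map_dfr(sets, tidy)
  sig <- dplyr::filter(all_res, .data$significant)

  blood_labels <- c("subgroup:blood", "subgroup:serum", "subgroup:plasma",
                    "subgroup:pbmc", "subgroup:whole_blood")
  per_mirna <- sig |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(
      n_analyses_significant = dplyr::n(),
      min_p_adj = min(pmax(.data$p_adj_reml, .data$p_adj_eb)),
      max_abs_logOR = max(abs(.data$mu_reml)),
      blood_detectable = any(.data$label %in% blood_labels),
      .groups = "drop"
    ) |>
    dplyr::left_join(consistency, by = "mirna")

  bias_tab <- if (!is.null(bias) && nrow(bias)) {
    tibble::as_tibble(bias) |>
      dplyr::select("mirna", survives_bias_correction = "significant_after_correction")
  } else {
    tibble::tibble(mirna = character(), survives_bias_correction = logical())
  }
  per_mirna <- dplyr::left_join(per_mirna, bias_tab, by = "mirna") |>
    dplyr::mutate(on_target_pathway = .data$mirna %in% pathway_inputs)

  reasons <- dplyr::case_when(
    per_mirna$status == "inconsistent" ~ "direction inconsistent across analyses",
    !pathway_significant ~ "target pathway not significantly impacted",
    !per_mirna$on_target_pathway ~ "not biologically enriched on target pathway",
    !is.na(per_mirna$survives_bias_correction) & !per_mirna$survives_bias_correction ~
      "effect not significant after trim-and-fill correction",
    TRUE ~ NA_character_
  )
  excluded <- per_mirna |>
    dplyr::mutate(reason = reasons) |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("mirna", "reason")

  profiles <- per_mirna |>
    dplyr::filter(is.na(reasons)) |>
    dplyr::mutate(consistent_direction = sub("^consistent_", "", .data$status)) |>
    dplyr::select("mirna", "consistent_direction", "n_analyses_significant",
                  "min_p_adj", "max_abs_logOR", "blood_detectable",
                  "on_target_pathway", "survives_bias_correction")
  structure(profiles, class = c("mir_profiles", class(profiles)),
            excluded = excluded, target_pathway_id = target_pathway_id)
}

#' Priority-ranked biomarker list
#'
#' Ranks candidate profiles by the two-key priority — (1) detectable in blood
#' or a blood fraction (tier 1) before all others (tier 2); (2) number of
#' analyses in which the candidate was significant — made into a total order
#' with three documented tie-breaks: smaller minimum adjusted p first, larger
#' maximum absolute log odds ratio first, then name alphabetically.
#'
#' @param profiles A `mir_profiles` tibble from [collect_evidence()].
#' @return A `mir_ranking` tibble: `rank`, `mirna`, `tier`, plus the evidence
#'   columns. Empty input yields an empty ranking, not an error.
#' @export
select_and_rank <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  if (nrow(profiles) == 0) {
    out <- tibble::tibble(rank = integer(), mirna = character(), tier = integer())
    return(structure(out, class = c("mir_ranking", class(out))))
  }
  out <- profiles |>
    dplyr::mutate(tier = dplyr::if_else(.data$blood_detectable, 1L, 2L)) |>
    dplyr::arrange(.data$tier, dplyr::desc(.data$n_analyses_significant),
                   .data$min_p_adj, dplyr::desc(.data$max_abs_logOR), .data$mirna) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  structure(out, class = c("mir_ranking", class(out)))
}

#' @export
tidy.mir_ranking <- function(x, ...) tibble::as_tibble(x)

#' Write the biomarker ranking to TSV
#' @param ranking A `mir_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  readr::write_tsv(tibble::as_tibble(ranking), path, progress = FALSE)
  invisible(path)
}
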