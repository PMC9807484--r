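#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (typically read from YAML) with:
#' `paths` (`corpus`, `ledgers` (vector), `retractions`, `pathways`,
#' optional `alias_table`, `out_dir`), optional `meta` (arguments to
#' [meta_config()]), `subgroup_axes`, `sensitivity_thresholds`,
#' optional `bias_targets`, `impact` (`n_perm`, `seed`, `adjust`,
#' `top_pct`), and `selection` (`target_pathway_id`, `alpha`).
#'
#' @param config A list or a path to a YAML file.
#' @return The validated config list (class `mir_run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (p in c("corpus", "ledgers", "retractions", "pathways", "out_dir")) {
    if (is.null(config$paths[[p]])) {
      abort(paste0("config validation error: paths$", p, " is required"))
    }
  }
  if (is.null(config$impact$seed)) {
    abort("config validation error: impact$seed is mandatory (stochastic stage enabled)")
  }
  if (is.null(config$selection$target_pathway_id)) {
    abort("config validation error: selection$target_pathway_id is required")
  }
  config$meta <- config$meta %||% list()
  config$subgroup_axes <- config$subgroup_axes %||% c("tissue", "blood_fraction", "platform")
  config$sensitivity_thresholds <- config$sensitivity_thresholds %||% c(25, 50)
  config$impact$n_perm <- config$impact$n_perm %||% 2000
  config$impact$adjust <- config$impact$adjust %||% "BH"
  config$impact$top_pct <- config$impact$top_pct %||% 1.4
  config$selection$alpha <- config$selection$alpha %||% 0.05
  structure(config, class = c("mir_run_config", "list"))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage `", stage, "` failed: ", conditionMessage(e)))
  })
}

#' Run the full evidence-synthesis pipeline
#'
#' Executes corpus reading, overall meta-analysis, subgroup and sensitivity
#' analyses, direction-consistency mapping, publication-bias reporting,
#' interaction-evidence filtering, pathway augmentation, impact analysis and
#' biomarker selection, in that order. Any stage failure halts the run with
#' the failing stage named. The returned bundle carries a manifest recording
#' the configuration hash, seed, content hashes of every input file and
#' per-stage record counts, so a rerun with the same config and inputs is
#' bit-reproducible.
#'
#' @param config A [run_config()] list or YAML path.
#' @return A `mir_bundle` list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  paths <- config$paths

  alias <- if (!is.null(paths$alias_table)) {
    readr::read_tsv(paths$alias_table,
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else NULL

  corpus <- with_stage("corpus", read_corpus(paths$corpus, alias_table = alias))
  cfg <- do.call(meta_config, config$meta)

  overall <- with_stage("meta", run_meta(corpus, cfg, label = "overall"))
  subgroups <- with_stage("subgroups", {
    purrr::map(config$subgroup_axes, ~ run_subgroups(corpus, cfg, axis = .x)) |>
      setNames(config$subgroup_axes)
  })
  sensitivity <- with_stage("sensitivity",
                            run_sensitivity(corpus, cfg, config$sensitivity_thresholds))
  all_sets <- c(list(overall = overall),
                purrr::flatten(purrr::map(subgroups, "sets")),
                sensitivity$sets)
  consistency <- with_stage("consistency", direction_consistency(all_sets))
  bias <- with_stage("bias",
                     bias_summary(overall, corpus, targets = config$bias_targets))

  robust <- with_stage("interaction_filter", {
    ledgers <- purrr::map(paths$ledgers, read_interactions)
    retracted <- readr::read_lines(paths$retractions, progress = FALSE)
    retracted <- retracted[nzchar(retracted)]
    merged <- merge_sources(purrr::map(ledgers, prediction_top_filter,
                                       top_pct = config$impact$top_pct),
                            alias_table = alias)
    filter_robust(apply_retractions(merged, retracted))
  })

  impact <- with_stage("impact", {
    pathways <- read_pathways(paths$pathways)
    augs <- purrr::map(pathways, augment_pathway, robust = robust)
    impact_analysis(augs, perturbation_input(all_sets, consistency),
                    n_perm = config$impact$n_perm,
                    seed = config$impact$seed,
                    adjust = config$impact$adjust)
  })

  selection <- with_stage("selection", {
    profiles <- collect_evidence(all_sets, consistency, impact, bias,
                                 target_pathway_id = config$selection$target_pathway_id,
                                 alpha = config$selection$alpha)
    list(profiles = profiles, ranking = select_and_rank(profiles))
  })

  input_files <- c(paths$corpus, paths$ledgers, paths$retractions,
                   paths$pathways, paths$alias_table)
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$impact$seed,
    inputs = as.list(tools::md5sum(input_files)),
    stage_counts = list(
      substudies = nrow(corpus$records),
      mirnas_analysed = nrow(overall),
      mirnas_significant = sum(overall$significant),
      analysis_sets = length(all_sets),
      bias_targets = nrow(bias),
      robust_pairs = nrow(robust$pairs),
      pathways = nrow(impact),
      pathways_enriched = sum(impact$p_g_adj < config$selection$alpha),
      candidates = nrow(selection$profiles),
      ranked = nrow(selection$ranking)
    )
  )

  structure(
    list(config = config, corpus = corpus, overall = overall,
         subgroups = subgroups, sensitivity = sensitivity,
         consistency = consistency, bias = bias, robust = robust,
         impact = impact, profiles = selection$profiles,
         ranking = selection$ranking, manifest = manifest),
    class = "mir_bundle"
  )
}

#' Write the report bundle to stable file names
#'
#' Writes one TSV per analysis set (`meta_<label>.tsv`, with the presentation
#' convention |logOR| plus a direction column), the consistency map, the
#' bias report, the robust interaction set, the impact table with per-node
#' perturbation factors, the biomarker ranking, a machine-readable
#' `manifest.json` and a `summary.json` of headline counts. An existing
#' manifest blocks overwriting unless `force = TRUE`.
#'
#' @param bundle A `mir_bundle` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @param force Overwrite an existing report set.
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(bundle, out_dir = bundle$config$paths$out_dir,
                          force = FALSE) {
  stopifnot(inherits(bundle, "mir_bundle"))
  if (file.exists(file.path(out_dir, "manifest.json")) && !force) {
    abort(paste0("reports already exist in ", out_dir, "; use force = TRUE to overwrite"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(name) {
    files <<- c(files, file.path(out_dir, name))
    file.path(out_dir, name)
  }

  all_sets <- c(list(overall = bundle$overall),
                purrr::flatten(purrr::map(bundle$subgroups, "sets")),
                bundle$sensitivity$sets)
  for (s in all_sets) {
    label <- gsub("[^a-z0-9]+", "_", tolower(attr(s, "label")))
    readr::write_tsv(meta_report_table(s), put(paste0("meta_", label, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(bundle$consistency, put("direction_consistency.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(bundle$bias), put("bias_report.tsv"), progress = FALSE)
  write_robust_set(bundle$robust, put("robust_interactions.tsv"))
  readr::write_tsv(tidy(bundle$impact), put("impact.tsv"), progress = FALSE)
  readr::write_tsv(node_perturbations(bundle$impact), put("node_perturbations.tsv"),
                   progress = FALSE)
  write_ranking(bundle$ranking, put("ranking.tsv"))

  jsonlite::write_json(bundle$manifest, put("manifest.json"), auto_unbox = TRUE)
  summary <- list(
    n_significant = bundle$manifest$stage_counts$mirnas_significant,
    k0_per_tested_mirna = setNames(as.list(bundle$bias$k0), bundle$bias$mirna),
    n_enriched_pathways = bundle$manifest$stage_counts$pathways_enriched,
    ranking = bundle$ranking$mirna
  )
  jsonlite::write_json(summary, put("summary.json"), auto_unbox = TRUE, null = "list")
  invisible(files)
}

# presentation layer: absolute pooled logORs plus an explicit direction column
meta_report_table <- function(analysis) {
  tibble::as_tibble(analysis) |>
    dplyr::transmute(
      .data$mirna, .data$k,
      abs_logOR_reml = abs(.data$mu_reml),
      ci_low = .data$ci_low, ci_high = .data$ci_high,
      p_raw_reml = .data$p_raw_reml, p_adj_reml = .data$p_adj_reml,
      abs_logOR_eb = abs(.data$mu_eb), p_adj_eb = .data$p_adj_eb,
      tau2_reml = .data$tau2_reml, tau2_eb = .data$tau2_eb,
      direction = .data$direction, significant = .data$significant
    )
}

#' @export
print.mir_bundle <- function(x, ...) {
  cat("<mir_bundle>\n")
  str(x$manifest$stage_counts, give.head = FALSE)
  invisible(x)
}

#' Simulate inputs, write them to disk, and return a ready-to-run config
#'
#' Convenience wrapper used by the examples and the end-to-end tests:
#' generates a corpus, interaction ledgers, retraction list and pathway
#' graphs from one [simulation_config()], writes them in the documented TSV
#' dialects under `dir`, and returns a validated [run_config()] pointing at
#' them.
#'
#' @param cfg A [simulation_config()].
#' @param dir Directory for the generated inputs and reports.
#' @param n_perm Permutations for the impact stage (default 500).
#' @return A list: `config` (a `mir_run_config`) and `truth` (`mir_truth`).
#' @export
simulate_run_inputs <- function(cfg, dir, n_perm = 500) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_corpus(cfg)
  db <- simulate_interaction_db(cfg, sim$truth)
  pws <- simulate_pathways(cfg, sim$truth)

  corpus_path <- file.path(dir, "corpus.tsv")
  write_corpus(sim$corpus, corpus_path)
  ledger_path <- file.path(dir, "interactions.tsv")
  write_interactions(db$ledger, ledger_path)
  retract_path <- file.path(dir, "retracted.txt")
  readr::write_lines(db$retracted, retract_path)
  pathway_path <- file.path(dir, "pathways.tsv")
  write_pathways(pws, pathway_path)

  config <- run_config(list(
    paths = list(corpus = corpus_path, ledgers = ledger_path,
                 retractions = retract_path, pathways = pathway_path,
                 out_dir = file.path(dir, "reports")),
    impact = list(n_perm = n_perm, seed = derive_seed(cfg$seed, 4L)),
    selection = list(target_pathway_id = sim$truth$planted_pathway_id)
  ))
  list(config = config, truth = sim$truth)
}
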