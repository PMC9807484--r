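#' Configuration for the synthetic evidence-corpus generator
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes: per-microRNA binomial dysregulation events in case and control
#' arms, log-normally distributed sample sizes, between-substudy
#' heterogeneity on the log-odds scale, tissue/blood-fraction/platform
#' strata, optional selective-reporting censoring of small null effects (to
#' induce funnel asymmetry), and interaction ledgers with a retracted subset.
#'
#' @param n_mirnas Number of microRNAs in the corpus (default 50).
#' @param n_studies Number of parent studies (default 40).
#' @param substudies_per_study Named probability vector over cohort counts
#'   per study (default 80% one cohort, 20% two).
#' @param sample_size List `median`, `sigma` of the log-normal combined
#'   sample size per cohort, truncated to `[10, 500]` (default median 60,
#'   sigma 0.5).
#' @param baseline_event_prob Control-arm dysregulation-event probability
#'   (default 0.15).
#' @param effect_mirnas Number of microRNAs with a planted effect (default 5).
#' @param effect_logOR Magnitude of the planted log odds ratio (default 2.0);
#'   planted directions alternate up/down.
#' @param tau_between Between-substudy SD of the per-substudy log odds ratio
#'   (default 0.3).
#' @param report_prob Probability that a given cohort reports a given
#'   microRNA (default 0.15, giving a mean of roughly 6-8 substudies per
#'   microRNA at the defaults).
#' @param tissue_mix,fraction_mix,platform_mix Named probability vectors for
#'   the strata (defaults emulate a blood-dominated corpus).
#' @param censor_rule `"none"` or `"suppress_small_null"`.
#' @param censor_threshold,censor_prob Under `suppress_small_null`, a
#'   null-microRNA substudy whose observed |logOR| falls below the threshold
#'   is dropped with this probability.
#' @param retracted_fraction Fraction of all ledger PMIDs marked retracted
#'   (default 0.05).
#' @param targets_per_mirna Planted target genes per effect microRNA
#'   (default 3).
#' @param n_null_pathways Matched decoy pathways (default 5).
#' @param seed Mandatory master seed; each artefact (corpus, ledger,
#'   pathways) derives its own stream from it.
#' @return A validated `mir_sim_config` list.
#' @export
simulation_config <- function(n_mirnas = 50, n_studies = 40,
                              substudies_per_study = c("1" = 0.8, "2" = 0.2),
                              sample_size = list(median = 60, sigma = 0.5),
                              baseline_event_prob = 0.15,
                              effect_mirnas = 5, effect_logOR = 2.0,
                              tau_between = 0.3, report_prob = 0.15,
                              tissue_mix = c(blood = 0.75, muscle = 0.05,
                                             pancreatic = 0.04, adipose = 0.05,
                                             vessel = 0.03, heart = 0.03,
                                             kidney = 0.02, other = 0.03),
                              fraction_mix = c(serum = 0.33, plasma = 0.35,
                                               pbmc = 0.12, whole_blood = 0.20),
                              platform_mix = c(pcr = 0.94, seq = 0.04,
                                               array = 0.01, nanostring = 0.01),
                              censor_rule = c("none", "suppress_small_null"),
                              censor_threshold = 0.5, censor_prob = 0.8,
                              retracted_fraction = 0.05,
                              targets_per_mirna = 3, n_null_pathways = 5,
                              seed) {
  censor_rule <- match.arg(censor_rule)
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory for simulation")
  stopifnot(
    effect_mirnas <= n_mirnas,
    baseline_event_prob > 0, baseline_event_prob < 1,
    abs(sum(tissue_mix) - 1) < 1e-8, abs(sum(fraction_mix) - 1) < 1e-8,
    abs(sum(platform_mix) - 1) < 1e-8,
    abs(sum(substudies_per_study) - 1) < 1e-8,
    retracted_fraction >= 0, retracted_fraction <= 1, tau_between >= 0
  )
  structure(
    list(n_mirnas = n_mirnas, n_studies = n_studies,
         substudies_per_study = substudies_per_study, sample_size = sample_size,
         baseline_event_prob = baseline_event_prob, effect_mirnas = effect_mirnas,
         effect_logOR = effect_logOR, tau_between = tau_between,
         report_prob = report_prob, tissue_mix = tissue_mix,
         fraction_mix = fraction_mix, platform_mix = platform_mix,
         censor_rule = censor_rule, censor_threshold = censor_threshold,
         censor_prob = censor_prob, retracted_fraction = retracted_fraction,
         targets_per_mirna = targets_per_mirna, n_null_pathways = n_null_pathways,
         seed = as.integer(seed)),
    class = "mir_sim_config"
  )
}

sim_mirna_names <- function(n) {
  arm <- rep(c("-5p", "-3p"), length.out = n)
  paste0("miR-", 100 + seq_len(n), arm)
}

sample_mix <- function(n, mix) sample(names(mix), n, replace = TRUE, prob = mix)

#' Simulate a substudy corpus with planted ground truth
#'
#' Effects are planted on the logit scale: control events are
#' `Binomial(n_ctrl, p0)` and case events `Binomial(n_case, p1)` with
#' `logit(p1) = logit(p0) + delta`, where `delta` is drawn per substudy from
#' `Normal(true_logOR, tau_between^2)` (mean zero for null microRNAs), so
#' the 2x2 log odds ratio estimand approximately equals the planted value.
#' Tissue and platform are sampled per study, cohort sample sizes from the
#' truncated log-normal, and each cohort reports each microRNA independently
#' with `report_prob`. Under `censor_rule = "suppress_small_null"`,
#' null-microRNA substudies with small observed |logOR| are dropped with the
#' configured probability, inducing funnel asymmetry.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `corpus` (a `mir_corpus`) and `truth` (a `mir_truth`
#'   list: `effect_set`, `true_logOR`, `true_direction`,
#'   `planted_pathway_id`, `planted_targets`).
#' @export
simulate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "mir_sim_config"))
  set.seed(derive_seed(cfg$seed, 1L))

  mirnas <- sim_mirna_names(cfg$n_mirnas)
  effect_set <- head(mirnas, cfg$effect_mirnas)
  sgn <- rep(c(1, -1), length.out = cfg$effect_mirnas)
  true_logor <- setNames(rep(0, cfg$n_mirnas), mirnas)
  true_logor[effect_set] <- sgn * cfg$effect_logOR

  fraction_label <- c(serum = "serum", plasma = "plasma", pbmc = "PBMC",
                      whole_blood = "whole blood")
  tissue_label <- c(blood = NA, muscle = "skeletal muscle",
                    pancreatic = "pancreatic islets", adipose = "adipose tissue",
                    vessel = "blood vessel", heart = "heart", kidney = "kidney",
                    other = "gingival crevicular fluid")

  p0 <- cfg$baseline_event_prob
  rows <- list()
  for (s in seq_len(cfg$n_studies)) {
    study_id <- sprintf("S%03d", s)
    tissue <- sample_mix(1, cfg$tissue_mix)
    fraction <- if (tissue == "blood") sample_mix(1, cfg$fraction_mix) else "none"
    tissue_raw <- if (tissue == "blood") fraction_label[[fraction]] else tissue_label[[tissue]]
    platform <- sample_mix(1, cfg$platform_mix)
    n_cohorts <- as.integer(sample(names(cfg$substudies_per_study), 1,
                                   prob = cfg$substudies_per_study))
    for (co in seq_len(n_cohorts)) {
      n_total <- round(min(500, max(10, rlnorm(1, log(cfg$sample_size$median),
                                               cfg$sample_size$sigma))))
      n_case <- max(1L, min(n_total - 1L, as.integer(round(n_total * runif(1, 0.4, 0.6)))))
      n_ctrl <- as.integer(n_total) - n_case
      reported <- mirnas[runif(cfg$n_mirnas) < cfg$report_prob]
      if (!length(reported)) next
      delta <- rnorm(length(reported), true_logor[reported], cfg$tau_between)
      p1 <- plogis(qlogis(p0) + delta)
      ev_case <- rbinom(length(reported), n_case, p1)
      ev_ctrl <- rbinom(length(reported), n_ctrl, p0)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        substudy_id = paste0(study_id, ".c", co, ".", reported),
        parent_study_id = study_id,
        mirna = reported,
        tissue = tissue_raw,
        blood_fraction = fraction,
        platform = platform,
        n_case = n_case, n_ctrl = n_ctrl,
        events_case = ev_case, events_ctrl = ev_ctrl
      )
    }
  }
  records <- dplyr::bind_rows(rows)

  eff <- effect_from_counts(dplyr::mutate(records, reported_direction = "up"))
  records$reported_direction <- dplyr::if_else(eff$y >= 0, "up", "down")

  if (cfg$censor_rule == "suppress_small_null") {
    is_null <- !(records$mirna %in% effect_set)
    small <- abs(eff$y) < cfg$censor_threshold
    drop <- is_null & small & runif(nrow(records)) < cfg$censor_prob
    records <- records[!drop, , drop = FALSE]
  }

  planted_targets <- purrr::map(
    seq_len(cfg$effect_mirnas),
    ~ sprintf("G%03d", (.x - 1) * cfg$targets_per_mirna + seq_len(cfg$targets_per_mirna))
  )
  names(planted_targets) <- effect_set

  truth <- structure(
    list(effect_set = effect_set,
         true_logOR = true_logor,
         true_direction = ifelse(true_logor >= 0, "up", "down")[effect_set],
         planted_pathway_id = "pw_disease",
         planted_targets = planted_targets,
         mirnas = mirnas),
    class = "mir_truth"
  )
  list(corpus = mir_corpus(records, provenance = paste0("simulated(seed=", cfg$seed, ")")),
       truth = truth)
}

#' Simulate microRNA-target interaction ledgers with a retracted subset
#'
#' Planted pairs (effect microRNA x its planted target genes) receive three
#' experimental PMIDs spread over two experimental databases plus a predicted
#' record well inside the top-percentile cut, so they survive the robustness
#' filter unless retraction sampling removes two of their three articles.
#' Decoy pairs (null microRNAs x decoy genes) are generated in four flavours:
#' fully qualifying, single-PMID, experimental-only, and prediction-only.
#' A `retracted_fraction` of all PMIDs is then marked retracted.
#'
#' @param cfg A [simulation_config()].
#' @param truth The `mir_truth` from [simulate_corpus()].
#' @return A list: `ledger` (interaction records tibble), `retracted`
#'   (character vector of retracted PMIDs), `decoy_robust` (tibble of decoy
#'   pairs constructed to qualify, before retraction).
#' @export
simulate_interaction_db <- function(cfg, truth) {
  stopifnot(inherits(cfg, "mir_sim_config"), inherits(truth, "mir_truth"))
  set.seed(derive_seed(cfg$seed, 2L))

  pmid_counter <- 0L
  next_pmids <- function(n) {
    pmid_counter <<- pmid_counter + n
    as.character(20000000L + seq.int(pmid_counter - n + 1L, pmid_counter))
  }

  planted <- purrr::imap_dfr(truth$planted_targets, function(genes, m) {
    purrr::map_dfr(genes, function(g) {
      pm <- next_pmids(3L)
      tibble::tibble(
        mirna = m, gene = g,
        source_type = c("experimental", "experimental", "predicted"),
        database = c("expdb_a", "expdb_b", "preddb"),
        pmids = list(pm[1:2], pm[3], character()),
        prediction_rank_pct = c(NA, NA, runif(1, 0.05, 1.0))
      )
    })
  })

  # decoys draw from the full microRNA pool (so null pathways can still pick
  # up the odd measured input), but never reuse a planted target gene
  n_decoys <- max(8L, 2L * cfg$n_mirnas)
  decoy_genes <- sprintf("D%03d", seq_len(max(20L, n_decoys)))
  flavours <- rep(c("qualifying", "one_pmid", "no_prediction", "prediction_only"),
                  length.out = n_decoys)
  decoys <- purrr::map_dfr(seq_len(n_decoys), function(i) {
    m <- sample(truth$mirnas, 1)
    g <- decoy_genes[i]
    switch(flavours[i],
      qualifying = tibble::tibble(
        mirna = m, gene = g,
        source_type = c("experimental", "predicted"),
        database = c("expdb_a", "preddb"),
        pmids = list(next_pmids(2L), character()),
        prediction_rank_pct = c(NA, runif(1, 0.05, 1.3))
      ),
      one_pmid = tibble::tibble(
        mirna = m, gene = g,
        source_type = c("experimental", "predicted"),
        database = c("expdb_b", "preddb"),
        pmids = list(next_pmids(1L), character()),
        prediction_rank_pct = c(NA, runif(1, 0.05, 1.3))
      ),
      no_prediction = tibble::tibble(
        mirna = m, gene = g,
        source_type = "experimental",
        database = "expdb_a",
        pmids = list(next_pmids(3L)),
        prediction_rank_pct = NA_real_
      ),
      prediction_only = tibble::tibble(
        mirna = m, gene = g,
        source_type = "predicted",
        database = "preddb",
        pmids = list(character()),
        prediction_rank_pct = runif(1, 0.05, 1.3)
      )
    )
  })

  ledger <- dplyr::bind_rows(planted, decoys)
  all_pmids <- sort(unique(unlist(ledger$pmids)))
  n_retract <- round(cfg$retracted_fraction * length(all_pmids))
  retracted <- if (n_retract > 0) sample(all_pmids, n_retract) else character()

  list(ledger = ledger, retracted = retracted,
       decoy_robust = dplyr::distinct(
         decoys[flavours[match(decoys$gene, decoy_genes)] == "qualifying", c("mirna", "gene")]
       ))
}

random_dag_edges <- function(nodes, extra_prob = 0.15, pos_prob = 0.7) {
  # connected DAG: chain backbone in a random topological order + extras
  n <- length(nodes)
  ord <- sample(nodes)
  edges <- tibble::tibble(src = ord[-n], dst = ord[-1])
  for (i in seq_len(n - 2)) {
    js <- which(runif(n - i - 1) < extra_prob)
    if (length(js)) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(src = ord[i], dst = ord[i + 1 + js]))
    }
  }
  edges <- dplyr::distinct(edges, .data$src, .data$dst)
  edges$beta <- ifelse(runif(nrow(edges)) < pos_prob, 1, -1)
  edges$relation <- ifelse(edges$beta > 0, "activation", "inhibition")
  edges
}

#' Simulate signed directed pathway graphs
#'
#' The planted disease pathway is a connected DAG over all planted target
#' genes plus filler genes, wired with mixed activation/inhibition edges.
#' Matched null pathways have the same node count and edge-generation
#' profile but contain no planted target.
#'
#' @param cfg A [simulation_config()].
#' @param truth The `mir_truth` from [simulate_corpus()].
#' @return A named list of `mir_pathway` graphs; the planted one is named
#'   `truth$planted_pathway_id`.
#' @export
simulate_pathways <- function(cfg, truth) {
  stopifnot(inherits(cfg, "mir_sim_config"), inherits(truth, "mir_truth"))
  set.seed(derive_seed(cfg$seed, 3L))

  planted_genes <- unique(unlist(truth$planted_targets))
  n_nodes <- max(length(planted_genes) + 8L, 20L)
  filler <- sprintf("F%03d", seq_len(n_nodes - length(planted_genes)))
  planted <- pathway_graph(truth$planted_pathway_id, "planted disease pathway",
                           random_dag_edges(c(planted_genes, filler)))

  # null pathways share the decoy gene namespace (D###) so decoy interactions
  # can attach to them, but never contain a planted target
  decoy_pool <- sprintf("D%03d", seq_len(max(20L, 2L * cfg$n_mirnas)))
  nulls <- purrr::map(seq_len(cfg$n_null_pathways), function(i) {
    n_decoy_nodes <- min(10L, length(decoy_pool))
    nodes <- c(sample(decoy_pool, n_decoy_nodes),
               sprintf("F%d_%03d", i, seq_len(n_nodes - n_decoy_nodes)))
    pathway_graph(sprintf("pw_null_%02d", i), sprintf("null pathway %d", i),
                  random_dag_edges(nodes))
  })
  out <- c(list(planted), nulls)
  setNames(out, purrr::map_chr(out, "pathway_id"))
}
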