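#' Read a microRNA-target interaction ledger
#'
#' Ledger TSV columns: `mirna`, `gene`, `source_type`
#' (`experimental`/`predicted`), `database`, `pmids` (semicolon-separated,
#' may be empty for predicted records), `prediction_rank_pct` (percentile
#' rank in (0, 100], set for predicted records). Internally `pmids` is a
#' list-column of character vectors.
#'
#' @param path Path to a TSV file.
#' @return An interaction ledger tibble.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) abort(paste0("ledger file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(
    mirna = readr::col_character(), gene = readr::col_character(),
    source_type = readr::col_character(), database = readr::col_character(),
    pmids = readr::col_character(), prediction_rank_pct = readr::col_double()
  ), progress = FALSE)
  raw |>
    dplyr::mutate(pmids = purrr::map(.data$pmids, split_pmids)) |>
    validate_ledger()
}

split_pmids <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

validate_ledger <- function(ledger) {
  ledger <- tibble::as_tibble(ledger)
  need <- c("mirna", "gene", "source_type", "database", "pmids", "prediction_rank_pct")
  missing <- setdiff(need, names(ledger))
  if (length(missing)) {
    abort(paste0("ledger schema error: missing column(s) ", paste(missing, collapse = ", ")))
  }
  if (!all(ledger$source_type %in% c("experimental", "predicted"))) {
    abort("source_type must be experimental or predicted")
  }
  n_pm <- purrr::map_int(ledger$pmids, length)
  if (any(ledger$source_type == "experimental" & n_pm == 0)) {
    abort("experimental records must carry at least one PMID")
  }
  if (any(ledger$source_type == "predicted" & is.na(ledger$prediction_rank_pct))) {
    abort("predicted records must carry prediction_rank_pct")
  }
  ledger
}

#' Write an interaction ledger to TSV
#' @param ledger An interaction ledger tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(ledger, path) {
  out <- ledger |>
    dplyr::mutate(pmids = purrr::map_chr(.data$pmids, paste, collapse = ";"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Merge interaction ledgers with name canonicalisation
#'
#' Binds the ledgers, canonicalises microRNA names (so alias spellings of the
#' same mature microRNA collapse), and unions PMIDs and database names over
#' records sharing `(mirna, gene, source_type)`. For predicted records the
#' best (smallest) prediction rank percentile is retained.
#'
#' @param ledgers A list of ledger tibbles (or a single tibble).
#' @param alias_table Alias table forwarded to [normalize_mirna_name()].
#' @return A merged ledger tibble with columns `mirna`, `gene`,
#'   `source_type`, `databases` (list), `pmids` (list),
#'   `prediction_rank_pct`; attribute `n_collapsed` counts collapsed
#'   duplicate records.
#' @export
merge_sources <- function(ledgers, alias_table = NULL) {
  if (is.data.frame(ledgers)) ledgers <- list(ledgers)
  merged <- purrr::map_dfr(ledgers, validate_ledger)
  nm <- normalize_mirna_name(merged$mirna, alias_table)
  merged$mirna <- dplyr::coalesce(nm$canonical, merged$mirna)
  out <- merged |>
    dplyr::group_by(.data$mirna, .data$gene, .data$source_type) |>
    dplyr::summarise(
      databases = list(sort(unique(unlist(.data$database)))),
      pmids = list(sort(unique(unlist(.data$pmids)))),
      prediction_rank_pct = if (all(is.na(.data$prediction_rank_pct))) NA_real_
                            else min(.data$prediction_rank_pct, na.rm = TRUE),
      .groups = "drop"
    )
  attr(out, "n_collapsed") <- nrow(merged) - nrow(out)
  out
}

#' Remove retracted evidence from a ledger
#'
#' Retracted PMIDs are removed from every record's support *before* any
#' support counting, so a pair with three supporting articles that loses one
#' retraction can still qualify later. Experimental records left with no
#' PMIDs are dropped. Removals are recorded in the `removals` attribute.
#'
#' @param ledger A merged ledger (from [merge_sources()]).
#' @param retracted_pmids Character (or coercible) vector of retracted PMIDs.
#' @return The filtered ledger.
#' @export
apply_retractions <- function(ledger, retracted_pmids) {
  retracted <- as.character(retracted_pmids)
  before <- purrr::map_int(ledger$pmids, length)
  out <- ledger |>
    dplyr::mutate(pmids = purrr::map(.data$pmids, ~ setdiff(.x, retracted)))
  after <- purrr::map_int(out$pmids, length)
  removals <- tibble::tibble(
    mirna = ledger$mirna, gene = ledger$gene, source_type = ledger$source_type,
    n_removed = before - after
  ) |> dplyr::filter(.data$n_removed > 0)
  dropped <- out$source_type == "experimental" & after == 0
  out <- out[!dropped, , drop = FALSE]
  attr(out, "removals") <- removals
  attr(out, "n_dropped_records") <- sum(dropped)
  out
}

#' Keep only the top-ranked predicted interactions
#'
#' Retains predicted records whose rank percentile is at or below `top_pct`
#' (inclusive boundary: "top 1.4%" names a quantile cut that includes its
#' boundary). Experimental records pass through untouched.
#'
#' @param ledger An interaction ledger.
#' @param top_pct Percentile threshold (default 1.4).
#' @return The filtered ledger.
#' @export
prediction_top_filter <- function(ledger, top_pct = 1.4) {
  dplyr::filter(
    ledger,
    .data$source_type != "predicted" | .data$prediction_rank_pct <= top_pct
  )
}

#' Robustness filter for microRNA-target interactions
#'
#' A pair `(mirna, gene)` is robust when (a) the union of its experimental
#' PMIDs, after retraction removal, has at least `min_pmids` distinct
#' members, and (b) the pair is also supported by a bioinformatic prediction
#' record — two types of database. Stage counts are recorded so the filter's
#' accounting is auditable and monotone.
#'
#' @param ledger A merged, retraction-cleaned ledger.
#' @param min_pmids Minimum distinct experimental PMIDs (default 2).
#' @return A `mir_robust` object: `pairs` tibble (`mirna`, `gene`,
#'   `n_pmids`, `pmids`, `databases`), and `filter_stats` (stage, n_pairs).
#' @export
filter_robust <- function(ledger, min_pmids = 2) {
  exp_support <- ledger |>
    dplyr::filter(.data$source_type == "experimental") |>
    dplyr::group_by(.data$mirna, .data$gene) |>
    dplyr::summarise(
      pmids = list(sort(unique(unlist(.data$pmids)))),
      databases = list(sort(unique(unlist(.data$databases)))),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_pmids = purrr::map_int(.data$pmids, length))
  predicted <- ledger |>
    dplyr::filter(.data$source_type == "predicted") |>
    dplyr::distinct(.data$mirna, .data$gene)

  all_pairs <- dplyr::distinct(ledger, .data$mirna, .data$gene)
  enough <- dplyr::filter(exp_support, .data$n_pmids >= min_pmids)
  robust <- dplyr::semi_join(enough, predicted, by = c("mirna", "gene")) |>
    dplyr::arrange(.data$mirna, .data$gene) |>
    dplyr::select("mirna", "gene", "n_pmids", "pmids", "databases")

  structure(
    list(
      pairs = robust,
      filter_stats = tibble::tibble(
        stage = c("distinct_pairs", paste0("experimental_pmids>=", min_pmids),
                  "plus_prediction"),
        n_pairs = c(nrow(all_pairs), nrow(enough), nrow(robust))
      )
    ),
    class = "mir_robust"
  )
}

#' @export
print.mir_robust <- function(x, ...) {
  cat("<mir_robust> ", nrow(x$pairs), " robust pairs\n", sep = "")
  print(x$filter_stats)
  invisible(x)
}

#' @export
tidy.mir_robust <- function(x, ...) x$pairs

#' @export
glance.mir_robust <- function(x, ...) {
  tidyr::pivot_wider(x$filter_stats, names_from = "stage", values_from = "n_pairs")
}

#' Write a robust interaction set with provenance
#' @param robust A `mir_robust` object.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_robust_set <- function(robust, path) {
  out <- robust$pairs |>
    dplyr::mutate(
      pmids = purrr::map_chr(.data$pmids, paste, collapse = ";"),
      databases = purrr::map_chr(.data$databases, paste, collapse = ";")
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
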