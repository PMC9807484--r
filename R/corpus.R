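#' Canonicalise microRNA labels
#'
#' Expression-profiling studies spell microRNA names inconsistently
#' ("hsa-miR-126", "MiR-30c-5p", "microRNA-21"). This function maps raw labels
#' to one canonical spelling (`miR-` / `let-7` prefix, lower-case body) so that
#' substudies of the same microRNA pool together. An optional alias table is
#' consulted *after* prefix normalisation, which is how family names without an
#' arm suffix ("miR-126") are resolved to a canonical mature form
#' ("miR-126-3p").
#'
#' Canonicalisation is idempotent: normalising a canonical name returns it
#' unchanged with `resolved_via = "exact"` (provided alias targets are not
#' themselves alias keys). Labels that match neither the `miR`/`microRNA` nor
#' the historical `let-7` pattern and have no alias entry are flagged
#' `unresolved`, never dropped.
#'
#' @param raw Character vector of raw labels (non-empty strings).
#' @param alias_table Either `NULL`, a named character vector
#'   (`raw -> canonical`), or a two-column data frame with columns
#'   `raw`, `canonical`.
#'
#' @return A tibble with one row per input: `raw_label`, `canonical`
#'   (`NA` when unresolved), and `resolved_via`
#'   (`exact`, `alias_table`, `prefix_rule` or `unresolved`).
#' @export
#' @examples
#' normalize_mirna_name(c("MiR-30c-5p", "hsa-miR-126", "let-7a", "SNORD44"),
#'   alias_table = c("miR-126" = "miR-126-3p")
#' )
normalize_mirna_name <- function(raw, alias_table = NULL) {
  stopifnot(is.character(raw))
  if (any(is.na(raw) | !nzchar(trimws(raw)))) {
    abort("raw microRNA labels must be non-empty strings")
  }
  alias <- as_alias_vector(alias_table)

  x <- stringr::str_trim(raw)
  core <- stringr::str_remove(x, stringr::regex("^hsa-", ignore_case = TRUE))
  is_mir <- stringr::str_detect(
    core, stringr::regex("^(microrna|mir)-?\\d", ignore_case = TRUE)
  )
  is_let <- stringr::str_detect(
    core, stringr::regex("^let-?7", ignore_case = TRUE)
  )

  canonical <- rep(NA_character_, length(x))
  body <- stringr::str_remove(
    core, stringr::regex("^(microrna|mir)-?", ignore_case = TRUE)
  )
  canonical[is_mir] <- paste0("miR-", tolower(body[is_mir]))
  let_body <- stringr::str_remove(
    core, stringr::regex("^let-?7", ignore_case = TRUE)
  )
  canonical[is_let & !is_mir] <- paste0("let-7", tolower(let_body[is_let & !is_mir]))

  resolved_via <- dplyr::case_when(
    is.na(canonical) ~ "unresolved",
    canonical == x ~ "exact",
    TRUE ~ "prefix_rule"
  )

  if (length(alias)) {
    key <- dplyr::coalesce(canonical, x)
    hit <- key %in% names(alias)
    canonical[hit] <- unname(alias[key[hit]])
    resolved_via[hit] <- "alias_table"
  }

  tibble::tibble(raw_label = raw, canonical = canonical, resolved_via = resolved_via)
}

as_alias_vector <- function(alias_table) {
  if (is.null(alias_table)) {
    return(character())
  }
  if (is.data.frame(alias_table)) {
    if (!all(c("raw", "canonical") %in% names(alias_table))) {
      abort("alias table data frame needs columns `raw` and `canonical`")
    }
    return(setNames(as.character(alias_table$canonical), alias_table$raw))
  }
  if (is.character(alias_table) && !is.null(names(alias_table))) {
    return(alias_table)
  }
  abort("alias_table must be NULL, a named character vector, or a raw/canonical data frame")
}

#' Default microRNA alias table
#'
#' A small curated table shipped with the package (tab-separated, columns
#' `raw`, `canonical`) mapping common arm-less family labels and known
#' typographical variants to canonical mature names. It is deliberately
#' minimal and editable; it does not attempt full registry-scale alias
#' resolution.
#'
#' @return A tibble with columns `raw` and `canonical`.
#' @export
default_alias_table <- function() {
  path <- system.file("extdata", "alias_default.tsv", package = "metamirna")
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Classify tissue labels into analysis strata
#'
#' Free-text tissue labels are mapped to the tissue classes used in subgroup
#' analysis. All circulating sources (serum, plasma, PBMCs, whole blood) are
#' classified as `blood` together with their blood fraction; whole pancreas and
#' pancreatic islets are classified as `pancreatic`. Labels outside the mapping
#' fall through to `other:<label>` with a warning, never an error, and never
#' carry a blood fraction.
#'
#' @param tissue_raw Character vector of raw tissue labels.
#' @param mapping A data frame with columns `label`, `tissue_class`,
#'   `blood_fraction` (defaults to [default_tissue_mapping()]); matching is
#'   case-insensitive on the trimmed label.
#'
#' @return A tibble with columns `tissue_raw`, `tissue_class`,
#'   `blood_fraction` (one of serum/plasma/pbmc/whole_blood, or `none`).
#' @export
#' @examples
#' classify_tissue(c("serum", "pancreatic islets", "Whole blood"))
classify_tissue <- function(tissue_raw, mapping = default_tissue_mapping()) {
  stopifnot(is.character(tissue_raw))
  key <- tolower(stringr::str_trim(tissue_raw))
  idx <- match(key, tolower(mapping$label))
  tissue_class <- mapping$tissue_class[idx]
  blood_fraction <- mapping$blood_fraction[idx]

  unknown <- is.na(idx)
  if (any(unknown)) {
    slug <- stringr::str_replace_all(key[unknown], "[^a-z0-9]+", "_")
    tissue_class[unknown] <- paste0("other:", slug)
    blood_fraction[unknown] <- "none"
    warn(paste0(
      "unmapped tissue label(s) classified as other: ",
      paste(unique(tissue_raw[unknown]), collapse = ", ")
    ))
  }
  tibble::tibble(
    tissue_raw = tissue_raw,
    tissue_class = tissue_class,
    blood_fraction = blood_fraction
  )
}

#' @rdname classify_tissue
#' @export
default_tissue_mapping <- function() {
  tibble::tribble(
    ~label,                                ~tissue_class, ~blood_fraction,
    "serum",                               "blood",       "serum",
    "plasma",                              "blood",       "plasma",
    "pbmc",                                "blood",       "pbmc",
    "pbmcs",                               "blood",       "pbmc",
    "peripheral blood mononuclear cells",  "blood",       "pbmc",
    "whole blood",                         "blood",       "whole_blood",
    "blood",                               "blood",       "whole_blood",
    "pancreas",                            "pancreatic",  "none",
    "whole pancreas",                      "pancreatic",  "none",
    "pancreatic islets",                   "pancreatic",  "none",
    "pancreatic tissue",                   "pancreatic",  "none",
    "skeletal muscle",                     "muscle",      "none",
    "muscle",                              "muscle",      "none",
    "adipose",                             "adipose",     "none",
    "adipose tissue",                      "adipose",     "none",
    "blood vessel",                        "vessel",      "none",
    "blood vessels",                       "vessel",      "none",
    "vessel",                              "vessel",      "none",
    "heart",                               "heart",       "none",
    "kidney",                              "kidney",      "none",
    "kidneys",                             "kidney",      "none"
  )
}

corpus_columns <- c(
  "substudy_id", "parent_study_id", "mirna", "tissue", "blood_fraction",
  "platform", "n_case", "n_ctrl", "events_case", "events_ctrl",
  "reported_direction"
)

platform_levels <- c("pcr", "seq", "array", "nanostring")
fraction_levels <- c("serum", "plasma", "pbmc", "whole_blood", "none")

#' Build a validated study corpus from substudy records
#'
#' A corpus is the unit of analysis for the meta-analytic stages: one row per
#' study-by-microRNA observation ("substudy") carrying 2x2 dysregulation-event
#' counts (`events_case` of `n_case`, `events_ctrl` of `n_ctrl`), strata labels
#' and a parent study identifier (several substudies may share a parent
#' publication; publication-bias tests need to know this). All row-level
#' validation failures are collected and reported together.
#'
#' @param records A data frame with the documented columns (see
#'   [read_corpus()] for the file schema).
#' @param alias_table Alias table forwarded to [normalize_mirna_name()].
#' @param provenance Free-text provenance note stored on the corpus.
#'
#' @return A `mir_corpus` object: list with `records` (tibble, canonicalised),
#'   `alias_table` and `provenance`.
#' @export
mir_corpus <- function(records, alias_table = NULL, provenance = "in-memory") {
  records <- tibble::as_tibble(records)
  missing <- setdiff(corpus_columns, names(records))
  if (length(missing)) {
    abort(paste0("corpus schema error: missing column(s) ", paste(missing, collapse = ", ")))
  }
  records <- dplyr::select(records, dplyr::all_of(corpus_columns))
  for (col in c("n_case", "n_ctrl", "events_case", "events_ctrl")) {
    records[[col]] <- as.integer(records[[col]])
  }

  nm <- normalize_mirna_name(records$mirna, alias_table)
  cls <- classify_tissue(records$tissue)

  rec <- records |>
    dplyr::mutate(
      mirna_raw = .data$mirna,
      mirna = dplyr::coalesce(nm$canonical, .data$mirna),
      resolved_via = nm$resolved_via,
      tissue_class = cls$tissue_class,
      # the tissue label can imply the fraction (e.g. "serum"); fill it in
      # when the column says none, otherwise keep the file's value and let
      # validation catch contradictions
      blood_fraction = dplyr::if_else(
        cls$tissue_class == "blood" & .data$blood_fraction == "none",
        cls$blood_fraction, .data$blood_fraction
      )
    )

  problems <- character()
  bad <- function(cond, what) {
    ids <- rec$substudy_id[cond]
    if (length(ids)) paste0(what, ": ", paste(ids, collapse = ", ")) else character()
  }
  dup <- unique(rec$substudy_id[duplicated(rec$substudy_id)])
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate substudy_id: ", paste(dup, collapse = ", ")))
  }
  problems <- c(
    problems,
    bad(rec$n_case < 1 | rec$n_ctrl < 1, "arm size < 1"),
    bad(rec$events_case < 0 | rec$events_ctrl < 0, "negative event count"),
    bad(rec$events_case > rec$n_case, "events_case > n_case"),
    bad(rec$events_ctrl > rec$n_ctrl, "events_ctrl > n_ctrl"),
    bad(!rec$platform %in% platform_levels, "unknown platform"),
    bad(!rec$blood_fraction %in% fraction_levels, "unknown blood fraction"),
    bad(!rec$reported_direction %in% c("up", "down"), "invalid reported_direction"),
    bad(rec$tissue_class == "blood" & rec$blood_fraction == "none",
        "blood tissue without blood fraction"),
    bad(rec$tissue_class != "blood" & rec$blood_fraction != "none",
        "blood fraction on non-blood tissue")
  )
  if (length(problems)) {
    abort(paste0("corpus validation failed:\n", paste("-", problems, collapse = "\n")))
  }

  n_unresolved <- sum(rec$resolved_via == "unresolved")
  if (n_unresolved > 0) {
    inform(paste0(n_unresolved, " record(s) carry unresolved microRNA labels"))
  }

  structure(
    list(records = rec, alias_table = as_alias_vector(alias_table), provenance = provenance),
    class = "mir_corpus"
  )
}

#' Read a substudy corpus from a tab-separated file
#'
#' The documented dialect is UTF-8, tab-separated, `.` decimal, header
#' required, with columns exactly: `substudy_id`, `parent_study_id`, `mirna`,
#' `tissue`, `blood_fraction`, `platform`, `n_case`, `n_ctrl`, `events_case`,
#' `events_ctrl`, `reported_direction`. microRNA names are canonicalised on
#' read and all record invariants are validated; failures are reported
#' together, citing the offending `substudy_id`s.
#'
#' @param path Path to the TSV file.
#' @param alias_table Alias table forwarded to [normalize_mirna_name()].
#' @return A `mir_corpus` object.
#' @export
read_corpus <- function(path, alias_table = NULL) {
  if (!file.exists(path)) abort(paste0("corpus file not found: ", path))
  records <- readr::read_tsv(
    path,
    col_types = readr::cols(
      substudy_id = readr::col_character(),
      parent_study_id = readr::col_character(),
      mirna = readr::col_character(),
      tissue = readr::col_character(),
      blood_fraction = readr::col_character(),
      platform = readr::col_character(),
      n_case = readr::col_integer(),
      n_ctrl = readr::col_integer(),
      events_case = readr::col_integer(),
      events_ctrl = readr::col_integer(),
      reported_direction = readr::col_character()
    ),
    progress = FALSE
  )
  mir_corpus(records, alias_table = alias_table, provenance = path)
}

#' Write a corpus back to the documented TSV dialect
#'
#' Writes the canonicalised table in the documented column order, so that
#' `write_corpus(read_corpus(f))` round-trips byte-identically for files
#' already in canonical form.
#'
#' @param corpus A `mir_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "mir_corpus"))
  out <- dplyr::select(corpus$records, dplyr::all_of(corpus_columns))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.mir_corpus <- function(x, ...) {
  cat("<mir_corpus> ", nrow(x$records), " substudies, ",
      dplyr::n_distinct(x$records$mirna), " microRNAs, ",
      dplyr::n_distinct(x$records$parent_study_id), " parent studies\n",
      "  combined sample size: ",
      sum(x$records$n_case + x$records$n_ctrl), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mir_corpus <- function(x, ...) x$records
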