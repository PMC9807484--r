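relation_beta <- function(relation) {
  known_neg <- c("inhibition", "repression")
  known_pos <- c("activation", "expression")
  unknown <- !(tolower(relation) %in% c(known_neg, known_pos))
  if (any(unknown)) {
    warn(paste0("unknown relation type(s) default to +1: ",
                paste(unique(relation[unknown]), collapse = ", ")))
  }
  ifelse(tolower(relation) %in% known_neg, -1, 1)
}

#' Construct a signed directed pathway graph
#'
#' @param pathway_id Identifier.
#' @param name Human-readable name.
#' @param edges Tibble with columns `src`, `dst` and either `beta`
#'   (+1/-1) or `relation` (activation/inhibition-style labels mapped to
#'   +1/-1; unknown labels default to +1 with a warning).
#' @param nodes Optional node set; defaults to the edge endpoints.
#' @return A `mir_pathway` list: `pathway_id`, `name`, `nodes`, `edges`
#'   (tibble `src`, `dst`, `beta`, `relation`).
#' @export
pathway_graph <- function(pathway_id, name = pathway_id, edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("src", "dst") %in% names(edges))) abort("edges need src and dst columns")
  if (!"relation" %in% names(edges)) edges$relation <- NA_character_
  if (!"beta" %in% names(edges)) {
    edges$beta <- relation_beta(edges$relation)
  }
  if (!all(edges$beta %in% c(-1, 1))) abort("edge beta must be +1 or -1")
  edges <- dplyr::distinct(edges, .data$src, .data$dst, .data$beta, .keep_all = TRUE)
  conflicting <- edges |>
    dplyr::count(.data$src, .data$dst) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicting)) {
    abort(paste0("conflicting duplicate edges in ", pathway_id, ": ",
                 paste(paste0(conflicting$src, "->", conflicting$dst), collapse = ", ")))
  }
  nodes <- sort(unique(c(nodes, edges$src, edges$dst)))
  if (!all(c(edges$src, edges$dst) %in% nodes)) abort("edge endpoints must be nodes")
  structure(list(pathway_id = pathway_id, name = name, nodes = nodes,
                 edges = dplyr::select(edges, "src", "dst", "beta", "relation")),
            class = "mir_pathway")
}

#' Read pathway graphs from an edge-list TSV or GraphML file
#'
#' The TSV dialect has columns `pathway_id`, `src`, `dst`, `beta`,
#' `relation` (one file may hold many pathways). GraphML files (one pathway
#' per file, via igraph) must carry `beta` or `relation` edge attributes and
#' take the pathway id from the graph `name` attribute or the file name.
#'
#' @param path File path (`.tsv`/`.txt` or `.graphml`).
#' @return A named list of `mir_pathway` objects.
#' @export
read_pathways <- function(path) {
  if (!file.exists(path)) abort(paste0("pathway file not found: ", path))
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    edges <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges"))
    names(edges)[1:2] <- c("src", "dst")
    id <- igraph::graph_attr(g, "name") %||% sub("\\.graphml$", "", basename(path))
    pw <- pathway_graph(id, id, edges, nodes = igraph::V(g)$name)
    return(setNames(list(pw), id))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    pathway_id = readr::col_character(), src = readr::col_character(),
    dst = readr::col_character(), beta = readr::col_double(),
    relation = readr::col_character()
  ), progress = FALSE)
  tab |>
    dplyr::group_split(.data$pathway_id) |>
    purrr::map(~ pathway_graph(.x$pathway_id[1], .x$pathway_id[1], .x)) |>
    (\(l) setNames(l, purrr::map_chr(l, "pathway_id")))()
}

#' Write pathway graphs to the edge-list TSV dialect
#' @param pathways A list of `mir_pathway` (or one `mir_pathway`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(pathways, path) {
  if (inherits(pathways, "mir_pathway")) pathways <- list(pathways)
  out <- purrr::map_dfr(pathways, function(p) {
    dplyr::mutate(p$edges, pathway_id = p$pathway_id, .before = 1)
  })
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Augment a pathway with microRNA repression edges
#'
#' For every robust pair `(m, g)` whose target gene `g` is on the pathway, a
#' microRNA node `m` is added (once) together with a repression edge
#' `m -> g` with `beta = -1`. MicroRNAs with no target on the pathway are not
#' added. Augmentation is idempotent.
#'
#' @param pw A `mir_pathway`.
#' @param robust A `mir_robust` object or a pairs tibble (`mirna`, `gene`).
#' @return A `mir_augmented` list: `base`, `mirna_nodes`, `added_edges`,
#'   `nodes`, `edges` (base plus repression edges).
#' @export
augment_pathway <- function(pw, robust) {
  stopifnot(inherits(pw, "mir_pathway"))
  pairs <- if (inherits(robust, "mir_robust")) robust$pairs else tibble::as_tibble(robust)
  hits <- pairs |>
    dplyr::distinct(.data$mirna, .data$gene) |>
    dplyr::filter(.data$gene %in% pw$nodes) |>
    # idempotence: never duplicate a repression edge already in the graph
    dplyr::anti_join(pw$edges, by = c(mirna = "src", gene = "dst"))
  added <- tibble::tibble(src = hits$mirna, dst = hits$gene, beta = -1,
                          relation = "repression")
  structure(
    list(base = pw,
         mirna_nodes = sort(unique(hits$mirna)),
         added_edges = added,
         nodes = sort(unique(c(pw$nodes, hits$mirna))),
         edges = dplyr::bind_rows(pw$edges, added),
         pathway_id = pw$pathway_id, name = pw$name),
    class = "mir_augmented"
  )
}

#' Propagate measured perturbations through an augmented pathway
#'
#' Solves the linear perturbation system `(I - B) PF = dE` where
#' `B[i, j] = beta(j -> i) / outdegree(j)` (source out-degree normalisation),
#' `dE` holds the measured perturbations (signed pooled log odds ratios of
#' dysregulated microRNAs; zero elsewhere), `PF` is the perturbation factor
#' per node and `Acc = PF - dE` the accumulation. If the system is
#' ill-conditioned (reciprocal condition below 1e-12, as happens with
#' feedback loops of gain one) all betas are damped by 0.9 and the solve is
#' retried with a warning flag.
#'
#' @param aug A `mir_augmented` (or `mir_pathway`).
#' @param delta_e Named numeric vector of measured perturbations; names must
#'   be graph nodes.
#' @return A list: `pf` and `acc` (named vectors over nodes), `t_a`
#'   (total accumulation), `damped` flag.
#' @export
propagate <- function(aug, delta_e) {
  nodes <- aug$nodes
  edges <- aug$edges
  if (length(delta_e) && !all(names(delta_e) %in% nodes)) {
    abort("delta_e names must be nodes of the pathway")
  }
  n <- length(nodes)
  de <- setNames(numeric(n), nodes)
  de[names(delta_e)] <- delta_e

  b <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    outdeg <- table(factor(edges$src, levels = nodes))
    w <- edges$beta / as.numeric(outdeg[edges$src])
    for (e in seq_len(nrow(edges))) {
      b[edges$dst[e], edges$src[e]] <- b[edges$dst[e], edges$src[e]] + w[e]
    }
  }
  a <- diag(n) - b
  damped <- FALSE
  if (rcond(a) < 1e-12) {
    damped <- TRUE
    a <- diag(n) - 0.9 * b
    if (rcond(a) < 1e-12) {
      abort(paste0("perturbation system singular after damping in pathway ",
                   aug$pathway_id))
    }
  }
  pf <- setNames(as.numeric(solve(a, de)), nodes)
  acc <- pf - de
  list(pf = pf, acc = acc, t_a = sum(acc), damped = damped)
}

#' Hypergeometric over-representation probability
#'
#' Upper-tail probability `P(X >= n_de_on_pathway)` for the number of
#' differentially expressed entities falling on a pathway when `n_pathway`
#' entities are drawn from a measured universe of `n_universe` containing
#' `n_de` differentially expressed ones.
#'
#' @param n_universe,n_de,n_pathway,n_de_on_pathway Counts.
#' @return A probability.
#' @export
#' @examples
#' ora_p(20, 5, 4, 3) # 155/4845
ora_p <- function(n_universe, n_de, n_pathway, n_de_on_pathway) {
  if (n_de > n_universe || n_pathway > n_universe ||
      n_de_on_pathway > min(n_de, n_pathway)) {
    abort("impossible over-representation configuration")
  }
  phyper(n_de_on_pathway - 1, n_de, n_universe - n_de, n_pathway,
         lower.tail = FALSE)
}

#' Build a perturbation input from meta-analysis results
#'
#' Given a single analysis set, the measured universe is every microRNA
#' meta-analysed and the differentially expressed set the significant ones.
#' Given a *list* of sets (overall plus subgroups plus sensitivity runs), the
#' differentially expressed set is every microRNA significant in at least one
#' set — dropping direction-inconsistent ones when a consistency map is
#' supplied — which mirrors how dysregulated microRNAs identified across the
#' different meta-analyses feed the pathway stage. Each input carries its
#' signed REML pooled log odds ratio, taken from the overall set when
#' available there and otherwise from the set with its smallest adjusted p.
#'
#' @param analysis A `mir_analysis`, or a list of them.
#' @param consistency Optional [direction_consistency()] map; inconsistent
#'   microRNAs are excluded from the input set.
#' @return A `mir_perturbation` list: `delta_e` (named vector),
#'   `measured_universe`, `de_set`.
#' @export
perturbation_input <- function(analysis, consistency = NULL) {
  if (inherits(analysis, "mir_analysis")) analysis <- list(analysis)
  all_res <- purrr::map_dfr(analysis, tidy)
  sig <- dplyr::filter(all_res, .data$significant)
  if (!is.null(consistency)) {
    keep <- consistency$mirna[consistency$status != "inconsistent"]
    sig <- dplyr::filter(sig, .data$mirna %in% keep)
  }
  # one signed perturbation per microRNA: prefer the overall pooled estimate
  picked <- sig |>
    dplyr::mutate(from_overall = .data$label == "overall") |>
    dplyr::group_by(.data$mirna) |>
    dplyr::arrange(dplyr::desc(.data$from_overall), .data$p_adj_reml,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup()
  structure(
    list(delta_e = setNames(picked$mu_reml, picked$mirna),
         measured_universe = unique(all_res$mirna),
         de_set = picked$mirna),
    class = "mir_perturbation"
  )
}

#' Topology-aware pathway impact analysis
#'
#' For each augmented pathway the observed total accumulation `t_A` is
#' combined with two probabilities: `p_acc`, from a permutation null that
#' reassigns the observed perturbation values to uniformly resampled
#' measured entities on that pathway (median-centred two-sided tail with a
#' +1 pseudo-count), and `p_ora`, the hypergeometric over-representation
#' tail over the measured universe. The combined evidence
#' `c = p_ora * p_acc` gives `p_G = c - c log(c)` (Fisher product), adjusted
#' across pathways by Benjamini-Hochberg (or Bonferroni).
#'
#' Pathways with no measured entity get `p_G = 1` and a flag.
#'
#' @param augs List of `mir_augmented` pathways.
#' @param perturbation A `mir_perturbation` (see [perturbation_input()]).
#' @param n_perm Number of permutations (>= 100; default 2000).
#' @param seed Mandatory integer seed for the permutation stream.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return A `mir_impact` tibble: `pathway_id`, `name`, `t_a`, `p_ora`,
#'   `p_acc`, `p_g`, `p_g_adj`, `n_de_on_pathway`, `no_measured`, `damped`,
#'   plus list-columns `pf`, `acc`, `de_nodes`.
#' @export
impact_analysis <- function(augs, perturbation, n_perm = 2000, seed,
                            adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory for impact analysis")
  stopifnot(n_perm >= 100)
  if (inherits(augs, "mir_augmented")) augs <- list(augs)
  set.seed(as.integer(seed))

  rows <- purrr::map_dfr(augs, function(aug) {
    nodes <- aug$nodes
    measured_on <- intersect(perturbation$measured_universe, nodes)
    de_on <- intersect(perturbation$de_set, nodes)
    n_de_on <- length(de_on)
    if (length(measured_on) == 0) {
      return(tibble::tibble(
        pathway_id = aug$pathway_id, name = aug$name, t_a = 0,
        p_ora = 1, p_acc = 1, p_g = 1, n_de_on_pathway = 0L,
        no_measured = TRUE, damped = FALSE,
        pf = list(setNames(numeric(length(nodes)), nodes)),
        acc = list(setNames(numeric(length(nodes)), nodes)),
        de_nodes = list(character())
      ))
    }
    de <- perturbation$delta_e[de_on]
    prop <- propagate(aug, de)

    # t_A is linear in dE: t_A = sum_j (colSums((I-B)^-1) - 1)[j] dE[j],
    # so the permutation null needs one coefficient per node, not a solve
    # per draw.
    coefs <- impact_linear_coefs(aug)
    t_obs <- sum(coefs[de_on] * de)
    vals <- unname(de)
    t_null <- if (n_de_on > 0) {
      replicate(n_perm, {
        idx <- sample(measured_on, n_de_on)
        sum(coefs[idx] * vals)
      })
    } else {
      numeric(n_perm)
    }
    med <- median(t_null)
    p_acc <- (sum(abs(t_null - med) >= abs(t_obs - med) - 1e-12) + 1) / (n_perm + 1)
    p_ora <- ora_p(length(perturbation$measured_universe),
                   length(perturbation$de_set),
                   length(measured_on), n_de_on)
    cc <- p_ora * p_acc
    p_g <- if (cc >= 1) 1 else cc - cc * log(cc)
    tibble::tibble(
      pathway_id = aug$pathway_id, name = aug$name, t_a = prop$t_a,
      p_ora = p_ora, p_acc = p_acc, p_g = p_g,
      n_de_on_pathway = n_de_on, no_measured = FALSE, damped = prop$damped,
      pf = list(prop$pf), acc = list(prop$acc), de_nodes = list(de_on)
    )
  })
  method <- if (adjust == "BH") "BH" else "bonferroni"
  rows$p_g_adj <- p.adjust(rows$p_g, method = method)
  rows <- dplyr::relocate(rows, "p_g_adj", .after = "p_g")
  structure(rows, class = c("mir_impact", class(rows)))
}

# coefficient vector c with t_A(dE) = sum(c[j] * dE[j]); c = colSums(A^-1) - 1
impact_linear_coefs <- function(aug) {
  nodes <- aug$nodes
  edges <- aug$edges
  n <- length(nodes)
  b <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    outdeg <- table(factor(edges$src, levels = nodes))
    w <- edges$beta / as.numeric(outdeg[edges$src])
    for (e in seq_len(nrow(edges))) {
      b[edges$dst[e], edges$src[e]] <- b[edges$dst[e], edges$src[e]] + w[e]
    }
  }
  a <- diag(n) - b
  if (rcond(a) < 1e-12) a <- diag(n) - 0.9 * b
  inv <- solve(a)
  setNames(colSums(inv) - 1, nodes)
}

#' @export
tidy.mir_impact <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select(-dplyr::any_of(c("pf", "acc", "de_nodes")))
}

#' @export
glance.mir_impact <- function(x, ...) {
  tibble::tibble(n_pathways = nrow(x),
                 n_enriched = sum(x$p_g_adj < 0.05, na.rm = TRUE))
}

#' Per-node perturbation factors in long form
#'
#' @param impact A `mir_impact` result.
#' @return A tibble `pathway_id`, `node`, `pf`, `acc` suitable for external
#'   rendering of perturbation maps.
#' @export
node_perturbations <- function(impact) {
  purrr::pmap_dfr(
    list(impact$pathway_id, impact$pf, impact$acc),
    function(id, pf, acc) {
      tibble::tibble(pathway_id = id, node = names(pf),
                     pf = unname(pf), acc = unname(acc))
    }
  )
}
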