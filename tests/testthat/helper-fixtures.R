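# shared fixture builders and independent oracles

make_effects <- function(y, v, parent = NULL) {
  k <- length(y)
  if (length(v) == 1) v <- rep(v, k)
  tibble::tibble(
    y = y, v = v,
    substudy_id = sprintf("s%02d", seq_len(k)),
    parent_study_id = parent %||% sprintf("p%02d", seq_len(k)),
    mirna = "miR-1-3p",
    corrected = FALSE
  )
}

`%||%` <- rlang::`%||%`

make_records <- function(mirna, events_case, n_case, events_ctrl, n_ctrl,
                         tissue = "serum", fraction = "serum",
                         platform = "pcr", parent = NULL) {
  k <- length(events_case)
  rep_len2 <- function(x) rep_len(x, k)
  tibble::tibble(
    substudy_id = sprintf("%s_s%02d", gsub("[^A-Za-z0-9]", "", mirna), seq_len(k)),
    parent_study_id = parent %||% sprintf("p%02d", seq_len(k)),
    mirna = mirna,
    tissue = rep_len2(tissue),
    blood_fraction = rep_len2(fraction),
    platform = rep_len2(platform),
    n_case = rep_len2(as.integer(n_case)),
    n_ctrl = rep_len2(as.integer(n_ctrl)),
    events_case = as.integer(events_case),
    events_ctrl = as.integer(events_ctrl),
    reported_direction = "up"
  )
}

# independent REML oracle: coarse-to-fine 1-D grid search of the restricted
# log-likelihood at final step 1e-6
reml_grid_oracle <- function(y, v, cap = NULL) {
  ll <- function(t) {
    w <- 1 / (v + t)
    mu <- sum(w * y) / sum(w)
    -0.5 * (sum(log(v + t)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  cap <- cap %||% max(10, 100 * stats::var(y))
  grid <- seq(0, cap, length.out = 20001)
  vals <- vapply(grid, ll, 0)
  best <- grid[which.max(vals)]
  step <- grid[2] - grid[1]
  fine <- seq(max(0, best - step), min(cap, best + step), by = 1e-6)
  fine[which.max(vapply(fine, ll, 0))]
}

# independent propagation oracle: accumulate perturbation in topological order
topo_propagate_oracle <- function(nodes, edges, de) {
  g <- igraph::graph_from_data_frame(edges[, c("src", "dst")],
                                     vertices = nodes, directed = TRUE)
  ord <- names(igraph::topo_sort(g, mode = "out"))
  pf <- stats::setNames(numeric(length(nodes)), nodes)
  pf[names(de)] <- de
  outdeg <- table(factor(edges$src, levels = nodes))
  for (n in ord) {
    inc <- edges[edges$dst == n, , drop = FALSE]
    if (nrow(inc)) {
      pf[n] <- pf[n] + sum(inc$beta * pf[inc$src] / as.numeric(outdeg[inc$src]))
    }
  }
  pf
}

random_dag_fixture <- function(n_nodes = 8, edge_prob = 0.35) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(seq_len(n_nodes), 2))
  keep <- stats::runif(nrow(pairs)) < edge_prob
  # guarantee at least one edge
  if (!any(keep)) keep[1] <- TRUE
  edges <- tibble::tibble(
    src = nodes[pairs[keep, 1]],
    dst = nodes[pairs[keep, 2]],
    beta = sample(c(-1, 1), sum(keep), replace = TRUE),
    relation = "x"
  )
  pathway_graph("dag", "dag", edges, nodes = nodes)
}
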