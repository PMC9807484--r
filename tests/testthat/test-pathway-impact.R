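chain_pathway <- function() {
  pathway_graph("chain", "chain", tibble::tibble(
    src = c("m", "A"), dst = c("A", "B"), beta = c(-1, 1), relation = c("repression", "activation")
  ))
}

test_that("augmentation adds repression edges only for on-pathway targets, idempotently", {
  pw <- pathway_graph("pw1", "toy", tibble::tibble(
    src = c("A", "B"), dst = c("B", "C"), beta = c(1, -1), relation = NA
  ))
  robust_pairs <- tibble::tibble(mirna = c("m1", "m1", "m2", "m1"),
                                 gene = c("A", "B", "D", "A")) # duplicate m1->A
  aug <- augment_pathway(pw, robust_pairs)
  expect_setequal(aug$mirna_nodes, "m1")
  expect_equal(nrow(aug$added_edges), 2)
  expect_true(all(aug$added_edges$beta == -1))
  expect_false("m2" %in% aug$nodes)

  # idempotence: augmenting the augmented graph changes nothing
  aug2 <- augment_pathway(
    pathway_graph(aug$pathway_id, aug$name, aug$edges, nodes = aug$nodes),
    robust_pairs
  )
  expect_equal(aug2$nodes, aug$nodes)
  expect_equal(dplyr::arrange(aug2$edges, src, dst),
               dplyr::arrange(aug$edges, src, dst))

  # empty robust set: graph unchanged
  aug0 <- augment_pathway(pw, robust_pairs[0, ])
  expect_equal(aug0$nodes, pw$nodes)
})

test_that("perturbation propagation solves the chain by hand and damps cycles", {
  aug <- augment_pathway(chain_pathway(), tibble::tibble(mirna = character(), gene = character()))
  out <- propagate(aug, c(m = 2))
  expect_equal(out$pf, c(A = -2, B = -2, m = 2)[names(out$pf)])
  expect_equal(out$acc, c(A = -2, B = -2, m = 0)[names(out$acc)])
  expect_equal(out$t_a, -4)
  expect_false(out$damped)

  # zero input propagates nothing
  out0 <- propagate(aug, c(m = 0))
  expect_true(all(out0$pf == 0))
  expect_equal(out0$t_a, 0)

  # unit-gain 2-cycle is singular; damping by 0.9 gives the analytic solution
  cyc <- pathway_graph("cyc", "cyc", tibble::tibble(
    src = c("A", "B"), dst = c("B", "A"), beta = c(1, 1), relation = NA
  ))
  outc <- propagate(cyc, c(A = 1))
  expect_true(outc$damped)
  expect_equal(unname(outc$pf["A"]), 1 / (1 - 0.81), tolerance = 1e-10)
  expect_equal(unname(outc$pf["B"]), 0.9 / (1 - 0.81), tolerance = 1e-10)
})

test_that("propagation is linear in the input and matches a topological oracle on DAGs", {
  set.seed(2024)
  for (i in 1:50) {
    dag <- random_dag_fixture(n_nodes = sample(5:10, 1))
    de_nodes <- sample(dag$nodes, sample(1:3, 1))
    de <- setNames(runif(length(de_nodes), -2, 2), de_nodes)
    out <- propagate(dag, de)
    oracle <- topo_propagate_oracle(dag$nodes, dag$edges, de)
    expect_equal(out$pf[order(names(out$pf))], oracle[order(names(oracle))],
                 tolerance = 1e-10)
    # linearity in the perturbation
    out3 <- propagate(dag, 3 * de)
    expect_equal(out3$pf, 3 * out$pf, tolerance = 1e-10)
    expect_equal(out3$t_a, 3 * out$t_a, tolerance = 1e-10)
  }
})

test_that("over-representation p is the hypergeometric upper tail", {
  expect_equal(ora_p(20, 5, 4, 3), 155 / 4845, tolerance = 1e-12)
  expect_equal(ora_p(20, 5, 4, 0), 1)
  expect_equal(ora_p(20, 20, 4, 4), 1) # everything differentially expressed
  expect_error(ora_p(20, 5, 4, 5), "impossible")
})

test_that("Fisher product combination and its boundary", {
  p_ora <- 0.01; p_acc <- 0.02
  cc <- p_ora * p_acc
  expect_equal(cc - cc * log(cc), 1.9034e-3, tolerance = 1e-4)
  # boundary c = 1 must give exactly 1 inside impact_analysis; checked via a
  # pathway with no differentially expressed input below
})

test_that("impact analysis is seeded, bounded, and flags unmeasured pathways", {
  pw <- pathway_graph("pw1", "toy", tibble::tibble(
    src = c("A", "B", "C"), dst = c("B", "C", "D"), beta = c(1, -1, 1), relation = NA
  ))
  pairs <- tibble::tibble(mirna = c("miR-1-3p", "miR-2-5p"), gene = c("A", "B"))
  aug <- augment_pathway(pw, pairs)
  empty_aug <- augment_pathway(
    pathway_graph("pw2", "no-measured", tibble::tibble(
      src = "X", dst = "Y", beta = 1, relation = NA
    )),
    pairs
  )
  pert <- structure(list(
    delta_e = c(`miR-1-3p` = 2, `miR-2-5p` = -1),
    measured_universe = c("miR-1-3p", "miR-2-5p", "miR-3-5p", "miR-4-3p"),
    de_set = c("miR-1-3p", "miR-2-5p")
  ), class = "mir_perturbation")

  res <- impact_analysis(list(aug, empty_aug), pert, n_perm = 400, seed = 9)
  expect_equal(res$p_g_adj, pmin(1, stats::p.adjust(res$p_g, "BH")))
  expect_true(all(res$p_acc >= 1 / 401 & res$p_acc <= 1))
  expect_true(res$no_measured[res$pathway_id == "pw2"])
  expect_equal(res$p_g[res$pathway_id == "pw2"], 1)
  expect_equal(res$n_de_on_pathway[res$pathway_id == "pw1"], 2L)
  # accumulation identity acc = pf - delta_e on the pathway's own nodes
  pf <- res$pf[[1]]; acc <- res$acc[[1]]
  de_full <- setNames(numeric(length(pf)), names(pf))
  de_full[res$de_nodes[[1]]] <- pert$delta_e[res$de_nodes[[1]]]
  expect_equal(acc, pf - de_full, tolerance = 1e-12)

  # reproducible under the seed, different under another
  res2 <- impact_analysis(list(aug, empty_aug), pert, n_perm = 400, seed = 9)
  expect_equal(res$p_acc, res2$p_acc)
  expect_error(impact_analysis(list(aug), pert, n_perm = 400), "seed")
})

test_that("pathway IO round-trips edge lists and reads GraphML", {
  pws <- list(
    pathway_graph("p1", "one", tibble::tibble(src = "A", dst = "B", beta = 1,
                                              relation = "activation")),
    pathway_graph("p2", "two", tibble::tibble(src = c("C", "D"), dst = c("D", "E"),
                                              beta = c(-1, 1),
                                              relation = c("inhibition", "activation")))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pathways(pws, path)
  back <- read_pathways(path)
  expect_setequal(names(back), c("p1", "p2"))
  expect_equal(back$p2$edges$beta, c(-1, 1))

  # GraphML via igraph with beta as an edge attribute
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B"), to = c("B", "C"), beta = c(1, -1),
               relation = c("activation", "inhibition"))
  )
  gml <- withr::local_tempfile(fileext = ".graphml")
  igraph::write_graph(g, gml, format = "graphml")
  back2 <- read_pathways(gml)
  expect_equal(length(back2), 1)
  expect_setequal(back2[[1]]$nodes, c("A", "B", "C"))
  expect_equal(sort(back2[[1]]$edges$beta), c(-1, 1))

  # unknown relation labels default to +1 with a warning
  expect_warning(
    pathway_graph("p3", "three",
                  tibble::tibble(src = "A", dst = "B", relation = "mystery")),
    "unknown relation"
  )
})
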