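test_that("edge decays reproduce the canonical per-step factors", {
  p <- pathway_params()
  expect_equal(edge_decay("covalent", 1.5, p), 0.6)
  # hydrogen bond at the offset distance: exponential argument zero
  expect_equal(edge_decay("hbond", 2.8, p), 0.36)
  # through-space jump at the offset distance, cap not reached
  expect_equal(edge_decay("space", 1.4, p), 0.3)
  # decays are capped at the covalent factor
  expect_equal(edge_decay("hbond", 1.0, p), 0.6)
  expect_error(edge_decay("weird", 2, p), "unknown edge kind")
  expect_error(pathway_params(eps_cov = 1.2), "eps_cov")
  expect_error(pathway_params(ts_max = 1.0), "ts_max")
})

test_that("geometric edge detection classifies covalent, hbond, space", {
  # two carbons at 1.5 A: single covalent edge with eps 0.6
  s <- line_structure(2, d = 1.5)
  g <- build_graph(s, donor = list(resno = 1), acceptor = list(resno = 2))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$kind, "covalent")
  expect_equal(g$edges$eps, 0.6)

  # N and O at exactly 2.8 A: hydrogen bond with eps 0.36
  s2 <- as_structure(tibble::tibble(
    model = 1L, chain = "A", resno = 1:2, resname = "X",
    atom = c("N1", "O1"), element = c("N", "O"),
    x = c(0, 2.8), y = 0, z = 0, hetero = FALSE))
  g2 <- build_graph(s2, list(resno = 1), list(resno = 2))
  expect_equal(g2$edges$kind, "hbond")
  expect_equal(g2$edges$eps, 0.36)

  # two carbons at 3.0 A: not bonded, not N/O/S -> through-space
  s3 <- line_structure(2, d = 3.0)
  g3 <- build_graph(s3, list(resno = 1), list(resno = 2))
  expect_equal(g3$edges$kind, "space")
  expect_equal(g3$edges$eps, 0.3 * exp(-1.7 * (3.0 - 1.4)))

  # metal coordination joins the graph as covalent
  s4 <- as_structure(tibble::tibble(
    model = 1L, chain = "A", resno = 1:2, resname = c("CUA", "HIS"),
    atom = c("CU", "ND1"), element = c("CU", "N"),
    x = c(0, 2.1), y = 0, z = 0, hetero = c(TRUE, FALSE)))
  g4 <- build_graph(s4, list(element = "CU"), list(resno = 2))
  expect_equal(g4$edges$kind, "covalent")

  expect_error(build_graph(s, list(resno = 99), list(resno = 2)),
               "donor selector")
})

test_that("covalent chains give the closed-form coupling 0.6^k", {
  for (k in c(5, 19)) {
    toy <- make_toy_complex(k + 1)
    g <- graph_from_edges(toy$graph, toy$donor, toy$acceptor)
    bp <- best_path(g)
    expect_equal(bp$T_DA, 0.6^k, tolerance = 1e-12)
    expect_equal(length(bp$per_edge_eps), k)
    expect_true(all(bp$kind_sequence == "covalent"))
  }
  # 19 covalent steps: same order of magnitude as strong protein couplings
  expect_equal(0.6^19, 6.1e-5, tolerance = 0.01)
})

test_that("no-path graphs yield an explicit zero-coupling result", {
  edges <- tibble::tibble(a = c("a", "c"), b = c("b", "d"),
                          kind = "covalent", distance = 1.5)
  g <- graph_from_edges(edges, donor = "a", acceptor = "d")
  bp <- best_path(g)
  expect_false(bp$found)
  expect_equal(bp$T_DA, 0)
  expect_length(top_k_paths(g, 3), 0)
})

test_that("best_path equals exhaustive enumeration on 200 seeded graphs", {
  for (s in 1:200) {
    n <- sample(4:10, 1)
    g <- random_et_graph(n, seed = s)
    bp <- best_path(g)
    oracle <- brute_force_tda(g$edges, g$donor_nodes, g$acceptor_nodes)
    expect_equal(bp$T_DA, oracle, tolerance = 1e-12)
  }
})

test_that("top_k_paths matches brute force ordering and k = 1 is best_path", {
  # graph with exactly two simple donor-acceptor paths
  edges <- tibble::tibble(
    a = c("d", "m", "d", "n"), b = c("m", "a", "n", "a"),
    kind = c("covalent", "covalent", "covalent", "hbond"),
    distance = c(1.5, 1.5, 1.5, 3.0))
  g <- graph_from_edges(edges, "d", "a")
  paths <- top_k_paths(g, 5)
  expect_length(paths, 2)
  expect_equal(paths[[1]]$T_DA, 0.36)             # covalent-covalent route
  expect_equal(paths[[2]]$T_DA,
               0.6 * 0.36 * exp(-1.7 * 0.2))      # covalent + hbond route
  expect_gt(paths[[1]]$T_DA, paths[[2]]$T_DA)

  for (s in c(7, 23, 91)) {
    g2 <- random_et_graph(8, seed = s)
    expect_equal(top_k_paths(g2, 1)[[1]]$T_DA, best_path(g2)$T_DA)
    all_paths <- brute_force_paths(g2$edges, g2$donor_nodes, g2$acceptor_nodes)
    prods <- sort(purrr::map_dbl(all_paths, "T_DA"), decreasing = TRUE)
    got <- purrr::map_dbl(top_k_paths(g2, 3), "T_DA")
    expect_equal(got, prods[seq_along(got)], tolerance = 1e-12)
  }
})

test_that("parallel equal-coupling routes break ties deterministically", {
  edges <- tibble::tibble(a = c("d", "m1", "d", "m2"),
                          b = c("m1", "a", "m2", "a"),
                          kind = "covalent", distance = 1.5)
  g <- graph_from_edges(edges, "d", "a")
  b1 <- best_path(g)
  b2 <- best_path(g)
  expect_identical(b1$path, b2$path)
  expect_equal(b1$path, c("d", "m1", "a"))   # lexicographic tie-break
})

test_that("adding an edge never decreases the best coupling", {
  for (s in 1:40) {
    g <- random_et_graph(8, seed = s)
    base <- best_path(g)$T_DA
    nodes <- g$nodes$name
    withr::with_seed(1000 + s, {
      pick <- sample(nodes, 2)
    })
    extra <- tibble::tibble(a = pick[1], b = pick[2], kind = "covalent",
                            distance = 1.5)
    if (any(paste(g$edges$a, g$edges$b) %in%
              c(paste(pick[1], pick[2]), paste(pick[2], pick[1])))) next
    g2 <- graph_from_edges(dplyr::bind_rows(g$edges, extra),
                           g$donor_nodes, g$acceptor_nodes)
    expect_gte(best_path(g2)$T_DA, base - 1e-14)
  }
})

test_that("coupling is invariant under donor/acceptor swap", {
  for (s in c(3, 14, 159)) {
    g <- random_et_graph(9, seed = s)
    swapped <- graph_from_edges(g$edges, g$acceptor_nodes, g$donor_nodes)
    expect_equal(best_path(swapped)$T_DA, best_path(g)$T_DA, tolerance = 1e-12)
  }
})

test_that("perturbing an atom off the best path leaves the coupling unchanged", {
  toy <- make_toy_complex(8)
  s <- toy$structure
  # add a spectator atom far from the chain
  spect <- tibble::tibble(model = 1L, chain = "X", resno = 99L,
                          resname = "SPC", atom = "S99", element = "C",
                          x = 5, y = 40, z = 0, hetero = TRUE)
  s2 <- as_structure(dplyr::bind_rows(s, spect))
  g1 <- build_graph(s2, list(atom = toy$donor), list(atom = toy$acceptor))
  t1 <- best_path(g1)$T_DA
  spect2 <- dplyr::mutate(spect, y = 55)
  s3 <- as_structure(dplyr::bind_rows(s, spect2))
  g2 <- build_graph(s3, list(atom = toy$donor), list(atom = toy$acceptor))
  expect_equal(best_path(g2)$T_DA, t1)
})
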