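# shared fixtures and independent oracles

# tiny hand-built structure: n atoms on a line, spacing d
line_structure <- function(n, d = 1.5, element = "C", chain = "A") {
  as_structure(tibble::tibble(
    model = 1L, chain = chain, resno = seq_len(n), resname = "UNK",
    atom = sprintf("A%d", seq_len(n)), element = element,
    x = (seq_len(n) - 1) * d, y = 0, z = 0, hetero = FALSE
  ))
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force max-product path oracle by exhaustive simple-path enumeration
brute_force_tda <- function(edges, donor, acceptor) {
  adj <- list()
  add <- function(a, b, eps) {
    adj[[a]] <<- c(adj[[a]], setNames(eps, b))
  }
  for (i in seq_len(nrow(edges))) {
    add(edges$a[i], edges$b[i], edges$eps[i])
    add(edges$b[i], edges$a[i], edges$eps[i])
  }
  best <- 0
  recurse <- function(node, visited, prod) {
    if (node %in% acceptor) {
      best <<- max(best, prod)
      return()
    }
    for (nb in names(adj[[node]])) {
      if (!nb %in% visited) {
        for (eps in adj[[node]][names(adj[[node]]) == nb]) {
          recurse(nb, c(visited, nb), prod * eps)
        }
      }
    }
  }
  for (d in donor) recurse(d, d, 1)
  best
}

# all simple donor->acceptor paths with their products (small graphs only)
brute_force_paths <- function(edges, donor, acceptor) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    adj[[edges$a[i]]] <- c(adj[[edges$a[i]]], setNames(edges$eps[i], edges$b[i]))
    adj[[edges$b[i]]] <- c(adj[[edges$b[i]]], setNames(edges$eps[i], edges$a[i]))
  }
  out <- list()
  recurse <- function(node, visited, prod) {
    if (node %in% acceptor) {
      out[[length(out) + 1L]] <<- list(path = visited, T_DA = prod)
      return()
    }
    for (nb in names(adj[[node]])) {
      if (!nb %in% visited) recurse(nb, c(visited, nb), prod * adj[[node]][[nb]])
    }
  }
  for (d in donor) recurse(d, d, 1)
  out
}

# seeded random connected graph on n nodes with mixed edge kinds
random_et_graph <- function(n, seed, p_extra = 0.35) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    # spanning path guarantees connectivity
    edges <- tibble::tibble(a = nodes[-n], b = nodes[-1],
                            kind = sample(c("covalent", "hbond", "space"),
                                          n - 1, replace = TRUE,
                                          prob = c(0.6, 0.2, 0.2)))
    extra <- t(utils::combn(nodes, 2))
    extra <- extra[runif(nrow(extra)) < p_extra, , drop = FALSE]
    if (nrow(extra)) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        a = extra[, 1], b = extra[, 2],
        kind = sample(c("covalent", "hbond", "space"), nrow(extra),
                      replace = TRUE)))
    }
    edges <- dplyr::distinct(edges, a, b, .keep_all = TRUE)
    edges$distance <- dplyr::case_when(
      edges$kind == "covalent" ~ 1.5,
      edges$kind == "hbond" ~ runif(nrow(edges), 2.6, 3.4),
      TRUE ~ runif(nrow(edges), 3.0, 5.5))
    graph_from_edges(edges, donor = nodes[1], acceptor = nodes[n])
  })
}

# minimal parser for the CNS tbl dialect emitted by write_restraints
parse_tbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("^assign", lines)]
  purrr::map_dfr(lines, function(ln) {
    nums <- regmatches(ln, gregexpr("-?[0-9]+\\.[0-9]+", ln))[[1]]
    nums <- as.numeric(utils::tail(nums, 3))
    sels <- regmatches(ln, gregexpr("\\(([^()]+)\\)", ln))[[1]]
    tibble::tibble(target = nums[1], dminus = nums[2], dplus = nums[3],
                   n_selections = length(sels))
  })
}

# grid-search superposition oracle: best rmsd over sampled rotations
grid_search_rmsd <- function(P, Q, n_angles = 24) {
  angles <- seq(0, 2 * pi, length.out = n_angles + 1)[-1]
  best <- Inf
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  for (a in angles) for (b in angles) for (c in angles) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3, byrow = TRUE)
    R <- Rz %*% Ry %*% Rx
    best <- min(best, sqrt(mean(rowSums((Pc %*% R - Qc)^2))))
  }
  best
}

# two-chain docking "pose": receptor block plus ligand bridge at given length
make_pose <- function(n_bridge, offset = 0, seed = 1) {
  # receptor: 5 atoms around origin incl. a Cu donor; ligand: bridge chain
  # ending in an Fe acceptor, connected via n_bridge covalent steps
  rec <- tibble::tibble(
    model = 1L, chain = "B", resno = 1:4, resname = c("CUA", rep("GLY", 3)),
    atom = c("CU", "CA", "CB", "CG"), element = c("CU", "C", "C", "C"),
    x = c(0, -2, -3.5, -2.6), y = c(0, 0, 0.8, 1.9), z = c(0, 0, 0, 0.7),
    hetero = c(TRUE, FALSE, FALSE, FALSE))
  lig <- tibble::tibble(
    model = 1L, chain = "A", resno = 10 + seq_len(n_bridge),
    resname = "BRG", atom = sprintf("C%d", seq_len(n_bridge)), element = "C",
    x = 2.2 + (seq_len(n_bridge) - 1) * 1.5, y = offset, z = 0,
    hetero = FALSE)
  fe <- tibble::tibble(model = 1L, chain = "A", resno = 99, resname = "HEC",
                       atom = "FE", element = "FE",
                       x = max(lig$x) + 2.2, y = offset, z = 0, hetero = TRUE)
  as_structure(dplyr::bind_rows(rec, lig, fe))
}
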