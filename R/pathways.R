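#' Parameters of the Pathways tunneling-decay model
#'
#' Per-step decay factors of the empirical tunneling-pathway model: a
#' covalent bond contributes a constant factor `eps_cov`; a hydrogen bond
#' decays as `eps_cov^2 * exp(-beta (R - hb_offset))`; a through-space jump
#' as `(eps_cov / 2) * exp(-beta (R - ts_offset))`. All decays are capped at
#' `eps_cov`. Donor-acceptor heavy-atom geometry defines edge detection:
#' covalent within `cov_max` (relaxed to `cov_max_s` when sulfur or a metal
#' is involved, and to metal-ligand cutoffs for Cu/Fe centres), hydrogen
#' bonds between N/O/S heteroatoms within `hbond_max`, through-space
#' contacts within `ts_max`.
#'
#' @param eps_cov covalent per-step decay.
#' @param beta distance-decay constant, 1/Angstrom.
#' @param hb_offset,ts_offset decay offsets, Angstrom.
#' @param hbond_max,ts_max,cov_max,cov_max_s detection cutoffs, Angstrom.
#' @param cu_ligand_max,fe_ligand_max metal-ligand covalent cutoffs,
#'   Angstrom (Cu-N/O/S and Fe-porphyrin-N coordination bonds are treated
#'   as covalent steps so metal centres join the bonded graph).
#' @return a validated parameter list of class `pathway_params`.
#' @export
pathway_params <- function(eps_cov = 0.6, beta = 1.7, hb_offset = 2.8,
                           ts_offset = 1.4, hbond_max = 3.5, ts_max = 6.0,
                           cov_max = 1.9, cov_max_s = 2.2,
                           cu_ligand_max = 2.6, fe_ligand_max = 2.4) {
  p <- list(eps_cov = eps_cov, beta = beta, hb_offset = hb_offset,
            ts_offset = ts_offset, hbond_max = hbond_max, ts_max = ts_max,
            cov_max = cov_max, cov_max_s = cov_max_s,
            cu_ligand_max = cu_ligand_max, fe_ligand_max = fe_ligand_max)
  for (nm in names(p)) assert_scalar_num(p[[nm]], nm, positive = TRUE)
  if (p$eps_cov >= 1) abort("eps_cov must be < 1")
  if (p$ts_max <= p$ts_offset) abort("ts_max must exceed ts_offset")
  structure(p, class = "pathway_params")
}

#' Decay factor for a single pathway step
#'
#' @param kind `"covalent"`, `"hbond"` or `"space"`.
#' @param distance step length, Angstrom (ignored for covalent steps).
#' @param params a [pathway_params()] list.
#' @return decay factor in `(0, eps_cov]`.
#' @export
edge_decay <- function(kind, distance, params = pathway_params()) {
  eps <- dplyr::case_when(
    kind == "covalent" ~ params$eps_cov,
    kind == "hbond" ~ params$eps_cov^2 *
      exp(-params$beta * (distance - params$hb_offset)),
    kind == "space" ~ (params$eps_cov / 2) *
      exp(-params$beta * (distance - params$ts_offset)),
    TRUE ~ NA_real_
  )
  if (any(is.na(eps))) abort("unknown edge kind")
  pmin(eps, params$eps_cov)
}

node_id <- function(struct) paste(struct$chain, struct$resno, struct$atom, sep = "/")

metal_elements <- c("FE", "CU", "ZN", "MN", "MG", "NI", "CO")

cov_cutoff <- function(el_a, el_b, params) {
  metal <- el_a %in% metal_elements | el_b %in% metal_elements
  cu <- el_a == "CU" | el_b == "CU"
  fe <- el_a == "FE" | el_b == "FE"
  s_or_metal <- el_a == "S" | el_b == "S" | metal
  out <- rep(params$cov_max, length(el_a))
  out[s_or_metal] <- params$cov_max_s
  out[fe] <- params$fe_ligand_max
  out[cu] <- params$cu_ligand_max
  out
}

#' Build the decay-weighted molecular graph of a structure
#'
#' Detects covalent, hydrogen-bond and through-space edges between heavy
#' atoms from geometry (see [pathway_params()] for the criteria), assigns
#' each edge its tunneling decay factor, and attaches virtual donor and
#' acceptor super-nodes connected by unit-decay edges to every atom matched
#' by the corresponding selector. Hydrogens are excluded by default since
#' docked or crystallographic models rarely carry reliable proton
#' positions; hydrogen bonds are therefore detected on heavy-atom
#' donor-acceptor distance without an angle criterion.
#'
#' @param struct atom table (first model used).
#' @param donor,acceptor selector lists passed to [atom_select()]
#'   (e.g. `list(element = "CU")`, `list(resname = "HEC")`), each matching
#'   at least one atom.
#' @param params a [pathway_params()] list.
#' @param include_hydrogens keep hydrogen atoms in the graph.
#' @return an `et_graph`: list with `nodes`, `edges` (tibble `a`, `b`,
#'   `kind`, `distance`, `eps`), `donor_nodes`, `acceptor_nodes`, `params`.
#' @export
build_graph <- function(struct, donor, acceptor, params = pathway_params(),
                        include_hydrogens = FALSE) {
  s <- struct[struct$model == min(struct$model), ]
  if (!include_hydrogens) s <- s[s$element != "H", ]
  ids <- node_id(s)
  don <- node_id(do.call(atom_select, c(list(s), donor)))
  acc <- node_id(do.call(atom_select, c(list(s), acceptor)))
  if (!length(don)) abort("donor selector matches no atoms")
  if (!length(acc)) abort("acceptor selector matches no atoms")
  xyz <- coords_matrix(s)
  dm <- as.matrix(dist(xyz))
  n <- nrow(s)
  pair <- which(upper.tri(dm) & dm <= params$ts_max, arr.ind = TRUE)
  if (nrow(pair)) {
    i <- pair[, 1]; j <- pair[, 2]
    d <- dm[pair]
    el_i <- s$element[i]; el_j <- s$element[j]
    is_cov <- d <= cov_cutoff(el_i, el_j, params)
    hetero_ok <- el_i %in% c("N", "O", "S") & el_j %in% c("N", "O", "S")
    is_hb <- !is_cov & hetero_ok & d <= params$hbond_max
    kind <- ifelse(is_cov, "covalent", ifelse(is_hb, "hbond", "space"))
    edges <- tibble(a = ids[i], b = ids[j], kind = kind, distance = d,
                    eps = edge_decay(kind, d, params))
  } else {
    edges <- tibble(a = character(0), b = character(0), kind = character(0),
                    distance = numeric(0), eps = numeric(0))
  }
  new_et_graph(
    nodes = tibble(name = ids, chain = s$chain, resno = s$resno,
                   atom = s$atom, element = s$element),
    edges = edges, donor_nodes = don, acceptor_nodes = acc, params = params
  )
}

#' Build an `et_graph` from a declared edge list
#'
#' Used with toy complexes and generated random graphs where the topology
#' is specified rather than detected; decays come from [edge_decay()]
#' unless an explicit `eps` column is present.
#'
#' @param edges tibble with columns `a`, `b`, `kind`, `distance`
#'   (optionally `eps`).
#' @param donor,acceptor character vectors of node names.
#' @param params a [pathway_params()] list.
#' @return an `et_graph`.
#' @export
graph_from_edges <- function(edges, donor, acceptor,
                             params = pathway_params()) {
  edges <- as_tibble(edges)
  assert_cols(edges, c("a", "b", "kind"), "edge table")
  if (!"distance" %in% names(edges)) edges$distance <- NA_real_
  if (!"eps" %in% names(edges)) edges$eps <- NA_real_
  need <- is.na(edges$eps)
  if (any(need)) {
    edges$eps[need] <- edge_decay(edges$kind[need], edges$distance[need],
                                  params)
  }
  if (any(edges$a == edges$b)) abort("self-edges are not allowed")
  if (any(edges$eps <= 0 | edges$eps > params$eps_cov)) {
    abort("edge decays must lie in (0, eps_cov]")
  }
  nodes <- tibble(name = sort(unique(c(edges$a, edges$b, donor, acceptor))))
  new_et_graph(nodes = nodes, edges = edges,
               donor_nodes = donor, acceptor_nodes = acceptor,
               params = params)
}

new_et_graph <- function(nodes, edges, donor_nodes, acceptor_nodes, params) {
  structure(list(nodes = nodes, edges = edges, donor_nodes = donor_nodes,
                 acceptor_nodes = acceptor_nodes, params = params),
            class = "et_graph")
}

#' @export
print.et_graph <- function(x, ...) {
  cat(sprintf("et_graph: %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              paste(sprintf("%s %d", names(table(x$edges$kind)),
                            table(x$edges$kind)), collapse = ", ")))
  cat(sprintf("donor atoms: %d; acceptor atoms: %d\n",
              length(x$donor_nodes), length(x$acceptor_nodes)))
  invisible(x)
}

# igraph with super source/sink; weights are -log(eps) >= 0
as_igraph_st <- function(g) {
  super <- tibble(a = c(rep("..D", length(g$donor_nodes)),
                        rep("..A", length(g$acceptor_nodes))),
                  b = c(g$donor_nodes, g$acceptor_nodes),
                  kind = "terminal", distance = NA_real_, eps = 1)
  ed <- bind_rows(g$edges[, c("a", "b", "kind", "distance", "eps")], super)
  ig <- igraph::graph_from_data_frame(
    mutate(ed, weight = -log(.data$eps)), directed = FALSE,
    vertices = sort(unique(c(g$nodes$name, "..D", "..A"))))
  ig
}

path_result <- function(g, node_seq) {
  nodes <- setdiff(node_seq, c("..D", "..A"))
  if (length(nodes) < 1L) {
    return(structure(list(path = character(0), per_edge_eps = numeric(0),
                          kind_sequence = character(0), T_DA = 0,
                          found = FALSE), class = "et_path"))
  }
  eps <- numeric(0); kinds <- character(0)
  if (length(nodes) > 1L) {
    for (i in seq_len(length(nodes) - 1L)) {
      hit <- g$edges[(g$edges$a == nodes[i] & g$edges$b == nodes[i + 1]) |
                       (g$edges$b == nodes[i] & g$edges$a == nodes[i + 1]), ]
      # parallel edges: the path used the strongest one
      hit <- hit[which.max(hit$eps), ]
      eps <- c(eps, hit$eps)
      kinds <- c(kinds, hit$kind)
    }
  }
  structure(list(path = nodes, per_edge_eps = eps, kind_sequence = kinds,
                 T_DA = prod(eps), found = TRUE), class = "et_path")
}

#' @export
print.et_path <- function(x, ...) {
  if (!x$found) {
    cat("et_path: no donor-acceptor path (T_DA = 0)\n")
    return(invisible(x))
  }
  cat(sprintf("et_path: %d step(s), T_DA = %.3e\n", length(x$per_edge_eps),
              x$T_DA))
  cat(paste(x$path, collapse = " -> "), "\n")
  if (length(x$kind_sequence)) {
    cat("steps:", paste(sprintf("%s(%.3g)", x$kind_sequence, x$per_edge_eps),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Dominant electron-tunneling pathway
#'
#' Finds the donor-to-acceptor path maximizing the decay product `T_DA`,
#' implemented as a shortest path on edge weights `-log(eps)` (valid since
#' every decay is capped below 1). Ties are broken deterministically by the
#' lexicographically smallest node sequence. Disconnected donor/acceptor
#' yields an explicit no-path result with `T_DA = 0`.
#'
#' @param g an `et_graph`.
#' @return an `et_path`: `path` (atom node names), `per_edge_eps`,
#'   `kind_sequence`, `T_DA`, `found`.
#' @export
best_path <- function(g) {
  ig <- as_igraph_st(g)
  suppressWarnings({
    d <- igraph::distances(ig, v = "..D", to = "..A")[1, 1]
  })
  if (!is.finite(d)) return(path_result(g, character(0)))
  suppressWarnings({
    all_sp <- igraph::all_shortest_paths(ig, from = "..D", to = "..A")$vpaths
  })
  seqs <- map(all_sp, ~ names(.x))
  keys <- map_chr(seqs, ~ paste(.x, collapse = "\r"))
  path_result(g, seqs[[order(keys)[1]]])
}

#' k best tunneling pathways
#'
#' Enumerates the `k` highest-coupling simple donor-acceptor paths
#' (Yen-style enumeration via \pkg{igraph}), distinct and sorted by
#' decreasing `T_DA` with lexicographic tie-break.
#'
#' @param g an `et_graph`.
#' @param k number of paths requested (fewer are returned if the graph has
#'   fewer simple paths).
#' @return list of `et_path` objects.
#' @export
top_k_paths <- function(g, k) {
  if (k < 1) abort("k must be >= 1")
  ig <- as_igraph_st(g)
  suppressWarnings({
    d <- igraph::distances(ig, v = "..D", to = "..A")[1, 1]
  })
  if (!is.finite(d)) return(list())
  res <- igraph::k_shortest_paths(ig, from = "..D", to = "..A", k = k)
  paths <- map(res$vpaths, ~ path_result(g, names(.x)))
  # drop duplicates that differ only by terminal attachment
  keys <- map_chr(paths, ~ paste(.x$path, collapse = "\r"))
  paths <- paths[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  ord <- order(-map_dbl(paths, "T_DA"), keys)
  head(paths[ord], k)
}
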