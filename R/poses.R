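#' Score a docking pose ensemble by electron-tunneling coupling
#'
#' For every pose the decay-weighted molecular graph is built and the best
#' donor-acceptor coupling `T_DA` computed; poses are returned sorted by
#' decreasing coupling. Poses whose donor and acceptor are disconnected get
#' `T_DA = 0` and sort last; per-pose graph failures are recorded and the
#' run continues. When an external (docking) score column is supplied it is
#' carried along but never overrides the coupling ranking: tunneling
#' efficiency is the primary criterion.
#'
#' @param poses named list of atom tables (one complex per pose).
#' @param donor,acceptor selector lists (see [build_graph()]).
#' @param params a [pathway_params()] list.
#' @param external_scores optional named numeric vector of per-pose docking
#'   scores.
#' @return a `pose_score` tibble: `pose_id`, `T_DA`, `n_steps`,
#'   `path` (list-column), `external_score`, `error`.
#' @export
score_poses <- function(poses, donor, acceptor, params = pathway_params(),
                        external_scores = NULL) {
  if (is.null(names(poses))) names(poses) <- sprintf("pose_%03d", seq_along(poses))
  rows <- imap(poses, function(pose, id) {
    res <- tryCatch({
      g <- build_graph(pose, donor, acceptor, params)
      bp <- best_path(g)
      tibble(pose_id = id, T_DA = bp$T_DA,
             n_steps = length(bp$per_edge_eps),
             path = list(bp), error = NA_character_)
    }, error = function(e) {
      tibble(pose_id = id, T_DA = NA_real_, n_steps = NA_integer_,
             path = list(NULL), error = conditionMessage(e))
    })
    res
  })
  out <- bind_rows(rows)
  if (!is.null(external_scores)) {
    out$external_score <- unname(external_scores[out$pose_id])
  } else {
    out$external_score <- NA_real_
  }
  ok <- !is.na(out$T_DA)
  if (any(!ok)) {
    warn(sprintf("score_poses: %d pose(s) skipped after graph failure", sum(!ok)))
  }
  out <- out[order(-replace(out$T_DA, is.na(out$T_DA), -Inf), out$pose_id), ]
  out
}

#' Intermolecular contacts of a pose versus the CSP interface
#'
#' Finds ligand residues with any heavy atom within `cutoff` of a receptor
#' heavy atom and compares them with the CSP-derived direct-contact set
#' (precision/recall); contacts falling inside flagged allosteric windows
#' are listed separately.
#'
#' @param pose atom table containing both molecules.
#' @param ligand_chain,receptor_chain chain labels of the two molecules.
#' @param interface_set integer residues of the CSP direct-contact call
#'   (on the ligand chain).
#' @param allosteric_set optional integer residues of allosteric windows.
#' @param cutoff heavy-atom contact distance, Angstrom.
#' @return list: `contacts` (ligand residues in contact), `precision`,
#'   `recall`, `allosteric_contacts`.
#' @export
contacts_vs_csp <- function(pose, ligand_chain, receptor_chain, interface_set,
                            allosteric_set = integer(0), cutoff = 5) {
  s <- pose[pose$model == min(pose$model) & pose$element != "H", ]
  lig <- s[s$chain %in% ligand_chain, ]
  rec <- s[s$chain %in% receptor_chain, ]
  if (!nrow(lig) || !nrow(rec)) abort("pose must contain both chains")
  contacts <- integer(0)
  if (cutoff > 0) {
    lx <- coords_matrix(lig); rx <- coords_matrix(rec)
    for (res in unique(lig$resno)) {
      sub <- lx[lig$resno == res, , drop = FALSE]
      hit <- FALSE
      for (i in seq_len(nrow(sub))) {
        if (any(rowSums((rx - matrix(sub[i, ], nrow(rx), 3L, byrow = TRUE))^2)
                <= cutoff^2)) { hit <- TRUE; break }
      }
      if (hit) contacts <- c(contacts, res)
    }
  }
  contacts <- sort(contacts)
  tp <- length(intersect(contacts, interface_set))
  precision <- if (length(contacts)) tp / length(contacts) else NA_real_
  recall <- if (length(interface_set)) tp / length(interface_set) else NA_real_
  list(contacts = contacts, precision = precision, recall = recall,
       allosteric_contacts = intersect(contacts, allosteric_set))
}

#' Generate ambiguous interaction restraints (AIRs) from active residues
#'
#' HADDOCK-style information-driven restraints: active residues are the
#' CSP-derived, surface-exposed residues; passive residues are surface
#' neighbours within `passive_radius` of any active residue. Each active
#' residue yields one ambiguous record pairing it against the OR-ed set of
#' partner active-plus-passive selections, with the HADDOCK effective
#' distance convention (0 to 2 Angstrom by default). Fully buried active
#' residues are excluded with a warning.
#'
#' @param active integer residue numbers (CSP interface call).
#' @param struct atom table of the molecule carrying the active residues.
#' @param partner_active,partner_passive integer residues on the partner
#'   molecule used as the OR-ed selection set; when omitted, the
#'   restraints pair actives against the partner segment id only.
#' @param chain,partner_chain segment ids written into the selections.
#' @param passive_radius neighbour search radius, Angstrom.
#' @param sasa_threshold relative SASA below which an active residue counts
#'   as buried.
#' @param target,lower,upper restraint distance and bounds, Angstrom.
#' @return restraint tibble (one ambiguous record per exposed active
#'   residue) with attribute `passive` (the passive residue set on the
#'   same molecule).
#' @export
generate_airs <- function(active, struct, chain = "A",
                          partner_chain = "B",
                          partner_active = integer(0),
                          partner_passive = integer(0),
                          passive_radius = 6.5, sasa_threshold = 0.15,
                          target = 0, lower = 0, upper = 2) {
  s <- struct[struct$model == min(struct$model), ]
  present <- intersect(active, unique(s$resno))
  if (!length(present)) abort("no active residue exists in the structure")
  rel <- residue_relative_sasa(s)
  rs <- rel$rel_sasa[match(present, rel$resno)]
  exposed <- present[!is.na(rs) & rs >= sasa_threshold]
  buried <- setdiff(present, exposed)
  if (length(buried)) {
    warn(sprintf("generate_airs: excluding buried active residue(s): %s",
                 paste(buried, collapse = ", ")))
  }
  if (!length(exposed)) abort("all active residues are buried")
  # passive: surface residues near any active residue
  act_xyz <- coords_matrix(s[s$resno %in% exposed, ])
  surf <- rel$resno[!is.na(rel$rel_sasa) & rel$rel_sasa >= sasa_threshold]
  passive <- integer(0)
  for (res in setdiff(surf, exposed)) {
    sub <- coords_matrix(s[s$resno == res, ])
    mind <- min(as.matrix(stats::dist(rbind(sub, act_xyz)))[seq_len(nrow(sub)),
                                                            -seq_len(nrow(sub))])
    if (mind <= passive_radius) passive <- c(passive, res)
  }
  partner_sel <- if (length(partner_active) + length(partner_passive)) {
    map_chr(sort(unique(c(partner_active, partner_passive))),
            function(r) cns_sel(segid = partner_chain, resid = r))
  } else cns_sel(segid = partner_chain)
  recs <- map(sort(exposed), function(r) {
    restraint_record("ambiguous",
                     sel_a = cns_sel(segid = chain, resid = r),
                     sel_b = partner_sel,
                     target = target, lower = lower, upper = upper)
  })
  out <- bind_rows(recs)
  attr(out, "passive") <- sort(passive)
  out
}

#' Unambiguous distance restraints measured on a pose
#'
#' Measures specified atom pairs in the best pose and emits unambiguous
#' records with symmetric bounds, for use in a follow-up restraint-driven
#' modelling round.
#'
#' @param pose atom table of the complex.
#' @param pairs data frame with columns `chain_a`, `resno_a`, `atom_a`,
#'   `chain_b`, `resno_b`, `atom_b`.
#' @param tol symmetric bound width, Angstrom.
#' @return restraint tibble with one unambiguous record per pair.
#' @export
extract_unambiguous_restraints <- function(pose, pairs, tol = 1.0) {
  s <- pose[pose$model == min(pose$model), ]
  pairs <- as_tibble(pairs)
  assert_cols(pairs, c("chain_a", "resno_a", "atom_a",
                       "chain_b", "resno_b", "atom_b"), "pair spec")
  recs <- pmap(pairs, function(chain_a, resno_a, atom_a,
                               chain_b, resno_b, atom_b, ...) {
    a <- s[s$chain == chain_a & s$resno == resno_a & s$atom == atom_a, ]
    b <- s[s$chain == chain_b & s$resno == resno_b & s$atom == atom_b, ]
    if (nrow(a) != 1L) {
      abort(sprintf("pair atom not found: %s/%d/%s", chain_a, resno_a, atom_a))
    }
    if (nrow(b) != 1L) {
      abort(sprintf("pair atom not found: %s/%d/%s", chain_b, resno_b, atom_b))
    }
    if (identical(a[, c("chain", "resno", "atom")], b[, c("chain", "resno", "atom")])) {
      abort("pair spec selects the same atom twice")
    }
    d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
    restraint_record("unambiguous",
                     sel_a = cns_sel(chain_a, resno_a, atom_a),
                     sel_b = cns_sel(chain_b, resno_b, atom_b),
                     target = d, lower = max(d - tol, 0), upper = d + tol)
  })
  bind_rows(recs)
}

#' Check poses against unambiguous restraints
#'
#' Measures each restrained atom pair in every pose and keeps poses whose
#' distances all fall within the bounds. This is the desk-scale stand-in
#' for a second restraint-driven modelling round: the restraints extracted
#' from the best pose filter the ensemble down to poses sharing its
#' binding geometry, strictly reducing ensemble heterogeneity.
#'
#' @param poses named list of atom tables.
#' @param restraints restraint tibble with unambiguous records built from
#'   [cns_sel()] selections (`segid ... and resid ... and name ...`).
#' @return tibble `pose_id`, `max_violation` (Angstrom, 0 when satisfied),
#'   `satisfied`.
#' @export
check_restraints <- function(poses, restraints) {
  if (is.null(names(poses))) names(poses) <- sprintf("pose_%03d", seq_along(poses))
  parse_sel <- function(sel) {
    seg <- sub(".*segid (\\S+).*", "\\1", sel)
    resid <- as.integer(sub(".*resid (\\S+).*", "\\1", sel))
    name <- sub(".*name (\\S+).*", "\\1", sel)
    list(chain = seg, resno = resid, atom = name)
  }
  rows <- imap(poses, function(pose, id) {
    s <- pose[pose$model == min(pose$model), ]
    viol <- map_dbl(seq_len(nrow(restraints)), function(i) {
      a <- parse_sel(restraints$sel_a[[i]][1])
      b <- parse_sel(restraints$sel_b[[i]][1])
      pa <- s[s$chain == a$chain & s$resno == a$resno & s$atom == a$atom, ]
      pb <- s[s$chain == b$chain & s$resno == b$resno & s$atom == b$atom, ]
      if (nrow(pa) != 1L || nrow(pb) != 1L) return(Inf)
      d <- sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2 + (pa$z - pb$z)^2)
      max(0, d - restraints$upper[i], restraints$lower[i] - d)
    })
    tibble(pose_id = id, max_violation = max(viol),
           satisfied = max(viol) <= 0)
  })
  bind_rows(rows)
}
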