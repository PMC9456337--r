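test_that("pose scoring ranks by bridge length with the closed-form couplings", {
  poses <- list(long = make_pose(9), short = make_pose(5), mid = make_pose(7))
  sc <- score_poses(poses, donor = list(element = "CU"),
                    acceptor = list(element = "FE"))
  expect_equal(sc$pose_id, c("short", "mid", "long"))
  # bridge of n carbons: n+1 covalent steps donor->...->acceptor
  expect_equal(sc$T_DA, 0.6^c(6, 8, 10), tolerance = 1e-10)
  # identical poses give identical couplings
  sc2 <- score_poses(list(a = make_pose(5), b = make_pose(5)),
                     donor = list(element = "CU"),
                     acceptor = list(element = "FE"))
  expect_equal(sc2$T_DA[1], sc2$T_DA[2])
})

test_that("ranking is invariant under pose order permutation", {
  poses <- list(p1 = make_pose(4), p2 = make_pose(8), p3 = make_pose(6))
  a <- score_poses(poses, list(element = "CU"), list(element = "FE"))
  b <- score_poses(poses[c(3, 1, 2)], list(element = "CU"),
                   list(element = "FE"))
  expect_equal(a$pose_id, b$pose_id)
  expect_equal(a$T_DA, b$T_DA)
})

test_that("rank versus bridge length is a perfect negative Spearman correlation", {
  lens <- c(3, 5, 6, 8, 10, 12)
  poses <- setNames(purrr::map(lens, make_pose), sprintf("L%02d", lens))
  sc <- score_poses(poses, list(element = "CU"), list(element = "FE"))
  got_len <- lens[match(sc$pose_id, sprintf("L%02d", lens))]
  expect_equal(cor(seq_len(nrow(sc)), got_len, method = "spearman"), 1)
  # i.e. coupling decreases with bridge length: rho(T_DA, length) = -1
  expect_equal(cor(sc$T_DA, got_len, method = "spearman"), -1)
})

test_that("disconnected poses score zero and sort last; failures are recorded", {
  far <- make_pose(5)
  far$x[far$chain == "A"] <- far$x[far$chain == "A"] + 50
  poses <- list(ok = make_pose(5), apart = as_structure(far))
  sc <- score_poses(poses, list(element = "CU"), list(element = "FE"))
  expect_equal(sc$pose_id, c("ok", "apart"))
  expect_equal(sc$T_DA[2], 0)

  broken <- list(ok = make_pose(5), nofe = make_pose(5)[make_pose(5)$element != "FE", ])
  expect_warning(sc2 <- score_poses(broken, list(element = "CU"),
                                    list(element = "FE")), "skipped")
  expect_true(is.na(sc2$T_DA[sc2$pose_id == "nofe"]))
  expect_match(sc2$error[sc2$pose_id == "nofe"], "acceptor")
})

test_that("contact detection against the CSP interface set", {
  pose <- make_pose(5)
  # ligand chain A bridge residues 11..15 all touch the receptor region?
  rep_close <- contacts_vs_csp(pose, ligand_chain = "A",
                               receptor_chain = "B",
                               interface_set = c(11L, 12L), cutoff = 5)
  expect_true(all(c(11L, 12L) %in% rep_close$contacts))
  expect_equal(rep_close$recall, 1)

  # molecules far apart: no contacts
  far <- pose
  far$y[far$chain == "A"] <- far$y[far$chain == "A"] + 100
  rep_far <- contacts_vs_csp(as_structure(far), "A", "B", c(11L, 12L))
  expect_length(rep_far$contacts, 0)
  expect_equal(rep_far$recall, 0)

  # zero cutoff: empty set by construction
  expect_length(contacts_vs_csp(pose, "A", "B", c(11L, 12L),
                                cutoff = 0)$contacts, 0)

  # allosteric-window contacts are reported separately
  rep_allo <- contacts_vs_csp(pose, "A", "B", interface_set = c(11L, 12L),
                              allosteric_set = c(13L, 14L), cutoff = 5)
  expect_true(all(rep_allo$allosteric_contacts %in% c(13L, 14L)))
})

test_that("AIR generation keeps exposed actives and collects passives", {
  # a surface patch: single-layer sheet of CA atoms, all exposed
  grid <- expand.grid(x = seq(0, 30, 3.5), y = seq(0, 30, 3.5))
  sheet <- as_structure(tibble::tibble(
    model = 1L, chain = "A", resno = seq_len(nrow(grid)), resname = "ALA",
    atom = "CA", element = "C", x = grid$x, y = grid$y, z = 0,
    hetero = FALSE))
  active <- c(23L, 24L)
  airs <- generate_airs(active, sheet, chain = "A", partner_chain = "B",
                        partner_active = c(100L, 101L), passive_radius = 4)
  expect_equal(nrow(airs), 2)
  expect_true(all(airs$kind == "ambiguous"))
  expect_true(all(purrr::map_int(airs$sel_b, length) == 2))
  # passives are neighbours of the active patch, not the actives themselves
  passive <- attr(airs, "passive")
  expect_false(any(active %in% passive))
  expect_gt(length(passive), 0)
  # HADDOCK effective-distance convention
  expect_true(all(airs$target == 0 & airs$upper == 2))

  expect_error(generate_airs(9999L, sheet), "no active residue")
})

test_that("AIRs serialize with one assign per active residue", {
  grid <- expand.grid(x = seq(0, 14, 3.5), y = seq(0, 14, 3.5))
  sheet <- as_structure(tibble::tibble(
    model = 1L, chain = "A", resno = seq_len(nrow(grid)), resname = "ALA",
    atom = "CA", element = "C", x = grid$x, y = grid$y, z = 0,
    hetero = FALSE))
  airs <- generate_airs(c(7L, 8L, 12L), sheet, partner_active = 50L)
  f <- withr::local_tempfile(fileext = ".tbl")
  write_restraints(airs, f)
  parsed <- parse_tbl(f)
  expect_equal(nrow(parsed), 3)
  expect_equal(parsed$target, rep(0, 3))
  expect_equal(parsed$dplus, rep(2, 3))
})

test_that("unambiguous restraints measure pose distances with symmetric bounds", {
  pose <- make_pose(5)
  pairs <- tibble::tibble(chain_a = "B", resno_a = 1L, atom_a = "CU",
                          chain_b = "A", resno_b = 11L, atom_b = "C1")
  recs <- extract_unambiguous_restraints(pose, pairs, tol = 1.0)
  expect_equal(recs$target, 2.2, tolerance = 1e-9)
  expect_equal(recs$lower, 1.2, tolerance = 1e-9)
  expect_equal(recs$upper, 3.2, tolerance = 1e-9)

  missing <- dplyr::mutate(pairs, atom_b = "C99")
  expect_error(extract_unambiguous_restraints(pose, missing), "not found")
  dup <- dplyr::mutate(pairs, chain_b = "B", resno_b = 1L, atom_b = "CU")
  expect_error(extract_unambiguous_restraints(pose, dup), "same atom")
})

test_that("restraint filtering keeps near-native poses and reduces spread", {
  best <- make_pose(5)
  pairs <- tibble::tibble(chain_a = "B", resno_a = 1L, atom_a = "CU",
                          chain_b = "A", resno_b = 99L, atom_b = "FE")
  recs <- extract_unambiguous_restraints(best, pairs, tol = 1.5)

  # ensemble: small rigid shifts of the ligand (near-native) plus far poses
  shift_pose <- function(dx) {
    p <- make_pose(5)
    p$x[p$chain == "A"] <- p$x[p$chain == "A"] + dx
    as_structure(p)
  }
  poses <- list(native = best, near1 = shift_pose(0.5),
                near2 = shift_pose(-0.5), far1 = shift_pose(4),
                far2 = shift_pose(8))
  checks <- check_restraints(poses, recs)
  expect_true(all(checks$satisfied[checks$pose_id %in%
                                     c("native", "near1", "near2")]))
  expect_false(any(checks$satisfied[checks$pose_id %in% c("far1", "far2")]))

  kept <- checks$pose_id[checks$satisfied]
  spread_all <- etbridge:::pose_spread(poses, "A", "B")
  spread_kept <- etbridge:::pose_spread(poses[kept], "A", "B")
  expect_lte(spread_kept, spread_all)
})
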