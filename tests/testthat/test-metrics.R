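test_that("Kabsch superposition: identity, pure rotation, handedness", {
  s <- make_toy_complex(6, seed = 1, jitter = 0.5)$structure
  same <- superpose(s, s)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)
  expect_equal(same$R, diag(3), tolerance = 1e-8)

  withr::with_seed(2, {
    R <- random_rotation()
  })
  xyz <- cbind(s$x, s$y, s$z) %*% R
  rot <- dplyr::mutate(s, x = xyz[, 1] + 4, y = xyz[, 2] - 2, z = xyz[, 3])
  fit <- superpose(rot, s)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(fit$R), 1, tolerance = 1e-10)  # no reflection
  expect_equal(fit$transformed$x, s$x, tolerance = 1e-8)

  expect_error(superpose(s[s$resno <= 2, ], s[s$resno <= 2, ]), "3 matched")
})

test_that("Kabsch rmsd matches a rotation-grid-search oracle on 4-atom toys", {
  withr::with_seed(3, {
    P <- matrix(rnorm(12, sd = 3), 4)
    Q <- matrix(rnorm(12, sd = 3), 4)
  })
  mk <- function(m) as_structure(tibble::tibble(
    model = 1L, chain = "A", resno = 1:4, resname = "X",
    atom = sprintf("A%d", 1:4), element = "C",
    x = m[, 1], y = m[, 2], z = m[, 3], hetero = FALSE))
  kabsch_rmsd <- superpose(mk(P), mk(Q))$rmsd
  grid_rmsd <- grid_search_rmsd(P, Q, n_angles = 20)
  # the analytic optimum can only be better than a finite grid search
  expect_lte(kabsch_rmsd, grid_rmsd + 1e-9)
  expect_lt(abs(kabsch_rmsd - grid_rmsd), 0.15)
})

test_that("ensemble stats: rigid core is exact and Dmax is the max over models", {
  ens <- make_ensemble(n_models = 5, n_res = 40, core = 10:30, jitter = 0,
                       seed = 4)
  st <- ensemble_stats(ens, core = 10:30, backbone_atoms = "CA")
  expect_equal(st$mean_core_rmsd, 0, tolerance = 1e-9)
  expect_equal(st$dmax_ensemble, max(st$dmax_per_model))
  expect_equal(st$n_models, 5)
  expect_error(ensemble_stats(ens[ens$model == 1, ], core = 10:30), "2 models")
})

test_that("jittered cores show the expected RMSD scale", {
  # per-coordinate jitter sigma gives rmsd-to-mean ~ sigma * sqrt(3)
  ens <- make_ensemble(n_models = 40, n_res = 30, core = 1:30, jitter = 0.29,
                       seed = 5)
  st <- ensemble_stats(ens, core = 1:30, backbone_atoms = "CA")
  expect_equal(st$mean_core_rmsd, 0.29 * sqrt(3), tolerance = 0.08)
})

test_that("p(r) basics: two-atom case, normalization, rigid-motion invariance", {
  s <- line_structure(2, d = 10)
  pr <- pr_from_coords(s)
  expect_equal(attr(pr, "Dmax"), 10)
  expect_equal(sum(pr$p > 0), 1)
  expect_equal(sum(pr$p) * attr(pr, "bin_width"), 1)

  blob <- make_toy_complex(15, seed = 6, jitter = 1.2)$structure
  pr0 <- pr_from_coords(blob)
  withr::with_seed(7, {
    R <- random_rotation()
  })
  xyz <- cbind(blob$x, blob$y, blob$z) %*% R
  moved <- dplyr::mutate(blob, x = xyz[, 1] + 12, y = xyz[, 2], z = xyz[, 3] - 5)
  pr1 <- pr_from_coords(moved)
  expect_equal(pr1$p, pr0$p, tolerance = 1e-12)
  expect_equal(attr(pr1, "Dmax"), attr(pr0, "Dmax"), tolerance = 1e-10)
})

test_that("sphere point cloud Dmax approaches the diameter", {
  withr::with_seed(8, {
    v <- matrix(rnorm(3000), ncol = 3)
    v <- v / sqrt(rowSums(v^2)) * 15   # radius 15 shell
  })
  s <- as_structure(tibble::tibble(
    model = 1L, chain = "A", resno = seq_len(nrow(v)), resname = "X",
    atom = sprintf("A%d", seq_len(nrow(v))), element = "C",
    x = v[, 1], y = v[, 2], z = v[, 3], hetero = FALSE))
  expect_equal(attr(pr_from_coords(s), "Dmax"), 30, tolerance = 0.2)
})

test_that("Guinier fit is exact on ideal profiles and respects the qRg window", {
  sx <- make_saxs(22.7, I0 = 3.5)
  gf <- guinier_fit(sx)
  expect_equal(gf$Rg, 22.7, tolerance = 1e-6)
  expect_equal(gf$I0, 3.5, tolerance = 1e-6)
  expect_lte(gf$qmaxRg, 1.3 + 0.05)

  # recovery from a generated noisy profile stays close
  noisy <- make_saxs(22.7, I0 = 3.5, noise_sd = 0.02, seed = 9)
  expect_equal(guinier_fit(noisy)$Rg, 22.7, tolerance = 0.5)

  rising <- as_saxs(tibble::tibble(q = seq(0.01, 0.1, 0.01),
                                   I = exp(seq(0.01, 0.1, 0.01)^2 * 100)))
  expect_error(guinier_fit(rising), "no valid Guinier window")
})

test_that("dimensionless Kratky peak of an ideal Guinier curve is 3/e at sqrt(3)", {
  sx <- make_saxs(20, I0 = 2, q = seq(0.001, 0.12, 0.0005))
  kr <- kratky(sx, Rg = 20, I0 = 2)
  peak <- kr[which.max(kr$kratky), ]
  expect_equal(peak$kratky, 3 / exp(1), tolerance = 1e-3)
  expect_equal(peak$qRg, sqrt(3), tolerance = 0.02)
})

test_that("SASA closed forms: isolated atom, buried atom, two-sphere oracle", {
  one <- as_structure(tibble::tibble(
    model = 1L, chain = "A", resno = 1L, resname = "X", atom = "C1",
    element = "C", x = 0, y = 0, z = 0, hetero = FALSE))
  a <- sasa(one, probe = 1.4, n_points = 960)
  expect_equal(a$area, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-2)

  # atom enclosed by a tight shell of neighbours
  withr::with_seed(10, {
    shell <- matrix(rnorm(3 * 80), ncol = 3)
    shell <- shell / sqrt(rowSums(shell^2)) * 2.0
  })
  buried <- as_structure(tibble::tibble(
    model = 1L, chain = "A", resno = c(1L, rep(2L, 80)), resname = "X",
    atom = c("C0", sprintf("S%d", 1:80)), element = "C",
    x = c(0, shell[, 1]), y = c(0, shell[, 2]), z = c(0, shell[, 3]),
    hetero = FALSE))
  expect_equal(sasa(buried, n_points = 480)$area[1], 0)

  # two overlapping spheres: analytic spherical-cap solution
  d <- 2.5
  two <- line_structure(2, d = d)
  got <- sasa(two, probe = 1.4, n_points = 4000)
  R <- 1.7 + 1.4
  # cap height cut off each sphere: h = R - d/2 (equal radii)
  analytic <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  expect_equal(got$area, rep(analytic, 2), tolerance = 0.01 * analytic)

  bad <- dplyr::mutate(one, element = "XX")
  expect_error(sasa(bad), "van der Waals")
})

test_that("approach of a second molecule monotonically buries surface", {
  base <- line_structure(3, d = 1.5)
  areas <- purrr::map_dbl(c(5.5, 4.5, 3.6, 3.0), function(gap) {
    other <- dplyr::mutate(line_structure(3, d = 1.5), resno = resno + 10L,
                           atom = paste0("B", resno), y = gap)
    both <- as_structure(dplyr::bind_rows(base, other))
    sum(sasa(both, n_points = 960)$area[1:3])
  })
  expect_true(all(diff(areas) < 0))
})

test_that("group SASA fraction compares context against the free group", {
  lig <- line_structure(4, d = 1.5)
  shellv <- dplyr::mutate(line_structure(4, d = 1.5), resno = resno + 10L,
                          atom = paste0("B", resno), y = 3.2)
  both <- as_structure(dplyr::bind_rows(lig, shellv))
  gs <- group_sasa(both, group = list(resno = 1:4), n_points = 480)
  expect_lt(gs$fraction, 1)
  expect_gt(gs$fraction, 0)
  expect_equal(gs$free_area, sum(sasa(lig, n_points = 480)$area),
               tolerance = 1e-6)
})

test_that("sequence mass matches independent references", {
  # free glycine: residue mass + water
  expect_equal(sequence_mass("G"), 75.07, tolerance = 1e-2)
  # cross-check a peptide against seqinr's implementation
  pep <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(sequence_mass(pep), seqinr::pmw(seqinr::s2c(pep)),
               tolerance = 0.5)
  # signal-peptide truncation removes N-terminal residues
  expect_equal(sequence_mass("MAAAG", signal_peptide_length = 1),
               sequence_mass("AAAG"))
  expect_error(sequence_mass(""), "empty|non-standard")
  expect_error(sequence_mass("AXZ"), "non-standard")
})

test_that("isoelectric point behaves sensibly and tracks seqinr", {
  # acidic vs basic sequences order correctly
  expect_lt(isoelectric_point("DDEEDDEE"), 5)
  expect_gt(isoelectric_point("KKRRKKRR"), 10)
  pep <- "ACDEFGHIKLMNPQRSTVWY"
  expect_equal(isoelectric_point(pep),
               seqinr::computePI(seqinr::s2c(pep)), tolerance = 0.4)
})

test_that("structured fraction reproduces simple range arithmetic", {
  expect_equal(structured_fraction(24:132, 153), 100 * 109 / 153)
  expect_equal(round(structured_fraction(24:132, 153)), 71)
})
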