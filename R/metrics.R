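#' Least-squares rigid superposition (Kabsch)
#'
#' Superposes the selected atoms of a mobile model onto a target model by
#' the singular-value-decomposition solution of the orthogonal Procrustes
#' problem, with the reflection branch excluded so handedness is preserved.
#'
#' @param mobile,target atom tables, each a single model sharing the
#'   selected atoms.
#' @param selection optional list of [atom_select()] arguments restricting
#'   the atoms used for the fit (the returned transform still applies to
#'   all atoms).
#' @return list with `R` (3x3 rotation, row-vector convention
#'   `x_new = x %*% R + t`), `t` (translation), `rmsd` (over the selection)
#'   and `transformed` (the full mobile table moved onto the target).
#' @export
superpose <- function(mobile, target, selection = NULL) {
  msel <- if (is.null(selection)) mobile else do.call(atom_select, c(list(mobile), selection))
  tsel <- if (is.null(selection)) target else do.call(atom_select, c(list(target), selection))
  key_m <- paste(msel$chain, msel$resno, msel$atom)
  key_t <- paste(tsel$chain, tsel$resno, tsel$atom)
  common <- intersect(key_m, key_t)
  if (length(common) < 3L) abort("superpose needs at least 3 matched atoms")
  P <- coords_matrix(msel[match(common, key_m), ])
  Q <- coords_matrix(tsel[match(common, key_t), ])
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_vec <- cq - cp %*% R
  rmsd <- sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  moved <- mobile
  xyz <- coords_matrix(mobile) %*% R
  moved$x <- xyz[, 1] + t_vec[1]
  moved$y <- xyz[, 2] + t_vec[2]
  moved$z <- xyz[, 3] + t_vec[3]
  list(R = R, t = as.numeric(t_vec), rmsd = rmsd, transformed = moved)
}

#' Ensemble statistics: core RMSD, per-residue RMSD profile, maximum extent
#'
#' All models are superposed on the core backbone (two passes: onto the
#' first model, then onto the resulting mean coordinates). The mean core
#' RMSD is by default the average over models of the RMSD to the mean
#' structure; the average over all model pairs is also reported since
#' ensemble RMSD conventions differ between the two. The per-residue
#' profile is the post-superposition RMSD to the mean over all of a
#' residue's atoms, and the maximum extent is the largest interatomic
#' distance within each model.
#'
#' @param ensemble multi-model atom table.
#' @param core integer residue numbers defining the rigid core.
#' @param backbone_atoms atom names used for the superposition (`N, CA, C,
#'   O` by default; CA-only traces are handled automatically).
#' @return an `ensemble_stats` list: `mean_core_rmsd`,
#'   `mean_pairwise_core_rmsd`, `per_residue_rmsd` (tibble), `dmax_per_model`,
#'   `dmax_ensemble`, `n_models`.
#' @export
ensemble_stats <- function(ensemble, core,
                           backbone_atoms = c("N", "CA", "C", "O")) {
  models <- sort(unique(ensemble$model))
  if (length(models) < 2L) abort("ensemble_stats needs at least 2 models")
  avail <- intersect(backbone_atoms, unique(ensemble$atom))
  if (!length(avail)) abort("no backbone atoms found in ensemble")
  sel <- list(resno = core, atom = avail, hetero = FALSE)
  ref <- ensemble[ensemble$model == models[1], ]
  aligned <- map(models, function(m) {
    superpose(ensemble[ensemble$model == m, ], ref, sel)$transformed
  })
  core_mat <- function(s) coords_matrix(do.call(atom_select, c(list(s), sel)))
  mean_core <- Reduce(`+`, map(aligned, core_mat)) / length(models)
  mean_tbl <- do.call(atom_select, c(list(aligned[[1]]), sel))
  mean_tbl$x <- mean_core[, 1]; mean_tbl$y <- mean_core[, 2]
  mean_tbl$z <- mean_core[, 3]
  aligned <- map(aligned, function(s) superpose(s, mean_tbl, sel)$transformed)
  mean_core <- Reduce(`+`, map(aligned, core_mat)) / length(models)
  core_rmsds <- map_dbl(aligned, function(s) {
    sqrt(mean(rowSums((core_mat(s) - mean_core)^2)))
  })
  pair_rmsd <- c()
  for (i in seq_along(models)) {
    for (j in seq_along(models)) {
      if (j > i) {
        pair_rmsd <- c(pair_rmsd, sqrt(mean(rowSums(
          (core_mat(aligned[[i]]) - core_mat(aligned[[j]]))^2))))
      }
    }
  }
  # per-residue profile over all (non-hetero) atoms, post core superposition
  all_aligned <- bind_rows(aligned)
  prot <- all_aligned[!all_aligned$hetero, ]
  mean_xyz <- summarise(group_by(prot, .data$chain, .data$resno, .data$atom),
                        mx = mean(.data$x), my = mean(.data$y),
                        mz = mean(.data$z), .groups = "drop")
  prot <- left_join(prot, mean_xyz, by = c("chain", "resno", "atom"))
  per_res <- summarise(
    group_by(prot, .data$resno),
    rmsd = sqrt(mean((.data$x - .data$mx)^2 + (.data$y - .data$my)^2 +
                       (.data$z - .data$mz)^2)),
    .groups = "drop")
  dmax <- map_dbl(models, function(m) {
    max(dist(coords_matrix(ensemble[ensemble$model == m, ])))
  })
  structure(list(mean_core_rmsd = mean(core_rmsds),
                 mean_pairwise_core_rmsd = mean(pair_rmsd),
                 per_residue_rmsd = per_res,
                 dmax_per_model = setNames(dmax, models),
                 dmax_ensemble = max(dmax),
                 n_models = length(models)),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("ensemble of %d models\n", x$n_models))
  cat(sprintf("  core RMSD to mean: %.3f A (pairwise mean %.3f A)\n",
              x$mean_core_rmsd, x$mean_pairwise_core_rmsd))
  cat(sprintf("  Dmax: %.1f A (max over models)\n", x$dmax_ensemble))
  invisible(x)
}

#' Pair-distance distribution from coordinates
#'
#' Normalized histogram of all heavy-atom pairwise distances of one model;
#' the histogram integrates to 1 (`sum(p) * bin_width = 1`) and `Dmax` is
#' the largest distance.
#'
#' @param struct atom table.
#' @param model model number (default: first).
#' @param bin_width histogram bin, Angstrom.
#' @return tibble `r` (bin centres), `p`, with attributes `Dmax` and
#'   `bin_width`.
#' @export
pr_from_coords <- function(struct, model = NULL, bin_width = 1) {
  m <- model %||% min(struct$model)
  s <- struct[struct$model == m & struct$element != "H", ]
  if (nrow(s) < 2L) abort("pr_from_coords needs at least 2 atoms")
  d <- as.numeric(dist(coords_matrix(s)))
  dmax <- max(d)
  breaks <- seq(0, dmax + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  p <- h$counts / (sum(h$counts) * bin_width)
  out <- tibble(r = h$mids, p = p)
  attr(out, "Dmax") <- dmax
  attr(out, "bin_width") <- bin_width
  out
}

#' Guinier analysis of a scattering profile
#'
#' Linear fit of `ln I` against `q^2` over the low-angle window, with the
#' window upper limit determined iteratively so that `q_max * Rg` does not
#' exceed `qRg_limit`. The slope gives `Rg = sqrt(-3 * slope)` and the
#' intercept `I0`.
#'
#' @param profile SAXS tibble (`q`, `I`).
#' @param qRg_limit Guinier-validity limit (1.3 for globular scatterers).
#' @param min_points minimum points in the fit window.
#' @return a `guinier_result`: `Rg`, `I0`, `q_range`, `n_points`,
#'   `residual`, `qmaxRg`.
#' @export
guinier_fit <- function(profile, qRg_limit = 1.3, min_points = 5) {
  p <- as_tibble(profile)
  assert_cols(p, c("q", "I"), "SAXS profile")
  p <- p[p$I > 0, ]
  if (nrow(p) < min_points) abort("too few positive-intensity points for a Guinier fit")
  qmax <- p$q[min(nrow(p), max(min_points, 10L))]
  Rg <- NA_real_
  for (iter in seq_len(50L)) {
    w <- p[p$q <= qmax, ]
    if (nrow(w) < min_points) {
      w <- p[seq_len(min_points), ]
    }
    fit <- lm(log(I) ~ I(q^2), data = w)
    slope <- coef(fit)[[2]]
    if (slope >= 0) abort("no valid Guinier window: ln I not decreasing in q^2")
    Rg_new <- sqrt(-3 * slope)
    qmax_new <- qRg_limit / Rg_new
    if (is.finite(Rg) && abs(Rg_new - Rg) < 1e-6 * Rg_new) {
      Rg <- Rg_new
      break
    }
    Rg <- Rg_new
    qmax <- qmax_new
  }
  w <- p[p$q <= qRg_limit / Rg, ]
  if (nrow(w) < min_points) w <- p[seq_len(min_points), ]
  fit <- lm(log(I) ~ I(q^2), data = w)
  Rg <- sqrt(-3 * coef(fit)[[2]])
  I0 <- exp(coef(fit)[[1]])
  structure(list(Rg = Rg, I0 = I0,
                 q_range = range(w$q), n_points = nrow(w),
                 residual = sqrt(mean(residuals(fit)^2)),
                 qmaxRg = max(w$q) * Rg),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.2f A, I0 = %.4g (%d points, qmax*Rg = %.2f)\n",
              x$Rg, x$I0, x$n_points, x$qmaxRg))
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' @param profile SAXS tibble.
#' @param Rg,I0 reference radius of gyration and forward scattering
#'   (typically from [guinier_fit()]).
#' @return tibble `qRg`, `kratky` = `(q Rg)^2 I / I0`. For an ideal
#'   Guinier-law scatterer the curve peaks at `qRg = sqrt(3)` with value
#'   `3/e`.
#' @export
kratky <- function(profile, Rg, I0) {
  p <- as_tibble(profile)
  tibble(qRg = p$q * Rg, kratky = (p$q * Rg)^2 * p$I / I0)
}

# ---- solvent accessibility -------------------------------------------------

vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, FE = 2.00, CU = 1.40, ZN = 1.39, MG = 1.73,
               MN = 2.00, NI = 1.63, CO = 2.00, "NA" = 2.27, CL = 1.75,
               BR = 1.85)

# deterministic quasi-uniform sphere points (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolling-probe SASA by deterministic sphere sampling: each atom's
#' accessible area is the fraction of `n_points` quasi-uniform test points
#' on its probe-expanded sphere not buried inside any neighbour, times the
#' sphere area.
#'
#' @param struct atom table (single model; first model used).
#' @param probe probe radius, Angstrom (water 1.4).
#' @param n_points test points per atom.
#' @return tibble with per-atom `chain`, `resno`, `resname`, `atom`,
#'   `element`, `radius` (vdW) and `area` (Angstrom^2).
#' @export
sasa <- function(struct, probe = 1.4, n_points = 960) {
  s <- struct[struct$model == min(struct$model), ]
  unknown <- setdiff(unique(s$element), names(vdw_radii))
  if (length(unknown)) {
    abort(sprintf("no van der Waals radius for element(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  r <- unname(vdw_radii[s$element]) + probe
  xyz <- coords_matrix(s)
  pts <- sphere_points(n_points)
  n <- nrow(s)
  area <- numeric(n)
  for (i in seq_len(n)) {
    test <- pts * r[i] + matrix(xyz[i, ], n_points, 3L, byrow = TRUE)
    acc <- rep(TRUE, n_points)
    dn <- sqrt(rowSums((xyz - matrix(xyz[i, ], n, 3L, byrow = TRUE))^2))
    nb <- which(dn < r + r[i] & seq_len(n) != i)
    for (j in nb) {
      if (!any(acc)) break
      d2 <- rowSums((test - matrix(xyz[j, ], n_points, 3L, byrow = TRUE))^2)
      acc <- acc & d2 > r[j]^2
    }
    area[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  tibble(chain = s$chain, resno = s$resno, resname = s$resname,
         atom = s$atom, element = s$element,
         radius = unname(vdw_radii[s$element]), area = area)
}

#' Group SASA and its free-state fraction
#'
#' Total accessible area of a selected atom group in the context of the
#' whole structure, compared with the same group extracted alone (fully
#' free); the fraction quantifies, e.g., how much of a heme group remains
#' exposed to bulk solvent.
#'
#' @param struct atom table.
#' @param group list of [atom_select()] arguments defining the group.
#' @param probe,n_points see [sasa()].
#' @return list `area`, `free_area` (Angstrom^2), `fraction`.
#' @export
group_sasa <- function(struct, group, probe = 1.4, n_points = 960) {
  s <- struct[struct$model == min(struct$model), ]
  gsel <- do.call(atom_select, c(list(s), group))
  if (!nrow(gsel)) abort("group selector matches no atoms")
  full <- sasa(s, probe, n_points)
  key <- paste(full$chain, full$resno, full$atom)
  gkey <- paste(gsel$chain, gsel$resno, gsel$atom)
  in_context <- sum(full$area[key %in% gkey])
  alone <- sum(sasa(gsel, probe, n_points)$area)
  list(area = in_context, free_area = alone, fraction = in_context / alone)
}

# ---- sequence descriptors --------------------------------------------------

aa_residue_mass <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
                     V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
                     I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
                     K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
                     F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

#' Average molecular mass of a protein sequence
#'
#' Sum of average-isotopic residue masses plus one water. An N-terminal
#' stretch (e.g. a predicted signal peptide) can be removed first.
#'
#' @param sequence one-letter amino-acid string (or vector of letters).
#' @param signal_peptide_length residues removed from the N-terminus before
#'   the calculation.
#' @return mass in Dalton.
#' @export
sequence_mass <- function(sequence, signal_peptide_length = 0) {
  aa <- prep_sequence(sequence, signal_peptide_length)
  sum(aa_residue_mass[aa]) + 18.01528
}

prep_sequence <- function(sequence, signal_peptide_length = 0) {
  aa <- if (length(sequence) == 1L) strsplit(toupper(sequence), "")[[1]] else toupper(sequence)
  if (signal_peptide_length > 0) {
    if (signal_peptide_length >= length(aa)) abort("signal peptide removes the whole sequence")
    aa <- aa[-seq_len(signal_peptide_length)]
  }
  if (!length(aa)) abort("empty sequence")
  bad <- setdiff(unique(aa), names(aa_residue_mass))
  if (length(bad)) {
    abort(sprintf("non-standard residue letter(s): %s", paste(bad, collapse = ", ")))
  }
  aa
}

# EMBOSS ionizable-group pKa values
pka_sets <- list(
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1, H = 6.5,
             K = 10.8, R = 12.5, Y = 10.1)
)

#' Isoelectric point by bisection on the net charge
#'
#' Henderson-Hasselbalch net charge over the ionizable side chains and
#' termini, using a documented pKa table (EMBOSS values by default); the pI
#' is the pH at which the net charge crosses zero, found by bisection.
#'
#' @param sequence one-letter amino-acid string.
#' @param pKa_set name of a built-in pKa table (`"emboss"`) or a named
#'   numeric vector with entries `Nterm`, `Cterm` and the ionizable
#'   residues.
#' @param signal_peptide_length residues removed from the N-terminus first.
#' @return the isoelectric point (pH units).
#' @export
isoelectric_point <- function(sequence, pKa_set = "emboss",
                              signal_peptide_length = 0) {
  aa <- prep_sequence(sequence, signal_peptide_length)
  pk <- if (is.character(pKa_set)) {
    if (!pKa_set %in% names(pka_sets)) abort("unknown pKa set")
    pka_sets[[pKa_set]]
  } else pKa_set
  counts <- table(aa)
  net_charge <- function(pH) {
    pos <- 1 / (1 + 10^(pH - pk[["Nterm"]])) +
      sum(map_dbl(c("K", "R", "H"), function(a) {
        n <- counts[a]; if (is.na(n)) 0 else n / (1 + 10^(pH - pk[[a]]))
      }))
    neg <- 1 / (1 + 10^(pk[["Cterm"]] - pH)) +
      sum(map_dbl(c("D", "E", "C", "Y"), function(a) {
        n <- counts[a]; if (is.na(n)) 0 else n / (1 + 10^(pk[[a]] - pH))
      }))
    pos - neg
  }
  lo <- 0; hi <- 14
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    if (net_charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Structured fraction of a chain from a residue range
#'
#' @param core integer residue numbers of the structured part.
#' @param n_total chain length.
#' @return percentage of the chain in the structured part.
#' @export
structured_fraction <- function(core, n_total) {
  100 * length(unique(as.integer(core))) / n_total
}
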