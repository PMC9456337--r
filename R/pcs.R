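#' Pseudocontact shift of a nucleus near an anisotropic paramagnetic centre
#'
#' Evaluates the point-dipole pseudocontact shift
#' `d_pc = 1/(24 pi r^3) * ((2 chi_zz - chi_xx - chi_yy)(3 n^2 - 1)
#'   + 3 (chi_xx - chi_yy)(l^2 - m^2))`
#' where `r` is the nucleus-centre distance and `(l, m, n)` are the
#' direction cosines of the nucleus position in the principal frame of the
#' magnetic susceptibility tensor. The algebraically identical axial/rhombic
#' form `1/(12 pi r^3) * (dchi_ax (3 n^2 - 1) + 3/2 dchi_rh (l^2 - m^2))`
#' with `dchi_ax = chi_zz - (chi_xx + chi_yy)/2` and
#' `dchi_rh = chi_xx - chi_yy` is available via `form = "axial_rhombic"`.
#' Units follow the tensor: with `chi` in m^3 and `r` in m the result is the
#' dimensionless shift fraction (multiply by 1e6 for ppm); see
#' [pcs_ppm()] for the common Angstrom / 1e-32 m^3 convention.
#'
#' @param r distance from the paramagnetic centre (> 0); vectorized.
#' @param l,m,n direction cosines (`l^2 + m^2 + n^2 = 1` within 1e-9).
#' @param chi numeric length-3 principal values `c(xx, yy, zz)`.
#' @param form `"full"` (24 pi form) or `"axial_rhombic"`.
#' @return pseudocontact shift, units of `chi / r^3`.
#' @export
pseudocontact_shift <- function(r, l, m, n, chi,
                                form = c("full", "axial_rhombic")) {
  form <- match.arg(form)
  if (any(r <= 0)) abort("pseudocontact shift undefined at r <= 0")
  if (length(chi) != 3L) abort("chi must be the 3 principal values c(xx, yy, zz)")
  norm <- l^2 + m^2 + n^2
  if (any(abs(norm - 1) > 1e-9)) {
    abort("direction cosines must satisfy l^2 + m^2 + n^2 = 1 (tol 1e-9)")
  }
  cxx <- chi[[1]]; cyy <- chi[[2]]; czz <- chi[[3]]
  if (form == "full") {
    (1 / (24 * pi * r^3)) *
      ((2 * czz - cxx - cyy) * (3 * n^2 - 1) + 3 * (cxx - cyy) * (l^2 - m^2))
  } else {
    dax <- czz - (cxx + cyy) / 2
    drh <- cxx - cyy
    (1 / (12 * pi * r^3)) * (dax * (3 * n^2 - 1) + 1.5 * drh * (l^2 - m^2))
  }
}

#' Pseudocontact shift in ppm from anisotropies in 1e-32 m^3 and r in Angstrom
#'
#' Convenience wrapper using the common paramagnetic-NMR convention:
#' anisotropies `dchi_ax`, `dchi_rh` given in units of 1e-32 m^3 and
#' distances in Angstrom give shifts in ppm.
#'
#' @param r_A distance, Angstrom.
#' @param l,m,n direction cosines.
#' @param dchi_ax,dchi_rh axial and rhombic anisotropy, 1e-32 m^3.
#' @return shift in ppm.
#' @export
pcs_ppm <- function(r_A, l, m, n, dchi_ax, dchi_rh = 0) {
  r_m <- r_A * 1e-10
  val <- (1 / (12 * pi * r_m^3)) *
    ((dchi_ax * 1e-32) * (3 * n^2 - 1) + 1.5 * (dchi_rh * 1e-32) * (l^2 - m^2))
  val * 1e6
}

#' Per-nucleus pseudocontact-shift field over a structure
#'
#' Computes the geometry of every atom relative to a paramagnetic centre
#' atom, rotates positions into the tensor principal frame, and applies
#' [pseudocontact_shift()]. Supplying a second tensor returns the per-atom
#' difference of the two fields, which models the doubled (major/minor)
#' resonances produced by a fluxional axial ligand switching the tensor
#' between two states.
#'
#' @param struct atom table (a single model; the first model is used).
#' @param center_atom list/row identifying the centre, as accepted by
#'   [atom_select()] arguments (e.g. `list(resname = "HEC", atom = "FE")`).
#' @param chi length-3 principal values.
#' @param frame 3x3 rotation matrix mapping molecular to principal axes.
#' @param chi2 optional second tensor (same frame) for the two-state
#'   splitting difference.
#' @return tibble with per-atom geometry (`r`, `l`, `m`, `n`) and `d_pc`
#'   (column `splitting` instead when `chi2` is given). Atoms coincident
#'   with the centre are skipped with a warning.
#' @export
pcs_field <- function(struct, center_atom, chi, frame = diag(3), chi2 = NULL) {
  s <- struct[struct$model == min(struct$model), ]
  ctr <- do.call(atom_select, c(list(s), center_atom))
  if (nrow(ctr) != 1L) {
    abort(sprintf("center_atom must select exactly 1 atom (got %d)", nrow(ctr)))
  }
  if (any(abs(crossprod(frame) - diag(3)) > 1e-8)) {
    abort("tensor frame must be orthonormal")
  }
  is_ctr <- s$chain == ctr$chain & s$resno == ctr$resno & s$atom == ctr$atom
  s <- s[!is_ctr, ]
  rel <- cbind(s$x - ctr$x, s$y - ctr$y, s$z - ctr$z)
  r <- sqrt(rowSums(rel^2))
  keep <- r > 1e-6
  if (any(!keep)) {
    warn(sprintf("pcs_field: skipping %d atom(s) coincident with the centre",
                 sum(!keep)))
  }
  rel <- rel[keep, , drop = FALSE]
  r <- r[keep]
  pc <- rel %*% t(frame)   # principal-frame coordinates
  lmn <- pc / r
  out <- tibble(chain = s$chain[keep], resno = s$resno[keep],
                atom = s$atom[keep], r = r,
                l = lmn[, 1], m = lmn[, 2], n = lmn[, 3])
  if (is.null(chi2)) {
    mutate(out, d_pc = pseudocontact_shift(r, .data$l, .data$m, .data$n, chi))
  } else {
    mutate(out,
           d_pc_major = pseudocontact_shift(r, .data$l, .data$m, .data$n, chi),
           d_pc_minor = pseudocontact_shift(r, .data$l, .data$m, .data$n, chi2),
           splitting = .data$d_pc_major - .data$d_pc_minor)
  }
}
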