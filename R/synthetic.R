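#' Seeded generators for synthetic pipeline inputs
#'
#' Every generator is a pure function of its arguments and `seed`: the RNG is
#' seeded locally and the caller's RNG state restored, and the planted ground
#' truth (graph, interface set, true parameters) is always returned alongside
#' the data so downstream recovery can be tested without real depositions.
#'
#' @name synthetic_data
NULL

#' Toy donor-bridge-acceptor complex with a known bond graph
#'
#' Builds a linear bridge whose consecutive links are covalent bonds,
#' hydrogen bonds or through-space jumps of specified lengths, embedded along
#' a straight line in 3D so every specified link distance is exact. The
#' intended molecular graph is returned for oracle comparison; it is the
#' generator's ground truth, independent of any later geometric edge
#' detection.
#'
#' @param bridge either a single integer `n` (a chain of `n` atoms joined by
#'   `n - 1` covalent 1.5-Angstrom bonds) or a data frame with columns
#'   `kind` (`"covalent"`, `"hbond"`, `"space"`) and `distance` (Angstrom),
#'   one row per consecutive link.
#' @param element element symbol for the bridge atoms (chemistry realism is
#'   not the goal; graph realism is).
#' @param seed optional seed for the placement jitter.
#' @param jitter standard deviation (Angstrom) of isotropic coordinate
#'   jitter; 0 keeps link distances exact.
#' @return list with `structure` (atom table, one model), `graph` (edge
#'   tibble `a`, `b`, `kind`, `distance` naming atoms), `donor` and
#'   `acceptor` atom names (first and last bridge atom).
#' @export
make_toy_complex <- function(bridge, element = "C", seed = NULL, jitter = 0) {
  if (is.numeric(bridge) && length(bridge) == 1L) {
    n <- as.integer(bridge)
    if (n < 2L) abort("bridge must have at least 2 atoms")
    links <- tibble(kind = rep("covalent", n - 1L), distance = 1.5)
  } else {
    links <- as_tibble(bridge)
    assert_cols(links, c("kind", "distance"), "bridge spec")
    if (!all(links$kind %in% c("covalent", "hbond", "space"))) {
      abort("bridge link kinds must be covalent, hbond or space")
    }
  }
  if (any(!is.finite(links$distance) | links$distance <= 0)) {
    abort("bridge spec is not geometrically embeddable: distances must be > 0")
  }
  n <- nrow(links) + 1L
  xs <- c(0, cumsum(links$distance))
  with_seed(seed, {
    jx <- if (jitter > 0) rnorm(n, 0, jitter) else numeric(n)
    jy <- if (jitter > 0) rnorm(n, 0, jitter) else numeric(n)
    jz <- if (jitter > 0) rnorm(n, 0, jitter) else numeric(n)
    atoms <- sprintf("A%d", seq_len(n))
    struct <- as_structure(tibble(
      model = 1L, chain = "X", resno = seq_len(n), resname = "BRG",
      atom = atoms, element = element,
      x = xs + jx, y = jy, z = jz, hetero = TRUE
    ), source_id = "toy_complex")
    graph <- tibble(a = atoms[-n], b = atoms[-1L],
                    kind = links$kind, distance = links$distance)
    list(structure = struct, graph = graph,
         donor = atoms[1L], acceptor = atoms[n])
  })
}

#' Free/bound amide peak lists with a planted interface
#'
#' Emulates two-state slow-exchange complex formation observed in an
#' 15N-HSQC: interface residues are displaced by per-residue effect sizes
#' drawn around the given scales, a fraction of them broadens beyond
#' detection, all bound-state intensities drop globally (complex-size
#' broadening) with extra attenuation at the interface, and non-interface
#' residues wander by referencing noise only. Allosteric residues shift
#' (conformational response) but keep interface-free intensity behaviour,
#' which is what lets the interface caller demote them.
#'
#' @param n_residues chain length; residues are numbered 1..n.
#' @param interface integer set of planted direct-contact residues.
#' @param allosteric integer set of planted allosterically responding
#'   residues (disjoint from `interface`).
#' @param csp_effect named numeric `c(H = , N = )` ppm displacement scales
#'   at the interface. Defaults give combined shifts well above the noise.
#' @param allo_effect scale factor applied to `csp_effect` for allosteric
#'   residues.
#' @param broadened_fraction fraction of interface residues whose bound
#'   cross-peak disappears (status `broadened_out`).
#' @param global_attenuation bound-state intensity factor applied to all
#'   residues; `interface_attenuation` is applied on top at the interface.
#' @param noise_sd ppm standard deviation of non-specific shift noise
#'   (applied to both nuclei; the 15N noise is scaled by 5 to keep the
#'   noise isotropic in combined-shift space).
#' @param seed RNG seed.
#' @return list `free`, `bound` (peak-list tibbles) and `truth` (planted
#'   sets and per-residue displacements).
#' @export
make_peaklists <- function(n_residues, interface, allosteric = integer(0),
                           csp_effect = c(H = 0.2, N = 1.0),
                           allo_effect = 0.6,
                           broadened_fraction = 0.3,
                           global_attenuation = 0.6,
                           interface_attenuation = 0.4,
                           noise_sd = 0.02, seed = NULL) {
  interface <- as.integer(interface)
  allosteric <- as.integer(allosteric)
  if (length(intersect(interface, allosteric))) {
    abort("interface and allosteric sets must be disjoint")
  }
  if (n_residues < max(c(interface, allosteric, 1L))) {
    abort("n_residues smaller than the largest planted residue number")
  }
  with_seed(seed, {
    resno <- seq_len(n_residues)
    free <- tibble(
      resno = resno,
      deltaH = runif(n_residues, 7.5, 9.5),
      deltaN = runif(n_residues, 105, 130),
      intensity = runif(n_residues, 0.8, 1.2),
      status = "observed"
    )
    shiftH <- rnorm(n_residues, 0, noise_sd)
    shiftN <- rnorm(n_residues, 0, noise_sd * 5)
    is_int <- resno %in% interface
    is_allo <- resno %in% allosteric
    effH <- abs(rnorm(n_residues, csp_effect[["H"]], csp_effect[["H"]] / 4))
    effN <- abs(rnorm(n_residues, csp_effect[["N"]], csp_effect[["N"]] / 4))
    sgnH <- sample(c(-1, 1), n_residues, replace = TRUE)
    sgnN <- sample(c(-1, 1), n_residues, replace = TRUE)
    shiftH[is_int] <- shiftH[is_int] + (sgnH * effH)[is_int]
    shiftN[is_int] <- shiftN[is_int] + (sgnN * effN)[is_int]
    shiftH[is_allo] <- shiftH[is_allo] + (sgnH * effH * allo_effect)[is_allo]
    shiftN[is_allo] <- shiftN[is_allo] + (sgnN * effN * allo_effect)[is_allo]
    atten <- rep(global_attenuation, n_residues)
    atten[is_int] <- atten[is_int] * interface_attenuation
    n_broad <- round(broadened_fraction * length(interface))
    broad <- if (n_broad > 0) sample(interface, n_broad) else integer(0)
    bound <- mutate(free,
                    deltaH = .data$deltaH + shiftH,
                    deltaN = .data$deltaN + shiftN,
                    intensity = .data$intensity * atten *
                      exp(rnorm(n_residues, 0, 0.05)))
    is_broad <- resno %in% broad
    bound$status[is_broad] <- "broadened_out"
    bound$deltaH[is_broad] <- NA_real_
    bound$deltaN[is_broad] <- NA_real_
    bound$intensity[is_broad] <- NA_real_
    list(free = free, bound = bound,
         truth = list(interface = interface, allosteric = allosteric,
                      broadened = sort(broad),
                      shiftH = shiftH, shiftN = shiftN))
  })
}

#' Synthetic titration series from a forward model plus Gaussian noise
#'
#' @param kind `"morrison"`, `"nernst"` or `"ph_activity"`.
#' @param true_params named list of model parameters: Morrison needs
#'   `Kd`, `dImax`, `Pt` and optionally `n`; Nernst needs `Em` and optionally
#'   `T`; pH-activity needs `pKa_sh`, `pKa_acid`, `pKa_alk`, `A_base`,
#'   `A_sh`.
#' @param x evaluation grid (ligand concentration M, potential mV, or pH).
#' @param noise_sd Gaussian noise standard deviation on y.
#' @param seed RNG seed.
#' @return a titration tibble (attribute `kind`) with the generating
#'   parameters stored in attribute `truth`.
#' @export
make_titration <- function(kind = c("morrison", "nernst", "ph_activity"),
                           true_params, x, noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  p <- true_params
  y <- switch(kind,
    morrison = morrison_curve(x, Kd = p$Kd, dImax = p$dImax, Pt = p$Pt,
                              n = p$n %||% 1),
    nernst = nernst_fraction(x, Em = p$Em, T = p$T %||% 298.15),
    ph_activity = ph_activity(x, pKa_sh = p$pKa_sh, pKa_acid = p$pKa_acid,
                              pKa_alk = p$pKa_alk, A_base = p$A_base,
                              A_sh = p$A_sh %||% 0,
                              shoulder = p$shoulder %||% "multiplicative")
  )
  with_seed(seed, {
    yn <- y + if (noise_sd > 0) rnorm(length(x), 0, noise_sd) else 0
    out <- as_titration(tibble(x = x, y = yn,
                               sigma = rep(max(noise_sd, 0), length(x))), kind)
    attr(out, "truth") <- p
    out
  })
}

#' Rigid-core plus disordered-tail multi-model ensemble
#'
#' Emulates an NMR ensemble of a globular domain with intrinsically
#' disordered termini as a CA trace: a compact seeded self-avoiding core
#' conformation shared by all models up to small jitter, and per-model
#' random-walk tails (3.8 Angstrom virtual CA-CA steps). The result has a
#' low core RMSD and a large, model-variable maximum extent.
#'
#' @param n_models number of models.
#' @param n_res chain length.
#' @param core integer residue range forming the rigid core.
#' @param jitter per-coordinate Gaussian jitter (Angstrom) applied to core
#'   atoms in each model. The default 0.3 gives a core RMSD-to-mean near
#'   0.5 Angstrom, typical of a well-defined NMR core.
#' @param step virtual CA-CA step length, Angstrom.
#' @param seed RNG seed.
#' @return an atom table with `n_models` models (CA atoms only).
#' @export
make_ensemble <- function(n_models = 20, n_res = 153, core = 24:132,
                          jitter = 0.3, step = 3.8, seed = NULL) {
  core <- sort(as.integer(core))
  if (!all(core %in% seq_len(n_res))) abort("core range outside 1..n_res")
  with_seed(seed, {
    core_xyz <- compact_walk(length(core), step = step,
                             radius = max(10, 1.2 * step * length(core)^(1/3)))
    n_head <- min(core) - 1L
    n_tail <- n_res - max(core)
    models <- map(seq_len(n_models), function(m) {
      xyz <- matrix(NA_real_, n_res, 3L)
      xyz[core, ] <- core_xyz + matrix(rnorm(3L * length(core), 0, jitter),
                                       ncol = 3L)
      if (n_head > 0) {
        head_walk <- free_walk(n_head, start = xyz[min(core), ], step = step,
                               avoid = xyz[core, , drop = FALSE])
        xyz[rev(seq_len(n_head)), ] <- head_walk
      }
      if (n_tail > 0) {
        tail_walk <- free_walk(n_tail, start = xyz[max(core), ], step = step,
                               avoid = xyz[core, , drop = FALSE])
        xyz[max(core) + seq_len(n_tail), ] <- tail_walk
      }
      tibble(model = m, chain = "A", resno = seq_len(n_res), resname = "ALA",
             atom = "CA", element = "C",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], hetero = FALSE)
    })
    as_structure(bind_rows(models), source_id = "synthetic_ensemble")
  })
}

# compact self-avoiding walk confined to a sphere (CA-trace core stand-in)
compact_walk <- function(n, step, radius, min_sep = 3.0, max_try = 200L) {
  xyz <- matrix(0, n, 3L)
  for (i in seq_len(n)[-1]) {
    for (k in seq_len(max_try)) {
      dir <- rnorm(3L)
      cand <- xyz[i - 1L, ] + step * dir / sqrt(sum(dir^2))
      if (sqrt(sum(cand^2)) > radius) next
      if (i > 2L) {
        prev <- xyz[seq_len(i - 2L), , drop = FALSE]
        d2 <- rowSums((prev - matrix(cand, i - 2L, 3L, byrow = TRUE))^2)
        if (any(d2 < min_sep^2)) next
      }
      xyz[i, ] <- cand
      break
    }
    if (k == max_try) xyz[i, ] <- cand  # accept last candidate; stay robust
  }
  xyz - matrix(colMeans(xyz), n, 3L, byrow = TRUE)
}

# outward random walk avoiding a fixed atom set (disordered tail)
free_walk <- function(n, start, step, avoid, min_sep = 3.0, max_try = 50L) {
  out <- matrix(NA_real_, n, 3L)
  prev <- start
  for (i in seq_len(n)) {
    for (k in seq_len(max_try)) {
      dir <- rnorm(3L)
      cand <- prev + step * dir / sqrt(sum(dir^2))
      d2 <- rowSums((avoid - matrix(cand, nrow(avoid), 3L, byrow = TRUE))^2)
      if (all(d2 >= min_sep^2)) break
    }
    out[i, ] <- cand
    prev <- cand
  }
  out
}

#' Synthetic small-angle scattering profile
#'
#' Guinier-Porod profile: the low-q region follows
#' `I(q) = I0 exp(-q^2 Rg^2 / 3)` exactly, crossing over to a `q^-4` Porod
#' decay at `q1 = sqrt(6)/Rg` with continuous intensity.
#'
#' @param Rg_true radius of gyration, Angstrom (> 0).
#' @param I0 forward scattering.
#' @param q momentum-transfer grid, 1/Angstrom, strictly increasing.
#' @param noise_sd relative Gaussian noise level (0 = noise-free).
#' @param seed RNG seed.
#' @return a SAXS tibble; generating parameters in attribute `truth`.
#' @export
make_saxs <- function(Rg_true, I0 = 1, q = seq(0.005, 0.5, by = 0.005),
                      noise_sd = 0, seed = NULL) {
  assert_scalar_num(Rg_true, "Rg_true", positive = TRUE)
  q1 <- sqrt(6) / Rg_true
  guinier <- I0 * exp(-q^2 * Rg_true^2 / 3)
  B <- I0 * exp(-q1^2 * Rg_true^2 / 3) * q1^4
  I <- ifelse(q <= q1, guinier, B / q^4)
  with_seed(seed, {
    if (noise_sd > 0) I <- I * (1 + rnorm(length(q), 0, noise_sd))
    out <- as_saxs(tibble(q = q, I = I, sigma = pmax(noise_sd, 1e-12) * abs(I)))
    attr(out, "truth") <- list(Rg = Rg_true, I0 = I0)
    out
  })
}
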