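#' Run the end-to-end interface-to-pathway analysis
#'
#' Orchestrates the two-stage complex characterisation on a set of inputs:
#' CSP computation and interface calling from free/bound peak lists,
#' optional titration fits, coupling-based scoring of a docking pose
#' ensemble, selection of the best pose, extraction of unambiguous
#' restraints from it, and restraint-based filtering of the ensemble with
#' before/after heterogeneity statistics. Machine-readable stage outputs
#' and a run manifest (package version, seed, config hash) are written to
#' `out_dir`; the run is deterministic given (inputs, config, seed).
#'
#' @param config a list with elements:
#'   * `free`, `bound`: peak-list tibbles or file paths (required)
#'   * `titrations`: optional named list; elements `morrison` (list with
#'     `series`, `Pt`), `nernst` (list with `series`), `ph` (list with
#'     `series`)
#'   * `poses`: optional named list of complex atom tables (or a directory
#'     of PDB files), with `donor`, `acceptor` selector lists,
#'     `ligand_chain`, `receptor_chain`, and optional `restraint_pairs`
#'     data frame for [extract_unambiguous_restraints()]
#'   * `out_dir`: output directory (required)
#'   * `seed`: integer seed for all stochastic steps (default 1)
#'   * `n_boot`: bootstrap resamples for fits (default 200)
#' @return a list with `csp_summary`, `interface`, `fits`, `pose_scores`,
#'   `restraints`, `filtered`, `manifest` (invisibly also written to disk).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) abort("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  n_boot <- config$n_boot %||% 200L
  log_stage <- function(...) inform(paste0("[pipeline] ", sprintf(...)))
  load_peaks <- function(x) if (is.character(x)) read_peaklist(x) else validate_peaklist(x)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- CSP and interface ----------------------------------------------------
  log_stage("csp")
  free <- stage("csp", load_peaks(config$free %||% abort("config$free is required")))
  bound <- stage("csp", load_peaks(config$bound %||% abort("config$bound is required")))
  csp <- stage("csp", compute_csp(free, bound))
  summary <- stage("csp", classify_csp(csp))
  readr::write_csv(summary$table, file.path(config$out_dir, "csp_table.csv"))
  log_stage("interface")
  iface <- stage("interface", call_interface(summary, structure = config$structure))

  # --- optional titration fits ----------------------------------------------
  fits <- list()
  tt <- config$titrations
  if (!is.null(tt$morrison)) {
    log_stage("fit morrison")
    fits$morrison <- stage("fit_morrison",
      fit_morrison(tt$morrison$series, Pt = tt$morrison$Pt,
                   n_boot = n_boot, seed = seed))
  }
  if (!is.null(tt$nernst)) {
    log_stage("fit nernst")
    fits$nernst <- stage("fit_nernst",
      fit_nernst(tt$nernst$series, n_boot = n_boot, seed = seed))
  }
  if (!is.null(tt$ph)) {
    log_stage("fit ph_activity")
    fits$ph <- stage("fit_ph_activity",
      fit_ph_activity(tt$ph$series, n_boot = n_boot, seed = seed))
  }

  # --- pose stages ----------------------------------------------------------
  pose_scores <- NULL; restraints <- NULL; filtered <- NULL
  pc <- config$poses
  if (is.null(pc) || is.null(pc$poses)) {
    log_stage("pose stages skipped (no pose ensemble in config)")
  } else {
    poses <- pc$poses
    if (is.character(poses)) {
      files <- sort(list.files(poses, pattern = "\\.pdb$", full.names = TRUE))
      poses <- setNames(map(files, read_structure),
                        sub("\\.pdb$", "", basename(files)))
    }
    log_stage("score %d poses", length(poses))
    pose_scores <- stage("score_poses",
      score_poses(poses, pc$donor, pc$acceptor,
                  params = pc$params %||% pathway_params()))
    readr::write_csv(select(pose_scores, -"path"),
                     file.path(config$out_dir, "pose_scores.csv"))
    best_id <- pose_scores$pose_id[1]
    best_pose <- poses[[best_id]]
    log_stage("best pose: %s (T_DA = %.3e)", best_id, pose_scores$T_DA[1])
    consistency <- stage("contacts_vs_csp",
      contacts_vs_csp(best_pose, pc$ligand_chain, pc$receptor_chain,
                      iface$direct_contact, iface$allosteric_candidates))
    if (!is.null(pc$restraint_pairs)) {
      log_stage("extract unambiguous restraints")
      restraints <- stage("restraints",
        extract_unambiguous_restraints(best_pose, pc$restraint_pairs,
                                       tol = pc$tol %||% 1.0))
      write_restraints(restraints,
                       file.path(config$out_dir, "unambiguous.tbl"))
      log_stage("filter ensemble by restraints")
      checks <- stage("filter", check_restraints(poses, restraints))
      keep <- checks$pose_id[checks$satisfied]
      filtered <- list(
        checks = checks,
        kept = keep,
        spread_before = pose_spread(poses, pc$ligand_chain,
                                    pc$receptor_chain),
        spread_after = if (length(keep) >= 2) {
          pose_spread(poses[keep], pc$ligand_chain, pc$receptor_chain)
        } else 0
      )
      readr::write_csv(checks, file.path(config$out_dir, "restraint_checks.csv"))
    }
    attr(pose_scores, "consistency") <- consistency
  }

  manifest <- list(
    package = "etbridge",
    version = as.character(utils::packageVersion("etbridge")),
    seed = seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    stages = c("csp", "interface", names(fits),
               if (!is.null(pose_scores)) c("score_poses", "restraints"))
  )
  results <- list(csp_summary = summary, interface = iface, fits = fits,
                  pose_scores = pose_scores, restraints = restraints,
                  filtered = filtered, manifest = manifest)
  jsonlite::write_json(
    list(manifest = manifest,
         interface = iface[c("direct_contact", "allosteric_candidates")],
         sd = summary$sd,
         fits = map(fits, function(f) f$params),
         best_pose = if (!is.null(pose_scores)) pose_scores$pose_id[1],
         kept_poses = filtered$kept),
    file.path(config$out_dir, "results.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(results)
}

# ligand positional heterogeneity across poses: receptors are superposed,
# then the rmsd of ligand atoms around their across-pose mean is averaged
pose_spread <- function(poses, ligand_chain, receptor_chain) {
  ref <- poses[[1]]
  aligned <- map(poses, function(p) {
    superpose(p, ref, list(chain = receptor_chain))$transformed
  })
  # only ligand atoms present in every pose enter the spread
  keys <- map(aligned, function(p) {
    q <- p[p$chain %in% ligand_chain, ]
    paste(q$chain, q$resno, q$atom)
  })
  common <- Reduce(intersect, keys)
  if (!length(common)) abort("poses share no ligand atoms")
  lig <- map(aligned, function(p) {
    q <- p[p$chain %in% ligand_chain, ]
    coords_matrix(q[match(common, paste(q$chain, q$resno, q$atom)), ])
  })
  mean_lig <- Reduce(`+`, lig) / length(lig)
  mean(map_dbl(lig, function(m) sqrt(mean(rowSums((m - mean_lig)^2)))))
}
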