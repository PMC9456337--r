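#' Per-residue chemical-shift perturbations between free and bound states
#'
#' Computes generalized amide chemical-shift differences between a free and
#' a ligand-saturated peak list. The combined shift is the geometric
#' distance in (1H, 15N) space with the 15N axis compressed by `hn_weight`
#' (1H shifts weighted `hn_weight`-fold relative to 15N):
#' `combined = sqrt(dH^2 + (dN / hn_weight)^2)`.
#'
#' Residues observed free but undetectable in the bound state are reported
#' with status `broadened_out` and an undefined combined shift; they are
#' never dropped, since disappearance beyond the detection limit is itself
#' interface evidence. The intensity ratio is `I_free / I_bound` where both
#' states are observed.
#'
#' @param free,bound peak-list tibbles (see [read_peaklist()]).
#' @param hn_weight 1H-vs-15N weighting factor (default 5).
#' @return tibble with columns `resno`, `deltaH`, `deltaN`, `combined`,
#'   `intensity_ratio`, `status`.
#' @export
compute_csp <- function(free, bound, hn_weight = 5) {
  free <- validate_peaklist(free)
  bound <- validate_peaklist(bound)
  assert_scalar_num(hn_weight, "hn_weight", positive = TRUE)
  common <- intersect(free$resno, bound$resno)
  if (!length(common)) abort("free and bound peak lists share no residues")
  f <- free[match(common, free$resno), ]
  b <- bound[match(common, bound$resno), ]
  status <- dplyr::case_when(
    f$status == "unassigned" | b$status == "unassigned" ~ "unassigned",
    f$status == "observed" & b$status == "broadened_out" ~ "broadened_out",
    f$status == "observed" & b$status == "observed" ~ "observed",
    TRUE ~ "unassigned"
  )
  dH <- b$deltaH - f$deltaH
  dN <- b$deltaN - f$deltaN
  combined <- sqrt(dH^2 + (dN / hn_weight)^2)
  ratio <- f$intensity / b$intensity
  obs <- status == "observed"
  tibble(
    resno = common,
    deltaH = ifelse(obs, dH, NA_real_),
    deltaN = ifelse(obs, dN, NA_real_),
    combined = ifelse(obs, combined, NA_real_),
    intensity_ratio = ifelse(obs, ratio, NA_real_),
    status = status
  )
}

#' Classify CSP magnitudes against the ensemble standard deviation
#'
#' Residues are binned against the standard deviation (SD) of the combined
#' shifts over observed residues and against SD/2: `above_sd`,
#' `sd_half_to_sd`, `below_half_sd`; residues broadened beyond detection
#' form their own `broadened` class. A median-absolute-deviation threshold
#' is available but plain SD is the default, which on typical amide
#' perturbation sets lands near 0.1 ppm.
#'
#' @param records CSP tibble from [compute_csp()].
#' @param method `"sd"` (default) or `"mad"` (scaled MAD) for the
#'   classification threshold.
#' @return a `csp_summary` object: list with `table` (records plus `class`
#'   column), `sd`, `half_sd`, `mean_intensity_ratio`, `method`.
#' @export
classify_csp <- function(records, method = c("sd", "mad")) {
  method <- match.arg(method)
  assert_cols(records, c("resno", "combined", "intensity_ratio", "status"),
              "CSP records")
  obs <- records$status == "observed"
  if (sum(obs) < 5L) abort("classify_csp needs at least 5 observed residues")
  s <- if (method == "sd") sd(records$combined[obs]) else mad(records$combined[obs])
  if (s == 0) warn("classify_csp: zero spread in combined shifts; all residues classified below_half_sd")
  cls <- dplyr::case_when(
    records$status == "broadened_out" ~ "broadened",
    records$status == "unassigned" ~ "unassigned",
    s > 0 & records$combined > s ~ "above_sd",
    s > 0 & records$combined > s / 2 ~ "sd_half_to_sd",
    TRUE ~ "below_half_sd"
  )
  out <- list(
    table = mutate(as_tibble(records), class = cls),
    sd = s,
    half_sd = s / 2,
    mean_intensity_ratio = mean(records$intensity_ratio[obs], na.rm = TRUE),
    method = method
  )
  class(out) <- "csp_summary"
  out
}

#' @export
print.csp_summary <- function(x, ...) {
  cat(sprintf("CSP summary (%s threshold): SD = %.4f ppm, SD/2 = %.4f ppm\n",
              x$method, x$sd, x$half_sd))
  cat(sprintf("mean intensity ratio (I_free/I_bound): %.3f\n",
              x$mean_intensity_ratio))
  print(table(x$table$class))
  invisible(x)
}

#' Call the direct-contact interface from classified CSPs
#'
#' Direct-contact candidates are contiguous runs (gaps up to
#' `contiguity_window` residues) of residues classified `above_sd` or
#' `broadened`. Runs whose observed members show no elevation of the
#' intensity ratio relative to the ensemble mean are demoted to allosteric
#' candidates: genuine contact residues suffer extra line broadening in the
#' complex, so a large shift without an intensity-ratio elevation points to
#' a conformational response transmitted from the interface instead. When a
#' structure is supplied, runs whose residues are predominantly buried
#' (relative side-chain-level SASA below `sasa_threshold`) are likewise
#' demoted, since a buried residue cannot form the contact surface.
#'
#' @param summary a `csp_summary`.
#' @param structure optional atom table used for the burial check (first
#'   model is used).
#' @param contiguity_window maximum gap (residues) bridged within a run.
#' @param ratio_margin multiplicative elevation over the mean intensity
#'   ratio required to keep a run as direct contact.
#' @param sasa_threshold relative per-residue SASA below which a residue
#'   counts as buried.
#' @return list with integer vectors `direct_contact` and
#'   `allosteric_candidates`, plus the run table in `runs`.
#' @export
call_interface <- function(summary, structure = NULL, contiguity_window = 3,
                           ratio_margin = 1.2, sasa_threshold = 0.15) {
  stopifnot(inherits(summary, "csp_summary"))
  tab <- summary$table
  hits <- sort(tab$resno[tab$class %in% c("above_sd", "broadened")])
  if (!length(hits)) {
    return(list(direct_contact = integer(0),
                allosteric_candidates = integer(0),
                runs = tibble(start = integer(0), end = integer(0),
                              demoted = logical(0))))
  }
  run_id <- cumsum(c(1L, diff(hits) > contiguity_window))
  rel_sasa <- if (!is.null(structure)) residue_relative_sasa(structure) else NULL
  runs <- map(split(hits, run_id), function(rs) {
    members <- tab[tab$resno %in% rs, ]
    ratios <- members$intensity_ratio[members$status == "observed"]
    broad_frac <- mean(members$class == "broadened")
    # broadened-out members are maximal intensity loss: count them as elevated
    elevated <- broad_frac > 0 ||
      (length(ratios) > 0 &&
         median(ratios) > ratio_margin * summary$mean_intensity_ratio)
    buried <- FALSE
    if (!is.null(rel_sasa)) {
      rs_sasa <- rel_sasa$rel_sasa[match(rs, rel_sasa$resno)]
      rs_sasa <- rs_sasa[!is.na(rs_sasa)]
      buried <- length(rs_sasa) > 0 && median(rs_sasa) < sasa_threshold
    }
    tibble(start = min(rs), end = max(rs),
           n = length(rs), broadened_fraction = broad_frac,
           demoted = !elevated || buried,
           members = list(rs))
  })
  runs <- bind_rows(runs)
  direct <- sort(unlist(runs$members[!runs$demoted]))
  # member-level pruning: a residue merged into a contact run stays only if
  # it is broadened, strongly shifted (>= 2 SD), or intensity-elevated itself
  if (length(direct)) {
    mem <- tab[match(direct, tab$resno), ]
    keep_mem <- mem$class == "broadened" |
      (!is.na(mem$combined) & mem$combined >= 2 * summary$sd) |
      (!is.na(mem$intensity_ratio) &
         mem$intensity_ratio > ratio_margin * summary$mean_intensity_ratio)
    pruned <- direct[!keep_mem]
    direct <- direct[keep_mem]
  } else {
    pruned <- integer(0)
  }
  allo <- sort(unique(c(unlist(runs$members[runs$demoted]), pruned)))
  list(direct_contact = as.integer(direct %||% integer(0)),
       allosteric_candidates = as.integer(allo %||% integer(0)),
       runs = select(runs, -"members"))
}

# per-residue SASA relative to an extended reference, first model only
residue_relative_sasa <- function(structure, probe = 1.4, n_points = 120) {
  s1 <- structure[structure$model == min(structure$model) & !structure$hetero, ]
  sa <- sasa(s1, probe = probe, n_points = n_points)
  per_res <- summarise(group_by(sa, .data$resno),
                       area = sum(.data$area), .groups = "drop")
  # reference: same atoms isolated (fully exposed)
  iso <- summarise(group_by(sa, .data$resno),
                   ref = sum(4 * pi * (.data$radius + probe)^2),
                   .groups = "drop")
  out <- left_join(per_res, iso, by = "resno")
  mutate(out, rel_sasa = .data$area / .data$ref)
}
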