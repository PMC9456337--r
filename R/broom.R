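#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn fit_morrison tidy method: one row per fitted parameter with
#'   bootstrap interval.
#' @param x a `titration_fit`.
#' @param ... unused.
#' @method tidy titration_fit
#' @export
tidy.titration_fit <- function(x, ...) {
  if (!length(x$params)) return(tibble(term = character(0)))
  est <- tibble(term = names(x$params),
                estimate = map_dbl(x$params, ~ as.numeric(.x)[1]))
  if (nrow(x$ci)) left_join(est, x$ci, by = "term") else est
}

#' @describeIn fit_morrison glance method: one-row fit summary.
#' @method glance titration_fit
#' @export
glance.titration_fit <- function(x, ...) {
  tibble(kind = x$kind, converged = x$converged,
         residual_norm = x$residual_norm, n = nrow(x$data),
         seed = x$seed)
}

#' @describeIn classify_csp tidy method: the per-residue classified table.
#' @param x a `csp_summary`.
#' @param ... unused.
#' @method tidy csp_summary
#' @export
tidy.csp_summary <- function(x, ...) x$table

#' @describeIn classify_csp glance method: thresholds and class counts.
#' @method glance csp_summary
#' @export
glance.csp_summary <- function(x, ...) {
  tab <- table(x$table$class)
  tibble(sd = x$sd, half_sd = x$half_sd,
         mean_intensity_ratio = x$mean_intensity_ratio,
         n_observed = sum(x$table$status == "observed"),
         n_above_sd = sum(x$table$class == "above_sd"),
         n_broadened = sum(x$table$class == "broadened"),
         method = x$method)
}

#' @describeIn guinier_fit glance method: one-row summary.
#' @param x a `guinier_result`.
#' @param ... unused.
#' @method glance guinier_result
#' @export
glance.guinier_result <- function(x, ...) {
  tibble(Rg = x$Rg, I0 = x$I0, n_points = x$n_points,
         qmaxRg = x$qmaxRg, residual = x$residual)
}

#' @describeIn ensemble_stats tidy method: the per-residue RMSD profile.
#' @param x an `ensemble_stats`.
#' @param ... unused.
#' @method tidy ensemble_stats
#' @export
tidy.ensemble_stats <- function(x, ...) x$per_residue_rmsd

#' @describeIn ensemble_stats glance method: one-row ensemble summary.
#' @method glance ensemble_stats
#' @export
glance.ensemble_stats <- function(x, ...) {
  tibble(n_models = x$n_models, mean_core_rmsd = x$mean_core_rmsd,
         mean_pairwise_core_rmsd = x$mean_pairwise_core_rmsd,
         dmax_ensemble = x$dmax_ensemble)
}
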