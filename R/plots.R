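#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_line geom_hline
#'   geom_vline labs theme_minimal autoplot scale_y_log10
#' @export
ggplot2::autoplot

#' CSP histogram with SD and SD/2 threshold lines
#'
#' Per-residue combined chemical-shift perturbations; the dashed lines mark
#' the classification thresholds, and residues broadened beyond detection
#' are drawn as ticks at the top of the panel.
#'
#' @param object a `csp_summary`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot csp_summary
#' @export
autoplot.csp_summary <- function(object, ...) {
  tab <- object$table
  broad <- tab[tab$class == "broadened", ]
  ymax <- max(tab$combined, na.rm = TRUE)
  p <- ggplot(tab[!is.na(tab$combined), ],
              aes(x = .data$resno, y = .data$combined, fill = .data$class)) +
    geom_col(width = 0.8) +
    geom_hline(yintercept = object$sd, linetype = "dashed", colour = "red") +
    geom_hline(yintercept = object$half_sd, linetype = "dashed",
               colour = "orange") +
    labs(x = "residue", y = "combined shift (ppm)",
         title = "chemical-shift perturbation") +
    theme_minimal()
  if (nrow(broad)) {
    p <- p + geom_point(data = mutate(broad, combined = ymax * 1.05),
                        aes(x = .data$resno, y = .data$combined),
                        inherit.aes = FALSE, shape = 8)
  }
  p
}

#' Titration data with the fitted model curve
#'
#' @param object a `titration_fit`.
#' @param n_grid evaluation points for the fitted curve.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot titration_fit
#' @export
autoplot.titration_fit <- function(object, n_grid = 200, ...) {
  d <- object$data
  p <- ggplot(d, aes(x = .data$x, y = .data$y)) + geom_point() +
    theme_minimal()
  if (object$converged) {
    grid <- tibble(x = seq(min(d$x), max(d$x), length.out = n_grid))
    grid$y <- predict(object$fit, newdata = grid)
    p <- p + geom_line(data = grid, colour = "steelblue")
  }
  lab <- switch(object$kind,
                morrison = c("total ligand (M)", "signal change"),
                nernst = c("potential (mV)", "reduced fraction"),
                ph_activity = c("pH", "activity"))
  p + labs(x = lab[1], y = lab[2], title = sprintf("%s fit", object$kind))
}

#' Scattering profile with the Guinier window highlighted
#'
#' @param profile SAXS tibble.
#' @param guinier optional `guinier_result`; its fit window is marked.
#' @return a ggplot (log-intensity scale).
#' @export
plot_saxs <- function(profile, guinier = NULL) {
  p <- ggplot(as_tibble(profile), aes(x = .data$q, y = .data$I)) +
    geom_point(size = 0.8) + scale_y_log10() +
    labs(x = "q (1/A)", y = "I(q)") + theme_minimal()
  if (!is.null(guinier)) {
    p <- p + geom_vline(xintercept = guinier$q_range, linetype = "dotted")
  }
  p
}

#' Per-residue RMSD profile of an ensemble
#'
#' @param object an `ensemble_stats`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ensemble_stats
#' @export
autoplot.ensemble_stats <- function(object, ...) {
  ggplot(object$per_residue_rmsd, aes(x = .data$resno, y = .data$rmsd)) +
    geom_line() +
    labs(x = "residue", y = "RMSD to mean (A)",
         title = "per-residue ensemble RMSD") +
    theme_minimal()
}

#' Coupling versus pose index
#'
#' @param scores a pose-score tibble from [score_poses()].
#' @return a ggplot of `T_DA` by ranked pose.
#' @export
plot_pose_scores <- function(scores) {
  d <- mutate(as_tibble(scores), rank = row_number())
  ggplot(d, aes(x = .data$rank, y = pmax(.data$T_DA, 1e-12))) +
    geom_point() + scale_y_log10() +
    labs(x = "pose (ranked)", y = "T_DA") + theme_minimal()
}
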