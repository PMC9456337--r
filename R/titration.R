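#' Morrison tight-binding isotherm
#'
#' Quadratic-root binding isotherm, valid when ligand depletion matters
#' (dissociation constant comparable to the concentrations used):
#' `dI_obs = dImax * (nPt + Lt + Kd - sqrt((nPt + Lt + Kd)^2 - 4 nPt Lt)) / (2 nPt)`.
#' The curve is continuous, monotone non-decreasing in `Lt`, and saturates
#' at `dImax`. The discriminant is clamped at zero as a numerical guard
#' (it is non-negative for valid inputs).
#'
#' @param Lt total titrant (ligand) concentration, M; vectorized.
#' @param Kd dissociation constant, M (> 0).
#' @param dImax maximum signal change at saturation (> 0).
#' @param Pt total observed-protein concentration, M (> 0).
#' @param n binding sites per titrant molecule (default 1).
#' @return signal change at each `Lt`.
#' @export
morrison_curve <- function(Lt, Kd, dImax, Pt, n = 1) {
  assert_scalar_num(Kd, "Kd", positive = TRUE)
  assert_scalar_num(dImax, "dImax", positive = TRUE)
  assert_scalar_num(Pt, "Pt", positive = TRUE)
  assert_scalar_num(n, "n", positive = TRUE)
  s <- n * Pt + Lt + Kd
  disc <- pmax(s^2 - 4 * n * Pt * Lt, 0)
  dImax * (s - sqrt(disc)) / (2 * n * Pt)
}

#' One-electron Nernst reduced fraction
#'
#' `f_red(E) = 1 / (1 + 10^((E - Em)/s))` with slope
#' `s = ln(10) R T / F` in mV (59.16 mV at 298.15 K); a single-electron
#' redox centre titrating around midpoint potential `Em`.
#'
#' @param E applied potential, mV; vectorized.
#' @param Em midpoint potential, mV.
#' @param T temperature, K.
#' @return reduced fraction in (0, 1).
#' @export
nernst_fraction <- function(E, Em, T = 298.15) {
  assert_scalar_num(T, "T", positive = TRUE)
  s <- nernst_slope_mV(T)
  1 / (1 + 10^((E - Em) / s))
}

nernst_slope_mV <- function(T) log(10) * 8.314462618 * T / 96485.33212 * 1000

#' Bell-shaped pH-activity model with an acidic shoulder equilibrium
#'
#' The base profile is the classic two-pKa bell
#' `Phi(pH) = 1 / (1 + 10^(pKa_acid - pH) + 10^(pH - pKa_alk))` attributed
#' to essential protonatable catalytic groups. The acidic shoulder is
#' modelled as an extra activity component tied to protonation of a
#' partner-protein group (a histidine-like site),
#' `theta_sh(pH) = 1 / (1 + 10^(pH - pKa_sh))`. By default the shoulder
#' multiplies the bell amplitude, `A = (A_base + A_sh * theta_sh) * Phi`;
#' the additive variant `A = A_base * Phi + A_sh * theta_sh` is provided.
#' With `A_sh = 0` both reduce to the plain bell.
#'
#' @param pH pH values; vectorized.
#' @param pKa_sh,pKa_acid,pKa_alk shoulder, acidic-limb and alkaline-limb
#'   pKa values (must be ordered `pKa_sh < pKa_acid < pKa_alk`).
#' @param A_base activity scale of the bell.
#' @param A_sh shoulder amplitude (0 disables the shoulder).
#' @param shoulder `"multiplicative"` (default) or `"additive"`.
#' @return modelled activity.
#' @export
ph_activity <- function(pH, pKa_sh, pKa_acid, pKa_alk, A_base, A_sh = 0,
                        shoulder = c("multiplicative", "additive")) {
  shoulder <- match.arg(shoulder)
  if (!(pKa_sh < pKa_acid && pKa_acid < pKa_alk)) {
    abort("require pKa_sh < pKa_acid < pKa_alk")
  }
  ph_activity_raw(pH, pKa_sh, pKa_acid, pKa_alk, A_base, A_sh, shoulder)
}

# unvalidated evaluation; used inside optimizer steps where intermediate
# parameter vectors may transiently violate the pKa ordering
ph_activity_raw <- function(pH, pKa_sh, pKa_acid, pKa_alk, A_base, A_sh,
                            shoulder = "multiplicative") {
  theta <- 1 / (1 + 10^(pH - pKa_sh))
  phi <- 1 / (1 + 10^(pKa_acid - pH) + 10^(pH - pKa_alk))
  if (shoulder == "multiplicative") (A_base + A_sh * theta) * phi
  else A_base * phi + A_sh * theta
}

# ---- fitting ---------------------------------------------------------------

new_titration_fit <- function(kind, fit, data, params, ci, converged, seed,
                              extra = list()) {
  res <- if (converged) residuals(fit) else rep(NA_real_, nrow(data))
  out <- c(list(kind = kind, params = params, ci = ci,
                residual_norm = if (converged) sqrt(sum(res^2)) else NA_real_,
                converged = converged, data = data, fit = fit, seed = seed),
           extra)
  class(out) <- "titration_fit"
  out
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s)\n", x$kind,
              if (x$converged) "converged" else "NOT converged"))
  for (nm in names(x$params)) {
    ci <- x$ci[x$ci$term == nm, ]
    if (nrow(ci)) {
      cat(sprintf("  %-8s %.6g  [%.6g, %.6g]\n", nm, x$params[[nm]],
                  ci$conf.low, ci$conf.high))
    } else {
      cat(sprintf("  %-8s %.6g\n", nm, x$params[[nm]]))
    }
  }
  if (!is.na(x$residual_norm)) {
    cat(sprintf("  residual norm: %.4g\n", x$residual_norm))
  }
  invisible(x)
}

# residual-bootstrap confidence intervals for an nls-type refitting closure
bootstrap_ci <- function(data, fitted_y, resid, refit, n_boot, seed,
                         level = 0.95) {
  draws <- with_seed(seed, {
    map(seq_len(n_boot), function(b) {
      yb <- fitted_y + sample(resid, length(resid), replace = TRUE)
      tryCatch(refit(yb), error = function(e) NULL)
    })
  })
  draws <- keep(draws, ~ !is.null(.x))
  if (!length(draws)) return(tibble(term = character(0)))
  mat <- do.call(rbind, draws)
  a <- (1 - level) / 2
  tibble(term = colnames(mat),
         conf.low = apply(mat, 2L, quantile, probs = a, na.rm = TRUE),
         conf.high = apply(mat, 2L, quantile, probs = 1 - a, na.rm = TRUE))
}

clamp_ci <- function(ci, params) {
  # bootstrap intervals must bracket the point estimate
  if (!nrow(ci)) return(ci)
  est <- unlist(params)[ci$term]
  mutate(ci, conf.low = pmin(.data$conf.low, est),
         conf.high = pmax(.data$conf.high, est))
}

#' Fit the Morrison isotherm to a binding titration
#'
#' Least-squares fit of `Kd` and `dImax` (and optionally the site number
#' `n`) with seeded residual-bootstrap confidence intervals. The site
#' number defaults to fixed `n = 1`, appropriate when saturation is reached
#' near a 1:1 molar ratio; set `fit_n = TRUE` to estimate it.
#'
#' @param series titration tibble (`x` = total ligand concentration M,
#'   `y` = signal change).
#' @param Pt total observed-protein concentration, M.
#' @param fix_n fixed site number when `fit_n = FALSE`.
#' @param fit_n estimate `n` as a free parameter.
#' @param n_boot bootstrap resamples (0 skips interval estimation).
#' @param seed bootstrap seed.
#' @return a `titration_fit`.
#' @export
fit_morrison <- function(series, Pt, fix_n = 1, fit_n = FALSE,
                         n_boot = 500, seed = 1) {
  d <- as_tibble(series)
  assert_cols(d, c("x", "y"), "titration")
  if (nrow(d) < 5L) abort("fit_morrison needs at least 5 points")
  assert_scalar_num(Pt, "Pt", positive = TRUE)
  start <- list(lKd = log(max(Pt, 1e-9)), dImax = max(d$y))
  if (fit_n) start$n <- fix_n
  form <- if (fit_n) {
    y ~ morrison_curve(x, Kd = exp(lKd), dImax = dImax, Pt = Pt, n = n)
  } else {
    y ~ morrison_curve(x, Kd = exp(lKd), dImax = dImax, Pt = Pt, n = fix_n)
  }
  do_fit <- function(dd) {
    minpack.lm::nlsLM(form, data = dd, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- tryCatch(do_fit(d), error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_titration_fit("morrison", fit, d, list(), tibble(term = character(0)),
                             FALSE, seed,
                             extra = list(diagnostics = conditionMessage(fit))))
  }
  cf <- coef(fit)
  params <- list(Kd = unname(exp(cf[["lKd"]])), dImax = unname(cf[["dImax"]]),
                 n = if (fit_n) unname(cf[["n"]]) else fix_n, Pt = Pt)
  ci <- tibble(term = character(0))
  if (n_boot > 0) {
    fy <- predict(fit)
    rs <- residuals(fit)
    ci <- bootstrap_ci(d, fy, rs, function(yb) {
      f <- minpack.lm::nlsLM(form, data = mutate(d, y = yb), start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      cb <- coef(f)
      out <- c(Kd = unname(exp(cb[["lKd"]])), dImax = unname(cb[["dImax"]]))
      if (fit_n) out <- c(out, n = unname(cb[["n"]]))
      out
    }, n_boot, seed)
    ci <- clamp_ci(ci, params)
  }
  new_titration_fit("morrison", fit, d, params, ci, TRUE, seed)
}

#' Fit a one-electron Nernst curve to a redox titration
#'
#' @param series titration tibble (`x` = potential mV, `y` = reduced
#'   fraction, expected in `[0, 1]`).
#' @param T temperature, K (fixed; the slope is not fitted).
#' @param n_boot,seed residual-bootstrap settings.
#' @return a `titration_fit` with parameter `Em` (mV).
#' @export
fit_nernst <- function(series, T = 298.15, n_boot = 500, seed = 1) {
  d <- as_tibble(series)
  assert_cols(d, c("x", "y"), "titration")
  if (any(d$y < -0.05 | d$y > 1.05)) {
    warn("fit_nernst: y outside [0, 1]; expected a reduced fraction")
  }
  if (diff(range(d$y)) < 1e-3) {
    return(new_titration_fit("nernst", NULL, d, list(), tibble(term = character(0)),
                             FALSE, seed, extra = list(diagnostics = "flat series")))
  }
  start <- list(Em = d$x[which.min(abs(d$y - 0.5))])
  form <- y ~ nernst_fraction(x, Em = Em, T = T)
  fit <- tryCatch(minpack.lm::nlsLM(form, data = d, start = start),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_titration_fit("nernst", fit, d, list(), tibble(term = character(0)),
                             FALSE, seed,
                             extra = list(diagnostics = conditionMessage(fit))))
  }
  params <- list(Em = unname(coef(fit)[["Em"]]), T = T)
  ci <- tibble(term = character(0))
  if (n_boot > 0) {
    ci <- bootstrap_ci(d, predict(fit), residuals(fit), function(yb) {
      c(Em = unname(coef(minpack.lm::nlsLM(form, data = mutate(d, y = yb),
                                           start = start))[["Em"]]))
    }, n_boot, seed)
    ci <- clamp_ci(ci, params)
  }
  new_titration_fit("nernst", fit, d, params, ci, TRUE, seed)
}

#' Fit the pH-activity model with an acidic shoulder
#'
#' Fits `pKa_sh`, `pKa_acid`, `pKa_alk`, `A_base` and `A_sh`. When the
#' bootstrap interval of `A_sh` spans zero the shoulder is flagged as
#' non-identifiable (`shoulder_identifiable = FALSE`); fitting a plain-bell
#' dataset should produce exactly that flag.
#'
#' @param series titration tibble (`x` = pH, `y` = activity).
#' @param shoulder `"multiplicative"` or `"additive"` shoulder form.
#' @param start optional named list of starting values.
#' @param n_boot,seed residual-bootstrap settings.
#' @return a `titration_fit`.
#' @export
fit_ph_activity <- function(series, shoulder = c("multiplicative", "additive"),
                            start = NULL, n_boot = 500, seed = 1) {
  shoulder <- match.arg(shoulder)
  d <- as_tibble(series)
  assert_cols(d, c("x", "y"), "titration")
  if (nrow(d) < 6L) abort("fit_ph_activity needs at least 6 points")
  # the acid pKa plus strictly positive offsets keeps the three equilibria
  # ordered (pKa_sh = pKa_acid - d_sh, pKa_alk = pKa_acid + d_alk) and
  # prevents label swapping between the shoulder and the alkaline limb
  start <- start %||% list(pKa_acid = d$x[which.max(d$y)] - 1,
                           d_sh = 2, d_alk = 2,
                           A_base = max(d$y) * 2, A_sh = max(d$y) * 0.1)
  # offsets are bounded by the measured pH window: a shoulder (or alkaline
  # limb) located outside the data cannot be identified and would otherwise
  # drift to absorb baseline noise
  span <- diff(range(d$x))
  lower <- c(pKa_acid = 0, d_sh = 0.1, d_alk = 0.1, A_base = 0, A_sh = 0)
  upper <- c(pKa_acid = 14, d_sh = span, d_alk = span, A_base = Inf,
             A_sh = Inf)
  do_fit <- function(dd) {
    # multi-start over shoulder placements; among solutions with
    # statistically indistinguishable residuals, prefer one whose shoulder
    # offset sits in the interior of the window (a d_sh pinned at its bound
    # marks the degenerate valley where the shoulder has left the data)
    cands <- list()
    for (d_sh0 in c(1, 2, 3)) {
      for (ash0 in c(0.05, 0.3) * max(dd$y)) {
        st <- start
        st$d_sh <- d_sh0
        st$A_sh <- ash0
        f <- tryCatch(ph_lm_fit(dd, st, lower, upper, shoulder),
                      error = function(e) NULL)
        if (!is.null(f)) cands[[length(cands) + 1L]] <- f
      }
    }
    if (!length(cands)) abort("no start converged")
    rss <- map_dbl(cands, ~ sum(residuals(.x)^2))
    interior <- map_lgl(cands, function(f) {
      d_sh <- f$par[["d_sh"]]
      d_sh > lower[["d_sh"]] + 1e-6 && d_sh < upper[["d_sh"]] - 1e-6
    })
    ok <- interior & rss <= 1.05 * min(rss)
    pick <- if (any(ok)) which(ok)[which.min(rss[ok])] else which.min(rss)
    cands[[pick]]
  }
  fit <- tryCatch(do_fit(d), error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_titration_fit("ph_activity", fit, d, list(),
                             tibble(term = character(0)), FALSE, seed,
                             extra = list(diagnostics = conditionMessage(fit))))
  }
  to_params <- function(cf) {
    c(pKa_sh = unname(cf[["pKa_acid"]] - cf[["d_sh"]]),
      pKa_acid = unname(cf[["pKa_acid"]]),
      pKa_alk = unname(cf[["pKa_acid"]] + cf[["d_alk"]]),
      A_base = unname(cf[["A_base"]]), A_sh = unname(cf[["A_sh"]]))
  }
  params <- as.list(to_params(coef(fit)))
  # shoulder support: F-test of the full model against the plain bell
  # (the shoulder amplitude alone is degenerate with the bell amplitude
  # when pKa_sh crowds pKa_acid, so interval coverage of A_sh is not enough)
  bell_fit <- tryCatch(
    ph_lm_fit(d, c(start[c("pKa_acid", "d_alk", "A_base")],
                   list(d_sh = 2, A_sh = 0)),
              c(lower[c("pKa_acid", "d_alk", "A_base")],
                d_sh = 2, A_sh = 0),
              upper, shoulder, fixed = c("d_sh", "A_sh")),
    error = function(e) NULL)
  shoulder_p <- NA_real_
  if (!is.null(bell_fit)) {
    rss1 <- sum(residuals(fit)^2)
    rss0 <- sum(residuals(bell_fit)^2)
    df2 <- nrow(d) - 5L
    f_stat <- ((rss0 - rss1) / 2) / (rss1 / df2)
    shoulder_p <- stats::pf(f_stat, 2, df2, lower.tail = FALSE)
  }
  ci <- tibble(term = character(0))
  identifiable <- NA
  if (n_boot > 0) {
    ci <- bootstrap_ci(d, predict(fit), residuals(fit), function(yb) {
      to_params(coef(do_fit(mutate(d, y = yb))))
    }, n_boot, seed)
    ci <- clamp_ci(ci, params)
    ash <- ci[ci$term == "A_sh", ]
    scale_y <- max(abs(d$y))
    if (nrow(ash)) {
      identifiable <- ash$conf.low > 1e-3 * scale_y &&
        (!is.na(shoulder_p) && shoulder_p < 0.05)
    }
  }
  new_titration_fit("ph_activity", fit, d, params, ci, TRUE, seed,
                    extra = list(shoulder = shoulder,
                                 shoulder_identifiable = identifiable,
                                 shoulder_p = shoulder_p))
}

# direct Levenberg-Marquardt fit of the pH-activity model in the ordered
# (pKa_acid, d_sh, d_alk, A_base, A_sh) parametrization; avoids the nls
# object construction, which rejects the near-degenerate Jacobian that a
# weak shoulder legitimately produces
ph_lm_fit <- function(d, start, lower, upper, shoulder,
                      fixed = character(0)) {
  all_names <- c("pKa_acid", "d_sh", "d_alk", "A_base", "A_sh")
  start <- unlist(start)[all_names]
  free <- setdiff(all_names, fixed)
  fn <- function(p_free) {
    p <- start
    p[free] <- p_free
    d$y - ph_activity_raw(d$x,
                          pKa_sh = p[["pKa_acid"]] - p[["d_sh"]],
                          pKa_acid = p[["pKa_acid"]],
                          pKa_alk = p[["pKa_acid"]] + p[["d_alk"]],
                          A_base = p[["A_base"]], A_sh = p[["A_sh"]],
                          shoulder = shoulder)
  }
  res <- suppressWarnings(
    minpack.lm::nls.lm(par = start[free], fn = fn,
                       lower = unlist(lower)[all_names][free],
                       upper = unlist(upper)[all_names][free],
                       control = minpack.lm::nls.lm.control(maxiter = 1000)))
  # info 0 = improper input; stalled iterations (info 5) are kept and
  # resolved by the multi-start lowest-residual selection
  if (res$info == 0L) abort("improper LM input")
  par <- start
  par[free] <- res$par
  structure(list(par = par, data = d, shoulder = shoulder,
                 info = res$info, n_free = length(free)),
            class = "ph_fit")
}

#' @export
coef.ph_fit <- function(object, ...) object$par

#' @export
predict.ph_fit <- function(object, newdata = NULL, ...) {
  x <- (newdata %||% object$data)$x
  p <- object$par
  ph_activity_raw(x, pKa_sh = p[["pKa_acid"]] - p[["d_sh"]],
                  pKa_acid = p[["pKa_acid"]],
                  pKa_alk = p[["pKa_acid"]] + p[["d_alk"]],
                  A_base = p[["A_base"]], A_sh = p[["A_sh"]],
                  shoulder = object$shoulder)
}

#' @export
residuals.ph_fit <- function(object, ...) object$data$y - predict(object)
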