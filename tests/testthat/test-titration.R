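test_that("Morrison curve: limits, monotonicity, quadratic-root oracle", {
  # no ligand, no signal
  expect_equal(morrison_curve(0, Kd = 2e-6, dImax = 1, Pt = 1e-5), 0)

  # tight-binding limit Kd -> 0: dI = dImax * min(Lt, nPt) / nPt
  Lt <- seq(0, 3e-5, length.out = 13)
  tight <- morrison_curve(Lt, Kd = 1e-15, dImax = 2, Pt = 1e-5)
  expect_equal(tight, 2 * pmin(Lt, 1e-5) / 1e-5, tolerance = 1e-4)

  # independent oracle: dI/dImax * nPt solves x^2 - (nPt+Lt+Kd) x + nPt Lt = 0
  # (smaller root), evaluated with polyroot
  pars <- list(nPt = 1e-6, Lt = 1e-6, Kd = 2e-6)
  x <- min(Re(polyroot(c(pars$nPt * pars$Lt, -(pars$nPt + pars$Lt + pars$Kd), 1))))
  expect_equal(morrison_curve(1e-6, Kd = 2e-6, dImax = 1, Pt = 1e-6),
               x / 1e-6)

  # monotone and bounded by dImax over random valid parameter draws
  withr::with_seed(5, {
    for (i in 1:20) {
      Kd <- 10^runif(1, -8, -4); Pt <- 10^runif(1, -7, -4)
      dImax <- runif(1, 0.5, 5); n <- sample(1:2, 1)
      y <- morrison_curve(seq(0, 20 * n * Pt, length.out = 50), Kd, dImax, Pt, n)
      expect_true(all(diff(y) >= -1e-12))
      expect_true(all(y <= dImax + 1e-12))
    }
  })
})

test_that("Morrison fit recovers Kd exactly at zero noise and robustly with noise", {
  Pt <- 1e-5
  tt <- make_titration("morrison", list(Kd = 2e-6, dImax = 1, Pt = Pt),
                       x = c(seq(0, 2e-5, 2e-6), seq(2.5e-5, 6e-5, 1e-5)))
  fit <- fit_morrison(tt, Pt = Pt, n_boot = 50, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$params$Kd, 2e-6, tolerance = 1e-6)
  expect_equal(fit$params$dImax, 1, tolerance = 1e-6)
  # CI brackets the estimate (for bootstrapped parameters)
  td <- tidy(fit)
  td <- td[!is.na(td$conf.low), ]
  expect_gt(nrow(td), 0)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  # saturation: fitted curve tends to dImax at large Lt
  expect_equal(morrison_curve(1e-2, fit$params$Kd, fit$params$dImax, Pt),
               fit$params$dImax, tolerance = 1e-3)

  kds <- purrr::map_dbl(1:30, function(s) {
    noisy <- make_titration("morrison", list(Kd = 2e-6, dImax = 1, Pt = Pt),
                            x = tt$x, noise_sd = 0.05, seed = s)
    fit_morrison(noisy, Pt = Pt, n_boot = 0)$params$Kd
  })
  expect_lt(abs(median(kds) - 2e-6) / 2e-6, 0.2)
})

test_that("Nernst fraction: midpoint, slope point and symmetry", {
  expect_equal(nernst_fraction(162.1, Em = 162.1), 0.5)
  s <- log(10) * 8.314462618 * 298.15 / 96485.33212 * 1000
  expect_equal(s, 59.159, tolerance = 1e-4)
  # one decade below the midpoint: 10/11 reduced
  expect_equal(nernst_fraction(162.1 - s, Em = 162.1), 10 / 11)
  # symmetry f(Em + x) + f(Em - x) = 1
  x <- seq(-120, 120, 7.5)
  expect_equal(nernst_fraction(162.1 + x, 162.1) +
                 nernst_fraction(162.1 - x, 162.1), rep(1, length(x)))
})

test_that("Nernst fit recovers the midpoint and flags flat series", {
  tt <- make_titration("nernst", list(Em = 162.1), x = seq(40, 290, 12.5))
  fit <- fit_nernst(tt, n_boot = 50, seed = 2)
  expect_true(fit$converged)
  expect_equal(fit$params$Em, 162.1, tolerance = 1e-6)

  flat <- as_titration(tibble::tibble(x = seq(100, 200, 10), y = 0.5), "nernst")
  ff <- fit_nernst(flat, n_boot = 0)
  expect_false(ff$converged)
  expect_match(ff$diagnostics, "flat")
})

test_that("pH-activity model: closed forms, limits and shoulder behaviour", {
  # plain bell at pH = pKa_acid
  bell_at_acid <- ph_activity(8.5, pKa_sh = 6.7, pKa_acid = 8.5,
                              pKa_alk = 10.5, A_base = 1, A_sh = 0)
  expect_equal(bell_at_acid, 1 / (1 + 1 + 10^(8.5 - 10.5)))
  # far below the shoulder pKa the protonated fraction saturates
  theta_low <- ph_activity(2, 6.7, 8.5, 10.5, A_base = 0, A_sh = 1,
                           shoulder = "additive")
  expect_equal(theta_low, 1 / (1 + 10^(2 - 6.7)))
  expect_gt(theta_low, 0.9999)
  # the shoulder adds acidic-side activity relative to the plain bell
  with_sh <- ph_activity(7, 6.7, 8.5, 10.5, A_base = 1, A_sh = 0.5)
  without <- ph_activity(7, 6.7, 8.5, 10.5, A_base = 1, A_sh = 0)
  expect_gt(with_sh, without)
  expect_error(ph_activity(7, 8.5, 6.7, 10.5, 1), "pKa_sh < pKa_acid")
})

test_that("pH-activity fit recovers all three pKa values at zero noise", {
  truth <- list(pKa_sh = 6.7, pKa_acid = 8.5, pKa_alk = 10.5,
                A_base = 10, A_sh = 2)
  tt <- make_titration("ph_activity", truth, x = seq(5.5, 12, 0.25))
  fit <- fit_ph_activity(tt, n_boot = 50, seed = 3)
  expect_true(fit$converged)
  expect_equal(fit$params$pKa_sh, 6.7, tolerance = 1e-3)
  expect_equal(fit$params$pKa_acid, 8.5, tolerance = 1e-3)
  expect_equal(fit$params$pKa_alk, 10.5, tolerance = 1e-3)
  expect_true(fit$shoulder_identifiable)
})

test_that("fitting a plain bell flags the shoulder as non-identifiable", {
  truth <- list(pKa_sh = 6.0, pKa_acid = 8.5, pKa_alk = 10.5,
                A_base = 10, A_sh = 0)
  tt <- make_titration("ph_activity", truth, x = seq(5.5, 12, 0.25),
                       noise_sd = 0.05, seed = 4)
  fit <- fit_ph_activity(tt, n_boot = 100, seed = 4)
  expect_true(fit$converged)
  expect_false(fit$shoulder_identifiable)
})

test_that("headline-parameter recovery is nearly unbiased over noisy replicates", {
  # 30 replicates per model at the reference ground-truth values
  Pt <- 1e-5
  x_m <- c(seq(0, 2e-5, 2e-6), seq(2.5e-5, 6e-5, 1e-5))
  kd <- purrr::map_dbl(1:30, ~ fit_morrison(
    make_titration("morrison", list(Kd = 2e-6, dImax = 1, Pt = Pt),
                   x = x_m, noise_sd = 0.03, seed = .x),
    Pt = Pt, n_boot = 0)$params$Kd)
  expect_lt(abs(mean(kd) - 2e-6) / 2e-6, 0.05)

  em <- purrr::map_dbl(1:30, ~ fit_nernst(
    make_titration("nernst", list(Em = 162.1), x = seq(40, 290, 12.5),
                   noise_sd = 0.02, seed = .x), n_boot = 0)$params$Em)
  expect_lt(abs(mean(em) - 162.1) / 162.1, 0.05)

  pks <- purrr::map_dbl(1:30, ~ fit_ph_activity(
    make_titration("ph_activity",
                   list(pKa_sh = 6.7, pKa_acid = 8.5, pKa_alk = 10.5,
                        A_base = 10, A_sh = 2),
                   x = seq(5.5, 12, 0.25), noise_sd = 0.02, seed = .x),
    n_boot = 0)$params$pKa_sh)
  expect_lt(abs(mean(pks) - 6.7) / 6.7, 0.05)
})

test_that("tidy/glance methods expose estimates and fit diagnostics", {
  tt <- make_titration("nernst", list(Em = 150), x = seq(50, 250, 10),
                       noise_sd = 0.01, seed = 5)
  fit <- fit_nernst(tt, n_boot = 20, seed = 5)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in%
                    names(tidy(fit))))
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$kind, "nernst")
  expect_equal(g$n, nrow(tt))
})
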