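test_that("the lifetime transform reproduces its closed-form hand evaluation", {
  h <- tibble::tibble(bin_center = c(5.5, 6.5), count = c(60L, 40L),
                      density = c(0.6, 0.4), loading_rate = c(1, 1))
  attr(h, "bin_width") <- 1
  attr(h, "n") <- 100L
  class(h) <- c("unfolding_histogram", class(h))
  lc <- histogram_to_lifetimes(h)
  expect_equal(lc$lifetime, c(0.7 / 0.6, 0.5), tolerance = 1e-12)

  # single occupied bin degenerates to dF / (2 Fdot)
  h1 <- h[1, ]
  h1$density <- 1
  h1$count <- 100L
  attr(h1, "bin_width") <- 1
  class(h1) <- c("unfolding_histogram", class(h1))
  expect_equal(histogram_to_lifetimes(h1)$lifetime, 0.5)

  hbad <- h
  hbad$density <- hbad$density * 2
  expect_error(histogram_to_lifetimes(hbad),
               class = "tweezfold_validation_error")
})

test_that("the transform tracks Bell lifetimes within 5% on resolvable bins", {
  tau0 <- 1e3
  dx <- 5
  rf <- simulate_rupture_forces(
    domain_spec("d", unfold_tau0 = tau0, unfold_dx = dx, delta_lc = 30),
    loading_rate = 1, n = 1e5, seed = 17, dt = 0.002)
  ev <- tibble::tibble(direction = "unfold",
                       rupture_force = rf$rupture_force, loading_rate = 1)
  lc <- histogram_to_lifetimes(unfolding_histogram(ev, bin_width = 0.5))
  tau_true <- tau0 * exp(-lc$force * dx / kBT())
  ok <- lc$count >= 100 & lc$lifetime >= 1 # resolvable: tau >= 2 dF/Fdot
  expect_gt(sum(ok), 8)
  expect_lt(max(abs(lc$lifetime[ok] / tau_true[ok] - 1)), 0.05)
})

test_that("a noiseless Bell curve is recovered essentially exactly", {
  curve <- make_bell_curve(1.3e3, 4.5)
  fit <- fit_lifetimes(curve, "bell", n_boot = 0)
  expect_equal(fit$tau0, 1.3e3, tolerance = 1e-8)
  expect_equal(fit$dx_ddagger, 4.5, tolerance = 1e-8)

  # refolding role: force opposes folding, lifetimes grow with force
  curve_u <- make_bell_curve(0.05, 7, role = "U->F")
  expect_true(all(diff(curve_u$lifetime) > 0))
  fit_u <- fit_lifetimes(curve_u, "bell", n_boot = 0)
  expect_equal(fit_u$tau0, 0.05, tolerance = 1e-8)
  expect_equal(fit_u$dx_ddagger, 7, tolerance = 1e-8)

  expect_error(fit_lifetimes(curve[1:3, ], n_boot = 0),
               class = "tweezfold_invalid_input")
})

test_that("Bell parameters are recovered within bootstrap CIs across replicates", {
  tau0 <- 1.3e3
  dx <- 4.5
  dom <- make_apo_domain()
  n_rep <- 20
  hits <- matrix(FALSE, n_rep, 2)
  for (r in seq_len(n_rep)) {
    rf <- simulate_rupture_forces(dom, 1, 1000, seed = 200 + r, dt = 0.005)
    ev <- tibble::tibble(direction = "unfold",
                         rupture_force = rf$rupture_force, loading_rate = 1)
    lc <- histogram_to_lifetimes(unfolding_histogram(ev, bin_width = 0.75))
    fit <- tryCatch(fit_lifetimes(lc, "bell", n_boot = 200, seed = r),
                    error = function(e) NULL)
    if (is.null(fit)) next
    td <- tidy(fit)
    hits[r, 1] <- td$conf.low[1] <= tau0 && tau0 <= td$conf.high[1]
    hits[r, 2] <- td$conf.low[2] <= dx && dx <= td$conf.high[2]
  }
  expect_gte(mean(hits[, 1]), 0.8)
  expect_gte(mean(hits[, 2]), 0.8)
})

test_that("Bell fits of DHS-generated lifetimes carry a systematic tau0 bias", {
  kT <- kBT()
  dhs <- kinetic_params(1e3, 4, dg_ddagger = 20, nu = 1 / 2)
  f <- seq(4, 10, by = 0.75)
  curve <- tibble::tibble(force = f, lifetime = lifetime_at(dhs, f),
                          count = 1000, loading_rate = 1e4)
  attr(curve, "role") <- "F->U"
  attr(curve, "bin_width") <- 0.75
  class(curve) <- c("lifetime_curve", class(curve))
  bell <- fit_lifetimes(curve, "bell", n_boot = 0)
  # cusp-model log-lifetimes are convex in force, so a straight-line Bell
  # extrapolation from a finite force window lands below the true tau0
  expect_gt(abs(bell$tau0 - 1e3), 100)
  expect_lt(bell$tau0, 1e3)

  # nesting: DHS with nu = 1 collapses to the Bell fit
  curve_b <- make_bell_curve(1.3e3, 4.5)
  fit_b <- fit_lifetimes(curve_b, "bell", n_boot = 0)
  fit_d1 <- fit_lifetimes(curve_b, "dhs", nu = 1, n_boot = 0)
  expect_equal(fit_d1$tau0, fit_b$tau0, tolerance = 1e-4)
  expect_equal(fit_d1$dx_ddagger, fit_b$dx_ddagger, tolerance = 1e-4)

  # DHS self-recovery
  curve_d <- tibble::tibble(force = seq(3, 10, by = 0.5),
                            lifetime = lifetime_at(dhs, seq(3, 10, by = 0.5)),
                            count = 1000, loading_rate = 1e4)
  attr(curve_d, "role") <- "F->U"
  attr(curve_d, "bin_width") <- 0.5
  class(curve_d) <- c("lifetime_curve", class(curve_d))
  fit_d <- fit_lifetimes(curve_d, "dhs", nu = 1 / 2, n_boot = 0)
  expect_equal(fit_d$tau0, 1e3, tolerance = 0.02)
  expect_equal(fit_d$dx_ddagger, 4, tolerance = 0.02)

  # force beyond the DHS critical force is a domain error
  expect_error(lifetime_at(dhs, 1e4), class = "tweezfold_domain_error")
})

test_that("reconstructed rupture-force densities normalize and peak correctly", {
  kT <- kBT()
  params <- kinetic_params(1.3e3, 4.5)
  p <- reconstruct_force_distribution(params, 1, seq(0, 30, by = 0.01))
  expect_equal(sum(p$density) * 0.01, 1, tolerance = 1e-3)
  mode_analytic <- (kT / 4.5) * log(1 * 4.5 * 1.3e3 / kT)
  expect_equal(mode_analytic, 6.5, tolerance = 0.05)
  expect_equal(p$force[which.max(p$density)], mode_analytic,
               tolerance = 0.01 / mode_analytic + 1e-3)
})

test_that("the closed loop reconstruct -> sample -> transform -> fit holds to 3%", {
  tau0 <- 1.3e3
  dx <- 4.5
  dens <- bell_rupture_density(tau0, dx, 1, grid = seq(0, 25, by = 0.005))
  dF <- 0.005
  cdf <- cumsum(dens$density) * dF
  inc <- c(TRUE, diff(cdf) > 0) # drop the flat saturated tail
  set.seed(99)
  u <- runif(1e5) * max(cdf)
  samples <- approx(cdf[inc], dens$force[inc], xout = u, rule = 2)$y
  ev <- tibble::tibble(direction = "unfold", rupture_force = samples,
                       loading_rate = 1)
  lc <- histogram_to_lifetimes(unfolding_histogram(ev, bin_width = 0.25))
  fit <- fit_lifetimes(lc, "bell", n_boot = 0)
  expect_equal(fit$tau0, tau0, tolerance = 0.03)
  expect_equal(fit$dx_ddagger, dx, tolerance = 0.03)
})

test_that("lifetimes are monotone in force with the correct sign per role", {
  curve <- make_bell_curve(1.3e3, 4.5, forces = seq(2, 12, by = 0.5))
  expect_true(all(diff(curve$lifetime) < 0))
  fit <- fit_lifetimes(curve, n_boot = 0)
  grid <- seq(0.5, 15, by = 0.5)
  expect_true(all(diff(lifetime_at(fit, grid)) < 0))
  fit_u <- fit_lifetimes(make_bell_curve(0.05, 7, role = "U->F"), n_boot = 0)
  expect_true(all(diff(lifetime_at(fit_u, grid)) > 0))
})
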