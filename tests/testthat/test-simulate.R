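test_that("invalid protocols and domains are rejected", {
  expect_error(pulling_protocol(pull_velocity = -1),
               class = "tweezfold_invalid_protocol")
  expect_error(pulling_protocol(min_force = 10, max_force = 5),
               class = "tweezfold_invalid_protocol")
  expect_error(domain_spec("x", unfold_tau0 = -1, unfold_dx = 4,
                           delta_lc = 10),
               class = "tweezfold_invalid_protocol")
  expect_error(domain_spec("x", unfold_tau0 = 10, unfold_dx = 4,
                           n_residues = 5, d_nc = 10),
               class = "tweezfold_invalid_protocol")
  expect_error(simulate_force_clamp(make_hopper(), 11, duration = -1),
               class = "tweezfold_invalid_parameter")
  expect_error(simulate_force_clamp(make_hopper(), 11, 1, noise_sd = -1),
               class = "tweezfold_invalid_parameter")
})

test_that("zero unfolding hazard yields smooth monotone curves and no events", {
  dom <- domain_spec("inert", unfold_tau0 = Inf, unfold_dx = 4.5,
                     delta_lc = 30)
  sim <- simulate_force_ramp(dom, pulling_protocol(), n_cycles = 2, seed = 1)
  expect_equal(nrow(sim$ground_truth), 0)
  st <- sim$trace[sim$trace$segment == "stretch" & sim$trace$cycle_id == 1, ]
  expect_true(all(diff(st$force) > 0))
  expect_true(all(diff(st$extension) > 0))
  expect_equal(nrow(detect_rips(sim$trace)), 0)
})

test_that("mean rupture force at constant loading rate matches the quadrature oracle", {
  dom <- make_apo_domain()
  rf <- simulate_rupture_forces(dom, loading_rate = 1, n = 5000, seed = 7,
                                dt = 0.005)
  dens <- bell_rupture_density(1.3e3, 4.5, 1)
  dF <- diff(dens$force[1:2])
  m_oracle <- sum(dens$force * dens$density) * dF
  se <- sd(rf$rupture_force) / sqrt(nrow(rf))
  expect_lt(abs(mean(rf$rupture_force) - m_oracle), 2 * se)
})

test_that("rupture forces follow the Bell-Evans density (chi-square, 20 bins)", {
  dom <- make_apo_domain()
  rf <- simulate_rupture_forces(dom, loading_rate = 1, n = 5000, seed = 3,
                                dt = 0.005)
  dens <- bell_rupture_density(1.3e3, 4.5, 1)
  breaks <- quantile(rf$rupture_force, probs = seq(0, 1, length.out = 21))
  breaks[1] <- 0; breaks[21] <- 40
  obs <- table(cut(rf$rupture_force, breaks))
  cdf_at <- approxfun(dens$force, cumsum(dens$density) * diff(dens$force[1:2]),
                      rule = 2)
  p_exp <- diff(cdf_at(breaks))
  p_exp <- p_exp / sum(p_exp)
  stat <- sum((as.numeric(obs) - 5000 * p_exp)^2 / (5000 * p_exp))
  expect_gt(pchisq(stat, df = 19, lower.tail = FALSE), 0.01)
})

test_that("folded-state survival under constant force is exponential (KS)", {
  # balanced hopper at 11 pN: folded dwells are Exp(1 / tau_F(11))
  dom <- make_hopper(tau_hop = 0.02)
  sim <- simulate_force_clamp(dom, 11, duration = 250, sample_rate = 200,
                              seed = 5)
  dw <- sim$ground_truth$dwells
  folded <- dw$duration[dw$state == "folded" & !dw$censored]
  expect_gt(length(folded), 4500)
  ks <- suppressWarnings(ks.test(folded, "pexp", rate = 1 / 0.02))
  expect_lt(unname(ks$statistic), 0.02)
  expect_gt(ks$p.value, 0.01)
})

test_that("noiseless clamp trace is an exact two-level telegraph", {
  dom <- make_hopper(delta_lc = 13, tau_hop = 0.1)
  sim <- simulate_force_clamp(dom, 11, duration = 30, sample_rate = 500,
                              noise_sd = 0, seed = 2)
  lv <- sort(unique(sim$trace$extension))
  expect_length(lv, 2)
  xi <- frac_extension_at(11, wlc_params(0.65))
  expect_equal(diff(lv), 13 * xi, tolerance = 1e-12)
  expect_gt(length(sim$ground_truth$transitions), 20)
})

test_that("empirical dwell means and occupancy match the generating rates", {
  # 1/tau_F = 1/tau_U = 5 per second
  dom <- make_hopper(tau_hop = 0.2)
  sim <- simulate_force_clamp(dom, 11, duration = 200, sample_rate = 100,
                              seed = 11)
  dw <- sim$ground_truth$dwells
  for (s in c("folded", "unfolded")) {
    d <- dw$duration[dw$state == s & !dw$censored]
    expect_equal(mean(d), 0.2, tolerance = 0.1)
  }
  # at tau_F = tau_U occupancy is 1/2 up to sampling error
  expect_equal(mean(sim$ground_truth$states$state), 0.5, tolerance = 0.05)
})

test_that("titration counts hit the trivial limits and the partition function", {
  bm <- binding_model(K_A = 17, K_B = 10, gamma = 3)
  z <- simulate_titration_counts(bm, 0, 500, seed = 1)
  expect_equal(z$n_A0B0, 500)
  sat <- simulate_titration_counts(bm, 1e6, 500, seed = 1)
  expect_gt(sat$n_A1B1 / 500, 0.99)
  big <- simulate_titration_counts(bm, 10, 1e5, seed = 2)
  expected <- 1e5 * c(0.230, 0.135, 0.230, 0.405)
  counts <- as.numeric(big[1, c("n_A0B0", "n_A1B0", "n_A0B1", "n_A1B1")])
  se <- sqrt(expected * (1 - expected / 1e5))
  expect_true(all(abs(counts - expected) < 3 * se + 1e5 * 5e-4))
  expect_error(simulate_titration_counts(bm, -1, 10),
               class = "tweezfold_invalid_input")
})

test_that("identical seeds reproduce bit-identical simulations", {
  dom <- make_domain()
  a <- simulate_force_ramp(dom, n_cycles = 2, seed = 9, noise_sd = 1)
  b <- simulate_force_ramp(dom, n_cycles = 2, seed = 9, noise_sd = 1)
  expect_identical(a$trace$extension, b$trace$extension)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_force_ramp(dom, n_cycles = 2, seed = 10, noise_sd = 1)
  expect_false(identical(a$trace$extension, c$trace$extension))

  s1 <- simulate_force_clamp(make_hopper(), 11, 5, seed = 4, noise_sd = 1)
  s2 <- simulate_force_clamp(make_hopper(), 11, 5, seed = 4, noise_sd = 1)
  expect_identical(s1$trace$extension, s2$trace$extension)
})

test_that("extension jumps only at true events while force stays bounded", {
  dom <- make_domain(delta_lc = 30)
  sim <- simulate_force_ramp(dom, n_cycles = 4, seed = 21, noise_sd = 0)
  tr <- sim$trace
  gt <- sim$ground_truth
  for (cyc in 1:4) {
    st <- tr[tr$cycle_id == cyc & tr$segment == "stretch", ]
    jumps <- which(abs(diff(st$extension)) > 5)
    ev <- gt$time[gt$cycle_id == cyc & gt$segment == "stretch"]
    # every big extension jump coincides with a true event (within 2 samples)
    for (j in jumps) {
      expect_true(any(abs(st$time[j] - ev) < 2 / 200))
    }
    # force is finite and within the protocol's working range
    expect_true(all(st$force > 0 & st$force < 30))
  }
})
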