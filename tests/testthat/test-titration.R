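paper_model <- binding_model(K_A = 17, K_B = 10, gamma = 3)

test_that("species fractions match the partition function and its limits", {
  f0 <- species_fractions(paper_model, 0)
  expect_equal(as.numeric(f0[1, -1]), c(1, 0, 0, 0))

  f10 <- species_fractions(paper_model, 10)
  expect_equal(as.numeric(f10[1, -1]), c(0.230, 0.135, 0.230, 0.405),
               tolerance = 0.001 / 0.135)

  # independence limit: gamma = 1, K_A = K_B factorizes into isotherms
  ind <- binding_model(K_A = 20, K_B = 20, gamma = 1)
  L <- c(2, 20, 200)
  fr <- species_fractions(ind, L)
  p <- L / (L + 20)
  expect_equal(fr$f_A0B0, (1 - p)^2, tolerance = 1e-12)
  expect_equal(fr$f_A1B0, p * (1 - p), tolerance = 1e-12)
  expect_equal(fr$f_A1B1, p^2, tolerance = 1e-12)

  expect_error(species_fractions(paper_model, -1),
               class = "tweezfold_invalid_input")
})

test_that("fractions sum to one, are monotone, and close the thermodynamic cycle", {
  L <- 10^seq(-2, 5, length.out = 120)
  fr <- species_fractions(paper_model, L)
  expect_lt(max(abs(rowSums(fr[, -1]) - 1)), 1e-12)
  expect_true(all(diff(fr$f_A1B1) > 0))
  expect_true(all(diff(fr$f_A0B0) < 0))

  # detailed balance: K_A * (K_B/gamma) equals K_B * (K_A/gamma)
  m <- paper_model
  path_via_A <- m$K_A * (m$K_B / m$gamma)
  path_via_B <- m$K_B * (m$K_A / m$gamma)
  expect_lt(abs(path_via_A - path_via_B), 1e-12)
})

test_that("liganded-state classification follows the decision cascade", {
  # fully bound: reversible hopping transition present
  hop_ev <- tibble::tibble(
    direction = c("unfold", "refold", "unfold", "unfold", "unfold"),
    rupture_force = c(10.8, 10.5, 11.2, 16.5, 19.8),
    delta_lc = c(13.2, 12.5, 12.8, 50.2, 30.1),
    reversible = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(classify_trajectory(hop_ev), "A1B1")

  # cAMP-bound CNB-A without N3A: the ~30 nm fingerprint
  a1b0 <- tibble::tibble(direction = c("unfold", "unfold"),
                         rupture_force = c(8.1, 14.2),
                         delta_lc = c(50.5, 29.8),
                         reversible = FALSE)
  expect_equal(classify_trajectory(a1b0), "A1B0")

  # CNB-B bound: elevated-force CNB-A with folded N3A + apo-force CNB-B
  a0b1 <- tibble::tibble(direction = c("unfold", "unfold"),
                         rupture_force = c(8.4, 12.6),
                         delta_lc = c(50.1, 45.3),
                         reversible = FALSE)
  expect_equal(classify_trajectory(a0b1), "A0B1")

  # apo: two full-length rips in the 7-9 pN window
  a0b0 <- tibble::tibble(direction = c("unfold", "unfold"),
                         rupture_force = c(7.4, 8.9),
                         delta_lc = c(45.2, 50.4),
                         reversible = FALSE)
  expect_equal(classify_trajectory(a0b0), "A0B0")

  expect_equal(classify_trajectory(a0b0[0, ]), "unclassified")
  odd <- tibble::tibble(direction = "unfold", rupture_force = 25,
                        delta_lc = 70, reversible = FALSE)
  expect_equal(classify_trajectory(odd), "unclassified")
})

test_that("simulated cycles classify to their generating liganded state", {
  proto <- pulling_protocol(pull_velocity = 25, sample_rate = 1000)
  # A1B1: hopping N3A + stabilized domains
  hop <- make_hopper(delta_lc = 13, f_hop = 11, tau_hop = 0.07, dx = 3)
  cnbb_holo <- domain_spec("CNB-B", unfold_tau0 = 3e4, unfold_dx = 2.2,
                           refold_tau0 = 0.05, refold_dx = 7, delta_lc = 50)
  sim <- simulate_force_ramp(list(hop, cnbb_holo), proto, n_cycles = 2,
                             seed = 61, noise_sd = 1)
  rips <- detect_rips(sim$trace)
  cls <- vapply(split(rips, rips$cycle_id), classify_trajectory,
                character(1))
  expect_true(all(cls == "A1B1"))

  # A1B0: 30 nm CNB-A rip at elevated force + apo CNB-B, no hopping
  cnba_camp <- make_domain(delta_lc = 30, tau0 = 1e4, dx = 2.5,
                           name = "CNB-A")
  cnbb_apo <- make_apo_domain(delta_lc = 50, name = "CNB-B")
  sim2 <- simulate_force_ramp(list(cnba_camp, cnbb_apo),
                              pulling_protocol(), n_cycles = 3, seed = 62,
                              noise_sd = 1)
  rips2 <- detect_rips(sim2$trace)
  stretch2 <- rips2[rips2$segment == "stretch", ]
  cls2 <- vapply(split(stretch2, stretch2$cycle_id), classify_trajectory,
                 character(1))
  expect_true(all(cls2 == "A1B0"))
})

test_that("the global multinomial fit is consistent on plug-in counts", {
  conc <- 10^seq(0, log10(150), length.out = 12)
  fr <- species_fractions(paper_model, conc)
  counts <- tibble::tibble(
    conc_nM = conc,
    n_A0B0 = round(1e6 * fr$f_A0B0), n_A1B0 = round(1e6 * fr$f_A1B0),
    n_A0B1 = round(1e6 * fr$f_A0B1), n_A1B1 = round(1e6 * fr$f_A1B1))
  fit <- fit_global(counts, ci = "none")
  expect_equal(fit$model$K_A, 17, tolerance = 5e-4)
  expect_equal(fit$model$K_B, 10, tolerance = 5e-4)
  expect_equal(fit$model$gamma, 3, tolerance = 5e-4)
})

test_that("Wald intervals cover the generating parameters across replicates", {
  conc <- 10^seq(0, log10(150), length.out = 12)
  n_rep <- 15
  cover <- matrix(FALSE, n_rep, 3)
  for (r in seq_len(n_rep)) {
    cts <- simulate_titration_counts(paper_model, conc, 100, seed = 500 + r)
    fit <- fit_global(cts, ci = "wald")
    td <- tidy(fit)
    truth <- c(17, 10, 3)
    cover[r, ] <- td$conf.low <= truth & truth <= td$conf.high
  }
  expect_gte(mean(cover[, 1]), 0.8)
  expect_gte(mean(cover[, 2]), 0.8)
  expect_gte(mean(cover[, 3]), 0.8)
})

test_that("the likelihood-ratio test detects cooperativity at n = 1200", {
  conc <- 10^seq(0, log10(150), length.out = 12)
  crit <- qchisq(0.95, 1)
  n_rep <- 15
  reject <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cts <- simulate_titration_counts(paper_model, conc, 100, seed = 700 + r)
    full <- fit_global(cts, ci = "none")
    restr <- fit_global(cts, ci = "none", fix_gamma = 1)
    reject[r] <- lr_test(full, restr)$statistic > crit
  }
  expect_gte(mean(reject), 0.8)
})

test_that("two-species data reduce to the single-site isotherm MLE", {
  set.seed(12)
  conc <- c(1, 3, 10, 30, 100)
  K_true <- 10
  n <- 200
  bound <- rbinom(length(conc), n, conc / (conc + K_true))
  counts <- tibble::tibble(conc_nM = conc, n_A0B0 = n - bound,
                           n_A1B0 = 0L, n_A0B1 = bound, n_A1B1 = 0L)
  fit <- fit_global(counts, ci = "none", fix_gamma = 1)
  # independent single-site MLE by 1-D optimization of the binomial lik
  nll1 <- function(logK) {
    p <- conc / (conc + exp(logK))
    -sum(bound * log(p) + (n - bound) * log(1 - p))
  }
  K_mle <- exp(optimize(nll1, c(-5, 10))$minimum)
  expect_equal(fit$model$K_B, K_mle, tolerance = 0.01)

  # degenerate: every molecule in one species
  apo_only <- tibble::tibble(conc_nM = conc, n_A0B0 = 100L, n_A1B0 = 0L,
                             n_A0B1 = 0L, n_A1B1 = 0L)
  expect_error(fit_global(apo_only, ci = "none"),
               class = "tweezfold_unidentifiable_model")
})
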