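#' Sequential cooperative two-site binding model
#'
#' Microscopic dissociation constants for the first cAMP binding to each
#' CNB domain and a shared cooperativity factor: binding of the first
#' ligand lowers the second site's Kd by `gamma` (gamma > 1 means positive
#' cooperativity). A single shared gamma closes the thermodynamic cycle
#' between the two binding paths by construction.
#'
#' @param K_A Microscopic Kd for ligand binding to CNB-A with CNB-B empty, nM.
#' @param K_B Microscopic Kd for ligand binding to CNB-B with CNB-A empty, nM.
#' @param gamma Cooperativity factor (> 0); second-site Kd = K / gamma.
#' @return A list of class `binding_model`.
#' @examples
#' binding_model(K_A = 17, K_B = 10, gamma = 3)
#' @export
binding_model <- function(K_A, K_B, gamma = 1) {
  if (K_A <= 0 || K_B <= 0 || gamma <= 0) {
    abort("K_A, K_B and gamma must all be positive.",
          class = "tweezfold_invalid_parameter")
  }
  structure(list(K_A = K_A, K_B = K_B, gamma = gamma),
            class = "binding_model")
}

#' Equilibrium fractions of the four liganded species
#'
#' For free ligand concentration `L` the binding polynomial is
#' `Z = 1 + L/K_A + L/K_B + gamma L^2/(K_A K_B)` and the species fractions
#' are `(1, L/K_A, L/K_B, gamma L^2/(K_A K_B)) / Z` for
#' (A0B0, A1B0, A0B1, A1B1). The fractions sum to 1 exactly.
#'
#' @param model A [binding_model()].
#' @param conc Ligand concentration(s), nM, `>= 0`.
#' @return A tibble with columns `conc_nM`, `f_A0B0`, `f_A1B0`, `f_A0B1`,
#'   `f_A1B1`.
#' @examples
#' species_fractions(binding_model(17, 10, 3), conc = 10)
#' @export
species_fractions <- function(model, conc) {
  stopifnot(inherits(model, "binding_model"))
  if (any(conc < 0)) {
    abort("Ligand concentration must be >= 0.",
          class = "tweezfold_invalid_input")
  }
  L <- conc
  w1 <- rep(1, length(L))
  wA <- L / model$K_A
  wB <- L / model$K_B
  wAB <- model$gamma * L^2 / (model$K_A * model$K_B)
  Z <- w1 + wA + wB + wAB
  tibble::tibble(conc_nM = L, f_A0B0 = w1 / Z, f_A1B0 = wA / Z,
                 f_A0B1 = wB / Z, f_A1B1 = wAB / Z)
}

#' Default decision thresholds for liganded-state classification
#'
#' Windows on rupture forces (pN) and contour-length changes (nm) used by
#' [classify_trajectory()]. The defaults encode the mechanical fingerprints
#' of the PKA regulatory subunit: a reversible ~11 pN / ~13 nm hopping
#' transition marks a folded, docked N3A motif (fully bound state); a
#' CNB-A rip near 30 nm marks the cAMP-bound, N3A-destabilized domain; a
#' CNB-A rip in the mid-40s nm with elevated force plus a CNB-B rupture at
#' apo-like force marks the A0B1 intermediate; two apo-force full-length
#' rips mark the apo state.
#'
#' @param hop_force Force window for the reversible hopping transition, pN.
#' @param hop_delta_lc Contour-length window for the hopping transition, nm.
#' @param cnba_no_n3a CNB-A delta-Lc window without the N3A motif, nm.
#' @param cnba_n3a_folded CNB-A delta-Lc window with a folded N3A motif, nm.
#' @param apo_force Apo-state rupture-force window, pN.
#' @param elevated_force Threshold above which a CNB-A rupture force counts
#'   as elevated, pN.
#' @param full_length_lc Minimum delta-Lc for a full-length domain rip, nm.
#' @return A named list of thresholds.
#' @export
classify_rules <- function(hop_force = c(9.5, 12.5),
                           hop_delta_lc = c(10, 16),
                           cnba_no_n3a = c(27, 33),
                           cnba_n3a_folded = c(42, 48),
                           apo_force = c(5, 10.5),
                           elevated_force = 10.5,
                           full_length_lc = 40) {
  list(hop_force = hop_force, hop_delta_lc = hop_delta_lc,
       cnba_no_n3a = cnba_no_n3a, cnba_n3a_folded = cnba_n3a_folded,
       apo_force = apo_force, elevated_force = elevated_force,
       full_length_lc = full_length_lc)
}

.in_window <- function(x, w) x >= w[1] & x <= w[2]

#' Classify one pulling cycle into a liganded species
#'
#' Decision-rule cascade on the rip events of a single pulling cycle of a
#' both-domain construct: (1) a reversible hopping transition in the
#' hopping force/delta-Lc windows implies the fully bound state A1B1;
#' (2) otherwise a CNB-A rip with delta-Lc in the "no-N3A" window implies
#' A1B0; (3) otherwise a CNB-A rip in the "N3A-folded" window at elevated
#' force together with a CNB-B rupture at apo-like force implies A0B1;
#' (4) otherwise two full-length rips at apo-like forces imply A0B0.
#' Anything else is returned as `"unclassified"`, never forced.
#'
#' @param events A tibble of rip events for one cycle (needs columns
#'   `rupture_force`, `delta_lc`, `direction`, `reversible`).
#' @param rules Thresholds from [classify_rules()].
#' @return A single string: `"A0B0"`, `"A1B0"`, `"A0B1"`, `"A1B1"` or
#'   `"unclassified"`.
#' @export
classify_trajectory <- function(events, rules = classify_rules()) {
  if (is.null(events) || nrow(events) == 0) return("unclassified")
  unf <- events[events$direction == "unfold", , drop = FALSE]
  if (nrow(unf) == 0) return("unclassified")

  hop <- unf$reversible & .in_window(unf$rupture_force, rules$hop_force) &
    .in_window(unf$delta_lc, rules$hop_delta_lc)
  if (any(hop)) return("A1B1")

  # irreversible rips only from here on
  rips <- unf[!unf$reversible, , drop = FALSE]
  if (nrow(rips) == 0) return("unclassified")

  if (any(.in_window(rips$delta_lc, rules$cnba_no_n3a))) return("A1B0")

  cnba <- .in_window(rips$delta_lc, rules$cnba_n3a_folded) &
    rips$rupture_force > rules$elevated_force
  cnbb_apo <- .in_window(rips$rupture_force, rules$apo_force) &
    rips$delta_lc >= rules$full_length_lc
  if (any(cnba) && any(cnbb_apo)) return("A0B1")

  apo_like <- .in_window(rips$rupture_force, rules$apo_force) &
    rips$delta_lc >= rules$full_length_lc
  if (nrow(rips) >= 2 && all(apo_like)) return("A0B0")

  "unclassified"
}

.counts_matrix <- function(counts) {
  need <- c("conc_nM", "n_A0B0", "n_A1B0", "n_A0B1", "n_A1B1")
  if (!all(need %in% names(counts))) {
    abort(paste("`counts` needs columns:", paste(need, collapse = ", ")),
          class = "tweezfold_invalid_input")
  }
  as.matrix(counts[, c("n_A0B0", "n_A1B0", "n_A0B1", "n_A1B1")])
}

.titration_nll <- function(logpar, conc, cmat, fix_gamma = NULL) {
  K_A <- exp(logpar[1]); K_B <- exp(logpar[2])
  gamma <- if (is.null(fix_gamma)) exp(logpar[3]) else fix_gamma
  fr <- species_fractions(binding_model(K_A, K_B, gamma), conc)
  P <- pmax(as.matrix(fr[, c("f_A0B0", "f_A1B0", "f_A0B1", "f_A1B1")]),
            1e-300)
  -sum(cmat * log(P))
}

#' Globally fit the two-site cooperative binding model to species counts
#'
#' Maximum-likelihood fit of [species_fractions()] probabilities to
#' per-concentration multinomial species counts, optimized in
#' log-parameter space. 95% confidence intervals come from a seeded
#' parametric bootstrap (refitting counts simulated at the MLE), or from
#' the observed-information (Wald) approximation on the log scale.
#'
#' @param counts A `species_counts` tibble (see
#'   [simulate_titration_counts()] for the schema).
#' @param start A [binding_model()] used as the starting point.
#' @param seed Integer seed for the bootstrap.
#' @param ci One of `"bootstrap"`, `"wald"`, `"none"`.
#' @param n_boot Bootstrap resamples (default 500).
#' @param fix_gamma Optional fixed value for the cooperativity factor
#'   (restricted fit, e.g. `fix_gamma = 1` for the no-cooperativity null).
#' @return An object of class `binding_fit`: the fitted [binding_model()]
#'   plus CIs, the maximized log-likelihood and the data. Methods:
#'   [tidy.binding_fit()], [glance.binding_fit()], [autoplot.binding_fit()].
#' @export
fit_global <- function(counts, start = binding_model(20, 20, 1), seed = 1,
                       ci = c("bootstrap", "wald", "none"), n_boot = 500,
                       fix_gamma = NULL) {
  ci <- match.arg(ci)
  cmat <- .counts_matrix(counts)
  conc <- counts$conc_nM
  if (length(unique(conc)) < 4 ||
      diff(log10(range(conc[conc > 0]))) < 1) {
    abort("Need >= 4 concentrations spanning at least one decade.",
          class = "tweezfold_invalid_input")
  }
  if (sum(cmat) < 100) {
    abort("Need at least 100 classified molecules in total.",
          class = "tweezfold_invalid_input")
  }
  occupied <- colSums(cmat) > 0
  if (sum(occupied) < 2) {
    abort("All mass in one species at every concentration: model unidentifiable.",
          class = "tweezfold_unidentifiable_model")
  }

  p0 <- if (is.null(fix_gamma)) log(c(start$K_A, start$K_B, start$gamma))
        else log(c(start$K_A, start$K_B))
  fit <- optim(p0, .titration_nll, conc = conc, cmat = cmat,
               fix_gamma = fix_gamma, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12), hessian = TRUE)
  est <- exp(fit$par)
  model <- if (is.null(fix_gamma)) binding_model(est[1], est[2], est[3])
           else binding_model(est[1], est[2], fix_gamma)

  par_names <- if (is.null(fix_gamma)) c("K_A", "K_B", "gamma")
               else c("K_A", "K_B")
  ci_tab <- NULL
  if (ci == "wald") {
    vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
    if (!is.null(vc)) {
      se_log <- sqrt(pmax(diag(vc), 0))
      ci_tab <- tibble::tibble(
        term = par_names,
        conf.low = exp(fit$par - 1.96 * se_log),
        conf.high = exp(fit$par + 1.96 * se_log))
    }
  } else if (ci == "bootstrap") {
    set.seed(seed)
    n_per <- rowSums(cmat)
    fr_hat <- species_fractions(model, conc)
    P <- as.matrix(fr_hat[, c("f_A0B0", "f_A1B0", "f_A0B1", "f_A1B1")])
    boot <- matrix(NA_real_, n_boot, length(par_names))
    for (b in seq_len(n_boot)) {
      cb <- t(vapply(seq_along(conc), function(i)
        as.numeric(rmultinom(1, n_per[i], P[i, ])), numeric(4)))
      fb <- optim(fit$par, .titration_nll, conc = conc, cmat = cb,
                  fix_gamma = fix_gamma, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-10))
      boot[b, ] <- exp(fb$par)
    }
    qs <- apply(boot, 2, quantile, probs = c(0.025, 0.975))
    ci_tab <- tibble::tibble(term = par_names,
                             conf.low = qs[1, ], conf.high = qs[2, ])
  }

  structure(
    list(model = model, ci = ci_tab, logLik = -fit$value,
         fixed_gamma = !is.null(fix_gamma), counts = counts,
         convergence = fit$convergence),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Two-site cooperative binding fit\n")
  cat(sprintf("  K_A = %.3g nM, K_B = %.3g nM, gamma = %.3g%s\n",
              x$model$K_A, x$model$K_B, x$model$gamma,
              if (x$fixed_gamma) " (fixed)" else ""))
  cat(sprintf("  logLik = %.2f\n", x$logLik))
  invisible(x)
}

#' Likelihood-ratio test between nested binding fits
#'
#' Compares a restricted fit (e.g. `fix_gamma = 1`) against the full fit
#' with the chi-squared approximation for the likelihood-ratio statistic.
#'
#' @param fit_full Unrestricted [fit_global()] result.
#' @param fit_restricted Restricted fit (fewer free parameters).
#' @param df Degrees of freedom of the restriction, default 1.
#' @return A one-row tibble with `statistic`, `df`, `p.value`.
#' @export
lr_test <- function(fit_full, fit_restricted, df = 1) {
  stat <- 2 * (fit_full$logLik - fit_restricted$logLik)
  tibble::tibble(statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE))
}
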