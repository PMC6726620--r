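#' Transform an unfolding-force histogram into force-dependent lifetimes
#'
#' Survival-over-density estimator: for occupied bin `i` with density
#' `h_i`, bin width `dF` and loading rate `Fdot_i`,
#' `tau(F_i) = ((h_i/2 + sum_{k>i} h_k) dF) / (h_i Fdot_i)`.
#' Empty bins are omitted.
#'
#' @param hist An [unfolding_histogram()] (columns `bin_center`, `count`,
#'   `density`, `loading_rate`).
#' @param role `"F->U"` (unfolding, default) or `"U->F"`.
#' @return A `lifetime_curve` tibble: `force`, `lifetime`, `count`,
#'   `loading_rate`; attribute `role`.
#' @examples
#' h <- tibble::tibble(bin_center = c(5.5, 6.5), count = c(60L, 40L),
#'                     density = c(0.6, 0.4), loading_rate = c(1, 1))
#' attr(h, "bin_width") <- 1; attr(h, "n") <- 100L
#' class(h) <- c("unfolding_histogram", class(h))
#' histogram_to_lifetimes(h)$lifetime # 1.1667, 0.5
#' @export
histogram_to_lifetimes <- function(hist, role = c("F->U", "U->F")) {
  role <- match.arg(role)
  need <- c("bin_center", "count", "density", "loading_rate")
  if (!all(need %in% names(hist))) {
    abort("`hist` must be an unfolding histogram with per-bin loading rates.",
          class = "tweezfold_invalid_input")
  }
  dF <- attr(hist, "bin_width") %||% median(diff(hist$bin_center))
  total <- sum(hist$density * dF)
  if (abs(total - 1) > 1e-6) {
    abort(sprintf("Histogram integrates to %.6f, not 1: not normalized.",
                  total), class = "tweezfold_validation_error")
  }
  h <- hist$density
  surv_above <- rev(cumsum(rev(h))) - h # sum over bins strictly above i
  tau <- ((h / 2 + surv_above) * dF) / (h * hist$loading_rate)
  keep <- hist$count > 0 & is.finite(tau)
  out <- tibble::tibble(force = hist$bin_center[keep],
                        lifetime = tau[keep],
                        count = hist$count[keep],
                        loading_rate = hist$loading_rate[keep])
  attr(out, "role") <- role
  attr(out, "bin_width") <- dF
  attr(out, "n") <- attr(hist, "n") %||% sum(hist$count)
  class(out) <- c("lifetime_curve", class(out))
  out
}

# model lifetime, dg in kBT units; role flips the sign of the force term
.tau_model <- function(force, tau0, dx, dg, nu, role, kT) {
  s <- if (role == "U->F") -1 else 1
  if (nu == 1 || is.na(dg)) {
    return(tau0 * exp(-s * force * dx / kT))
  }
  u <- 1 - s * nu * force * dx / (dg * kT)
  if (any(u <= 0)) {
    abort("Force beyond the critical force of the DHS model (nu F dx >= dG).",
          class = "tweezfold_domain_error")
  }
  tau0 * u^(1 - 1 / nu) * exp(-dg * (1 - u^(1 / nu)))
}

#' Lifetime predicted by fitted kinetic parameters
#'
#' @param params A `kinetic_params` object from [fit_lifetimes()] or
#'   [kinetic_params()].
#' @param force Force(s), pN.
#' @return Predicted lifetime(s), s.
#' @export
lifetime_at <- function(params, force) {
  stopifnot(inherits(params, "kinetic_params"))
  .tau_model(force, params$tau0, params$dx_ddagger, params$dg_ddagger,
             params$nu, params$role, kBT(params$temperature))
}

#' Construct kinetic parameters directly
#'
#' @param tau0 Zero-force lifetime, s.
#' @param dx_ddagger Distance to the transition state, nm.
#' @param dg_ddagger Barrier height in kBT units (DHS only; `NA` for Bell).
#' @param nu Model shape: 1 (Bell), 2/3 (linear-cubic) or 1/2 (cusp).
#' @param role `"F->U"` or `"U->F"`.
#' @param temperature Temperature, K.
#' @return A `kinetic_params` object.
#' @export
kinetic_params <- function(tau0, dx_ddagger, dg_ddagger = NA_real_, nu = 1,
                           role = c("F->U", "U->F"), temperature = 293.15) {
  role <- match.arg(role)
  if (tau0 <= 0 || dx_ddagger <= 0 || !nu %in% c(1, 2 / 3, 1 / 2)) {
    abort("tau0 and dx_ddagger must be positive; nu must be 1, 2/3 or 1/2.",
          class = "tweezfold_invalid_parameter")
  }
  structure(list(model = if (nu == 1) "bell" else "dhs", nu = nu,
                 role = role, tau0 = tau0, dx_ddagger = dx_ddagger,
                 dg_ddagger = dg_ddagger, temperature = temperature,
                 ci = NULL, curve = NULL),
            class = "kinetic_params")
}

# bins whose estimated lifetime approaches the bin crossing time dF/Fdot
# sit near the estimator's resolution floor (tau >= dF/(2 Fdot) by
# construction) and are systematically biased upward (still ~5% at one
# crossing time); drop bins below twice the crossing time from fits
.valid_bins <- function(curve, dF) {
  curve$lifetime >= 2 * dF / curve$loading_rate
}

.fit_lifetime_curve <- function(curve, model, nu, role, kT) {
  f <- curve$force
  y <- log(curve$lifetime)
  wts <- curve$count
  if (model == "bell") {
    fit <- lm(y ~ f, weights = wts)
    slope <- coef(fit)[[2]]
    s <- if (role == "U->F") -1 else 1
    list(tau0 = exp(coef(fit)[[1]]), dx = -s * slope * kT, dg = NA_real_)
  } else {
    obj <- function(p) {
      tau0 <- exp(p[1]); dx <- exp(p[2]); dg <- exp(p[3])
      s <- if (role == "U->F") -1 else 1
      u <- 1 - s * nu * f * dx / (dg * kT)
      if (any(u <= 1e-9)) return(1e12)
      pred <- log(tau0) + (1 - 1 / nu) * log(u) - dg * (1 - u^(1 / nu))
      sum(wts * (y - pred)^2)
    }
    # start from the Bell solution with a generous barrier
    b <- .fit_lifetime_curve(curve, "bell", 1, role, kT)
    p <- optim(log(c(b$tau0, b$dx, max(10, 2 * max(f) * b$dx / kT))), obj,
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
    list(tau0 = exp(p$par[1]), dx = exp(p$par[2]), dg = exp(p$par[3]))
  }
}

#' Fit Bell or Dudko-Hummer-Szabo kinetics to a lifetime curve
#'
#' Weighted least squares on `log(lifetime)` vs force, with per-bin
#' event counts as weights (Poisson error propagation: sparse tail bins
#' carry little weight). Bell: `log tau = log tau0 - F dx / kBT` (the
#' refolding role uses the opposite sign, since force opposes folding).
#' DHS (`nu` = 1/2 or 2/3) is fitted by numerical optimization in
#' log-parameter space. Confidence intervals come from a seeded
#' multinomial bootstrap of the underlying histogram counts, re-running
#' the full transform + fit on each resample.
#'
#' By default only bins within the transform's validity domain are used:
#' a bin whose lifetime is comparable to its own crossing time
#' `dF / loading_rate` cannot be resolved by the survival-over-density
#' estimator (its estimate floors at half the crossing time and is still
#' biased by several percent at one crossing time), so bins below twice
#' the crossing time are excluded; set `valid_only = FALSE` to keep every
#' occupied bin.
#'
#' @param curve A `lifetime_curve` from [histogram_to_lifetimes()].
#' @param model `"bell"` or `"dhs"`.
#' @param nu Shape parameter for DHS (1/2 or 1/2); forced to 1 for Bell.
#' @param n_boot Bootstrap resamples (default 1000; 0 to skip).
#' @param seed Integer seed for the bootstrap.
#' @param valid_only Drop bins outside the estimator's validity domain
#'   (default TRUE).
#' @param temperature Temperature, K.
#' @return A `kinetic_params` object with `tau0` (s), `dx_ddagger` (nm),
#'   `dg_ddagger` (kBT, DHS only), 95% CIs and the input curve attached.
#' @export
fit_lifetimes <- function(curve, model = c("bell", "dhs"), nu = 1,
                          n_boot = 1000, seed = 1, valid_only = TRUE,
                          temperature = 293.15) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "lifetime_curve"))
  role <- attr(curve, "role") %||% "F->U"
  dF_full <- attr(curve, "bin_width") %||% median(diff(curve$force))
  fit_curve <- if (valid_only) curve[.valid_bins(curve, dF_full), ] else curve
  if (nrow(fit_curve) < 4) {
    abort("Need at least 4 occupied (and resolvable) bins to fit force-dependent lifetimes.",
          class = "tweezfold_invalid_input")
  }
  if (model == "bell") nu <- 1
  if (model == "dhs" && !nu %in% c(1 / 2, 2 / 3, 1)) {
    abort("DHS shape `nu` must be 1/2, 2/3 or 1.",
          class = "tweezfold_invalid_parameter")
  }
  kT <- kBT(temperature)
  est <- .fit_lifetime_curve(fit_curve, model, nu, role, kT)

  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    n <- attr(curve, "n") %||% sum(curve$count)
    dF <- attr(curve, "bin_width") %||% median(diff(curve$force))
    probs <- curve$count / sum(curve$count)
    draws <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      cb <- as.numeric(rmultinom(1, n, probs))
      keep <- cb > 0
      if (sum(keep) < 4) next
      hb <- tibble::tibble(bin_center = curve$force,
                           count = cb,
                           density = cb / (n * dF),
                           loading_rate = curve$loading_rate)
      attr(hb, "bin_width") <- dF
      attr(hb, "n") <- n
      class(hb) <- c("unfolding_histogram", class(hb))
      lb <- histogram_to_lifetimes(hb, role = role)
      if (valid_only) lb <- lb[.valid_bins(lb, dF), ]
      if (nrow(lb) < 4) next
      eb <- tryCatch(.fit_lifetime_curve(lb, model, nu, role, kT),
                     error = function(e) NULL)
      if (!is.null(eb)) draws[b, ] <- c(eb$tau0, eb$dx, eb$dg)
    }
    qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    terms <- c("tau0", "dx_ddagger", "dg_ddagger")
    ci <- tibble::tibble(term = terms, conf.low = qs[1, ],
                         conf.high = qs[2, ])
    if (model == "bell") ci <- ci[ci$term != "dg_ddagger", ]
  }

  out <- kinetic_params(est$tau0, est$dx, est$dg, nu = nu, role = role,
                        temperature = temperature)
  out$model <- model
  out$ci <- ci
  out$curve <- curve
  out
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("%s kinetics (%s)\n", toupper(x$model), x$role))
  cat(sprintf("  tau0 = %.4g s, dx = %.3g nm", x$tau0, x$dx_ddagger))
  if (!is.na(x$dg_ddagger)) cat(sprintf(", dG = %.3g kBT", x$dg_ddagger))
  cat("\n")
  invisible(x)
}

#' Reconstruct the rupture-force distribution from kinetic parameters
#'
#' First-passage density under a constant loading rate:
#' `p(F) = [Fdot tau(F)]^-1 exp(-int_0^F [Fdot tau(f)]^-1 df)`, evaluated
#' by trapezoidal integration on `grid`. Over a grid extending to
#' negligible survival the density integrates to 1.
#'
#' @param params A `kinetic_params` object.
#' @param loading_rate Loading rate, pN/s.
#' @param grid Force grid, pN (ascending, starting near 0).
#' @return A tibble with columns `force`, `density`, `survival`.
#' @export
reconstruct_force_distribution <- function(params, loading_rate,
                                           grid = seq(0, 40, by = 0.05)) {
  stopifnot(inherits(params, "kinetic_params"))
  if (loading_rate <= 0) {
    abort("`loading_rate` must be positive.",
          class = "tweezfold_invalid_parameter")
  }
  k <- 1 / lifetime_at(params, grid)
  integrand <- k / loading_rate
  dF <- diff(grid)
  cum <- c(0, cumsum((integrand[-1] + integrand[-length(integrand)]) / 2 * dF))
  surv <- exp(-cum)
  tibble::tibble(force = grid, density = integrand * surv, survival = surv)
}
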