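#' Bayesian two-state hidden Markov analysis of a hopping trace
#'
#' Gibbs sampler for a two-state (folded/unfolded) Gaussian-emission HMM:
#' each sweep alternates (a) a state-path draw by forward-filtering
#' backward-sampling, (b) conjugate normal-inverse-gamma draws of the two
#' state means and the shared noise SD, and (c) per-row Beta
#' (Dirichlet(1,1)) draws of the stay probabilities. Label switching is
#' resolved by ordering the state means (folded = lower extension). Point
#' estimates are posterior medians with 95% credible intervals.
#'
#' Before sampling, the trace is screened for degeneracy: a constant trace,
#' a trace whose initial two-level split leaves a state essentially
#' unoccupied, or (when the mclust package is available) a trace for which
#' a one-component Gaussian beats a two-component mixture by BIC, all
#' raise a degenerate-trace error.
#'
#' @param trace A `force_clamp_trace` (tibble with `time`, `extension`).
#' @param n_samples Total Gibbs sweeps (>= 500 recommended).
#' @param burn_in Discarded sweeps; default 20% of `n_samples`.
#' @param seed Integer seed.
#' @param priors List with elements `m0` (length-2 prior means; default the
#'   0.25/0.75 extension quantiles), `k0` (prior precision scale, default
#'   0.01), `a0`, `b0` (inverse-gamma shape/rate for the noise variance,
#'   default 0.001 each).
#' @return A `bhmm_fit` object: posterior `draws` tibble (`mean_folded`,
#'   `mean_unfolded`, `noise_sd`, `p_stay_folded`, `p_stay_unfolded`),
#'   `summary` tibble with medians and 95% CIs, the sampling interval,
#'   setpoint force, split-chain diagnostic `rhat`, and the seed.
#' @export
fit_bhmm <- function(trace, n_samples = 2000, burn_in = NULL, seed = 1,
                     priors = list()) {
  stopifnot(inherits(trace, "force_clamp_trace"))
  y <- trace$extension
  n <- length(y)
  if (n < 100) {
    abort("Trace too short for hopping analysis (need >= 100 samples).",
          class = "tweezfold_invalid_input")
  }
  if (n_samples < 100) {
    abort("`n_samples` must be at least 100.",
          class = "tweezfold_invalid_parameter")
  }
  if (is.null(burn_in)) burn_in <- floor(0.2 * n_samples)
  dt <- if (!is.null(attr(trace, "sample_rate")))
    1 / attr(trace, "sample_rate") else median(diff(trace$time))

  if (sd(y) == 0) {
    abort("Constant trace: fewer than 2 occupied states.",
          class = "tweezfold_degenerate_trace")
  }
  set.seed(seed)

  # initial two-level split
  m0_init <- as.numeric(quantile(y, c(0.25, 0.75)))
  thr <- mean(m0_init)
  hard <- as.integer(y > thr)
  if (min(sum(hard == 0), sum(hard == 1)) < max(5, 1e-3 * n)) {
    abort("Initialization leaves a state essentially unoccupied: degenerate trace.",
          class = "tweezfold_degenerate_trace")
  }
  if (length(unique(y)) > 2 && requireNamespace("mclust", quietly = TRUE)) {
    ys <- if (n > 10000) y[seq(1, n, length.out = 10000)] else y
    bic <- tryCatch(
      mclust::mclustBIC(ys, G = 1:2, modelNames = "E", verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(bic) && all(is.finite(bic[, "E"])) &&
        bic[1, "E"] > bic[2, "E"]) {
      abort("One Gaussian component explains the trace better than two: degenerate trace.",
            class = "tweezfold_degenerate_trace")
    }
  }

  pr <- modifyList(list(m0 = m0_init, k0 = 0.01, a0 = 1e-3, b0 = 1e-3),
                   priors)
  mu <- m0_init
  sigma <- max(sd(y - mu[hard + 1L]), 1e-8)
  p00 <- p11 <- 0.99

  keep <- n_samples - burn_in
  draws <- matrix(NA_real_, keep, 5)
  colnames(draws) <- c("mean_folded", "mean_unfolded", "noise_sd",
                       "p_stay_folded", "p_stay_unfolded")
  for (it in seq_len(n_samples)) {
    s <- ffbs_gauss2(y, mu[1], mu[2], max(sigma, 1e-9), p00, p11)
    n1 <- sum(s)
    n0 <- n - n1
    # conjugate mean draws (shared sigma), then variance
    for (k in 1:2) {
      nk <- if (k == 1) n0 else n1
      sk <- if (k == 1) sum(y[s == 0L]) else sum(y[s == 1L])
      if (nk > 0) {
        post_mean <- (pr$k0 * pr$m0[k] + sk) / (pr$k0 + nk)
        mu[k] <- rnorm(1, post_mean, sigma / sqrt(pr$k0 + nk))
      }
    }
    if (mu[1] > mu[2]) { # resolve label switching by ordering means
      mu <- rev(mu)
      s <- 1L - s
      n1 <- n - n1
      n0 <- n - n1
    }
    resid <- y - ifelse(s == 1L, mu[2], mu[1])
    sigma2 <- 1 / rgamma(1, pr$a0 + n / 2, pr$b0 + sum(resid^2) / 2)
    sigma <- sqrt(sigma2)
    s_head <- s[-n]
    s_tail <- s[-1]
    n00 <- sum(s_head == 0L & s_tail == 0L)
    n01 <- sum(s_head == 0L & s_tail == 1L)
    n10 <- sum(s_head == 1L & s_tail == 0L)
    n11 <- sum(s_head == 1L & s_tail == 1L)
    p00 <- rbeta(1, 1 + n00, 1 + n01)
    p11 <- rbeta(1, 1 + n11, 1 + n10)
    if (it > burn_in) {
      draws[it - burn_in, ] <- c(mu[1], mu[2], sigma, p00, p11)
    }
  }
  draws <- tibble::as_tibble(draws)

  qs <- function(v) quantile(v, c(0.5, 0.025, 0.975), names = FALSE)
  sep <- draws$mean_unfolded - draws$mean_folded
  summ <- dplyr::bind_rows(lapply(names(draws), function(nm) {
    q <- qs(draws[[nm]])
    tibble::tibble(term = nm, estimate = q[1], conf.low = q[2],
                   conf.high = q[3])
  }))
  q_sep <- qs(sep)
  summ <- dplyr::bind_rows(summ, tibble::tibble(
    term = "delta_x", estimate = q_sep[1], conf.low = q_sep[2],
    conf.high = q_sep[3]))

  # split-chain diagnostic on the mean separation
  half <- floor(length(sep) / 2)
  ch <- list(sep[seq_len(half)], sep[(half + 1):(2 * half)])
  W <- mean(vapply(ch, var, numeric(1)))
  B <- half * var(vapply(ch, mean, numeric(1)))
  rhat <- if (W > 0) sqrt(((half - 1) / half * W + B / half) / W) else 1

  structure(
    list(draws = draws, summary = summ, sample_interval = dt,
         setpoint_force = attr(trace, "setpoint_force"),
         n_samples = n_samples, burn_in = burn_in, seed = seed,
         rhat = rhat, n_obs = n),
    class = "bhmm_fit")
}

#' @export
print.bhmm_fit <- function(x, ...) {
  cat(sprintf("Two-state BHMM fit (%d draws after burn-in, rhat = %.3f)\n",
              nrow(x$draws), x$rhat))
  print(x$summary)
  invisible(x)
}

#' Posterior dwell lifetimes from a hopping fit
#'
#' Per posterior draw, `tau_state = -dt / log(p_stay_state)`; medians and
#' 95% credible intervals are reported. Draws with `p_stay == 1` (infinite
#' lifetime) are excluded with a warning.
#'
#' @param fit A `bhmm_fit`.
#' @param sample_interval Sampling interval, s; defaults to the one stored
#'   in the fit.
#' @return A tibble with rows `folded` and `unfolded`: `tau`, `conf.low`,
#'   `conf.high` (seconds) and `n_draws`.
#' @export
dwell_lifetimes <- function(fit, sample_interval = NULL) {
  stopifnot(inherits(fit, "bhmm_fit"))
  dt <- sample_interval %||% fit$sample_interval
  out <- lapply(c(folded = "p_stay_folded", unfolded = "p_stay_unfolded"),
                function(col) {
    p <- fit$draws[[col]]
    inf <- p >= 1
    if (any(inf)) {
      warn(sprintf("%d draw(s) with p_stay = 1 (infinite lifetime) excluded from %s.",
                   sum(inf), col))
      p <- p[!inf]
    }
    tau <- -dt / log(p)
    nd <- length(tau)
    q <- quantile(tau, c(0.5, 0.025, 0.975), names = FALSE)
    tibble::tibble(tau = q[1], conf.low = q[2], conf.high = q[3],
                   n_draws = nd)
  })
  dplyr::bind_rows(out, .id = "state")
}

#' Contour-length change from a hopping posterior
#'
#' Divides the posterior extension separation between unfolded and folded
#' states by the worm-like chain fractional extension at the clamp force:
#' `delta_lc = (mean_unfolded - mean_folded) / xi(F)`. Uncertainty is
#' propagated draw-by-draw.
#'
#' @param fit A `bhmm_fit`.
#' @param clamp_force Clamp force, pN; defaults to the trace setpoint
#'   stored in the fit.
#' @param persistence Unfolded-chain persistence length, nm.
#' @param temperature Temperature, K.
#' @return One-row tibble: `delta_lc`, `se` (posterior SD), `conf.low`,
#'   `conf.high`, `delta_x`, `n_draws`.
#' @export
delta_lc_from_hopping <- function(fit, clamp_force = NULL,
                                  persistence = 0.65, temperature = 293.15) {
  stopifnot(inherits(fit, "bhmm_fit"))
  f <- clamp_force %||% fit$setpoint_force
  if (is.null(f) || is.na(f) || f <= 0) {
    abort("`clamp_force` must be positive.",
          class = "tweezfold_invalid_parameter")
  }
  xi <- frac_extension_at(f, wlc_params(persistence,
                                        temperature = temperature))
  dlc <- (fit$draws$mean_unfolded - fit$draws$mean_folded) / xi
  q <- quantile(dlc, c(0.5, 0.025, 0.975), names = FALSE)
  tibble::tibble(delta_lc = q[1], se = sd(dlc), conf.low = q[2],
                 conf.high = q[3],
                 delta_x = median(fit$draws$mean_unfolded -
                                    fit$draws$mean_folded),
                 n_draws = length(dlc))
}

#' Maximum a posteriori state path for a hopping trace
#'
#' Viterbi decoding of the trace under the posterior-median BHMM
#' parameters; useful for dwell-time histograms and overlay plots.
#'
#' @param fit A `bhmm_fit`.
#' @param trace The `force_clamp_trace` the fit was computed from.
#' @return An integer vector (0 = folded, 1 = unfolded), one per sample.
#' @export
state_path <- function(fit, trace) {
  stopifnot(inherits(fit, "bhmm_fit"), inherits(trace, "force_clamp_trace"))
  s <- fit$summary
  g <- function(term) s$estimate[s$term == term]
  viterbi_gauss2(trace$extension, g("mean_folded"), g("mean_unfolded"),
                 max(g("noise_sd"), 1e-9), g("p_stay_folded"),
                 g("p_stay_unfolded"))
}
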