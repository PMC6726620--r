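#' Detect unfolding/refolding rips in a force-extension trace
#'
#' Events are located per (cycle, segment) as jumps in the extension
#' signal: the difference between forward- and backward-looking moving
#' means must exceed a robust threshold (median + `threshold_k` * MAD of
#' that difference, with an absolute floor `min_jump`). Candidates closer
#' than `min_separation` are merged, keeping the larger jump. For each
#' event the pre- and post-rip baselines (linear in force, truncated at
#' neighbouring events) are extrapolated to the rupture force, giving the
#' extension change `delta_x`; `delta_lc = delta_x / xi(F)` with `xi` the
#' Marko-Siggia fractional extension of the unfolded chain. The loading
#' rate is the slope of a linear force-vs-time fit over the
#' `loading_window` ending at rupture. Events whose force window is
#' re-crossed repeatedly within one segment (>= 3 events of mixed
#' direction within `hop_cluster_pn` and with comparable jump sizes) are
#' flagged `reversible`.
#'
#' @param trace A `force_ramp_trace`.
#' @param smooth_window Moving-mean half-window in samples (default 5).
#' @param threshold_k Robust threshold multiplier (default 6).
#' @param min_jump Absolute floor on the detectable extension jump, nm.
#' @param min_separation Minimum event separation, s (default 0.025).
#' @param min_force_drop Required concurrent force change magnitude, pN.
#' @param baseline_window Pre/post baseline fit window, s. Long enough to
#'   pin down the local extension-vs-force slope; truncated at
#'   neighbouring events.
#' @param loading_window Force-vs-time fit window for the loading rate, s.
#' @param persistence Unfolded-chain persistence length, nm.
#' @param hop_cluster_pn Force width used to cluster hopping events, pN.
#' @return A tibble of rip events: `cycle_id`, `segment`, `direction`,
#'   `time`, `rupture_force`, `delta_x`, `delta_lc`, `loading_rate`,
#'   `reversible`.
#' @export
detect_rips <- function(trace, smooth_window = 5, threshold_k = 6,
                        min_jump = 2, min_separation = 0.025,
                        min_force_drop = 0.4, baseline_window = 0.25,
                        loading_window = 0.05,
                        persistence = 0.65, hop_cluster_pn = 2.5) {
  stopifnot(inherits(trace, "force_ramp_trace"))
  proto <- attr(trace, "protocol")
  temperature <- if (!is.null(proto)) proto$temperature else 293.15
  sr <- if (!is.null(proto)) proto$sample_rate else
    1 / median(diff(trace$time))
  wp <- wlc_params(persistence, temperature = temperature)
  w <- as.integer(smooth_window)
  bw <- max(3L, round(baseline_window * sr))
  bw_lr <- max(3L, round(loading_window * sr))
  sep <- max(1L, round(min_separation * sr))

  groups <- split(seq_len(nrow(trace)),
                  paste(trace$cycle_id, trace$segment, sep = "."))
  out <- list()
  for (ix in groups) {
    x <- trace$extension[ix]
    f <- trace$force[ix]
    tt <- trace$time[ix]
    n <- length(x)
    if (n < 2 * w + 2) {
      abort(sprintf("Segment with %d samples is too short to smooth (need > %d).",
                    n, 2 * w + 1), class = "tweezfold_too_short_trace")
    }
    cs <- cumsum(c(0, x))
    fwd <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w # mean x[i..i+w-1]
    # d[i] = mean(x[i+1 .. i+w]) - mean(x[i-w+1 .. i]), defined for i in w..n-w
    i_lo <- w
    i_hi <- n - w
    d <- fwd[(i_lo + 1):(i_hi + 1)] - fwd[(i_lo - w + 1):(i_hi - w + 1)]
    centers <- i_lo:i_hi
    thr <- max(threshold_k * stats::mad(d), min_jump)
    med <- median(d)
    cand <- which(d > med + thr | d < med - thr)
    if (length(cand) == 0) next

    # merge candidates closer than the minimum separation, keep larger jump
    ord <- cand[order(-abs(d[cand] - med))]
    keep <- integer(0)
    for (i in ord) {
      if (all(abs(centers[i] - centers[keep]) > max(sep, w))) {
        keep <- c(keep, i)
      }
    }
    keep <- sort(keep)
    ev_centers <- centers[keep]

    seg <- trace$segment[ix[1]]
    cyc <- trace$cycle_id[ix[1]]
    for (j in seq_along(keep)) {
      c0 <- ev_centers[j]
      up <- d[keep[j]] - med > 0
      prev_c <- if (j > 1) ev_centers[j - 1] else 0L
      next_c <- if (j < length(keep)) ev_centers[j + 1] else n + 1L
      pre_ix <- max(prev_c + w + 1, c0 - w - bw + 1):(c0 - 1)
      post_ix <- (c0 + w + 1):min(next_c - w - 1, c0 + w + bw)
      pre_ix <- pre_ix[pre_ix >= 1 & pre_ix <= n]
      post_ix <- post_ix[post_ix >= 1 & post_ix <= n]
      if (length(pre_ix) < 2 || length(post_ix) < 2) next
      f_r <- f[max(1, c0 - 1)]

      base_at <- function(ii) {
        if (diff(range(f[ii])) < 0.02) return(mean(x[ii]))
        cf <- coef(lm(x[ii] ~ f[ii]))
        cf[1] + cf[2] * f_r
      }
      dx <- base_at(post_ix) - base_at(pre_ix)
      if (!up) dx <- -abs(dx) else dx <- abs(dx)
      # concurrent force change: drop for unfolding, rise for refolding
      df_ev <- mean(f[post_ix[seq_len(min(3, length(post_ix)))]]) -
        mean(f[pre_ix[pmax(1, length(pre_ix) - 2):length(pre_ix)]])
      if (up && df_ev > -min_force_drop) next
      if (!up && df_ev < min_force_drop) next

      lr_ix <- max(1, c0 - bw_lr + 1):c0
      lr <- if (length(lr_ix) >= 3)
        unname(coef(lm(f[lr_ix] ~ tt[lr_ix]))[2]) else NA_real_
      xi <- frac_extension_at(f_r, wp)
      out[[length(out) + 1L]] <- tibble::tibble(
        cycle_id = cyc, segment = seg,
        direction = if (up) "unfold" else "refold",
        time = tt[c0], rupture_force = f_r,
        delta_x = abs(dx), delta_lc = abs(dx) / xi,
        loading_rate = lr, reversible = FALSE)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      cycle_id = integer(), segment = character(), direction = character(),
      time = numeric(), rupture_force = numeric(), delta_x = numeric(),
      delta_lc = numeric(), loading_rate = numeric(), reversible = logical()))
  }
  events <- dplyr::bind_rows(out)

  # hopping: a transition re-crossed repeatedly shows up as >= 3 events of
  # mixed direction, at nearby forces, with comparable jump sizes
  events <- events |>
    dplyr::group_by(.data$cycle_id, .data$segment) |>
    dplyr::group_modify(function(g, key) {
      m <- nrow(g)
      if (m >= 3) {
        link <- abs(outer(g$rupture_force, g$rupture_force, "-")) <=
          hop_cluster_pn &
          outer(g$delta_x, g$delta_x, function(a, b)
            pmax(a, b) / pmin(a, b)) <= 2.5
        comp <- seq_len(m)
        repeat { # label propagation to connected components
          new <- vapply(seq_len(m), function(i) min(comp[link[i, ]]),
                        numeric(1))
          if (identical(new, comp)) break
          comp <- new
        }
        for (k in unique(comp)) {
          members <- which(comp == k)
          if (length(members) >= 3 &&
              length(unique(g$direction[members])) == 2) {
            g$reversible[members] <- TRUE
          }
        }
      }
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cycle_id, .data$time)
  events
}

#' Aggregate rip events into per-domain rupture statistics
#'
#' @param events Rip events from [detect_rips()], optionally with extra
#'   grouping columns.
#' @param domain Optional character vector assigning each event to a
#'   domain; if missing, an existing `domain` column is used, else all
#'   events form one group.
#' @param condition Optional condition label(s) (e.g. apo / cAMP / cGMP).
#' @return A tibble with one row per (domain, condition): `F_avg`, `F_sd`,
#'   `N`, `delta_lc_mean`.
#' @export
aggregate_rips <- function(events, domain = NULL, condition = NULL) {
  if (nrow(events) == 0) {
    abort("No events to aggregate.", class = "tweezfold_missing_group")
  }
  ev <- events
  if (!is.null(domain)) ev$domain <- domain
  if (!"domain" %in% names(ev)) ev$domain <- "all"
  if (!is.null(condition)) ev$condition <- condition
  if (!"condition" %in% names(ev)) ev$condition <- "unspecified"
  ev |>
    dplyr::group_by(.data$domain, .data$condition) |>
    dplyr::summarise(
      F_avg = mean(.data$rupture_force),
      F_sd = if (dplyr::n() > 1) sd(.data$rupture_force) else 0,
      N = dplyr::n(),
      delta_lc_mean = mean(.data$delta_lc),
      .groups = "drop") |>
    dplyr::arrange(.data$domain, .data$condition)
}

#' Level separation of a reversible hopping transition in ramp data
#'
#' Per-event extension jumps of a fast two-state hopper in a force ramp
#' are noisy: short dwells truncate or contaminate the local baselines.
#' This estimator instead treats each reversible event cluster as a short
#' two-level region and fits a shared-slope two-line model
#' `x = a + b f + s delta_x` (state `s` latent) by a small EM-style
#' alternation: assign each sample to the nearer line, refit, repeat.
#' Fitting the state offset jointly with the baseline slope matters
#' because occupancy drifts with force across the hopping window, which
#' would otherwise leak level separation into the detrend. The level
#' separation at the cluster's mean force gives one (force, delta_x)
#' point per cluster; the pooled points are fed to [fit_delta_lc()].
#'
#' @param trace The `force_ramp_trace` the events came from.
#' @param events Rip events from [detect_rips()] (only rows with
#'   `reversible = TRUE` are used).
#' @param pad Time padding around each cluster, s.
#' @param persistence Unfolded-chain persistence length, nm.
#' @return A list with `points` (one row per hopping cluster: `force`,
#'   `delta_x`, `n_samples`) and `fit` (the pooled [fit_delta_lc()]
#'   result, or NULL if fewer than 3 clusters).
#' @export
fit_hopping_ramp <- function(trace, events, pad = 0.05,
                             persistence = 0.65) {
  rev_ev <- events[events$reversible, , drop = FALSE]
  if (nrow(rev_ev) == 0) {
    abort("No reversible events: nothing to fit.",
          class = "tweezfold_missing_group")
  }
  clusters <- rev_ev |>
    dplyr::group_by(.data$cycle_id, .data$segment) |>
    dplyr::summarise(t0 = min(.data$time), t1 = max(.data$time),
                     .groups = "drop")
  fwin <- rev_ev |>
    dplyr::group_by(.data$cycle_id, .data$segment) |>
    dplyr::summarise(f_lo = min(.data$rupture_force) - 0.5,
                     f_hi = max(.data$rupture_force) + 0.5,
                     .groups = "drop")
  clusters <- dplyr::left_join(clusters, fwin,
                               by = c("cycle_id", "segment"))
  pts <- purrr::pmap_dfr(clusters, function(cycle_id, segment, t0, t1,
                                            f_lo, f_hi) {
    sel <- trace$cycle_id == cycle_id & trace$segment == segment &
      trace$time >= t0 - pad & trace$time <= t1 + pad &
      trace$force >= f_lo & trace$force <= f_hi
    x <- trace$extension[sel]
    f <- trace$force[sel]
    if (length(x) < 30) return(NULL)
    # shared-slope two-line EM: init states from detrended residual sign
    r0 <- stats::residuals(lm(x ~ f))
    s <- as.integer(r0 > median(r0))
    sep <- NA_real_
    for (it in 1:25) {
      cf <- coef(lm(x ~ f + s))
      if (is.na(cf[["s"]])) break
      sep_new <- cf[["s"]]
      resid0 <- x - cf[[1]] - cf[[2]] * f
      s_new <- as.integer(abs(resid0 - sep_new) < abs(resid0))
      if (!is.na(sep) && abs(sep_new - sep) < 1e-10) {
        s <- s_new; sep <- sep_new; break
      }
      s <- s_new; sep <- sep_new
    }
    if (is.na(sep) || min(mean(s), 1 - mean(s)) < 0.05) return(NULL)
    # a genuine hopper re-crosses: a single step (e.g. an adjacent
    # irreversible zip swallowed by the window) changes state only once
    if (sum(diff(s) != 0) < 3) return(NULL)
    tibble::tibble(force = mean(f), delta_x = abs(sep),
                   n_samples = length(x))
  })
  fit <- NULL
  if (nrow(pts) >= 3) {
    if (diff(range(pts$force)) >= 2) {
      fit <- fit_delta_lc(data.frame(force = pts$force,
                                     delta_x = pts$delta_x),
                          persistence = persistence)
    } else {
      # hopping is confined to a narrow force window; with little force
      # leverage the one-parameter model reduces to averaging per-cluster
      # delta_x / xi(F)
      dlc <- pts$delta_x / frac_extension_at(pts$force,
                                             wlc_params(persistence))
      fit <- tibble::tibble(delta_lc = mean(dlc),
                            se = sd(dlc) / sqrt(length(dlc)),
                            n_points = length(dlc))
    }
  }
  list(points = pts, fit = fit)
}

#' Unfolding-force histogram with per-bin loading rates
#'
#' Normalized probability density of unfolding rupture forces, with the
#' mean loading rate of the events in each bin (needed by the
#' lifetime transform).
#'
#' @param events Rip events; only `direction == "unfold"` rows are used.
#' @param bin_width Bin width, pN.
#' @return An `unfolding_histogram` tibble: `bin_center`, `count`,
#'   `density`, `loading_rate`; attributes `bin_width` and `n`.
#' @export
unfolding_histogram <- function(events, bin_width = 1) {
  stopifnot(bin_width > 0)
  unf <- events[events$direction == "unfold", , drop = FALSE]
  if (nrow(unf) == 0) {
    abort("No unfolding events: cannot build a histogram.",
          class = "tweezfold_empty_histogram")
  }
  f <- unf$rupture_force
  lo <- floor(min(f) / bin_width) * bin_width
  breaks <- seq(lo, max(f) + bin_width, by = bin_width)
  bin <- findInterval(f, breaks, rightmost.closed = TRUE)
  n <- length(f)
  tab <- tibble::tibble(bin = bin, force = f, lr = unf$loading_rate) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(count = dplyr::n(),
                     loading_rate = mean(.data$lr, na.rm = TRUE),
                     .groups = "drop")
  out <- tibble::tibble(bin = seq_len(length(breaks) - 1L)) |>
    dplyr::left_join(tab, by = "bin") |>
    dplyr::mutate(
      bin_center = breaks[.data$bin] + bin_width / 2,
      count = dplyr::coalesce(.data$count, 0L),
      density = .data$count / (n * bin_width)) |>
    dplyr::select("bin_center", "count", "density", "loading_rate")
  attr(out, "bin_width") <- bin_width
  attr(out, "n") <- n
  class(out) <- c("unfolding_histogram", class(out))
  out
}
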