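#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_step
#'   geom_tile geom_errorbar facet_wrap labs scale_x_log10 scale_y_log10
#'   theme_minimal
NULL

.ci_lookup <- function(ci, term) {
  if (is.null(ci) || !term %in% ci$term) return(c(NA_real_, NA_real_))
  c(ci$conf.low[ci$term == term], ci$conf.high[ci$term == term])
}

#' Tidy a kinetic-parameter fit
#'
#' @param x A `kinetic_params` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.kinetic_params <- function(x, ...) {
  terms <- c("tau0", "dx_ddagger")
  est <- c(x$tau0, x$dx_ddagger)
  if (!is.na(x$dg_ddagger)) {
    terms <- c(terms, "dg_ddagger")
    est <- c(est, x$dg_ddagger)
  }
  ci <- t(vapply(terms, .ci_lookup, numeric(2), ci = x$ci))
  tibble::tibble(term = terms, estimate = est,
                 conf.low = ci[, 1], conf.high = ci[, 2])
}

#' @rdname tidy.kinetic_params
#' @export
glance.kinetic_params <- function(x, ...) {
  tibble::tibble(model = x$model, nu = x$nu, role = x$role,
                 n_bins = if (is.null(x$curve)) NA_integer_ else
                   nrow(x$curve),
                 temperature = x$temperature)
}

#' Tidy a binding-model fit
#'
#' @param x A `binding_fit` object.
#' @param ... Unused.
#' @return A tibble with rows `K_A`, `K_B`, `gamma`.
#' @export
tidy.binding_fit <- function(x, ...) {
  terms <- c("K_A", "K_B", "gamma")
  est <- c(x$model$K_A, x$model$K_B, x$model$gamma)
  ci <- t(vapply(terms, .ci_lookup, numeric(2), ci = x$ci))
  tibble::tibble(term = terms, estimate = est,
                 conf.low = ci[, 1], conf.high = ci[, 2])
}

#' @rdname tidy.binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, fixed_gamma = x$fixed_gamma,
                 n_conc = nrow(x$counts),
                 n_molecules = sum(.counts_matrix(x$counts)),
                 convergence = x$convergence)
}

#' Tidy a hopping BHMM fit
#'
#' @param x A `bhmm_fit` object.
#' @param ... Unused.
#' @return The posterior summary tibble (`term`, `estimate`, `conf.low`,
#'   `conf.high`).
#' @export
tidy.bhmm_fit <- function(x, ...) x$summary

#' @rdname tidy.bhmm_fit
#' @export
glance.bhmm_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_draws = nrow(x$draws),
                 burn_in = x$burn_in, rhat = x$rhat,
                 setpoint_force = x$setpoint_force %||% NA_real_)
}

#' Plot a force-extension trace
#'
#' @param object A `force_ramp_trace`.
#' @param ... Unused.
#' @return A ggplot: force vs extension, coloured by segment, one panel
#'   per cycle.
#' @export
autoplot.force_ramp_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$extension, y = .data$force,
                     colour = .data$segment)) +
    geom_path_grouped() +
    facet_wrap(~cycle_id) +
    labs(x = "extension (nm)", y = "force (pN)", colour = NULL) +
    theme_minimal()
}

# thin wrapper so the plot draws stretch and relax as separate paths
geom_path_grouped <- function() {
  ggplot2::geom_path(aes(group = interaction(.data$cycle_id,
                                             .data$segment)),
                     linewidth = 0.3)
}

#' Plot a constant-force hopping trace
#'
#' @param object A `force_clamp_trace`.
#' @param downsample Keep every `downsample`-th point (default 1).
#' @param ... Unused.
#' @return A ggplot of extension vs time.
#' @export
autoplot.force_clamp_trace <- function(object, downsample = 1, ...) {
  df <- object[seq(1, nrow(object), by = downsample), ]
  ggplot(df, aes(x = .data$time, y = .data$extension)) +
    geom_line(linewidth = 0.2) +
    labs(x = "time (s)", y = "extension (nm)") +
    theme_minimal()
}

#' Plot a lifetime curve with its kinetic fit
#'
#' @param object A `kinetic_params` object with an attached curve.
#' @param ... Unused.
#' @return A ggplot: measured lifetimes vs force (log y) with the model
#'   line.
#' @export
autoplot.kinetic_params <- function(object, ...) {
  curve <- object$curve
  if (is.null(curve)) {
    abort("No lifetime curve attached to this fit.",
          class = "tweezfold_invalid_input")
  }
  grid <- seq(min(curve$force), max(curve$force), length.out = 100)
  fitted <- tibble::tibble(force = grid,
                           lifetime = lifetime_at(object, grid))
  ggplot(curve, aes(x = .data$force, y = .data$lifetime)) +
    geom_point() +
    geom_line(data = fitted, colour = "black") +
    scale_y_log10() +
    labs(x = "force (pN)", y = "lifetime (s)") +
    theme_minimal()
}

#' Plot a titration fit
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot: observed species fractions vs concentration with the
#'   fitted curves.
#' @export
autoplot.binding_fit <- function(object, ...) {
  counts <- object$counts
  cmat <- .counts_matrix(counts)
  tot <- rowSums(cmat)
  obs <- tibble::tibble(conc_nM = rep(counts$conc_nM, 4),
                        species = rep(c("A0B0", "A1B0", "A0B1", "A1B1"),
                                      each = nrow(counts)),
                        fraction = as.numeric(cmat) / rep(tot, 4))
  grid <- exp(seq(log(max(min(counts$conc_nM), 0.1)),
                  log(max(counts$conc_nM)), length.out = 80))
  fr <- species_fractions(object$model, grid) |>
    tidyr::pivot_longer(-"conc_nM", names_to = "species",
                        values_to = "fraction") |>
    dplyr::mutate(species = sub("^f_", "", .data$species))
  ggplot(obs, aes(x = .data$conc_nM, y = .data$fraction,
                  colour = .data$species)) +
    geom_point() +
    geom_line(data = fr) +
    scale_x_log10() +
    labs(x = "ligand (nM)", y = "species fraction", colour = NULL) +
    theme_minimal()
}

#' Plot a partitioned contact map
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot tile map of contacts coloured by partition.
#' @export
autoplot.contact_map <- function(object, ...) {
  both <- dplyr::bind_rows(
    object,
    dplyr::rename(object, res_i = "res_j", res_j = "res_i"))
  ggplot(both, aes(x = .data$res_i, y = .data$res_j,
                   fill = .data$partition)) +
    geom_tile() +
    labs(x = "residue", y = "residue", fill = NULL) +
    theme_minimal()
}

#' Plot posterior distributions of a hopping fit
#'
#' @param object A `bhmm_fit`.
#' @param ... Unused.
#' @return A ggplot of posterior histograms per parameter.
#' @export
autoplot.bhmm_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$draws, dplyr::everything(),
                              names_to = "term", values_to = "value")
  ggplot(long, aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60) +
    facet_wrap(~term, scales = "free") +
    labs(x = NULL, y = "posterior draws") +
    theme_minimal()
}

#' Plot an energy-landscape summary
#'
#' Schematic piecewise-linear landscape per condition: unfolded state at
#' zero, barrier at its fitted position and height, folded well at the
#' equilibrium depth.
#'
#' @param landscape Output of [landscape_summary()].
#' @return A ggplot.
#' @export
plot_landscape <- function(landscape) {
  seg <- landscape |>
    dplyr::rowwise() |>
    dplyr::reframe(
      condition = .data$condition,
      x = c(0, .data$barrier_position,
            .data$reaction_coordinate_span),
      G = c(.data$dG_eq, .data$barrier_height, 0))
  ggplot(seg, aes(x = .data$x, y = .data$G, colour = .data$condition)) +
    geom_line() +
    geom_point() +
    labs(x = "pulling coordinate from folded state (nm)",
         y = "free energy (kcal/mol, unfolded = 0)", colour = NULL) +
    theme_minimal()
}
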