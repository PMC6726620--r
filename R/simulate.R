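#' Pulling protocol for force-ramp simulations
#'
#' Instrument-side parameters of a force-ramp experiment: trap velocity,
#' sampling, force limits, refolding hold, trap stiffness and the effective
#' DNA-handle worm-like chain. Defaults follow common practice for
#' MiniTweezers-style protein pulling: 75 nm/s pulling velocity, 200 Hz
#' sampling, a 10 s refolding hold at 2 pN.
#'
#' @param pull_velocity Trap velocity in nm/s.
#' @param sample_rate Sampling rate in Hz.
#' @param refold_hold_force Hold force between cycles, pN.
#' @param refold_hold_time Hold duration between cycles, s.
#' @param min_force Force at which a stretch segment starts, pN.
#' @param max_force Force at which a stretch segment ends, pN.
#' @param temperature Temperature, K.
#' @param trap_stiffness Trap spring constant, pN/nm.
#' @param handle_contour Effective contour length of the DNA handles, nm.
#'   The default 260 nm stands in for 2 x (350 + 30) bp of dsDNA.
#' @param handle_persistence Persistence length of the handle WLC, nm.
#' @param protein_persistence Persistence length of unfolded polypeptide, nm.
#' @return A list of class `pulling_protocol`.
#' @export
pulling_protocol <- function(pull_velocity = 75, sample_rate = 200,
                             refold_hold_force = 2, refold_hold_time = 10,
                             min_force = 2, max_force = 25,
                             temperature = 293.15, trap_stiffness = 0.1,
                             handle_contour = 260, handle_persistence = 10,
                             protein_persistence = 0.65) {
  vals <- c(pull_velocity = pull_velocity, sample_rate = sample_rate,
            refold_hold_force = refold_hold_force,
            refold_hold_time = refold_hold_time,
            min_force = min_force, max_force = max_force,
            temperature = temperature, trap_stiffness = trap_stiffness,
            handle_contour = handle_contour,
            handle_persistence = handle_persistence,
            protein_persistence = protein_persistence)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All pulling-protocol parameters must be positive and finite.",
          class = "tweezfold_invalid_protocol")
  }
  if (min_force >= max_force) {
    abort("`min_force` must be smaller than `max_force`.",
          class = "tweezfold_invalid_protocol")
  }
  structure(as.list(vals), class = "pulling_protocol")
}

#' Domain specification for the trajectory simulator
#'
#' Describes one cooperatively (un)folding structural unit: the contour
#' length it releases on unfolding, its folded end-to-end distance, and Bell
#' unfolding/refolding kinetics. The released contour is
#' `n_residues * l_aa - d_nc`; it can also be given directly via `delta_lc`.
#'
#' @param name Domain label.
#' @param unfold_tau0 Folded-state lifetime extrapolated to zero force, s.
#' @param unfold_dx Distance to the unfolding transition state, nm.
#' @param refold_tau0 Unfolded-state lifetime at zero force, s.
#' @param refold_dx Distance to the refolding transition state, nm. Force
#'   opposes refolding, so the refolding rate carries `exp(-F dx / kBT)`.
#' @param n_residues Number of residues in the folded unit (optional if
#'   `delta_lc` is given).
#' @param d_nc Folded-state end-to-end (N-to-C) distance, nm.
#' @param delta_lc Contour length released on unfolding, nm. Computed from
#'   `n_residues`, `l_aa` and `d_nc` when missing.
#' @param l_aa Contour length per residue, nm (default 0.365).
#' @param reversible Logical; marks a hopping-capable unit (for example, an
#'   N3A-like motif that interconverts repeatedly within one ramp).
#' @return A list of class `domain_spec`.
#' @examples
#' domain_spec("CNB-A_apo", unfold_tau0 = 1.3e3, unfold_dx = 4.5,
#'             refold_tau0 = 0.05, refold_dx = 7, n_residues = 133,
#'             d_nc = 3.5)
#' @export
domain_spec <- function(name, unfold_tau0, unfold_dx, refold_tau0 = Inf,
                        refold_dx = 7, n_residues = NULL, d_nc = 0,
                        delta_lc = NULL, l_aa = 0.365, reversible = FALSE) {
  if (unfold_tau0 <= 0 || unfold_dx <= 0 || refold_tau0 <= 0 ||
      refold_dx <= 0 || d_nc < 0 || l_aa <= 0) {
    abort("Domain kinetic and geometric parameters must be positive (d_nc >= 0).",
          class = "tweezfold_invalid_protocol")
  }
  if (is.null(delta_lc)) {
    if (is.null(n_residues)) {
      abort("Give either `delta_lc` or `n_residues`.",
            class = "tweezfold_invalid_protocol")
    }
    delta_lc <- n_residues * l_aa - d_nc
  }
  if (delta_lc <= 0) {
    abort("Released contour length must be positive: check n_residues, l_aa and d_nc.",
          class = "tweezfold_invalid_protocol")
  }
  structure(
    list(name = name, unfold_tau0 = unfold_tau0, unfold_dx = unfold_dx,
         refold_tau0 = refold_tau0, refold_dx = refold_dx,
         n_residues = n_residues, d_nc = d_nc, delta_lc = delta_lc,
         l_aa = l_aa, reversible = isTRUE(reversible)),
    class = "domain_spec"
  )
}

# Bell hazards, 1/s
.unfold_rate <- function(domain, force, kT) {
  exp(force * domain$unfold_dx / kT) / domain$unfold_tau0
}
.refold_rate <- function(domain, force, kT) {
  exp(-force * domain$refold_dx / kT) / domain$refold_tau0
}

# Serial-compliance tether model: trap spring + handle WLC + unfolded
# polypeptide WLC + rigid folded cores. Returns interpolators between trap
# displacement D and force F for a given folded/unfolded state.
.tether_model <- function(domains, protocol) {
  kT <- kBT(protocol$temperature)
  wp_h <- wlc_params(protocol$handle_persistence, protocol$handle_contour,
                     protocol$temperature)
  wp_p <- wlc_params(protocol$protein_persistence,
                     temperature = protocol$temperature)
  f_grid <- c(seq(0.01, 2, by = 0.01),
              seq(2.02, 1.8 * protocol$max_force + 10, by = 0.02))
  xi_h <- frac_extension_at(f_grid, wp_h)
  xi_p <- frac_extension_at(f_grid, wp_p)
  cache <- new.env(parent = emptyenv())
  get_maps <- function(folded) {
    key <- paste(as.integer(folded), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    lc_unf <- sum(vapply(domains[!folded],
                         function(d) d$delta_lc + d$d_nc, numeric(1)))
    rigid <- sum(vapply(domains[folded], function(d) d$d_nc, numeric(1)))
    D <- f_grid / protocol$trap_stiffness +
      protocol$handle_contour * xi_h + lc_unf * xi_p + rigid
    m <- list(D = D, F = f_grid)
    cache[[key]] <- m
    m
  }
  list(
    force_at = function(D, folded) {
      m <- get_maps(folded)
      if (any(D > max(m$D) | D < min(m$D))) {
        abort(sprintf(
          "Extension solver out of range: trap displacement maps outside force grid [%.2f, %.2f] pN.",
          min(m$F), max(m$F)), class = "tweezfold_numerical_error")
      }
      approx(m$D, m$F, xout = D)$y
    },
    displacement_at = function(force, folded) {
      m <- get_maps(folded)
      approx(m$F, m$D, xout = force)$y
    },
    xi_protein = function(force) approx(f_grid, xi_p, xout = force)$y,
    kT = kT
  )
}

# First-event sampler on a per-step frozen-rate grid. rates: matrix
# [steps x domains] of hazards. Returns NULL or list(index, domain).
.sample_event <- function(rates, dt) {
  total <- rowSums(rates)
  H <- cumsum(total * dt)
  E <- rexp(1)
  if (E > H[length(H)] || length(H) == 0) return(NULL)
  idx <- which(H >= E)[1]
  p <- rates[idx, ]
  dom <- sample.int(length(p), 1, prob = p)
  list(index = idx, domain = dom)
}

#' Simulate force-ramp pulling cycles
#'
#' Kinetic Monte-Carlo simulation of repeated stretch/relax cycles at
#' constant trap velocity. Instantaneous force solves the serial-compliance
#' balance (trap spring, handle WLC, unfolded-polypeptide WLC, rigid folded
#' cores) at each 1/`sample_rate` time step; within a step hazards are
#' frozen (Gillespie-style thinning). Folded domains unfold with Bell hazard
#' `exp(F dx/kBT)/tau0`, unfolded ones refold with `exp(-F dx/kBT)/tau0`;
#' a `reversible` domain may interconvert many times within one ramp.
#' Between cycles the tether is held at the refolding force for the
#' protocol's hold time (state evolves but is not recorded).
#'
#' @param domains A list of [domain_spec()] objects (a single spec is
#'   accepted).
#' @param protocol A [pulling_protocol()].
#' @param n_cycles Number of stretch/relax cycles.
#' @param seed Integer seed; all randomness flows from it.
#' @param noise_sd Gaussian measurement noise added to extension, nm.
#' @param construct Construct label stored with the trace.
#' @return A list with `trace` (a `force_ramp_trace` tibble: `time`,
#'   `extension`, `force`, `cycle_id`, `segment`) and `ground_truth`
#'   (tibble of true events: `cycle_id`, `segment`, `domain`, `direction`,
#'   `time`, `force`).
#' @export
simulate_force_ramp <- function(domains, protocol = pulling_protocol(),
                                n_cycles = 1, seed = 1, noise_sd = 0,
                                construct = "sim") {
  if (inherits(domains, "domain_spec")) domains <- list(domains)
  stopifnot(length(domains) >= 1, inherits(protocol, "pulling_protocol"))
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "tweezfold_invalid_parameter")
  }
  set.seed(seed)
  model <- .tether_model(domains, protocol)
  kT <- model$kT
  dt <- 1 / protocol$sample_rate
  v <- protocol$pull_velocity
  nd <- length(domains)
  dom_names <- vapply(domains, `[[`, character(1), "name")

  all_folded <- rep(TRUE, nd)
  D_start <- model$displacement_at(protocol$min_force, all_folded)
  D_end <- model$displacement_at(protocol$max_force, rep(FALSE, nd))

  folded <- all_folded
  t_now <- 0
  traces <- vector("list", n_cycles)
  events <- list()

  rate_matrix <- function(force_vec) {
    m <- matrix(0, length(force_vec), nd)
    for (j in seq_len(nd)) {
      m[, j] <- if (folded[j]) .unfold_rate(domains[[j]], force_vec, kT)
                else .refold_rate(domains[[j]], force_vec, kT)
    }
    m
  }

  run_segment <- function(D_vec, segment, cycle, t0) {
    n <- length(D_vec)
    force <- numeric(n)
    i <- 1L
    while (i <= n) {
      f_rest <- model$force_at(D_vec[i:n], folded)
      if (segment == "stretch") {
        # end the stretch once the setpoint maximum force is reached
        over <- which(f_rest >= protocol$max_force)
        if (length(over) > 0 && (i + over[1] - 1L) < n) {
          n <- i + over[1] - 1L
          f_rest <- f_rest[seq_len(n - i + 1L)]
          force <- force[seq_len(n)]
          D_vec <- D_vec[seq_len(n)]
        }
      }
      ev <- .sample_event(rate_matrix(f_rest), dt)
      if (is.null(ev)) {
        force[i:n] <- f_rest
        break
      }
      j <- i + ev$index - 1L
      force[i:j] <- f_rest[seq_len(ev$index)]
      d <- ev$domain
      events[[length(events) + 1L]] <<- tibble::tibble(
        cycle_id = cycle, segment = segment, domain = dom_names[d],
        direction = if (folded[d]) "unfold" else "refold",
        time = t0 + (j - 1L) * dt, force = force[j])
      folded[d] <<- !folded[d]
      i <- j + 1L
    }
    tibble::tibble(
      time = t0 + (seq_len(n) - 1L) * dt,
      extension = D_vec[seq_len(n)] - force / protocol$trap_stiffness +
        if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0,
      force = force,
      cycle_id = cycle, segment = segment)
  }

  for (cyc in seq_len(n_cycles)) {
    n_up <- max(2L, ceiling((D_end - D_start) / (v * dt)))
    D_up <- D_start + (seq_len(n_up) - 1L) * v * dt
    st <- run_segment(D_up, "stretch", cyc, t_now)
    t_now <- st$time[nrow(st)] + dt
    D_top <- D_start + (nrow(st) - 1L) * v * dt
    n_dn <- max(2L, ceiling((D_top - D_start) / (v * dt)))
    D_dn <- D_top - (seq_len(n_dn) - 1L) * v * dt
    rx <- run_segment(D_dn, "relax", cyc, t_now)
    t_now <- rx$time[nrow(rx)] + dt
    traces[[cyc]] <- dplyr::bind_rows(st, rx)

    # refolding hold at constant force (state evolves, samples not recorded)
    f_hold <- protocol$refold_hold_force
    t_h <- 0
    repeat {
      r <- vapply(seq_len(nd), function(j) {
        if (folded[j]) .unfold_rate(domains[[j]], f_hold, kT)
        else .refold_rate(domains[[j]], f_hold, kT)
      }, numeric(1))
      if (sum(r) <= 0) break
      t_h <- t_h + rexp(1, sum(r))
      if (t_h > protocol$refold_hold_time) break
      d <- sample.int(nd, 1, prob = r)
      events[[length(events) + 1L]] <- tibble::tibble(
        cycle_id = cyc, segment = "hold", domain = dom_names[d],
        direction = if (folded[d]) "unfold" else "refold",
        time = t_now + t_h, force = f_hold)
      folded[d] <- !folded[d]
    }
    t_now <- t_now + protocol$refold_hold_time
  }

  trace <- dplyr::bind_rows(traces)
  attr(trace, "protocol") <- protocol
  attr(trace, "construct") <- construct
  class(trace) <- c("force_ramp_trace", class(trace))
  gt <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(cycle_id = integer(), segment = character(),
                   domain = character(), direction = character(),
                   time = numeric(), force = numeric())
  list(trace = trace, ground_truth = gt)
}

#' Sample rupture forces at a constant loading rate
#'
#' Direct kinetic Monte-Carlo sampling of first unfolding forces for a
#' single domain under a linear force ramp `F(t) = f_start + loading_rate t`,
#' with the hazard frozen within each time step. This is the
#' constant-loading-rate idealization used to validate the rupture-force
#' machinery against the Bell-Evans first-passage density.
#'
#' @param domain A [domain_spec()].
#' @param loading_rate Loading rate, pN/s.
#' @param n Number of independent pulls.
#' @param seed Integer seed.
#' @param dt Time step, s.
#' @param f_start Starting force, pN.
#' @param temperature Temperature, K.
#' @param f_max Upper force bound for the grid, pN.
#' @return A tibble with columns `rupture_force` (pN) and `loading_rate`.
#' @export
simulate_rupture_forces <- function(domain, loading_rate, n, seed = 1,
                                    dt = 0.005, f_start = 0,
                                    temperature = 293.15, f_max = 60) {
  stopifnot(inherits(domain, "domain_spec"))
  if (loading_rate <= 0) {
    abort("`loading_rate` must be positive.",
          class = "tweezfold_invalid_protocol")
  }
  set.seed(seed)
  kT <- kBT(temperature)
  f_grid <- seq(f_start, f_max, by = loading_rate * dt)
  haz <- .unfold_rate(domain, f_grid, kT)
  H <- cumsum(haz * dt)
  E <- rexp(n)
  idx <- findInterval(E, H) + 1L
  if (any(idx > length(f_grid))) {
    abort("Force grid too short: some pulls survived past `f_max`.",
          class = "tweezfold_numerical_error")
  }
  tibble::tibble(rupture_force = f_grid[idx], loading_rate = loading_rate)
}

#' Simulate a constant-force hopping trace
#'
#' Two-state telegraph process between folded and unfolded states of one
#' domain at a fixed clamp force, with exponential dwell times set by the
#' Bell hazards at that force. Recorded extension is the state mean (levels
#' separated by `delta_lc * xi(F)`) plus Gaussian measurement noise.
#'
#' @param domain A [domain_spec()].
#' @param clamp_force Setpoint force, pN.
#' @param duration Trace length, s.
#' @param sample_rate Sampling rate, Hz.
#' @param noise_sd Gaussian noise SD on extension, nm.
#' @param seed Integer seed.
#' @param protein_persistence Persistence length of the unfolded chain, nm.
#' @param temperature Temperature, K.
#' @param construct Construct label.
#' @return A list with `trace` (a `force_clamp_trace` tibble: `time`,
#'   `extension`) and `ground_truth` (list with `states` tibble of the true
#'   state at every sample, `dwells` tibble, and the level separation
#'   `delta_x`).
#' @export
simulate_force_clamp <- function(domain, clamp_force, duration,
                                 sample_rate = 1000, noise_sd = 0, seed = 1,
                                 protein_persistence = 0.65,
                                 temperature = 293.15, construct = "sim") {
  stopifnot(inherits(domain, "domain_spec"))
  if (duration <= 0) {
    abort("`duration` must be positive.", class = "tweezfold_invalid_parameter")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "tweezfold_invalid_parameter")
  }
  set.seed(seed)
  kT <- kBT(temperature)
  k_u <- .unfold_rate(domain, clamp_force, kT)
  k_f <- .refold_rate(domain, clamp_force, kT)
  xi <- frac_extension_at(clamp_force,
                          wlc_params(protein_persistence,
                                     temperature = temperature))
  delta_x <- domain$delta_lc * xi

  # exact Gillespie dwell sampling
  trans <- numeric(0)
  state0 <- 0L # 0 = folded
  s <- state0
  t <- 0
  repeat {
    rate <- if (s == 0L) k_u else k_f
    if (rate <= 0) break
    t <- t + rexp(1, rate)
    if (t >= duration) break
    trans <- c(trans, t)
    s <- 1L - s
  }
  n <- floor(duration * sample_rate)
  time <- (seq_len(n) - 1L) / sample_rate
  state <- (state0 + findInterval(time, trans)) %% 2L
  extension <- state * delta_x +
    if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0

  trace <- tibble::tibble(time = time, extension = extension)
  attr(trace, "setpoint_force") <- clamp_force
  attr(trace, "sample_rate") <- sample_rate
  attr(trace, "construct") <- construct
  class(trace) <- c("force_clamp_trace", class(trace))

  bounds <- c(0, trans, duration)
  dwell_states <- (state0 + seq_along(bounds[-1]) - 1L) %% 2L
  gt <- list(
    states = tibble::tibble(time = time, state = state),
    dwells = tibble::tibble(
      state = ifelse(dwell_states == 0L, "folded", "unfolded"),
      duration = diff(bounds),
      censored = seq_along(dwell_states) %in% c(1L, length(dwell_states))),
    delta_x = delta_x,
    transitions = trans
  )
  list(trace = trace, ground_truth = gt)
}

#' Simulate titration species counts
#'
#' Draws per-concentration multinomial counts of the four liganded species
#' (A0B0, A1B0, A0B1, A1B1) from the equilibrium fractions of a sequential
#' cooperative two-site binding model, emulating the classification of
#' single-molecule pulling trajectories across a ligand titration.
#'
#' @param model A [binding_model()].
#' @param concentrations Ligand concentrations, nM.
#' @param n_molecules_per_conc Molecules classified per concentration
#'   (recycled).
#' @param seed Integer seed.
#' @return A `species_counts` tibble with columns `conc_nM`, `n_A0B0`,
#'   `n_A1B0`, `n_A0B1`, `n_A1B1`.
#' @export
simulate_titration_counts <- function(model, concentrations,
                                      n_molecules_per_conc, seed = 1) {
  if (any(concentrations < 0)) {
    abort("Concentrations must be >= 0.", class = "tweezfold_invalid_input")
  }
  if (any(n_molecules_per_conc <= 0)) {
    abort("`n_molecules_per_conc` must be positive.",
          class = "tweezfold_invalid_input")
  }
  set.seed(seed)
  n_per <- rep_len(n_molecules_per_conc, length(concentrations))
  fr <- species_fractions(model, concentrations)
  counts <- t(vapply(seq_along(concentrations), function(i) {
    p <- as.numeric(fr[i, c("f_A0B0", "f_A1B0", "f_A0B1", "f_A1B1")])
    as.integer(rmultinom(1, n_per[i], p))
  }, integer(4)))
  out <- tibble::tibble(
    conc_nM = concentrations,
    n_A0B0 = counts[, 1], n_A1B0 = counts[, 2],
    n_A0B1 = counts[, 3], n_A1B1 = counts[, 4])
  class(out) <- c("species_counts", class(out))
  out
}
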