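# Shared synthetic constructs for the test suite.

# Bell-kinetics hopper balanced at f_hop: tau_F(f_hop) = tau_U(f_hop) = tau_hop
make_hopper <- function(delta_lc = 13, f_hop = 11, tau_hop = 0.2, dx = 4,
                        reversible = TRUE, name = "N3A") {
  kT <- kBT()
  domain_spec(name,
              unfold_tau0 = tau_hop * exp(f_hop * dx / kT), unfold_dx = dx,
              refold_tau0 = tau_hop * exp(-f_hop * dx / kT), refold_dx = dx,
              delta_lc = delta_lc, reversible = reversible)
}

# hopper with asymmetric dwells at the clamp force
make_hopper_asym <- function(delta_lc, f_hop, tau_F, tau_U, dx = 4,
                             name = "N3A") {
  kT <- kBT()
  domain_spec(name,
              unfold_tau0 = tau_F * exp(f_hop * dx / kT), unfold_dx = dx,
              refold_tau0 = tau_U * exp(-f_hop * dx / kT), refold_dx = dx,
              delta_lc = delta_lc, reversible = TRUE)
}

# irreversibly unfolding domain, apo-CNB-like kinetics by default
make_domain <- function(delta_lc = 30, tau0 = 1e4, dx = 2.5,
                        refold_tau0 = 0.1, name = "dom") {
  domain_spec(name, unfold_tau0 = tau0, unfold_dx = dx,
              refold_tau0 = refold_tau0, refold_dx = 7, delta_lc = delta_lc)
}

# apo-window domain: unfolds near 7-9 pN
make_apo_domain <- function(delta_lc = 50, name = "apo") {
  domain_spec(name, unfold_tau0 = 1.3e3, unfold_dx = 4.5,
              refold_tau0 = 0.05, refold_dx = 7, delta_lc = delta_lc)
}

# analytic Bell-Evans rupture-force density by quadrature
bell_rupture_density <- function(tau0, dx, loading_rate,
                                 grid = seq(0, 40, by = 0.005),
                                 temperature = 293.15) {
  reconstruct_force_distribution(
    kinetic_params(tau0, dx, temperature = temperature),
    loading_rate, grid)
}

# exact Bell lifetime curve (no sampling noise) as a lifetime_curve object
make_bell_curve <- function(tau0, dx, forces = seq(3, 10, by = 1),
                            loading_rate = 1e4, counts = 1000,
                            role = "F->U", temperature = 293.15) {
  kT <- kBT(temperature)
  s <- if (role == "U->F") -1 else 1
  out <- tibble::tibble(force = forces,
                        lifetime = tau0 * exp(-s * forces * dx / kT),
                        count = rep_len(counts, length(forces)),
                        loading_rate = rep_len(loading_rate, length(forces)))
  attr(out, "role") <- role
  attr(out, "bin_width") <- diff(forces[1:2])
  attr(out, "n") <- sum(out$count)
  class(out) <- c("lifetime_curve", class(out))
  out
}

# brute-force residue contact oracle: direct double loop over residue pairs
brute_force_contacts <- function(atoms, cutoff) {
  res <- sort(unique(atoms$resno))
  out <- list()
  for (a in seq_along(res)) {
    for (b in seq_along(res)) {
      if (b <= a) next
      if (abs(res[b] - res[a]) < 2) next
      ia <- atoms[atoms$resno == res[a], c("x", "y", "z")]
      ib <- atoms[atoms$resno == res[b], c("x", "y", "z")]
      dmin <- Inf
      for (i in seq_len(nrow(ia))) {
        for (j in seq_len(nrow(ib))) {
          d <- sqrt(sum((ia[i, ] - ib[j, ])^2))
          if (d < dmin) dmin <- d
        }
      }
      if (dmin <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(res_i = res[a], res_j = res[b],
                                              min_dist = dmin)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(res_i = integer(), res_j = integer(), min_dist = numeric())
}
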