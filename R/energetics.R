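#' Equilibrium folding free energy from zero-force lifetimes
#'
#' Two-state relation `dG = R T ln(tau0_F / tau0_U)` with
#' R = 1.9872e-3 kcal/(mol K). Positive values mean the folded state is
#' more stable.
#'
#' @param tau0_F Folded-state lifetime at zero force, s.
#' @param tau0_U Unfolded-state lifetime at zero force, s.
#' @param temperature Temperature, K.
#' @return Free energy in kcal/mol.
#' @examples
#' equilibrium_dG(1e3, 1) # about 4.02 kcal/mol at 20 C
#' @export
equilibrium_dG <- function(tau0_F, tau0_U, temperature = 293.15) {
  if (any(tau0_F <= 0) || any(tau0_U <= 0)) {
    abort("Lifetimes must be positive.", class = "tweezfold_invalid_input")
  }
  .R_kcal * temperature * log(tau0_F / tau0_U)
}

#' Free-energy change from lifetime fold-changes
#'
#' A perturbation that multiplies the folded-state lifetime by `fold_F`
#' and divides the unfolded-state lifetime by `fold_U` changes the
#' equilibrium stability by `ddG = R T ln(fold_F * fold_U)`.
#'
#' @param fold_F Fold-increase of the folded-state lifetime.
#' @param fold_U Fold-decrease of the unfolded-state lifetime.
#' @param temperature Temperature, K.
#' @return Stability change in kcal/mol.
#' @examples
#' ddG_from_fold_changes(30, 4) # about 2.79 kcal/mol
#' @export
ddG_from_fold_changes <- function(fold_F, fold_U, temperature = 293.15) {
  if (any(fold_F <= 0) || any(fold_U <= 0)) {
    abort("Fold-changes must be positive.", class = "tweezfold_invalid_input")
  }
  .R_kcal * temperature * log(fold_F * fold_U)
}

#' Dissect ligand-binding and inter-domain free-energy contributions
#'
#' Given equilibrium stabilities for a domain measured (i) isolated and
#' ligand-free (type I, apo), (ii) isolated and ligand-bound (type I,
#' holo) and (iii) selectively pulled next to its ligand-bound neighbour
#' (type II, holo):
#' `dG_ligand = dG(I, holo) - dG(I, apo)` and
#' `dG_interdomain = dG(II, holo) - dG(I, holo)`. The decomposition
#' identity `dG(II, holo) = dG(I, apo) + dG_ligand + dG_interdomain`
#' holds exactly by construction.
#'
#' @param energies A data frame with columns `domain`, `construct`
#'   (`"I"`/`"II"`), `condition` (`"apo"`/`"holo"`) and `dG_eq`
#'   (kcal/mol).
#' @param temperature Temperature, K (carried into the output).
#' @return An energy table tibble, one row per domain: `dG_apo`,
#'   `dG_holo_isolated`, `dG_holo_interdomain`, `dG_ligand`,
#'   `dG_interdomain`, `temperature`.
#' @examples
#' dissect(data.frame(domain = "CNB-B", construct = c("I", "I", "II"),
#'                    condition = c("apo", "holo", "holo"),
#'                    dG_eq = c(7.6, 10.4, 13.6)))
#' @export
dissect <- function(energies, temperature = 293.15) {
  need <- c("domain", "construct", "condition", "dG_eq")
  if (!all(need %in% names(energies))) {
    abort(paste("`energies` needs columns:", paste(need, collapse = ", ")),
          class = "tweezfold_invalid_input")
  }
  energies |>
    dplyr::group_by(.data$domain) |>
    dplyr::group_modify(function(g, key) {
      pick <- function(con, cond) {
        v <- g$dG_eq[g$construct == con & g$condition == cond]
        if (length(v) != 1) {
          abort(sprintf(
            "Domain '%s': need exactly one dG_eq for (type %s, %s); found %d.",
            key$domain, con, cond, length(v)),
            class = "tweezfold_incomplete_design")
        }
        v
      }
      a <- pick("I", "apo")
      h <- pick("I", "holo")
      ii <- pick("II", "holo")
      tibble::tibble(dG_apo = a, dG_holo_isolated = h,
                     dG_holo_interdomain = ii,
                     dG_ligand = h - a, dG_interdomain = ii - h,
                     temperature = temperature)
    }) |>
    dplyr::ungroup()
}

#' Summarize folding energy landscapes from kinetic parameter pairs
#'
#' For each condition with matched unfolding (F->U) and refolding (U->F)
#' Bell parameters, places the landscape on a common convention: the
#' unfolded state sits at zero; the barrier height above the unfolded
#' state is `R T ln(tau0_U * k_att)` with an explicit attempt-rate
#' convention `k_att` (reported in the output); the folded-well depth
#' below the barrier follows from the equilibrium free energy
#' `R T ln(tau0_F / tau0_U)`; barrier positions along the pulling
#' coordinate come from the fitted transition-state distances.
#'
#' @param kinetics A data frame with one row per condition: columns
#'   `condition`, `tau0_F`, `tau0_U`, `dx_FU` (nm), `dx_UF` (nm).
#' @param temperature Temperature, K.
#' @param k_att Attempt rate, 1/s (convention; default 1e6).
#' @return A tibble per condition: `barrier_height` (above unfolded,
#'   kcal/mol), `dG_eq` (folded-well depth, kcal/mol), `barrier_position`
#'   (distance from the folded state, nm), `unfolded_level` (always 0),
#'   `k_att`.
#' @export
landscape_summary <- function(kinetics, temperature = 293.15, k_att = 1e6) {
  need <- c("condition", "tau0_F", "tau0_U", "dx_FU", "dx_UF")
  miss <- setdiff(need, names(kinetics))
  if (length(miss)) {
    abort(sprintf("`kinetics` is missing matched parameter column(s): %s.",
                  paste(miss, collapse = ", ")),
          class = "tweezfold_incomplete_design")
  }
  RT <- .R_kcal * temperature
  tibble::tibble(
    condition = kinetics$condition,
    barrier_height = RT * log(kinetics$tau0_U * k_att),
    dG_eq = equilibrium_dG(kinetics$tau0_F, kinetics$tau0_U, temperature),
    barrier_position = kinetics$dx_FU,
    reaction_coordinate_span = kinetics$dx_FU + kinetics$dx_UF,
    unfolded_level = 0,
    k_att = k_att)
}
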