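---
title: "Models and methods behind tweezfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tweezfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tweezfold)
```

tweezfold analyses single-molecule optical-tweezers experiments on
multi-domain proteins, with the cAMP-dependent protein kinase A (PKA)
regulatory subunit as the motivating system: two homologous
cyclic-nucleotide-binding domains (CNB-A, CNB-B) whose folding energy
landscapes respond to cAMP occupancy and to each other, plus a ~30-residue
N-terminal helical motif (the N3A motif) that behaves as a two-state
conformational switch. This vignette states the models, the estimators,
the defaults, and the limits of what the synthetic-data tests demonstrate.

## Mechanics: the worm-like chain

All elasticity goes through the Marko-Siggia interpolation formula

$$F(\xi) = \frac{k_BT}{P}\left[\frac{1}{4(1-\xi)^2} - \frac14 + \xi\right],
\qquad \xi = x/L_c,$$

with persistence length $P$ and contour length $L_c$. `ms_force()` and its
numerical inverse `frac_extension_at()` round-trip to better than
$10^{-9}$ pN over 0.1-60 pN. We use the interpolation form rather than an
extensible WLC because protein unfolding here lives below ~25 pN, where
enthalpic stretching contributes negligibly. Defaults: unfolded
polypeptide $P = 0.65$ nm (the community-standard value; configurable
everywhere it enters), dsDNA handles $P = 10$ nm, contour per residue
$l_{aa} = 0.365$ nm, temperature 293.15 K (a 20 °C temperature-controlled
room). A domain of $n$ residues with folded end-to-end distance $d_{NC}$
releases $\Delta L_c = n\,l_{aa} - d_{NC}$ of contour on unfolding
(`expected_delta_lc()`); for the CNB-A domain (133 residues,
$d_{NC} \approx 3.5$ nm) this gives the expected 45 nm.

## The trajectory simulator

`simulate_force_ramp()` is a kinetic Monte-Carlo engine with a
serial-compliance force balance. At trap displacement $D$ the force solves

$$D = \frac{F}{k_{trap}} + L_h\,\xi_h(F) + L_{unf}\,\xi_p(F) + \sum_{folded} d_{NC},$$

i.e. trap spring, one effective handle WLC (contour 260 nm standing in for
2 x (350 + 30) bp of dsDNA, persistence 10 nm), the unfolded polypeptide
WLC, and rigid folded cores. The balance is precomputed on a dense force
grid per folding state and inverted by interpolation, so a rip appears as
a concurrent extension jump and force drop with the trap position
continuous. Folded domains unfold with the Bell hazard
$k_u(F) = \tau_{0,F}^{-1}e^{F\Delta x^\ddagger/k_BT}$ and unfolded ones
refold with $k_f(F) = \tau_{0,U}^{-1}e^{-F\Delta x^\ddagger/k_BT}$ (force
opposes folding). Hazards are frozen within each $1/\text{sample rate}$
step (Gillespie-style thinning); at 200 Hz and 75 nm/s the force moves
~0.03 pN per step, so the frozen-rate error is far below sampling noise.
The default protocol mirrors standard practice: 75 nm/s, 200 Hz, 2-25 pN,
a 10 s refolding hold at 2 pN between cycles (the hold evolves the state
but is not recorded). Trap stiffness (0.1 pN/nm) and handle persistence
are declared defaults, not inferred quantities: the underlying experiments
do not report them, and every recovery test uses matched
generator/analysis values.

`simulate_force_clamp()` draws exact exponential dwells for a two-state
telegraph at fixed force, maps states to extension levels separated by
$\Delta L_c\,\xi_p(F)$, and adds white Gaussian measurement noise.
`simulate_rupture_forces()` is the constant-loading-rate idealization used
to validate rupture statistics against the Bell-Evans first-passage
density by quadrature.

What the generator does *not* emulate — and hence what passing recovery
tests cannot certify about real data: instrument drift, feedback-loop
dynamics and correlated (filtered) noise, bead hydrodynamics, tether
failure, multi-trap geometries, and any intra-rip intermediates. Noise is
white and Gaussian by construction, which flatters the BHMM's noise
model in particular.

## Rip detection and contour-length changes

`detect_rips()` scores each sample by the difference between
forward- and backward-looking moving means (half-window 5 samples) and
thresholds it at median + 6 x MAD with a 2 nm absolute floor; candidates
within 25 ms merge, keeping the larger jump (favouring the
cooperative-unit reading of near-simultaneous ruptures). Pre/post
baselines — linear in force, up to 0.25 s, truncated at neighbouring
events — are extrapolated to the rupture force to give $\Delta x$, and
$\Delta L_c = \Delta x/\xi_p(F)$. A long baseline window matters: the
local extension-vs-force slope is poorly determined over 50 ms at 200 Hz
and its error is amplified by extrapolation across the force drop. The
loading rate is the slope of a 50 ms force-vs-time fit ending at rupture.
Candidate events must also show the mechanically required concurrent
force change (drop on unfolding, rise on refolding; 0.4 pN default).
These thresholds are declared defaults exposed as arguments — the
original analyses in this field typically used unpublished in-house
detectors, so the algorithm here is specified to be deterministic and
tunable rather than to replicate any particular program.

Reversibility: a transition re-crossed repeatedly inside one ramp shows
up as three or more events of mixed direction at nearby forces
(within 2.5 pN) with comparable jump sizes; connected components under
that linkage are flagged `reversible`. Per-event $\Delta x$ for fast
hoppers is unreliable (short dwells truncate baselines), so
`fit_hopping_ramp()` re-analyses each flagged cluster as a short
two-level region, fitting extension = baseline(F) + state offset with a
shared slope by an EM-style alternation. Fitting the offset jointly with
the slope is essential because occupancy drifts with force across the
hopping window; a plain detrend leaks level separation into the
baseline. Clusters whose latent path changes state fewer than three
times are dropped (a single step is a swallowed irreversible zip, not
hopping). When the pooled clusters span under 2 pN — the usual case,
since hopping is confined to a narrow force window — the one-parameter
model reduces to averaging $\Delta x/\xi(F)$ per cluster.

`fit_delta_lc()` pools (force, $\Delta x$) pairs across an ensemble and
solves the one-parameter least-squares problem
$\Delta x = \Delta L_c\,\xi_p(F) - d_{fold}$ with $d_{fold} = 0$ by
default (appropriate for rip-to-rip differences). It requires at least 3
points spanning at least 2 pN; degenerate designs raise an
ill-conditioned-fit error.

## From rupture-force histograms to kinetics

`unfolding_histogram()` bins rupture forces (density normalized to 1)
and carries each bin's mean loading rate. `histogram_to_lifetimes()`
applies the survival-over-density transform

$$\tau(F_i) = \frac{(h_i/2 + \sum_{k>i}h_k)\,\Delta F}{h_i\,\dot F(F_i)}.$$

The transform has a hard resolution floor: by construction
$\tau(F_i) \ge \Delta F/(2\dot F)$, so bins whose true lifetime is
comparable to the bin crossing time $\Delta F/\dot F$ are biased upward
(about +5% at one crossing time, unbounded below it — measured on exact
bin probabilities). `fit_lifetimes()` therefore excludes bins with
$\tau < 2\Delta F/\dot F$ by default; this matters because those deep-tail
bins are also the most populous under count weighting and would otherwise
tilt the whole fit. The Bell fit is weighted least squares on
$\log\tau$ vs $F$ with per-bin counts as weights (Poisson error
propagation: sparse tail bins should not be over-trusted); the DHS family
($\nu = 1/2$ cusp, $2/3$ linear-cubic) is fitted by Nelder-Mead in
log-parameter space and reduces exactly to Bell at $\nu = 1$. Bell is the
default because the quantities reported for this system are
$(\tau_0, \Delta x^\ddagger)$ pairs. Confidence intervals come from a
seeded multinomial bootstrap of the histogram counts, re-running
transform + fit per resample (1000 by default): $\tau_0$ spans decades
and fold-changes of it are the scientifically meaningful output, so
percentile intervals on the nonlinear extrapolation are worth their cost.
One documented mismatch effect: data generated from the cusp model and
fitted with Bell underestimate $\tau_0$, because cusp log-lifetimes are
convex in force and a straight-line extrapolation from a finite window
lands low.

`reconstruct_force_distribution()` inverts the fit back to
$p(F) = [\dot F\tau(F)]^{-1}\exp(-\int_0^F [\dot F\tau(f)]^{-1}df)$ by
trapezoidal integration; over a grid extending to negligible survival it
integrates to 1 within $10^{-3}$, and the closed loop
reconstruct &rarr; sample &rarr; transform &rarr; fit returns Bell
parameters within 3%.

## Bayesian two-state hopping analysis

`fit_bhmm()` is a Gibbs sampler for a two-state Gaussian-emission HMM
with a shared noise SD: (a) the state path is drawn exactly by
forward-filtering backward-sampling (compiled kernel), (b) state means
and the noise variance use conjugate normal-inverse-gamma draws (broad
priors: prior means at the 25/75% extension quantiles, prior precision
scale 0.01, IG(0.001, 0.001)), (c) each transition-matrix row gets a
Beta draw from a Dirichlet(1,1) prior. Exactly two states are assumed —
the hopping this targets is two-state by construction and by
observation — and label switching is resolved by ordering the means
(folded = lower extension). Defaults: 2000 sweeps, 20% burn-in; a
split-chain diagnostic on the level separation is reported and is
expected below 1.05. Dwell lifetimes use the transition-probability
route, $\tau = -\Delta t/\ln p_{stay}$ per posterior draw (draws with
$p_{stay} = 1$ are excluded with a warning), rather than dwell-histogram
fitting: it uses every sample, not only completed dwells, and
propagates into credible intervals with no extra machinery.
$\Delta L_c = (\mu_U - \mu_F)/\xi_p(F_{clamp})$ is computed per draw.

Degeneracy screening happens before sampling: constant traces and traces
whose initial two-level split leaves a state essentially unoccupied are
refused, and when the mclust package is available a one- vs
two-component Gaussian BIC comparison (on at most 10,000 subsampled
points) rejects traces that a single Gaussian explains better.

## The liganded-species titration

Sequential binding of a ligand at concentration $L$ to two sites with
microscopic dissociation constants $K_A$, $K_B$ and one shared
cooperativity factor $\gamma$ (the second site's $K_d$ divided by
$\gamma$) gives the binding polynomial
$Z = 1 + L/K_A + L/K_B + \gamma L^2/(K_AK_B)$ and species fractions
$(1, L/K_A, L/K_B, \gamma L^2/K_AK_B)/Z$ for
$(A_0B_0, A_1B_0, A_0B_1, A_1B_1)$. A single $\gamma$ closes the
thermodynamic cycle identically (both orderings of the two binding
events imply the same doubly-bound constant); a two-$\gamma$ variant
would need an explicit cycle constraint and is deliberately not the
default.

`classify_trajectory()` maps one pulling cycle's rip events to a
species by a fixed cascade on mechanical fingerprints: a reversible
~11 pN / ~13 nm transition (folded, docked N3A) implies $A_1B_1$; a
CNB-A rip in the 27-33 nm "no-N3A" window implies $A_1B_0$; an
elevated-force CNB-A rip in the 42-48 nm "N3A-folded" window together
with an apo-force CNB-B rupture implies $A_0B_1$; two apo-force
full-length rips imply $A_0B_0$; anything else stays unclassified and is
excluded from the likelihood rather than being forced into a bin. The
window defaults live in `classify_rules()` and are validated against
the simulator only — the thresholds used in the original analyses are
not public.

`fit_global()` maximizes the product of independent per-concentration
multinomial likelihoods in log-parameter space. A multinomial likelihood
rather than least squares on fractions is the substantive choice: with
5-10 molecules per condition, count noise is the dominant error and has
the wrong variance structure for least squares. Intervals are a seeded
parametric bootstrap (500 refits at the MLE) or a log-scale Wald
approximation; `fix_gamma = 1` gives the no-cooperativity null for a
likelihood-ratio test (`lr_test()`).

## Free-energy dissection

With zero-force lifetimes from the kinetic fits,
$\Delta G = RT\ln(\tau_{0,F}/\tau_{0,U})$ (`equilibrium_dG()`,
$R = 1.9872\times10^{-3}$ kcal/(mol K), 293.15 K unless overridden). This
two-state lifetime-ratio route — not work distributions or
fluctuation-theorem estimators — matches how the quantities being
reproduced were defined. Perturbation effects compose as
$\Delta\Delta G = RT\ln(f_F \times f_U)$ for fold-changes of the two
lifetimes (`ddG_from_fold_changes()`); the internal consistency check
$7.6 + RT\ln(30\times4) = 10.4$ kcal/mol reproduces the printed CNB-B
stabilities from their printed fold-changes. `dissect()` splits
ligand-binding from inter-domain contributions across construct types
(isolated domain apo/holo; domain pulled next to its holo neighbour),
with the decomposition identity holding to machine precision.
`landscape_summary()` places barriers on an absolute scale only via an
explicit attempt-rate convention ($k_{att} = 10^6\,s^{-1}$ by default,
always reported in the output): absolute barrier heights from
$RT\ln(\tau_0 k_{att})$ are convention-dependent and the landscapes are
schematic summaries, not deconvolved profiles.

## Structure utilities

`contact_map()` computes minimum heavy-atom distances per residue pair
(hydrogens dropped by element; the criterion is all-heavy-atom, not
C-alpha, because side-chain contacts are what an 8 Å cutoff is meant to
capture), retains pairs within the cutoff with $|i-j| \ge 2$, and
partitions them by named regions (within the N3A motif; N3A to B/C
helix; N3A to CNB-B; other). PDB files are read with bio3d; tests use
synthetic geometries checked against a brute-force distance oracle,
plus rigid-body invariance.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed, and identical
seeds give bit-identical output. The test suite runs its recovery and
coverage studies at deliberately chosen sizes: rupture-force oracles at
5000 pulls; ramp ensembles of 40-60 cycles for rip-detection recall and
$\Delta L_c$ recovery; clamp traces of 30-120 s at 500-1000 Hz for the
BHMM, with 10 coverage replicates at 600 sweeps; titration coverage at
15 replicates of 12 concentrations x 100 molecules with Wald intervals
(the bootstrap is exercised once end-to-end). These sizes make the
binomial noise on coverage assertions explicit — a nominal 95% interval
is asserted to cover in at least 80% of 10-15 replicates, which a
calibrated method passes with high probability while a materially
miscalibrated one fails.

## Known limitations

- The lifetime transform cannot resolve lifetimes below the bin
  crossing time; the validity cut removes those bins, which shortens
  the usable force window at high loading rates.
- Per-event $\Delta L_c$ for transitions with dwells shorter than the
  baseline window is noisy; use the cluster-level estimator.
- The BHMM assumes white Gaussian noise and exactly two states; filtered
  instrument noise will inflate apparent transition rates.
- The classification cascade is only as good as its windows; with real
  data the windows should be re-derived from the observed fingerprint
  distributions, not taken from the simulator defaults.
- Absolute barrier heights depend on the attempt-rate convention;
  only differences between conditions are convention-free.
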