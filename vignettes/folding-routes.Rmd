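---
title: "Folding routes from optimal control on a Gaussian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding routes from optimal control on a Gaussian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldpath)
```

## The model

foldpath treats folding as a control problem on a coarse-grained chain. Each
residue is a bead at its Cα position; per Cartesian axis, the deviation
vector `x = R − R_native` follows overdamped dynamics

$$\beta \dot x = \Gamma x + u,$$

with friction `β`, the Gaussian-network connectivity matrix
`Γ = −γ L_init` of the *initial* structure (negative spring-weighted graph
Laplacian of its contact map plus the covalent backbone; one zero eigenvalue
for rigid translation, `n−1` negative), and a force field `u`. Inertia is
neglected — appropriate at the heavily damped, diffusive time scales of
folding — and the dynamics are deterministic: `u` is not thermal noise but
is *synthesized* so that the chain both avoids high-energy regions and takes
routes with little entropy loss. Concretely, an infinite-horizon linear
quadratic regulator minimizes

$$\int_0^\infty \left( x^\top Q x + \alpha\, u^\top P u \right) dt .$$

The first term is the harmonic excess energy measured on the currently
formed contacts; the second is an entropic penalty — large forces drive the
chain down steep, entropy-squandering routes, and weighting them by `α`
keeps the cumulative entropy above a desired floor. The two terms cannot be
improved simultaneously; `α` selects the compromise.

The state weight is rebuilt from geometry. For a contacting pair (i, j) the
squared deviation of the pair vector from its native value is a quadratic
form $x^\top D_{ij}^\top D_{ij} x$ with $D_{ij}$ the row vector holding −1
at i and +1 at j. Summing over the *non-covalent* contacts of the current
map and adding a ridge gives

$$Q = L_c - L_{bb} + \varepsilon I,$$

the contact-map Laplacian minus the covalent-bond Laplacian. The ridge is
required: a Laplacian has a zero mode, and without `ε > 0` no stabilizing
gain exists (the translational mode would never be pulled to the native
state). All row sums of `Q` equal `ε`.

The optimal law is `u = −K x` with `K = (αP)^{-1} B^\top S`, `S` the
stabilizing solution of the continuous algebraic Riccati equation. Because
`Γ 1 = 0` and `Q 1 = ε 1`, the span of the all-ones vector is an invariant
subspace of the Riccati map when `P = I`; restricted to it the equation is
scalar and gives the row sums of `K` in closed form. The gain therefore
decomposes *exactly* as

$$K = K' + k I, \qquad k = \sqrt{\varepsilon / \alpha},$$

with `K′` a zero-row-sum harmonic spring-constant matrix: the controller
synthesizes a spring network (topology *and* strengths), plus `n` identical
weak springs anchoring each residue to its native position. The closed loop
`β \dot x = (Γ − K′ − kI) x` is again a Gaussian network — the package
computes `k` analytically and verifies the row-sum identity on every solve
rather than fitting it.

## The learning loop and the dynamic contact map

`run_folding()` iterates: measure the contact map of the current
conformation; rebuild `Q`; solve the Riccati equation; propagate the closed
loop for one sampling interval `t_sample`; update `R = R_native + x`. The
map is re-measured fresh each cycle (contacts may break; no accumulation
rule), and convergence demands *exact set equality* with the native map
plus an RMSD tolerance. The sequence of maps — which entries fill in, and
when — is the predicted folding route. `Γ` stays frozen at the initial
structure (the `update_gamma` flag rebuilds it per cycle for sensitivity
studies; in practice it barely changes the route since the dynamic
information enters through `Q`).

`Q` is initialized from the initial conformation's map — for an extended
start this is `εI`, the unique choice consistent with applying the update
rule at `t = 0`. With `Q = εI` the early gain is a function of `Γ` alone,
so fast local modes dominate first: local structure forms before non-local
structure as an emergent property, not by construction.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 7 | Å | Cα–Cα contact distance |
| `alpha` | 1 | – | energy vs. entropy-loss trade-off; larger = slower, gentler folding |
| `epsilon` | 0.01 | – | Q ridge; anchor spring `k = sqrt(epsilon/alpha)` |
| `beta` | 1 | force·time/length | friction; rescales time only |
| `spring_constant` | 1 | force/length | Γ spring; with β fixes the time unit |
| `t_sample` | 1 | time | contact re-measurement interval |
| `dt_record` | 0.1 | time | recording grid (contact times are grid-resolved) |
| `rmsd_tol` | 0.5 | Å | convergence tolerance alongside map equality |

`beta`, `spring_constant` and `t_sample` have no published values; the
defaults make time dimensionless, so all folding times are in arbitrary
units and only their *ordering* is meaningful. `alpha` and `epsilon` are
the genuine tuning knobs: `alpha` shifts every event later (and lowers the
entropic penalty integral at the price of the energy integral), `epsilon`
sets how strongly residues are tethered to their native positions (kept
small so pairwise interactions dominate). Within each cycle the linear
dynamics are propagated by spectral decomposition of the symmetric stable
closed-loop matrix — exact up to floating point, no integration error — so
`dt_record` affects only the resolution of reported event times.

## Synthetic native structures

`make_fixture()` generates the study systems: an ideal α-helix (canonical
Cα geometry: rise 1.5 Å, radius 2.3 Å, 100°/residue — producing the
(i, i+3)/(i, i+4) contact signature), an extended chain (no non-covalent
contacts at 7 Å), a 20-residue helix-hairpin (two 8-residue antiparallel
helices, axes 8 Å apart, joined by a 4-residue turn placed by a
deterministic bond-length refinement; it carries both local helical
contacts and ≥3 inter-helix contacts with |i−j| ≥ 12), and a two-domain
chain (two helical blocks joined by an extended linker, no cross-domain
contacts). All virtual bonds lie in [3.7, 3.9] Å and every contact graph is
connected — the one-zero-eigenvalue premise of the whole method.

These fixtures emulate the *topological* features the route prediction
depends on (local vs. non-local contact classes, connectedness, realistic
bond geometry). They do not emulate side chains, sequence-specific
interaction strengths, solvent, or thermal noise — so passing tests show
the machinery is faithful to the model, not that the model's routes match
any particular experimental φ-value set. On real structures the same
qualitative findings (local clusters first; non-local clusters
cooperatively later; zipping via falling ECO) are what the method predicts.

## Numerical choices

* **Riccati solver.** Newton–Kleinman iteration from the stabilizing start
  `S₀ = I` (valid because `A` is negative semidefinite and
  `B(αP)⁻¹Bᵀ` positive definite), each step an exact Lyapunov solve via
  spectral decomposition of the symmetric iterate. Dense linear algebra
  throughout — the method targets chains of tens to a few hundred residues.
  Every solve asserts a residual ≤ 1e-8·‖Q‖ and positive definiteness;
  failure raises "no stabilizing solution" rather than returning garbage.
* **Q from the measured map.** The covalent Laplacian subtracted from
  `L_c` is restricted to covalent pairs actually present in the map, which
  coincides with the path-graph Laplacian whenever every virtual bond is
  within the cutoff (always, in practice) and guarantees `Q ≻ 0` even in
  the pathological case of a stretched bond.
* **Degenerate inputs.** Coincident beads simply produce a contact;
  disconnected contact graphs are rejected (Γ would have a second zero
  mode); a chain needs n ≥ 3; non-convergence within `max_cycles` returns
  the trajectory with `converged = FALSE` and a warning, never an error.
* **Excluded volume** is diagnosed (non-bonded pairs < 2 Å logged per
  cycle), not enforced; transient isolated violations are expected of a
  harmonic-network model and the routes are robust to them. Hard-core
  constraints are out of scope.
* **Determinism.** Only the `random_coil` initializer consumes randomness,
  through an internal RNG stream that restores the caller's seed state;
  identical config + seed reproduce trajectories bit for bit.

## Problem sizes used in the tests

The suite exercises chains of 4–40 residues: the 20-residue helix-hairpin
for full folding runs (≈20 cycles, under a second), 50-instance random
ensembles for the Q oracle and the gain row-sum identity, and n ≤ 12 graphs
for ECO against exhaustive path enumeration. These sizes make every
analytic identity checkable at tight tolerances while keeping the whole
suite in seconds; nothing in the method changes at protein scale other
than dense-algebra cost (n³ per cycle).

## Known limitations

* Linear harmonic dynamics about the native state: no unfolded-state
  ensemble, no thermal activation, no misfolded traps; the trajectory is a
  single deterministic relaxation path.
* Folding times are in arbitrary units; only event orderings are
  comparable across runs with the same settings.
* Contact strength is binary and sequence-blind; residue-specific springs
  and side-chain definitions of contact are out of scope.
* The optional per-cycle `Γ` update breaks the "connectivity of the initial
  structure" premise and is provided for sensitivity analysis only.
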