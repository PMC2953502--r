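# foldpath

Predicts the **time-ordered sequence of native-contact formation** — the
folding route — of a protein from knowledge of its native structure alone.

The chain is coarse-grained to its Cα atoms and treated as an overdamped
Gaussian network. Folding is cast as an optimal-control problem: the
deviations `x = R − R_native` (per Cartesian axis) obey

    β dx/dt = Γ x + u,

where `Γ = −γ L` is the negative spring-weighted Laplacian of the initial
structure's contact graph (plus the covalent backbone), `β` a friction
coefficient and `u` the folding force field. An infinite-horizon linear
quadratic regulator chooses `u = −K x` to minimize

    ∫ ( xᵀ Q x + α uᵀ P u ) dt,

where the state weight `Q = L_c − L_bb + ε I` is built from the **dynamic
contact map**: the contacts actually present at each sampling interval
(`L_c` their Laplacian, `L_bb` the covalent-bond Laplacian, `ε` a small
ridge). The first term is the harmonic excess energy over the native state;
the second penalizes forceful, high-entropy-loss routes, with `α` the
trade-off knob. `K` comes from the continuous algebraic Riccati equation and
decomposes exactly as

    K = K′ + k I,   k = √(ε/α),

a zero-row-sum "harmonic spring constant matrix" `K′` (the synthesized
network) plus a uniform spring `k` anchoring every residue to its native
position. The closed loop `β dx/dt = (Γ − K′ − k I) x` is itself a Gaussian
network; re-measuring contacts every `Δt`, rebuilding `Q` and re-solving the
regulator yields a learning control loop whose contact-map sequence
converges to the native map. The order in which the map fills in *is* the
predicted folding route; diagnostics include fractional cluster contacts
f(t), contact initiation times, radius of gyration, the energy/entropic
penalty decay, and the effective contact order (ECO — shortest loop-closure
path through covalent bonds plus already-formed contacts).

Intended for structural bioinformaticians studying folding mechanisms
(local-first zipping, cooperative non-local assembly) without running
molecular dynamics: a full folding route for a 64-residue protein takes
seconds.

## Worked example

```r
library(foldpath)

native <- make_fixture("helix_hairpin", 20)   # two 8-residue helices + turn
traj   <- run_folding(native, folding_config())
#> cycle 1: 1 excluded-volume violation(s) (< 2.0 A), closest 1.82 A
traj
#> <folding_trajectory> synthetic:helix_hairpin20: 20 residues, 17 cycle(s),
#>   t = [0, 17], converged
```

The run starts from an extended chain (Rg 21.9 Å), converges in 17
optimization–simulation cycles to the exact native contact map at RMSD
0.10 Å (Rg 6.07 Å). The transient excluded-volume contact is logged, not
prevented — the model has no hard-core repulsion. The route:

```r
ev <- contact_events(traj)
median(ev$t_init[ev$is_native & ev$co <= 6])    # local contacts (|i−j| ≤ 6)
#> [1] 3.1
median(ev$t_init[ev$is_native & ev$co >= 12])   # inter-helix contacts
#> [1] 15.4
```

Local (helical) contacts initiate first; the non-local helix–helix pairing
follows once the local structure has lowered its effective contact order —
the local-first, zipping-like mechanism. ECO itself:

```r
effective_contact_order(1, 10, formed = cbind(3, 8), n = 10)
#> [1] 5        # the (3,8) contact shortcuts the 9-bond loop
```

Real structures enter through `read_ca_chain("file.pdb", "A")`; a shell
interface is installed as `exec/foldpath` (`foldpath run --pdb ... --out dir`,
`foldpath fixtures --kind helix_hairpin --n 20 --out fixture.pdb`).

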