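---
title: "Methods: transport kinetics and the proteome-allocation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transport kinetics and the proteome-allocation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophos)
```

trophos asks a single question two ways: given an external nutrient
concentration, what is the best a bacterium can do if it imports the
nutrient through a phosphotransferase system (PTS), and what if it uses a
binding-protein-dependent ABC transporter? The answer — growth rate,
cell geometry, proteome composition and emergent uptake affinity — is
computed by maximising the steady-state exponential growth rate of a
coarse-grained self-replicator cell. This vignette documents the model,
its parameters and units, the numerical choices, and what the shipped
baseline can and cannot support.

## Transport kinetics

**PTS.** Substrate in the periplasm binds the membrane transport unit
(rate constant `k1`) and is translocated irreversibly (`k2`). At steady
state the uptake rate is exactly Michaelis–Menten,
$v = k_2 [T]_{tot}\, S_p/(K_T + S_p)$ with $K_T = k_2/k_1$: the
half-saturation concentration is an intrinsic property of the
transporter. All transport rates in the package are expressed as change
in *periplasmic* concentration per time; `periplasm_to_cytoplasm()`
converts with the volume ratio $f_p/(1-f_p)$.

**ABC.** The four-step scheme — reversible substrate binding to a
periplasmic binding protein (`k0f`, `k0r`), docking of the loaded BP on
the transport unit (`k1p`), irreversible translocation (`k2p`), BP
release (`k3p`) — yields a coupled steady-state system.
`abc_steady_state()` reduces it to one scalar equation in the
substrate:BP complex: the flux relation fixes the translocation complex,
the two conservation laws fix the free pools, and the binding
equilibrium closes the system. The equation is monotone and bracketed,
so bisection-based root refinement (to ~1e-15 of the pool size) is
exact for practical purposes; there is no iterative fallback to
ill-conditioned polynomial arithmetic. An independent check,
`abc_relaxation_oracle()`, integrates the mass-action ODEs (resolving
the post-translocation T:BP complex as its own species) to steady state;
the two routes agree to 1e-6 relative over randomised rate sets spanning
±2 decades.

**Emergent affinity.** When binding proteins outnumber occupied
transport units and free transport units are scarce, the uptake rate is
approximately Michaelis–Menten with
$V'_{max} = \tfrac{k'_2 k'_3}{k'_2+k'_3}[T]_{tot}\tfrac{[BP]_{tot}}{K'_T+[BP]_{tot}}$
and $K'_M = \tfrac{K'_T K_D}{K'_T + [BP]_{tot}}$
(`abc_mm_approx()`). The half-saturation *falls* with BP abundance: a
cell with a merely micromolar binding protein ($K_D = 1\ \mu M$) can
reach nanomolar effective affinity by stacking its periplasm with
binding proteins. `effective_half_saturation()` extracts $(V_{max},
K_M)$ from any uptake curve by sampling a log grid (default 60 points,
$10^{-7}$–$10^2$ mM), taking $V_{max}$ at the grid top, and bisecting
for the half-rate concentration to 1e-10 relative — a definition that
needs no least-squares fit; the $R^2$ of the MM form over the grid is
reported as a diagnostic. Reported `K_eff` values always come from the
full transport equations (the closed-form $K'_M$ is stored alongside);
the extraction uses the transport system alone by default, and
`keff_profile(fit, include_diffusion = TRUE)` switches to profiling
against the external concentration with the diffusive supply step
folded in.

## The cell model

The cell is a sphere of radius $r$; a fraction $f_p$ of its volume is
periplasm. Five metabolite pools are tracked: periplasmic substrate
$S_p$ (per periplasmic volume), cytoplasmic substrate $S_c$, amino-acid
precursors $A$, membrane units $W$ and protein $P$ (all per cytoplasmic
volume; $P$ in amino acids). Five reactions connect them: diffusive
supply $v_{diff} = 3D(S_{ext}-S_p)/(f_p r^2)$ (diffusion-limited, not
porin-limited), transport $v_c$ (PTS or ABC, from the kinetics module),
catabolism converting 5 substrate into 6 precursors, membrane synthesis
and protein synthesis. Enzyme concentrations are proteome fractions
times $P$ over the protein's amino-acid cost, $[X] = \phi_X P / n_X$;
`stoichiometry()` exposes the matrix, with the periplasm-to-cytoplasm
conversion of the uptake flux as an explicit entry.

Constraints:

* **Growth balances** (5 equalities): $N v_r = \mu x_m$ for balanced
  exponential growth.
* **Proteome closure**: the five optimised fractions plus two fixed
  "other" fractions ($\phi_{O,cyto}, \phi_{O,peri}$) sum to one. The
  five optimised groups are binding protein, transport unit, metabolic
  enzymes, membrane synthesis and ribosomes; PTS cells have
  $\phi_{BP} \equiv 0$.
* **Membrane coverage** (equality): membrane units must cover the outer
  sphere plus the inner sphere of relative area $(1-f_p)^{2/3}$.
* **Density caps** (2 inequalities): molecular crowding limits on the
  cytoplasm ($m_S S_c + m_A A + m_{aa} P \le \rho_{cyto}$) and the
  periplasm ($m_S S_p + $ BP mass $\le \rho_{peri}$).
* **Real estate** (inequality): transport units occupy inner-membrane
  area; at most a fraction $f_{SA}$ of it is available to them.

Two printed-form subtleties are implemented as stated and switchable:
the membrane-coverage and real-estate constraints multiply
concentrations by the *total* cell volume even though $W$ and $[T]$ are
declared on per-compartment bases (`strict_volume_basis = TRUE` gives
the self-consistent variant; results in this package use the printed
form), and membrane units are excluded from the cytoplasmic density sum
by default (`density_includes_membrane = TRUE` includes them — they sit
in the bilayer, so exclusion is the physical default). The density sums
follow the constraint text literally: the full protein pool $P$ counts
toward the cytoplasmic cap while binding-protein mass additionally
counts toward the periplasmic cap on the periplasmic basis. This
literal bookkeeping is what produces the periplasm-inflation mechanism:
binding proteins are capped per periplasmic volume, so an oligotrophic
ABC cell must dilate $f_p$ to hold more of them. A side effect worth
knowing: at external concentrations of tens of mM the periplasmic free
substrate itself carries appreciable mass ($m_S S_p$), competing with
binding proteins in the periplasmic budget, so the ABC growth curve
flattens — and may dip by a percent or two — at the very top of the
concentration range. Optimal growth is provably nondecreasing in
$S_{ext}$ only while that term is negligible.

## Units

Concentrations mM, time s, length µm, mass Da, areas µm². Conversions
happen in exactly one place: geometric constraints need molecule counts,
via the constant $6.022\times 10^5$ molecules µm⁻³ mM⁻¹. Density caps
are in mM·Da ($10^5$ mM·Da = 100 g/L).

## Baseline parameters

The transport rate constants are the measured reference set for
*E. coli*'s glucose PTS and maltose ABC system: $k_2 = k'_2 = 200$ /s,
$K_T \approx K'_T = 10\ \mu M$, $K_D = 1\ \mu M$ ($k'_{0f} = 10^5$
/mM/s, $k'_{0r} = 100$ /s), with the ABC docking and release steps 100×
slower than their PTS counterparts ($k'_1 = 0.01 k_1$,
$k'_3 = 0.01 k'_2$) because both are limited by diffusion of the bulky
(~40 kDa) binding protein. Note that $k'_3 = 0.01 k'_2$ makes
$K'_T = 9.901\ \mu M$ — equal to $K_T$ to 1%, not exactly.

The remaining parameters are package baselines chosen once at
*E. coli* scale:

| parameter | value | rationale |
|---|---|---|
| `D` | 100 µm²/s | small-molecule diffusivity near a cell |
| `kR`, `n_R` | 20 aa/s, 7459 aa | ribosome elongation rate and protein cost |
| `kE`, `n_E` | 2 /s, 2500 aa | lumped catabolic pathway flux per unit |
| `kW`, `n_M` | 0.5 /s, 500 aa | fatty-acid-synthesis-scale lipid production |
| `n_T`, `n_BP` | 1500, 375 aa | ABC importer complex; BP 4× cheaper |
| `a_w` | 0.5 nm² | membrane area per lipid (bilayer) |
| `a_T` | 25 nm² | footprint of a transport unit |
| `f_SA` | 0.3 | membrane share available to one transporter class |
| `rho_cyto` | 3×10⁵ mM·Da | ~300 g/L cytoplasmic dry mass |
| `rho_peri` | 5×10⁴ mM·Da | ~50 g/L periplasmic macromolecule cap |
| `phi_O` | 0.35 + 0.05 | fixed housekeeping proteome |
| `r` | 0.06–10 µm | SA:V ≤ 50 /µm; upper bound is the model domain |

At saturating concentrations the optimal radius is weakly determined
above a few µm (membrane costs fall off as $1/r$ while nothing else
pushes back until diffusion binds), so the search is bounded at 10 µm;
the periplasmic fraction is kept in [0.0025, 0.9975] so constraint
functions stay finite. With this baseline the qualitative structure of
the rate–affinity trade-off emerges without tuning: the growth-rate
crossover sits near $10^{-4}$ mM, the periplasmic density cap and the
real-estate constraint are active where expected, the PTS
transport-to-metabolic capacity ratio reaches the $10^4$ scale at 1 nM,
and the oligotrophic ABC cell reaches `K_eff` near 10 nM.
Because this parameterisation is the package's own, the test suite
asserts these *properties* — crossover existence and persistence,
monotone trends, constraint activity, order-of-magnitude ratios — not
any externally printed optimisation values; the transport-kinetics
layer, whose constants are measured, is tested quantitatively.

## The optimisation

`allocate_proteome()` maximises $\mu$ for one transport type and one
environment. Two coupled parameterisations are used:

1. **Nested (exact) evaluation.** Given $(\phi, r, f_p)$, the growth
   balances collapse in closed form: the ribosome balance gives $A$ from
   $\mu$, membrane coverage gives $W$, the membrane balance gives $P$,
   the precursor balance gives the required catabolic flux and hence
   $S_c$, the substrate balance gives the required uptake and hence (by
   inverting the transport system, closed-form for both PTS and ABC)
   $S_p$. The one remaining scalar — the periplasmic supply balance —
   is monotone in $\mu$ and solved by bisection to ~1e-14 relative.
   States produced this way satisfy the equalities at round-off level.
2. **Smooth refinement.** For local optimisation, all nine (ABC; eight
   for PTS) coordinates — log proteome fractions, log $r$, logit $f_p$,
   log pools, and log of the substrate:BP complex as the transport
   coordinate — are free variables, every constraint is closed-form
   smooth, and an augmented-Lagrangian loop over a quasi-Newton inner
   solver (`nlminb`) handles the three scaled equalities and the
   inequality margins.

A solve ranks a large pool (20× the start count) of nested-feasible
candidates by penalised growth rate, refines the best `n_starts` of
them, and re-polishes the winner in the nested parameterisation so the
returned optimum carries equality residuals at round-off. Candidate
generation draws log-uniform within bounds; for ABC cells, half the
candidates are seeded at the periplasmic density cap, because the
density-limited basin that dominates in oligotrophic conditions
otherwise has a small random-sampling footprint. Feasibility is always
re-verified in unscaled units (`validate_solution()`) before a solution
is accepted; ties within 1e-9 relative in $\mu$ go to the smaller
residual norm, then the lower start index. All randomness derives from
`(seed, start index)`, so solves are bitwise reproducible.

Default problem sizes: 50 starts for a standalone solve, 12 for sweep
points (which add warm starts from both neighbouring grid points in a
forward and a backward pass, keeping the better), 8–16 in the test
suite. The sweep grid defaults to 40 log-spaced points over
$10^{-6}$–$10^2$ mM; the acceptance script uses 9 points at one per
decade. Warm-started and cold-started solves of the same point agree to
well under 0.5% in $\mu$ in the shipped checks.

## Degenerate inputs and edge behaviour

Zero binding protein, zero transport units or zero substrate give exact
zero flux through dedicated branches (no 0/0). `S_ext = 0` is refused:
the model has no growing steady state there. Saturated ABC pools (the
scalar equation's bracket collapsing) return the pool-exhausted state.
The oracle warns, reporting final derivative norms, if a pathological
rate set has not settled within its horizon.

## Known limitations

* The energy budget of transport (ATP per translocation) is not
  modelled; the trade-off here is purely proteomic/geometric.
* Outer-membrane porin limitation is not modelled; supply is purely
  diffusive.
* Translocation and BP docking are irreversible; the reversible
  extension would add three rate constants.
* The optimiser is a local method with multi-start — no global
  certificate. The shipped seeds and start counts are calibrated to the
  baseline's basin structure; far-from-baseline parameter sets may need
  more starts.
* The synthetic environment is a homogeneous, constant concentration;
  shifts, gradients and stochasticity are out of scope.

## A worked micro-example

```{r example, eval = FALSE}
cp <- cell_params(S_ext = 1e-6)                       # 1 nM
abc <- allocate_proteome(cp, "abc", solver_config(n_starts = 16, seed = 11))
pts <- allocate_proteome(cp, "pts", solver_config(n_starts = 12, seed = 11))
summary(abc)
abc$observables$K_eff * 1e6                            # K_eff in nM
pts$mu < abc$mu                                        # oligotroph wins
```

Outputs of this kind (and every number quoted above) are computed by
the test suite and the acceptance script; see `scripts/acceptance.R`.
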