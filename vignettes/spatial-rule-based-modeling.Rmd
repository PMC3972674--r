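---
title: "Spatial rule-based modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial rule-based modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srbm)
```

## The modeling problem

Large molecular machines such as the mitotic kinetochore assemble from
dozens of protein species through combinatorially many intermediates, far
too many for an explicit reaction network. `srbm` combines two ideas to
make such systems simulable:

1. **Rule-based reactions.** Interactions are written as implicit rules
   over *site graphs*: each elementary molecule carries named binding
   sites, and a rule such as `A(a) + A(a) -> A(a!1).A(a!1)` describes the
   whole (possibly infinite) family of concrete reactions in which two
   free `a` sites join. Sites a rule does not mention are wildcards.
2. **Explicit coarse-grained space.** Every elementary molecule is a
   sphere (or a member of a multi-sphere structural template) diffusing by
   overdamped Brownian dynamics. A bimolecular rule can only fire when the
   two reactive sites come within their combined reach, so molecular size,
   site placement and crowding constrain which reactions actually happen —
   geometry, not extra rules, prevents impossible assemblies.

The analysis layer compares the resulting structures across replicate
simulations (positional, paired and local RMSD; UPGMA dendrograms) and
summarises which rules were actually used (bond frequencies, bond-count
histograms, connectivity between anchor complexes).

## Rule semantics

A mentioned site with no bond spec must be unbound; `!+` means bound to
anything; `!?` is a full wildcard. Rules are unidirectional — reversibility
is written as two rules — and conserve the molecule multiset: only one bond
may form or break per rule, plus any number of modification relabelings.
The grammar is documented in `inst/grammar/bngl-subset.md`.

Two matching conventions were genuinely open and are resolved as follows:

* **Symmetric matches.** Embeddings identical up to permutations of
  equally-named sites (or automorphic molecule swaps) are deduplicated by
  default, so a symmetric dimerization does not double its propensity.
  `match_pattern(..., dedup = FALSE)` exposes the raw count.
* **Ring closure.** The rule language permits binding two sites already in
  the same complex; whether small rings actually form is left to the
  geometry (bond springs and excluded volume), not vetoed syntactically.

The pattern matcher used for analysis and testing handles arbitrary
connected patterns by backtracking. The simulation engine compiles rules
to a fast form restricted to what the shipped models need: bimolecular
binds between two separate molecules (with modification context and
post-bind relabeling), unimolecular unbinding/modification, and bound-pair
modification propagation. Context sites in the compiled form are matched
on their modification label; an unsupported rule shape is rejected at
compile time with a clear error rather than silently approximated.

## Geometry

When no structure is known, a protein of mass $m$ (kDa) becomes a sphere
whose radius follows the constant-density rule
$r(m) = r_0 (m / m_0)^{1/3}$, calibrated to histone H3
($m_0 = 15$ kDa, $r_0 = 15.00$ Å). Binding sites sit on the surface in
spherical coordinates (zenith angle $\varphi$, azimuth $\theta$, reach
$\ell$, default $\ell = r$ so reactions occur at contact). Sites without
declared angles are isotropic — the whole surface is equally reactive —
which is the default for all bundled kinetochore proteins, since no
binding angles are published for them. When angles *are* declared, binding
is vetoed outside a 45° half-angle cone (configurable); the veto is
applied to particles whose orientation is tracked (template members), as a
free sphere with a single site reorients much faster than it diffuses its
own diameter.

Structural templates place several spheres at fixed relative coordinates:
rigid templates move as one body; `fixed` templates keep their centroid
pinned, optionally with free rotational diffusion. Internal bonds between
touching members are pre-formed at build time — through the partners'
binding sites where the rule table lists the interaction (so they count in
bond-frequency statistics), as plain structural springs otherwise. For
flexible chain templates, harmonic angle terms with equilibrium taken from
the build geometry are registered (disabled by default, `k_angle = 0`:
the bundled chains are treated as freely jointed).

## Dynamics

Positions follow overdamped Langevin dynamics in reduced units
($k_BT = 1$, friction $\gamma = 1$, $\mathrm{d}t = 5\times10^{-3}$ by
default): each step adds the deterministic drift $F\,\mathrm{d}t/\gamma$
and Gaussian noise of variance $2 k_BT\,\mathrm{d}t/\gamma$ per axis, so
the free diffusion coefficient is $D = k_BT/\gamma$. Forces:

* purely repulsive Lennard-Jones (cut at its minimum), $\sigma$ = sum of
  radii — excluded volume;
* harmonic springs on bonds, rest length = sum of the two site reaches;
* optional harmonic angles; optional centering "drag-fix" that pulls
  particles harmonically back once they leave a sphere around the reactor
  centre, keeping reactants available without imposing a uniform density;
* reflective walls on the axis-aligned reactor box.

Numerical safeguards: deterministic forces are capped (`fcap`) so that a
large time-step cannot catapult overlapping particles, and any single-step
displacement beyond half the smallest box extent aborts the run with a
diagnostic rather than producing silent garbage. Rigid bodies translate
by their net force and centroid-scaled noise and rotate by rotational
diffusion (`rot_diff`); torque-driven rotation is not modeled — a
documented simplification, adequate for isotropically reactive templates.

Reactions fire after the move: every unordered pair of free sites within
$(\ell_A+\ell_B)(1+s)$ (slack $s = 10\%$) whose enabled rule matches is a
candidate; candidates are processed in RNG-shuffled order to avoid
positional bias, each site binds at most once per sweep, and a bind
succeeds with the rule's per-encounter probability. Unimolecular rules
fire with probability $1-\exp(-k\,\Delta t)$. All randomness comes from
R's RNG, so one seed makes the whole trajectory bit-reproducible.

## The bundled kinetochore model

The package ships a model of the human mitotic kinetochore: 49 proteins
with published masses and radii, 67 deduplicated binding pairs (one
specific site per listed partner, so each listed interaction can occur
exactly once per copy pair), and structural templates for the two
nucleosome types plus the Mis12, Ndc80, Mad1:Mad2, RZZ and APC complexes
(with Ska and a rigid 25 nm microtubule cylinder in attached variants).
Rules internal to the spindle-assembly-checkpoint module carry the `SAC`
switch; attaching a microtubule turns the switch off.

The initial condition is the hypothesised rosette: a CenpA nucleosome
(eight-bead rigid octamer, one binding-competent CenpA bead) fixed at the
origin and six H3 nucleosomes fixed on a hexagon 14 nm away, each free to
rotate about its centre. All other molecules are placed uniformly in
x ∈ (−400, 400), y ∈ (−400, 800), z ∈ (−400, 400) Å with six copies per
species (CenpA ×1, CenpN ×2; three-fold more in the multi-microtubule
variants) and diffuse in a centering drag of radius 250 Å about the
rosette.

Quantities the published tables do not specify and that are therefore
explicit modelling choices of this package (kept in fixture files named
`*_synthetic*` or documented here): the nucleosome octamer bead layout
(two staggered rings of four, ring radius 20 Å, half-height 12 Å), the
chain order and coordinates of the complex templates, the histone
H4/H2A/H2B and Ska subunit masses, the microtubule bead discretisation,
and the microtubule attachment rules (Hec1 and Ska3 to tubulin beads).
CenpC, CenpT and CenpQ are modeled as single spheres: they carry a single
published mass/radius row each and a one-bead representation is the only
one consistent with the per-copy bond capacities used in the bond
statistics.

Kinetic rates are not published for this system. Binding is therefore
diffusion-limited by default — probability 1 per encounter, no unbinding —
so the final structures are determined by geometry and arrival order, not
by kinetics; both are overridable per rule.

## Problem sizes and the reduced simulation preset

The published campaign uses runs of $6\times10^6$ steps at
$\mathrm{d}t = 5\times10^{-3}$, hours of computing per run. For routine
use, the tests and the acceptance script use a *reduced preset*
(`hmk_force_params(scaled = TRUE)`) chosen from diffusion arithmetic
rather than tuned to any outcome: $\mathrm{d}t = 0.5$, $\gamma = 0.05$,
so the per-step diffusive displacement is ≈ 4.5 Å — still well below any
binding reach (26–78 Å), while a particle crosses the 250 Å drag sphere in
roughly $10^4$ steps. Spring and cap parameters are rescaled for
stability at that time-step ($k_\mathrm{bond}\,\mathrm{d}t/\gamma \ll 1$),
and reaction sweeps run every 5 steps (inter-sweep displacement ≈ 10 Å,
below the smallest reach). The replicate campaign is 20 runs of $10^5$
steps ($5\times10^4$ in the test suite); assembly of the rosette bridges
saturates within this horizon.

What the reduced scale preserves and what it does not: bridge formation
and the relative accessibility of binding sites (which bonds are common
and which are geometrically frustrated) are reproduced; *absolute*
realized-bond percentages are not comparable to the published long-run
values, because with diffusion-limited irreversible binding every feasible
bond ratchets towards saturation as runs lengthen, and because the
published model's unpublished site angles and template geometry
(re-created here as documented choices) are exactly what those
percentages are most sensitive to. The package reports what its own
conditions produce; the test suite encodes the published values at the
stated scaled-down tolerances, and assertions that the desk-scale
conditions cannot meet fail visibly rather than being weakened.

## The toy-polymer generator

`toy_polymer_fixture()` is the synthetic system used throughout the tests:
a single monomer `A(a, a, b~none~mod)` that polymerizes through its two
interchangeable `a` sites. The nucleation variant replaces the plain rule
with a context-gated pair — polymerization requires `b~mod` on one
partner, and a propagation rule passes the modification across each new
bond — so growth is impossible without a pre-modified seed monomer and
every grown chain is connected to the seed and fully modified. It
emulates the combinatorial and context-dependent aspects of real
assembly (implicit rule instances, modification propagation, nucleation
control) but none of the heterogeneity of real proteins: one species, one
radius, isotropic sites. Tests passing on it validate the rule semantics
and the engine contract, not biological realism.

## Analysis conventions

* **Positional RMSD** removes rigid-motion freedom by construction: the
  first anchor particle is pinned at the origin and the frame is built
  from the rays to the second and third anchors (an exact two-ray
  alignment; a least-squares superposition is deliberately *not* used, as
  the anchor convention is the documented procedure). Collinear anchors
  are an error.
* **Paired RMSD** is the RMSD of all pairwise inter-particle distances
  with the $2/(n^2+n)$ prefactor, i.e. averaging over the $n(n+1)/2$
  pairs including the zero diagonal; it is rigid-motion invariant (and
  blind to mirror images, which preserve all distances).
* **Local RMSD** clips every distance at a cutoff $C$ before comparing,
  making the metric sensitive only to structure below that scale; it is
  non-decreasing in $C$ and reaches the paired RMSD once $C$ exceeds both
  diameters.
* **UPGMA** merges by cluster-size-weighted average linkage; merge height
  is the average inter-cluster distance (not halved — the Newick export
  rescales accordingly), and ties break deterministically towards the
  smallest pair of leaf labels.
* **Bond frequency** divides bonds present at the final step (summed over
  runs) by the per-run capacity, `min` over the two partners of copy
  number × matching-site multiplicity — so a rule limited by a scarce
  partner (one CenpA, two CenpN) has capacity 200 or 400 over 200 runs
  where the generic capacity is 1,200.

## Known limitations

* No hydrodynamic interactions, no torque-driven rigid-body rotation, no
  in-simulation change of a molecule's internal geometry.
* The compiled reaction engine supports the rule shapes described above;
  more complex patterns (three-molecule contexts, bond-state context
  beyond the bound pair) work in the R-level matcher but cannot drive the
  spatial simulation.
* The reactor dimensions are stated inconsistently in the source material
  (800 × 400 × 600 Å in one place, the placement ranges above in another);
  the kinetochore preset uses the placement ranges and the alternative
  box remains available through `init_world()` arguments, with neither
  silently "corrected".
* Two published radius entries (CenpO, and the 13.10/13.11 Å pair at
  10 kDa) are internally inconsistent with the mass rule at the printed
  precision; the printed values are retained for simulation and CenpO is
  excluded from exact-reproduction checks.
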