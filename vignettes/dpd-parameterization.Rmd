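---
title: "From chemical structure to DPD self-assembly: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chemical structure to DPD self-assembly: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdchem)
```

dpdchem builds dissipative particle dynamics (DPD) force fields for neutral
surfactants directly from a fragment-level chemical description, simulates
their self-assembly in water, and measures the observables experimentalists
care about: the critical micelle concentration (CMC), the weight-average
aggregation number, and the aggregate shape. This vignette is the package's
account of the underlying models, the numerical choices, and what the test
suite does and does not demonstrate.

## The interaction model

DPD beads interact through a soft, truncated repulsion. For beads $i$ and
$j$ at distance $r$ the conservative force has magnitude
$a_{ij}(1 - r/R_{ij})$ for $r < R_{ij}$ and vanishes beyond; the associated
potential is $\tfrac{1}{2} a_{ij} R_{ij} (1 - r/R_{ij})^2$. $R_{ij}$ is a
pair contact radius mixed arithmetically from per-bead radii,
$R_{ij} = (R_{ii} + R_{jj})/2$, and the repulsion amplitude combines a mean
self term with a chemistry-dependent mismatch:

$$a_{ij} = \frac{a_{ii} + a_{jj}}{2} + \Delta a_{ij}.$$

The packaged tables carry $a$, $\Delta a$ and $R$ for the fourteen bead
types used by the eleven surfactant families (esters, amides, sugars); these
are the published reference values, and `build_paramset(mode = "table")`
uses them verbatim. `mode = "computed"` instead derives $\Delta a_{ij}$ from
the solvation model below, which is how the parameter set extends to new
fragments.

Bonded beads additionally feel a harmonic spring
$\tfrac{1}{2} k_b (r - r_0)^2$ with $k_b = 150\,k_BT$, and 1–3 triples a
harmonic angle $\tfrac{1}{2} k_a (\theta - \theta_0)^2$ with
$k_a = 5\,k_BT$; both spring constants are established choices for bead
density 3 and are exposed in `param_config()`.

## SSIP solvation: from fragments to transfer free energies

Each bead is described by surface site interaction points (SSIPs): discrete
sites on the fragment's van der Waals surface, each carrying a polarity
$\varepsilon$ (positive for hydrogen-bond-donor character, negative for
acceptor character). A liquid is a well-mixed bath of SSIPs at
concentrations set by the reference liquid of the bead. Two SSIPs $x$, $y$
associate 1:1 with equilibrium constant

$$K_{xy} = \exp\!\big(-(\varepsilon_x \varepsilon_y + E_{vdW})/RT\big),$$

where $E_{vdW} = -5.6$ kJ/mol is the polarity-independent dispersion
contribution of a contact; complementary donor/acceptor pairs
($\varepsilon_x \varepsilon_y < 0$) bind tighter. Mass balance over all 1:1
pairings gives, for every species, the free fraction $x_f$ satisfying

$$x_f = \frac{1}{1 + \sum_y K_{xy}\, y_f\, c_y},$$

solved simultaneously by damped fixed-point iteration (relaxation 0.5,
falling back on stronger damping when the map oscillates at high occupancy;
residuals are driven below $10^{-12}$, and the suite checks $10^{-8}$ on
every packaged liquid).

The solvation free energy of an SSIP in a solved phase is

$$\Delta G_x(i) = RT \big( \ln x_f - \ln x_f^{\mathrm{conf}}(\theta) \big),$$

the difference between the pairing term and a confinement reference in
which every association constant is unity at the same fractional SSIP
occupancy $\theta = \sum_x c_x / c_{\max}$ (with $c_{\max} = 300$ M). The
unit-constant reference has the closed form
$x_f^{\mathrm{conf}} = (\sqrt{1 + 4c_{\mathrm{tot}}} - 1)/(2 c_{\mathrm{tot}})$,
and the suite cross-checks it against an explicit $K \equiv 1$ speciation
solve. A bead's transfer free energy $\Delta G_{ij}$ (pure liquid $i$ to
dilute solution in $j$) sums the per-SSIP solvation differences; the dilute
convention solves the solvent phase alone and lets the solute SSIPs probe
the solvent's free-SSIP concentrations.

The mismatch term is then

$$\Delta a_{ij} = \frac{(v_r/v_i)\,\Delta G_{ij} + (v_r/v_j)\,\Delta G_{ji}}
{2\, c_P\, RT},$$

with $v_r$ the water-bead volume (42.0 Å³), $v_i, v_j$ the fragment
volumes, and $c_P = 0.291$ the matching constant appropriate for bead
density 3. Each transfer free energy is normalized per reference volume —
a large fragment's free energy is spread over proportionally more contact
area — averaged over the two transfer directions and converted from thermal
to repulsion units. With this pipeline the computed amide mismatches order
exactly as the published ones
($\Delta a_{\mathrm{AM3'-W}} < \Delta a_{\mathrm{AM3-W}} <
\Delta a_{\mathrm{AM2-W}} < 0$): tertiary amides lose no amide–amide
hydrogen bonds on entering water and are therefore more water-compatible
than the secondary amide, whose pure liquid is strongly self-associated.
The absolute computed magnitudes are smaller than the published table
values — the reference-liquid concentrations and the confinement treatment
carry real uncertainty — so the packaged tables remain the default
parameter source and the computed route is used for ordering, trends, and
new beads.

### Reference-liquid concentrations and the water convention

The speciation needs the SSIP concentration of each pure bead liquid. These
are not tabulated anywhere; the package computes them from 25 °C densities
and molar masses of the named reference molecules (methyl acetate for ES,
N-methylacetamide for AM2, N,N-dimethylacetamide for AM3′/AM3, methanol for
OH1/OH′, ethanol for OH2, half of dimethoxyethane's concentration for
EO/AC′, a quarter of n-octane's for the C2-type beads and an eighth for
T1), with the provenance (molecule, density, molar mass, divisor) stored in
the packaged YAML library. The water bead represents two water molecules in
simulation; its liquid concentration is correspondingly half the molar
concentration of water. Both conventions (one or two waters per bead) are
available through `default_bead_library(w_per_bead = )`; the two-water
default matches the simulation mapping and reproduces the published
mismatch signs slightly better.

## Bond-length calibration

Because bonded beads also repel each other through the soft potential, the
spring rest length $r_0$ must undershoot the desired bond length
$r_{\mathrm{target}}$. Setting the derivative of spring-plus-soft-repulsion
to zero at the target gives the closed form

$$r_0 = r_{\mathrm{target}} - \frac{a_{ij}}{k_b}
\Big(1 - \frac{r_{\mathrm{target}}}{R_{ij}}\Big),$$

valid for $r_{\mathrm{target}} < R_{ij}$; beyond the repulsion range the
correction vanishes and $r_0 = r_{\mathrm{target}}$. Evaluated on the
tabulated pair parameters this reproduces the published calibrated rest
lengths, and the acceptance suite verifies the round trip dynamically: a
two-bead molecule with a calibrated head-group bond (amide–hydroxyl,
ester–hydroxyl), solvated in a water box at density 3, holds its
time-averaged bond length within 2% of target.

Two caveats that the closed form deliberately ignores, both visible in
simulation: (i) the radial Boltzmann average carries a Jacobian ($r^2$)
bias of order $2 k_BT / (k_b r)$ that stretches bonds slightly; (ii) the
surrounding solvent adds a potential of mean force between the bonded pair.
For hydrophilic head-group pairs in water the two effects are small and
largely cancel. For hydrophobic pairs in water the solvent-induced term is
an attraction (the microscopic driver of micellization itself) that
compresses tail–tail bonds noticeably below target; this is a property of
the medium, not of the calibration, and no two-body rest length can remove
it.

## The simulation engine

The engine integrates the standard DPD equations: conservative forces as
above, a pairwise thermostat with drag $-\gamma w(r)^2 (\hat e \cdot
v_{ij})\hat e$ and random force $\sigma w(r) \zeta_{ij} \hat e / \sqrt{dt}$
with $w(r) = 1 - r/R_{ij}$, tied by the fluctuation–dissipation relation
$\sigma^2 = 2\gamma k_BT$ ($\gamma = 4.5$, $\sigma = 3$, $k_BT = 1$), and
velocity Verlet with half-step velocities entering the drag force. The
timestep is 0.01 in DPD units, the bead density 3, and the box cubic and
periodic. In laboratory units one length unit is $r_c = 5.64$ Å and a
solvent bead is two waters; `unit_map()` holds these conversions.

Numerical choices worth knowing:

* **Noise stream.** The pair noise $\zeta_{ij}$ is a counter-based hash of
  (seed, step, $i$, $j$), uniform with unit variance, symmetric in the pair
  by construction. Trajectories are bitwise reproducible from the seed, the
  thermostat conserves momentum exactly, and no global RNG state leaks
  between components.
* **Neighbor search.** Cell lists with cell width at least the largest
  $R_{ij}$; boxes too small for three cells per edge fall back to an
  all-pairs loop. The diagnostic force evaluator accumulates pairs in
  sorted order, so cell-list and all-pairs sums agree bitwise — the suite
  asserts identity, not closeness.
* **Degenerate geometry.** Coincident beads receive a deterministic,
  seeded tie-break direction; collinear angle triples use a floored
  $\sin\theta$ so forces stay finite.
* **Stability guard.** A displacement larger than half the box in one step
  aborts the run as an integration failure rather than wrapping silently.

## Micelle analysis

Aggregates are connected components of the molecule graph in which two
molecules are linked when any pair of their hydrophobic tail beads
(C2, C2′, T1, T2) sits within a cutoff, 1.0 $r_c$ by default — the
interaction range; the cutoff is exposed and results should be quoted with
it. Monomers are aggregates of size one. Pooling post-equilibration frames
gives the size distribution $P(N)$, from which the premicelle/micelle
threshold $N_{\mathrm{cut}}$ is read: the midpoint of the first empty gap
in the support when the populations separate cleanly, otherwise the deepest
interior valley between the low-$N$ and high-$N$ modes; a histogram with no
second population yields a flagged sentinel. The CMC is the time average of
the concentration of molecules in aggregates below $N_{\mathrm{cut}}$
(monomers included), converted to mM through the box volume; the
aggregation number is the weight average $\sum N_i^2 / \sum N_i$ over
micelles, reported with its observed range because micelle formation and
breakup make it fluctuate even at equilibrium. Equilibration is either
user-specified or detected as the first frame where a rolling mean of the
free-monomer count settles into the band of its late-run values.

Shapes come from the gyration tensor of each micelle's (unwrapped) bead
positions: eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$ give
semi-axes $(A, B, C) = \sqrt{5\lambda}$ under the uniform-ellipsoid
convention — only the ratios $A/B$ and $B/C$ matter, and they are
convention-free. Classes use a ratio threshold of 1.5: spheres (both ratios
small), prolate/rod-like ($A/B$ large), oblate/disc-like ($B/C$ large),
irregular (both large). The threshold is a presentation choice, exposed as
an argument; the published shape maps are qualitative regions, not sharp
boundaries.

## Synthetic data: what it emulates and what it does not

`make_planted_trajectory()` manufactures trajectories with known truth:
ellipsoidal micelles of prescribed sizes and axis ratios, free monomers,
rigid per-frame jitter, and verified connectivity/separation at the
clustering cutoff. It emulates the *geometry* that the analysis pipeline
must invert — not the physics: there is no exchange of molecules between
aggregates, no premicelle population, no thermal shape fluctuation.
Recovery tests on planted data therefore validate the clustering,
$N_{\mathrm{cut}}$, CMC accounting and shape classification exactly, but
say nothing about whether a simulated system equilibrates; that is what the
scaled-down engine runs are for.

## Scaled-down study conditions

The package's self-assembly checks run at reduced scale chosen once:
a 10 $r_c$ box (3,000 beads) at 5 wt % for the homolog comparison,
$2 \times 10^5$ steps with frames every $10^3$; bond round-trip and
thermostat checks use a 5 $r_c$ water box (375 beads). At this scale a box
holds one or two micelles, so the CMC estimator rests on a handful of free
molecules and carries large frame-to-frame spread; the suite therefore
asserts the robust, order-of-magnitude observable — the CMC drops at least
five-fold from a C8 to a C10 tail within a family, the expected homolog
behavior — rather than absolute concentrations. Production-scale boxes
(40 $r_c$, 192,000 beads, millions of steps) are configurable but not run
by the tests.

## Known limitations

* Computed $\Delta a$ magnitudes are reliable for sign and ordering, not
  for absolute reproduction of the packaged table; the table is the
  default.
* Tail–tail bonds in water sit below their targets due to hydrophobic
  solvent-induced attraction (see above).
* The clustering cutoff and shape threshold are conventions; near-critical
  aggregates and very soluble surfactants make $N_{\mathrm{cut}}$ — and
  hence the CMC — genuinely sensitive to them.
* Small boxes suppress large aggregates: weight-average aggregation
  numbers at 10–15 $r_c$ cannot exceed the number of molecules present,
  so only trends, not absolute aggregation numbers, are meaningful at
  desk scale.
* Charged head groups, electrostatics and temperature dependence of the
  SSIP polarities are out of scope.
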