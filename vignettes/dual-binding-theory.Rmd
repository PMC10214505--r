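---
title: "The dual-binding model of PPI stabilizers: theory, scoring and workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dual-binding model of PPI stabilizers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualbind)
library(dplyr)
```

## The ternary equilibrium model

A protein--protein interaction (PPI) stabilizer, or molecular glue, is a
small molecule S that promotes formation of the ternary complex R·L·S
between a receptor protein R and a ligand protein L. `dualbind` models the
coupled mass-action system

* R + S &#8652; RS, dissociation constant $K_{RS}$,
* L + S &#8652; LS, dissociation constant $K_{LS}$,
* RS + L &#8652; RLS and LS + R &#8652; RLS, with the ternary step's
  dissociation constant divided by the cooperativity factor $\varphi$.

The cooperativity factor multiplies the ternary association identically from
both routes, so the thermodynamic cycle closes (detailed balance); the
equilibrium then satisfies $[RLS] = \varphi [R][L][S_f]/(K_{RS} K_{LS})$
with $[S_f]$ the free stabilizer.

Binding free energies are interconverted with dissociation constants by
$K_D = \exp(\Delta\Delta G / RT)$ with
$R = 1.9872 \times 10^{-3}$ kcal/(mol·K). The model temperature defaults to
298.15 K -- the standard-state convention for quoting $K_D$ -- and is
exposed as a parameter throughout. All concentrations are molar internally;
the command-line interface accepts `uM`/`nM`/`mM` suffixes.

### Exact solution

`solve_equilibrium()` reduces the three conservation equations to a single
equation in $[S_f]$. Given $[S_f]$, the free receptor and ligand follow
from a quadratic with one positive root (evaluated in its
cancellation-free form), and total stabilizer is a strictly increasing
function of $[S_f]$. The root is therefore bracketed on $[0, S_0]$ and
found by safeguarded bisection (relative tolerance $10^{-12}$ scale) with a
final Newton polish -- convergence is guaranteed and no spurious roots can
occur. The solver refuses to return a state whose stabilizer mass balance
is off by more than $10^{-6}$ relative; the test suite checks conservation
to $10^{-8}$ and agreement with an independent dense-grid oracle to
$10^{-6}$ relative in $[RLS]$.

Dissociation constants derived from energies up to |40| kcal/mol remain
inside double-precision range ($\exp(\pm 67.5)$), so no log-space
reformulation is needed; if the ternary optimum ever underflows, the
effective dissociation constant is reported as `Inf` rather than a bogus
number.

### Dilute closed form, optimal dose and the hook effect

When R and L are far below both dissociation constants, depletion is
negligible and

$$[RLS] = \frac{\varphi\,[R_0][L_0][S_f]}{(K_{RS}+[S_f])(K_{LS}+[S_f])}.$$

This rises with $[S_f]$, peaks at $[S_f] = \sqrt{K_{RS} K_{LS}}$, and falls
again as the binary RS and LS complexes saturate -- the hook effect: excess
stabilizer fills both proteins' sites separately and starves the ternary
complex. At the optimum the effective protein--protein dissociation
constant is

$$K_{RL,\mathrm{eff}} = \frac{[R_0][L_0]}{[RLS^{opt}]}
  = \frac{(\sqrt{K_{RS}} + \sqrt{K_{LS}})^2}{\varphi}.$$

`optimal_dose()` maximises $[RLS]$ over the *total* dose with a
golden-section search on a log-dose scale over the exact solver, so the
closed-form laws above are verified properties of the solution, not
assumptions. Two consequences used throughout:

* the geometric-mean law means a stabilizer is only as good as its *weaker*
  side, $\max\{\Delta\Delta G_{RS}, \Delta\Delta G_{LS}\}$;
* along the symmetric diagonal $K_{RL,\mathrm{eff}} = 4\exp(\Delta\Delta
  G/RT)/\varphi$, so each 1 kcal/mol of per-partner affinity buys a factor
  $\exp(1/RT) \approx 5.4$ in effective affinity.

```{r threshold}
ts <- threshold_scan(seq(-1, -10, by = -0.5))
ts
```

At 1 µM of each protein and $\varphi = 1$, the least-negative symmetric
per-partner energy whose optimal-dose $K_{RL,\mathrm{eff}}$ reaches the
sub-millimolar (micromolar) range is **-5 kcal/mol**
($4\exp(-5/RT) = 0.86$ mM, while $-4.5$ gives $2.0$ mM). The boundary is a
parameter (default $10^{-3}$ M, the millimolar/micromolar divide) because
it is a convention, not a law.

## Scoring stabilizers from interaction-energy tables

End-point MM/GBSA post-processing of MD ensembles yields per-frame
interaction free energies $\Delta\Delta G_{RS}$, $\Delta\Delta G_{LS}$, the
total $\Delta\Delta G_{(RL)S}$ and the direct protein--protein term
$\Delta\Delta G_{RL}$. `dualbind` consumes these tables (long or wide
delimited text); it never computes them.

Aggregation follows the ensemble convention: per-replica means first, then
the mean and *sample standard deviation across replica means* (five
replicas of 75 frames from the last 30 ns of a 50 ns trajectory is the
shape the defaults emulate). The binding balance
$|\Delta\Delta G_{RS} - \Delta\Delta G_{LS}|$ is computed per frame and
aggregated the same way. Because the absolute value is convex, the
frame-wise balance generally exceeds the difference of the reported means;
both conventions are reported (`balance_mean` and `mean_gap`) since
published tables are not always explicit about which was used.

Two decision rules follow from the theory:

* `classify_mechanism()`: dual-binding iff the weaker side is $\le -5$
  kcal/mol (the micromolar threshold above). Anything weaker is an
  *allosteric candidate* -- it cannot act by bridging, but may still
  stabilize by pre-organising one partner's interface, a hypothesis that
  needs long simulations outside this package's scope. The comparison is
  non-strict at the boundary (configurable); on the bundled 18-complex
  benchmark the rule calls exactly 4 complexes allosteric (A1-b, B2, B4,
  B5).
* `select_dual_binding()`: shortlist iff the weaker side is *strictly*
  below -15 kcal/mol and the balance strictly below 10 kcal/mol, matching
  "lower than / smaller than" shortlist semantics; both cutoffs and
  strictness are parameters.

```{r classify}
known_stabilizer_energetics() |>
  classify_mechanism() |>
  count(call)
```

`rank_compounds()` orders candidates by total, receptor, ligand,
weaker-side or balance energy (ascending; ties broken by identifier so
ranking is a deterministic total order). Ranking by the weaker (ligand)
side rather than receptor or total energy is the dual-binding reranking
strategy. `shielding_overlap()` quantifies how much of the unfavorable
(positive-energy) receptor--ligand contact set coincides with the
stabilizer-contact residues; because published contact definitions vary,
the stabilizer-contact set is an *input*, not a guessed cutoff.

## Structure and pocket geometry

Atom--probe contact uses one rule everywhere: distance strictly below the
sum of radii, with tabulated radii H 1.2, C 1.7, N 1.55, O 1.52, F 1.47,
B 1.92, P 1.8, S 1.8 Å. Chlorine defaults to 1.75 Å; a 0.2 Å
value seen in some published radii tables is physically implausible (it
would suppress every Cl contact) and is available only behind the
`cl_radius` argument for strict reproduction.

* Interface residues: any atom within 5 Å of the partner protein
  (cell-list grid, provably identical to the all-pairs loop).
* SASA: Shrake--Rupley with a deterministic Fibonacci-lattice point set
  (default 960 points/atom, bit-stable results; single spheres reproduce
  $4\pi(r+w)^2$ within 2%). Water probe 1.4 Å; hydrogens excluded by
  default (conventional), included on request. Buried surface area
  $BSA_{RS} = (SASA_R + SASA_S - SASA_{RS})/2$; the ratio
  $BSA_{LS}/BSA_{RS}$ is a quick geometric proxy for dual contact.
* Superposition: Kabsch via SVD with the determinant correction (proper
  rotations only); collinear or tiny point sets are rejected. Interface
  RMSD superposes interface heavy atoms (or backbone only) onto the
  starting structure and reports the post-fit RMSD, with an optional
  sliding-window mean given the frame spacing.
* Pockets: probes come from external pocket-detection output (PQR-style
  records grouped by pocket id, polar/apolar tagged); pocket and drug
  scores are consumed from a sidecar, never recomputed. A pocket is an
  interface pocket at threshold $m$ when $\ge m$ *distinct* atoms from each
  protein side touch its probes; the ligand coverage fraction is the share
  of stabilizer atoms (hydrogens included when present) touching $\ge 1$
  probe. Pocket volumes are an input series; `volume_summary()` reports the
  fraction of frames at or above the ligand volume (the "can accommodate
  the stabilizer" fraction).

## The discovery pipeline

`run_pipeline()` wires the stages of an in-silico stabilizer hunt: pocket
statistics and ranking on a complex structure, descriptor pre-filter
(molecular weight 375--425 Da, LogP 2--4.5, BertzCT-type complexity
$\le 700$ -- the physicochemical envelope of known interface stabilizers;
windows inclusive, complexity removals are `> 700`), optional seeded
subsampling, docking through a pluggable adapter, a docking-score cut
("better than -6 kcal/mol" = more negative, $\le -6$), and dual-binding
evaluation of the survivors. Docking and MD never run in-core: adapters
are command templates or functions, with a deterministic mock shipped for
testing, and precomputed score tables short-circuit the stage entirely
(the two routes are tested to give identical downstream results). Every
stage writes TSV plus a YAML manifest; one top-level seed drives all
stages via name-derived seeds, so a rerun with the same config and seed
reproduces the outputs byte for byte.

## Synthetic fixtures: what they do and do not show

`make_toy_complex()`, `make_pocket_fixture()`, `make_energy_tables()` and
`make_compound_roster()` generate every input the package consumes, with
planted ground truth re-verified by brute force before anything is
written and recorded in a manifest (realized statistics, not nominal
ones). Frame energies are Gaussian around planted means -- a modelling
convenience, not a claim about MM/GBSA error distributions. Default
shapes follow the study conditions the package targets: 5 replicas x 75
frames per energy table; a 50-candidate evaluation set of which 34 pass
the (-15, 10) selector; descriptor windows as above. Toy structures are
geometric clusters with valid PDB records (chains R/L, HETATM group S),
not protein-like geometry.

Passing tests on these fixtures therefore demonstrate *contract*
correctness -- conservation laws, brute-force equality, planted-truth
recovery, determinism -- and the exactness of the equilibrium theory. They
do not demonstrate that MM/GBSA energies predict potency for any real
system, nor that real pockets are druggable; those claims require
simulations and experiments outside this package.

## Numerical choices and limitations

* Problem sizes in the test suite (100 random systems for the solver
  oracle, $10^3$ randomized contact pairs, tens of atoms per SASA
  fixture) were chosen so the whole suite runs in well under a minute
  while still exercising every code path; all tolerances above are
  asserted there.
* Ties are always broken by identifier; filters report per-criterion audit
  counts in declared order (weight, LogP, complexity) -- order affects only
  attribution, never the kept set.
* One stabilizer species per system; no kinetics; no fitting of $K$ or
  $\varphi$ to dose--response data; no entropy corrections or per-atom
  energy decomposition; multi-model PDB is the only trajectory format.
* The flat-objective guard in `optimal_dose()` returns the left-most
  maximiser with a warning for degenerate parameter sets.
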