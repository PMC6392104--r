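---
title: "A multiscale Cellular Potts model of the CD8 T-cell response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale Cellular Potts model of the CD8 T-cell response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd8potts)
```

## The model

`cd8potts` simulates a CD8 T-cell immune response in a lymph node as three
coupled layers, advanced together once per Monte Carlo step (MCS, one
simulated minute):

1. **A 2D Cellular Potts population.** Cells are sets of nodes on a periodic
   square lattice (one node = 4 µm). Shape and motion emerge from
   energy-biased index copies: a random node attempts to copy its cell index
   onto a random first-order neighbour, and the attempt is accepted by the
   Metropolis rule on the energy change. The energy (Hamiltonian) sums a
   quadratic area constraint, a quadratic perimeter constraint (perimeter =
   boundary node-edges × 4 µm, so a 3×3 cell exactly meets its 48 µm
   target), and heterotypic contact energies `J`. A per-cell motility term —
   the dot product of a privileged heading with the copy direction — biases
   movement. One MCS performs `N = 3S` attempts on an `S`-node lattice;
   three sweeps per step keep cell speeds compatible with the one-minute
   time mapping of the molecular layer.

2. **A six-variable intracellular network per cell.** Non-activated IL2
   receptors `R`, activated receptors `LR`, Tbet `Tb`, activated Fas `Fs`,
   Caspases `Cas` and Eomes `E` (all mol/L) evolve by ODEs driven by five
   per-cell environment inputs: the number of bound APCs `f_APC`, the
   activation-history flag `G`, the Fas-engagement flag `H` (non-naive cell
   touching an effector or memory cell), the membrane IL2 `IL2cm`, and the
   summed Tbet of contacting effector/memory cells `Tbcm`. The Tbet equation
   carries a Hill-type positive feedback (exponent `n`) that makes it
   bistable: once APC contact ends, a cell's Tbet relaxes either to 0 or to
   a high stable state, separated by an unstable threshold — the molecular
   basis of the short-lived-effector versus memory-precursor dichotomy.

3. **A diffusing extracellular IL2 field.** Engaged CD8 T-cells (pre-activated
   and beyond; never naive cells or APCs) secrete IL2 at a rate saturating
   in `LR`, driven by APC contact and inhibited by Tbet. The field diffuses
   isotropically with periodic boundaries and decays first-order. Each
   cell's `IL2cm` is the field summed over its boundary nodes.

**Cell rules** close the loop. A naive (or restimulated memory) cell binding
an APC becomes pre-activated and adheres to it; when `LR` reaches `IL2R_th`
the cell activates, detaches, and starts cycling. Cycle lengths are drawn at
birth from `U[c_k − 4, c_k + 4]` hours with `c_k = 6 + 28k²/(k² + 100)` for
the k-th division, so early divisions are fast and later ones slow toward
34 h. At division the mother's six concentrations are partitioned unevenly:
per protein, one daughter inherits `k_i [i]` and the other `(2 − k_i) [i]`
with `k_i ~ U[1 − m/100, 1]` (degree of unevenness `m`, default 10%, i.e. at
most a 45/55 split). The first division after activation is *asymmetric*:
Tbet alone is split with `K ~ U[0.5, 1]`, the proximal daughter receiving
`(2 − K)[Tb]`. Daughters are typed by Tbet (`activated` below `Tbet_th`,
`effector` at or above); a dividing cell whose Eomes exceeds `Eomes_th`
instead converts to memory and stops proliferating. A non-naive cell dies
when Caspases reach `Caspases_th`; APCs live `U[48, 96]` hours. Division is
realised spatially by bisecting the cell perpendicular to the principal axis
of its nodes into two connected, near-equal halves (alternating
breadth-first growth from the two extreme nodes, which guarantees
connectivity of both daughters for any mother shape).

The update order within an MCS is fixed for reproducibility: Potts step →
contact map and environment inputs → molecular step per cell → field step →
rules (binding, activation, cycle/division, apoptosis). Naive cells are
clamped to the all-zero molecular state until their first APC contact.

## Parameters and the shipped calibrated set

All rates are per hour; concentrations are mol/L; one MCS is 1/60 h. The
numeric parameter set shipped as the defaults of `molecular_params()`,
`field_params()`, `potts_config()` and `cd8_thresholds()` is this package's
own calibration, produced by iterative scaled-down simulation under four
hard constraints, in this order of priority:

1. **Bistability by construction.** With `n = 2` the positive Tbet fixed
   points solve `x² − (λ_T2/k_T)x + λ_T3² = 0`, so `λ_T2/k_T = 21 + 118`
   and `λ_T3 = √(21·118)` place the unstable and stable states at exactly
   21 and 118 mol/L. `tbet_fixed_points()` verifies this numerically.
2. **Resting memory profile.** With no stimulation, `E* = λ_E4/k_E = 26`,
   `Tb* = 0`, and `Cas* = λ_c1 / (k_c (1 + 26 λ_E2)) = 9` mol/L;
   `R* = λ_E1 E*/k_R = 26`, so memory cells hold more IL2 receptors than
   naive cells (which have none) — the mechanism that makes the secondary
   response faster.
3. **A stable receptor loop.** The `R → LR → R` feedback has loop gain
   `< (μ_IL2⁻ + λ_R2)/(μ_IL2⁻ + k_e)`, which must stay below 1
   (`λ_R2 < k_e`) or receptor levels diverge in IL2-rich environments.
4. **The qualitative response course at scaled-down size** (next section).

Three structural choices came out of the calibration and are worth
recording. First, the effector death program is *autonomous but
Eomes-gated*: `λ_c1/k_c = 25` exceeds `Caspases_th = 19`, so an activated
cell left unprotected dies in about two days, while the Eomes factor
`1/(1 + λ_E2 E)` lifts the equilibrium below threshold once `E ≳ 10`. Fas
engagement (`λ_c4 Fs`) accelerates death where effectors crowd, and is
self-limiting as they die. Second, Eomes is a *fast, Tbet-gated* module
(`k_E = 0.1`/h, `λ_E7 = 0.3`): cells that commit to low Tbet are rescued
and converted to memory within a day or two, whereas high-Tbet cells keep
`E ≈ 0.7` and die — this race, not a hard-coded fate, decides each
lineage. Third, Tbet at activation must straddle the unstable point: with
`λ_T1 = 4.1` and activation reached roughly 8–12 h into APC contact, the
asymmetric first division (`K ~ U[0.5, 1]`) sends proximal daughters above
and a fraction of distal daughters below 21 mol/L, seeding both fates.

The contact-energy table encodes the adhesion story: `J(pre-activated, APC)
= 2` is the lowest entry (a pre-activated cell holds on to its APC),
`J(activated/effector, APC) = 30` detaches cells once they start cycling,
and naive/memory cells sit at 8, enough to bind and enter the scheme.
`λ_area = 12`, `λ_pm = 0.2` and `T = 15` were chosen together so that shape
fluctuations are live at the working temperature — with a much stiffer
perimeter weight the lattice freezes and naive cells never reach an APC.

## Numerical choices

* **Molecular integrator:** classical RK4 with one step per MCS (1/60 h),
  automatically subdivided ×10 when any variable would change by more than
  20% of `max(|x|, 1)` in a single step. Negative undershoots are clipped to
  zero and counted; a run warns if clips exceed 0.1% of steps. Blow-ups
  (non-finite values) abort with the offending variable named.
* **Field update:** forward-time centred-space with the 4-neighbour
  Laplacian and periodic wrap, subcycled so `D·dt_sub/Δx² ≤ 1/4`. Decay is
  applied as an exact exponential factor per substep (operator splitting),
  so pure decay follows `exp(−δt)` to rounding; the stencil conserves mass
  exactly (to rounding) at zero decay.
* **Metropolis convention:** a copy whose motility-adjusted energy change is
  non-positive is accepted outright, otherwise with probability
  `exp(−ΔE/T)`. (The alternative sign convention, taken literally, would
  accept energy-raising moves with "probability" above one.)
* **Neighbourhood:** first-order (4-neighbour) both for copy targets and
  contact energies.
* **Memory conversion** is checked at cycle completion: the mother converts
  *instead of* dividing. The alternative (divide, then both daughters
  memory) is available via `cd8_thresholds(memory_divides = TRUE)`.
* **Threshold comparisons:** `LR ≥ IL2R_th` and `Tb ≥ Tbet_th` ("reaches"),
  `E > Eomes_th` strict, `Cas ≥ Caspases_th`.
* **Fas saturation:** the Fas activation term is read as
  `H μ_F⁺ [Tbcm] (λ_F/k_F − Fs)`, giving a bounded `Fs`; the product
  reading `λ_F·k_F` is available via `fas_cap_mode = "product"`.
* **Membrane IL2** sums the field over the cell's boundary nodes; summing
  over all nodes or over adjacent medium nodes is switchable in
  `il2_at_membrane()`.
* **RNG:** a single R session stream (`set.seed()`) drives every stochastic
  element, reached from compiled code through R's own generator. Runs are
  bit-reproducible given seed and configuration. Per-mechanism sub-streams
  were considered and rejected to keep the standard R seeding contract.
* **No division cap:** the cycle-length formula is used as printed; its
  upper tail slightly exceeds the nominal 2–32 h range (supremum 38 h) and
  no cap on division number is imposed.
* **Pre-activated cells never revert** to naive, even if their APC dies
  before activation; they persist (and can die once `G = 1`).

## Scaled-down preset and what the tests show

Full-scale runs (preset `"full"`: 150×150 lattice, 30,000 MCS ≈ day 4 to
day 24.8 post-infection, 30 naive cells + 3 APCs) take minutes each;
replicate sweeps take hours. The test suite and the acceptance script
therefore use the `"ci"` preset: a 60×60 lattice, 12,000 MCS (day 4 to day
12.3), 10 naive cells + 1 APC — sized so a run finishes in well under a
minute while still traversing activation, clonal expansion, an interior
peak, contraction and memory emergence. The 12,000-MCS horizon was chosen
because a shorter one (a few thousand MCS) ends before the contraction
phase that the qualitative checks need.

Under the shipped defaults the scaled-down primary response activates
within half a day, peaks around day 7 with essentially the whole population
in the activated/effector state, loses roughly half to nine-tenths of the
peak population to apoptosis (seed-dependent at this small size; the
full-scale analogue of this quantity is the in-silico contraction of about
two thirds), and converts the surviving low-Tbet lineages to memory after
the peak. The ranked Tbet profile at the end is bimodal around the
unstable point: high-Tbet cells carry high Caspases and low Eomes, low-Tbet
cells the reverse. A paired secondary run (same seed, 10 memory cells
seeded with the asymptotic memory profile) activates faster, peaks at least
as high, and ends with a several-fold larger memory pool.

What the scaled-down tests do **not** show: quantitative peak sizes or
timings at the full lattice size (the peak population is partly limited by
lattice capacity, which differs between presets); the full-scale
unevenness-sweep orderings (at this population size the sweep reproduces
the declining peak for moderate `m`, but at extreme unevenness, 80%,
stochastic dilution of Caspases lets lineages outrun the death program — a
small-population artifact that the slow Caspase clock makes possible); and
anything about real in-vivo data, since the reference series used by the
calibration metrics is a synthetic fixture.

## The synthetic reference fixture

`make_reference_fixture()` generates smooth per-subject time series with
the canonical shape of a murine CD8 response — activated/effector fraction
above 0.94 at the day-8 peak, memory majority by day 22, IL2 receptor level
peaking at day 5, Tbet plateauing over days 6–8 before declining, Eomes
rising monotonically to day 8 — plus small subject-level noise. It stands
in for in-vivo calibration data so that the distance metrics (`d_cell()`,
`d_prot()`: mean absolute fraction/normalised-level differences over
simulation-subject pairs, `D = D_cell + D_prot`) and the coordinate search
(`local_search()`) are fully testable offline. It emulates the *shape* of
real data, not its sampling noise, inter-animal variance structure, or
absolute scale; conclusions drawn against it are about machinery, not
biology.

## Known limitations

* Two spatial dimensions; no chemotaxis up IL2 gradients; no receptor-level
  IL2 depletion from the field.
* The lattice caps the attainable peak population, so peak sizes are
  preset-dependent.
* One amalgamated "gene activity + protein" level per factor; no
  transcription/translation distinction and no stochastic gene expression.
* No cap on division number; no TCR-affinity dependence of polarisation.
* The shipped parameter set is *a* calibration satisfying the stated
  constraints, not an estimate: other sets satisfying them exist, and none
  of the quantitative outputs should be read as fitted to real data.

## A minimal session

```{r, eval = FALSE}
library(cd8potts)

set.seed(1)
sim <- run_primary(sim_config("ci"))
glance(sim)          # peak size/day, memory pool, death fraction
autoplot(sim)        # population dynamics by type
plot_tbet_profile(tbet_profile(sim))  # ranked bimodal Tbet profile

set.seed(1)
mem <- run_secondary(sim_config("ci"))
glance(mem)$final_memory / glance(sim)$final_memory
```
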