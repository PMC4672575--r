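---
title: "A cellular-automaton model of radiation-induced bystander effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cellular-automaton model of radiation-induced bystander effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`bystandr` simulates how the damage signature of an irradiated cell
population spreads to its non-irradiated neighbours. The world is a
two-dimensional lattice of 10 µm sites of three kinds — *cell*, *medium*
and *wall* — advanced synchronously in 0.1 s steps. Four coupled
processes act per step:

1. **Irradiation.** Dose arrives as discrete track traversals. Each
   track deposits a fixed elementary dose $D_\mathrm{1track}$
   (0.001 Gy, the γ-ray value) and tracks arrive per masked site as a
   Poisson process ($10^3$ tracks/min by default, i.e. a 1 Gy/min dose
   rate). The exposure lasts exactly `dose / dose_rate`.

2. **Two virtual signals.** Irradiated cells produce, in proportion to
   the step dose ($\alpha = 1$ unit/Gy), a medium-mediated signal $M$
   (MDP) and a gap-junctional signal $G$ (GJP). Both obey an explicit
   8-neighbour diffusion scheme in which orthogonal neighbours are
   weighted twice and diagonal ones once, gated by *direction
   constants*: the MDP signal exchanges with cell and medium sites
   alike ($w_M = 10^{-10}\,\mathrm{m^2/s}$), the GJP signal only
   between contiguous cell sites
   ($w_G = 5\times10^{-11}\,\mathrm{m^2/s}$), and walls exchange
   nothing. Each signal decays exponentially ($\beta_M =
   4.6\times10^{-6}\,\mathrm{s^{-1}}$: still active after days;
   $\beta_G = 1.18\times10^{-3}\,\mathrm{s^{-1}}$: a ~14 min lifetime
   patterned on calcium efflux).

3. **DSB bookkeeping.** Every cell carries an integer count $Z$ of DNA
   double-strand breaks. Per step, four independent Poisson sources add
   breaks — direct dose ($\lambda_{ZR} R$), each signal
   ($\lambda_{ZM} M \Delta t$, $\lambda_{ZG} G \Delta t$) and
   endogenous background — and each existing break is repaired
   independently with a per-cell probability (binomial thinning of the
   previous step's count, so a break created in a step cannot be
   repaired in that same step).

4. **The virtual clock.** Each cell progresses through G1, S, G2, M1
   and M2 with individually sampled periods (means 11, 8, 4, 0.5,
   0.5 h — a 24 h cycle). At the four phase boundaries the clock parks
   and halts while $Z$ is at or above the checkpoint threshold
   (means 5, 40, 20, 40 breaks), re-evaluated every step so repair
   releases the arrest. Crossing the reproductive-death threshold sends
   a proliferating cell to the pre-reproductive-death state (1–3
   further divisions, then a permanently stopped clock); crossing the
   twice-as-large interphase-death threshold dooms the cell to removal
   within one division, returning its site to medium. Division claims
   a uniformly chosen adjacent medium site; with none available the
   cell parks in G0 and re-enters G1 when space opens (a
   contact-inhibition analogue, switchable off). Reproductively dead
   cells keep conducting both signals.

All per-cell coefficients are drawn from the positive part of normal
distributions (rejection sampling), per phase group, from the catalogue
in `inst/extdata/default_parameters.yaml`; `default_catalogue()` loads
it and any entry can be overridden.

## Resolved ambiguities and open design choices

Several quantities in the model's source formulation carry units that
do not match the way they enter the update equations. The package makes
each reading explicit and configurable, with these defaults:

* **Signal decay** (`decay_mode`): the update subtracts $\beta\phi$
  once per step although $\beta$ is stated per second. The default
  applies the fraction $\beta\,\Delta t$ per step — with the stated
  $\beta_G$ a literal per-step reading would shorten the GJP lifetime
  from ~14 min to ~85 s, contradicting the calcium-efflux rationale, so
  units win over typography. `literal` mode is available.
* **Repair probability** (`repair_mode`): the repair flowchart compares
  a uniform draw against $\lambda_{Zr}$ once per step, and the fitted
  values only reproduce the observed ~20 h DSB-decay horizon under
  that per-step reading, so `per_step` is the default even though the
  catalogue labels the value s⁻¹. `per_second` applies
  $\lambda\,\Delta t$.
* **Background induction** (`background_mode`): same structure; the
  per-step reading is what reproduces a ~22 % DSB-positive control
  fraction at 30 min, and is the default.
* **Truncation bounds** are not stated numerically; all default to 0
  ("positive part"), configurable per parameter.
* **Re-sampling at phase transitions**: the catalogue specifies
  distinct distributions per phase group and no carry-over rule. When a
  cell enters a phase in a different group, that field is re-drawn;
  fields whose group spans both phases keep their value. Daughters
  re-sample everything at birth.
* **Division bookkeeping** (paper-silent, all configurable): breaks are
  split binomially between daughters (`inherit_mode`, alternatives
  `copy`/`zero`); the junctional signal is halved (cytoplasm
  partition); the medium-mediated signal already present at the
  daughter site is untouched; both daughters inherit the residual
  division countdown.
* **Arrest ties**: $Z \ge H$ counts as arrest.
* **Geometry**: the stated 103×303 space is realised as a one-site wall
  ring around a 101×301 interior, which gives the diffusion scheme
  uniform zero-flux boundaries. Indexing reported to users is 1-based,
  so the centre row is row 52.
* **Irradiated-disc radius**: the three-area scenario irradiates a
  central disc of area B; its radius is not stated and defaults to 20
  sites. This is the largest free geometric parameter affecting the
  quantitative bystander numbers.
* **Signal normalisation**: the narrative description of the
  post-exposure signal amplitude ("around 1 unit" after 0.1 Gy) is a
  factor ~10 above the literal production law $\alpha R$; the package
  implements the literal law and exposes `signal_scale` for users who
  prefer the narrative normalisation.

## The three-area scenario

`build_three_area_world()` reproduces the canonical experiment: three
disc colonies (radius 40 sites) side by side. Area A is seeded at 15 %
density with uniformly random clock positions, so cycle effects are
visible; areas B and C are confluent discs of quiescent (G0) cells.
Only the central disc of area B is irradiated: its bystanders receive
both signals, areas A and C the medium-mediated signal only, and the
B–C contrast isolates the gap-junctional contribution. Counting
follows the experimental convention: irradiated cells are excluded in
area B, and area C's counts can be baselined against its initial G0
population.

With catalogue defaults and 5 Gy at 1 Gy/min, the mean DSB burden of
non-irradiated G1 cells in area B rises to its maximum within about an
hour and then falls as the junctional signal decays and repair takes
over, while area C's burden — fed only by the slowly decaying,
long-range medium signal — climbs for many hours to a much lower, later
maximum. These two curves are what `scripts/acceptance.R` recomputes.

## What the generator emulates — and what it does not

All inputs are generated programmatically: the scenario builders *are*
the study conditions (sample sizes, densities, doses, parameter
distributions as listed above). They emulate a 2-D monolayer culture
with one cell per 10 µm site, dose delivered uniformly within a masked
disc, and signal kinetics reduced to linear production–diffusion–decay
of two non-interacting species. They do not emulate 3-D cultures,
signal-molecule chemistry (NO, cytokines, calcium handling), receptor
saturation, repair-pathway structure or misrepair, cell migration, or
apoptosis signalling. Passing tests therefore certify the model's
internal consistency and its agreement with the stated operating
points, not fidelity to any particular cell line.

The bundled calibration fixture
(`inst/extdata/synthetic_dsb_decay_g1.csv`) is a synthetic curve
generated by `harness_dsb_decay()` at the catalogue repair value with
the stochastic width collapsed to zero; the original experimental
points behind the calibration figures are third-party data and are not
redistributed.

## Numerical choices

* The explicit scheme is stable iff $3\,\Delta t\,w/d^2 \le 1$
  (`stability_check()`); `sim_config()` refuses violating
  configurations. At the defaults the margins are 0.3 (MDP) and 0.15
  (GJP), and fields stay non-negative.
* The synchronous update is double-buffered: both fields and all
  cellular decisions read the state at $t$; lattice edits (division,
  removal) take effect the next step.
* The four Poisson sources are drawn as one Poisson with the summed
  mean (distributionally identical, by superposition).
* `harness_dsb_decay()` draws the count at each output time by
  blockwise binomial thinning, which is *exactly* the distribution of
  the per-step process (no approximation); `harness_survival()`
  collapses the per-step track/DSB cascade the same way.
* Degenerate distributions (`sd = 0`) short-circuit the rejection
  sampler; rejection otherwise regenerates only failed draws.
* Reproducibility: every trial's stream is derived from the master
  seed with `derive_seed()`; equal seeds give bit-identical records.

## Problem sizes

The full three-area geometry (103×303, ~10,800 cells, 72,000 steps for
2 h of culture) runs in a few minutes; the acceptance script averages
two such trials, a deliberate compromise between replicate averaging
and turnaround (the reference analysis used ten). The test suite
verifies the long-horizon and dose-response properties on
proportionally scaled geometries (scale 1/3–2/5, coarser steps still
satisfying the stability bound), where the area-ordering and shape
properties are preserved; the 12 h area-C maximum is checked as an
ordering property at scale 0.4 rather than at full scale. Life-state
kinetics over 96 h (interphase- vs reproductive-death waves) are
checked in a directly irradiated sparse colony with signalling
disabled, since once the damage is set those kinetics are driven by
the clock, not by diffusion, and this permits a coarse time step.

## Limitations

Bystander DSB maxima depend quantitatively on the under-specified
irradiated-disc radius and signal normalisation discussed above;
treat absolute values with those caveats (the shapes and the B/C
ordering are robust). The G0 re-entry rule and the removal timing of
arrested doomed cells are plausible conventions, not measured biology.
Parameters assembled from multiple cell lines mean no single line is
represented exactly.
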