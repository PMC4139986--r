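---
title: "Modeling carrier-mediated auxin fluxes in actinorhizal nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling carrier-mediated auxin fluxes in actinorhizal nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodusim)
```

## The question

Actinorhizal plants such as *Discaria trinervis* and *Casuarina glauca* form
nitrogen-fixing root nodules with the actinomycete *Frankia*. In mature
nodules, auxin (phenylacetic acid) is detected inside the hypertrophied
cortical cells that host *Frankia*, and auxin response markers are active in
the nodule meristem. Immunolocalization and promoter-reporter studies place
the auxin carriers differently in the two species:

* *D. trinervis*: a PIN1-like **efflux** carrier on the plasma membranes of
  **infected** cells; the AUX1 **influx** carrier expressed in the
  **meristem**.
* *C. glauca*: the AUX1 influx carrier on **infected** cells; a PIN1-like
  efflux carrier on the **uninfected** cells surrounding them.

`nodusim` asks the cell-scale question: *given a digitized nodule section
and a carrier layout, where does a compartmental transport model predict
auxin to accumulate?* The *C. glauca* layout is the positive control — both
carriers pump toward infected cells, and the model should (and does) drive
auxin into them. The scientific payload is the *D. trinervis* layout, where
efflux carriers sit on the very cells in which auxin is observed.

## Virtual tissues

A tissue is a cell-adjacency graph: cells carry a type (infected,
uninfected, meristematic), an area, and optionally a *Frankia* compartment;
interfaces carry the shared wall length between two adjacent cells.
`import_label_map()` digitizes a segmented section image (an integer label
matrix) into this graph under 4-connectivity: area is the pixel count times
the squared pixel size, wall length is the count of adjacent pixel pairs
times the pixel size. Diagonal pixel contact has zero boundary measure and
produces no interface — wall lengths must scale with the boundary, which
8-connectivity would violate. Geometry and concentrations are
nondimensional; `pixel_size` defaults to 1.

The apoplast (cell-wall space) is *not* an explicit compartment: interfaces
carry transport directly between cell interiors, with influx carriers
standing in for uptake from the shared wall. The tissue exterior is
no-flux, i.e. the section is treated as a closed system.

### The synthetic generator

Real digitized nodule sections of this kind are not publicly deposited, so
`generate_nodule_tissue()` produces surrogates with the same qualitative
anatomy, on an integer pixel grid so that the digitization round trip
(`render_label_map()` then `import_label_map()`) is exact and reproducible:

* an elongated elliptical lobe (aspect ratio 2.2);
* a contiguous **meristematic cap** of unit cells at the apex, ~10% of the
  cells by default;
* an **infection zone** directly beneath the cap: hypertrophied infected
  cells (2×2 pixel blocks, i.e. four times the area of an uninfected cell)
  are placed there first, reflecting nodule zonation in which newly
  infected cells lie just below the meristem;
* the remaining cortex tiled by seeded rejection sampling so that infected
  cells (35% of cortical cells by default) are interspersed among small
  uninfected cells, every infected cell keeping at least one uninfected
  neighbor (a logged post-hoc repair enforces this in the rare case
  sampling cannot).

Defaults (200 cells) were chosen so that a full simulation completes in a
few seconds on one core; the generator spec exposes all fractions so users
can span plausible anatomical variation. What the generator does *not*
emulate: vasculature (no vascular cell type is modeled), multi-lobed
nodules, cell-shape irregularity, and section-to-section thickness
variation. Passing tests on synthetic tissues therefore validate the
machinery and the qualitative carrier logic, not any specific real nodule's
geometry.

```{r}
tissue <- generate_nodule_tissue(nodule_spec(seed = 1))
tissue
```

## The transport model

Let $a_i$ be the auxin concentration (amount per unit area) of cell $i$.
For cells $i,j$ sharing a wall, the flux per unit wall length, positive
from $i$ to $j$, is

$$
J_{i \to j} = \left[d + p\,\mathrm{pin}_{i|ij}\right] a_i
            - \left[d + p\,\mathrm{pin}_{j|ij}\right] a_j
            + q\,\mathrm{aux}_{j|ij}\, a_i
            - q\,\mathrm{aux}_{i|ij}\, a_j ,
$$

where $d$ is the passive wall permeability (`d_wall`), $p$ and $q$ the
efflux- and influx-carrier permeability coefficients (`p_pin`, `p_aux`),
and $\mathrm{pin}_{i|ij}$, $\mathrm{aux}_{i|ij}$ the dimensionless carrier
densities on cell $i$'s membrane at that interface. Efflux carriers push
auxin out of their own cell; influx carriers pull auxin in from the
neighbor. Each cell then obeys

$$
\frac{da_i}{dt} = \frac{1}{A_i} \sum_j w_{ij} J_{j \to i}
  + \sigma + s_F\,[\text{Frankia}_i] - \delta\, a_i ,
$$

with cell area $A_i$, wall length $w_{ij}$, basal production $\sigma$,
*Frankia*-compartment source $s_F$, and first-order decay $\delta$.

Kinetics are deliberately **linear** (no Michaelis–Menten saturation): no
kinetic constants are available for these carriers, and linearity gives a
unique steady state, an exact conservation structure, and a direct-solve
oracle. The whole system is affine, $\dot a = Ma + c$, with $M$ Metzler and
the transport part conserving the area-weighted total
$\sum_i A_i a_i$ exactly. With $\delta > 0$, $M$ is strictly stable, so
the steady state $a^\* = -M^{-1}c$ exists, is unique, nonnegative, and
independent of the initial state.

### Default parameters

| parameter | meaning | default |
|---|---|---|
| `d_wall` | passive wall permeability / unit wall | 1 |
| `p_pin` | efflux-carrier coefficient | 10 |
| `p_aux` | influx-carrier coefficient | 10 |
| `sigma` | basal production / unit area | 0.1 |
| `delta` | first-order decay | 0.1 |
| `s_frankia` | *Frankia*-compartment source | 1 (low) / 10 (high) |
| `a0` | initial uniform level | 1 |

All nondimensional. Carrier coefficients are set tenfold above the passive
permeability so that carrier placement, not background diffusion, shapes
the pattern; carrier "density" is a presence/absence multiplier (the
immunolocalization evidence is qualitative). These magnitudes are model
choices, which is exactly why `sweep_parameters()` exists.

### Numerical scheme

`simulate_fluxes()` integrates with explicit Euler. The step is capped at
$0.9/\max_i |M_{ii}|$, which both satisfies the usual stability bound and
makes the update matrix $I + \Delta t\,M$ nonnegative — so nonnegativity of
concentrations is preserved *structurally*, with no clipping that could
mask an integration error. Steady state is declared when
$\max_i |\dot a_i| / \max_i a_i$ falls below `steady_tol` (default 1e-8).
`steady_state_direct()` solves the linear system directly and serves as the
independent precision reference; the two agree to ~1e-7 relative on random
systems in the test suite, and a third, deliberately naive per-interface
rate implementation in the tests pins down the flux-law algebra itself.

## Scenarios

Three source regimes are encoded by `scenario()`:

* **production_only** — no initial auxin, uniform basal production;
* **initial_pool** — a uniform initial pool, no production. With decay and
  no source the absolute level tends to zero, so the captured observable is
  the *normalized profile* $a/\sum a$, which converges to the dominant
  eigenmode of the transport operator; `run_scenario()` integrates until
  the profile is stationary (or computes the eigenmode directly with
  `method = "direct"`);
* **frankia_source_low/high** — the source confined to the *Frankia*
  compartment of infected cells, at strength 1 or 10 (the two strengths
  bracket "*Frankia* as a minor vs dominant auxin source").

## Pattern classification

`classify_pattern()` reduces a steady state to area-weighted mean
concentrations per cell type (area weighting because the claim concerns
where auxin accumulates *spatially*, and infected cells are hypertrophied;
an unweighted variant is available). Labels:

* a type whose mean exceeds the runner-up by a relative margin
  $\ge \varepsilon$ (default 0.01) wins: `infected`, `uninfected` or
  `meristem`;
* if no single type wins but infected and meristematic cells are the top
  two and both exceed the uninfected mean by $\ge \varepsilon$, the label
  is `infected_and_meristem` — the joint pattern matching the biological
  observation (auxin in infected cells, response in the meristem);
* anything else is `uniform_ambiguous`.

The precedence — single dominant type first, joint label only among
near-tied leaders — is a deliberate design decision. A naive "both above
uninfected" rule would label the *C. glauca* control `infected_and_meristem`
merely because the carrier-free meristem sits passively above the
PIN-depleted uninfected cells, while infected cells exceed everything
tenfold; reading that pattern as joint accumulation would be absurd. Margins
are ratios, so labels are invariant to uniform rescaling — necessary because
the initial-pool profile is only defined up to scale. The $\varepsilon$
threshold is this package's operationalization of "accumulation"; the
underlying micrographs provide no quantitative threshold.

## What the model predicts, and an honest caveat

With default parameters the *C. glauca* layout robustly classifies
`infected` — the positive control behaves. Under the *D. trinervis* layout
the model predicts auxin depletion from infected cells (uninfected means
exceed infected roughly tenfold) in every scenario; the biological
`infected_and_meristem` pattern never appears, at defaults or anywhere on
the default 256-configuration sweep. In this respect the simulation
supports the conclusion that PIN1-on-infected / AUX1-on-meristem placement
cannot, by itself, explain the observed auxin accumulation in infected
cells — other transporters or mechanisms must be missing.

One model-specific behavior deserves emphasis: in this flux law, influx
carriers on all meristem membranes make the meristem a net sink with a
per-interface equilibrium ratio of $(d + q)/d$ (11 at defaults) over its
neighbors, while meristem decay capacity $\delta A_\text{mer}$ is small
against its boundary conductance. Consequently the meristem's mean
typically ends *above* the uninfected mean, and the default runs classify
`meristem` rather than `uninfected` (with uninfected far above infected in
all cases). Hand analysis suggests this is not a quirk of parameters: any
local linear carrier law with a strong meristem influx term behaves this
way, including explicit-apoplast variants. A model whose meristem does not
accumulate auxin would need a different influx mechanism (e.g. saturable
uptake, or recapture-only kinetics). The operator form `build_rate_operator()`
is the intended extension point for such variants.

## Reproducing the analysis

```{r, eval = FALSE}
fig <- run_figure7(tissue_seeds = c(1, 2, 3), layout = "discaria")
fig$summary
summarize_patterns(fig$calls)

tab <- sweep_parameters(sweep_spec(seed = 1))
nrow(find_reproducing_configs(tab, "infected_and_meristem"))
```

The parameter sweep spans, per axis, two decades around the defaults
(`d_wall` 0.1–3, `p_pin` and `p_aux` 0.1–100, source scale 0.1–100; 4
log-spaced values each, 256 configurations) under the Frankia-source
scenario — chosen because a *Frankia*-derived source is the biological
hypothesis for auxin inside infected cells, so an exploration that omitted
it could not fail informatively. Patterns are scale-invariant in a linear
model, so the source-scale axis doubles as an internal consistency check.
Problem sizes throughout (200-cell tissues, three seeds, 256 configurations)
are the package's desk-scale defaults; everything scales up by passing a
larger `nodule_spec()` or a denser grid.

## Known limitations

* No subcellular PIN polarity, no canalization feedback, no
  carrier regulation by auxin, no growth or division.
* No vascular cell type, although AUX1 expression is also seen in the
  vasculature; the three-type tissue model cannot represent it.
* 2-D sections only; a 3-D lobe would change surface-to-volume ratios and
  hence the meristem-sink balance discussed above.
* Linear kinetics: saturation of carriers at high auxin is not modeled.
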