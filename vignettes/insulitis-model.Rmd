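---
title: "An agent-based model of CD8+ T cell / Beta cell interactions in insulitis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of CD8+ T cell / Beta cell interactions in insulitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulitisSim)
```

## The model

`insulitisSim` simulates the autoimmune attack on pancreatic islets in the
NOD mouse on a two-dimensional lattice. A tissue section of 200 x 200 sites
(10 um each) carries circular islets of insulin-producing Beta cells, one
cell per site, each islet encased in a one-site-thick basement-membrane ring.
Naive, effector and memory CD8+ T cells move across the section in
one-minute ticks over a ten-week horizon that represents mouse ages 4 to
14 weeks.

The rules, in outline:

* **Motility.** T cells perform a persistent random walk: 10 um/min, a
  uniformly drawn direction from the 8 lattice directions, persistence times
  of 1--4 min. Cells walking over the tissue boundary leave the simulation
  (efflux); naive cells immigrate at the boundary at 1.7% of the resident
  population per day (a Poisson stream). Blocked steps waste the tick, so no
  cell exceeds one site per minute.
* **Basement membrane.** Every ring site starts at the scenario's membrane
  strength, interpreted as effector-minutes per site (1440 = one effector
  needs one day to open one site; 20160 = fourteen days). Each site with
  remaining strength loses one unit per adjacent effector per minute; a site
  at zero is a permanent opening (no repair). An effector adjacent to intact
  membrane is *engaged*: it arrests in place, erodes the ring, and its
  lifespan clock pauses (adhesion-derived survival signals); it resumes
  moving when an opening or an accessible target appears beside it.
* **Antigen contact.** Recognition requires physical access: a Beta cell in
  the Moore neighbourhood that is not separated by intact membrane. Beta
  cells on the original islet footprint are reachable only from inside the
  islet or from an opened ring site; regrowth outside the footprint is
  exposed. One predicate drives activation, cycling, memory recall and
  conjugation. Cells standing beside a reachable opening step through it
  (invasion) rather than diffusing away; this is a purely local rule, not
  chemotaxis, which the model deliberately excludes.
* **Killing.** An effector with spare capacity (at most two simultaneous
  engagements) conjugates up to two reachable adjacent Beta cells, chosen
  uniformly. The kill is decided once, at formation, with probability 0.55;
  killed cells are removed immediately while the conjugate holds the
  effector in place for 90 min.
* **Proliferation.** A single antigen encounter commits a naive or effector
  cell to a programmed division burst: the cell cycles with a 360-min
  division time, both products advance one generation and restart at age 0,
  and products below generation 8 re-enter the cycle autonomously.
  From generation 8 on, each product independently becomes a memory cell
  with probability 0.20 (otherwise an effector), and further cycles require
  renewed contact. Cycling cells in contact are arrested; an active
  conjugate counts as contact. Daughters occupy a random free neighbouring
  site; division is deferred while none is free.
* **Memory.** Memory cells are long-lived (6 months) and re-acquire effector
  function (age reset to 0, generation kept) on renewed accessible contact.
* **Lifespans.** Naive 8 weeks, effector 6 days, memory 6 months, enforced
  as hard cut-offs on the age clock; week = 7 days, month = 30.42 days.
* **Beta regeneration.** An islet is marked as attacked the first time a
  T cell stands on one of its membrane or interior sites, an effector
  engages its ring, or one of its Beta cells is conjugated. From then on
  each of its living Beta cells divides with per-tick probability
  `rate/1440` (scenarios use 0 or 5%/day). A daughter takes a free
  neighbouring site; when the mother is fully crowded, growth pressure
  pushes the newborn along a straight line of Beta cells to the nearest
  free site, so it emerges at the islet surface. Growing islets therefore
  visibly bulge past their membrane ring, and the regrowth — but never the
  protected core — is exposed to the T cells outside. Division is skipped
  only when no such path exists.

The tick applies sub-steps in a fixed order: ageing and culling; conjugate
countdown; movement with efflux; membrane degradation; memory recall;
conjugate formation and killing; activation and proliferation; regeneration
triggering and Beta division; influx. Agents act in a freshly randomised
order each tick, all randomness derives from one seeded stream per
replicate, and a given seed and configuration reproduce a run bit for bit.

## Where the rules are the package's own choices

The source description of this model leaves several mechanisms
under-determined, and the package had to commit to specific lattice
semantics. The major commitments, and why:

* **The membrane ring is walkable; it gates contact and entry, not
  transit.** The basement membrane is extracellular matrix: it prevents
  migration *into* the islet and the formation of lytic contacts, but a
  T cell can sit on or beside it. This also gives the attack-trigger rule
  ("a T cell occupies a membrane site") a pre-breach meaning.
* **Engagement arrest with a paused lifespan clock.** With three initial
  T cells, opening a 20160-strength site requires fourteen uninterrupted
  effector-days -- more than twice the effector lifespan. Freely diffusing
  effectors would deliver a few minutes per site and the strong-membrane
  scenarios could never breach. Arrest at the target and engagement-derived
  survival are both well documented in intravital imaging of islet
  infiltration, and they make breach time scale linearly with membrane
  strength, which is exactly the published pattern (half-loss at day ~4,
  ~10 and ~23 for strengths 1440, 10080, 20160).
* **The programmed division burst.** The proliferation ladder the model
  implements (fast cycle, memory branching from generation 8) describes a
  burst that antigen contact commits a cell to. Implementing every division
  as contact-gated starves the response: a killing effector removes its
  target at conjugate formation and is then never "in contact" even though
  it is physically conjugated for 90 minutes. The burst semantics -- one
  encounter, seven autonomous doublings, then contact-dependent
  restimulation -- reproduce both the explosive intra-islet response and
  its collapse once targets are gone.
* **Surface-emergent growth.** Interior Beta cells have no free
  neighbours, so purely local daughter placement would cap effective growth
  far below the nominal rate. Letting the newborn emerge at the nearest
  free site along a straight path restores the nominal compound rate and
  produces islets "grown over their original size", whose exposed regrowth
  is what amplifies the T-cell response when regeneration is on (the
  epitope-spreading analogue: more targets, more contact, more
  proliferation) — while the membrane-protected core is only ever consumed
  through actual breaches.
* **Symmetric division with age reset.** Both division products are new
  cells (generation +1, age 0). A lineage under sustained stimulation
  therefore persists; an abandoned effector dies six days after its last
  division.
* **Uniform tie-breaks.** Target choice under capacity limits, daughter
  placement and displacement directions are uniform draws; no priority
  rules.

Two printed inconsistencies in the source tables are resolved in favour of
the running text: the initial-T-cell-count comparison is simulated with
regeneration at 5%/day (as the text and figure captions state, though the
table caption says otherwise), and the half-loss day is operationalised as
the first day the cross-replicate *median* Beta count reaches 50% of the
median initial count.

## Parameters that matter

| parameter | default | units | note |
|---|---|---|---|
| `membraneStrength` | 20160 | effector-min/site | scenario range 1440--20160 |
| `isletDensityClass` | medium | -- | area fractions low 0.7--3.1%, medium 2.9--5.2%, high 4.2--7.7% |
| `isletDiameterRange` | 100--160 | um | 10--16 sites |
| `nInitialTcells` | 3 | cells | scenarios 3--27, split 2:1 effector:naive |
| `betaRegenRate` | 0.05 | fraction/day | values above 5%/day give runaway growth |
| `killProb` | 0.55 | -- | decided at conjugate formation |
| `conjDuration` | 90 | min | effector immobile, capacity occupied |
| `maxConjugates` | 2 | -- | simultaneous engagements |
| `memoryDiffProb`, `memoryDiffGeneration` | 0.2, 8 | -- | memory branch of the ladder |
| `divisionCycleTime` | 360 | min | the fast-cycle duration is not stated numerically in the source and is exposed for calibration; 360 min makes the weak-membrane scenario reach half loss in ~4 days from 3 cells, as published |
| `influxRate` | 0.017 | fraction/day | of the current resident population |
| `persistenceRange` | 1--4 | min | persistent random walk |

## The synthetic tissue generator

`generateTissue()` draws a target area fraction uniformly inside the density
class range, then places islets one at a time: diameter uniform in
100--160 um, rasterised as the sites whose centres fall within the radius,
rejection-sampled centres, islet-plus-ring kept one site clear of other
islets and of the boundary. Placement stops when the achieved fraction
reaches the target (or, if no further islet fits under the class ceiling,
as soon as the fraction is inside the class range). The generator emulates
islet size and density statistics of pancreatic sections; it does not
attempt anatomical islet shapes, vasculature, ducts or three-dimensional
structure, so passing scenario checks support the model's internal
consistency, not organ-level realism.

## Numerical choices and degenerate inputs

Quantiles use linear interpolation (R type 7), whiskers the 1.5 IQR fences.
The inflammation window is operationalised explicitly since the source read
its windows off box plots: onset is the first day the median Beta count
falls below 95% of the median initial count; the end is the first
subsequent day after which the median moves by less than 1% of the initial
count over the following five days; both thresholds are arguments of
`inflammationWindow()`. Runs freeze once both populations are extinct (the
state can never change again); `stopAtBetaExtinction = TRUE` freezes a run
when the last Beta cell dies, which leaves the Beta series exact and is
used when only Beta metrics are needed. A zero-width density range gives an
empty tissue; a zero-day horizon returns only the initialisation record;
an unattainable density target raises a placement error.

## Validation scaffolding

Deterministic micro-fixtures (`buildFixture()`) pin each rule in a limit
where its outcome is exact: a lone pinned effector opens a strength-S site
at tick S exactly; kill probability 1 destroys an adjacent exposed Beta
cell on the first tick; a single antigen encounter yields a 2^g-cell
lineage after g cycles; a tissue without T cells never changes; isolated
pre-triggered islets grow at the closed-form branching mean
`(1 + rate/1440)^ticks`. Stochastic rules are checked at the literature
values with exact binomial acceptance regions (`statisticalCheck()`,
alpha = 0.01, fixed seeds): the 55% kill fraction over 10^4 independent
conjugates and the 20% memory fraction over 10^4 generation-8 products.
Movement is validated against an independent re-simulation of the
persistent random walk (mean squared displacement at one hour).

Scenario-level checks run scaled-down ensembles (7 replicates in the test
suite, 15 in `scripts/acceptance.R`, against 100 in the source protocol)
with scenario-specific horizons of 20--60 days chosen to cover the expected
crossing comfortably. At this scale the ensemble median half-loss day
carries a few days of sampling noise, which is within the +/-25%-or-4-day
comparison bands for most scenarios; the moderate-membrane no-regeneration
scenario and the strong-membrane regeneration scenario sit within about
two days of their band edges and can fall on either side at desk scale.

## Known limitations

The model excludes dendritic cells, macrophages, CD4+ and regulatory
T cells, explicit antigens, insulin secretion and three-dimensional tissue,
exactly as scoped. The influx base population is the current in-tissue
count, so an attack that dies out is not re-seeded from the lymph node;
with three initial cells a minority of replicates lose all attackers before
first contact and never progress, which is one source of the desk-scale
median noise. Openings admit cells only at the opened site; the membrane
ring does not collapse as a whole. Figure-level reproduction (snapshot
layouts, exact box-plot shapes) is out of scope.
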