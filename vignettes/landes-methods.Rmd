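---
title: "Models and methods in landes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in landes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`landes` quantifies a suite of ecosystem services — timber production and
forest carbon, water purification, canola pollination, and a biodiversity
intactness index — on a single cellular landscape, with human harvest
decisions represented by mill agents. This vignette is the package's own
account of the models, their assumptions, the parameters that matter, and
the design decisions taken where the design was genuinely open. It states
no empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The cellular landscape

The landscape is a uniform grid of square cells (default 800 m → 64 ha, the
quarter-section scale of prairie land administration; the cell size is a
free parameter). Each cell stores the **area in hectares of every landcover
and footprint class** present, partitioned into natural classes (forest,
grassland, shrub, water, and semi-natural tame pasture) and human-footprint
classes (road, trail, forestry cutblock, cropland, industrial, urban). The
taxonomy is configurable; unknown classes are rejected rather than silently
pooled, because a pooled class would silently acquire whatever coefficients
the pool carries.

Two invariants are enforced everywhere (`validate_landscape()`):

1. **Composition closure** — per-cell class areas sum to the cell area
   (relative tolerance `1e-6`). Every operation that moves area (harvest,
   pasture conversion) moves it *between* classes.
2. **Cohort balance** — forest stand cohorts (stand type × ecozone × age ×
   area) in a cell sum to the cell's forest **plus cutblock** area. Harvest
   transfers the harvested area from the forest class into the cutblock
   footprint class while the regenerating age-0 cohort stays in the cohort
   table; the cutblock share of the balance is exactly the regenerating
   area. This keeps closure and footprint accounting consistent at the cost
   of letting "cutblock" double as both a footprint class and a
   regenerating-forest carrier, which is also how the biodiversity model
   wants to see it.

Sub-cell spatial arrangement is discarded by design; what is retained is
the area of small high-leverage features (roads) that per-cell majority
classification would destroy.

## Synthetic landscapes: what they emulate

`generate_synthetic_landscape()` is first-class, tested code, not a test
fixture. It emulates the regional structure of a large west–east watershed:
column-band regions (Mountains 15%, Foothills 20%, Boreal 20%, Parkland
25%, Grassland 20%) with per-region composition archetypes realized as
Dirichlet draws (concentration 60) so cells vary realistically around the
regional mix; elevation falling ~1500→600 m west to east with Gaussian
roughness (sd 15 m) and a slight north–south tilt to break ties;
precipitation falling 900→420 mm; stand ages drawn exponentially with mean
70 years (a fire-cycle analogue, giving roughly a third of stands at or
above the 80-year eligibility age) capped at 200; two FMUs over the
forested west, each with one mill whose AAC is set *sustainably* as the
FMU's volume-at-80 divided by an 80-year rotation; and monitoring points at
the highest-accumulation river cell of each calibration region group plus
the network outlet. Everything derives from one seed: identical seed and
config give a bitwise-identical landscape.

What it does **not** emulate: real GIS fidelity (projections, vector
geometry), spatial autocorrelation beyond the regional gradient, wildfire
and other natural disturbance, and empirically fitted coefficient tables.
Passing tests on synthetic landscapes therefore demonstrate the *structural
properties* of the models (conservation, monotonicity, orderings,
reproducibility), not calibrated predictions for any real region.

## Forest growth, carbon, and harvest

Volume `V(a)` (m³/ha) and carbon `C(a)` (t CO₂e/ha, a single combined
above- and below-ground pool; no dead-organic-matter dynamics and no
wood-product decay) are polynomials in stand age per (stand type ×
ecozone), **clamped at zero and held flat beyond `age_max`**. Fitted
polynomials diverge outside their data range; the plateau is a declared
modelling decision, not a fitted feature. The shipped curves are documented
placeholder fits with the qualitative shape of boreal stand dynamics
(sustained rise, plateau near 140–150 years; montane strata slightly
slower); deployments should load fitted tables via `read_curve_table()`.

Each year every cohort ages by one, then each mill:

1. draws its realized AAC fraction from a normal distribution truncated to
   [0, 1] (inverse-CDF sampling; defaults mean 0.9, sd 0.05 — config, since
   historical harvest-rate distributions are jurisdiction data);
2. ranks harvestable cells by accumulated least transport cost to the mill
   (Dijkstra on the 8-connected grid; a step costs the mean of the two
   cells' road-class rates, ×√2 diagonally; ties break by row then column
   so replays are deterministic);
3. harvests cells in that order until the volume target is met, never
   splitting the final cell — the target may be overshot by at most one
   cell's volume, honoring whole-cell clearcuts;
4. books cash flow `volume × (conversion × price − unit cost − transport
   cost)`, discounted at rate `r` (default 2%) with the first year
   discounted once (t = 1 convention).

Under **variable retention**, a selected cell loses 25%, 50% or 75% of its
volume, chosen uniformly per cell; only intensity changes, never spatial
pattern, which is all an 800 m cell can express. The retained cohort keeps
its age; the harvested fraction regenerates at age 0.

**Green-up rule.** Mills do not re-enter a cell that already carries an
active cutblock (`harvestable_cells()`). Without it a partial-retention
mill would simply return to its cheapest cells year after year — the
retained timber is still eligible and still cheapest — and variable
retention would collapse into a slow-motion clearcut of the same few cells.
No-re-entry (green-up) constraints are standard operational practice, and
with them variable retention exhibits its characteristic signature: the
same volume target spreads across roughly twice as many cells, each less
severely affected, at a lower NPV (the marginal cells are more expensive to
reach). The cost surface is static over the simulation; re-planning as
harvest proceeds is a possible extension.

In the harvest-strategy comparison the carbon baseline is the **no-harvest
counterfactual at the same horizon** (the landscape aged 20 years without
harvest), so the reported carbon delta isolates the harvest impact from
growth; water and biodiversity baselines use the current landscape, whose
composition aging does not change.

## Water purification

The water year is an **annual aggregate**: no storm events, no baseflow, no
groundwater — matching the annual-coefficient formulation of the loading
model. The chain is:

1. **Sink filling** by priority flood with an epsilon gradient (default
   `1e-4` m) imposed on filled flats, so D8 directions resolve everywhere
   and every cell drains to a grid edge. The output DEM is elementwise ≥
   the input; already-drainable surfaces pass through unchanged.
2. **D8 directions**: steepest descent over the 8 neighbors (diagonal
   distance √2·cell); ties break by the fixed E, SE, S, SW, W, NW, N, NE
   order. Flow accumulation counts upstream cells + 1.
3. **River network**: cells with accumulation ≥ a config threshold (default
   1% of the grid, minimum 5 cells — stream-initiation thresholds are a
   free parameter, not a fitted quantity); links follow D8 and form a
   forest.
4. **Loading**: runoff depth = precipitation × area-weighted runoff
   coefficient; `load_s = precip (mm) × Σ_class area (ha) ×
   e(class, s, region)` for N, P, TSS; sediment = RUSLE
   `A = R·K·LS·C·P` with C area-weighted over the cell, R proportional to
   annual precipitation, K and LS per cell.
5. **Overland routing**: each origin's annual runoff parcel follows its D8
   path; at every *transit* cell it loses that cell's area-weighted
   retention fraction per substance (the origin's own load leaves
   unattenuated — a cell does not filter what it itself sheds). Parcels
   that reach the grid edge before any river cell are tallied against an
   implicit edge outlet, reported separately. Water volume is conserved;
   only loads attenuate. The implementation is a single topological pass
   (upstream first, ordered by filled elevation) that is algebraically
   identical to the per-parcel product chain
   `delivered = load × Π (1 − r_i)`, and is tested against that chain and
   against brute-force upstream-set summation oracles.
6. **River accumulation**: no in-stream retention or decay (removal happens
   only overland); each monitoring point reports cumulative annual flow and
   load of everything upstream.

Mass balance — per substance, loading = supplied to river + supplied past
the edge + retained overland — holds to floating-point exactness and is
asserted on every `run_water_year()` result.

**Calibration** selects, independently for each region group ({Mountains},
{Foothills}, {Boreal+Parkland+Grassland pooled — topographically and
geologically similar}), the candidate export-coefficient set minimizing the
**RMSE of cumulative annual loads** over that group's monitoring points.
RMSE is a declared choice (the natural L2 objective for load recovery);
candidate sets come from Latin hypercube designs, which place exactly one
sample in each equal-width stratum of every parameter's range. All shipped
runoff/export/retention values are placeholder magnitudes with the correct
ordering (developed and cropped classes export more and retain less than
intact cover); they are meant to be calibrated.

## Pollination

Bee abundance is Michaelis–Menten in nesting habitat:
`a(h) = a_max · h / (h + h_half)` — zero at zero habitat, monotone,
saturating; the per-hectare yield uplift is proportional to abundance with
ceiling `uplift_max` (0.3 t/ha default against a 1.3 t/ha baseline yield).
The functional form is deliberately pluggable: every shipped behaviour and
test relies only on the zero/monotonicity/saturation properties, because
the empirical field-data fit behind any particular coefficients is not
portable.

**Neighborhood.** Nesting habitat is natural + tame-pasture area over all
cells whose centroids fall within the foraging radius. The default radius
of 750 m is measured **from the field edge**: a field spans its cell, so
the equivalent centroid radius is `radius + cell_size/2` = 1150 m, reaching
the focal cell plus its 8 neighbors at 800 m cells. This matters: with a
pure centroid reading, 750 m < 800 m collapses the neighborhood to the
focal cell and conversion of a neighboring pasture could never affect a
field — severing exactly the spatial coupling the model exists to express.
`nesting_habitat_area()` itself keeps plain centroid semantics
(`radius_basis = "centroid"` restores them throughout); the
half-saturation default (200 ha) is scaled to 3×3-neighborhood habitat
totals.

**Fields.** A *field* is a planting unit: one (cell, rotation-year) parcel
of canola. Converted pasture is assigned its own rotation year and so forms
a new field, distinct from the cell's pre-existing cropland parcel. The
per-field value is total NPV divided by the number of such parcels. Value
is `canola area × uplift(a(h)) × price` (default $461.81/t, the 2010 crop
price), discounted at 2% over the repeating 4-year rotation with the t = 1
convention.

## Biodiversity intactness

A cell's index is `clamp(intercept + Σ coef_c × footprint area_c, 0, 100)`
with intercept 100 (a footprint-free cell is at reference condition) and
non-positive per-class coefficients; `fit_footprint_model()` refits the
coefficients by OLS and errors on rank-deficient designs naming the
collinear classes. There is **no temporal element**: the index is a
point-in-time function of footprint, with no recovery as cutblocks age.
Variable-retention cutblocks contribute footprint proportional to the
harvested fraction — i.e. a partial harvest is treated as a smaller
clearcut. That is a documented bias, not a feature: the residual-structure
mosaic variable retention creates is a distinct condition that a
footprint-area regression cannot see, so index values under variable
retention are conservative (too low) even though the *spatial pattern* of
impact (more cells, less each) is captured.

## Scenario engines

- **Harvest-strategy comparison** runs both modes from the same baseline
  and seed, then evaluates water and biodiversity on the post-harvest
  landscapes (pollination is excluded — commercial forestry and cropping do
  not overlap). Indicators are standardized to the baseline; timber NPV,
  which has no baseline, standardizes to the clearcut run.
- **ES standardization** expresses each landscape's indicator as a
  percentage of the maximum across the compared landscapes. The
  biodiversity index is already a percentage and passes through. Indicators
  scale only against themselves; cross-indicator comparison of scores is
  meaningless by construction.
- **Agricultural-expansion sweep**: at each conversion proportion `p`
  (0–100% in 5% steps), every pasture-holding cell converts independently
  from the *baseline* landscape when its uniform draw < `p`; its whole
  pasture becomes cropland growing canola in one random rotation year.
  Within a replicate the same per-cell draws serve every level (common
  random numbers): converted sets are then nested across levels, which
  reduces between-level variance and makes the replicate-averaged response
  curves clean monotone functions of `p` rather than noisy ones. Each level
  runs the pollination model, one water year, and the biodiversity index
  (timber excluded); stochastic indicators are reported as means with
  standard errors over replicates (default 20).

## Numerical choices and degenerate inputs

- Tolerances: composition closure `1e-6` relative; mass balance asserted at
  `1e-9` relative (achieved at ~`1e-16`).
- Tie-breaks are all deterministic and documented: D8 neighbor order,
  harvest cost ties by (row, col), LHS and all stochastic draws under named
  seed substreams derived from one master seed (`derive_seed()`), so adding
  a module never perturbs another module's stream.
- Degenerate inputs have defined behaviour: zero AAC or zero target → empty
  schedule; empty eligible set → exhausted flag, not an error; river
  threshold above all accumulation → empty network with a warning;
  zero-precipitation year → all-zero water result; constant biodiversity
  response → flagged undefined r²; a cohort-free landscape ages to itself.
- Problem sizes used by the shipped test suite and acceptance script — the
  package's choices for a desk-scale demonstration — are 50×50 (water
  conservation), 30×30 × 20 years (harvest contracts), 18×18 × 20 paired
  seeds (strategy ordering), and 40×40 × 21 levels × 20 replicates
  (expansion sweep).

## Known limitations

No wildfire or natural disturbance; no wood-product carbon release; no
sub-annual hydrology, groundwater, or in-lake chemistry; one mill per FMU
(quota holders are not separate agents); static transport-cost surfaces; no
landowner interdependencies in the conversion model (cells decide
independently); the biodiversity index is a community average unsuitable
for single-species decisions; and all shipped coefficient tables are
placeholders pending calibration against local data.
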