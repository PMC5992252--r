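---
title: "Decomposing the young adult mortality hump: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the young adult mortality hump: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humpdec)
```

## The model and its assumptions

`humpdec` treats the force of mortality between ages 10 and 90 as the sum
of two latent schedules: a *senescence* component that rises monotonically
with age (possibly flattening into a plateau), and a *hump* component, the
transient young-adult excess, whose logarithm is concave — it rises once,
peaks once, and decays. Observed death counts are Poisson with a composed
mean,

$$\mathbf d \sim \mathrm{Poisson}(\mathbf C\boldsymbol\gamma),\qquad
  \mathbf C = [\mathbf E : \mathbf E],\qquad
  \boldsymbol\gamma = [\boldsymbol\gamma_H : \boldsymbol\gamma_S],$$

with $\mathbf E$ the diagonal exposure matrix, and each component an
exponentiated P-spline, $\gamma_j = \exp(\mathbf B\beta_j)$. The grid is
truncated below at the age of minimum mortality (near 10): ontogenescent
mortality is excluded by design, and the open-ended old-age behaviour is
handled by the nonparametric senescence curve rather than a parametric
law.

The assumptions that carry interpretive weight are: (1) additivity — every
death is attributed to exactly one of the two processes, with no
interaction; (2) shape — senescence never falls with age, and the hump is
a single log-concave bump; (3) smoothness — both components vary smoothly
on the log scale. Nothing is assumed about individual risk trajectories.

## Identification: why shape constraints are not enough

The likelihood only constrains the *sum* $\gamma_H + \gamma_S$. Any
monotone, log-concave curve can be moved from one component to the other
without changing the fit, as long as both components stay in their cones —
for instance the hump can absorb a slowly rising share of senescence. The
shape constraints make the components non-interchangeable but leave this
flat direction open, and a fit driven only by them drifts to whichever
split happens to be smoothest.

The package closes the gap with three devices, applied in this order of
importance:

1. **Asymmetric smoothing.** The senescence component is offered a much
   heavier smoothing grid (`lambda_grid_S = 10^(4:8)` against
   `lambda_grid_H = 10^(2:6)`). Under heavy second-order smoothing the
   log-senescence curve is pushed towards a straight Gompertz line unless
   the data demand otherwise, which operationalizes "the prevailing
   senescent trend" as the reference from which excess is measured.
2. **A third-order hump penalty.** The hump's difference penalty has
   order 3 (`order = c(3, 2)`), so heavy smoothing shrinks the log-hump
   towards a quadratic — a Gaussian-shaped bump — rather than towards a
   line. This is the natural null shape for a single excess episode and
   keeps strong smoothing from flattening the hump into an exponential.
3. **Minimal hump mass.** A small linear penalty,
   `hump_mass * sum(e * gamma_H)` with `hump_mass = 1e-3` per expected
   death, prefers the decomposition with the *smallest* hump among
   likelihood-equivalent splits: the hump is the minimal excess over a
   maximal admissible background. The penalty is orders of magnitude
   below the likelihood curvature wherever the data identify the hump
   (relative bias about $\kappa\mu/(e\gamma_H)$, i.e. $10^{-8}$ at
   national exposures), and only acts as a tie-break.

## Tunable parameters

| Parameter | Default | Units / role |
|---|---|---|
| `knot_spacing` | 2 | years between B-spline knots (43 cubic basis functions on 10–90) |
| `degree` | 3 | spline degree |
| `order` | `c(3, 2)` | difference-penalty order (hump, senescence) |
| `lambda_grid_H`, `lambda_grid_S` | `10^(2:6)`, `10^(4:8)` | BIC candidates per component |
| `shape_weight` | `1e6` | starting weight of the asymmetric shape penalties; escalated ×100 up to `1e12` until coefficient-level violations fall below `1e-9` |
| `hump_mass` | `1e-3` | tie-break penalty per expected hump death |
| `constraint_weight` | `1e5` | regression weight of the sum-constraint rows in the cause-deleted system |
| `tol`, `max_iter` | `1e-6`, 200 | IRLS relative coefficient-change tolerance and cap |

Smoothing weights are chosen by `BIC = deviance + log(m)·ed` over the
two-dimensional grid, with deterministic ties broken towards heavier
smoothing. On noiseless validation fixtures BIC degenerates (the deviance
is near zero at any smoothing), so the package's reference setting for
such fits is the fixed pair `lambdas = c(1e3, 1e7)`: light enough to
follow an exact hump, heavy enough on senescence to keep the split
identified.

## The constrained cause decomposition

For $K\ge 2$ selected causes the cause-deleted count vectors
$\mathbf d^{-\kappa}$ are refit jointly, subject to
$\hat{\mathbf d}_H = \mathbf e\sum_\kappa\delta_H^\kappa$ and
$\hat{\mathbf d}_S - \mathbf d^{\mathrm{nonhump}} =
 \mathbf e\sum_\kappa\delta_S^\kappa$, where
$\delta_j^\kappa = \hat\gamma_j - \gamma_j^{-\kappa}$. Rewriting the
constraints in the unknowns turns their responses into
$(K-1)\hat{\mathbf d}_H$ and
$(K-1)\hat{\mathbf d}_S + \mathbf d^{\mathrm{nonhump}}$, stacked under
the data rows with regression weight $10^5$; the whole system is one
composite link model whose composition matrix repeats $\mathbf E$
block-diagonally (data rows) and in block rows (constraint rows). The
sums then match the all-cause components with relative $L_2$ residuals
around $10^{-5}$ — well inside the $10^{-3}$ the soft weights guarantee.

Two deliberate choices: smoothing weights are *inherited* from the
all-cause fit, so component differences reflect cause removal and not
smoothing changes; and the non-selected causes' deaths entering the
senescence constraint are first replaced by their own P-spline smooth.
The constraint equates expectations, and feeding it raw Poisson noise at
weight $10^5$ makes the heavily smoothed cause-deleted senescence curves
chase unfittable wiggles (visible as misallocated hump shares on noisy
input). With noiseless input the smoothing is a near-no-op. A single
selected cause ($K = 1$) has no sum to constrain; `decompose_hump()` then
simply refits the cause-deleted data and takes the component difference.

Contributions are reported as computed: small negative $\delta$ values
are kept, not clipped, and surface in `glance()`.

## Screening hump-candidate causes

`shape_distance()` compares, per year, the first difference over age of
each cause's force of mortality with a reference profile inside the
window 10–34; `pca_flag()` reduces the cause-by-year distances to two
principal components (year columns standardized across causes) and flags
a candidate set.

The default reference is the all-cause profile. It behaves well when the
typology is wide,
because every cause is small against the total and hump contributors
stand out by tracking the aggregate hump dynamics. With only a handful of
broad causes it breaks down structurally: the total is dominated by the
largest hump causes, so a cause with a *small* hump is as far from the
total's profile as a humpless one (on the packaged four-cause example the
small-hump cause A and the Gompertz cause D are numerically
indistinguishable under this distance). For such settings
`reference = "senescent"` measures the distance to the difference profile
of a log-linear trend fitted to the all-cause schedule, and
`normalize = TRUE` compares unit-length profiles: *any* rise-and-fall
shape then scores high regardless of its share, and the screen separates
the hump causes cleanly. The flagging rule is a deterministic 2-means
split of the PC plane oriented by the reference (`"similarity"`), with a
plain `k`×median-norm outlier rule as an alternative for wide typologies.
Either way the scores are exported: the screen shortlists, the analyst
decides.

Practical note: the statistic works on year-by-year differences of rates,
so it needs exposures large enough for those differences to be signal
rather than noise — at $10^5$ person-years per age every cause's profile
is noise-dominated and no screen can work; the packaged screening fixture
uses $2\times 10^6$, the scale of a large national population.

## Graduation, life tables, and life expectancy lost

Abridged counts are graduated with the same composite link machinery:
expected group counts are $\mathbf G(\mathbf e\exp(\mathbf B\beta))$ with
$\mathbf G$ the age-grouping matrix, so observed group totals are
preserved in expectation instead of being interpolated away; the
smoothing weight is chosen per cause by BIC. `rescale_to_total()` then
applies the per-age multiplicative factor that makes cause-specific rates
sum exactly to a given all-cause schedule.

Life tables use radix 1, $a_x = 0.5$ (no infant correction is needed at
ages 10+), $q_x = m_x/(1+(1-a_x)m_x)$, and an open last interval with
exponential closure $L = l/m$. Life expectancy lost (LEL) to a deletion
is $e^{\mathrm{cf}} - e^{\mathrm{obs}}$ at the base age — by default the
lower bound of the fitted grid (age 10), since no schedule below 10 is
modelled; supplying a full schedule and `base_age = 0` gives LEL at
birth. Three deletions are compared: the hump only (`L1`, rates
$\mu - \sum_\kappa\delta_H^\kappa$), all deaths in the window (`L2`), and
the selected causes' deaths in the window (`L3` — by construction
$\le$ `L2`). Age contributions use the symmetrical Arriaga decomposition
(the average of the two directions), which conserves exactly and is
antisymmetric under swapping the tables. Cause shares of `L1` rescale the
per-cause Arriaga totals so interactions are spread proportionally and
shares sum to one; `L2`/`L3` shares prorate each age's contribution by
the cause's share of the deleted rate at that age.

## The synthetic example

`toy_params()` defines four causes on ages 10–90, each a log-Gaussian
bump plus a logistic-ramp plateau plus a Gompertz trend. The defaults
reproduce, as testable orderings: C is the leading cause at ages 13–20
(early narrow hump over a Gompertz trend), B's hump is higher and wider
than A's with a stable plateau after 40, D is pure Gompertz, leads from
the late twenties on, and lies above A everywhere; the total schedule
shows exactly one hump episode (its log-curvature changes sign twice
between 10 and 50). `sample_deaths()` draws independent Poisson counts
(or returns expectations with `noiseless = TRUE`);
`simulate_toy_surface()` adds smooth, phase-shifted period trends to the
hump heights so the screening step has year-to-year structure to
summarize.

What the generator does *not* emulate — and what passing tests therefore
do not certify for real data: coding discontinuities across ICD
revisions, cohort effects (the generator is a pure period model),
overdispersion and late-registration artefacts, migration-driven
exposure error, abridged-age observation (the toy is generated at single
ages), and humps that are genuinely bimodal or shared across more causes
than the typology separates.

## Numerical choices

The solver is one penalized IRLS routine shared by every fit: linearize
the composed mean through $\mathbf U = \mathbf C\,\mathrm{diag}(\gamma)\mathbf X$,
solve the penalized weighted normal equations, and step-halve against the
penalized log-likelihood so accepted iterations never decrease it beyond
floating-point resolution at its magnitude. Near convergence the Fisher
step is replaced by an observed-information Newton step (with fallback),
which restores fast convergence in the weakly curved directions where
Fisher scoring only crawls. Shape constraints are active-set asymmetric
penalties re-derived each iteration; their weight escalates from $10^6$
by factors of 100 (capped at $10^{12}$) until residual coefficient
violations drop below $10^{-9}$, which leaves curve-level violations
comfortably under $10^{-8}$ relative. Log-rates are capped at 40 against
overflow; a ridge of $10^{-6}$ stabilizes the normal equations; means are
floored at $10^{-10}$ inside weights.

Initialization is deterministic: senescence starts from a log-linear fit
to ages 55–90 extrapolated over the grid; the hump starts from a
penalized smooth of the log residual $\max(\mathrm{rate} - \gamma_S^0,
10^{-12})$; cause-deleted fits start from an equal split of the
constrained sums. Degenerate inputs are handled explicitly: all-zero
causes graduate to floor rates ($10^{-12}$) with a warning, zero rates
give $q = 0$ with a zero-person-year closure, and a zero closing rate
sets the open-interval person-years to zero so an immortal schedule
returns the age span exactly.

Validation problem sizes: 81 single ages, exposures $10^5$–$10^7$
person-years per age, up to eight causes, 20-year surfaces, and a
50-fixture randomized suite for the shape invariants; the brute-force
equivalence check runs at 5 ages × 2 causes with a degree-0 basis, where
the augmented IRLS solution matches an independently written exact-Newton
maximizer to ~$10^{-11}$ relative.

## Known limitations

* Pointwise recovery of a component where it is a small fraction of the
  total is noise-limited: at $10^5$ person-years per age, the hump's
  mask-edge values carry ~10% relative sampling error even for an oracle
  parametric fit, and the age-10 boundary amplifies draws. Expect
  reliable curves at national exposures, shares and LEL summaries
  (which integrate over age) much sooner.
* The sum constraints are soft (weight $10^5$): conservation holds to
  ~$10^{-5}$ relative in practice, $10^{-3}$ guaranteed — not to machine
  precision.
* The hump/senescence split inside the overlap region is identified by
  the smoothing asymmetry and the minimal-mass convention, not by the
  likelihood; a background that genuinely bends (e.g. an early plateau)
  can exchange a few percent of mass with the hump tail.
* The screen is descriptive. Its flag set depends on the reference and
  rule (documented above) and is meant to be reviewed, amended, and only
  then fed to the decomposition.
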