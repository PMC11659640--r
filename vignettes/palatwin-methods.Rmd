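---
title: "Palatal morphometrics and twin variance-component models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Palatal morphometrics and twin variance-component models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palatwin)
```

palatwin does two things: it measures palatal morphology from digital
maxillary dental cast meshes plus anatomical landmarks, and it estimates how
much of the variation in those measurements is genetic versus environmental
using the classical monozygotic/dizygotic (MZ/DZ) twin design. This vignette
explains the models, the geometric constructions, the numerical choices, and
what the synthetic-data generators do and do not emulate.

## Landmarks and reference planes

Each cast carries named landmarks: the midpoint of the dento-gingival
junction on the palatal side of every tooth (`dg_<FDI code>`), three
mid-palatal raphe points (`raphe_anterior` — the incisive papilla,
`raphe_middle`, `raphe_posterior`), and the most distal palatal points of the
terminal teeth (`distal_<FDI code>`). Tooth sets depend on dentition stage:
deciduous codes (51–55/61–65) in the primary dentition, deciduous canines and
molars alongside permanent incisors and first molars in the mixed dentition,
and 11–16/21–26 in the permanent dentition.

Three reference planes are derived purely from landmarks, never from mesh
axes, because casts are scanned in arbitrary orientation:

- **Gingival plane** — the total-least-squares plane through all
  dento-gingival midpoints (the singular vector of least variance), oriented
  so that the vault side (containing `raphe_middle`) is interior.
- **Mid-palatal plane** — the plane containing the least-squares line
  through the three raphe points projected onto the gingival plane,
  constructed orthogonal to the gingival plane by taking its normal as the
  cross product of the projected raphe direction and the gingival normal.
  Orthogonality therefore holds by construction (asserted at 1e-9).
- **Posterior plane** — the transverse plane through the midpoint of the two
  distal landmarks, orthogonal to both planes above, oriented so the
  anterior side is interior.

Plane orientation never relies on anatomical axis conventions: a
deterministic sign rule (largest-magnitude normal component positive) is
refined by the requirement that raphe landmarks sit on the negative side of
clipping planes.

## Missing landmarks

Missing landmarks are data, not errors. A missing bilateral landmark is
imputed by mirroring the configuration across the current mid-sagittal
estimate, relabelling every landmark as its antimere (FDI quadrant 1↔2,
5↔6), rigidly superimposing the mirrored copy onto the original over all
shared landmarks (rotation + translation via the Kabsch solution — no
scaling), and reading the missing coordinate off the superimposed copy. On a
perfectly symmetric cast this reduces to the exact mirror image; on
asymmetric casts the superimposition absorbs the global component of the
asymmetry. One completion pass is performed (missingness is sparse by
contract: never both members of an antimere pair), and imputed landmarks are
flagged.

## The seven measurements

Widths are Euclidean distances between dento-gingival midpoints (canines for
anterior, terminal molars for posterior width). The antero-posterior length
is the perpendicular distance from the incisive papilla to the posterior
plane.

**Depths** need an operational definition of "the deepest point of the vault
at a dental station". palatwin sections the mesh with the transverse plane
containing the reference dento-gingival line and the gingival normal
(edge–plane interpolation, so the section is tessellation-independent up to
surface curvature), keeps section points within `eps` of the mid-palatal
plane (default 0.5 mm — the raphe region) and on the vault side of the
gingival plane, and takes the maximum perpendicular distance to the
reference line. Restricting candidates to the station's own cross-section is
essential: a global search over the whole raphe would always find the
posterior vault (the deepest part of any palate) and make the anterior depth
meaningless. For section points the perpendicular distance to the line has
no along-line component, so a flat palate measures exactly zero.

**Area and volume** use plane clipping. Triangles entirely inside the
intersection of the two interior half-spaces are kept, straddling triangles
are split at the plane (on-plane vertices within 1e-7 mm count as interior,
avoiding sliver triangles; intersection points are computed once per
canonically ordered edge so the cut boundary stays exactly closed). Area is
the triangle-area sum of the clipped vault surface only — the palatal
surface, not a closed solid. Volume closes the surface with planar caps and
applies the divergence theorem; the caps are built by fanning every open
boundary edge from one apex point chosen on the intersection line of the two
clipping planes (or on the single plane carrying the boundary), which keeps
each cap planar for arbitrarily shaped, even non-convex, boundary loops.
Boundary vertices on neither plane (tolerance 1e-5 mm) indicate a
non-closable surface and raise an error rather than a silent bias.

## The classical twin model

For a trait with path coefficients a (additive genetic), c (shared
environment), d (dominance) and e (non-shared environment), the implied
covariance of a twin pair is compound symmetric with total variance
$V = a^2+c^2+d^2+e^2$ and within-pair correlations

$$r_{MZ} = \frac{a^2+c^2+d^2}{V}, \qquad
  r_{DZ} = \frac{a^2/2 + c^2 + d^2/4}{V},$$

reflecting latent correlations of 1 (MZ) and 1/2 (DZ) for additive effects,
1 and 1/4 for dominance, and 1 for the shared environment in both
zygosities. C and D are not simultaneously identifiable in twins reared
together, so the candidate set is {ACE, ADE, AE, CE, E}. The DE model is
excluded from the default ladder — dominance without additive variance is
biologically implausible — but can be fitted directly with
`fit_twin_model()`. Assumptions inherited from the design: random mating,
equal shared environments across zygosity, no gene–environment interaction
or covariation.

### Fitting

The model likelihood factorizes as $V \cdot R_z(\text{proportions})$, so
given the standardized proportions the grand mean has a closed-form
generalized-least-squares solution and $V$ a closed-form variance solution.
palatwin therefore concentrates the likelihood and numerically optimizes
only the 0–2 free proportions: one bounded 1-D optimization for AE/CE, and a
box-constrained quasi-Newton search over (total familial proportion,
additive share) from three fixed deterministic starts — a method-of-moments
start from the sample pair correlations plus two spread starts — followed by
exact evaluation of the boundary candidates for ACE/ADE. This is the same
optimum as optimizing raw path coefficients with a squared-path
non-negativity parameterization, but it handles boundary solutions (a
component estimated at exactly 0) exactly and makes each fit cheap enough
for the replicate-level checks below. A single grand mean is shared across
zygosities and twins; all likelihood quantities depend on the data only
through within-pair-symmetric sufficient statistics, so the fit is exactly
invariant to twin ordering.

Because everything is deterministic (no random restarts), the same data
always give the same fit.

### Model selection, tests and intervals

Nested models are compared by chi-squared likelihood-ratio tests: a simpler
model survives unless dropping to it loses fit at $\alpha = 0.05$ against
every fitted full model (ACE and/or ADE) containing it. Among survivors the
fewest-parameter model wins, with AIC ($-2\ln L + 2k$) breaking ties and
arbitrating non-nested pairs such as AE vs CE. The naive $\chi^2$ reference
is used by default even though variance components on the boundary make it
conservative; the 50:50 boundary-mixture reference is available via a flag
on `twin_lrt()`. The full decision trace (every comparison, Δ, df, p, AIC)
is retained.

95% confidence intervals on standardized components are profile-likelihood
intervals: each bound is where the profiled $-2\ln L$ (re-optimizing all
other parameters, with mean and variance profiled in closed form) rises
3.841 above the minimum, clamped to [0, 1]. Profiling matches the asymmetric
intervals typical of published twin tables near boundaries. Narrow-sense
heritability is $h^2 = a^2/V$ — dominance, when present, contributes to the
denominator only.

## Reliability and descriptive statistics

Within-pair resemblance and test–retest reliability use the one-way
random-effects intraclass correlation, $(MS_B - MS_W)/(MS_B + MS_W)$ —
twin pairs have no rater structure, so the one-way form is the standard
choice. Duplicate-measurement error reports both the Dahlberg estimator
$\sqrt{\sum d_i^2 / 2n}$ (which folds systematic session offsets into the
error) and the mean-corrected method-of-moments estimator
$\sqrt{\sum (d_i-\bar d)^2 / 2(n-1)}$ (which removes them); reporting both
makes the random/systematic split explicit, and they satisfy the identity
$\text{Dahlberg}^2 = \text{MME}^2 (n-1)/n + \bar d^2/2$.

Group comparisons use Welch's t-test by default (a flag restores the
pooled-variance Student test) with a Bonferroni threshold `alpha / m`, `m`
defaulting to the number of traits. Twin observations are clustered within
families, so individual-level comparisons within the cohort are flagged as
such; the random-intercept mixed model (`fit_twin_lmm()`, maximum
likelihood via lme4 with family as the random effect) is the principled way
to test fixed effects of zygosity, sex and stage.

## Synthetic data: what it emulates

`simulate_twin_pairs()` draws trait values directly from the bivariate
normal implied by chosen standardized components — the classical twin model
constrains only these second moments, so simulating at the phenotype level
exactly matches the fitted model's assumptions. `simulate_cohort()` builds a
three-stage longitudinal cohort whose default generating configuration is
the published reference summary of a longitudinal palatal twin study
(`palatal_reference_means()`, `palatal_reference_components()`): per-stage
trait means and SDs, ACE components for area and volume in the primary
dentition, AE elsewhere, and per-stage MZ/DZ pair counts of 104/124, 106/119
and 77/93 (456, 450 and 340 records). Attrition is completely at random;
family rosters are nested when counts shrink and topped up with new
recruits when they grow. Stage-to-stage within-person correlation is *not*
modelled — the per-stage univariate analyses never use it — so the cohort
is not suitable for longitudinal (Cholesky-type) modelling.

`generate_palate()` builds a vault as superellipse cross-sections (default
exponent 2.5) lofted along the raphe, with monotone (Hyman-filtered spline)
half-width and depth profiles interpolating the requested dimensions at the
canine and terminal-molar stations, a gingival skirt and posterior margin
extending 2 mm past the clipping planes so clipping is genuinely exercised,
and landmarks placed analytically (widths and depths are exact by
construction). Its default dimensions are the published primary-dentition
means (22.1/27.4 mm widths, 4.6/10.6 mm depths, 25.3 mm length). The
enclosed volume of the lofted solid has a quadrature closed form
(cross-section area $c_k\,w(y)\,d(y)$ integrated along the raphe) used as a
mesh-independent oracle; the surface area has no closed form and is checked
by refinement convergence and against analytic shapes (hemisphere,
half-ellipsoid) instead. Asymmetry is emulated as a coherent rotation of
the right-side landmarks about the raphe axis — the kind of global
asymmetry a real cast shows — not as independent landmark noise.

What passing tests therefore do **not** show about real data: the generator
has no rugae, no tooth impressions, no scanning noise or holes, and its
vault is a smooth graph surface; real casts may need the `eps` band or
clipping tolerances adjusted, and real landmark error is not modelled.

## Problem sizes and numerical checks

The test suite and acceptance computations use: 500 replicate cohorts of
104 + 124 pairs for AE/ACE parameter recovery (tolerances ±0.01 and ±0.03 —
the ACE profile is flat in the A/C split, hence the wider band); 500
replicates for the boundary-null likelihood-ratio calibration; 300
replicates at 77 + 93 pairs for profile-interval coverage (accepted range
90–98%, reflecting boundary conservatism); spheres/ellipsoids at ~90×180
tessellation for 1% agreement with closed-form areas and volumes; and
0.5 mm target edge length for generated palates, where measured widths,
depths and length agree with ground truth to well under 0.1 mm. These sizes
were chosen as the smallest that make the Monte-Carlo error visibly smaller
than each tolerance.

Known limitations: no REML option for the mixed model; no sex-limitation,
gene–environment interaction, or multivariate/longitudinal twin models; no
ascertainment correction; area excludes the cap polygons by definition (the
palatal surface), so it is not comparable to closed-solid surface areas;
and the E-only model has no free component, so no profile interval is
reported for it.
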