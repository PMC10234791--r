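---
title: "Methods: landmark-based dimorphism scoring and the paternal-involvement cue analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark-based dimorphism scoring and the paternal-involvement cue analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facecue)
```

`facecue` tests whether male facial masculinity is used as a cue to paternal
involvement, and whether that cue is accurate. This vignette describes the
model and procedure each module implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices, and the package's known limitations.

## 1. The shape model: GPA and the vector method

A face is an ordered configuration of 2D landmarks in image pixels (point
order is semantic: landmark *k* corresponds across faces). `gpa()` performs
Generalized Procrustes Analysis: every configuration is centred, scaled to
unit centroid size, and rotated to the running consensus; the consensus
(coordinate-wise mean shape) is recomputed until it changes by less than a
tolerance. Three choices matter:

- **Partial Procrustes, no reflections.** Only rotations are allowed when
  superimposing. Faces have handedness; permitting reflections would let a
  mirrored delineation masquerade as shape change.
- **Joint alignment.** Reference faces (both sexes) and target faces enter
  *one* GPA, so means and projections live in a single shape space. Aligning
  targets to a frozen reference consensus is a defensible alternative; joint
  alignment is the common geometric-morphometrics workflow and is what
  `analyse_study()` does.
- **Convergence.** Tolerance `1e-10` on the Frobenius norm of the consensus
  update, at most 100 sweeps. GPA on facial data converges in a handful of
  iterations; non-convergence raises an error with diagnostics rather than
  returning a half-aligned sample.

`dimorphism_axis()` takes the aligned female and male reference mean shapes
m_F and m_M and forms the axis v = m_M − m_F in flattened shape space
(all x coordinates, then all y). `score_faces()` projects each aligned face:

$$ s_i = \frac{(x_i - m_F) \cdot v}{\lVert v \rVert^2} $$

so s(m_F) = 0, s(m_M) = 1, and higher scores are more male-like. The spec of
the original procedure says only that faces are "projected" onto the vector
and that scores are "scaled"; we fix the affine-position normalisation above
(any monotone variant gives identical standardized regression results) and
define the scaled score as the z-score of s across the target sample, which
matches the standardized coefficients reported downstream.

**Not implemented, by design:** projection to tangent space and sliding
semilandmarks. At facial-shape variation scales the linear projection on
superimposed coordinates is an excellent approximation, but this is a
limitation to keep in mind for samples with extreme shape variation.

## 2. Ratings and self-report scales

Ratings arrive as one record per (rater, face, trait) with a 1–10 value;
each rater judges a single trait. `filter_raters()` drops all records of
raters scoring below 5 on the 7-point seriousness scale (threshold
tunable). `aggregate_trait()` computes per-face arithmetic means, optionally
restricted to male or female raters; raters of other/unknown sex count
toward the overall mean but neither sex subgroup. No reliability statistic
is computed — the design instead targets a minimum of 30 ratings per face
and trait, which `coverage_check()` audits.

Self-report instruments are scored as item means on the common 1–5 range:
the 9-item nurturant-fathering scale (no "not applicable" option; an NA
there is an error) and the two 20-domain father-involvement subscales
(reported and desired involvement; "not applicable" items are dropped from
the mean, and an all-NA subscale propagates as missing into the
complete-case analysis). Scoring by means rather than sums keeps the three
instruments comparable and leaves standardized analyses unchanged.
Non-fathers answer imagining an 8-year-old child; father status is carried
as a subset flag, never a scoring change.

`apply_participant_exclusions()` removes participants in a fixed order: no
usable photo, seriousness below 5, language issues, duplicate enrolment. A
duplicate enrolment is one participant with two roster records, and the
duplicate step removes both; the report counts records and participants
separately, so record counts always sum to (input − kept). With the
emulated study's funnel — a 312-record roster carrying 28/21/2/1 injected
flags — exactly 259 participants remain.

## 3. The statistical engine

- **Winsorisation** (`winsorize`): values beyond mean ± k·SD (default k = 3)
  are set to the threshold, using the mean and SD of the *original* vector —
  one pass, no re-estimation after clipping, which is the natural reading of
  "winsorised to ±3 SDs from the mean". A zero-SD vector is returned
  unchanged; missing values pass through.
- **Standardized regression** (`standardized_ols`): outcome and predictors
  are z-scored on the complete cases of each model, then ordinary least
  squares; reported per predictor are the standardized beta, t, residual df
  = n − p − 1, and the two-sided p. With a single predictor the beta equals
  the Pearson r. Missingness is handled listwise per regression and pairwise
  for correlation tables.
- **JZS Bayes factors** (`jzs_bf`): "uninformative priors" is
  operationalised as the default Zellner–Siow setup — a Cauchy prior with
  scale √2/2 (tunable) on standardized slopes, equivalently a g-prior with
  g ~ InverseGamma(1/2, n·r²/2). The Bayes factor of a model with p
  predictors and fit R² against the intercept-only null is the
  one-dimensional integral over g given in `R/bayes.R`; the effect-level
  (inclusion) Bayes factor is the ratio full-model BF / reduced-model BF on
  identical cases, so bf10 > 1 favours keeping the focal predictor.
- **Power analysis** (`required_n`): smallest N at which a noncentral-F test
  (df1 numerator df, N − p − 1 denominator df, noncentrality f²·N) reaches
  the target power, found by iterating N upward. Defaults α = .05, df1 = 1,
  p = 2 predictors: conventions the original sample-size statement omits.
  For the pre-registered small effect f² = 0.027 at 80% power the answer is
  293, and it is insensitive to p between 1 and 3.

### Numerical choices

The Bayes-factor integrand is evaluated on the log-g scale, shifted by its
mode (found with `optimize`) before exponentiation, and integrated
adaptively over (−∞, ∞) at `rel.tol = 1e-10`; `(1+g)` terms use a stable
log1p-of-exp form so extreme tails cannot overflow. The test suite holds
this implementation to within 0.1% of an independent 10⁶-node fixed-grid
quadrature. Rotation estimation uses the closed-form 2×2 SVD solution with
the determinant sign forced positive; ties (e.g., a 180° ambiguity in a
perfectly symmetric configuration) are resolved by the SVD convention and
never arise for face-like data. Degenerate inputs — zero centroid size,
coincident sex means, zero-variance outcomes, rank-deficient designs —
raise typed errors instead of propagating NaN.

## 4. The analysis grid

`run_analysis()` crosses two focal predictors (objective dimorphism,
perceived masculinity) with two samples (full, fathers-only) over four
outcomes (NFS, FIS-involved, FIS-desired, perceived paternal involvement),
each model optionally including attractiveness as covariate (the robustness
variant omits it; another recomputes rating means from male or female raters
only). Winsorisation is applied within each analysis sample, and that choice
— rather than winsorising once before subsetting — is recorded in the run
log, since the original description does not fix it. The run log also
captures every exclusion, the per-model n (always the complete-case count),
winsorised-value counts per variable, and all settings; no timestamps are
logged, so identical inputs yield byte-identical outputs. Significance
stars use the conventional .05/.01/.001 ladder.

## 5. What the generator emulates — and what it does not

`simulate_study()` produces a full synthetic study under one seed:

- **Faces.** A deterministic, stylised 131-landmark template (three
  elliptical rings with a mild asymmetric wobble — no claim of anatomical
  realism, only a non-degenerate configuration); a hidden dimorphism
  direction drawn orthogonal to the similarity-group tangent so the injected
  signal is pure shape change; female and male reference means at positions
  0 and 1 along it; reference faces (49 + 53) and participant faces (259,
  drawn around the male mean with SD 0.5) with isotropic landmark noise
  (default 6 px, about 9% of the axis length — delineation-scale error well
  below the 25% at which recovery degrades); and a random similarity
  transform per face so Procrustes invariance is genuinely exercised.
- **Judgements.** Latent attractiveness and perceived masculinity correlate
  0.16 and 0.28 with the true dimorphism position (matching the observed
  facial-metric correlation structure); latent perceived involvement is the
  configured linear function of dimorphism and attractiveness. A pool of
  422 raters (140/240/42 male/female/other), each assigned one trait and a
  random face subset targeting ≈ 33.55 ratings per face per trait, maps
  latents to 1–10 integers through a per-rater bias (SD 0.5), residual noise
  (SD 1.5), and rounding; about 1% of raters are flagged low-seriousness.
- **Self-reports.** Latent scale outcomes carry residual correlations 0.6
  (NFS–FIS-involved) and 0.1 (elsewhere) — the observed structure in which
  reported and desired involvement are nearly separate constructs — plus
  the configured true effects; items are discretised to 1–5 with noise, and
  FIS items go missing ("not applicable") at rate 0.08. The roster wraps
  the 259 kept participants with the exact exclusion funnel above.

Default true effects are zero for dimorphism on everything and negative for
attractiveness: −0.44 on perceived involvement and −0.13 on desired
involvement, the configuration matching the emulated study's findings.
`gen_analysis_data()` is the *measurement-level arm* of the same generative
model: it simulates the dimorphism score (true position plus the projection
of landmark noise on the axis), rating means over a fixed number of
discretised ratings, and scored scales directly, without constructing
landmark files or individual raters. The calibration experiments use it
because they need thousands of replicate studies: the type-I-error check
(2,000 replicates at n = 259) and the effect-recovery check (200
replicates) in the acceptance tests, which would be needlessly slow through
full landmark synthesis, while the landmark → score path is validated
separately (noiseless recovery, similarity invariance at 131 landmarks,
recovery correlation > 0.9 with default noise).

What the generator does **not** emulate: photographic standardisation
artefacts (head angle, lighting, hairstyle) that contaminate real
dimorphism scores and rating judgements; rater-specific taste beyond an
additive bias; non-linear latent-trait relations; and systematic
missing-data mechanisms. Passing tests therefore demonstrate that the
pipeline recovers truth *under the analysis model's own assumptions* —
linear effects, additive Gaussian noise — not that those assumptions hold
for real photographs.

A note on the recovered attractiveness effect: with measurement noise on
both the predictor (rating means over ~34 ratings) and the outcome, the
expected estimated standardized beta is mildly attenuated relative to the
latent −0.44 (to about −0.42 at the default noise levels); the recovery
check's ±0.10 band sits around the latent value and comfortably absorbs
this.

## 6. Replication mode

`replicate_from_csv()` re-runs the identical analysis grid on an external
participant-level CSV (scores and rating means already computed), validating
the column contract and labelling the run log as replication mode. The
package performs no network access; obtaining any real deposit is the
user's responsibility.

## 7. Known limitations

- No tangent-space projection, semilandmark sliding, or allometry
  correction; no 3D landmarks; no image processing or composite rendering.
- The dimorphism score inherits whatever non-shape covariation the inputs
  carry (e.g., head angle); no correction is attempted because none is
  defined in the emulated procedure.
- Plain means aggregate ratings — no mixed-effects rater modelling — so
  rater-pool composition shifts the scores' scale, though not the
  standardized analyses.
- No multiple-testing correction across the model grid, mirroring the
  emulated analysis; interpret the 16-model effect table accordingly.
- The power computation treats the focal coefficient as a single
  noncentral-F df1 = 1 test; other conventions (e.g., testing the full
  model R²) give different Ns and are available via `df1`/`n_predictors`.

## 8. Problem sizes used in validation

The packaged experiments run at the emulated study's scale where the claim
depends on it (n = 259 datasets for calibration and recovery; 131-landmark
faces with the 49 + 53 reference design for score recovery) and at reduced
scale where only correctness of the algebra is at stake (25-landmark,
40-participant studies for pipeline plumbing; 50-face, 131-landmark samples
across 100 random similarity transforms for the invariance suite). These
sizes are the package's validation design, chosen to make every check a
few seconds to a few tens of seconds.
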