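---
title: "Quantifying parallelism of community change with change-vector analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying parallelism of community change with change-vector analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(changevec)
```

## The question and the model

When several host populations independently adapt to similar ecological
niches (benthic vs limnetic fish ecotypes, herbivores vs carnivores, and
so on), do their associated microbial communities change in similar ways?
"Similar" has two components: *direction* and *magnitude* of community
change. Change-vector analysis (in the morphometrics literature,
phenotypic change vector analysis) answers both quantitatively instead of
scoring parallelism as a yes/no PERMANOVA outcome.

The procedure:

1. Summarize all samples of one study system in **one shared ordination**.
   By default this is a principal coordinates analysis (PCoA) of
   Bray–Curtis dissimilarities between samples, but any precomputed
   distance matrix (e.g. weighted/unweighted UniFrac exported from another
   toolchain) or any externally computed sample scores (e.g. NMDS) can be
   supplied instead.
2. For each replicated contrast in a **comparison design** — either one
   vector per closely related population pair, or vectors from a common
   outgroup to each focal population — compute the **change vector**
   `v = centroid(to) − centroid(from)`, where a centroid is the arithmetic
   mean of the member samples' coordinates on all retained axes.
3. For every unordered pair of vectors compute the **angle**
   `θ = arccos( v·w / (‖v‖‖w‖) )` in degrees, and the mean of the two
   lengths, **meanL**. Small angles (< 90°) indicate parallel change,
   angles near 90° orthogonal (unrelated) change, and angles above 90°
   anti-parallel change. meanL is the magnitude covariate: it is what the
   angle–magnitude correlations are computed against.

The direction of every vector is taken exactly from the design file
(always ecotype A → ecotype B within a system) and never auto-flipped;
without a consistent direction convention the sign of an angle comparison
is meaningless. All vectors entering one angle table must come from one
shared ordination — the package enforces this with an ordination identity
token, because angles between coordinates expressed in different bases
are not comparable.

## Significance testing

Three complementary tests are provided; they probe different properties
and are expected to broadly agree on clear-cut data.

**Location test against 90°.** In high-dimensional spaces the angle
between two random directions concentrates around 90°, approximately
normally. A one-sample t-test of the observed angles against 90°,
one-sided toward smaller angles, is therefore a simple first test of
parallelism. A Shapiro–Wilk gate at `alpha = 0.05` switches to the
one-sample Wilcoxon signed-rank test when normality is rejected
(`summary(fit, methods = "auto")`); explicit `"t"` / `"wilcoxon"`
selections override the gate. The Wilcoxon test uses the exact signed-rank
distribution for n ≤ 25 without ties and the normal approximation with
continuity correction otherwise.

**Monte-Carlo test.** Pairwise angles from k vectors are not independent
(each vector participates in k−1 of them), so the t-test's independence
assumption is only an approximation. `monte_carlo_parallelism()` instead
simulates, per iteration, a whole set of k uniformly random unit
directions in the same dimensionality d (independent standard-normal
components, normalized) and records the mean of all `choose(k, 2)`
pairwise angles — preserving exactly the dependence structure of the
observed statistic. The p-value uses the add-one correction
`p = (1 + #{null ≤ observed}) / (iterations + 1)`, so a finite simulation
never reports exactly zero. The default is 10^5 iterations. An
alternative reading of this test would compare the observed mean against
a pooled distribution of *individual* random angles; we simulate whole
sets because that is the null of the statistic actually computed (a mean
of dependent angles), and it is the version whose p-values are uniform
under the null (verified in the test suite).

**Rayleigh test.** Parallelism can also be read as directional
concentration of the vectors themselves. With unit directions
`u_i = v_i/‖v_i‖` and mean resultant length `R̄`, the statistic
`S = k·d·R̄²` is referred to the upper tail of χ²_d. We use the basic
(uncorrected) Rayleigh statistic with d equal to the retained ordination
dimensionality; vector lengths do not enter. Note the Rayleigh null is
uniformity of directions — a set of mutually orthogonal vectors is not
concentrated, so the test behaves conservatively there.

Raw p-values are reported (no multiple-testing correction by default);
`stats::p.adjust` can be applied across study systems by the caller.

For cross-analysis comparisons the package provides Spearman rank
correlation (`spearman_cor`, exact for n ≤ 10 without ties) and a paired
t-test between two angle sets over the same comparisons
(`compare_angle_sets`), optionally restricted to comparisons where both
sets show parallelism-side angles (< 90°).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_axes` | all positive axes | PCoA axes retained for vectors and angles. Angles depend on dimensionality; published analyses often truncate. The default keeps every axis with positive eigenvalue. |
| `tol` (PCoA) | 1e-8 relative | eigenvalues at or below `tol · λ_max` are treated as numerical zero. |
| `iterations` | 10^5 | Monte-Carlo null draws; below 1000 a warning is raised. |
| `seed` | none (required) | one integer seed determines every stochastic output. |
| gate `alpha` | 0.05 | Shapiro–Wilk level for t-vs-Wilcoxon auto selection. |
| rarefaction `depth` | none (optional) | even subsampling depth; samples below it are dropped and logged. |
| symmetry `tol` | 1e-8 absolute | distance matrices asymmetric beyond this are rejected; within it they are symmetrized by averaging. |

## Numerical choices

* The arccos argument is clamped to [−1, 1]; coincident and antipodal
  vectors give exactly 0° and 180°.
* Bray–Curtis is non-Euclidean, so PCoA produces negative eigenvalues.
  Negative axes are dropped without Lingoes/Cailliez correction — matching
  the default behaviour of the QIIME2-era stack whose exports this package
  consumes — and the discarded negative mass is recorded on the ordination
  object and in the run log.
* PCoA axis signs are arbitrary. They are fixed by forcing the
  largest-|loading| entry of each axis positive, so repeated runs and
  shared ordinations use one consistent basis. Axes are scaled by
  √eigenvalue (the standard scaling, so Euclidean distances among
  coordinates reproduce Euclidean input distances).
* Rarefaction is a without-replacement (multivariate hypergeometric) draw;
  each sample uses a deterministic substream derived from the one user
  seed and the sample's column position, so one sample's draw does not
  depend on which other samples pass the depth filter.
* Zero-length change-vectors (coincident centroids) are an error, not a
  silent NaN: the angle is undefined.
* `make_vector_fan()` builds oracle vector sets whose pairwise angles are
  prescribed. The fan is constructed in a plane with `cospi`/`sinpi` (so
  0°/90°/180° are exact) and embedded by zero-padding, which preserves
  angles exactly; a generic random rotation is available separately but is
  only accurate to ~1e-6 degrees near 0°/180° because of `acos`
  conditioning.
* Degenerate statistics fail loudly: constant samples for the
  Shapiro gate and t-test, all-zero differences for the Wilcoxon test,
  constant inputs for Spearman. An exactly constant nonzero paired shift
  in `compare_angle_sets` reports the limiting `t = ±Inf, p = 0`.

## The simulators, and what passing tests do (and do not) show

`simulate_ordination_groups()` draws spherical Gaussian clouds
(`sd = dispersion`) around population centroids placed so that the *true*
change-vectors have exactly the requested geometry: all parallel (0°),
mutually orthogonal (90°), alternating antiparallel (180°), or uniformly
random. It returns the true vectors, so centroid-estimator recovery can
be checked directly.

`simulate_count_tables()` emulates the processed output of an amplicon
pipeline: per population a Dirichlet–multinomial count model (per-feature
concentration 0.5, sequencing depth 10,000 by default) around a shared
log-normal baseline composition; "to" populations receive log-fold shifts
(`shift_magnitude`) on 10% of features, with the shifted feature set
shared across pairs (parallel, per-feature reuse probability `overlap`),
disjoint (orthogonal), sign-flipped (antiparallel), or random. A nested
seven-rank taxonomy is generated so collapsing can be exercised at every
level. Defaults (4 pairs × 50 samples/group, dispersion 1, shift 5) are
fixtures chosen to be clearly resolvable, not claims about any real
system.

True angle geometry is defined at the centroid level in latent/composition
space. Bray–Curtis and PCoA distort angles nonlinearly, so end-to-end we
assert *rank-order* recovery (parallel < orthogonal < antiparallel mean
angles) and test rejection on the parallel scenario — not numeric equality
of latent and estimated angles. Passing these tests shows the machinery is
correct and calibrated under a known generative model; it does not show
that any particular real community follows that model (real data have
uneven sampling, non-spherical dispersion, phylogenetic correlation among
features, and batch structure that the simulators deliberately omit).

Validation problem sizes used by the test suite: null-centering checks at
k = 10, d = 20 (3,000–10,000 iteration sets) and 10^5 single pairs at
d = 50; p-value uniformity over 500 null replicates (800 iterations each);
type-I rates over 500 orthogonal-scenario replicates at n = 50/group;
end-to-end recovery on the default count scenario (400 samples × 200
features per mode).

## Known limitations

* UniFrac and other phylogenetic metrics are accepted only as precomputed
  matrices; the package does not compute them.
* Only direction-consistent parallelism is quantified. Classifying
  convergence vs divergence relative to ancestral states needs external
  information about the direction of evolutionary change, which the
  method does not model.
* Angles depend on the retained dimensionality; comparisons across study
  systems are most meaningful at matched or explicitly reported `n_axes`.
  The ordination dimensionality is recorded in every run manifest.
* The Rayleigh test uses the asymptotic χ²_d reference; for very small k
  its p-values are approximate.

## A compact worked example

```{r example}
set.seed(1)
spec <- scenario_spec(pairs_per_system = 4, n_per_group = 20,
                      n_features = 80, depth = 3000, seed = 42)
sim <- simulate_count_tables(spec)
fit <- cva(sim$counts, sim$metadata, sim$design, input = "counts")
print(fit)
summary(fit, methods = c("auto", "mc", "rayleigh"),
        iterations = 5000, seed = 7)
```

The same analysis driven from files, with rarefaction and a
genus-level collapse:

```{r pipeline, eval = FALSE}
run_pipeline(list(
  feature_table = "feature_table.tsv", taxonomy = "taxonomy.tsv",
  metadata = "metadata.tsv", design = "design.tsv",
  rarefaction_depth = 2000, taxonomy_level = "genus",
  methods = "all", iterations = 1e5, seed = 1, output_dir = "results"
))
```
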