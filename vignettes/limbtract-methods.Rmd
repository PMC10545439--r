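---
title: "Limb-specific thalamocortical tractometry with limbtract"
author: "limbtract authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limb-specific thalamocortical tractometry with limbtract}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbtract)
```

## The problem

In spastic cerebral palsy (CP), the ascending thalamocortical pathways that
carry tactile and proprioceptive information to the primary sensorimotor
cortex are a prime suspect for the observed sensorimotor deficits. Because
the sensorimotor cortex is somatotopically organized, tracts serving the
hand and the foot can be separated by seeding tractography from
limb-specific cortical locations — a single white-matter-surface voxel
placed either manually from anatomical landmarks or at the center of mass
of a proprioceptive fMRI activation. `limbtract` implements everything
downstream of tractography for such a study: bundle selection against
dilated seed regions, whole-tract and along-tract diffusion summaries
(mean diffusivity MD in mm²/s, fractional anisotropy FA, apparent fiber
density AFD), hemispheric asymmetry indices, composite behavioral scores,
and the group/correlation statistics — together with a synthetic phantom
generator so the full pipeline can be exercised and validated without any
patient data.

## Coordinate contract

All modules exchange **world coordinates in mm** (the NIfTI affine's RAS
output); voxel indices never cross a module boundary. Voxel indices are
0-based and a voxel's center sits at the integer index, which makes the
single-voxel (1 mm³) seed unambiguous. TRK streamline files use a
voxel-corner origin convention; this is normalized at read time so
downstream code never branches on dialect.

## Bundle selection

A candidate streamline set is reduced to a limb-specific bundle by, in
order:

1. **Orientation** (`orientBundle`): each streamline is flipped if needed
   so its first point is the endpoint nearer the thalamus mask. Position 0
   of every along-tract profile therefore sits on the thalamus surface.
2. **Midline rule** (`filterMidline`): streamlines whose x coordinates are
   not strictly on one side of the mid-sagittal plane are removed. A point
   exactly on the plane disqualifies the streamline — the conservative
   reading, since such a streamline touches both sides.
3. **Terminal-ROI membership** (`filterToROI`): a streamline joins the
   bundle when its cortical terminal point falls inside the seed ROI
   dilated by a 3 mm spherical kernel (123 voxels on a 1 mm grid; the
   closed-ball convention makes radius 0 return the seed voxel itself).
   Endpoint — rather than any-point — semantics were chosen because the
   seed sits on the white-matter surface where tracking terminates.
4. **Geometric outlier removal** (`outlierFilter`): streamlines whose mean
   closest-point distance to the bundle's medoid exceeds 3 robust z-scores
   (median/MAD) are dropped. This automated cleanup stands in for
   surface-based sulcus-jump detection and rater-verified spurious-fiber
   removal, both of which need inputs (a cortical reconstruction, a rater)
   that a reproducible pipeline cannot assume; users with surface
   reconstructions can substitute their own step between filters.
5. **Minimum support** (`enforceMinCount`): tracts with fewer than 5
   streamlines are excluded — 5 itself passes — and the exclusion is
   recorded in the QC table and provenance log rather than erased.

The midline and ROI filters commute, and every decision is logged.

## Whole-tract summaries and asymmetry

`bundleMean` supports two averaging modes. The default, `streamline`,
averages each streamline's mean sampled value with equal weight per
streamline (after uniform 1 mm arc-length resampling, so long and short
streamlines are comparable); `mask` averages the metric over the non-zero
voxels of the tract density image. Both are provided because whole-tract
reporting conventions differ between the two and field usage is split; the
mode is recorded in every output row.

The hemispheric asymmetry index is

AI = 100 · (V_nd − V_d) / ((V_nd + V_d) / 2),

positive when the non-dominant tract value is larger, bounded by ±200 for
positive inputs. The dominant *tract* is the hemisphere contralateral to
the dominant *hand* (in hemiplegic CP the dominant hand is defined as the
less-affected hand). An AI of a zero-valued pair raises an error rather
than returning 0, so degenerate bundles cannot masquerade as symmetric.
Correlation analyses use |AI|.

## Along-tract profiles

`profileMedian` walks from the thalamus surface toward the cortex in 1 mm
steps (the tracker's native point spacing is not portable across subjects,
so uniform arc-length resampling defines "distance"): at each position the
sampled metric values of all streamlines still reaching that distance are
collected and their **median** taken (medians resist the partial-volume
outliers near CSF), stopping at the first position reached by fewer than
5 streamlines. Even contributor counts use the mean-of-middle-two
convention. The 10-point moving average (`smoothProfile`, symmetric
window, shrinking at the ends) is presentation-only; all statistics run on
raw profiles. Pointwise group comparison uses the Kruskal-Wallis H-test at
each position with no multiplicity correction, and a position is tested
only when every group contributes at least 2 subjects.

## Behavioral composites

Raw test scores (e.g. Box-and-Block counts, where higher is better;
Nine-Hole-Peg times and center-of-force sway velocities, where lower is
better) are min-max normalized over all participants pooled — 0 is the
worst performance in the sample and 1 the best, with lower-is-better tests
reversed — then averaged into hand-skill and stability sum variables. A
subject missing strictly fewer than half of a domain's tests has the
missing cells replaced by the group-mean of that test's observed
normalized values (which preserves every group-test mean exactly); a
subject missing half or more gets an undefined sum variable. "Strictly
fewer than half" is the literal reading of the inclusion rule; missing
exactly half disqualifies. Cronbach's alpha is computed on the normalized
scores over complete rows only, so imputation cannot inflate the
consistency estimate, with 0.8 as the threshold for good consistency.

## Statistics

Group comparisons use the Kruskal-Wallis H-test (mid-ranks, tie-corrected,
chi-square approximation — standard at these group sizes; an exact/Monte
Carlo permutation p-value is available behind a flag for very small
samples). When the global test is significant at α = 0.05, pairwise
differences are assessed with the Conover-Iman post hoc on the pooled
mid-ranks, t_ij = (R̄_i − R̄_j) / √(S² · ((N−1−H)/(N−k)) · (1/n_i + 1/n_j)),
two-sided on N−k df, with Benjamini-Hochberg FDR across the pairs (the
FDR method is recorded in output metadata; the (N−1−H)/(N−k) pooled-
variance scaling is the documented default of the test). Calling the post
hoc without a significant global test is treated as a contract violation.

Structure-function correlations residualize both the tract measure and
the limb-matched sum variable on age (least squares with intercept) and
correlate the residuals — equivalent to the first-order partial
correlation — tested two-sided with t = r·√((n−3)/(1−r²)) on n−3 df under
listwise deletion. Each limb domain tests exactly 9 hypotheses (3 metrics
× {non-dominant, dominant, |AI|}), so the Bonferroni threshold is
0.05/9 ≈ 0.006.

## The phantom generator

`phantomSpec()` encodes the study conditions the synthetic cohorts
emulate:

| parameter | default | meaning |
|---|---|---|
| grid | 96³ voxels at 1 mm | matches the 1 mm³ interpolated metric grids |
| streamlines/bundle | 50 | bundle support well above the exclusion floor |
| MD baseline | 8·10⁻⁴ mm²/s | typical deep white matter |
| FA / AFD baseline | 0.5 / 0.3 | typical tract values |
| AFD profile | peaks at 10 mm and 45 mm (σ = 5 mm) | the two-peak along-tract AFD shape of the control upper-limb tract |
| δ_HP | +15% MD, non-dominant hemisphere only | lateralized involvement in hemiplegia |
| δ_DP | +10% MD, bilateral | bilateral involvement in diplegia |
| voxel noise | 5% of baseline, i.i.d. | measurement noise |
| subject scale sd | 3% | between-subject biological variability; cancels in AI |
| cohort | TD 19 / HP 15 / DP 10 | the emulated group sizes |
| age | uniform 10.5–18.1 y | the emulated age range |
| dominance P(right) | TD 1.0, HP 0.4, DP 0.6 | the emulated handedness mix |

Bundles are jittered quadratic arcs from the thalamus-blob surface to the
cortical seed voxel, and metric values are **painted along the bundle
geometry** (nearest-arc assignment within a tube) rather than bundles
being fit to pre-existing volumes — this guarantees a known ground-truth
profile for oracle tests. Behavioral scores come from group-specific
normal models (TD best; hand skill worst in HP, stability worst in DP)
with missing-at-random cells at rate 0.08.

What the phantom does **not** emulate: lesions and malformations, crossing
fibers and the dMRI signal itself, spatially correlated noise, realistic
cortical geometry, or rater variability. Passing tests therefore
demonstrate the correctness and calibration of the *analysis*, not the
validity of tractography on real data.

## Numerical choices

* Trilinear interpolation for all metric sampling; a point at a voxel
  center returns that voxel's value exactly, and sampling outside the grid
  is an error, never an extrapolation.
* Tract density counts each streamline at most once per voxel (the mask's
  non-zero rule is insensitive to segment-length weighting), walking
  segments at a tenth of the voxel size.
* Ties in the activation-seeding maximum and in surface projection break
  deterministically by lowest voxel index triple, replacing the original
  workflow's manual projection with a reproducible rule; the activation
  peak is the global suprathreshold maximum (a rater-guided local maximum
  is not reproducible).
* Seeds and replicate streams: every stochastic function either consumes
  the caller's RNG state or takes an explicit integer seed; cohort tables
  store a per-subject seed so each subject's imaging data regenerate
  bit-identically.

## Problem sizes used in the validation suite

The replicated recovery experiment uses `reducedPhantomSpec()` — a 48³
grid, 12 streamlines per bundle, proportionally shorter arcs, with the
effect sizes, noise and cohort composition unchanged — so that 100
replicate cohorts (plus 100 null replicates) complete in minutes on one
CPU. Single-cohort checks (e.g. two-peak AFD profile recovery) run on the
full 96³ default. With the default effect sizes the reduced-grid pipeline
detects the HP asymmetry increase and the DP non-dominant MD increase in
well over 90% of replicates, while the null rejection rate stays at the
nominal 5%.

## Known limitations

* Sulcus-jump removal requires a cortical surface reconstruction and is
  out of scope; the midline rule plus the geometric outlier filter are the
  automated stand-in.
* Whole-tract averages are reported in a declared mode because the
  streamline/mask ambiguity cannot be resolved from figures alone.
* The along-tract analysis aligns subjects by absolute mm distance from
  the thalamus surface, not by warping to a common atlas length; profiles
  of different lengths are compared only over their shared positions.
* Lesion type and timing are not modeled, matching the analysis scope this
  package reproduces.
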