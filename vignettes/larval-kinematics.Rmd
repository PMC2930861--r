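---
title: "Scoring larval chemotaxis trajectories: model, thresholds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring larval chemotaxis trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatrack)
```

## The measurement problem

Mosquito larvae respond to dissolved odorants not by steering toward a
source but by modulating how often they turn (klinokinesis) and how much
they move (orthokinesis). A single larva is released into a 10-cm circular
dish with the odorant at the opposite rim, and its head position is
recorded once per second for five minutes. The analysis problem is to
reduce each 300-point track to a small set of kinematic numbers that are
comparable across treatments, and to do so with operational definitions
that are robust to the animal's habit of swirling its body in place without
actually going anywhere.

`larvatrack` implements that reduction, the group statistics layered on top
of it, and a simulator that produces trajectories with known latent
structure so the whole chain can be verified against ground truth.

## Operational definitions

**Tracking vectors.** The displacement between consecutive samples. We
deliberately score per sampled interval rather than per detected
"movement event": the definitions below are stated on successive tracking
vectors, and tracking is per downloaded frame.

**Turn.** Two successive tracking vectors intersecting at an unsigned angle
strictly greater than `turn_threshold_deg` (default 45°). Angles come from
the arccosine of the normalized dot product, clamped to [-1, 1] first so
collinear vectors cannot produce `NaN`. Because an exactly-45° pair must
not count under a strict reading of the threshold, the comparison carries a
1e-9-degree guard: floating-point round-off in `acos` can otherwise inflate
a constructed 45° angle to 45 + 1e-14 and flip the decision.

**Direction-undefined vectors.** A vector shorter than `min_vector_mm`
(default 0.1 mm) has a numerically meaningless direction — at tracking
resolution it is jitter. Any pair involving such a vector is skipped
entirely; we do not evaluate the angle between the vectors flanking the
gap. Skipping is the conservative choice: it can only undercount turns,
never invent them from noise.

**Movement instance.** A displacement strictly exceeding
`movement_threshold_mm`. The threshold is derived from the body geometry:
when a larva of length L pivots 90° about an axis at its body-length
midpoint, its head (at radius L/2) travels a chord of
2·(L/2)·sin 45° = L·sin 45°. For the average body length of 3.25 mm this
is 2.298 mm ≈ 2.3 mm. Displacements at or below it are attributed to
in-place body swirls. `movement_threshold(3.25)` reproduces the number.

**Average velocity.** Total path length over observed duration, exactly.

**Resting time.** The binary complement of a movement instance: the summed
duration of intervals whose displacement does not exceed the movement
threshold. One threshold serves both definitions, so for uniformly sampled
tracks the identity
`resting_time + n_movements * sample_interval = duration` holds exactly and
is enforced in tests. A stricter near-zero resting criterion would be
defensible, but with nothing to pin its epsilon to we kept the single
threshold; the choice is isolated in `resting_time()` if a user disagrees.

Non-uniform sampling is tolerated — interval durations come from the
timestamps — but the movement threshold is *not* rescaled by interval
length, matching the fixed per-shift rule of the original definitions.

## Group statistics

Each metric is compared across groups with single-factor fixed-effects
ANOVA (`anova_oneway()`, delegating to `stats::oneway.test` with equal
variances), followed by Tukey–Kramer all-pairs comparisons. The critical
range for a pair (a, b) is

q(1 − α; k, N − k) · sqrt((MSW/2)(1/nₐ + 1/n_b)),

with the studentized-range quantile computed numerically by
`stats::qtukey` — never from a hard-coded table — so any k and df are
supported; the k = 2 case collapses to the pooled t-test
(q = √2·t), which the tests verify on random data. Pairwise results are
always reported but flagged authoritative only when the ANOVA itself is
significant, mirroring the significant-then-post-hoc convention. The
default α is 0.05 and is a configuration knob, not inferred. No correction
is applied across the four metrics — a caveat worth knowing when reading
reports: four families of tests are run per experiment.

Knockdown validation uses the Pfaffl efficiency-corrected ratio
E_t^ΔCt_t / E_ref^ΔCt_ref. The sign convention is fixed as
ΔCt = control − sample, so a knocked-down target (higher Ct in the sample)
yields a fold change below 1. This is stated prominently because the
opposite convention is equally common and silently inverts every result.
Efficiencies outside [1, 2.5] warn rather than fail: they are implausible,
not impossible.

## The simulator

`simulate_trajectory()` generates a two-state correlated random walk at the
sampling resolution:

- each second the larva is **moving** with probability `p_move`, otherwise
  it rests in place;
- a moving step draws its length from a gamma distribution with mean
  `step_mean_mm` and coefficient of variation `step_cv`;
- the heading takes a **large deflection** — uniform in (45°, 180°], random
  sign — with probability `p_big_turn`, else uniform wobble within
  ±`wobble_deg`.

Large deflections are strictly above the 45° scoring threshold and wobble
strictly below it, so latent turns are scoreable by construction and the
scorer can be tested against the latent state sequence exactly. Positions
leaving the arena are folded radially back inside and the heading is
realigned to the realized displacement.

Treatment effects act on the kinematic propensities, not on spatial taxis:
the four metrics are spatially unresolved kinesis measures, and simulating
odor gradients would add physics the analysis never probes. The realized
modulation is m = strength · log10(dose/dose_ref) · knockdown, clamped at
zero (a dose at or below the reference is neutral). Repellents multiply
`p_big_turn`, `p_move`, and `step_mean_mm` by (1 + m), probabilities capped
at 0.99; attractants divide by the same factor; `knockdown = 0` forces
baseline regardless of dose, which is exactly the abolished-response
phenotype of a fully silenced receptor. Log-linear-with-caps is the
simplest monotone form consistent with dose-dependent but unquantified
effects; it is a device for recovery testing, not a dose-response claim.

Per-larva seeds are hashed from (design seed, group label, larva index), so
a design reproduces byte-identical output regardless of group iteration
order.

### Defaults and what they emulate

| parameter | default | why |
|---|---|---|
| `p_move` | 0.6 | rest/move mix giving a control resting time near 240 s of 300 s |
| `step_mean_mm` | 2.0 | control steps straddle the 2.3 mm threshold, so movement counts are non-degenerate |
| `step_cv` | 0.6 | broad, right-skewed step lengths typical of intermittent locomotion |
| `p_big_turn` | 0.15 | ~20 scoreable turns per control assay |
| `wobble_deg` | 20 | heading persistence between turns, safely below 45° |
| `strength` | 0.5 | a 100× dose ratio doubles (repellent) or halves (attractant) the propensities |
| arena | 100 mm, release on rim | the dish geometry of the assay |

These are simulator defaults chosen for desk-scale testability, not claims
about real larvae. What the simulator reproduces is the *statistical
skeleton* the analysis assumes: rest/move intermittency, heavy-tailed
steps, discrete re-orientation events, dose-monotone and
knockdown-attenuated modulation. What it does not reproduce: spatial bias
toward or away from the source, inter-larva variability in baseline
parameters, tracking noise, body posture, or wall-following behavior.
Passing recovery tests therefore show the scoring and inference chain is
correct on data with this structure — they do not validate the biological
model against real video.

## Numerical and degenerate-input choices

- Strict inequalities at both thresholds ("exceeds"), with the
  1e-9-degree turn-angle guard above; movement displacements are compared
  without a guard since equality at the threshold is exact in the
  constructed cases that matter.
- Fewer than 3 points cannot be scored for turns; such larvae are skipped
  with a warning naming them at the table level and are an error when
  scored individually.
- A stationary interval contributes its full duration to resting time; a
  completely stationary track has velocity 0 and resting time equal to its
  duration.
- Wall handling is a radial fold (r → 2R − r) with heading realignment;
  overshoots beyond the far wall (impossible at default step scales) clamp
  to the rim.
- The closed-form movement fraction p_move · S_gamma(threshold) holds
  where wall reflections are negligible; kernel-identity tests therefore
  start the walk at the center of a 1000-mm arena. In the default dish a
  rim-started walk lingers near the boundary and reflections shorten a
  small fraction of displacements — a property of the assay geometry, not
  a scoring artifact.
- Child seeds are reduced modulo 2³¹ − 1 so they remain valid R integer
  seeds on every platform.

## Problem sizes

The verification suite runs the study's own scale — 5-min, 1-Hz tracks,
n = 10 per group — with 1000 random trajectories for scorer-vs-oracle
equivalence, 500 simulated replicates for type-I calibration, 200 for
power/directionality and knockdown nulls, and a 10,000-step track for the
closed-form kernel identity. These sizes keep Monte-Carlo error well inside
the asserted bounds while completing in about a minute.

## Known limitations

- The four metrics are spatially unresolved: no preference index, approach
  distance, or source-relative statistic is computed, so attraction is
  inferred from kinesis signatures only.
- ANOVA on counts (turns, movements) leans on approximate normality; at
  n = 10 with control means around 20 this is adequate (the type-I
  calibration test verifies it) but very low-activity groups would push
  the approximation.
- The `points_export` reader dialect is a best-effort convenience for bare
  tracker exports, not a fidelity claim about any specific tracker's
  schema.
- Ct values are taken as given; raw amplification curves are out of scope.
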