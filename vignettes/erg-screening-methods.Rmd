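---
title: "Methods: quality control and statistical screening of mouse ERG cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality control and statistical screening of mouse ERG cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electroretinography (ERG) records the retina's field potential in response to
light flashes. In a dark-adapted (scotopic) mouse the waveform carries four
measurable components in sequence — the cornea-negative a-wave (rod
photoreceptors), the positive b-wave (depolarizing bipolar cells), the slow
positive c-wave (retinal pigment epithelium with a Müller-cell contribution),
and a late negative deflection related to the fast oscillation ("FO-like",
basal RPE). Under light-adapted (photopic) conditions only a cone-driven
a- and b-wave are measured. A phenotyping screen compares knockout strains
against wildtype controls on these component amplitudes, strain by strain,
across an acquisition window of years.

Two features make this statistically awkward. First, raw trials are noisy and
occasionally artifactual, so amplitudes must be extracted from QC-filtered,
averaged waveforms. Second, the control population drifts slowly over the
years (equipment, handling, colony effects), so "all controls ever tested" is
the wrong comparison group for a mutant batch tested in one month.
`ergscreen` implements the full chain: validation, baseline correction,
inter-trial consistency QC, trial averaging, component extraction,
wildtype-referenced extreme-value QC, a sample-size gate, soft temporal
windowing of controls, weighted genotype ANOVA with percentage effect sizes,
and between-eye concordance hit calling — plus a seeded synthetic cohort
generator so that every stage can be validated without any external data.

## Measurement conventions

After baseline correction (subtracting the mean of the final 40 scotopic /
20 photopic pre-stimulus samples, so the pre-stimulus level is 0), components
are measured on the per-eye averaged waveform:

* **a-wave**: baseline to the most negative trough in the a-window, reported
  as a non-negative magnitude;
* **b-wave**: a-trough to the highest subsequent peak in the b-window —
  *not* baseline-to-peak, so a shallower a-trough reduces the measured b-wave
  even when mutant and control peaks coincide;
* **c-wave** (scotopic): baseline to the highest peak after the b-peak;
* **FO-like wave** (scotopic): c-peak down to the deepest subsequent trough.

Extrema are located on raw averaged samples (the acquisition bandpass,
0.125–50 Hz, already limits noise), with ties broken to the earliest sample.
Search windows are configurable; the defaults (scotopic a 3–60 ms, b
15–250 ms, c 400–3500 ms, FO-like from the c-peak to 5000 ms; photopic a
3–30 ms, b 15–100 ms) follow standard mouse ERG timing and the display
epochs conventionally used for these components, because exact window bounds
are not published for this protocol. Every run reports the windows used. If a
trace never goes negative in the a-window the a-amplitude is 0 (not an
error); a window left empty by the landmark-ordering constraints yields a
missing value for that component only.

## Quality control

1. **Generic validation**: mice with metadata conflicts, duplicate
   identifiers, incomplete trial sets, or sampling violations are reported
   and excluded. A keep/drop override table stands in for the manual-review
   step such screens perform interactively.
2. **Inter-trial consistency (MAD)**: for each mouse, eye and condition, the
   mean absolute deviation across repeated trials is computed per time point
   and summed over the trace. The cutoff is the empirical 99th percentile of
   the pooled per-condition score distribution, so ~1% of units are flagged
   *by construction* — this stage ranks inconsistency rather than testing a
   null hypothesis. A mouse flagged in either eye loses that condition only.
3. **Extreme values**: for each parameter and eye, limits are the wildtype
   mean ± 3 wildtype SD (n−1 denominator), applied to the whole dataset. The
   interval is closed: a value exactly at a limit passes (the conservative
   reading of "outside the limits"). Flagged wildtype mice leave the control
   pool too.
4. **Sample-size gate**: strains with fewer than 5 QC-passing mice (sexes
   combined) in a condition are reported as "insufficient data" and not
   tested for that condition.

The QC chain only ever removes records; it never alters a retained value.

## Soft temporal windowing

Controls are weighted in [0, 1] by temporal proximity to the mutant batch
dates. The kernel is a flat-top product of logistics: for distance `d` days
from the nearest mutant test date,

    w(d) = plogis(3k (1 + d/l)) * plogis(3k (1 - d/l))

which is ≈1 well inside the half-width `l`, 0.5 at `d = l`, and → 0 beyond,
with edge sharpness `k`. Multiple batch dates are aggregated by pointwise
maximum, so strains tested in well-separated batches get broad or bimodal
windows. `(l, k)` are chosen by exhaustive grid search
(`l ∈ {7, 14, 28, 56, 112, 224, 448}` days × `k ∈ {1, 2, 5, 10}`),
minimizing the weighted variance of the control values subject to an
effective control size (sum of weights) of at least
`max(20, number of mutants)`; ties resolve to the smaller `l`, then smaller
`k`, so the result is deterministic. If no grid point satisfies the
constraint the weights fall back to all ones with a warning, which reduces
the analysis to an unwindowed ANOVA. Each strain × parameter × eye analysis
is windowed independently, so the effective control group legitimately
differs across parameters of the same strain. Deployed screens of this design use published soft-windowing software whose
exact objective is not reproduced here; equivalence is behavioral (soft edges, flat top, multimodality,
variance-minimizing size), not numerical.

## The statistical model

Per strain, parameter and eye, amplitudes are fit by weighted least squares:

    Y = B0 + B1 * genotype,   genotype ∈ {0 = wildtype, 1 = mutant}

with mutant weights 1 and control weights from the window. `B0` is then the
weighted wildtype mean and the effect size is `100 · B1 / B0`, the percent
change from wildtype. Inference uses degrees of freedom based on the
*effective* sample size (sum of weights) minus the number of parameters, so
fractional control weights cannot inflate nominal n; with unit weights the
p-value reproduces classical one-way ANOVA exactly (the suite verifies
agreement to 10 significant figures). The "combined eyes" analysis pools the
left- and right-eye observations (up to two per mouse) into one weighted
fit — the plainest reading of "data combined between the two eyes"; the rule
is recorded in the run manifest because a meta-analytic combination is an
equally defensible alternative and exact p-values depend on the choice. The
mean-effect percentage is the arithmetic mean of the two per-eye effect
percentages.

A strain × parameter is a **hit** iff p ≤ 0.01 in the left eye AND p ≤ 0.01
in the right eye AND p ≤ 0.0001 combined. Results that clear the combined
threshold but miss a per-eye threshold are labelled *non-concordant* and are
never hits. No further multiple-testing correction is applied across strains
or parameters: the stringent triple threshold *is* the stated procedure.
Pooling correlated eyes makes the combined p-value anti-conservative in
isolation; the per-eye concordance requirement is what keeps the false-call
rate near zero (the suite's 500-strain null screen yields zero hits).

Sex enters only two side analyses: Welch's unequal-variance t-tests of male
vs female wildtype amplitudes per parameter and eye (12 tests, Bonferroni
threshold 0.004), and a sex × genotype interaction screen for strains with
at least 4 mutants per sex, using the same concordance rule on the
interaction term.

## The synthetic world

`generate_cohort()` emulates the screen's design: weekly wildtype cohorts of
5 males + 5 females, mutant strains of configurable size tested in 1–6
batches, 3 scotopic trials and 20 photopic sweeps per eye at 2000 Hz
(scotopic epoch −20 to 5000 ms, photopic −10 to 100 ms). Waveforms are sums
of smooth polarity-signed lobes — Gaussian a-, b-, FO-like and photopic
lobes, a gamma-shaped c-lobe — whose continuous extrema are computable in
closed form (`template_extrema()`), giving an extraction oracle that is
independent of the sampled pipeline. Strain effects multiply component
kernel amplitudes, because the screen's effect size is a percentage of the
wildtype mean. Nuisance structure: a shared lognormal per-mouse scale, an
independent lognormal per-eye scale, additive white trial noise, a constant
offset drift (removed exactly by baseline correction), a multiplicative gain
drift (what the soft window must absorb), per-trial artifact corruption, and
whole-mouse gross outliers. Ground truth (effects, artifact trials, outlier
mice) is emitted alongside every cohort and never read by the pipeline.

Default magnitudes are synthetic choices, not published values: kernel
amplitudes a 200, b 400, c 150, FO 120 µV (scotopic) and a 15, b 90 µV
(photopic); between-mouse CV 0.06; between-eye CV 0.24; trial noise 5 µV;
gain drift 5%/year; offset drift 50 µV/year; artifact rate 0.005/trial at
200 µV; outlier rate 0.01/mouse at 4–8 total SD. Two considerations fixed
the variance split. The control line is inbred and age-matched, so
between-animal biological variance is small, while per-eye technical factors
(electrode contact, tear film) dominate — which is also exactly why a
between-eye concordance requirement has teeth. And the total CV (~0.25,
typical of mouse ERG amplitudes) must be large enough that a strain with a
genuine −50% effect is *not* annihilated by the ±3 SD extreme-value limits:
at CV ≲ 0.17 such mutants sit ~3 SD below the wildtype mean and the QC
removes them wholesale. A consequence worth stating plainly: at this noise,
the sex × genotype interaction screen has modest power — a −40% male-only
effect with 6 mutants per sex is detected concordantly in well under half of
replicates (the suite asserts detection far above the null rate, not the
~80% that would be achievable at half this noise). Strong, large-sample
dimorphisms remain detectable, as the `"dimorphic"` fixture shows.

What a green test suite establishes: the measurement conventions, QC rules,
windowing and statistics behave as specified on data with this structure —
effects in {−50, −25, 0, +25}% are recovered without bias, null screens call
no hits, planted artifacts and outliers are recalled, drifted cohorts are
debiased by the window. What it does not establish: that real ERG noise is
lognormal-multiplicative, that real drift is linear, or that any specific deployed
screen's exact p-values are reproduced — that would require its raw data
and its exact windowing optimizer.

## Numerical choices and edge cases

* Quantile cutoffs use R's default (type 7) linear-interpolation quantile;
  with fewer than 100 scores per condition a stability warning is raised.
* Extraction ties break to the earliest time point; a flat trace yields
  zero amplitudes at the window starts.
* `B0 = 0` makes the percent effect undefined; it is reported missing with a
  warning rather than ±Inf.
* Identical groups give `B1 = 0`, p = 1; Welch's test on two identical
  constant samples returns t = 0, p = 1 (where `stats::t.test` would error).
* Weight-0 controls are algebraically equivalent to dropped observations,
  and the suite asserts this.
* Serialization packs samples as `;`-separated decimals at 1e-6 µV, the
  round-trip tolerance.
* All randomness flows from a single integer seed; cohorts are bit-identical
  across runs for a fixed seed and config.

## Known limitations

* The combined-eyes rule (pooling) is one reading of an underspecified
  procedure; exact replication of a deployed screen's combined p-values may require a
  different combination rule.
* MAD cutoffs are pooled across eyes within a condition (flag if either eye
  exceeds); deployed pipelines may split by eye instead.
* The windowing optimizer is a behavioral stand-in for published
  soft-windowing methods, not a reimplementation of any of them.
* Latencies are extracted and reported but excluded from screening
  statistics, mirroring amplitude-focused screening practice.
* No vendor acquisition formats, oscillatory-potential analysis, dark
  adaptation or paired-flash protocols, and no histology statistics.
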