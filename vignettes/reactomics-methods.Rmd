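---
title: "Reactomics: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactomics: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactomics)
```

## The reactomics idea

Classical serum diagnostics measures identified molecular biomarkers. The
*reactomics* approach instead reacts a serum sample against a small array of
biomimetic detectors — vesicles of defined lipid composition co-polymerized
with polydiacetylene (PDA) — and uses the *pattern* of reactions as the
diagnostic signal. PDA undergoes a blue-to-red chromatic transition when
membrane-perturbing species interact with the vesicle surface; the red phase
is strongly fluorescent, so the extent of reaction is read on a standard
fluorescence plate reader. Different lipid head-group/cholesterol
compositions make each detector differentially sensitive to the serum's mix
of lipoproteins, enzymes and amphiphiles, so a panel of ten vesicle types
(see `default_panel()`) assigns each serum a ten-dimensional reactivity
fingerprint.

This package implements the complete quantitative pipeline from raw
96-well fluorescence readings to classifier-based group discrimination with
significance assessment, together with a synthetic plate generator that
makes every stage testable without clinical specimens.

## From emission to feature: the chromatic response

The unit measurement is the **percentage fluorescent chromatic response**

$$\%FCR = \frac{Em_i - Em_c}{Em_r - Em_c} \times 100,$$

where $Em_c$ is the background fluorescence of unexposed (blue-phase)
vesicles, $Em_i$ the fluorescence after incubation with the sample, and
$Em_r$ the maximal fluorescence of heat-converted red-phase vesicles. Each
plate carries its own negative and positive color-control wells; their means
estimate $Em_c$ and $Em_r$ (`aggregate_plates()`), and each serum's \%FCR is
the mean over its replicate wells (triplicate by default). Two properties
matter:

* **Affine invariance.** Any gain/offset distortion applied to a whole
  plate — detector sensitivity drift, optical path differences — cancels
  exactly in the \%FCR ratio, because controls and samples are distorted
  together. This is an algebraic identity, and the test suite asserts it
  exactly.
* **No clipping.** Replicate noise can push \%FCR slightly outside
  $[0, 100]$; values are deliberately left unclipped, since clipping would
  bias downstream means and the classifier is indifferent to the range.

## Cross-plate standardization

A cohort of 150 sera in triplicate cannot fit on one 96-well plate, so each
detector vesicle is measured on several plates, and plate-to-plate biases
must be removed. Every plate carries identical aliquots of five
**standardization sera**. For each vesicle, the cross-plate reference value
of a standard is the mean of its \%FCR over all plates; each plate is then
mapped onto the references by a least-squares affine fit
$x \mapsto a + b\,x$ of its five standard values
(`standardize_across_plates()`).

Choices made here, where the underlying protocol is open:

* The affine least-squares alignment is the minimal model able to remove
  residual gain/offset structure at the \%FCR level, and it is exactly
  invertible — the tests construct a plate whose \%FCRs are an affine image
  of another's and verify the inversion to numerical precision.
* The fit is applied **after** triplicate averaging. The order is not
  observable from the data model; averaging first is deterministic and
  commutes with the affine map, so nothing is lost.
* The procedure is *near*-idempotent rather than exactly idempotent: a
  second pass re-fits against references that moved slightly during the
  first pass. The movement is second-order small (the suite bounds it at
  under 10% of the first correction); an exactly idempotent variant (moment
  matching of the standards) was considered and rejected because it does not
  minimize the squared deviation from the references.
* A plate whose standards are degenerate (zero variance) falls back to an
  offset-only correction with a warning rather than failing the run.

## Normalization to the clinical control group

After standardization, each plate's values are z-normalized against the
**healthy-control clinical samples on that plate**: subtract their mean,
divide by their sample standard deviation ($n-1$), per vesicle
(`normalize_to_controls()`). The normalized values form the feature matrix —
one row per serum, one column per detector vesicle.

Note the two distinct serum sets: the five *standardization sera* align
scales **between** plates; the *control-group samples* center and scale
values **within** a plate. The plate design must therefore place at least
two control-group sera on every plate, which the synthetic generator
guarantees by stratified assignment (below). Samples missing any vesicle
measurement are dropped with a warning, not imputed — imputation would
inject assumptions the classifier would then happily learn.

## Classification: exhaustive wrapper selection with a linear SVM

Each pairwise comparison (pancreatic cancer vs control, stomach cancer vs
control, stomach vs pancreatic) is a binary experiment
(`run_repeated_experiment()`):

1. **Partition**: each group is split at random into balanced training and
   test halves (25/25 for 50-sample groups). An alternative `"table2"`
   sizing (train 24 / test 26 positives) is exposed because published
   sensitivity/specificity denominators in this assay family imply a
   26-positive test set; both sizings are supported and neither is favored.
2. **Exhaustive wrapper selection**: for every one of the $2^{10}-1 = 1023$
   non-empty feature subsets, a linear-kernel SVM (LIBSVM via `e1071`,
   cost $C = 1$, no rescaling beyond the normalization above) is fit on the
   training set and scored on the training set itself (resubstitution).
   The winner is the subset with the highest training accuracy, ties broken
   by training MCC, then by fewer features, then by canonical enumeration
   order — a total order, making selection deterministic.
3. **Evaluation**: the winning model predicts the untouched test set, and
   Accuracy, Sensitivity, Specificity and the Matthews correlation
   coefficient
   $$MCC = \frac{tp\,tn - fp\,fn}
   {\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}$$
   are reported (MCC $=0$ when a marginal vanishes).
4. The procedure repeats over independent random partitions (five by
   default); features selected in **every** repeat form the *consensus set*.

Resubstitution scoring is a deliberate fidelity choice: it reproduces the
wrapper protocol this package validates, and its optimism is confined to
the training column of the report — all quality claims rest on the held-out
test set. An internal k-fold cross-validation scorer is available behind
`cv_folds=` for users who prefer an honest training-side estimate. The C
parameter and kernel are the library defaults; no hyper-parameter search is
performed, so the test set is never touched during model choice.

## Significance: exact binomial tail and label-shuffle null

Two complementary null arguments (`experiment_significance()`,
`run_shuffle_null()`):

* **Exact binomial tail.** A chance classifier that always guesses the
  majority class of a test set with $n_+ \ge n_-$ is correct with
  probability $p_0 = n_+/(n_++n_-)$. The probability of reaching $k$ or
  more correct predictions by chance is the inclusive upper tail
  $P(X \ge k)$, $X \sim \mathrm{Bin}(n, p_0)$, computed by stable log-space
  summation of the exact terms (no normal approximation). For example,
  reaching 43/51 correct (84.3% accuracy) against $p_0 = 26/51$ has
  $p \approx 7 \times 10^{-7}$. The majority-class chance model is the one
  under which that worked example is reproducible; a flat $p_0 = 0.5$ gives
  $\approx 3 \times 10^{-7}$ for the same counts.
* **Label shuffle.** Group labels of the whole cohort are permuted
  uniformly at random (preserving the 50/50/50 counts) and the *entire*
  experiment — partitioning, exhaustive selection, test evaluation — is
  re-run. Because the shuffled labels carry no information, the best
  models' test MCC scatters around zero; systematic deviation would expose
  leakage between selection and evaluation. The suite requires
  $|\overline{MCC}| < 0.15$ over 20 shuffles of the default cohort.

## The synthetic cohort generator

No public serum data exists for this assay, so `generate_cohort()` produces
plate data with the statistical structure the analysis assumes
(`synthetic_config()`):

* Each serum $s$ in group $g$ has a latent true response
  $f(s,v) \sim N(\mu_{g,v}, \sigma_{serum})$ per vesicle $v$, clamped to
  $[0,100]$ (with the default means and $\sigma_{serum} = 10$ the clamp is
  a $>4\sigma$ event, so truncation bias is negligible).
* A replicate well reads
  $gain_p\,(Em_c + f/100\,(Em_r-Em_c) + \varepsilon) + offset_p$ with
  $\varepsilon \sim N(0,\ \sigma_{rep}(Em_r-Em_c)/100)$; color controls
  read the distorted $Em_c$/$Em_r$ with the same replicate noise. The
  per-plate affine $(gain_p, offset_p)$ is exactly the artifact family the
  two-stage standardization/normalization chain is designed to remove,
  which makes removal *testable*: regenerating the same seed with zero
  distortion scales must reproduce the feature matrix to $10^{-9}$.
* The five standardization sera have latent responses drawn once per
  vesicle and shared across that vesicle's plates.
* 150 sera in triplicate exceed one plate, so sera are dealt to plates
  **stratified by group**: shuffled within group, then round-robin across
  as many plates as capacity requires (each also carrying 3+3 color
  controls and the 5 standards in triplicate). Stratification mirrors a
  sensible bench layout and guarantees every plate the control sera its
  normalization needs; fully random, potentially confounded layouts are
  not simulated.

Default study conditions — chosen once to emulate the clinical setting and
then frozen: 50 sera per group; $Em_c \approx 100$, $Em_r \approx 1100$
arbitrary units; control mean \%FCR between 44 and 55 across vesicles;
stomach-cancer means 2–5 points *below* control on every vesicle;
pancreatic-cancer means *above* control only on vesicles V3
(DMPC/Chl/PDA 1:1:3) and V5 (DMPE/PS/PDA 1:1:3) and at or below control
elsewhere — the qualitative group-by-vesicle pattern reported for this
assay. Effect magnitudes were calibrated once so the default cohort's
pancreatic-vs-control mean test accuracy falls in the 80–95% band that
regime occupies, and were not revisited. Replicate noise
$\sigma_{rep} = 2$ \%FCR points yields 10-repeat RSDs of 3–4%, comfortably
within the ≤8% repeatability the assay reports; gain SD 0.05 and offset SD
5 a.u. are plausible plate-reader drifts.

What passing tests on this generator do **not** show: robustness to
non-affine plate artifacts (edge effects, kinetic drift within a read),
non-Gaussian serum populations, batch-confounded plate layouts, or any
biological claim about real sera. The generator validates the *pipeline's
contracts*, not the assay's clinical performance.

## Numerical conventions and degenerate inputs

* Sample standard deviation ($n-1$) everywhere a SD appears.
* A plate whose positive-control mean does not exceed its negative-control
  mean is rejected as degenerate rather than producing nonsense \%FCR.
* A plate with fewer than two control-group samples, or zero control
  variance, fails normalization with a named error.
* RSD is undefined at zero mean and errors out.
* `binomial_tail_p(0, n, p)` is exactly 1 and `binomial_tail_p(n, n, p)`
  exactly $p^n$; the log-space sum matches R's exact binomial CDF to
  $10^{-12}$ across all $k$ for $n \le 20$.
* All randomness flows through explicit integer seeds; the RNG stream is
  consumed identically whatever the noise scales, so zero-noise and noisy
  cohorts under one seed are coupled — the basis of several oracle tests.
* Exhaustive enumeration refuses panels beyond 20 features; wrapper
  selection at that scale needs heuristics this package intentionally does
  not provide.

## Problem sizes used in validation

The shipped validation suite runs the full default cohort (150 sera × 10
vesicles, 70 plates) for the end-to-end properties — affine invariance,
chance-level behavior on a zero-effect cohort, a 20-shuffle label
permutation null, and a three-point effect-size monotonicity check — and
smaller stratified cohorts (3–5 vesicles, 10–15 sera per group) for
per-module contracts, where the exhaustive search shrinks from 1023 to
7–31 subsets. These sizes exercise every code path at full fidelity while
keeping the suite quick to run.

## Known limitations

* The pipeline is strictly pairwise-binary, as the underlying protocol is;
  no multiclass extension is offered.
* No multiple-testing correction is applied across the five repeats or
  three comparisons — the significance module quantifies each repeat's
  chance probability and leaves family-wise arguments to the analyst.
* The `"table2"` sizing and the majority-class chance model are
  reconstructions from published summary numbers, exposed as options and
  documented as such, not asserted as the original protocol.
* Kinetics (the 60-minute equilibration), visible-spectrum colorimetry and
  well-position effects are out of scope.
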