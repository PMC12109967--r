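---
title: "Predicting TNF-inhibitor response from tmTNF reverse signaling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting TNF-inhibitor response from tmTNF reverse signaling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnfiRS)
```

## The assay

About a third of rheumatoid arthritis (RA) patients do not respond to TNF
inhibitors (TNFi), and no routine test predicts who will. Beyond
neutralizing soluble TNF, TNFi biologics bind the transmembrane precursor
tmTNF, which can itself transduce a signal into the tmTNF-bearing cell
("reverse signaling"). In monocyte-derived macrophages this signal
activates the transcription factor Nrf2 and induces an anti-inflammatory
gene program — but only in some individuals. The assay implemented here
exploits that dichotomy: monocytes drawn before therapy are stimulated ex
vivo for 16 h with the TNFi planned for treatment, and the induction of
CD36 plus six Nrf2 target genes (FBXO30, GABARA, HMOX1, LBR, MAFG, OSGIN1)
is measured by RT-qPCR against the unstimulated condition. Donors who
activate the program are expected to respond clinically to antibody-class
TNFi (adalimumab, golimumab, infliximab) at three months; the assay is not
informative for the soluble receptor etanercept.

`tnfiRS` implements the complete analysis path — quantitation,
classification, clinical-response mapping, and concordance scoring — plus
a calibrated simulator so every stage can be validated without patient
samples.

## Quantitation model

Expression is quantified by the comparative-Ct convention. For a target
gene with cycle thresholds $Ct$ measured treated (T) and untreated (NT),
normalized to GAPDH:

$$
\mathrm{ratio} \;=\; 2^{-\left[(Ct_{gene,T}-Ct_{GAPDH,T}) -
(Ct_{gene,NT}-Ct_{GAPDH,NT})\right]}
$$

Choices behind this path, where the underlying laboratory convention
admits more than one reading:

* **Formula.** The $2^{-\Delta\Delta Ct}$ form with assumed 100%
  amplification efficiency is the field standard for SYBR-green relative
  quantitation; no primer-efficiency correction is attempted
  (`fold_change()`).
* **Replicates.** Technical replicates are collapsed by *mean Ct* before
  the ratio is formed (`collapse_replicates()`), not by averaging
  per-replicate ratios. Averaging on the Ct scale matches duplicate-well
  practice and keeps dropout handling per well.
* **Non-amplification.** A well with Ct above 40 cycles (or missing) is
  not amplified. A gene is evaluable in a sample only if it amplified in
  both conditions; the mean is taken over amplified replicates only, so a
  single surviving replicate still yields a measurement.
* **No normalizer, no sample.** If GAPDH fails in either condition the
  sample is invalid and reported as such, never imputed
  (`build_profiles()$invalid`).

## The decision band and the classifier

Repeated quantification of one sample (94 repeats, technical duplicates)
puts the coefficient of variation of the assay's fold-change ratios at
0.06, the largest value across the panel's genes. We take CV = SD/mean
(`coefficient_of_variation()`). A measured ratio inside
$(1-\mathrm{CV},\,1+\mathrm{CV}) = (0.94, 1.06)$ is therefore
indistinguishable from "no modulation" (`cv_band()`).

`classify_activation()` applies the two-stage rule per sample:

1. **CD36 gate.** CD36 ratio strictly below 0.94 → *NonActivator*.
   Inside the band (boundaries included) → *Uncertain*: the printed rule
   covers only the strict inequalities, and borderline samples are
   explicitly re-assayed in practice, so boundary equality resolves to
   the deferring class rather than to a forced call.
2. **Nrf2 majority.** CD36 strictly above 1.06 → count the evaluable Nrf2
   genes with ratios strictly above 1.06. At least 50% → *Activator*,
   otherwise *NonActivator*. Non-amplified genes leave the denominator
   (the assay tolerates panel dropout between donors); with zero
   evaluable Nrf2 genes the 50% rule is undefined on an empty set and the
   call is *Uncertain*. The Nrf2 hit threshold equals the upper band edge,
   mirroring the CD36 gate.

A sample whose CD36 is itself non-evaluable is refused outright — the
gate cannot be applied, and silently recycling the Nrf2 stage would
change the algorithm.

`consensus_call()` merges repeated assays: decisive calls vote by
majority, *Uncertain* abstains, ties stay *Uncertain*.

## Clinical response and concordance

Response at month 3 is classified from DAS28 by the EULAR grid
(`eular_response()`): with improvement $\Delta = \mathrm{M0}-\mathrm{M3}$,
*Good* requires $\Delta > 1.2$ and attained DAS28 $\le 3.2$; *None* is
$\Delta \le 0.6$, or an intermediate improvement ending above 5.1;
everything else is *Moderate*. The cut-points (3.2 / 5.1 / 1.2 / 0.6) and
the responder mapping (Good or Moderate → responder) are configuration,
not constants: published criteria vary by DAS28 variant, and the packaged
cohort was scored with DAS28-CRP. On that cohort the recomputed grid
agrees with the recorded clinical evolution for 12 of 15 antibody-arm
patients; the three discordant rows (recorded non-response despite a
grid-level response) are surfaced by the tests rather than reconciled,
and the recorded evolution column — the clinician's judgment — is treated
as ground truth for prediction scoring throughout.

`concordance()` scores *Activator* = predicted responder against that
column. *Uncertain* calls have no printed scoring rule, so the policy is
explicit: `exclude` them from the denominator (default), `count_wrong`,
or `count_correct_if_positive` (an uncertain-leaning-positive call
counts as a positive prediction). The packaged antibody arm has no
uncertain calls, so its 14/15 (93.3%) concordance is policy-invariant;
the etanercept arm (2 concordant, 2 uncertain, 6 wrong out of 10) is
where the policies differ, and the evaluator reports all classes side by
side instead of resolving the ambiguity.

Cohort statistics use a two-sided Fisher exact test with the
point-probability (minimum-likelihood) convention — the convention that
reproduces the published baseline-table p-values (0.697 for sex, 0.428
for erosion); a midrank Mann–Whitney U with exact enumeration up to
combined n = 12 and a tie-corrected normal approximation (no continuity
correction) beyond; a standard paired t-test for treated-vs-untreated
panels; and quartiles at the $(n+1)p$ order statistic
(`stats::quantile` type 6), which reproduces the published IQR bounds
4.15–5.58 exactly. The percentile convention is exposed as
configuration.

## The simulator

`simulate_cohort()` generates Ct-level cohorts with the statistical
structure the assay assumes, so parameter-recovery and calibration tests
run against known ground truth.

* **Noise.** Measurement error is injected as independent Gaussian
  perturbations on the Ct scale — qPCR error is approximately normal in
  cycles — with the per-well SD derived in closed form so that the
  downstream ratio (four replicate-averaged Cts pushed through
  $2^{-\Delta\Delta Ct}$) is lognormal with CV exactly equal to
  `ratio_cv`:
  $\sigma_{Ct} = \sqrt{\log(1+\mathrm{CV}^2)}\,\sqrt{n_{rep}}/(2\log 2)$.
  The default `ratio_cv = 0.06` is the assay's calibrated CV. A
  10,000-donor run recovers the target CV within 10% (asserted in the
  tests; this size keeps the check under a few seconds).
* **Effects.** The fold-change center acts as a $-\log_2(\mathrm{effect})$
  shift on the treated-condition Ct of target genes; GAPDH is never moved
  by treatment, so the normalizer stays clean. The center is the *median*
  of the lognormal ratio (the mean exceeds it by a factor
  $e^{\sigma^2/2} \approx 1.002$ at CV 0.06 — negligible). Defaults:
  activators 1.5, non-activators 1.0 (no modulation), with a suppressed
  center (e.g. 0.85) available to exercise the low gate. Observed cohorts
  report fold changes only as bar means, so these are conventions a
  practitioner would call realistic, not estimates.
* **Dropout.** Each (sample, gene, condition) well group independently
  fails amplification with probability `dropout_prob` (default 0.05) and
  is recorded at Ct 45, past the 40-cycle cutoff. GAPDH dropout
  invalidates the sample, as in the real pipeline.
* **Clinical records.** Responder status equals the activation truth
  label with probability `concordance` (default 1). DAS28 pairs are drawn
  inside unambiguous EULAR cells — responders in the Good cell
  (improvement > 1.2, endpoint ≤ 3.2), non-responders at improvement
  ≤ 0.6 — so the EULAR mapping reproduces the assigned label exactly and
  label-recovery tests are not confounded by grid edge cases. Baselines
  are uniform on 3.5–6.5, the active-disease range of the packaged
  cohort.

What the simulator does **not** emulate: plate and batch effects, primer
efficiency differences, inter-gene correlation of induction within a
donor, day-to-day biological drift, and any realistic distribution of
effect sizes across donors. Passing recovery tests therefore demonstrate
that the decision algorithm is faithful to its specification under the
assay's own noise model — not that the assay generalizes to new
laboratories or cohorts.

## Numerical and degenerate-input choices

* Band edges and the 50% rule use the comparisons exactly as printed
  (strict at the gates, `>=` at the majority); no tolerance fuzzing is
  applied to ratios.
* Fisher ties use the conventional $1+10^{-7}$ relative tolerance when
  comparing table probabilities.
* The exact Mann–Whitney branch enumerates all
  $\binom{n_a+n_b}{n_a}$ assignments of the pooled midranks; two-sided p
  is the proportion of assignments at least as extreme (in $|U - n_an_b/2|$)
  as observed.
* Degenerate inputs fail loudly: empty groups, zero-variance differences,
  missing DAS28, mismatched patient sets (with the orphan ids named),
  non-positive Ct values, and a fixture checksum mismatch are all errors,
  not warnings.

## Known limitations

* **The indecision band consumes borderline donors.** A donor whose true
  CD36 modulation sits near the band — e.g. a suppressed non-activator at
  0.85, which is only $\log(0.94/0.85)/\sigma_{\log} \approx 1.7$ SD below
  the lower gate at CV 0.06 — lands inside the band in roughly 5% of
  assays and is deferred as *Uncertain* rather than labeled. Decisive
  calls remain essentially always correct; single-shot *label* recovery,
  however, cannot exceed ~95% for such donors, and only repeat assays
  merged by `consensus_call()` push it higher. This is a property of the
  published decision rule itself, not of the implementation.
* The etanercept arm is not predictable by this panel (all ten packaged
  patients responded regardless of prediction), and the package makes no
  attempt to fix that: per-class gene panels are out of scope.
* The EULAR grid cannot reproduce three of the fifteen recorded antibody
  outcomes; since the recorded evolution is the scoring ground truth,
  those rows are diagnostics, not errors.
* Thresholds are calibrated, never learned: the band comes from the
  assay CV, not from fitting the cohort.
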