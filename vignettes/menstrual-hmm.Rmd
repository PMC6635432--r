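---
title: "Methods: a ten-state menstrual HMM for sympto-thermal tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a ten-state menstrual HMM for sympto-thermal tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the data model,
the selection criteria, the hidden Markov model and its estimands, the
synthetic-data generator that stands in for the proprietary app datasets,
and the numerical and design choices made where the problem left them open.

## 1. Data model and app dialects

The unit of analysis is a *cycle*: the ordered days from the first day of
menses to the day before the next menses. Each logged day carries up to
seven observations — basal body temperature (BBT) with measurement time and
an optional "questionable" flag, bleeding intensity, cervical mucus
category and quantity, cervix height/firmness/openness, vaginal sensation,
and sexual-intercourse events. Two app dialects are supported besides the
canonical CSV layout:

* **Sympto** reports temperature in °C at 0.05 precision with half-hour
  times, bleeding as a 1–3 score, mucus on a two-level scale, the cervix as
  a single three-level score, and folds withdrawal into unprotected sex.
* **Kindara** reports temperature in °F at 0.01 precision with minute
  times and a questionable-temperature flag, full mucus category × quantity,
  three separate cervix axes, four sensation levels, and separate
  withdrawal/insemination tokens.

Everything is normalized into one canonical vocabulary; temperatures are
converted to °C without rounding (rounding happens only at write time, at
each dialect's native precision). Two mappings deserve comment because no
cross-app correspondence is documented anywhere:

* Sympto's two mucus levels are canonicalized as (creamy, little) and
  (eggwhite, lots). This preserves the low/high-fertility grouping used in
  the frequency profiles without inventing granularity the app never
  recorded.
* Sympto's sensation levels dry/wet/very-wet map to dry/wet-moist/
  wet-lubricative. This is a pragmatic alignment, not a claim of semantic
  equivalence; analyses that depend on sensation should treat the two apps
  separately.

Days with no logged field are omitted from the day table (tracking
frequency counts stored days), but they remain time steps for the HMM.

## 2. Standard-cycle selection

Real self-tracked data contain on-going cycles, abandoned tracking and
bleeding-only logs. A cycle is *standard* when it is not the user's first
cycle nor their chronologically last one (a proxy for on-going cycles in
the absence of timestamps); no observation gap exceeds 15 days — gaps are
measured between consecutive logged days *and* from day 1 to the first
logged day and from the last logged day to the cycle end, the conservative
reading of a "gap within a cycle"; at least one FAM body sign (BBT, mucus
or cervix) was recorded; and, for cycles over 40 days, no mid-cycle
period-like bleeding occurred. Kindara cycles additionally need at least 8
FAM observation-days and a length of at least bleeding-days + 4; Sympto
cycles must be flagged ovulatory by the app's own sympto-thermal algorithm
and carry no breastfeeding/peri-menopause declaration.

Two terms in those rules are not defined by the data dictionaries and are
operationalized here:

* *Mid-cycle period-like bleeding*: ≥ 2 consecutive days of medium-or-
  heavier bleeding starting after day 7 and ending before the last 5 days.
  This separates a missed cycle boundary (a menses-like event) from
  ovulatory spotting without external information.
* *Sympto ovulatory determination*: the app's algorithm is proprietary and
  is **not** reimplemented. The pipeline accepts a per-cycle flag; when the
  flag is absent a clearly-labelled proxy stands in (three consecutive
  logged BBT values at least 0.15 °C above the cycle's reference
  temperature, i.e. a sustained rise exists).

Whether the breastfeeding/peri-menopause declarations are per-cycle or
per-user is likewise unstated; they are treated as per-cycle booleans with
absent meaning false.

## 3. Descriptive profiles

The ovulation signal in temperature is relative, not absolute, so each
cycle gets a *reference temperature*: the 25th percentile of its usable BBT
values, and ΔBBT = BBT − reference. Two conventions are deliberate:

* The quantile uses linear interpolation between order statistics
  (`stats::quantile` type 7), the common scientific-software default; the
  choice is configurable in the sense that the function is small and
  isolated, and it matters only at the 0.01 °C level.
* BBT values flagged questionable are excluded from both the reference and
  ΔBBT — the flag exists to mark unreliable readings.

Profiles aggregate per cycle-day, counted either from the cycle start
(first menses day = 1) or from the cycle end (last day = −1); the from-end
indexing is the informative one for ovulation-related signs because luteal
duration varies less than follicular duration. Category frequencies divide
by the **total number of standard cycles**, not by the per-day reporting
count, so sparsely tracked days correctly show low frequencies. Mucus is
collapsed into fertility grades: *high* = large egg-white-like plus
medium-or-large watery; *low* = everything else observed (little watery,
little/medium egg-white, any sticky or creamy; an egg-white or watery
observation with no quantity is read as low). Profiles default to 40 days
of depth from either end; longer cycles contribute their in-range days.

## 4. The hidden Markov model

### States and transitions

Ten states discretize the hormonal events: HM (menses onset, heavy/medium
flow), LM (light bleeding/spotting ending menses), LE (low estrogen), HE
(high estrogen), Ovu (ovulation), Rise (the progesterone-driven BBT rise),
HP (high progesterone), EP (the luteal estrogen peak), LP (low
progesterone) and End (an artificial absorbing end-of-cycle state). Only
forward transitions along that order, plus self-loops, carry mass.
Transitions are *quasi-uniform*: from each state the non-self mass is
spread over the allowed moves, and self-loop masses are set so the
geometric expected dwell times are HM ≈ 3 d, LM ≈ 2 d, LE ≈ 5 d, HE ≈ 4 d,
Rise ≈ 2 d, HP ≈ 6 d, EP ≈ 2 d, LP ≈ 4 d. Three structural choices:

* **Ovu has zero self-transition**, so "the ovulation day" is a single
  well-defined day.
* **End is absorbing and enterable only from EP/LP**, and the final day is
  *not* forced into it: the cycle boundary is defined by the next menses,
  which is not an observation of this cycle (right-censoring).
* **LM and EP can be skipped** with small probability (HM→LE, HP→LP).
  Whether the true process allows these skips is not observable from the
  data at hand; allowing them with low mass is the permissive default, and
  all tables ship in an editable YAML spec (`write_hmm_spec()` /
  `read_hmm_spec()`) so users can substitute their own.

The initial distribution reflects each app's cycle-start convention: Sympto
starts a cycle only on a recorded heavy-bleeding day, so all initial mass
sits on HM; Kindara starts are self-assessed, so mass is spread 0.9/0.1
over HM/LM.

### Emissions

Features are conditionally independent given the state (the standard HMM
factorization; no dependence structure is claimed by any source on these
data). ΔBBT is Gaussian per state — mean 0 in HM…Ovu, +0.36 °C in HP/EP,
+0.32 °C in LP (a slight end-of-cycle decline), +0.18 °C in Rise with a
wider sd, sd 0.15 °C elsewhere. Bleeding, mucus fertility grade, cervix
openness and sensation are categorical per state; heavy/medium bleeding has
zero mass outside HM (and medium a small mass in LM), high-fertility mucus
peaks in HE/Ovu. The exact tables are this package's own defaults, chosen
to encode the qualitative physiology above; no published emission tables
exist for these data. Every operation takes the spec explicitly.

**Missing data.** A missing feature contributes likelihood 1 (log 0):
missing-at-random marginalization. A fully unlogged day is a time step with
all features missing — the chain advances, which is what lets the model
bridge tracking gaps and still date ovulation.

### Decoding

Viterbi runs in log space; ties break toward the earlier state in chain
order (deterministic and physiologically conservative). The
forward–backward pass uses scaled (per-day normalized) recursions, the
numerically equivalent alternative to log-space that keeps the inner loop
in plain matrix arithmetic; posteriors are exact to the enumeration oracle
at 1e-9 and cycles of 120 days decode without underflow. An observation
sequence with no positive-probability path (possible only with user-edited
emission tables) raises "cycle inconsistent with model" rather than
returning garbage.

### Estimands

* **Ovulation day**: argmax over days of the Ovu posterior mass, earliest
  day on ties.
* **Uncertainty**: the sd of the day index under the normalized Ovu mass —
  a point-mass posterior gives 0; mass split evenly over 3 adjacent days
  gives √(2/3) ≈ 0.82 d.
* **Confidence score** (window = ovulation day ± 2, clipped):
  0.5 × (fraction of window days with BBT) + 0.3 × (fraction with mucus) +
  0.2 × max(0, 1 − sd(BBT times)/60 min). The ingredients (missingness and
  temperature-taking-time variation in a ~5-day window) are dictated by the
  problem; the weights and the centering of the window are this package's
  documented defaults, exposed as arguments. Fewer than two timed readings
  give time-consistency 1 (no inconsistency observed); a window with
  neither BBT nor mucus scores 0.
* **Temperature shift**: median ΔBBT over days [ovu+2, ovu+6] minus median
  over [ovu−5, ovu−1], each window requiring ≥ 2 BBT values. When an
  estimate near the cycle boundary clips a window below 2 values the shift
  is absent and the cycle fails the gate with reason `temp_shift` — absence
  of evidence for a shift is treated as failure, not as a pass.

The **reliability gate** (uncertainty ≤ 1.5 d, shift ≥ 0.15 °C, confidence
≥ 0.75; thresholds inclusive, in canonical °C with 0.27 °F being purely a
conversion) is monotone by construction: improving any component can never
flip a reliable cycle to unreliable.

## 5. The synthetic-data generator

The generator produces cohorts with known ground truth by sampling phase
durations directly and laying down the true state sequence — **not** by
simulating the inference model's transition matrix. Generator and estimator
therefore share no parameters, and parameter-recovery results are
meaningful rather than circular.

Defaults, fixed once as the study conditions this analysis assumes:

| quantity | default | rationale |
|---|---|---|
| users / cycles per user | 50 / 4 + NB(size 2, μ 3) | app users in scope have ≥ 4 cycles |
| follicular length | round lognormal, median 16 d, sdlog 0.26 | ~90% of ovulations between day 10 and 24 |
| luteal length | discrete on 7–17 d, median 13, sd ≈ 2.3 | 15% of cycles ≤ 10 d, so the short-luteal regime is exercised |
| BBT baseline / shift / noise | 36.4 / 0.36 / 0.15 °C | biphasic BBT with the canonical post-ovulatory shift |
| menses | HM 1–3 d then LM 1–3 d, heavy→light | menses start the cycle |
| terminal spotting | p = 0.15, 1–2 days, −0.08 °C BBT dip | end-of-cycle spotting with a small temperature decline |
| BBT time | per-user habit ± 45 min, daily jitter sd 20 min | feeds the confidence score only; the time-of-day temperature slope defaults to 0 °C/h |
| mucus misreport | p = 0.05 | observation error; no published error rates exist, the value is a placeholder, not a claim |
| logging probabilities | by goal, e.g. conception: BBT 0.90, mucus 0.80, bleeding 0.95 | conception-oriented users track more densely |

The Rise state ramps BBT fractionally across its 1–2 days, so the "noiseless
shift is exact" property is stated on the plateaus: with noise sd 0 and
full logging, mean BBT over HP/EP/LP days minus mean over pre-ovulation
days equals the configured shift to machine precision.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: pregnancies, post-partum/breastfeeding and
peri-menopausal episodes; between-cycle correlation within a user (cycle
lengths are drawn independently); realistic tracking *patterns* (real users
batch, lapse and resume; the generator masks days independently, and its
default cohorts track more densely than typical app users); calendar-time
effects; and any systematic BBT measurement bias beyond Gaussian noise.
Anovulatory cycles are supported (`anovulatory_cycle_prob`) but default to
0, matching a pipeline whose inputs are app-declared ovulatory or
gate-filtered cycles.

## 6. Problem sizes and test design

The distribution-level tests use cohorts sized to make their statistics
stable while keeping the default suite quick: 500 cycles (an 80-user
default-config cohort, fixed seed) for ovulation recovery, gate behaviour,
transition-perturbation robustness (3 perturbation draws × 300 reliable
cycles), emission-shift sensitivity and the missing-data asymmetry; 2 000
cycles for the phase-length goodness-of-fit checks; 50 random ≤ 9-day
fixtures for the exact-decoding oracle, which compares Viterbi and
forward–backward output against exhaustive enumeration over all valid
forward-only paths. Degenerate inputs are tested explicitly: empty files,
cycles with no BBT (absent reference), one-day cycles, boundary ovulation
estimates, zero-probability observation sequences.

## 7. Known limitations

* The emission/transition tables are qualitative encodings, not fitted
  parameters; parameter fitting (Baum–Welch) is deliberately out of scope
  because the estimator is meant to work a priori, and the robustness
  property (estimates stable under transition perturbation, sensitive to
  emission means) is what justifies shipping fixed tables.
* The confidence-score weights are plausibility choices; downstream users
  comparing gate pass rates across cohorts with different tracking habits
  should check sensitivity to them.
* Sympto's fertile-window algorithm is not reproduced; the proxy flag only
  captures its temperature criterion.
* The cohort-count table reproduces published dataset sizes for the two
  real apps for arithmetic cross-checks; the published sources report two
  different reliable-cycle counts for Sympto in different places (28,453
  and 24,119) — the table uses the former, and nothing in this package can
  adjudicate the discrepancy.
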