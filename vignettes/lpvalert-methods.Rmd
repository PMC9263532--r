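---
title: "Methods: a rule-based alerting engine for possible ARDS without lung-protective ventilation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a rule-based alerting engine for possible ARDS without lung-protective ventilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpvalert)
```

## The screening problem

Acute respiratory distress syndrome (ARDS) is under-recognized in the ICU,
and even recognized ARDS is often ventilated outside lung-protective
ventilation (LPV) targets. `lpvalert` implements a desk-scale,
fully auditable version of a clinical decision support "sniffer": an
event-driven engine that watches an encounter's charting stream, detects
*possible ARDS* from two Berlin-criteria components (bilateral infiltrates
on the chest-radiograph report, and qualifying hypoxemia by the
altitude-adjusted PaO~2~/FiO~2~ ratio), checks whether current treatment
already follows the computerized ventilation/oxygenation protocols, and
alerts treating clinicians only when it does not. Conditioning the alert on
*treatment* detection, not just *disease* detection, is the design's
alert-fatigue control: alerts that would merely confirm adherent care are
never sent.

The engine is deliberately rule-based end to end. Every decision — trigger,
inclusion, exclusion, text classification, adherence, suppression — is
recorded with its full reason list in replayable ledgers.

## Trigger logic

A cycle starts when a PaO~2~ is charted or a new chest radiograph arrives.
The P/F ratio pairs the new PaO~2~ with the most recent charted FiO~2~ at
or before it (the standard EHR convention; a radiograph triggers with the
most recent computable pair). The adjusted ratio is

$$\mathrm{P/F_{adj}} = \frac{\mathrm{PaO_2}}{\mathrm{FiO_2}}
  \cdot \frac{760}{P_b},$$

with barometric pressure $P_b$ configurable and defaulting to 760 mmHg, a
no-op: the default threshold of 255 mmHg is itself already an
altitude-adjusted rendering of the 300 mmHg Berlin cutoff
($300 \times 646/760 \approx 255$ at mountain altitude), so applying a
second adjustment by default would double-count.

Inclusion requires all of: age ≥ 18 years, a ventilator mode charted
< 168 h ago, adjusted P/F ≤ 255 (the threshold is inclusive; where source
material is ambiguous between `<` and `≤` we follow the tabulated logic,
which is the operational form), and intubation within the last 96 h.
Windows are measured in hours from the event timestamp, never in calendar
days, and all timestamps are held in UTC, because the 16-hour and 2-hour
windows downstream must be unambiguous. Exclusions (pediatric ICU,
palliative care, cardiothoracic attending, mechanical circulatory support,
T-piece/tracheostomy-mask breathing, pulmonary artery catheter) are
evaluated independently, and *every* failed criterion is reported, not just
the first — the audit trail is part of the contract. A patient charted as
intubated with no intubation time on record fails that criterion
explicitly with an `unknown` reason rather than being guessed at.

## The infiltrate detector

The production system this emulates used an NLP model whose internals are
not public. The package therefore ships a deterministic lexical stand-in
behind a pluggable interface: `run_cds_engine(detector = ...)` accepts any
function returning a `positive` flag, and everything downstream depends
only on that result. The stand-in's discriminatory performance is a
property of the stand-in, not a reproduction of any field NLP system.

The rules are a YAML lexicon (`inst/extdata/infiltrate_rules.yaml`):
a report is positive when an infiltrate term (*infiltrate(s), opacity/ies,
consolidation(s), airspace disease, ...*) and a laterality term
(*bilateral(ly), both lungs, right and left, ...*) co-occur in one
sentence within six tokens, with neither term inside a negation scope.
Negation cues (*no, without, no evidence of, resolution of, ...*) negate up
to five following tokens, ending early at a conjunction (*but, however*) or
a sentence boundary — a NegEx-style scope rule. Hedged findings
(*possible, cannot exclude*) keep positive polarity: the tool screens for
*possible* ARDS, so the rules err toward sensitivity. Tokenization is
whitespace/punctuation based and deterministic.

The classifier's acceptance oracle is a hand-labelled synthetic corpus of
72 templated reports (positive / hedged / negated / clear), shipped at
`inst/extdata/infiltrate_corpus.tsv`; the test suite requires 100%
agreement, and a monotonicity property (appending non-negated irrelevant
text never flips a positive to negative).

## LPV adherence checks

Given a positive detection, the engine re-checks the qualifying P/F ratio
at assessment time (the treatment-detection stage re-states the ≤ 255
requirement, and we implement it as a genuine re-check) and then runs four
rule families against the latest state. Exactly nine recommendation types
exist, partitioned into seven *adopt-protocol* types and two
*specific-setting* types:

* **Protocol orders** — neither protocol ordered yields the combined
  recommendation; a single missing protocol yields its specific type; the
  outputs are mutually exclusive.
* **Mode rules** — CPAP/PS is inappropriate when PEEP > 10 cmH~2~O,
  FiO~2~ > 0.50 or PS > 15 cmH~2~O (any branch). An inappropriate CPAP/PS
  additionally carries the companion advice to change to volume-control
  mode — in the deployment's adherence table these two recommendation
  types have identical counts, which is exactly the pairing this rule
  produces. Other modes are classed by configuration: compliant
  (volume control, by default), standard-but-noncompliant
  (pressure control, SIMV), and nonstandard (APRV, HFOV, anything
  unrecognized).
* **PEEP/FiO~2~ grid** — the charted FiO~2~ maps to the nearest grid level
  not above it; the combination is adherent when the charted PEEP is
  within ±1 cmH~2~O of an allowed value. The shipped grids are the public
  ARDSNet lower-PEEP and higher-PEEP tables
  (`inst/extdata/peep_fio2_grids.yaml`); the deployed protocol's exact
  grid is proprietary, so the check *structure* (editable YAML, level
  lookup, tolerance) is the contract, not the cell values.
* **Tidal volume** — predicted body weight uses the Devine formulas
  (male $50 + 0.91(h - 152.4)$ kg, female $45.5 + 0.91(h-152.4)$ kg,
  floored at 20 kg); a recommendation fires when Vt/PBW strictly exceeds
  6.5 mL/kg. The deployment never printed its cutoff; 6.5 mL/kg is the
  conventional low-tidal-volume adherence bound and it is configurable.
  With missing sex or height the check is skipped and flagged — PBW is
  undefined and is never imputed.

An event is LPV-adherent exactly when no recommendation applies; with no
ventilator settings ever charted the status is indeterminate and no event
is emitted. `assess_lpv()` is a pure function of (state, config), and
tightening any threshold can only add recommendations — both are tested.

## Alert lifecycle

A nonadherent possible-ARDS event makes the encounter *pending*. Alerts
deliver at chart-open, only to treating physicians and advanced practice
providers, and only if the clinician's rolling 16-hour window allows it
("once per shift"): we anchor the window to the last delivery per clinician
rather than to shift clock times, because that is deterministic without a
shift calendar. A clinician may be reminded at chart-close if at least one
delivered recommendation is unaddressed; "addressed" means a response was
recorded or the recommendation-specific check now passes — the same rule
used for adherence classification, applied to the session.

Responses are typed: ordering the protocol or acting on instructions never
changes suppression; *not ARDS* or a contraindication (elevated
intracranial pressure, status asthmaticus, severe COPD, or free-text
other) permanently suppresses alerts for the patient, for all clinicians,
for the remainder of the encounter — an absorbing state, verified by
randomized replay. Suppression is per encounter; whether it should persist
across a patient's later encounters is unspecified in the source design,
and per-encounter is the conservative reading. New biomedical data can
re-evoke the cycle at any time: an adherent re-evaluation clears the
pending state, a nonadherent one refreshes it.

## Service-outcome statistics

* **Initial guideline nonadherence** — encounters with ≥ 1 nonadherent
  possible-ARDS event divided by encounters with ≥ 1 trigger event
  (encounters, not events, in both positions).
* **Recommendation adherence** — followed recommendations over all
  delivered recommendations. A recommendation is *followed* when a
  consistent change (the relevant order, or settings moved into
  compliance) occurs within the adherence window after delivery; the
  window defaults to 120 minutes and is configurable because the source
  description hedges with "usually". Classification replays the stream
  and re-evaluates the recommendation-specific check at each charting
  event in the window.
* **Alerts prevented** — per site,
  $(\text{possible} - \text{nonadherent}) \times
  \text{alerts}/\text{nonadherent}$, summed; sites with no nonadherent
  events contribute zero; the percentage relates prevented alerts to the
  total under disease-detection-only alerting.
* **Binomial intervals** — both Clopper–Pearson (beta quantiles) and Wald
  are implemented and labelled. Deployed tools of this kind describe their
  intervals as "binomial exact" while their reported survey intervals
  follow Wald arithmetic and their contingency-metric intervals the exact
  form; implementing both, with the method recorded in the result,
  reproduces either rendering without misrepresenting the methodology.
* **Two-proportion contrast** — unpooled Wald interval, pooled z test; a
  degenerate zero standard error gets a 0.5-count continuity floor.
* **AUROC** — for a binary screen the nonparametric area is the
  tie-credited pairwise probability
  $A = (tp \cdot tn + \tfrac12(tp \cdot fp + fn \cdot tn))/(n_+ n_-)$,
  with the Hanley–McNeil standard error
  ($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$). The closed form is verified
  against an exhaustive pairwise-comparison oracle for every contingency
  table with total ≤ 40.
* Report rendering rounds half away from zero at the printed precision
  (one decimal for tables, whole percent for prose).

## The synthetic cohort generator

No patient data ships with or is needed by the package: `cohort_spec()` /
`generate_cohort()` produce a seeded, schema-valid event stream with
planted labels written to a sidecar the engine never reads — enforcing
that the engine sees only what a production system would see.

Defaults are the study conditions the generator emulates: 38% of
trigger-bearing encounters have a nonadherent episode; specific-setting
recommendations are followed with probability 0.65 and adopt-protocol
recommendations 0.14; violations are drawn with weights matching the
deployed tool's recommendation mix; encounters average three trigger
events; the site mix follows the tertiary-site encounter distribution.
Encounter-level possible-ARDS prevalence defaults to 0.60 — the source
reports an event-level rate near 0.50 and an encounter-level nonadherence
rate of 0.38, so the encounter-level prevalence must exceed 0.38; 0.60 is
a realistic middle value and is configurable. Nonadherence is planted at
encounter level against the trigger-encounter denominator, so the planted
0.38 is exactly the quantity the initial-nonadherence formula measures.
Corrective changes land uniformly 5–115 minutes after alert delivery when
followed and 125–175 minutes when not, so both outcomes occur on either
side of the 120-minute window; a fraction of non-followed alerts draw a
"not ARDS" or contraindication response, exercising permanent suppression
inside realistic streams.

What the generator does *not* emulate: physiological gas-exchange
trajectories (values are sampled to satisfy or violate thresholds),
free-text variety beyond the template families (the detector is exact on
templated text, so synthetic accuracy blocks show a perfect screen — a
property of the stand-in, not a field result), inter-encounter patient
identity, and shift calendars. Passing tests therefore demonstrate the
engine's logic and the estimators' correctness, not field performance of
any NLP component.

## Verification strategy and problem sizes

The suite combines worked arithmetic oracles (hand-checked P/F, PBW, CI
and adherence values), property tests (threshold monotonicity, absorbing
suppression and the 16-hour rate bound over 10^4^ randomized delivery
histories, byte-identical round-trips, determinism), and dual-route
checks: an independent brute-force re-evaluation of the full trigger table
over every stream prefix is compared with the incremental engine on
randomized streams of up to 50 events, and the AUROC closed form is
compared with exhaustive pairwise enumeration. Parameter recovery runs the
full pipeline on a 2000-encounter cohort and requires the planted
nonadherence and follow probabilities back within three binomial standard
errors; 2000 encounters keeps the Monte-Carlo error a few percentage
points while the whole suite stays desk-scale.

## Known limitations

* The infiltrate detector is a lexical stand-in; its sensitivity and
  predictive value on real radiology reports are unknown and not claimed.
* The PEEP/FiO~2~ grids are the public ARDSNet tables, not any
  institution's proprietary titration protocol.
* Weaning assessment and spontaneous-breathing-trial subprotocols are not
  adherence-checked; no rule content for them is defined.
* The alert catalogue is the nine-type recommendation taxonomy; richer
  per-message alert-code composition is out of scope.
* Suppression state does not persist across encounters of the same
  patient.
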