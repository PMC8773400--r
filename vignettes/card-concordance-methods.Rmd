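---
title: "Methods: reciprocity and concordance of BLE card and interview contact data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reciprocity and concordance of BLE card and interview contact data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardtrace)
```

## The problem

Contact tracing needs a list of who met whom. The traditional instrument is
the case investigation: an interviewer asks a case to recall, for each of
the preceding days, the people they met and for how long. The candidate
replacement is a worn BLE beacon ("card") that scans for peers every 15
seconds and logs the received signal strength (RSSI). Neither instrument
observes the ground truth. What *can* be measured is internal consistency —
when I log you, do you log me? — and cross-instrument concordance — of the
contacts people reported, how many did the cards see, and vice versa.

`cardtrace` implements that comparison as a reusable pipeline: a
synthetic-data generator that emulates the data-generating process, the
card-data reduction chain, reciprocity statistics on the resulting directed
networks, grouped-binomial trend models, and confusion-matrix concordance.
This vignette records the models, the tunable parameters, and the design
choices made where the published record of the motivating deployment is
silent.

## The radio model and proximity classes

RSSI at distance $d$ follows a log-distance path-loss model:

$$\mathrm{RSSI}(d) = \mathrm{RSSI}_{1\mathrm{m}} - 20\log_{10}(d) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

rounded to integer dBm. The card firmware discretises signal into proximity
classes with boundaries at $-50$, $-56$ and $-62$ dBm. With the calibration
$\mathrm{RSSI}_{1\mathrm{m}} = -50$ dBm, these correspond to 1 m
($-50$), 2 m ($-56.02$) and 4 m ($-62.04$): this is the unique calibration
of the path-loss model consistent with the published class table (class 0:
0–1 m; class 1: 1–2 m; class 2: 2–4 m), and it is why the generator caps
true contact distances at 4 m — beyond that, a noiseless reading cannot
clear the $-62$ dBm storage floor. Readings above the $-20$ dBm hardware
ceiling are clamped into class 0 rather than discarded: the ceiling is a
saturation limit, not a filter.

The generator's default noise is $\sigma = 4$ dBm, a mid-range figure for
body-worn BLE in the field; set `rssi_noise_sd = 0` to make class recovery
exact (the test suite exploits this).

## The card reduction chain

1. **2-minute windows.** Windows align to a 2-minute grid from the top of
   the hour (the firmware's alignment is unpublished; a fixed grid makes
   the reduction deterministic). A window is stored only if *all eight*
   15-second slots contain a reading at or above $-62$ dBm. The published
   description — not stored if signal "was not obtained continuously for
   2 min or was less than $-62$ dBm" — is ambiguous about whether the floor
   applies to every reading or to the window maximum; we apply it per
   reading, since sub-floor readings fall outside the class table's support
   and cannot contribute to any class. Duplicate readings in one slot keep
   the maximum, with a warning. The stored class is
   `classify_proximity(max RSSI in window)`.
2. **2-hour blocks** at even local hours, then **daily records** at local
   midnight, each a pure count aggregation: 2-minute record counts per
   class, times two, give minutes per class per directed dyad per day.
   Aggregation conserves counts at every level (property-tested against a
   brute-force recount).
3. **Cohort filters.** The symmetric-role filter removes cards that only
   ever observed or were only ever observed — they cannot corroborate
   anything. It runs in a single pass, not to a fixed point: removals can
   leave other cards one-sided, and those are kept, matching a one-shot
   filter whose removal counts are reported once. The boundary-day trim
   then drops the first and last trial days (roll-out and collection
   artifacts), reporting cards left without records. The order — roles,
   then days — matters for the removal counts and follows the deployment's
   reported sequence.

## The interview model

Interviewed participants report each true contact event independently with
probability `p_report` (default 0.65); a recalled event's date shifts one
day earlier or later with probability `p_date_shift` (default 0.05),
clamped at the trial boundaries rather than wrapped. Repeated same-day
contacts with one person collapse to a single report (interviewers record
at most one contact event per person per day); reports across days stay
separate. No published recall or compliance rates exist for the motivating
deployment, so these defaults are free parameters chosen as plausible
field values and exposed in `generator_config()`.

Under this model, a dyad with both members interviewed is mutual with
probability $p^2$ and asymmetric with probability $2p(1-p)$, so the
report-network reciprocity satisfies $r = p$ — the basis of the
parameter-recovery property test at 500 dyads.

**Date reassignment.** The sensitivity procedure for misremembered dates
moves an unreciprocated edge $i \to j$ on day $d$ to $d \pm 1$ only if (a)
$i$ reported no contact with $j$ on the adjacent day and (b) $j$ reported
contact with $i$ there. All conditions are evaluated against the original
network and the moves are applied simultaneously — a one-shot adjustment
with no cascading, so a moved edge cannot newly qualify a neighbour. When
both adjacent days qualify, the earlier day wins (`prefer = "earlier"`,
configurable); the choice is arbitrary but deterministic. One consequence
of strict simultaneity: if two unreciprocated edges sit on adjacent days
pointing at each other, both qualify and they swap days without creating a
mutual dyad. The alternative — pairing edges and moving only one — requires
its own arbitrary choice of which; we keep the simultaneous rule because it
is order-independent and verified by exhaustive enumeration of all
two-node, three-day configurations. Either way the adjustment never
destroys a mutual dyad and never changes the edge count.

## Reciprocity statistics

For a directed network with adjacency matrix $A$ on $N$ nodes, every
unordered pair is mutual, asymmetric or null; with $m$ mutual and $a$
asymmetric pairs,

$$r = \frac{2m}{2m + a}, \qquad
\hat\sigma_r = \sqrt{\frac{r(1-r)}{n}}, \quad n = \|A\|,$$

and the Garlaschelli–Loffredo density-adjusted measure is

$$\hat\rho = \frac{r - \bar a}{1 - \bar a}, \qquad
\bar a = \frac{\|A\|}{N(N-1)}.$$

$\hat\rho$ is zero when reciprocation is at the chance level implied by the
density, and tends to $r$ as $\bar a \to 0$. The density uses the
*explicit* node set: isolated nodes count. For the shipped trial summaries
this means $N = 736$ for the card network (cards surviving the
symmetric-role filter, before the day trim) and $N = 65$ for the interview
network (all retained interviewees, though only 23 appear in reciprocity
edges) — the only node sets whose densities reproduce the published
$\hat\rho$ values to four decimals, which is itself asserted in the test
suite.

The jackknife standard error is the leave-one-dyad-out form

$$\hat\sigma_\rho = \sqrt{\sum_{i<j}\left(\hat\rho_{-(ij)} - \hat\rho\right)^2},$$

where $\hat\rho_{-(ij)}$ zeroes both $a_{ij}$ and $a_{ji}$. Null dyads
leave $\hat\rho$ unchanged and contribute nothing; all mutual deletions
share one value and all asymmetric deletions another, so the sum collapses
to a closed form in $(m, a, N)$ — verified against the brute-force
$O(N^2)$ loop. We note that jackknifing over *nodes* instead of dyads
yields systematically larger values; this package reports the dyad form,
as defined above.

Pooling days sums reciprocated and total edge counts. The Wald interval
$r \pm z\sqrt{r(1-r)/n}$ suits the card network's thousands of edges; the
Agresti–Coull interval (add $z^2/2$ successes and $z^2$ trials first) is
reported alongside for the interview network's daily counts of 11–16.

## Trend models

Daily reciprocity is modelled as grouped-binomial counts
(reciprocated/total) with a logistic link:

- Model 1: `dataset + day`
- Model 2: `dataset + day + day²`
- Model 3: Model 2 plus `dataset × day` and `dataset × day²`

fitted by IRLS on 12 rows (5 card days, days 2–6; 7 interview days). The
day polynomial is, by default, the orthonormal basis over the observed rows
(`stats::poly`); a raw-power basis is available, and the quantities the
package reports as results — deviances, likelihood-ratio statistics
$G^2 = D_\text{small} - D_\text{large}$, and the dataset odds ratio
$e^{\beta_\text{dataset}}$ — are invariant to that choice (asserted to
$10^{-6}$). Coefficients of the day terms are basis-specific and are
printed with labelled columns for that reason. The dataset main effect is
*not* basis-invariant in Model 3, where interactions make it the effect at
"day zero" of whichever basis is in use — another reason inference rests
on Model 2, which the likelihood-ratio tests select.

Counts enter the models via `reconstruct_reciprocity_counts()`: published
tables print $r$ to four decimals next to the integer edge total $n$, so
the reciprocated count is recovered exactly as $\mathrm{round}(r \cdot n)$
and the function verifies that each reconstruction rounds back to the
printed $r$, refusing to proceed otherwise.

## Concordance

The confusion-matrix universe is every ordered (reporter, other, day)
triple with reporters in the interviewed cohort, others in the card node
set, over the analysis days — self-pairs included. For the shipped
summaries this gives $65 \times 736 \times 5 = 239{,}200$ pair-days,
exactly the sum of each published matrix; excluding self-pairs
($65 \times 735 \times 5$) does not, which is why the universe is defined
this way. A pair-day is card-positive when either direction's daily record
has non-zero minutes over the chosen class set — reports are
direction-agnostic, so detection is too — and report-positive when the
reporter reported that contact that day. Reported contacts are the "truth"
margin by convention, so the report margin (`tp + fn`) is constant across
class-set choices, and widening the class set can only move pair-days from
negative to card-positive: true and false positive rates are both
non-decreasing in the threshold, a partial ROC over the three contact
definitions.

Non-compliance has two signatures: reporters whose cards logged nothing on
a day (the card stayed home), and unreported dyad-days with $\ge 22$ h at
class 0 (two cards left together at home). The generator reproduces the
second deliberately: a flagged household-day forces its members' wear
indicators off and emits a full day of close-range readings between their
cards, which the pipeline turns into 1,440-minute class-0 records.

## Synthetic-trial defaults and what they do not emulate

The generator's defaults describe a cohort of 700 over 7 days, 13% of whom
are interviewed; households of size 1–6 (mean ≈ 2.4) with an extra
within-household contact process; 1.5 community contact events per
participant per day at distances mixed 50/30/20 over the three class
bands; log-normal durations (median 15 min, floor 2 min); wear compliance
decaying from 0.92 to 0.70 over the week; and a 15% per-household-day
card-left-home probability. These are realistic field values, not
published ones — the deployment released no compliance or recall rates —
so recovering them in tests demonstrates the pipeline's correctness, not
fidelity to any particular trial.

Deliberately not modelled: multipath and body-shadowing radio effects
(noise is i.i.d. Gaussian on the log scale), pseudonym rotation and
cryptography, battery and memory limits, interviewer-behaviour differences,
and contact events crossing midnight. Passing tests therefore show the
reduction and statistics are right, not that real RSSI maps cleanly to
distance — the motivating literature is clear that it often does not.

## Numerical choices and problem sizes

IRLS runs to a relative deviance tolerance of $10^{-12}$ (maximum 100
iterations), errors on non-convergence or boundary fitted probabilities,
and is cross-checked against a generic BFGS maximiser of the binomial
log-likelihood. Statistics are computed at full precision and rounded only
for display (tables print to 4 decimals). Seeded generator runs are
bit-reproducible; each operation draws from its own stream derived from the
configuration seed, so adding draws to one operation does not perturb the
others. The test suite exercises networks of up to 200 nodes against
$O(N^2)$ oracles, 500-dyad recall recovery, and Monte-Carlo rate checks at
60 replicates — sizes chosen to estimate each property's Monte-Carlo error
well while keeping the whole suite near ten seconds.

## Known limitations

- The dyad-level jackknife is the printed estimator, but no closed-form
  reference distribution accompanies it; treat $\hat\sigma_\rho$ as
  descriptive.
- Reconstruction from rounded tables is exact for counts but cannot
  recover which specific dyads were mutual; statistics that depend only on
  the census are exact, anything dyad-identity-dependent is out of reach.
- The simultaneous date-reassignment rule can swap a facing pair of
  misdated edges without creating a mutual dyad (discussed above).
- With heavy RSSI noise the per-direction detection probability depends on
  the full window process and has no closed form; tests compare the card
  network's $r$ to an empirical per-direction detection estimate instead.
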