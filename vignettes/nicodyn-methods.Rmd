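---
title: "Methods: craving dynamics and driver-node analysis in nicodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: craving dynamics and driver-node analysis in nicodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicodyn)
```

nicodyn analyses single-subject nicotine microdosing sessions at two
levels: the behavioural/pharmacokinetic level (craving versus dose) and the
network level (which brain regions control the rest of the addiction
circuit). This vignette documents the models, every tunable that matters,
the synthetic-data generator used in place of recordings, and the numerical
choices made where the design was genuinely open.

## 1. The craving model and its pharmacokinetic form

Under rapid fixed-interval dosing (inter-trial interval, ITI, of 120 s),
subjective craving relaxes from its withdrawal ceiling as a single
exponential in time from the first puff at $t_0$:

$$\mathrm{craving}(t) = A + B\,e^{-(t - t_0)/\tau},$$

with asymptote $A$ (residual craving at saturation), amplitude $B$
(relief achievable by dosing; the ceiling is $A + B$), and decay time
$\tau$ in seconds. Blood nicotine is modelled as a step function rising by
a fixed increment `c_inc` (default 0.6 ng/mL) per puff —
`simulate_concentration()` adds an optional first-order elimination term,
off by default, for adapting the machinery to shorter-half-life compounds.
Because concentration rises by `c_inc` every `iti` seconds, the time
constant maps onto a concentration constant

$$c_0 = c_\mathrm{inc}\,\tau/\mathrm{ITI},$$

giving the equivalent dose-response form
$\mathrm{craving}(c) = A + B\,e^{-c/c_0}$ (`craving_vs_concentration()`).
With the defaults (`c_inc` = 0.6 ng/mL, $\tau$ = 310 s, ITI = 120 s) this
yields $c_0$ = 1.55 ng/mL and a decay time of $310/120 \approx 2.6$ puffs.
`decay_in_puffs()` reports one decimal and keeps full precision in an
attribute; `decay_concentration()` reports two decimals, matching the
reporting convention used elsewhere in the package.

`delivery_efficiency()` divides the per-puff blood mass increment
(`c_inc` × distribution volume) by the nebulized mass (0.1 mg: 10 µL of a
3 mg/300 µL stock). The distribution volume is a configuration constant,
default 5.6 L. No authoritative volume accompanies the published per-puff
increment and efficiency figures; 5.6 L is the value that makes a
0.6 ng/mL increment from a 0.1 mg puff come out at 3.4%, and it is flagged
as a convention, not an estimate.

### Fitting

`fit_craving_model()` runs Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) on the samples at $t \ge t_0$. Choices:

* **Initialisation** — $A_0$ = mean of the last 10% of samples, $B_0$ =
  mean of the first 10% minus $A_0$ (floored at 0), $\tau_0$ = one third of
  the fitted span. Robust for any monotone decaying trace.
* **Bounds** — $B \ge 0$, $\tau \in (1\,\mathrm{s}, 10\cdot\mathrm{span})$.
* **Censoring** — samples sitting on the scale bounds (0 or `scale_max`)
  are excluded with a reported count, since censored values bias least
  squares.
* **Degenerate input** — a constant trace has a singular gradient at any
  start, so the fit short-circuits to $A = \bar y$, $B = 0$ with a warning
  rather than erroring; a fitted $\tau$ exceeding a third of the span also
  warns (the trace then covers fewer than three decay times).
* **Determinism** — no random restarts; identical traces give identical
  fits.

`recovery_experiment()` quantifies calibration: at 1 Hz sampling over
2400 s with Gaussian noise $\sigma = 0.3$ (about a tenth of the amplitude),
100 simulate-and-refit replicates put the median $\hat\tau$ within a few
seconds of the generating 310 s and the median $\hat A$ within about 0.01
of 4.2 — comfortably inside the ±45 s and ±0.07 uncertainties the
parameters carry.

### Rating scale

$A$ = 4.2 and $B$ = 3.2 sit far below a 0–100 Likert ceiling, and the
numeric scale on which they were estimated is not recorded; the generator
therefore takes `scale_max` as a parameter (default 10, which places
$A + B = 7.4$ comfortably inside the scale) instead of hard-coding either
convention.

## 2. Ad-libitum self-administration

`generate_adlib_behavior()` emulates the self-administration protocol (one
free puff, then puffs on request, at most one per 120 s, at most 20). The
behavioural model reuses the fitted dose-response curve: an effective
concentration $c_\mathrm{eff}$ jumps by `c_inc` at each puff and relaxes
with time constant $\tau$ between puffs, and craving is
$A + B e^{-c_\mathrm{eff}/c_0}$ — knocked down by each puff, recovering
towards $A + B$ as the effect washes out. A puff is requested at the first
second at which craving reaches the subject's threshold and the refractory
period has elapsed. The model is deterministic given its parameters; the
`seed` argument exists for interface uniformity. A threshold near the
ceiling produces the single free puff; a threshold near $A$ produces a
puff every refractory period up to the cap.

## 3. Dynamic connectivity states

The imaging analysis takes a denoised 23-region BOLD series (TR 0.802 s)
and a puff schedule, and works per condition:

* **abstinence** — the first 10 × 38 = 380 TRs (304.76 s), acquired before
  any puff, split into contiguous non-overlapping 38-TR windows;
* **satiety** — one 38-TR window per puff, starting 38 TRs (30.48 s) after
  the puff onset, onsets floored to the TR grid. At ITI 240 s consecutive
  starts are ~299 TRs apart, so windows never overlap; the extractor
  errors if they would.

Each window yields a 23 × 23 Pearson correlation matrix; its row sums
excluding the diagonal are the **nodal connectivity strengths** (10 × 23).
Strength is *signed* by default — the windowed matrices are weighted
correlation matrices and no sign-handling convention is recorded for this
step — with an `absolute` mode as a configuration flag. Correlating
strength vectors between windows across regions gives the 10 × 10 window
similarity matrix.

**Clustering.** Windows are clustered by average-linkage agglomerative
clustering on the distance $1 - $ similarity. The number of states is not
fixed a priori: `k = "auto"` picks $k \in \{2,\dots,5\}$ by maximal mean
silhouette width (ties to the smaller $k$). Reported controlled-node
percentages elsewhere imply a small data-driven state count rather than one
state per window, which motivates both the range and the data-driven
selection; a fixed `k` remains available. Labels are renumbered by first
occurrence, making the assignment deterministic and equivariant under
window permutation.

**State matrices.** Member windows' correlation matrices are averaged
entrywise after Fisher z-transform and transformed back — the
variance-stabilised average that is standard for correlations (the mean of
$r$-values {0.5, 0.9} is 0.766, not 0.70). Whether averaging should precede
or follow binarization is not determined by the procedure's description;
averaging first is implemented (binarizing individual windows and voting is
the noted alternative). The diagonal is forced to 1.

**Binarization.** Edge $(i,j)$ exists iff $r_{ij} \ge 0.65$; the
comparison is inclusive and applied to signed correlations by default (an
absolute-value mode exists). Both conventions had to be fixed somewhere;
both are configurable.

## 4. Minimum-dominating-set driver analysis

A set $S$ of nodes *dominates* a graph when every node is in $S$ or
adjacent to a member (closed neighborhoods — a node dominates itself, so
isolated nodes belong to every dominating set). `minimum_dominating_sets()`
enumerates **all** dominating sets of minimum cardinality exactly, by
branch-and-bound over bitmask neighborhoods: branch on an undominated node
with the fewest admissible dominators (every dominating set must contain
one), prune with a greedy upper bound and the covering lower bound
$\lceil \#\mathrm{undominated}/\max_v |N[v] \cap \mathrm{undominated}|\rceil$,
and exclude earlier branch choices so each set is generated exactly once.
The exact solver is capped at 30 nodes (23 are needed);
`greedy_dominating_set()` is the logarithmic-ratio fallback beyond that.

Minimum dominating sets are usually non-unique. Rather than privileging an
arbitrary one, a state's **driver candidates** default to the union of all
its minimum dominating sets; intersecting candidate sets across states
gives the **common drivers**. (The alternative — one canonical,
lexicographically first set per state — is exposed as
`candidate_policy = "first"`; an intersection of arbitrarily chosen single
sets would depend on enumeration order.) Each common driver's
**controlled percentage** is 100 × the mean over states of its open
neighborhood size over 23: slave nodes are the regions adjacent to the
driver, the driver itself excluded (`neighborhood = "closed"` includes it;
the reporting convention distinguishes driver from controlled nodes, which
favours the open default). `select_targets()` ranks common drivers by
controlled percentage, ties broken lexicographically by label, and returns
the top two as neuromodulation targets; fewer are returned when fewer
common drivers exist. Percentages are reported to two decimals.

## 5. The synthetic-data generator

`state_plan()` + `generate_roi_timeseries()` replace the unavailable
recordings. Each planted state is a 0/1 adjacency over 23 regions; each
analysis window belongs to one state; within a window, samples are drawn
i.i.d. from a zero-mean multivariate normal realizing that state's
adjacency:

* every **maximal clique** of the adjacency shares a latent factor, with a
  node in $k$ cliques loading $\sqrt{(r_w - r_b)/k}$ on each;
* all regions share one global factor with loading $\sqrt{r_b}$;
* independent residuals top variances up to 1.

For states that are unions of node-disjoint cliques — the default — the
implied correlation is exactly `within_edge_r` ($r_w$, default 0.8) on
edges and `background_r` ($r_b$, default 0.1) off edges, and positive
residual variance guarantees a positive definite covariance for any
$r_w < 1$. A per-edge-factor construction cannot do this around hubs: a
star whose spokes correlate at 0.8 against a 0.1 background is not a
correlation matrix at all for hub degree above $1/0.64$, and any latent
construction of such a star forces leaf–leaf correlations of at least
$0.8^2 = 0.64$ — directly under the 0.65 binarization threshold, where
sampling noise would toggle spurious edges. The default plan therefore
plants **hub-centred cliques**: one shared hub region (default the
anterior cingulate) joined with a disjoint 6-leaf set per state, fully
connected. The hub is then in a minimum dominating set of every state (the
plan constructor verifies this against the exact enumerator), is a common
driver, and controls 6/23 = 26.1% of regions per state, three times any
leaf — making it the unambiguous top target when recovery succeeds.

Window-to-state assignment defaults to states recycled over the 10 windows.
`simulate_session_series()` stitches a full session: abstinence windows
tile the baseline (which is 305 s in the default configuration, just over
the 380 TRs the abstinence condition consumes), satiety windows sit 38 TRs
after each of the 10 puffs at ITI 240 s, and the TRs in between carry
background-only correlation. One integer seed drives each generator call;
identical seeds give bit-identical output.

**What the generator does not emulate:** hemodynamic convolution and
autocorrelation (samples are white within windows), scanner drift and
motion, residual physiological noise structure, gradual state transitions
(switches are instantaneous at window boundaries), and craving-connectivity
coupling. Passing recovery tests therefore demonstrates that the pipeline's
inference is correct when its assumptions hold, not that real BOLD data
meet those assumptions.

## 6. Problem sizes and numerical conventions

The test-suite experiments use the sizes the analyses are designed around:
38-TR windows, 10 windows, 23 regions; 100–200 refits for parameter
recovery; 200 random graphs (4–10 nodes) for exhaustive-search
cross-validation of the enumerator; 50 seeds for end-to-end planted-hub
recovery (the acceptance bar is 90%). Correlations are clamped to
$|r| \le 1 - 10^{-15}$ before `atanh` so duplicated regions do not produce
infinities; zero-variance regions are an error by name, not a silent `NA`;
TR indexing is 0-based in window bookkeeping and onsets are floored to the
TR grid; all file formats are plain TSV/JSON with onsets printed to three
decimals, so reruns are byte-identical.

## 7. Known limitations

* The identity of the 23 regions is user-supplied; the built-in labels are
  a documented default, not an atlas.
* Craving fits are per-trace; no hierarchical pooling across subjects.
* Controllability here is graph domination, not linear-systems (Kalman)
  controllability; weighted or directed variants are out of scope.
* The ad-libitum behavioural model is a deterministic caricature intended
  to generate plausible schedules, not to be fit to behaviour.
* Subject-level percentages from real recordings depend on a state count
  and domination-policy convention that are configurable here precisely
  because no single convention is canonical.
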