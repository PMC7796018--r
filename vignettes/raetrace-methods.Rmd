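---
title: "Methods: recursive auto-encoders for abnormal-behaviour detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recursive auto-encoders for abnormal-behaviour detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raetrace)
```

## Scope and data model

`raetrace` detects dementia-related disruptions of daily routine in ambient
binary sensor streams from a single-resident smart home. The raw material is
a CASAS-style event log: one line per sensor activation with a timestamp,
a sensor id (31 motion + 3 door sensors in the default registry, N = 34),
a value, and optional `begin`/`end` activity annotations covering 11 daily
activity classes. Only activations (`ON`/`OPEN`) enter the analysis;
de-activations are parsed but ignored, because the representations below
deliberately consider the *activation* pattern only. A consequence worth
knowing: anomalies expressed purely through a sensor staying "on" (a door
left open) are invisible to this design.

## Features

The stream is tiled into consecutive one-minute windows (tumbling, not
overlapping: the per-minute tree construction downstream treats minutes as
disjoint units, and no overlap is defined anywhere in the procedure). Each
window gets two encodings:

* **BOS** — a length-N binary presence vector; position j is 1 iff sensor j
  fired at least once. Order and frequency are discarded.
* **RSM** — the ordered, repeat-preserving token sequence, one-hot encoded
  into a k×N matrix for k activations.

The canonical worked example: the window `M7,M3,M7,M3,M5,M4` over N = 34
yields the BOS bit-string with 1-based positions 3, 4, 5, 7 set and a 6×34
RSM matrix. By construction the BOS vector equals the column-wise OR of the
RSM rows, which the test suite asserts as a cross-feature invariant.

Windows spanning an activity boundary take the majority label by event
count, with ties resolved toward the activity seen earlier in the window —
an arbitrary but deterministic rule. Empty windows are kept in the window
table (BOS chunking needs the full tiling) but contribute nothing to RSM
training and score 0, i.e. normal: a zero-token tree is degenerate and has
no reconstruction to be bad at.

## The recursive auto-encoder

Children `c1, c2 ∈ R^n` are merged by `p = tanh(W1 [c1; c2] + b1)` and
reconstructed by `[c1'; c2'] = g(W2 p + b2)`; the node's error is the mean
squared difference over the 2n reconstructed entries. Design choices where
the procedure was genuinely open:

* **Parent dimension = n.** Forced by the recursion (parents re-enter as
  children) and by the fixed 1×34 root feature the model must emit.
* **Decoder activation g = identity** by default. The decoder's
  nonlinearity is never specified in the originating method; identity keeps
  the node error a plain MSE on unbounded reconstructions. `decode = "tanh"`
  is available and covered by the gradient tests.
* **No unit-normalisation of parent vectors.** Earlier recursive
  auto-encoder work normalises parents to unit length to avoid degenerate
  shrinking; the procedure this package follows does not mention it, so it
  is not applied. With tanh-bounded parents and one-hot leaves we observed
  no degeneracy at the scales tested.
* **Tie-breaking in the greedy merge:** leftmost minimal pair, so trees are
  reproducible.

Two tree builders:

* **linear** — rightmost pair first, each parent merged with the next row to
  its left; used for BOS chunks of w = 25 consecutive minutes (w − 1 parent
  errors per chunk). Chunks never straddle calendar days and a trailing
  chunk shorter than w is dropped (the procedure is silent; a partial chunk
  would change the score's scale).
* **greedy** — every adjacent pair is evaluated and the minimal-error pair
  merged, repeated until one parent remains; used for RSM sequences.

## Training

The corpus loss is the mean over trees of the mean per-node loss. In
unsupervised mode the node loss is the reconstruction MSE; in
semi-supervised mode it is `α·E_rec + (1−α)·E_xent`, where a softmax readout
at every parent is trained against the window's activity label (the same
label at every node of the tree). `α = 1` reduces to the unsupervised
objective exactly — asserted as an identity test. Cross-entropy clamps
probabilities at 1e-12.

Gradients flow by backpropagation through structure: a parent vector feeds
its own decoder and softmax *and* re-enters later merges as a child, and the
reconstruction *targets* of internal nodes are themselves parameter-dependent,
so that path is differentiated too. Analytic gradients match central
differences to better than 1e-8 relative (tested at 1e-4 tolerance for all
α ∈ {0, 0.2, 1}, both tree styles, both decoders).

Optimisation is mini-batch Adam (lr 0.01, batch 20) — mirroring the batch
settings used for the comparison networks in the source experiments, which
are silent about the RAE's optimiser — from uniform(−0.05, 0.05)
initialisation under the run seed. Greedy tree structures depend on the
parameters, so they are rebuilt at the start of every epoch; within an epoch
the structure is held fixed, which is what makes the gradient well-defined.
Default α = 0.2 in semi-supervised mode. Training runs in this package's
tests use 3 epochs: corpus loss typically drops by an order of magnitude in
the first epoch and the acceptance behaviours are stable from epoch 2 on;
more epochs buy little at desk scale.

## Scoring and evaluation

A trained model reconstructs familiar merges well, so anomaly scores are
reconstruction errors: for RSM windows either the mean over all parents
(`avg_parents`) or the root error (`root`); for BOS the mean of the 24
parent errors of each 25-row chunk. Flagging is `score > threshold`;
sweeping the threshold over all distinct scores yields the ROC. One
deliberate divergence: the evaluation formula sheet this work derives from
prints TN/(TN+FP) under the name FPR (that expression is specificity); the
ROC here uses the standard FPR = FP/(FP+TN), which is what a TPR-vs-FPR
curve requires. AUC is trapezoidal and equals the Mann–Whitney rank
statistic with ties at 1/2 (property-tested against an exhaustive oracle).
Macro precision/recall average per-class values unweighted; a class never
predicted contributes precision 0 so the average stays defined on
imbalanced data. For the supervised-classifier wrapper, per-class mean
training confidences `m_j` are computed and a test instance is flagged when
its confidence falls below `f·m_j`; the fraction f is the sweep variable.

## The synthetic world

No public dataset pairs ambient sensor streams with ground-truth dementia
anomalies, so the simulator states one explicitly. Its defaults are the
structural facts of the emulated testbed — 34 sensors, 11 activity classes —
plus choices a field researcher would call realistic, fixed once:

* Activities emit first-order Markov chains over small sensor subsets with
  exponential inter-event gaps at 0.6–4 events/min depending on activity.
  Ambient motion sensors fire as the resident *moves between* fields of
  view, so handoff transitions dominate and self-transitions are rare
  (0.02), except the deliberately repetitive breathing-exercise profile.
  This is also what makes sub-activity injections detectable in principle:
  a repeated characteristic sensor creates self-adjacencies that normal
  behaviour almost never produces.
* The schedule covers 24 h in ordered slots with 3-minute Gaussian boundary
  jitter, one away block with no events, and a contiguous night-sleep block
  so sleep-disorder injections have a well-defined target span.
* Planted answers for pattern mining: sleeping alternates the bed pair
  M002/M003 with handoff probability ≥ 0.9; work is dominated by M026
  alternating with M027; eating hubs on M014, meal preparation on the
  kitchen cluster M015–M019.

What the simulator does **not** emulate: multi-resident interleaving,
sensor noise/dropout, day-of-week structure, seasonal drift, OFF-event
dynamics, and the slow behavioural drift of real cognitive decline. A green
acceptance run therefore establishes that the pipeline recovers *injected*
anomalies in a *stationary* routine — a correctness statement about the
method, not a clinical performance claim.

## Anomaly injection

* **Activity-level**: a donor instance of a named activity is copied and
  inserted at a context-sanctioned abnormal position — sleep-set activities
  (relaxing, eating, bed-to-toilet, respirating) strictly inside a sleeping
  span, the daytime set (meal preparation, eating, work, washing dishes,
  leaving/entering home) inside an instance of a *different* daytime
  activity. The donor block is rigidly translated and linearly compressed if
  it would overrun its host, preserving the intra-activity order and
  frequency the RSM feature must see. Donors come from the log's own (or a
  designated training) instances — the procedure says instances are
  injected but not where they come from, and copying real instances keeps
  them individually plausible, leaving only their *context* anomalous.
* **Sub-activity**: in each of n randomly chosen target instances the
  activity's characteristic sensor (work→M26, eating→M14, meal
  preparation→M18, bed-to-toilet→M4) is inserted at random interior
  positions with multiplicity uniform on [2, 6] ("a random frequency" is
  otherwise unbounded; 2–6 keeps instances plausible while exceeding normal
  repetition), timestamps interpolated between neighbours.

Both injectors conserve events (output = input + inserted, originals a
subsequence) and return records carrying the inserted event indices and
times. Window-level ground truth is: abnormal iff at least one injected
event falls in the window — matching the per-window scoring granularity.

## Pattern mining

Frequently co-occurring adjacent activations are reconstructed well, so the
least-error nodes of trees built on the training set mark recurring
sub-activities. Nodes whose subtree spans exactly n leaves (n ∈ {2, 3})
contribute their left-to-right leaf tuple; tuples are counted per activity
class and ranked by frequency, ties broken lexicographically.

One design decision deviates from the assumed default. Selecting the top
500 nodes *globally* is degenerate in this synthetic world: one-hot leaves
make nodes over identical token pairs carry *identical* errors, so the
global top-500 fills up with copies of the single best-reconstructed pair
and every other class's pattern list comes out empty — while the reference
pattern table this mirrors lists patterns for all 11 classes. The selection
is therefore top-k *per activity class* by default (`per_class = FALSE`
restores the global rule). With real-valued or noisy features the two rules
would largely coincide.

## Numerical and degenerate-input choices

* Windows with one token: no merge exists; score 0, flagged `degenerate`.
* Greedy tree of one token: root is the leaf; root feature = the leaf.
* Cross-entropy clamp 1e-12; gradient checks use central differences at
  eps = 1e-6.
* Out-of-order timestamps in logs: stable sort with a warning (real
  deployment logs contain inversions); `strict = TRUE` errors instead.
* Instances that would emit fewer than two events are skipped by the
  generator (an instance needs a begin and an end marker).
* All timestamps are UTC at second resolution; ties are resolved stably so
  original events always remain a subsequence after injection.

## Limitations

The detector treats windows independently: it cannot relate one minute to
the next (beyond the 25-minute BOS chunks) and so misses anomalies expressed
purely as long-range temporal structure. BOS-based detection inherits
frequency-blindness within a window. The synthetic world's stationarity
makes detection easier than production deployment; reported AUCs on it are
upper bounds on what the same pipeline would achieve on real homes.
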