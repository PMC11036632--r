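---
title: "Extracting nested PICO templates from trial abstracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting nested PICO templates from trial abstracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picostruct)
```

## The task and the data model

A randomized controlled trial abstract states, in prose, a structured
record: a publication describing one clinical trial, with one study
population, one or more arms, each arm receiving an intervention with a
medication and reporting outcomes against endpoints, plus between-group
comparisons. `picostruct` represents this record as an *instance forest*:
typed template instances whose slots hold either verbatim text spans of
the abstract or child instances. The shipped schema
(`default_pico_schema()`) declares the ten template types of this data
model — Publication (root), ClinicalTrial, Population, EvidenceQuality,
Arm, Intervention, Medication, Outcome, Endpoint, DiffBetweenGroups —
derived from the C-TrO ontology of clinical-trial concepts. Slot names
are globally unique, so a slot label alone identifies its owning
template; Publication, ClinicalTrial and Population are marked
`fixed_cardinality = 1` because a single abstract describes exactly one
of each.

The full ontology defines a considerably larger slot inventory than the
subset shipped here; the schema file format (`load_schema()`) accepts any
inventory, and every component of the package is schema-driven, so
substituting the complete inventory is a configuration change, not a code
change.

Two structural conditions make the serialization machinery well defined,
and `validate_forest()` enforces them: the instance containment graph
must be **acyclic** (otherwise linearization would not terminate) and
**connected** from the root (an isolated instance has no place in the
serialization). Character offsets are 0-based half-open and token indices
1-based inclusive; the two round-trip exactly through `align_span()`.

## The extractive engine

The pipeline is a two-step architecture: extract all textual slot
fillers, then group them into template instances.

**Boundary tagging.** Contextual token vectors `h_i` feed two independent
affine–softmax heads predicting, per token, a *start* label and an *end*
label over all slots plus a no-slot class. Only boundary tokens are
tagged — interior tokens of a filler carry the no-slot label, unlike IOB
tagging. Predicted boundaries are joined sentence-wise: starts are
processed left to right, each consuming the nearest unconsumed same-label
end at or after it; unmatched boundaries are discarded. The greedy order
makes joining deterministic; ties cannot occur (the candidate end is
unique), and when two starts compete for one end the earlier start wins.
The join is count-optimal, and in balanced cases also total-distance
optimal; with unmatched boundaries a globally distance-minimal assignment
can differ, but the per-start nearest-end rule is the specified behavior
and is what the tagger's training distribution reflects.

**Compatibility and clustering.** Each filler is represented by
`e = relu(W_r(h_s + h_e) + b_r)`; the pairwise compatibility
`q(e_i, e_j) = σ(w' relu(W_h(e_i + e_j) + b_h) + b)` is symmetric by
construction (the sum commutes) — tests assert bit-for-bit symmetry, not
approximate symmetry. A cluster is scored by its mean pairwise
compatibility `g`, a clustering by the mean of its cluster scores `h`.
Two groupers are provided:

* `best_clustering_exhaustive()` enumerates all partitions with a given
  number of blocks (restricted growth strings, bounded at 10 fillers by
  default — the Bell numbers grow too fast beyond that) and returns the
  `h`-maximal partition, ties resolved to the lexicographically smallest;
* `hac_cluster()` removes the need to know the instance count: average-
  linkage agglomerative clustering on `q`, stopped when the best
  inter-cluster mean compatibility drops below a threshold τ. Average
  linkage is the one linkage consistent with the mean-compatibility
  objective `g`; the implementation delegates to `stats::hclust()` on the
  dissimilarity `1 − q` with a cut at height `1 − τ`, which realizes
  exactly this merge rule.

On the worked 4-filler example (two percentages, two time points) the
threshold 0.5 yields the two expected Outcome groupings, and the
exhaustive search at `m = 2` finds the same partition with `h = 0.75`.

*Scoring detail.* The literal mean over the cartesian product `C × C`
includes self-pairs `q(e, e)`, which the worked example leaves undefined.
The default therefore excludes self-pairs and averages over unordered
pairs, with singletons scoring 1.0; `include_self = TRUE` restores the
literal reading when a diagonal is available. The default reproduces the
worked example's numbers exactly.

*Threshold.* τ is fitted from training pairs as a function of two
averages — the mean compatibility of same-instance pairs and of
different-instance pairs. The combining rule is their midpoint by
default (`fit_threshold()`), overridable via the `combine` argument,
since only the two averages themselves are prescribed.

**Assembly.** One instance per cluster, each filler placed in the slot
the tagger assigned. Templates with fixed cardinality one bypass
clustering — all their fillers pool into a single instance. How the
extractive route populates template-valued slots is under-determined, so
assembly is deliberately conservative: an instance whose template has
exactly one (parent template, slot) pair in the schema is attached to the
parent instance when that parent is unique, with missing chain ancestors
(and the root) synthesized empty; with several candidate parents (e.g.
outcomes under multiple arms) the instance is left unattached and
reported. Consequently the extractive engine is scored on textual slots
only, instance-agnostic by default.

## The generative engine

**Linearization.** An instance serializes as `[start:T]`, its slots in
schema declaration order (the slot-ordering operator over slots), each
filler list ordered by document position — textual fillers by token
start, instance fillers by their earliest textual descendant — and each
filler wrapped in its slot's `[start:s] … [end:s]` specials, then
`[end:T]`. Both orderings only need to be *fixed*; declaration order and
document order are the natural canonical choices and make round trips
testable. Repeated fillers serialize as consecutive wrapped segments.

**Grammar.** Four rule shapes per schema: a HEAD rule
`T_HEAD := [start:T] T`, a terminator `T := [end:T]`, one rule per
textual slot `T := [start:s] TEXT [end:s] T` and one per template slot
`T := [start:s] C_HEAD [end:s] T`. The tail recursion through `T` lets
slots repeat; `TEXT` stands for any sequence of input-document tokens.
The start symbol is the root's HEAD non-terminal.

**Constrained decoding.** A stack tracks open frames: start specials
push, matching end specials pop. The allowed-next-token set is read off
the stack — slot starts or the end special inside a template frame;
document token *types* (not positions) plus the end special inside a
textual slot; the child's start special inside a template-valued slot.
Disallowed vocabulary entries are masked to −∞ and the argmax token
emitted greedily (beam search is deliberately out of scope). The output
is therefore derivable by construction; if the length cap (default 4× the
document length) hits mid-structure, open frames are auto-closed — an
open template-valued slot receives an empty child instance so the result
still parses — and the output is flagged truncated. The native
end-of-sequence token of a backbone never enters an allowed set; the
root's end special is the terminator. Parsed filler text that does not
occur verbatim in the document is kept and flagged `free_text` rather
than rejected; evaluation simply counts it as a wrong string.

## Desk-scale trainable backends

The engines are defined against two small contracts — an encoder mapping
a document to per-token vectors, and a logit provider mapping (input,
generated prefix) to vocabulary scores — so that paper-scale transformer
backbones can stand behind them. The shipped backends are deliberately
tiny, written in base R matrix arithmetic with hand-derived gradients and
Adam updates, sized to train in minutes on one CPU:

* the **tiny encoder** (d = 32) is a trainable token-embedding lookup
  over (previous, current, next) surfaces plus fixed sinusoidal position
  features, mixed by a trained `tanh` layer. Position features matter
  beyond tagging: the compatibility head receives sums of boundary
  vectors, and sums of sinusoids retain the *distance* between positions,
  which is the signal that same-instance fillers (stated in one sentence)
  are close together;
* the **decoder** scores `softmax(V d + b)` where `d` is a learned linear
  map of deterministic prefix features: previous-token embedding, the
  open frame on the decoding stack, a bag-of-embeddings of document
  tokens not yet copied, and a small count of tokens emitted inside the
  open slot. Three refinements proved necessary and are part of the
  design: surface-shape features (numeric magnitude, decimal, length,
  capitalization) in the fixed embeddings plus a feature-tied component
  of the output layer, so surfaces never seen in training are still
  scoreable; a learned copy-presence bias rewarding tokens still
  available in the document; and a slot-inventory bias on start specials
  — per-slot word inventories collected from the training linearizations,
  closed over the schema containment structure — carrying the decision
  whether another filler or instance remains to be generated. Without
  the latter, greedy decoding deterministically loops on repeatable
  slots; a full transformer would extract the same signal through cross-
  attention.

Training follows the regime of per-document updates (batch size 1) with
the exponential learning-rate schedule `lr(epoch) = lr0 · λ^epoch`.
Defaults: extractive — 20 epochs, `lr0 = 0.02`, `λ = 0.95`, then a
300-epoch full-batch compatibility stage with binary cross-entropy on
same-template filler pairs (positive iff same gold instance, negatives
subsampled 2:1 with a fixed seed); generative — 40 epochs, `lr0 = 0.03`,
`λ = 0.95`, gradients clipped to global norm 5 (per-document updates on
this loss surface otherwise spike). The two extractive losses are
trained in stages rather than jointly — the tagger first, then the
compatibility head on the trained encoder's representations — which
keeps both convex-ish and reproducible. All randomness (initialization,
data order, subsampling) flows from one seed; equal seeds give identical
checkpoints.

## The synthetic corpus

`generate_corpus()` emulates the *structure* of RCT abstracts, not their
language: multi-sentence documents in which every gold filler occurs
verbatim at a recorded span; one Publication/ClinicalTrial/Population/
EvidenceQuality per document; 1–2 arms, 1–4 outcomes, 1–2 between-group
differences per document (ranges chosen to bracket the instance counts
implied by reported per-template filler statistics, and configurable);
one Intervention and Medication per arm and one Endpoint per outcome;
each instance's textual fillers stated in a single sentence, as results
typically are. Filler pools are disjoint in token space, avoid the
scaffold vocabulary, give multi-word fillers unambiguous continuations,
and keep numeric slots in disjoint value ranges — so string-match
evaluation is unambiguous and pool membership is learnable from surface
shape alone. These are exactly the properties real abstracts only
approximate: passing the parameter-recovery experiments shows the
machinery is correct and trainable, not that these tiny backends would
reach useful accuracy on real PubMed text, where fillers share
vocabulary, cross sentence boundaries and appear in free variation.

The generator also supplies two oracles used throughout the tests: the
gold-indicator compatibility (1 iff same gold instance), under which
threshold clustering at τ = 0.5 must recover every gold cardinality, and
a teacher provider scoring the gold continuation highest, under which
constrained decoding must reproduce the gold linearization exactly.

## Numerical and degenerate-input choices

* Softmax rows are max-shifted before exponentiation; argmax ties break
  to the first label in fixed order.
* A singleton filler set clusters trivially; an empty extraction yields a
  bare root instance; an empty clustering or empty cluster is an error.
* `hclust` on a 1-element set is bypassed explicitly.
* Probabilities in cross-entropy are floored at 1e-12.
* Documents are whitespace-tokenized with exact character alignment;
  sentence boundaries are placed after `.`/`?`/`!` followed by an
  uppercase letter or digit — a deterministic rule in place of a learned
  splitter, adequate for abstracts and fully reproducible.
* Oversized inputs are not chunked: a backend that cannot encode a
  document fails loudly, since whole-document context is the point of
  the architecture.

## Evaluation protocol

The matching between predicted and gold fillers is not standardized for
this task, so the report states its criterion. Default: per slot,
one-to-one matching by exact whitespace-normalized string equality,
instance-agnostic (multiset intersection); micro F1 pools TP/FP/FN over
slots, per-template means average the per-slot F1 of each template's
active slots. The optional strict criterion first aligns instances per
template by greedy maximal filler overlap and scores only within aligned
pairs, penalizing mis-grouping. Absolute numbers are not comparable
across criteria. Cardinality is scored as the mean absolute deviation
between predicted and gold per-document instance counts, excluding the
fixed-cardinality templates for which both sides are one by definition.

## Problem sizes used in the shipped experiments

The round-trip suite uses 1000 generated forests; decode-validity runs
100 adversarial seeds; parameter recovery trains both engines on 200
synthetic documents and evaluates on 50 held-out documents (all seeded).
These sizes give stable percentages while keeping the full suite runnable
in minutes on a single CPU.

## Known limitations

* The extractive engine's inter-instance links are heuristic; with
  multiple candidate parent instances it reports unattached instances
  rather than guessing, and its learned-compatibility cardinality
  inference degrades for templates with many similar instances (Outcome
  being the hardest) — the grouping problem, not boundary detection, is
  the bottleneck.
* Greedy constrained decoding commits to its first grammar-consistent
  choice; beam search is out of scope.
* The tiny backends are capacity-limited feature models; they establish
  correctness and trainability of the surrounding machinery at desk
  scale and are not a substitute for transformer backbones on real text.
* The whitespace tokenizer assumes space-delimited punctuation, which
  the generator guarantees; real abstracts would need a subword-aware
  alignment layer, for which the span↔token projection API is already in
  place.
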