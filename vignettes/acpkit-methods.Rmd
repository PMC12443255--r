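---
title: "Methods: boundary-aware resampling, ensemble classification, and residue-level attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boundary-aware resampling, ensemble classification, and residue-level attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpkit)
```

acpkit classifies short anticancer peptides (ACPs, 5–50 residues) from
sequence. This vignette is the package's account of its methods: the
models and procedures, the parameters that matter, the numerical
conventions, and what the offline test fixtures do and do not
establish about real data.

## Sequence input

Peptides arrive as FASTA. The header token before the first whitespace
is the record id; class labels travel either as a `|label=0/1` suffix
on that token or in a two-column delimited sidecar file (both are
artifact conventions — public ACP datasets ship labels in ad hoc
ways). Validation is strict by default: the 20 canonical letters only,
because every downstream encoder assumes that alphabet; ambiguity
codes (X, B, Z), non-standard residues (U, O), stops and gaps either
abort (`reject`, default) or are dropped with a count (`drop`). The
length filter keeps the inclusive window `[5, 50]`, the range
characteristic of functional anticancer peptides; both bounds are
parameters. Redundancy clustering (CD-HIT-style) and PSSM profiles are
deliberately out of scope — they are external tools in any realistic
workflow, and the package only documents where their outputs would
enter.

## Feature extraction

Four classical encoders serve as baselines, each with a fixed
alphabetical feature order so matrices are bit-reproducible:

* **AAC** (20 dims) — residue frequencies.
* **DC** (400 dims) — adjacent dipeptide frequencies over the
  `L − 1` sliding windows, row-major pair order.
* **PAAC** (20 + λ dims) — Chou-style pseudo amino-acid composition
  over three standardized property scales (hydrophobicity, Hopp–Woods
  hydrophilicity, side-chain mass). Defaults λ = 4, w = 0.05: λ must
  stay below the sequence length, and with 5-residue peptides
  admissible, λ ≤ 4 keeps every valid input encodable; w = 0.05 is the
  customary sequence-order weight.
* **CTD** — composition/transition/distribution blocks over the
  seven-property, three-class Dubchak grouping (21 + 21 + 105 dims).
  Dimension tallies for CTD differ across the literature (a 60-dim
  convention circulates with no derivable grouping); the grouping
  table is therefore a parameter, and the default is the one stated
  above. Distribution percentiles are taken at 0/25/50/75/100% of each
  class's occurrences, positions reported as fractions of sequence
  length — the dominant CTDD convention. A class absent from a
  sequence contributes zeros rather than NA so matrices stay complete.

## Residue embeddings and the mock backend

Modern ACP classifiers feed per-residue embeddings from a pretrained
protein language model. The package defines the backend *contract* —
`embed_residues()` returns an `L × d` matrix with special-token rows
stripped — plus an adapter slot (`external_backend()`) into which a
caller can plug a real model. The adapter errors loudly when no
embedding function is supplied; there is never a silent fallback.
Residue-to-sequence pooling is the arithmetic mean. Mean pooling is
the convention for this model family, and because it is linear it
makes the per-residue decomposition of a pooled-feature model exact up
to the constant factor `L`.

The **mock backend** exists so everything downstream is testable with
no model download. Each row is a pure function of `(dim, seed)`: a
sparse non-negative *identity component* (dimension `j` belongs to
letter `l` when `(j − 1) mod 20 = l − 1`; magnitudes in `[0.5, 1]`
from a fixed multiplicative congruential stream) plus a small dense
positional jitter keyed by `(letter, position mod P)`, default
amplitude 0.1, period 7. The identity component is deliberate: real
language-model embeddings carry residue identity in linearly
decodable form, and that decodability is precisely what residue-level
attribution exploits. A mock with dense sign-symmetric random letter
vectors does not have this property — the global SHAP weight vector of
any monotone classifier is, per dimension, approximately (coefficient
× class shift), a product whose factors share a sign, so sign
information cancels and projection onto sign-symmetric embeddings
cannot separate enriched from unenriched letters. The default width
is 1152, mirroring the 600M-parameter model the toolkit targets;
tests use narrower widths for speed.

What the mock does **not** emulate: contextual semantics (rows depend
only on letter and position-mod-P, not on neighboring residues),
length effects, or any biochemical structure. Passing attribution
tests on the mock therefore demonstrates the correctness of the
attribution *machinery*, not biological validity on real embeddings.

## Class-imbalance correction

ADASYN is implemented as the reference: difficulty `r_i = Δ_i / k`
with `Δ_i` the majority count among the `k` nearest neighbors of
minority sample `x_i` in the full dataset (self excluded, distance
ties broken by lowest row index); normalization `r̃_i = r_i / Σ r_j`;
integer allocation `G_i ≈ r̃_i · G` by largest remainder so
`Σ G_i = G` exactly; synthesis `x_new = x_i + δ (x_z − x_i)` with
`δ ~ U(0, 1)` and `x_z` uniform among the `k` nearest *minority*
neighbors. Two degenerate conventions: an all-zero difficulty vector
(no minority point has a majority neighbor) falls back to uniform
allocation, since the normalization is undefined at `Σ r = 0`; and the
neighbor count is capped at `|minority| − 1`.

**ANBS** iterates a boundary step and a synthesis step until the
minority/majority ratio reaches `max_ratio`:

1. remove the single majority row at minimal Euclidean distance to any
   minority row (ties: lowest row index);
2. synthesize `ceil(max_ratio · |majority|) − |minority|` minority
   points through the ADASYN chain on the current sets.

Removing exactly one majority row per iteration and topping up to the
exact target are the conventions under which the balanced counts are
deterministic functions of the input counts: from 487 positives and
1,479 negatives at `max_ratio = 1`, one iteration yields 1,478 and
1,478. A useful consequence of the top-up rule: whenever both classes
start with at least two samples, the ratio guard is satisfied after
the first pass, so the loop provably terminates in one iteration and
`max_iter` acts purely as a safety cap (exhausting it warns, never
fails silently). Features are used as-is — no internal standardization
— so callers who want scaled distances must scale before sampling.
Synthetic rows carry provenance flags, and every ANBS run records a
per-iteration trace (removed/added counts) that the pipeline log
echoes, making the boundary behavior auditable.

Per-iteration cost is dominated by the majority-to-minority distance
computation, `O(N_t · P_t · d)` plus sorting — quadratic in the class
sizes at fixed dimensionality, which a loose empirical scaling test
confirms on generated fixtures.

## Classifier and evaluation

The final classifier is a soft-voting ensemble whose default members
are a random forest, an exact-split gradient-boosted tree model, and a
histogram-based gradient-boosted tree model (the two boosted members
are backed by xgboost with `tree_method = "exact"` and `"hist"`
respectively; the histogram learner is the R-side counterpart of
histogram gradient boosting). Probabilities are combined by a weighted
arithmetic mean with weights normalized to sum one; weights default to
equal because no principled weighting is assumed. Hyperparameters
default to library values with only the seed pinned, and every
hyperparameter is reachable through `ensemble_config(params = ...)`.
A combined probability at or exactly on the threshold (default 0.5)
maps to the positive class — a documented tie rule rather than an
accident of floating point.

Evaluation uses ACC, SN, SP, MCC, F1 and precision from the confusion
tallies, with the convention that any zero denominator yields 0 — the
choice that keeps MCC and F1 defined for degenerate predictors — and
ROC/AUC built over descending unique score thresholds with tied
scores grouped and trapezoidal integration (numerically identical to
the Mann–Whitney pairwise estimator with ties counted one half, which
the tests assert to 1e−12).

Cross-validation is stratified and seeded, with per-fold seeds derived
deterministically from the master seed. Three resampling modes:

* `"safe"` (default) applies ANBS inside each training fold only, so
  no synthetic point ever leaks into a test fold;
* `"paper"` balances the full dataset once and then folds it — the
  protocol used when one pre-balanced dataset feeds every model. Its
  test folds contain synthetic points, which typically inflates
  metrics; the package provides it for comparability and reports both
  modes side by side rather than asserting which is larger;
* `"none"` for unbalanced baselines.

## SHAP-Res attribution

The global weight vector is the mean *signed* Shapley value of the
positive-class probability, per embedding dimension, over an explained
instance set (default: the background itself), estimated by a seeded
permutation sampler with marginal contributions averaged over the full
background. When `d! ≤ n_samples` the permutations are enumerated
exhaustively and the estimate is exact for the given background — the
regime the linear-model tests pin down. Signed values are kept because
the inner product of Eq-style residue projection needs direction;
`method = "absolute"` provides magnitude-style rankings for
frequency-feature importance plots. The attribution target is the
positive-class (ACP) probability.

Residue scores are `s_i = e_i · w` with no `1/L` factor — the literal
projection — so with mean pooling the per-residue scores of a peptide
sum to `L ×` (the pooled feature's contribution); the constant is
documented rather than divided out. Min–max normalization maps each
peptide's scores to `[0, 1]`; a constant score vector (e.g. a
length-1 peptide) normalizes to all zeros because min–max scaling is
undefined there. Normalized scores are invariant under positive
scaling of `w`, so only the direction of the weight vector matters.
Per-letter aggregation averages normalized scores over every
occurrence of each letter across all explained peptides; letters that
never occur are flagged absent rather than zero-filled, since a zero
would be indistinguishable from a genuinely unimportant residue. For
models built on frequency features (where weights already live in
letter space), `rank_letter_weights()` ranks the per-letter weights
directly.

## Synthetic data and what the tests show

`make_blobs()` draws two isotropic Gaussian clusters, majority at the
origin and minority displaced by `class_separation` along the first
axis. Defaults mirror the canonical imbalanced training split — 487
minority / 1,479 majority at dim 16 — with separation 3 and spread 1,
a moderately overlapping regime in which resampling demonstrably
matters; well-separated configurations are available by parameter.
`make_sequences()` draws negatives i.i.d. uniform over the 20 letters
and positives from a multinomial with designated residues (default
K, L, F, G — the residues most consistently implicated in anticancer
activity through basicity, hydrophobicity and flexibility) upweighted
by `enrichment_factor` (default 3) and renormalized; lengths are
uniform on `[5, 50]`. Uniform background composition is the simplest
null under which the attribution-recovery property is testable; it
does not emulate natural amino-acid abundance or real ACP statistics.

The recovery study conditions are fixed once: 500 sequences per class,
enrichment 3, mock width 40, ensemble trained on pooled embeddings,
background 40 rows, 100 explained positives, 6 permutations per
instance. Under these conditions the top four letters of the
aggregation table are exactly {K, L, F, G}, and the result is stable
across independent generator seeds. The imbalance-benefit check uses
overlapping blobs at 1:3 (40/120, separation 2): fold-internal ANBS
raises minority sensitivity over no resampling at matched seeds,
directionally over five seeds.

Problem sizes throughout the test suite (three-fold CV on hundreds of
rows, narrow mock widths) are chosen as the smallest scales at which
each property is decidable; every quantity scales up by parameter.

## Known limitations

* Real-data benchmark results (pretrained-model embeddings, curated
  ACP datasets, comparisons against published ACP tools) are out of
  scope at desk scale; the property suite plus the deterministic
  balancing counts are the machine-checkable surface.
* The permutation SHAP estimator is exact only in the enumerable-`d!`
  regime; at realistic embedding widths it is a Monte Carlo estimate
  whose budget (`n_samples`, background size) the caller controls.
* ANBS treats features as-is; heterogeneous feature scales will bias
  both the boundary step and the neighbor search.
* The `"paper"` cross-validation mode reproduces a
  balance-then-fold protocol faithfully, including its leakage of
  synthetic points into test folds; conclusions about generalization
  should rest on `"safe"` mode.
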