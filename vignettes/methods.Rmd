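---
title: "Modelling multimodal EHR patient trajectories with ehrtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multimodal EHR patient trajectories with ehrtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrtraj)
```

## The problem

`ehrtraj` models longitudinal electronic health records (EHRs) of breast
cancer patients to predict disease-free survival (DFS) three years after
surgery. A patient's history is heterogeneous — dated visits carrying a
medical department and procedure, therapies, laboratory results, tumor
measurements, and free-text reports — and heavily imbalanced (roughly 6%
of patients relapse or die within the horizon). The package treats a
patient trajectory the way a language model treats a document: visits
are sentences, clinical events are tokens, and a bidirectional
transformer encoder learns contextual representations of those events,
first self-supervised (masked-event modelling) and then fine-tuned for
classification. A parallel model reads the free-text reports as a
chronological sequence of pooled report embeddings, and a
cross-attention module fuses the two modalities.

## Clinical feature engineering

**Dynamic Nottingham Prognostic Index.** The NPI combines the three
classical prognostic factors, `NPI = 0.2 * size(cm) + grade + node
stage`, with node stage 1 for zero involved nodes, 2 for one to three,
and 3 beyond. Because tumor size is re-measured along the care pathway
(clinical size at diagnosis, pathological size at surgery), the index is
recomputed at every new size measurement — the *dynamic* NPI — and the
trajectory carries its six-band prognostic group (Excellent to Very
Poor, thresholds 2.4/3.4/4.4/5.4/6.4 with upper bounds included in the
lower band) as a token at every visit, carrying the last value forward
between measurements. Missing node counts impute to zero, missing grades
to 2 (the modal values), and missing sizes to the modal size among
patients with the same TNM stage.

**Biological markers.** Five blood/serum features (MONO, LEUK, LYMP, PN,
CA 15-3) survive a 30% missingness filter; missingness is assessed over
visits at which a biology panel was drawn. Each measurement becomes two
tokens: a binary normal/abnormal token (1 outside the marker's normal
range, 2 inside; the closed boundary counts as normal — our convention,
as "outside the range" naturally reads as strict), and a discretized
between-visit delta, `round(delta / 10)`, with half-away-from-zero
rounding centralized in one helper because base R rounds to even. Zero
deltas are not emitted: an unchanged measurement adds no information and
the encoder's 512-token budget is scarce. The marker normal ranges
shipped as defaults are standard adult laboratory reference intervals
(e.g. leukocytes 4–10 x 10^9/L, CA 15-3 up to 30 kU/L); they are
configuration, not claims about any specific hospital's assay.

**Trajectory layout.** Each visit contributes up to 17 tokens in a
frozen canonical order (five bio binaries, five bio deltas, department,
procedure, therapy, subtherapy, age, dNPI group, subtype); missing
features are skipped, which the modality layer makes safe — a parallel
input layer names the feature type of every token, so the model always
knows what is present. Sequences start with `CLS`, every visit ends with
`SEP` (including the last, so visit blocks are uniformly delimited), and
a delay layer assigns every token of a visit the discretized gap to the
previous visit: week buckets `W0–W3` (7-day weeks, covering 0–27 days),
month buckets `M1–M12` (`ceiling(days/30)` clipped to 12, covering
28–364 days), `LT` beyond a year. The week/month boundary is not
uniquely determined by the bucket names alone; we chose the convention
that tiles the non-negative day axis exactly once and document it as
ours. Positions are 0-based token indices (BERT convention). Sequences
are truncated to their *first* 512 tokens — the early history carries
the diagnostic work-up and treatment decisions. Tabular history spans
182 days before diagnosis to 365 days after first surgery; text history
starts at diagnosis. Both windows are explicit function defaults.

**Cohort filters.** The index date is surgery + 365 days. Patients who
relapse before it are excluded (their trajectories would encode the
relapse itself), as are event-free patients censored before the 3-year
horizon (no label) and patients with fewer than three in-window visits.
Every exclusion carries exactly one reason code, and kept + excluded
always equals the input count.

## The encoder

No deep-learning framework is used: the package implements its own
transformer encoder in vectorized base R — input embeddings summed over
token, modality, delay and position tables; multi-head scaled
dot-product self-attention; residual connections with layer
normalization; a GELU feed-forward block; and analytic backpropagation
with Adam. Minibatches are "packed" (sequences stacked row-wise) so all
position-wise operations are single matrix products and only the
attention matrices are per-sequence. Every backward pass is pinned
against central finite differences in the test suite; training is
deterministic given the config seed. The reference configuration (5
layers, 12 heads, hidden 144, intermediate 133, 120 epochs, Adam at
1e-3, batch 64) ships as the default `encoder_config()`; tests and the
vignette use 2-layer/hidden-32 models, which the same code path serves.

## Masked-event pretraining

15% of eligible (non-special) positions are replaced by `MASK` and a
further 2% swapped for a random other content token, each position
independently (per-position Bernoulli rather than exact-count sampling,
matching the "randomly replaced 15%" reading and keeping positions
independent). Swapped positions do carry prediction targets by default —
the corruption mirrors the classical BERT objective — and
`swap_in_loss = FALSE` restores the noise-only reading; the choice is
exposed because the reference description does not settle it.
Cross-entropy is computed at corrupted positions only (verified by a
targets-only invariance test). Data are split 90/10 into train and
validation; validation corruption uses a fixed seed so the metric is
stable. Quality is measured by *precision*: top-1 accuracy at masked
positions. The structural baseline retrains the same model on sequences
whose content tokens (with their modalities) were permuted uniformly
after `CLS`, destroying visit structure while keeping every marginal;
the delay layer stays put since it describes visit timing, not token
identity. Embeddings are stabilized by running pretraining under
several seeds (five in the reference protocol), standardizing each
run's token table per dimension and averaging.

## Text pathway

Reports are preprocessed by lowercasing, accent and punctuation
stripping, and a configurable stopword list (the default list is a
package choice; medical abbreviations pass through). Each report is
embedded by summing the embeddings of its tokens — pooling is linear
and order-invariant — and a patient becomes a chronological sequence of
report vectors with the same delay buckets. The token embedder is a
pluggable contract (`embed(token) -> numeric(d)`, deterministic); the
shipped implementation hashes the token into a seeded pseudo-random
unit vector of dimension 768, which keeps the whole pathway
bit-reproducible on any machine and preserves the dimension plumbing of
a pretrained French clinical language model, which can be substituted
without API change. `CLS`/`SEP` are learned vectors (zero vectors would
make the sequence delimiters invisible to attention). The text
transformer reads the projected report vectors plus delay and position
embeddings; its `CLS` representation feeds a single feed-forward layer
with sigmoid.

## Classification and fusion

Both classifiers train on class-balanced batches: every batch holds
exactly half positives and half negatives, the majority class chunked
without replacement per epoch and the minority resampled, which keeps
the 6%-prevalence task from collapsing onto the majority class. The
tabular classifier initializes all layers from the pretrained encoder —
only the head differs between pretraining and fine-tuning.

The fusion module treats the text model's output as the query and the
tabular model's output as key and value. "Output" here means the
pre-sigmoid `CLS` representation (144-dimensional for the reference
tabular model), not the scalar score: a one-dimensional query/key/value
attention is degenerate, so the representation reading is the default
and a scalar-logit stacking mode is available behind
`fusion_config(mode = "scalar")`. With a single key the attention
output equals the value, so the block keeps the standard residual
connection from the query — the head reads
`Q + Attention(Q, K, V)` — and the fused representation genuinely
depends on both modalities. The text representation first passes a
linear projection (reference: 768 to 144) so dimensions agree.

Three numerical choices make this small meta-model train reliably, all
motivated by the fact that its inputs are frozen activations rather
than raw data. First, both representations are standardized per
dimension with statistics stored in the fitted model — the two encoders
produce activations on incommensurate scales. Second, the head and the
projection are warm-started from the frozen submodel heads (expressed
in the standardized bases), so at initialization the fused logit equals
a logistic stack of the two submodel scores and gradient descent can
only refine from there; random initialization frequently left the text
modality unused because the residual path dominates. Third, the fusion
set should be disjoint from the submodels' fine-tuning set: at desk
scale the submodels overfit their training data, and a meta-model
trained on in-sample representations learns to over-trust whichever
submodel memorized better. The shipped complementary-signal experiment
therefore fits the submodels on 60% of the training pool and the fusion
block on the remaining 40%; when the question is only whether planted
signal is recovered, training all three on the same pool also works.
Both submodels stay frozen during fusion training (a parameter digest
verifies they are bit-unchanged); only the projection, the attention
block and a fresh head learn. Joint fine-tuning through the submodels
is intentionally unsupported. Model selection across configurations
uses the average precision score on a validation split, the natural
criterion under heavy imbalance.

## Attribution and phrase mining

Integrated gradients attribute a prediction to its inputs along a
straight-line path from a baseline, using a midpoint Riemann sum; the
completeness gap (attributions minus the prediction difference from
baseline) is always reported. For the tabular model the baseline
replaces every token with `PAD` (the "empty trajectory"); for the text
model it zeroes the report vectors while keeping the learned
delimiters. Report-level scores drive a corpus-wide selection: within
each outcome class, reports whose signed relevance toward that class
exceeds the class's 95th percentile (a package default — the reference
procedure sets a threshold without printing it) form the
"predictive-for-DFS−" and "predictive-for-DFS+" collections. A
frequent-sequence miner counts, for every n-gram of 3–9 words, the
number of reports containing it (document frequency, because patients
are subsequently grouped by whether *a report contains* the phrase),
takes each collection's top 30 (ties broken lexicographically), reports
the phrases distinctive of the DFS− collection, and combines
overlapping phrases. Extracted phrases are validated by Kaplan–Meier
curves and a two-group log-rank test comparing patients with and
without the phrase; both estimators are implemented in the package and
cross-checked against the survival package in the tests.

## Synthetic cohorts

The generator emulates the structure the pipeline assumes, not any real
hospital's data. Visits follow the adjuvant breast-cancer care pathway
— screening/work-up, surgery, three-weekly chemotherapy cycles,
optional radiotherapy block, surveillance — so departments, procedures
and therapies co-occur within visits and cluster in time; that temporal
structure is exactly what masked-event pretraining can exploit and what
the shuffled baseline destroys. Static features use realistic marginals
(subtype mix 70/12/8/10% Luminal/TNBC/HER2+RH−/HER2+RH+, grade mix,
node and size distributions). Outcomes follow the design: an event time
drawn from an exponential whose rate scales a centred logistic linear
predictor on (NPI, TNBC, any abnormal CA 15-3) — default log-odds
effects 0.9 per NPI point, 1.0 for TNBC, 0.8 for abnormal CA 15-3 —
calibrated so the three-year event probability hits the 6.2% target
prevalence when effects are zero; censoring is drawn independently
(uniform 400–2600 days). Event times double as Kaplan–Meier-compatible
follow-up. Reports are templated pseudo-text (department/procedure
header plus filler drawn from a fixed vocabulary, mean 159 words);
event-bound patients receive a configured multi-word signal phrase with
probability 0.8 (0.05 otherwise), giving the attribution and phrase
mining machinery a recoverable target. The generator is deterministic
given its seed and restores the caller's RNG state.

What passing tests on these cohorts shows — and does not show: the
pipeline recovers planted structure of the kinds described (temporal
co-occurrence, NPI-mediated risk, discriminative phrases) at small
scale; it does not certify performance on real clinical text, real
visit processes, informative censoring, or hospital-specific coding
practices, none of which the generator attempts to imitate.

## Problem sizes used by the test suite

The shipped experiments are sized for a laptop-class single CPU:
synthetic cohorts of 120–2000 patients, trajectories truncated at 48–96
tokens, 2-layer/hidden-32 encoders trained for 2–16 epochs, and text
models over 16–32-dimensional hash embeddings. The pretraining
comparison against the shuffled baseline trains on 250-trajectory
subsamples of a 2000-patient cohort and evaluates precision on 400
held-out trajectories per seed. These sizes are the package's choices
for its own test suite; all reference-scale hyperparameters remain the
defaults of the corresponding configuration objects.

## Known limitations

* The encoder is pure R: fine for the desk-scale experiments it ships
  with, not for cohorts of tens of thousands of patients at 512 tokens.
* The hash embedder carries no semantics; two synonymous tokens get
  unrelated vectors. Conclusions about real clinical language require a
  pretrained medical embedder behind the same interface.
* Bayesian hyperparameter search is out of scope; configurations are
  explicit objects, and model selection uses average precision on a
  validation split.
* The generator's censoring is independent of covariates; informative
  censoring is not modelled.
* Counts of selected high-attribution reports depend on the chosen
  threshold quantile; the package reproduces the machinery, not any
  particular corpus's counts.
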