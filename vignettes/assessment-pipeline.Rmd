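---
title: "Speech-based AD assessment: models, decisions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech-based AD assessment: models, decisions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the representation

Alzheimer's disease (AD) alters spontaneous speech early: patients pause
more and longer, repeat themselves, use a narrower vocabulary, and produce
less speech per unit time. This package assesses AD likelihood from
one-minute spoken responses to neuropsychological tests (verbal fluency,
picture description, logical memory) by reducing each response to a
**Feature Sequence**: an ordered sequence of tokens $s_1, \dots, s_T$ drawn
from a closed vocabulary of base syllables plus one silence token. The
representation deliberately carries exactly the clinically relevant
signals — pausing (silence tokens), repetition (recurring tokens),
disfluency (alternation of silence and speech), and amount/speed of speech
(sequence length) — while remaining language-light: any unit list can be
supplied as the inventory.

The packaged inventory has 317 base syllables plus silence, a token space
of 318. The syllable file shipped under `inst/extdata/` is a constructed,
romanized stand-in list (marked `synthetic` in its filename): the package
treats the inventory as data, and deployments should substitute whatever
unit list fits their language and transcription conventions. Token ids are
assigned by list order with silence last, so a checkpoint is tied to its
inventory; checkpoints embed an inventory content hash and refuse to score
against a different token space.

## The transcriber (Feature Sequence Generator)

`train_generator()` / `transcribe_waveform()` implement a convolutional
recurrent network mapping audio to per-frame token posteriors, trained
with connectionist temporal classification (CTC):

* **Front end** — 80-dimensional log mel-filterbank energies, 25 ms
  window, 10 ms hop, followed by per-utterance cepstral mean and variance
  normalization (`cmvn()`). Per-utterance statistics were chosen so that
  single-utterance inference is self-contained. The mel filterbank uses
  the common HTK-style construction (Hann window, FFT size = next power
  of two above the window, no pre-emphasis); these details are
  config-exposed since they are conventions, not contributions.
* **Architecture** — three 2D convolution layers (filters 32/32/96,
  kernels (11,41)/(11,21)/(11,21)) with batch normalization before a
  clipped-ReLU activation (cap 20, following the Deep Speech 2 lineage
  the design descends from), then five bidirectional GRU layers of 512
  cells per direction with layer normalization, then a softmax layer with
  `inventory size + 1` classes — the extra class is the CTC blank, which
  is never part of a Feature Sequence.
* **Normalisation placement** — batch-norm statistics are computed over
  the time frames of the current utterance during training, with running
  moments used at inference; layer norm is applied per frame to each
  recurrent layer's input. Only the coarse placement (BN before the conv
  activations, LN in the recurrent layers) is fixed by the architecture;
  the concrete statistics and the input-side LN are this package's
  choices, documented here because alternatives (e.g. gate-internal LN)
  would be equally consistent.
* **Strides** — all-1 time strides by default, so one output frame
  corresponds to one 10 ms hop and the silence-threshold arithmetic
  below is exact. Downsampling convolutions are supported; the decode
  then recomputes its blank-run threshold from `effective_frame_s`.
  We default to no time downsampling because the 10 ms blank arithmetic
  is stated exactly and would otherwise be broken.
* **Training** — Adam at learning rate 5e-4, batch size 32, global
  gradient-norm clipping at 400, Glorot-normal initialization, utterances
  over 10 s removed before batching, 50000 iterations at full scale (one
  iteration = one batch; configurable, and desk-scale runs use far
  fewer). Silence tokens are stripped from CTC targets: silence is not an
  emission class but a decode-time construct.

All recurrent cells, convolutions, CTC and the optimiser are implemented
in C++ (RcppArmadillo) with hand-derived backward passes; every gradient
is validated against central finite differences in the test suite, and
the CTC forward recursion is validated against brute-force enumeration of
all `classes^frames` paths on small instances.

### Decoding and the silence rule

Greedy decoding takes the per-frame argmax (ties break to the lowest
class id, a documented determinism choice). The blank-collapse then runs
in a fixed order: maximal runs of at least $N$ consecutive blanks emit
one silence token, shorter blank runs are dropped but still separate
repeated tokens (preserving CTC semantics), and remaining runs of
identical labels merge to one token. $N$ comes from
`silence_run_threshold(threshold_s, effective_frame_s)` =
$\lceil \mathrm{threshold}/\mathrm{frame} \rceil$: at 10 ms frames a 3 s
threshold requires 300 consecutive blanks. Two boundary decisions are
deliberate: the run-length comparison is $\ge N$ (matching the worked
"at least 300" arithmetic), and non-divisible thresholds round up, so a
silence token always represents *at least* the requested duration.

## The assessment engine

`train_engine()` / `score_sequence()` implement the classifier
$\mathrm{score} = f(s_1,\dots,s_T) \in [0,1]$: a single bidirectional
recurrent layer (GRU by default; LSTM and the simple tanh cell are
available for comparison) encodes the token sequence, and the
final-timestep outputs of the two directions are concatenated and passed
through a fully-connected sigmoid head,
$\mathrm{score} = \sigma(W y_T + b)$. Defaults keep the total cell budget
fixed across directionality comparisons: 256 cells unidirectional, 128
per direction bidirectional. Desk-scale test runs use 16 cells per
direction — the classes the synthetic cohorts produce are separable
enough that capacity is not the binding constraint, and the architecture
is unchanged.

Design choices worth knowing:

* **Input encoding** is one-hot over the token space, realised as a
  column lookup into the input weight matrix (mathematically identical,
  much cheaper). A learned lower-dimensional embedding would be a
  reasonable alternative; one-hot is the smallest assumption.
* **Loss** is the cross-entropy *sum* over each batch (not the mean),
  taken literally from the training recipe, with Adam at 1e-3 and batch
  size 16. Since Adam normalises per-parameter step sizes, sum-vs-mean
  mostly re-scales the effective learning rate; we keep both values as
  stated.
* **Early stopping** monitors validation loss with patience 20 and
  returns the parameters of the best epoch. A `max_epochs` cap (default
  500) is this package's addition so that runs always terminate.
* Sequences are scored whole — one-minute responses yield at most a few
  hundred tokens — and batches are right-padded with a mask
  (`pad_and_mask()`); scoring reads each sequence's output at its true
  final timestep, so padding cannot leak into $y_T$ (a property the test
  suite asserts by comparing padded-batch scores with individual scores).

## Sequence-quality metrics

`edit_distance()` (unit-cost Levenshtein), `token_error_rate()` (edit
distance over reference length; can exceed 1) and `length_difference()`
evaluate automatic transcriptions against references. The length
difference is signed as *hypothesis minus reference* — negative values
mean the transcriber under-transcribes — a convention choice (the
opposite sign is available via an argument) since the quantity's
direction is not fixed by its definition. Silence tokens count as
ordinary tokens in all three metrics.

## The evaluation protocol

`run_experiment()` reproduces the cross-validation procedure: shuffle
once per trial, take test folds of 10 sequentially through the shuffled
order, split the remainder 85:15 into training and validation (the
validation count is round-*half-up* of 0.15 x remaining — base R's
banker's rounding would split 16.5 the other way), train from scratch per
fold, score the fold's test samples, pool all test scores of the trial,
and compute one AUROC plus sensitivity and specificity. Multiple trials
(6 at full scale; 3 in desk-scale runs) differ only in seed, and results
are reported as mean ± sd **across trials** (the alternative, across
folds, would mix sampling noise of 10-sample folds into the spread).
AUROC uses the midrank (Mann–Whitney) formulation with half-credit ties,
validated in the tests against explicit pair counting and against an
independent ROC implementation. Sensitivity/specificity use a 0.5
threshold with `>=` counting as positive; the protocol's source states no
threshold, so this is exposed as an argument.

## Synthetic cohorts: what they do and do not show

Because the clinical corpora are private, `generate_cohort()` provides a
first-order generative stand-in. Per position: copy the previous token
with the class's repeat probability, start a geometric silence run with
its silence probability, otherwise sample uniformly from the class's
active vocabulary; length is a rounded normal. Defaults emulate the
clinical study shape — 10 CH + 10 AD subjects x 6 tests = 120 one-minute
samples — with deliberately large effect sizes (CH: length 150 ± 20,
silence 0.05, repeat 0.05, vocabulary 100; AD: length 60 ± 12, silence
0.30, repeat 0.20, vocabulary 30), chosen once so that classifier
recovery is stable at desk scale. True clinical effect sizes are not
derivable from published per-class token statistics, and no claim is made
that these match them.

Consequently, passing the end-to-end tests shows that the pipeline —
representation, training loop, early stopping, fold protocol, pooling,
metrics — is implemented correctly and can recover a strong,
known-to-exist class difference. It does **not** show that real AD/CH
speech is separable to any particular AUROC; that is an empirical
property of clinical data this package cannot certify.

`corrupt_sequence()` emulates transcription errors (independent per-token
substitution/deletion, geometric insertions) so the manual-vs-automatic
robustness experiment can be exercised in shape: the test suite checks
that 5% corruption costs at most 0.1 AUROC on the synthetic cohort.
`generate_toy_audio()` renders token sequences as pure-tone audio with
known frame alignments, which lets the CTC transcriber train to low token
error rates in minutes on a single CPU — a functional check of the full
audio path, not a statement about Mandarin acoustics.

## Numerical and degenerate-input decisions

* Log energies are floored (`log_floor`, default 1e-10) so silent audio
  yields finite features; CMVN floors per-bin variance and zeroes
  constant bins; audio shorter than one window is an error, never a
  silent 0-frame success.
* CTC is computed entirely in the log domain; an infeasible target
  (more required emissions than frames) yields `Inf` loss, which
  training treats as an error rather than a gradient.
* Greedy-decode ties break to the lowest class id; fold-plan shuffles,
  cohort draws, corruption and training are all driven by explicit seeds
  and are bit-reproducible (asserted in the tests).
* Desk-scale problem sizes used by the test suite and the acceptance
  script — 120-sequence cohorts, 16-cell engines, 30-epoch caps, 3
  trials, 800 CTC iterations on 16 toy utterances — are the package's
  own choices to keep a full run in minutes on one CPU; all full-scale
  values remain the configuration defaults.

## Known limitations

* The shipped syllable list is a stand-in; the true reduced ZhuYin
  inventory underlying the token-space size is not reconstructible from
  public sources, and no tone-stripping or unit-merge rules are
  implemented.
* The transcriber trains and decodes correctly but is exercised only on
  toy audio here; training it to useful quality requires hundreds of
  hours of transcribed speech and is out of desk scope.
* Beam search, language models, attention, per-test-type engines and
  joint transcriber/engine training are out of scope.
* The fine-tuning-on-automatic-transcription experiment is supported
  only in shape (corruption model + continue-training via the generic
  train entry points); no claim is made about its clinical numbers.
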