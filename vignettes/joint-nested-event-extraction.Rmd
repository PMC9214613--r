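---
title: "Joint extraction of nested biomedical events: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint extraction of nested biomedical events: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioevents)
```

## The problem

Biomedical event extraction recovers structured statements — *what happened,
to which entities, caused by what* — from sentences in the literature. An
**event** is anchored by a **trigger** (a word or phrase whose label is the
event type, e.g. *expression* for a gene-expression event) and takes typed
**arguments** via semantic roles, here the core roles `Theme` and `Cause`.
What makes the biomedical flavour hard is **nesting**: an argument of a
regulation-type event may itself be an event, as in "TNF-alpha causes the
positive regulation of IL-8 expression", where the expression event fills the
Theme slot of the regulation event. Pipelines that first tag triggers and
then classify arguments compound their errors across stages; this package
implements a *joint* extractor in which the trigger classifier's full softmax
distribution is fed into the argument-role classifier, so role decisions
condition on trigger uncertainty and both tasks train against a single loss.

## The model

Per sentence, each token $w_i$ is embedded as $x_i = [a_i; b_i; c_i]$:

* $a_i$ — a frozen contextual embedding (a pretrained transformer when a
  provider is supplied; otherwise the deterministic fallback, a seeded
  unit-variance vector keyed by the token surface, so all experiments run
  offline);
* $b_i$ — a trained POS-tag embedding;
* $c_i$ — a trained embedding of the token's entity BIO label (entities are
  inputs, not predictions).

With the reference dimensions $768+64+64$ the fused width is $\mu = 896$;
the desk-scale configuration used by the tests (`toy_model_config()`) is
$32+8+8$ with a 32-unit BiLSTM per direction and a 64-unit tagger.

A 1-layer **BiLSTM** (hidden size $\varphi$ per direction) gives the context
matrix $L \in \mathbb{R}^{n\times 2\varphi}$.

In parallel, the dependency parse is collapsed into a three-relation
multigraph: for each arc one `along` edge (head → dependent), one `rev` edge
(dependent → head), and a `loop` self-edge per token — the ~50 parser
relation labels are discarded, only the direction class matters, and a
sentence with $a$ arcs has exactly $2a+n$ edges. A stacked (default
2-layer) **gated GCN**, initialised from the contextual embeddings,
propagates along these edges: edge $(u,v)$ with relation $r$ contributes
$g_{uv}\,(W_r h_u + b_r)$ to $v$, with a scalar sigmoid gate
$g_{uv} = \sigma(V_r h_u + d_r)$ learning edge importance; the incoming sum
passes through a ReLU, unnormalised (no neighbour-count division — the gates
can learn to damp high-degree nodes). **Multi-head self-attention** (2 heads)
over the GCN output yields the syntax matrix $M$; the head-averaged score
matrix is what `sentence_attention()` renders as a heat map.

A unidirectional **tagger LSTM** reads $[L; M]$ and produces the source
matrix $O$. The trigger head computes per-token distributions
$\mathrm{soft}_k = \mathrm{softmax}(W^{tri} O_k + b^{tri})$ over the BIO
trigger vocabulary ($2\cdot 19 + 1 = 39$ labels for a 19-type corpus). For
each (trigger span, candidate) pair — candidates are the sentence's entities
and every *other* trigger — the trigger and candidate vectors are mean-pooled
over their spans from the **fused representation** $[O_k; \mathrm{soft}_k]$
and concatenated; a softmax over $\{Theme, Cause, None\}$ decides the role.
Pooling is mean, so concatenate-then-pool equals pool-then-concatenate.
Every predicted trigger becomes exactly one event (the trigger category *is*
the event type); trigger-typed fillers resolve to that trigger's event,
which is how nested structures are emitted directly, with no postprocessing.
If predicted event-event links would form a cycle, links are admitted in
decreasing probability and cycle-closing links dropped, so the output is
always a valid standoff document.

## The joint Dice loss

Biomedical BIO tagging is heavily imbalanced (most tokens are `O`, most
candidate pairs are `None`). Cross-entropy, being accuracy-oriented, buys
precision at the cost of recall in this regime. The package's default loss
is the self-adjusting Dice loss, per scored decision
$$\ell(p) = 1 - \frac{2\,(1-p)^\beta\, p \cdot y + \lambda}
                     {(1-p)^\beta\, p + y + \lambda},$$
applied with $y=1$ to the probability the model assigns to the decision's
gold label; the $(1-p)^\beta$ factor down-weights easy examples, which is
what balances precision and recall. The per-sentence loss is the reduced sum
of the token-level trigger term and the pair-level role term, weighted
equally, averaged over sentences; a cross-entropy twin
(`cross_entropy_loss()`) exists for the ablation.

Three numerical choices deserve justification:

* **Within-sentence reduction.** Both `sum` (default) and `mean` are
  implemented. The defining equation's inner reduction is ambiguous in the
  source material, and the choice interacts strongly with the fixed
  optimiser: with plain SGD at learning rate 0.01, the mean divides every
  token gradient by sentence length, and at desk scale the tagger then
  cannot escape the all-`O` collapse within a few hundred epochs. The sum —
  which is also what the published reference implementation of this Dice
  loss uses over a batch — keeps the per-decision gradient independent of
  sentence length.
* **Smoothing $\lambda$ and focusing $\beta$.** Neither value is stated in
  the source material; `model_config()` defaults to $\lambda=\beta=1$ and
  both are exposed. Two structural properties of the self-adjusting form
  matter in practice. First, with $y=1$ the per-decision loss is minimised
  where $w = (1-p)^\beta p$ peaks, at $p^* = 1/(1+\beta)$: at $\beta = 1$
  the optimum sits exactly on the argmax boundary ($p^* = 1/2$), so
  converged decisions have no margin and flip chaotically under SGD noise;
  at $\beta = 1/2$ the optimum moves to $2/3$ and decoding stabilises,
  while the $(1-p)^\beta$ down-weighting of easy examples is retained.
  Second, the gap between a wrong prediction ($p \to 0$) and the optimum
  shrinks as $\lambda$ grows — at $\lambda = 1$ it is only $\tfrac12 -
  \tfrac13$, at $\lambda = 0.01$ about $0.4$. The desk-scale
  configuration therefore uses $\lambda = 0.01$, $\beta = 1/2$; these are
  optimisation-geometry choices, not a change of loss family.
* **Equal task weighting.** No weighting between the trigger and role terms
  is described; they enter with weight 1 each.

## Initialisation

The training conditions are deliberately spartan — plain SGD, learning rate
0.01, dropout 0.3, no momentum, no scheduler — so the starting point
matters. A randomly initialised stack of two LSTMs propagates a large
token-independent mean while the per-token variation that carries the
labelling signal shrinks to standard deviations of order $10^{-2}$ by the
source matrix; the classifier heads then receive vanishing gradients and the
model sits in an all-`O` collapse essentially indefinitely at this learning
rate. `calibrate_model()` therefore performs a data-dependent,
layer-sequential initialisation before training, in the spirit of
unit-variance initialisation schemes: running over the training sentences
once per module, it rescales each unit's incoming weights and absorbs the
data mean into the bias so that pre-activations are centred with unit
variance (BiLSTM, each GCN layer, the attention output projection, the
tagger, and both classifier heads), sets LSTM input/output gate biases to
+1 (mostly-open gates: the current token passes through at initialisation)
and gives the tagger's input weights an extra gain of 2.5, pushing its gates
into their high-contrast regime so that $O$ carries strong per-token
variation. Calibration only changes the starting point of optimisation —
the architecture and the number of parameters are untouched.

## Training procedure

`train_event_model()` follows the standard joint recipe per batch: run the
encoder to get $L$ and $M$, concatenate, run the tagger to get $O$, compute
the trigger softmax, fuse and classify the enumerated pairs, evaluate the
joint loss, backpropagate, update every parameter. Specifics:

* optimiser: plain SGD, learning rate 0.01, dropout 0.3 on the fused input
  embeddings and the tagger input (inverted dropout; evaluation is
  dropout-free);
* candidate pairs during training use gold trigger *locations* (teacher
  forcing) while the fused distribution is the model's own prediction;
* batches: sentences sorted by length then chunked (deterministic and
  memory-stable); batch size defaults to 1, because at a fixed small
  learning rate toy corpora need many updates per epoch — epoch counts and
  batch sizes are not stated in the source material and are exposed as
  configuration;
* global gradient-norm clipping at 5: plain SGD otherwise suffers rare
  exploding-recurrent-gradient steps that can destroy a converged run in a
  single update;
* all gradients come from a reverse-mode autodiff tape written for this
  package (no deep-learning framework is involved); its correctness is
  pinned by finite-difference tests over every parameter group;
* determinism: the same model, data and seed give bit-identical parameters.

## The synthetic corpus

`generate_corpus()` emits seed-deterministic toy corpora in exactly the
dialects the readers consume: standoff triples plus CoNLL-U with
document-level character offsets. Sentences are templated ("the
*expression* of IL-2 was observed", "STAT3 caused the *positive regulation*
of the *vessel development* of fibroblasts"), with multi-token trigger
surfaces sampled with configurable probability, projective template-defined
dependency trees, and a closed POS set. Gold events are derived by applying
a configurable `role_rule` — a deterministic map from (trigger type,
candidate kind) to a role — to every intra-sentence (trigger, candidate)
pair, so the correct role is a function the model can in principle learn
perfectly; nested sentences contain one regulation-type trigger whose Theme
is the inner event. Default conditions: 10 documents × 5 sentences (50
sentences), nesting probability 0.3 per root event, multi-token trigger
probability 0.3. Two opt-in conditions support the ablation experiments:
`no_event_prob` mixes in entity-only filler sentences, diluting the trigger
tokens to the heavily imbalanced (~95% `O`) regime the loss comparison
needs; `ambiguous_triggers` adds surfaces shared between a simple and a
regulation type ("induction", "stimulation"), so the event type — and with
it the correct role — is resolvable only from sentence context, which is
precisely when fusing the trigger distribution into the role classifier
carries non-redundant information.

What the generator does *not* emulate — and hence what passing tests do not
show about real corpora: lexical ambiguity (a surface form is never two
different trigger types), long-range or cross-sentence arguments, parser
noise (trees are template-truth), discontinuous entities, multiple events
anchored on one trigger, and realistic class imbalance beyond the
mostly-`O` token distribution. Results on the toy corpus demonstrate that
the machinery — representations, fusion, loss, decoding — can express and
learn nested event structure, not that it reaches any particular accuracy
on MLEE-like data; the published headline numbers for this architecture
require the licensed corpora, a pretrained biomedical transformer and
GPU-scale training, all outside this package's scope.

## Evaluation

`evaluate_events()` scores strictly: a trigger is correct on exact span and
type; an event is correct under recursive structural equality (same matched
trigger, same multiset of (role, filler), event fillers compared
recursively). Micro-averaged precision/recall/F1 are reported overall and
stratified **simple** versus **nested** — structurally by default (an event
is nested when some filler is an event), or by the coarse type rule
(regulation-family and planned-process types) via `nested_rule = "type"`.
Undefined precision (no predictions) is reported as 0. Strict matching is
conservative relative to shared-task approximate-span scoring; it is also
exactly reproducible, which matters more here.

## Problem sizes used by the test-suite and acceptance runs

The packaged experiments run on one CPU with the desk-scale configuration:
oracle-equivalence checks on random graphs of up to 10 tokens; round-trip
properties over 100 seeded documents; learnability on the default
50-sentence corpus trained up to 300 epochs; ablations (fusion versus
shared-source, Dice versus cross-entropy) on held-out splits of generated
corpora over 5 seeds with shorter budgets. These sizes were chosen as the
smallest that make the qualitative claims crisp.

## Ablation experiments at desk scale

The packaged experiments include the two ablations this architecture is
usually judged by: fusion versus the shared-source (soft-trigger) variant on
held-out data, and the Dice loss versus cross-entropy on a mostly-`O`
tagging task. Both are run exactly as specified — five paired seeds, equal
budgets per arm — but a caveat belongs here rather than in fine print: with
corpora of a few dozen sentences, held-out F1 varies enormously from run to
run, and a fully learnable closed-lexicon task lets cross-entropy fit the
data outright instead of exhibiting its large-corpus precision skew. The
directional claims these ablations probe are therefore weakly identified at
desk scale; the tests report whatever the fixed-seed runs measure, and the
acceptance script writes the underlying means so the reader can see the
effect sizes next to the run-to-run spread.

## Known limitations

* The contextual fallback embedder is a hash, not a language model: tokens
  are featurised by identity, not context, so polysemy is invisible.
* One event per trigger: corpora where a single trigger anchors several
  events are collapsed to the first.
* Sentence-level only: cross-sentence argument links are dropped with a
  warning at preparation time.
* Equiv lines, modification annotations and non-core roles of the standoff
  dialect are out of scope; role vocabularies beyond {Theme, Cause} are
  configurable but untested beyond the schema checks.
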