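# bioevents

Joint extraction of (possibly nested) biomedical events from annotated
sentences, in pure R.

Biomedical text mining represents a statement such as *"TNF-alpha causes the
positive regulation of IL-8 expression"* as **events**: an event is anchored
by a **trigger** (a word or phrase whose label is the event type) and takes
typed arguments through semantic roles (`Theme`, `Cause`). Crucially, an
argument may itself be an event — the expression event above fills the
Theme slot of the regulation event — and these **nested** structures are
where pipeline systems (tag triggers first, classify arguments second)
suffer most, because errors cascade across stages.

This package implements a *joint* neural extractor:

* per-token inputs `x_i = [a_i; b_i; c_i]` — contextual, POS and entity-BIO
  embeddings (a deterministic surface-keyed fallback embedder makes
  everything runnable offline);
* a BiLSTM context encoder producing `L`;
* a **gated graph convolutional network** over the dependency parse,
  simplified to three relation classes (along-arc, reversed-arc, self-loop);
  each edge's message is scaled by a learned sigmoid gate; two-head
  self-attention over the GCN output gives the syntax matrix `M`;
* a tagger LSTM over `[L; M]` producing the source matrix `O`, a softmax
  trigger head over the BIO trigger vocabulary, and an argument-role head
  that classifies every (trigger, candidate) pair from span-pooled
  `[O_k; soft_k]` features — the trigger classifier's **probability
  distribution is fused into the role classifier**, so argument decisions
  condition on trigger uncertainty;
* a joint **self-adjusting Dice loss**
  `1 − (2(1−p)^β p y + λ) / ((1−p)^β p + y + λ)` over both tasks, suited to
  the heavy class imbalance of BIO tagging (a cross-entropy twin exists for
  ablation);
* strict recursive evaluation with a simple/nested stratification, standoff
  (`.txt`/`.a1`/`.a2`) and CoNLL-U I/O, and a seed-deterministic synthetic
  corpus generator so the whole system is testable without downloads.

Training uses no deep-learning framework: gradients come from a small
reverse-mode autodiff tape included in the package and verified against
finite differences.

## Worked example

```r
library(bioevents)

# a 50-sentence synthetic corpus: standoff + CoNLL-U + gold emission log
corp  <- generate_corpus(generator_config(n_docs = 10, sentences_per_doc = 5,
                                          nesting_prob = 0.5, seed = 7))
model <- event_model(toy_corpus_schema(), toy_model_config(), seed = 1)
sents <- prepare_corpus(corp, model)
model <- calibrate_model(model, sents)      # data-dependent initialisation
model <- train_event_model(model, sents, epochs = 300, seed = 71)  # ~4 min on one CPU

gold <- lapply(corp$docs, `[[`, "document")
rep  <- evaluate_events(gold, predict_corpus(model, corp))
glance(rep)
```

```
#> # A tibble: 1 × 6
#>   trigger_precision trigger_recall trigger_f1 event_precision event_recall event_f1
#>               <dbl>          <dbl>      <dbl>           <dbl>        <dbl>    <dbl>
#> 1               100            100        100             100          100      100
```

A perfect score here means the model has memorised the training corpus —
the point of the exercise: the joint machinery (graph convolution, fusion,
Dice loss, nested decoding) can represent and learn nested event structure
end to end on one CPU. `tidy(rep)` breaks the metrics down by task and by
the simple/nested stratum; `autoplot(model)` shows the loss curve, and

```r
autoplot(sentence_attention(model, sents[[3]]))
```

renders the head-averaged attention heat map for a sentence (trigger rows
attend to their arguments).

Predicted documents are valid standoff annotation; `write_standoff(doc,
dir)` emits `.a2` files whose nested events reference other events'
ids.

## Command-line interface

A thin Rscript front end lives at `inst/cli/bioevents.R`:

```sh
Rscript inst/cli/bioevents.R simulate --out corpus/ --docs 10 --seed 7
Rscript inst/cli/bioevents.R validate corpus/
Rscript inst/cli/bioevents.R train    --corpus corpus/ --model ckpt.json --epochs 300
Rscript inst/cli/bioevents.R predict  --corpus corpus/ --model ckpt.json --out pred/
Rscript inst/cli/bioevents.R evaluate --gold corpus/ --pred pred/ --report report.json
Rscript inst/cli/bioevents.R attend   --corpus corpus/ --model ckpt.json --sentence 3 --out att.tsv
```

## Scope

Entity recognition is an input (gold entities), as is dependency parsing
(CoNLL-U produced by an external parser). Cross-sentence argument links,
equiv/modification standoff lines and non-core roles are out of scope. See
the methods vignette (`vignettes/joint-nested-event-extraction.Rmd`) for
the model's assumptions, the initialisation scheme, and what the synthetic
corpus does and does not emulate.
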