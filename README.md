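# kgrepur

Explainable, rule-based knowledge-graph completion for drug repurposing.

## The problem

Drug repurposing asks which diseases an existing compound might treat.
On a heterogeneous biomedical knowledge graph — typed nodes (Compound,
Disease, Gene, Anatomy, Side Effect, ...) connected by labelled edges
stored as triples *(h, r, t)* — the question becomes link prediction for
one target relation: given the query *q = (c, treats)*, rank candidate
diseases *d* by *p(d | G, q)*. Black-box embedding methods answer this
ranking question but cannot tell a pharmacologist *why*; the clinical
follow-up starts from the mechanism, not the score. `kgrepur` is built
for that audience: every prediction it makes is carried by **metapath
rules** — typed relation sequences such as

```
Compound --upregulates--> Gene --is expressed by--> Anatomy --is localized to--> Disease
```

— and by the concrete grounded paths that instantiate them, so each
candidate disease arrives with a human-readable justification and a
Cypher query that pulls the supporting paths out of a Neo4j copy of the
graph.

## The method

Three layers, each usable on its own:

1. **Bottom-up rule mining.** Random walks from the head of a known
   *(c, treats, d)* triple that land on *d* are generalised (entities
   replaced by their node types) into candidate rules. Each rule's
   **confidence** is the fraction of distinct (head, tail) pairs its body
   connects that are known treats pairs. A grounding may never travel
   through the very *(h, treats, t)* edge it would predict.
2. **Aggregation.** Several rules usually propose the same candidate.
   Scores are combined by the **maximum** rule confidence, by
   **noisy-OR** (`1 − Π(1 − c_i)`), or by **non-redundant noisy-OR**
   (rules whose grounding sets are nested are collapsed first).
3. **An EM-trained generator/predictor model** (`kg_train()`). An
   autoregressive **rule generator** `p_θ(z | q)` over relation
   sequences, initialised on the mined rules, proposes K rules per
   iteration; a log-linear **reasoning predictor**
   `p_ω(d | G, q, z) ∝ exp Σ_z ω_z log(1 + n_paths)` is fitted by
   maximum likelihood; each rule gets a quality score **H** (its
   leave-one-out likelihood gain plus a generator-prior term) and the
   generator is re-fitted on the best rules, weighted by H clipped at
   zero. The fitted object is a classed model with `print`, `summary`,
   `coef`, `predict`, `simulate` and `logLik` methods.

Evaluation follows the **filtered-rank** protocol (tail direction): the
compound's other known true diseases are removed before ranking the
held-out answer, and MRR / Hits@{1,3,10} are reported with exact
Clopper–Pearson binomial intervals (and a bootstrap interval for MRR),
because repurposing test sets are far too small for the Gaussian
approximation.

Because the real benchmark graphs are large downloads, the package ships
a seeded **synthetic generator** (`kg_synth_bundle()`): a typed graph in
which treats edges are created exactly where planted metapaths connect a
compound to a disease, plus configurable spurious-edge noise — so
mining, training, evaluation and explanation are all testable offline,
with a ground-truth ledger of planted rules and witnessing paths.

## Worked example

```r
library(kgrepur)

bundle <- kg_synth_bundle(kg_synth_config(seed = 1))
rules  <- kg_mine(bundle$split$traversal, bundle$split$train,
                  kg_budget(max_samples = 20000), seed = 1)
print(rules, n = 3)
#> Rule set: 14 rule(s) for target(s) CtD
#>   confidence support body_groundings target
#> 1  0.8125000     117             144    CtD
#> 2  0.8125000      52              64    CtD
#> 3  0.7692308      70              91    CtD
#>                                                       body provenance
#> 1 Compound -CuG-> Gene -AeG^-1-> Anatomy -DlA^-1-> Disease      mined
#> 2       Compound -CuG-> Gene -GrG-> Gene -DaG^-1-> Disease      mined
#> 3 Compound -CbG-> Gene -AeG^-1-> Anatomy -DlA^-1-> Disease      mined
```

The three top-confidence rules are exactly the planted metapaths: each
connects ~100 compound–disease pairs of which ~80% carry a known treats
edge in the training split (the rest are held out or noise). Fit the
model and rank diseases for a held-out compound:

```r
model <- kg_train(bundle$split$traversal,
                  data.frame(head = bundle$split$train$head,
                             tail = bundle$split$train$tail),
                  rules, kg_train_config(seed = 1))
pred <- predict(model, bundle$split$traversal, "Compound::C006", top_k = 3)
print(pred)
#> Model prediction for Compound::C006
#>                   candidate probability n_rules
#> Disease::D002 Disease::D002    0.135715       1
#> Disease::D003 Disease::D003    0.135715       1
#> Disease::D019 Disease::D019    0.135715       1
```

The tied top candidates are precisely the diseases reached by planted
paths from C006 (its true treats partners); the remaining ~30 diseases
share the residual probability. The report explains each candidate:

```r
rep <- kg_build_report(pred, bundle$split$traversal, top_k = 1)
cat(kg_report_markdown(rep), sep = "\n")
#> ## Disease::D002 (score 0.135715)
#> | rule_quality_H | paths | rule |
#> |---:|---:|---|
#> | 208.115 | 1 | [Compound --upregulates--> Gene --is expressed by--> Anatomy --is localized to--> Disease] |
#> - C006 --upregulates--> G104 --is expressed by--> A010 --is localized to--> D002
#> MATCH path = (n0:Compound {identifier: "Compound::C006"})-[:UPREGULATES_CuG]->(n1:Gene)<-[:EXPRESSES_AeG]-(n2:Anatomy)<-[:LOCALIZES_DlA]-(n3:Disease {identifier: "Disease::D002"}) RETURN path
```

`rule_quality_H` is the trained rule-quality score (higher = more useful
for prediction); `paths` counts the grounded witnesses; the Cypher query
retrieves them from a Neo4j deployment of the same graph.

Real graphs load the same way: `kg_read(path, dialect = "hetionet")`
accepts the public Hetionet edge file (`source/metaedge/target` header,
`Type::Id` node identifiers), and `kg_split()` accepts an inherited
external split so published train/test partitions can be reproduced
exactly.

A command-line wrapper with subcommands
`synth | mine | train | predict | evaluate | explain | run` lives at
`inst/cli/kgrepur.R`.

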