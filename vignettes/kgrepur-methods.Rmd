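---
title: "Rule-based knowledge-graph completion for drug repurposing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based knowledge-graph completion for drug repurposing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kgrepur)
```

## The model

A knowledge graph $\mathcal{G}$ is a set of triples $(h, r, t)$ over
typed entities. Repurposing is link prediction for one target relation:
for the query $q = (c, \mathrm{treats})$ we want
$p(d \mid \mathcal{G}, q)$ over diseases $d$. `kgrepur` factorises this
through latent metapath rules $z$ (typed relation sequences):

$$p_{\omega,\theta}(d \mid \mathcal{G}, q)
  = \sum_z p_\omega(d \mid \mathcal{G}, q, z)\, p_\theta(z \mid q),$$

a **rule generator** $p_\theta$ proposing rules and a **reasoning
predictor** $p_\omega$ grounding them in the graph. Rules make the
prediction auditable: the grounded paths *are* the explanation.

### Rules, groundings, confidence

A rule's body is an ordered list of (relation, node-type) steps; both
endpoints are variables, never constants — only fully general rules can
be expressed by a generator whose vocabulary is the relation set, and
only they transfer across compounds. The graph is inverse-augmented
(every $(h,r,t)$ gains $(t, r^{-1}, h)$, label suffix `^-1`,
involutive), so bodies traverse edges in both directions.

A grounding of a rule for the pair $(h, t)$ is a path instantiating the
body from $h$ to $t$. Three exclusions apply everywhere (mining,
confidence, application, the mock Cypher matcher):

* $h \ne t$ — an entity is never its own answer;
* the inverse of the target relation never appears in a body (it would
  explain each triple by its own reversal);
* a grounding may not step across the direct $(h, \mathrm{treats}, t)$
  edge of the very pair it supports, in either direction. Without this
  rule, bodies containing `treats` (for example
  *compound–gene–compound–treats–disease* similarity rules) ground every
  training pair through the pair's own edge — walks may revisit nodes —
  which inflates their confidence and their maximum-likelihood weight and
  collapses held-out ranking; the exclusion removes exactly the
  self-supporting groundings while keeping genuine cross-compound
  evidence. A live Neo4j execution of an emitted Cypher query does not
  apply this filter and may return the one additional self-supporting
  path.

Confidence is the rate of correct positive predictions among all
inferred predictions: distinct body-connected pairs are the predictions
(several paths to one pair count once), pairs that are known treats
triples are the support.

### Mining

The miner samples a training triple, walks `length` random edges from
its head on the traversal graph, and keeps walks that land on the tail;
the walk is generalised by replacing entities with their node types.
Distinct rules are scored and filtered by support and confidence.
Defaults: 100,000 walk attempts, body lengths 1–3, minimum support 2,
minimum confidence 0.01 — a budget that saturates the small study graphs
here in seconds and is configurable for larger graphs. Mining is
deterministic per seed and invariant to the input triple order (triples
are canonicalised before sampling).

### Aggregation

`max` keeps the best rule confidence (ties between candidates broken by
the lexicographic cascade over sorted score vectors); `noisy_or`
computes $1 - \prod_i (1 - c_i)$, treating rules as independent noisy
detectors; `nr_noisy_or` first collapses redundant rules — two rules are
redundant when one's grounding pair set contains the other's, a
deterministic simplification of learned redundancy clustering — taking
the maximum within a cluster and noisy-OR across clusters.

### The generator

$p_\theta(z \mid q)$ must support exact likelihood evaluation and
sampling of relation sequences up to length $L_{\max}$. The
implementation is an order-2 autoregressive categorical model: the next
token (relation or end) is a softmax over logits indexed by the previous
two tokens. The end token is masked at the first position and forced
beyond $L_{\max}$, so the probabilities of all bodies of length
$1..L_{\max}$ sum to one exactly. With $L_{\max} = 3$ an order-2 context
spans the whole body, so the model can represent any distribution over
the rule space while remaining exactly normalised and cheap to train by
teacher-forcing gradient ascent — properties a recurrent network matches
only approximately. Conditioning on $q$ is a constant for the single
target relation and is kept in the interface for multi-relation
extension. The target's inverse is excluded from the vocabulary.

### The predictor and filtered training

Scores are linear in per-rule evidence:
$\mathrm{score}(d) = \sum_z \omega_z\,\varphi(n_{\mathrm{paths}}(c,z,d))$
with $\varphi(n) = \log(1+n)$ (raw counts available by config); the
logarithm bounds the influence of hub-heavy neighbourhoods. The
distribution is the softmax over all entities of the answer type;
ungrounded candidates keep the zero baseline.

Training maximises the likelihood of the true answers by full-batch
gradient ascent, with a **filtered partition function**: each training
instance's other known true answers are masked from its softmax. This
mirrors the filtered evaluation protocol — a rule should be rewarded for
separating the answer from *wrong* candidates, not from the compound's
other true diseases, which no rule can (or should) distinguish. The
objective is concave in $\omega$, and the mean-normalised gradient makes
the trajectory invariant to duplicated instances.

### Rule quality and EM

Each EM iteration samples $K$ rules (default 100), fits the predictor,
scores every rule with

$$\mathcal{H}(z) = \sum_{q} \left[\log p_\omega(d^\ast \mid Z)
  - \log p_\omega(d^\ast \mid Z \setminus \{z\})\right]
  + \lambda \left[\log p_\theta(z) - \log p_0(z)\right],$$

and re-fits the generator on the top-$I$ rules (default 20) by maximum
likelihood weighted by $\mathcal{H}$ clipped below at zero. The first
term is the summed leave-one-out likelihood gain — a rule is credited
once for every training query it improves, and is exactly zero for a
rule that grounds nothing. The second term is the generator's preference
for the rule over the uniform-logit generator $p_0$ of the same body
length ($\lambda = 1$ by default). The centring matters: raw log-priors
of multi-token bodies are always several nats below zero, which would
push every $\mathcal{H}$ negative and make the clipped weighting vacuous;
measured against chance, junk rules score negative (clipped out) and
informative rules positive, so the clip does its intended job of
concentrating the generator. The per-iteration joint objective
$\sum_z p_\theta(z \mid q)\, p_\omega(d^\ast \mid \mathcal{G}, q, z)$ is
logged.

Defaults: 5 EM iterations, predictor 200 epochs at learning rate 0.5,
generator 100 epochs at 1.0, pretraining 300 epochs. On the study graphs
the generator concentrates on the planted rules within 2–3 iterations.

## Evaluation

Tail-direction filtered ranking: for each held-out $(c, d^\ast)$ the
compound's other known answers (train, validation, other test) are
removed, and the rank is $1 + \#\{\text{strictly above}\} +
\#\{\text{ties}\}/2$ — mean-over-ties is deterministic and unbiased,
where optimistic or pessimistic tie-breaking would not be. Summaries
report MRR and Hits@{1,3,10}. Because test sets of a few dozen queries
are too small for Gaussian intervals, Hits proportions carry exact
Clopper–Pearson bounds (Wilson by option) and MRR a seeded bootstrap
percentile interval (10,000 resamples by default). The exact 90%
Clopper–Pearson coverage at $n = 82$, $p = 0.5$ is 0.903.

## The synthetic study system

`kg_synth_config()` emulates the shape of a biomedical graph: 50
compounds, 30 diseases, 200 genes, 20 anatomies, 40 side effects;
background edges drawn independently per relation between the declared
endpoint types (Erdős–Rényi); treats edges placed exactly where at least
$\tau = 1$ grounded path of a planted metapath connects a compound to a
disease; and spurious treats edges added at rate $\rho = 0.02$ per
non-qualifying pair (~25 spurious against ~260 genuine edges, i.e.
roughly 10% label noise — of the order of the curation noise expected in
real repurposing edge sets). The planted metapaths are three-step
compound-to-disease rules of the kind recovered on real graphs
(upregulates/expressed-by/localized-to, upregulates/regulates/
associated-to, binds/expressed-by/localized-to). Edge densities (CuG
0.015, CbG 0.01, AeG 0.03, DlA 0.05, GrG 0.005, DaG 0.02, CcSE 0.05)
were chosen so that a compound touches a handful of genes and a disease
a couple of anatomies, yielding ~290 treats edges among 1,500 pairs —
dense enough to split 80/10/10 (floor rounding, remainder to test) with
a meaningful test set, sparse enough that rule discovery is not trivial.
Spurious edges always go to the training split: they are label noise for
the learner, never credit for the evaluator.

What the generator does *not* emulate: the heavy-tailed degree
distributions, edge multiplicities and correlated annotations of curated
graphs. Passing tests therefore demonstrate correctness of the
machinery and recoverability under controlled conditions, not
performance on any real benchmark; metrics on the synthetic bundle
(MRR ≈ 1 at these noise levels) are upper bounds of a regime where the
planted mechanism is fully identifiable.

## Numerical and degenerate-case choices

* Softmax computations subtract the row maximum; predictor training
  aborts on a non-finite objective with learning-rate advice.
* A rule with zero body groundings is *unevaluable* (excluded), not a
  zero-confidence rule; an empty rule set yields the uniform predictor
  distribution with a notice; a query head with no outgoing edges is
  flagged `no_evidence`.
* Duplicate input triples collapse to one with a warning; entity ids are
  case-sensitive opaque strings.
* All stochastic operations take explicit seeds; pipeline stages draw
  deterministic substream seeds from the global seed.
* Problem sizes in the test-suite and acceptance runs (graphs of ~1,100
  triples, 100,000-walk mining budgets, $K = 100$, 5 EM iterations,
  three seeds) were chosen as the smallest conditions under which the
  recovery properties are stable.

## Known limitations

* Constant-bearing rules (specific intermediate entities) are out of
  scope; the generator vocabulary cannot express them.
* The redundancy criterion for non-redundant noisy-OR is subset
  containment of grounding sets, not a tuned similarity threshold.
* Checkpoints store generator logits as JSON; for vocabularies of
  thousands of relations a binary format would be preferable.
* Emitted Cypher assumes node identity lives in an `identifier` property
  and relationship types follow the `VERB_Abbrev` convention; both are
  overridable, and the emitted text is never executed by the package
  itself.
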