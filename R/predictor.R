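#' Reasoning predictor: log-linear scorer over rule groundings
#'
#' Given a query head and a rule set, the predictor scores every entity of
#' the answer type as score(d) = sum_z omega_z * phi(n_paths(head, z, d)),
#' where n_paths counts the grounded body paths of rule z from the head to
#' d and phi is `log(1 + n)` (or the raw count). Probabilities are the
#' softmax of the scores over the whole candidate universe; entities
#' reached by no rule keep the zero baseline score.
#'
#' `kg_features()` precomputes the per-query feature matrices; the other
#' functions consume them.
#'
#' @name kg_predictor
NULL

#' Precompute path-count features for a set of query heads
#'
#' @param graph traversal `kg_graph`
#' @param heads character vector of query head ids
#' @param rules a `kg_rules` data.frame
#' @param answer_type node type of the candidate universe (e.g.
#'   `"Disease"`)
#' @param transform `"log1p"` (phi(n) = log(1+n)) or `"count"`
#' @param max_paths stored-path cap handed to [kg_apply_rule()]
#' @return object of class `kg_features`: list with `universe` (sorted
#'   candidate ids), `rules`, and `phi`, a list (one matrix per head:
#'   universe x rules)
#' @export
kg_features <- function(graph, heads, rules, answer_type = "Disease",
                        transform = c("log1p", "count"), max_paths = 100L) {
  transform <- match.arg(transform)
  universe <- sort(graph$entities$id[graph$entities$type == answer_type])
  if (!length(universe)) stop("no entities of answer type ", answer_type)
  parsed <- kg_rules_parsed(rules)
  heads <- unique(heads)
  phi <- lapply(heads, function(h) {
    m <- matrix(0, nrow = length(universe), ncol = max(nrow(rules), 1L),
                dimnames = list(universe, NULL))
    for (i in seq_along(parsed)) {
      r <- parsed[[i]]
      th <- kg_type(graph, h)
      if (is.na(th) || th != r$types[1L]) next
      res <- kg_apply_rule(graph, h, r, max_paths = max_paths)
      hit <- intersect(names(res), universe)
      if (length(hit)) {
        m[hit, i] <- vapply(res[hit], `[[`, 0L, "n_paths")
      }
    }
    if (transform == "log1p") m <- log1p(m)
    m
  })
  names(phi) <- heads
  structure(list(universe = universe, rules = rules, phi = phi,
                 transform = transform, answer_type = answer_type),
            class = "kg_features")
}

#' Predictor probability distribution over the candidate universe
#'
#' @param features a `kg_features` (single head of interest included)
#' @param head query head id (must be present in `features`)
#' @param weights numeric vector omega, one per rule (zero = untrained)
#' @return named probability vector over the candidate universe (sums to 1)
#' @export
kg_predictor_distribution <- function(features, head, weights) {
  m <- features$phi[[head]]
  if (is.null(m)) stop("no features for head ", head)
  if (nrow(features$rules) == 0L) {
    message("empty rule set: returning the uniform distribution")
    p <- rep(1 / length(features$universe), length(features$universe))
    names(p) <- features$universe
    return(p)
  }
  stopifnot(length(weights) == ncol(m))
  s <- drop(m %*% weights)
  e <- exp(s - max(s))
  p <- e / sum(e)
  names(p) <- features$universe
  p
}

#' Train the predictor weights by maximum likelihood
#'
#' Full-batch gradient ascent on the log-likelihood of the true answers
#' under the softmax distribution. Training is filtered, mirroring the
#' filtered evaluation protocol: for each query instance the compound's
#' other known true answers are removed from the partition function, so a
#' rule is rewarded for separating the instance's answer from the wrong
#' candidates, not from the compound's remaining true diseases. The
#' objective is checked to be non-decreasing across epochs up to `tol`; a
#' non-finite loss aborts with advice to lower the learning rate.
#'
#' @param features a `kg_features` covering all training heads
#' @param queries data.frame with columns `head`, `tail` (true answers;
#'   one row per query instance)
#' @param epochs gradient-ascent epochs
#' @param lr learning rate
#' @param tol tolerated per-epoch objective decrease (logged)
#' @param weights optional warm-start omega
#' @param known data.frame of known true (head, tail) pairs used for
#'   filtering; defaults to `queries` itself
#' @return list `weights` (omega), `loglik` (per-epoch mean filtered
#'   log-likelihood)
#' @export
kg_train_predictor <- function(features, queries, epochs = 200L, lr = 0.5,
                               tol = 1e-6, weights = NULL, known = NULL) {
  stopifnot(nrow(queries) > 0L)
  miss <- setdiff(queries$head, names(features$phi))
  if (length(miss)) stop("features missing for head(s): ",
                         paste(miss, collapse = ", "))
  nr <- max(nrow(features$rules), 1L)
  w <- weights %||% numeric(nr)
  n <- nrow(queries)
  keep <- query_keep_indices(features, queries, known)
  ll_hist <- numeric(0)
  for (e in seq_len(epochs)) {
    grad <- numeric(nr)
    ll <- 0
    for (qi in seq_len(n)) {
      m <- features$phi[[queries$head[qi]]][keep[[qi]], , drop = FALSE]
      s <- drop(m %*% w)
      s <- s - max(s)
      p <- exp(s) / sum(exp(s))
      ti <- match(queries$tail[qi], features$universe[keep[[qi]]])
      ll <- ll + log(p[ti])
      grad <- grad + m[ti, ] - drop(crossprod(m, p))
    }
    ll <- ll / n
    if (!is.finite(ll)) {
      stop("predictor training diverged (non-finite loss); lower the learning rate")
    }
    if (length(ll_hist) && ll < ll_hist[length(ll_hist)] - tol) {
      kg_log(sprintf("predictor objective decreased at epoch %d (%.6g -> %.6g)",
                     e, ll_hist[length(ll_hist)], ll))
    }
    ll_hist <- c(ll_hist, ll)
    w <- w + lr * grad / n
  }
  list(weights = unname(w), loglik = ll_hist)
}

# Per-query candidate indices kept in the filtered partition function:
# the whole universe minus the head's other known true answers.
query_keep_indices <- function(features, queries, known = NULL) {
  known <- known %||% queries
  lapply(seq_len(nrow(queries)), function(qi) {
    truth <- queries$tail[qi]
    ti <- match(truth, features$universe)
    if (is.na(ti)) stop("true answer outside the candidate universe: ", truth)
    others <- setdiff(known$tail[known$head == queries$head[qi]], truth)
    setdiff(seq_along(features$universe), match(others, features$universe))
  })
}

# mean log-likelihood of true answers under weights w
predictor_loglik <- function(features, queries, w) {
  lls <- vapply(seq_len(nrow(queries)), function(qi) {
    p <- kg_predictor_distribution2(features, queries$head[qi], w)
    log(p[match(queries$tail[qi], features$universe)])
  }, 0)
  mean(lls)
}

# distribution without the empty-rule message (internal fast path)
kg_predictor_distribution2 <- function(features, head, w) {
  m <- features$phi[[head]]
  s <- drop(m %*% w)
  e <- exp(s - max(s))
  e / sum(e)
}

#' Rule-quality score H
#'
#' Combines prediction and generation evidence per rule: the summed
#' leave-one-out likelihood gain of the true answers when rule z is kept
#' in the rule set versus removed (a rule is credited once for every
#' training query it improves), plus `lambda` times the generator
#' log-probability of the rule body centred by the uniform-generator
#' log-probability of the same body (so the prior term measures how much
#' the generator favours the rule over chance, on a scale comparable to
#' the gain term, and the clipped weighting of the generator update stays
#' informative). Rules that ground nothing have a likelihood-gain term of
#' exactly zero.
#'
#' @param features a `kg_features` over the training heads
#' @param queries training queries (`head`, `tail`)
#' @param weights trained omega for the current rule set
#' @param gen the `kg_generator` (or `NULL` to drop the prior term)
#' @param lambda weight of the generator-prior term
#' @param known known (head, tail) pairs for filtered likelihoods;
#'   defaults to `queries`
#' @return numeric vector H, one entry per rule in `features$rules`
#' @export
kg_rule_quality <- function(features, queries, weights, gen = NULL,
                            lambda = 1, known = NULL) {
  nr <- nrow(features$rules)
  if (nr == 0L) return(numeric(0))
  n <- nrow(queries)
  keep <- query_keep_indices(features, queries, known)
  scores <- lapply(seq_len(n), function(qi) {
    features$phi[[queries$head[qi]]][keep[[qi]], , drop = FALSE]
  })
  tis <- vapply(seq_len(n), function(qi) {
    match(queries$tail[qi], features$universe[keep[[qi]]])
  }, 0L)
  full_ll <- vapply(seq_len(n), function(qi) {
    s <- drop(scores[[qi]] %*% weights)
    s <- s - max(s)
    log(exp(s[tis[qi]]) / sum(exp(s)))
  }, 0)
  H <- numeric(nr)
  parsed <- kg_rules_parsed(features$rules)
  for (z in seq_len(nr)) {
    gain <- 0
    for (qi in seq_len(n)) {
      m <- scores[[qi]]
      if (all(m[, z] == 0)) next        # rule grounds nothing for this query
      s <- drop(m %*% weights) - weights[z] * m[, z]
      s <- s - max(s)
      gain <- gain + full_ll[qi] - log(exp(s[tis[qi]]) / sum(exp(s)))
    }
    H[z] <- gain
    if (!is.null(gen) && lambda != 0) {
      body <- parsed[[z]]$relations
      H[z] <- H[z] + lambda * (kg_gen_loglik(gen, body) -
                                 gen_uniform_loglik(gen, length(body)))
    }
  }
  H
}
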