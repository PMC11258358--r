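#' Mining budget for bottom-up rule learning
#'
#' @param max_samples maximum number of random-walk attempts (may be `NULL`
#'   when `max_seconds` is given)
#' @param max_seconds optional wall-clock budget in seconds
#' @param lengths allowed body lengths L
#' @param min_support minimum confirmed groundings for a rule to be kept
#' @param min_confidence minimum confidence for a rule to be kept
#' @return a `kg_budget` list
#' @export
kg_budget <- function(max_samples = 100000L, max_seconds = NULL,
                      lengths = 1:3, min_support = 2L,
                      min_confidence = 0.01) {
  if (is.null(max_samples) && is.null(max_seconds)) {
    stop("set at least one of max_samples / max_seconds")
  }
  stopifnot(min_confidence >= 0, min_confidence <= 1, all(lengths >= 1L))
  structure(list(max_samples = max_samples, max_seconds = max_seconds,
                 lengths = as.integer(lengths),
                 min_support = as.integer(min_support),
                 min_confidence = min_confidence),
            class = "kg_budget")
}

#' Sample one random ground path explaining a target triple
#'
#' Performs a uniform random walk of `length` edges from the triple's head
#' over the traversal graph (inverse edges usable). The walk succeeds when
#' it lands exactly on the triple's tail. The direct target edge between
#' the triple's endpoints and any edge labelled with the target relation's
#' inverse are excluded as steps, so a triple can never explain itself.
#'
#' @param graph traversal `kg_graph`
#' @param triple a list/row with `head`, `relation`, `tail`
#' @param length number of edges to walk (>= 1)
#' @return on success, a list with `nodes` (length + 1 entity ids) and
#'   `relations` (length labels); `NULL` when the walk dies or misses
#' @export
kg_sample_ground_path <- function(graph, triple, length) {
  stopifnot(length >= 1L)
  target <- triple$relation
  banned_rel <- kg_inverse_label(target)
  nodes <- character(length + 1L)
  rels <- character(length)
  nodes[1L] <- triple$head
  cur <- triple$head
  for (i in seq_len(length)) {
    o <- kg_out(graph, cur)
    keep <- o$relation != banned_rel &
      !(o$relation == target & cur == triple$head & o$tail == triple$tail)
    if (!any(keep)) return(NULL)
    idx <- which(keep)
    j <- idx[sample.int(length(idx), 1L)]
    rels[i] <- o$relation[j]
    cur <- o$tail[j]
    nodes[i + 1L] <- cur
  }
  if (cur != triple$tail) return(NULL)
  list(nodes = nodes, relations = rels)
}

#' Generalize a ground path into a metapath rule
#'
#' Replaces every entity on the path by its node type, yielding a fully
#' general rule for the target relation. A length-1 path whose only
#' relation is the target itself is rejected as a degenerate identity rule.
#'
#' @param graph the `kg_graph` supplying node types
#' @param ground a list with `nodes` and `relations` (see
#'   [kg_sample_ground_path()])
#' @param target target relation label
#' @return a `kg_rule`
#' @export
kg_generalize <- function(graph, ground, target) {
  stopifnot(length(ground$nodes) == length(ground$relations) + 1L)
  kg_rule(target, ground$relations, kg_type(graph, ground$nodes))
}

#' Score a rule's confidence on the traversal graph
#'
#' Confidence is the rate of correct positive predictions among all
#' inferred predictions: the body is grounded from every entity of the
#' rule's head type, distinct (head, tail) pairs connected by at least one
#' body path are the predictions (`body_groundings`), and those that are
#' known target triples are the `support`. Pairs, not paths, are counted:
#' several paths to the same pair make one prediction. A rule with zero
#' groundings is unevaluable (`NA` confidence), not a zero-confidence rule.
#'
#' @param graph traversal `kg_graph`
#' @param rule a `kg_rule`
#' @param known_targets data.frame of known target triples (head, tail)
#' @return the rule with `support`, `body_groundings`, `confidence` fields
#'   attached
#' @export
kg_confidence <- function(graph, rule, known_targets) {
  pairs <- rule_grounding_pairs(graph, rule)
  rule$body_groundings <- nrow(pairs)
  if (nrow(pairs) == 0L) {
    rule$support <- 0L
    rule$confidence <- NA_real_
    return(rule)
  }
  known <- pair_key(known_targets$head, known_targets$tail)
  rule$support <- sum(pair_key(pairs$head, pairs$tail) %in% known)
  rule$confidence <- rule$support / rule$body_groundings
  rule
}

# All distinct (head, tail) grounding pairs of a rule's body, heads ranging
# over every entity of the rule's head type; h == t and pairs supported
# only through their own direct target edge are excluded.
rule_grounding_pairs <- function(graph, rule) {
  heads <- graph$entities$id[graph$entities$type == rule$types[1L]]
  out_h <- character(); out_t <- character()
  for (h in heads) {
    tails <- names(kg_apply_rule(graph, h, rule, max_paths = 1L))
    if (length(tails)) {
      out_h <- c(out_h, rep(h, length(tails)))
      out_t <- c(out_t, tails)
    }
  }
  data.frame(head = out_h, tail = out_t, stringsAsFactors = FALSE)
}

#' Mine metapath rules bottom-up by random-walk sampling
#'
#' AnyBURL-style miner: repeatedly picks a known target triple, samples a
#' random ground path between its endpoints, generalizes the path to a
#' rule, and deduplicates, until the sampling budget is exhausted. Every
#' distinct rule is then scored by [kg_confidence()]; rules passing the
#' support and confidence thresholds are returned sorted by confidence
#' (descending), ties broken by body string.
#'
#' @param graph traversal `kg_graph` (inverse-augmented)
#' @param known_targets data.frame of training target triples
#'   (head, relation, tail)
#' @param budget a [kg_budget()]
#' @param seed integer seed; the mined set is reproducible per seed and
#'   invariant to the input triple order
#' @return a `kg_rules` data.frame
#' @export
kg_mine <- function(graph, known_targets, budget = kg_budget(), seed = 1L) {
  stopifnot(inherits(graph, "kg_graph"), nrow(known_targets) > 0L)
  target <- unique(known_targets$relation)
  if (length(target) != 1L) stop("known_targets must share one relation")
  # order-invariance: canonicalize the triple order before sampling
  kt <- known_targets[order(known_targets$head, known_targets$tail), ,
                      drop = FALSE]
  seen <- new.env(hash = TRUE)
  with_seed(seed, {
    n_max <- budget$max_samples %||% .Machine$integer.max
    t0 <- Sys.time()
    i <- 0L
    while (i < n_max) {
      i <- i + 1L
      if (!is.null(budget$max_seconds) && i %% 256L == 0L &&
          as.numeric(Sys.time() - t0, units = "secs") > budget$max_seconds) break
      row <- kt[sample.int(nrow(kt), 1L), ]
      L <- budget$lengths[sample.int(length(budget$lengths), 1L)]
      g <- kg_sample_ground_path(graph, row, L)
      if (is.null(g)) next
      if (L == 1L && g$relations[[1L]] == target[[1L]]) next
      r <- kg_generalize(graph, g, target[[1L]])
      assign(rule_key(r), r, envir = seen)
    }
  })
  rules <- as.list(seen)
  if (!length(rules)) {
    warning("no rules mined within budget")
    return(new_rules_df(list()))
  }
  scored <- lapply(rules, kg_confidence, graph = graph,
                   known_targets = known_targets)
  df <- new_rules_df(scored,
                     support = vapply(scored, `[[`, 0L, "support"),
                     body_groundings = vapply(scored, `[[`, 0L, "body_groundings"),
                     confidence = vapply(scored, `[[`, 0, "confidence"))
  keep <- !is.na(df$confidence) &
    df$support >= budget$min_support &
    df$confidence >= budget$min_confidence
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("zero rules survive the support/confidence filters")
  }
  df <- df[order(-df$confidence, df$body), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("kg_rules", "data.frame")
  df
}
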