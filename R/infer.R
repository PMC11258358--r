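#' Apply a rule to a query head
#'
#' Depth-first expansion of the rule body from `head` on the traversal
#' graph, with sorted neighbour expansion so the result is deterministic.
#' Returns every reachable tail of the rule's tail type (the head itself
#' is never its own answer), with up to `max_paths` witnessing paths each;
#' the exact path count is always recorded, paths beyond `max_paths` are
#' simply not stored.
#'
#' @param graph traversal `kg_graph`
#' @param head query head entity id; its type must equal the rule's head
#'   type
#' @param rule a `kg_rule`
#' @param max_paths maximum number of stored paths per candidate (> 0)
#' @param exclude_direct drop groundings that traverse the direct target
#'   edge between the query head and the path's own tail (in either
#'   direction), so no pair is ever supported by the very triple being
#'   predicted
#' @return named list, one entry per candidate tail (sorted), each a list
#'   with `n_paths` (integer) and `paths` (list of entity-id vectors)
#' @export
kg_apply_rule <- function(graph, head, rule, max_paths = 100L,
                          exclude_direct = TRUE) {
  if (max_paths <= 0L) stop("max_paths must be positive")
  ht <- kg_type(graph, head)
  if (is.na(ht) || ht != rule$types[1L]) {
    stop(sprintf("head %s has type %s, rule expects %s", head, ht,
                 rule$types[1L]))
  }
  L <- length(rule$relations)
  tgt <- rule$target
  tgt_inv <- kg_inverse_label(tgt)
  acc <- new.env(hash = TRUE)
  walk <- function(node, depth, trail) {
    if (depth > L) {
      if (node == head) return(invisible(NULL))
      if (exclude_direct && path_uses_direct_edge(trail, rule$relations,
                                                  head, node, tgt, tgt_inv)) {
        return(invisible(NULL))
      }
      e <- get0(node, envir = acc, inherits = FALSE)
      if (is.null(e)) e <- list(n_paths = 0L, paths = list())
      e$n_paths <- e$n_paths + 1L
      if (length(e$paths) < max_paths) e$paths <- c(e$paths, list(trail))
      assign(node, e, envir = acc)
      return(invisible(NULL))
    }
    tails <- kg_tails(graph, node, rule$relations[depth])
    if (!length(tails)) return(invisible(NULL))
    tails <- sort(tails[kg_type(graph, tails) == rule$types[depth + 1L]])
    for (t in tails) walk(t, depth + 1L, c(trail, t))
    invisible(NULL)
  }
  walk(head, 1L, head)
  out <- as.list(acc)
  if (!length(out)) return(list())
  out[order(names(out))]
}

# TRUE when a grounded path steps across the direct (head, target, tail)
# edge of the pair it supports, forwards or backwards.
path_uses_direct_edge <- function(nodes, relations, head, tail, tgt, tgt_inv) {
  for (i in seq_along(relations)) {
    r <- relations[i]
    if (r == tgt && nodes[i] == head && nodes[i + 1L] == tail) return(TRUE)
    if (r == tgt_inv && nodes[i] == tail && nodes[i + 1L] == head) return(TRUE)
  }
  FALSE
}

#' Aggregate per-rule scores into one score per candidate
#'
#' Several rules typically propose the same candidate, so their scores
#' must be combined. Three strategies are supported: `max` keeps the
#' highest rule confidence (ties between candidates are broken by the
#' next-highest distinct confidence, lexicographic cascade); `noisy_or`
#' combines independent evidence as 1 - prod(1 - c_i); `nr_noisy_or`
#' first collapses redundant rules (max within a redundancy cluster) and
#' then applies noisy-OR across clusters.
#'
#' @param candidates named list: candidate id -> numeric vector of rule
#'   scores in `[0, 1]`; vector names identify the contributing rules
#' @param strategy `"max"`, `"noisy_or"` or `"nr_noisy_or"`
#' @param clusters named integer/character vector mapping rule key ->
#'   cluster id, required for `nr_noisy_or` (rules missing from it form
#'   singleton clusters)
#' @return data.frame `candidate`, `score`, `n_rules`, sorted by score
#'   descending, ties by candidate id (plus the cascade for `max`)
#' @export
kg_aggregate <- function(candidates,
                         strategy = c("max", "noisy_or", "nr_noisy_or"),
                         clusters = NULL) {
  strategy <- match.arg(strategy)
  if (length(candidates) == 0L) {
    return(data.frame(candidate = character(), score = numeric(),
                      n_rules = integer(), stringsAsFactors = FALSE))
  }
  for (s in candidates) {
    if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
      stop("rule scores must lie in [0, 1]")
    }
  }
  score_of <- function(s) {
    switch(strategy,
           max = max(s),
           noisy_or = 1 - prod(1 - s),
           nr_noisy_or = {
             cl <- if (!is.null(clusters) && !is.null(names(s))) {
               cli <- clusters[names(s)]
               ifelse(is.na(cli), paste0(".single.", names(s)), cli)
             } else seq_along(s)
             1 - prod(1 - vapply(split(s, cl), max, 0))
           })
  }
  sc <- vapply(candidates, score_of, 0)
  nr <- vapply(candidates, length, 0L)
  ids <- names(candidates)
  if (strategy == "max") {
    # lexicographic cascade over the sorted score vectors
    o <- order_score_cascade(candidates, ids)
  } else {
    o <- order(-sc, ids)
  }
  data.frame(candidate = ids[o], score = unname(sc[o]),
             n_rules = unname(nr[o]), stringsAsFactors = FALSE,
             row.names = NULL)
}

# Order candidates by their sorted-descending score vectors, padding with
# -Inf; final tie-break on candidate id.
order_score_cascade <- function(candidates, ids) {
  k <- max(vapply(candidates, length, 0L))
  m <- t(vapply(candidates, function(s) {
    s <- sort(s, decreasing = TRUE)
    c(s, rep(-Inf, k - length(s)))
  }, numeric(k)))
  if (k == 1L) m <- matrix(m, ncol = 1L)
  do.call(order, c(lapply(seq_len(k), function(j) -m[, j]), list(ids)))
}

#' Redundancy clusters for non-redundant noisy-OR
#'
#' Two rules are redundant when one's grounding (head, tail) pair set
#' contains the other's (equal sets included): the smaller rule adds no
#' prediction the larger does not already make. Rules are clustered
#' greedily by decreasing grounding-set size; each rule joins the first
#' cluster whose representative's set is a superset of its own.
#'
#' @param graph traversal `kg_graph` used to enumerate groundings
#' @param rules a `kg_rules` data.frame
#' @return named character vector: rule key (`target\rbody`) -> cluster id
#' @export
kg_redundancy_clusters <- function(graph, rules) {
  parsed <- kg_rules_parsed(rules)
  keys <- vapply(parsed, rule_key, "")
  sets <- lapply(parsed, function(r) {
    p <- rule_grounding_pairs(graph, r)
    pair_key(p$head, p$tail)
  })
  o <- order(-lengths(sets), keys)
  reps <- integer(0) # indices (into o-ordered list) of cluster representatives
  cluster <- character(length(sets))
  for (i in o) {
    placed <- FALSE
    for (rix in reps) {
      if (all(sets[[i]] %in% sets[[rix]])) {
        cluster[i] <- keys[rix]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      cluster[i] <- keys[i]
    }
  }
  structure(cluster, names = keys)
}

#' Rank candidate answers for a query with a rule set
#'
#' Applies every rule to the query head, pools the per-rule confidences
#' per candidate, aggregates them with the chosen strategy and returns the
#' `top_k` candidates. Each candidate keeps its full contribution list so
#' predictions stay explainable.
#'
#' @param graph traversal `kg_graph`
#' @param head query head entity id (e.g. a compound)
#' @param rules non-empty `kg_rules` data.frame (confidences filled in)
#' @param strategy aggregation strategy, see [kg_aggregate()]
#' @param top_k number of candidates to return
#' @param max_paths per-(rule, candidate) stored-path cap
#' @return object of class `kg_prediction`: data.frame `candidate`,
#'   `score`, `n_rules` with attribute `contributions` (named list:
#'   candidate -> data.frame rule body / confidence / n_paths) and
#'   attribute `paths`
#' @export
kg_predict_rules <- function(graph, head, rules,
                             strategy = c("max", "noisy_or", "nr_noisy_or"),
                             top_k = 10L, max_paths = 100L) {
  strategy <- match.arg(strategy)
  if (nrow(rules) == 0L) stop("empty rule set")
  ht <- kg_type(graph, head)
  if (is.na(ht)) stop("unknown head entity: ", head)
  parsed <- kg_rules_parsed(rules)
  keys <- vapply(parsed, rule_key, "")
  cand <- list()   # candidate -> named score vector
  contrib <- list()
  paths <- list()
  for (i in seq_along(parsed)) {
    r <- parsed[[i]]
    if (ht != r$types[1L]) next
    res <- kg_apply_rule(graph, head, r, max_paths = max_paths)
    for (tl in names(res)) {
      sc <- rules$confidence[i]
      v <- cand[[tl]] %||% numeric(0)
      v <- c(v, structure(sc, names = keys[i]))
      cand[[tl]] <- v
      contrib[[tl]] <- rbind(contrib[[tl]], data.frame(
        body = rules$body[i], confidence = sc,
        n_paths = res[[tl]]$n_paths, stringsAsFactors = FALSE))
      paths[[tl]] <- c(paths[[tl]],
                       structure(list(res[[tl]]$paths), names = rules$body[i]))
    }
  }
  clusters <- NULL
  if (strategy == "nr_noisy_or") {
    clusters <- kg_redundancy_clusters(graph, rules)
  }
  agg <- kg_aggregate(cand, strategy, clusters = clusters)
  agg <- utils::head(agg, max(top_k, 0L))
  structure(agg,
            contributions = contrib[agg$candidate],
            paths = paths[agg$candidate],
            strategy = strategy, head = head, target = rules$target[1L],
            class = c("kg_prediction", "data.frame"))
}

#' @export
print.kg_prediction <- function(x, ...) {
  cat(sprintf("Query head %s (%s aggregation): %d candidate(s)\n",
              attr(x, "head"), attr(x, "strategy"), nrow(x)))
  print.data.frame(x)
  invisible(x)
}

#' Write ranked predictions as TSV
#'
#' Format: `query_head	rank	candidate	score	strategy	n_rules`;
#' per-candidate rule contributions go to a JSON-lines sidecar keyed by
#' (query_head, candidate).
#' @param predictions a `kg_prediction` (or list of them)
#' @param path output TSV path; the sidecar is `<path>.contributions.jsonl`
#' @return `path`, invisibly
#' @export
kg_predictions_write <- function(predictions, path) {
  if (inherits(predictions, "kg_prediction")) predictions <- list(predictions)
  rows <- list(); side <- character()
  for (p in predictions) {
    h <- attr(p, "head"); st <- attr(p, "strategy")
    if (nrow(p) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      query_head = h, rank = seq_len(nrow(p)), candidate = p$candidate,
      score = p$score, strategy = st, n_rules = p$n_rules,
      stringsAsFactors = FALSE)
    cb <- attr(p, "contributions")
    for (cd in names(cb)) {
      side <- c(side, jsonlite::toJSON(list(
        query_head = h, candidate = cd, contributions = cb[[cd]]),
        auto_unbox = TRUE, digits = NA))
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(side, paste0(path, ".contributions.jsonl"), useBytes = TRUE)
  invisible(path)
}
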