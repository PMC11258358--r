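# Shared fixtures: toy graphs built in code, a random-graph generator for
# property tests, and independent nested-loop oracles for rule grounding,
# confidence and candidate scoring. The oracles deliberately scan the
# triple table row by row and never touch the package's adjacency index.

toy_triples <- function() {
  data.frame(
    head = c("c1", "c1", "g1"),
    relation = c("treats", "upregulates", "associates"),
    tail = c("d1", "g1", "d1"),
    stringsAsFactors = FALSE)
}

toy_types <- c(c1 = "Compound", d1 = "Disease", g1 = "Gene")

toy_graph <- function(augment = FALSE) {
  g <- kg_graph(toy_triples(), entity_types = toy_types)
  if (augment) kg_augment(g) else g
}

# a typed random graph: 3 node types, 4 base relations, <= 200 triples
random_graph <- function(seed, n_per_type = 6L, p = 0.25) {
  set.seed(seed)
  ids <- list(A = sprintf("a%d", 1:n_per_type),
              B = sprintf("b%d", 1:n_per_type),
              C = sprintf("c%d", 1:n_per_type))
  types <- c(structure(rep("A", n_per_type), names = ids$A),
             structure(rep("B", n_per_type), names = ids$B),
             structure(rep("C", n_per_type), names = ids$C))
  schema <- list(tAB = c("A", "B"), tBC = c("B", "C"),
                 tBB = c("B", "B"), tAC = c("A", "C"))
  rows <- list()
  for (r in names(schema)) {
    hs <- ids[[schema[[r]][1]]]
    ts <- ids[[schema[[r]][2]]]
    for (h in hs) for (t in ts) {
      if (h != t && stats::runif(1) < p) {
        rows[[length(rows) + 1L]] <- data.frame(
          head = h, relation = r, tail = t, stringsAsFactors = FALSE)
      }
    }
  }
  kg_graph(do.call(rbind, rows), entity_types = types)
}

# random typed rules with target tAC over the random_graph schema
random_rules <- function(seed, n = 6L) {
  set.seed(seed)
  steps <- list(
    list(rel = "tAB", from = "A", to = "B"),
    list(rel = "tBB", from = "B", to = "B"),
    list(rel = "tBB^-1", from = "B", to = "B"),
    list(rel = "tBC", from = "B", to = "C"),
    list(rel = "tAB^-1", from = "B", to = "A"),
    list(rel = "tAC", from = "A", to = "C"),
    list(rel = "tBC^-1", from = "C", to = "B"))
  out <- list()
  guard <- 0L
  while (length(out) < n && guard < 500L) {
    guard <- guard + 1L
    L <- sample(1:3, 1L)
    cur <- "A"
    rels <- character(0); tys <- "A"
    ok <- TRUE
    for (i in seq_len(L)) {
      cand <- Filter(function(s) s$from == cur, steps)
      if (!length(cand)) { ok <- FALSE; break }
      s <- cand[[sample.int(length(cand), 1L)]]
      rels <- c(rels, s$rel); cur <- s$to; tys <- c(tys, s$to)
    }
    if (!ok || cur != "C") next
    if (L == 1L && rels[[1L]] == "tAC") next
    out[[length(out) + 1L]] <- kg_rule("tAC", rels, tys)
  }
  # deduplicate
  keys <- vapply(out, kg_format_body, "")
  out[!duplicated(keys)]
}

# ---- independent nested-loop oracles ------------------------------------

oracle_type <- function(graph, id) {
  graph$entities$type[match(id, graph$entities$id)]
}

# every complete grounding of `rule` from `head`, by scanning triples rows
oracle_paths <- function(graph, head, rule, exclude_direct = TRUE) {
  tr <- graph$triples
  partial <- list(head)
  for (i in seq_along(rule$relations)) {
    nxt <- list()
    for (p in partial) {
      cur <- p[length(p)]
      for (row in seq_len(nrow(tr))) {
        if (tr$head[row] == cur && tr$relation[row] == rule$relations[i] &&
            oracle_type(graph, tr$tail[row]) == rule$types[i + 1L]) {
          nxt[[length(nxt) + 1L]] <- c(p, tr$tail[row])
        }
      }
    }
    partial <- nxt
    if (!length(partial)) return(list())
  }
  partial <- Filter(function(p) p[length(p)] != head, partial)
  if (exclude_direct) {
    tgt <- rule$target
    tgt_inv <- kg_inverse_label(tgt)
    partial <- Filter(function(p) {
      leak <- FALSE
      for (i in seq_along(rule$relations)) {
        if ((rule$relations[i] == tgt && p[i] == head &&
             p[i + 1L] == p[length(p)]) ||
            (rule$relations[i] == tgt_inv && p[i] == p[length(p)] &&
             p[i + 1L] == head)) leak <- TRUE
      }
      !leak
    }, partial)
  }
  partial
}

# candidate tails with path counts, as apply_rule reports them
oracle_apply <- function(graph, head, rule) {
  paths <- oracle_paths(graph, head, rule)
  if (!length(paths)) return(data.frame(tail = character(), n = integer()))
  tails <- vapply(paths, function(p) p[length(p)], "")
  tab <- table(tails)
  data.frame(tail = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)[order(names(tab)), ]
}

oracle_confidence <- function(graph, rule, known_targets) {
  heads <- graph$entities$id[graph$entities$type == rule$types[1L]]
  pairs <- character(0)
  for (h in heads) {
    a <- oracle_apply(graph, h, rule)
    if (nrow(a)) pairs <- c(pairs, paste(h, a$tail, sep = "|"))
  }
  pairs <- unique(pairs)
  if (!length(pairs)) return(list(groundings = 0L, support = 0L,
                                  confidence = NA_real_))
  known <- paste(known_targets$head, known_targets$tail, sep = "|")
  supp <- sum(pairs %in% known)
  list(groundings = length(pairs), support = supp,
       confidence = supp / length(pairs))
}

oracle_aggregate <- function(score_sets, strategy, clusters = NULL) {
  vapply(score_sets, function(s) {
    if (strategy == "max") return(max(s))
    if (strategy == "noisy_or") return(1 - prod(1 - s))
    cl <- if (!is.null(clusters) && !is.null(names(s))) {
      cli <- clusters[names(s)]
      ifelse(is.na(cli), paste0("solo", names(s)), cli)
    } else seq_along(s)
    1 - prod(1 - tapply(s, cl, max))
  }, 0)
}

# full prediction oracle: per-rule groundings -> per-candidate score sets
oracle_predict <- function(graph, head, rules_df, strategy,
                           clusters = NULL) {
  parsed <- kg_rules_parsed(rules_df)
  sets <- list()
  for (i in seq_along(parsed)) {
    r <- parsed[[i]]
    if (oracle_type(graph, head) != r$types[1L]) next
    a <- oracle_apply(graph, head, r)
    key <- paste0(r$target, "\r", kg_format_body(r))
    for (t in a$tail) {
      sets[[t]] <- c(sets[[t]],
                     structure(rules_df$confidence[i], names = key))
    }
  }
  if (!length(sets)) {
    return(data.frame(candidate = character(), score = numeric()))
  }
  sc <- oracle_aggregate(sets, strategy, clusters)
  out <- data.frame(candidate = names(sets), score = unname(sc),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$candidate), ]
}

# small synthetic configuration used by fast tests (not the acceptance one)
small_synth_config <- function(seed = 1L, ...) {
  kg_synth_config(n_compound = 20L, n_disease = 12L, n_gene = 60L,
                  n_anatomy = 8L, n_sideeffect = 10L,
                  densities = c(CuG = 0.04, CbG = 0.03, AeG = 0.06,
                                DlA = 0.12, GrG = 0.01, DaG = 0.05,
                                CcSE = 0.08),
                  seed = seed, ...)
}
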