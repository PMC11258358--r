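#' Relation verb templates for natural-language rendering
#'
#' A template table maps every base relation to a forward phrase and an
#' inverse phrase (used when a rule traverses the edge backwards), plus
#' the relation's endpoint types, e.g. `CuG`: forward "upregulates"
#' (Compound to Gene), inverse "is upregulated by" (Gene to Compound).
#' The inverse phrase of `r` is by construction the forward phrase of
#' `r^-1`.
#'
#' `kg_templates_read()` loads the TSV format
#' `relation	forward_phrase	inverse_phrase	head_type	tail_type`;
#' `kg_default_templates()` returns the built-in table for the
#' Hetionet-style vocabulary used by the synthetic generator.
#'
#' @param path template TSV path
#' @return data.frame with columns `relation`, `forward`, `inverse`,
#'   `head_type`, `tail_type`
#' @export
kg_templates_read <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  names(df) <- sub("_phrase$", "", names(df))
  need <- c("relation", "forward", "inverse", "head_type", "tail_type")
  if (!all(need %in% names(df))) {
    stop("template table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df[, need]
}

#' @rdname kg_templates_read
#' @export
kg_templates_write <- function(templates, path) {
  df <- templates
  names(df)[match(c("forward", "inverse"), names(df))] <-
    c("forward_phrase", "inverse_phrase")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname kg_templates_read
#' @param templates a template data.frame (for the writer)
#' @export
kg_default_templates <- function() {
  data.frame(
    relation = c("CtD", "CuG", "CdG", "CbG", "CcSE", "AeG", "AuG", "AdG",
                 "DlA", "DaG", "GrG", "GiG"),
    forward = c("treats", "upregulates", "downregulates", "binds", "causes",
                "expresses", "upregulates", "downregulates", "localizes",
                "associates", "regulates", "interacts"),
    inverse = c("is treated by", "is upregulated by", "is downregulated by",
                "is bound by", "is caused by", "is expressed by",
                "is upregulated by", "is downregulated by",
                "is localized to", "is associated to", "is regulated by",
                "interacts with"),
    head_type = c("Compound", "Compound", "Compound", "Compound", "Compound",
                  "Anatomy", "Anatomy", "Anatomy", "Disease", "Disease",
                  "Gene", "Gene"),
    tail_type = c("Disease", "Gene", "Gene", "Gene", "Side Effect", "Gene",
                  "Gene", "Gene", "Anatomy", "Gene", "Gene", "Gene"),
    stringsAsFactors = FALSE)
}

# phrase for a (possibly inverse-labelled) relation
relation_phrase <- function(relation, templates) {
  base <- if (is_inverse_label(relation)) kg_inverse_label(relation) else relation
  i <- match(base, templates$relation)
  if (is.na(i)) stop("no verb template for relation: ", relation)
  if (is_inverse_label(relation)) templates$inverse[i] else templates$forward[i]
}

#' Render a rule in natural language
#'
#' Bracketed arrow form, node types interleaved with relation phrases:
#' `[Compound --upregulates--> Gene --is expressed by--> Anatomy
#' --is localized to--> Disease]`. Inverse-labelled relations use their
#' inverse phrase.
#'
#' @param rule a `kg_rule`
#' @param templates verb template table (see [kg_default_templates()])
#' @return a single string
#' @export
kg_render_rule <- function(rule, templates = kg_default_templates()) {
  if (length(rule$relations) == 0L) stop("rule body is empty")
  out <- rule$types[1L]
  for (i in seq_along(rule$relations)) {
    out <- paste0(out, " --", relation_phrase(rule$relations[i], templates),
                  "--> ", rule$types[i + 1L])
  }
  paste0("[", out, "]")
}

#' Parse a rendered rule back into a `kg_rule`
#'
#' Inverse grammar of [kg_render_rule()]: each (source type, phrase,
#' target type) step is resolved against the template table, preferring
#' the forward reading and falling back to the inverse.
#'
#' @param text rendered rule string
#' @param target target relation label
#' @param templates verb template table
#' @return a `kg_rule`
#' @export
kg_parse_rendered_rule <- function(text, target,
                                   templates = kg_default_templates()) {
  body <- sub("^\\[", "", sub("\\]$", "", text))
  parts <- strsplit(body, " --|--> ")[[1L]]
  types <- parts[seq(1L, length(parts), by = 2L)]
  phrases <- parts[seq(2L, length(parts), by = 2L)]
  rels <- character(length(phrases))
  for (i in seq_along(phrases)) {
    fwd <- which(templates$forward == phrases[i] &
                   templates$head_type == types[i] &
                   templates$tail_type == types[i + 1L])
    inv <- which(templates$inverse == phrases[i] &
                   templates$tail_type == types[i] &
                   templates$head_type == types[i + 1L])
    if (length(fwd)) {
      rels[i] <- templates$relation[fwd[1L]]
    } else if (length(inv)) {
      rels[i] <- kg_inverse_label(templates$relation[inv[1L]])
    } else {
      stop("cannot resolve phrase '", phrases[i], "' between ", types[i],
           " and ", types[i + 1L])
    }
  }
  kg_rule(target, rels, types)
}

#' Render a grounded path in natural language
#'
#' Entity display names interleaved with the rule's relation phrases:
#' `Epirubicin --upregulates--> EGF --regulates--> BRAF
#' --is associated to--> Breast cancer`. By default the `Type::` prefix of
#' Hetionet-style ids is stripped; pass `names` to map ids to display
#' names.
#'
#' @param nodes entity-id sequence of the path
#' @param rule the `kg_rule` the path grounds
#' @param templates verb template table
#' @param names optional named character vector id -> display name
#' @return a single string
#' @export
kg_render_path <- function(nodes, rule, templates = kg_default_templates(),
                           names = NULL) {
  stopifnot(length(nodes) == length(rule$relations) + 1L)
  disp <- vapply(nodes, function(id) {
    if (!is.null(names) && id %in% base::names(names)) names[[id]]
    else sub("^[^:]+::", "", id)
  }, "")
  out <- disp[1L]
  for (i in seq_along(rule$relations)) {
    out <- paste0(out, " --", relation_phrase(rule$relations[i], templates),
                  "--> ", disp[i + 1L])
  }
  out
}

# Neo4j relationship-type mapping, VERB_Abbrev convention (TREATS_CtD).
#' Default relation -> Neo4j relationship-type mapping
#' @param templates verb template table supplying the verbs
#' @return named character vector relation -> relationship type
#' @export
kg_default_mapping <- function(templates = kg_default_templates()) {
  verb <- toupper(gsub("[^A-Za-z0-9]+", "_", templates$forward))
  abbrev <- gsub("[^A-Za-z0-9]", "", templates$relation)
  structure(paste0(verb, "_", abbrev), names = templates$relation)
}

cypher_label <- function(type) {
  if (grepl("[^A-Za-z0-9_]", type)) paste0("`", type, "`") else type
}

#' Emit a Cypher query retrieving a rule's grounded paths
#'
#' Produces a single `MATCH path = (...) RETURN path` statement whose
#' relationship pattern mirrors the rule body: forward steps as
#' `-[:TYPE]->`, inverse-labelled steps with the arrow reversed
#' (`<-[:TYPE]-`) on the base relationship type. The head node is
#' constrained by an `identifier` property (name configurable); the tail
#' is constrained only when `tail` is given.
#'
#' @param rule a `kg_rule`
#' @param head head entity id
#' @param tail tail entity id, or `NULL` for a wildcard tail
#' @param mapping named character vector relation -> Neo4j relationship
#'   type (see [kg_default_mapping()])
#' @param id_property node identity property name
#' @return a Cypher query string
#' @export
kg_emit_cypher <- function(rule, head, tail = NULL,
                           mapping = kg_default_mapping(),
                           id_property = "identifier") {
  q <- sprintf('(n0:%s {%s: "%s"})', cypher_label(rule$types[1L]),
               id_property, head)
  for (i in seq_along(rule$relations)) {
    r <- rule$relations[i]
    base <- if (is_inverse_label(r)) kg_inverse_label(r) else r
    if (!base %in% names(mapping)) {
      stop("no Neo4j relationship type mapped for relation: ", base)
    }
    arrow <- if (is_inverse_label(r)) {
      sprintf("<-[:%s]-", mapping[[base]])
    } else {
      sprintf("-[:%s]->", mapping[[base]])
    }
    node <- if (i == length(rule$relations) && !is.null(tail)) {
      sprintf('(n%d:%s {%s: "%s"})', i, cypher_label(rule$types[i + 1L]),
              id_property, tail)
    } else {
      sprintf("(n%d:%s)", i, cypher_label(rule$types[i + 1L]))
    }
    q <- paste0(q, arrow, node)
  }
  paste0("MATCH path = ", q, " RETURN path")
}

#' Evaluate an emitted Cypher query against an in-memory graph
#'
#' A mock matcher for offline testing: parses the linear `MATCH path =`
#' pattern grammar emitted by [kg_emit_cypher()] and evaluates it by a
#' brute-force nested-loop join over the graph's base (non-inverse)
#' triples, honouring arrow directions, node labels and identifier
#' constraints. No Neo4j server is involved.
#'
#' @param query Cypher string produced by [kg_emit_cypher()]
#' @param graph a `kg_graph` (base triples; inverse-labelled triples are
#'   ignored so augmented graphs match too)
#' @param mapping the relation mapping used at emission time
#' @param id_property node identity property name
#' @param target optional target relation label; when given, paths that
#'   traverse the direct (head, target, tail) edge of their own endpoint
#'   pair are dropped, matching [kg_apply_rule()]'s scoring semantics
#' @return list of paths, each a character vector of entity ids
#' @export
kg_cypher_match <- function(query, graph, mapping = kg_default_mapping(),
                            id_property = "identifier", target = NULL) {
  pat <- sub("^MATCH path = ", "", sub(" RETURN path$", "", query))
  # tokenize into node patterns and relationship arrows
  node_re <- "\\((n\\d+):(`[^`]+`|[A-Za-z0-9_]+)( \\{[^}]*\\})?\\)"
  rel_re <- "(<-\\[:[A-Za-z0-9_]+\\]-|-\\[:[A-Za-z0-9_]+\\]->)"
  nodes <- list()
  rels <- list()
  rest <- pat
  repeat {
    m <- regexpr(paste0("^", node_re), rest)
    if (m == -1L) stop("unparseable node pattern at: ", rest)
    tok <- regmatches(rest, m)
    lab <- sub(node_re, "\\2", tok)
    lab <- gsub("`", "", lab)
    prop <- sub(node_re, "\\3", tok)
    id <- NA_character_
    if (nzchar(prop)) {
      id <- sub(sprintf('.*%s: "([^"]*)".*', id_property), "\\1", prop)
    }
    nodes[[length(nodes) + 1L]] <- list(label = lab, id = id)
    rest <- substring(rest, attr(m, "match.length") + 1L)
    if (!nzchar(rest)) break
    m <- regexpr(paste0("^", rel_re), rest)
    if (m == -1L) stop("unparseable relationship pattern at: ", rest)
    tok <- regmatches(rest, m)
    inverse <- startsWith(tok, "<-")
    rtype <- sub(".*\\[:([A-Za-z0-9_]+)\\].*", "\\1", tok)
    base <- names(mapping)[match(rtype, mapping)]
    if (is.na(base)) stop("relationship type not in mapping: ", rtype)
    rels[[length(rels) + 1L]] <- list(relation = base, inverse = inverse)
    rest <- substring(rest, attr(m, "match.length") + 1L)
  }
  base_triples <- graph$triples[!is_inverse_label(graph$triples$relation), ,
                                drop = FALSE]
  node_ok <- function(spec, id) {
    (is.na(spec$id) || spec$id == id) &&
      identical(kg_type(graph, id), gsub("`", "", spec$label))
  }
  # nested-loop join over partial bindings
  starts <- if (!is.na(nodes[[1L]]$id)) nodes[[1L]]$id else graph$entities$id
  partial <- lapply(starts[vapply(starts, function(i) node_ok(nodes[[1L]], i),
                                  TRUE)], function(i) i)
  for (step in seq_along(rels)) {
    rl <- rels[[step]]
    spec <- nodes[[step + 1L]]
    tr <- base_triples[base_triples$relation == rl$relation, , drop = FALSE]
    nxt <- list()
    for (p in partial) {
      cur <- p[length(p)]
      hits <- if (rl$inverse) tr$head[tr$tail == cur] else tr$tail[tr$head == cur]
      for (h in hits) {
        if (node_ok(spec, h)) nxt[[length(nxt) + 1L]] <- c(p, h)
      }
    }
    partial <- nxt
    if (!length(partial)) break
  }
  # a rule's head is never its own answer
  partial <- partial[vapply(partial, function(p) p[1L] != p[length(p)], TRUE)]
  if (!is.null(target)) {
    rel_labels <- vapply(rels, function(rl) {
      if (rl$inverse) kg_inverse_label(rl$relation) else rl$relation
    }, "")
    tgt_inv <- kg_inverse_label(target)
    partial <- partial[!vapply(partial, function(p) {
      path_uses_direct_edge(p, rel_labels, p[1L], p[length(p)], target,
                            tgt_inv)
    }, TRUE)]
  }
  partial
}

#' Build a per-compound explanation report
#'
#' The report lists, for each ranked candidate disease, the contributing
#' rules sorted by score, each with its natural-language body, the number
#' of witnessing paths, rendered example paths, and a Cypher query that
#' retrieves all supporting paths from a Neo4j-hosted copy of the graph.
#' Every listed rule is guaranteed at least one witnessing path.
#'
#' @param prediction a `kg_model_prediction` (from [predict.kg_model()])
#'   or `kg_prediction` (from [kg_predict_rules()])
#' @param graph traversal `kg_graph`
#' @param templates verb template table
#' @param mapping Neo4j relationship-type mapping
#' @param top_k candidates to include
#' @param max_example_paths rendered example paths per rule
#' @return object of class `kg_report` (nested list, JSON-serializable)
#' @export
kg_build_report <- function(prediction, graph,
                            templates = kg_default_templates(),
                            mapping = kg_default_mapping(),
                            top_k = 10L, max_example_paths = 3L) {
  head_id <- attr(prediction, "head")
  contribs <- attr(prediction, "contributions")
  score_col <- if ("probability" %in% names(prediction)) "probability" else "score"
  rule_score_col <- if (inherits(prediction, "kg_model_prediction")) {
    "rule_quality_H"
  } else "confidence"
  cand_rows <- utils::head(seq_len(nrow(prediction)), top_k)
  if (!length(cand_rows)) {
    return(structure(list(compound = head_id, score_column = rule_score_col,
                          note = "no predictions for this compound",
                          candidates = list()),
                     class = "kg_report"))
  }
  candidates <- lapply(cand_rows, function(i) {
    cd <- prediction$candidate[i]
    cb <- contribs[[cd]]
    rules <- list()
    if (!is.null(cb) && nrow(cb)) {
      o <- order(-cb[[rule_score_col]], cb$body)
      cb <- cb[o, , drop = FALSE]
      rules <- lapply(seq_len(nrow(cb)), function(j) {
        rule <- kg_parse_body(cb$body[j], attr(prediction, "target") %||% "CtD")
        res <- kg_apply_rule(graph, head_id, rule,
                             max_paths = max(max_example_paths, 1L))
        hit <- res[[cd]]
        examples <- character(0)
        n_paths <- 0L
        if (!is.null(hit)) {
          n_paths <- hit$n_paths
          examples <- vapply(utils::head(hit$paths, max_example_paths),
                             kg_render_path, "", rule = rule,
                             templates = templates)
        }
        list(rule = kg_render_rule(rule, templates),
             body = cb$body[j],
             score = unname(cb[[rule_score_col]][j]),
             n_paths = n_paths,
             example_paths = as.list(examples),
             cypher = kg_emit_cypher(rule, head_id, cd, mapping))
      })
      rules <- rules[vapply(rules, function(r) r$n_paths >= 1L, TRUE)]
    }
    list(candidate = cd, score = prediction[[score_col]][i], rules = rules)
  })
  structure(list(compound = head_id, score_column = rule_score_col,
                 candidates = candidates),
            class = "kg_report")
}

#' Serialize an explanation report
#'
#' `kg_report_json()` writes (or returns) the report as JSON, which
#' round-trips losslessly through [kg_report_from_json()];
#' `kg_report_markdown()` renders a human-readable Markdown document.
#'
#' @param report a `kg_report`
#' @param path optional output path
#' @return JSON string / markdown lines (invisibly when written to `path`)
#' @export
kg_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path, useBytes = TRUE)
    return(invisible(js))
  }
  js
}

#' @rdname kg_report_json
#' @export
kg_report_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(x, class = "kg_report")
}

#' @rdname kg_report_json
#' @export
kg_report_markdown <- function(report, path = NULL) {
  lines <- c(sprintf("# Repurposing report for %s", report$compound), "")
  if (!is.null(report$note)) lines <- c(lines, report$note, "")
  for (cand in report$candidates) {
    lines <- c(lines, sprintf("## %s (score %.6g)", cand$candidate,
                              cand$score), "")
    if (length(cand$rules)) {
      lines <- c(lines,
                 sprintf("| %s | paths | rule |", report$score_column),
                 "|---:|---:|---|")
      for (r in cand$rules) {
        lines <- c(lines, sprintf("| %.6g | %d | %s |", r$score, r$n_paths,
                                  r$rule))
      }
      lines <- c(lines, "")
      for (r in cand$rules) {
        if (length(r$example_paths)) {
          lines <- c(lines, sprintf("Example paths for %s:", r$rule),
                     paste0("- ", unlist(r$example_paths)), "")
        }
        lines <- c(lines, "```cypher", r$cypher, "```", "")
      }
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' @export
print.kg_report <- function(x, ...) {
  cat(paste(utils::head(kg_report_markdown(x), 30L), collapse = "\n"), "\n")
  invisible(x)
}
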