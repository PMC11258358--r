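#' Construct a typed knowledge graph from a triple table
#'
#' A knowledge graph is a multirelational graph stored as (head, relation,
#' tail) triples over typed entities (Compound, Disease, Gene, Anatomy,
#' Side Effect, ...). The object indexes outgoing edges per entity so that
#' random walks and rule application are cheap.
#'
#' @param triples data.frame with character columns `head`, `relation`,
#'   `tail`. Duplicate triples are collapsed with a warning.
#' @param entity_types named character vector mapping entity id to node type.
#'   Entities appearing in `triples` but absent here are assigned type
#'   `"Any"` (the sentinel used by untyped dialects).
#' @param augmented logical; whether the triple set already contains the
#'   inverse closure produced by [kg_augment()].
#' @return An object of class `kg_graph` with fields `triples` (data.frame),
#'   `entities` (data.frame of `id`, `type`), `relations` (character),
#'   `augmented` (logical), plus internal adjacency and type indices.
#' @seealso [kg_read()], [kg_augment()], [kg_split()]
#' @export
kg_graph <- function(triples, entity_types = NULL, augmented = FALSE) {
  stopifnot(is.data.frame(triples))
  if (nrow(triples) == 0L) {
    triples <- data.frame(head = character(), relation = character(),
                          tail = character(), stringsAsFactors = FALSE)
  }
  need <- c("head", "relation", "tail")
  if (!all(need %in% names(triples))) {
    stop("triples must have columns head, relation, tail")
  }
  triples <- data.frame(head = as.character(triples$head),
                        relation = as.character(triples$relation),
                        tail = as.character(triples$tail),
                        stringsAsFactors = FALSE)
  key <- paste(triples$head, triples$relation, triples$tail, sep = "\r")
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(sprintf("collapsed %d duplicate triple(s)", ndup), call. = FALSE)
    triples <- triples[!duplicated(key), , drop = FALSE]
    rownames(triples) <- NULL
  }
  ids <- unique(c(triples$head, triples$tail))
  types <- rep("Any", length(ids))
  names(types) <- ids
  if (!is.null(entity_types)) {
    known <- intersect(names(entity_types), ids)
    types[known] <- unname(entity_types[known])
    extra <- setdiff(names(entity_types), ids)
    if (length(extra)) {
      ids <- c(ids, extra)
      types <- c(types, entity_types[extra])
    }
  }
  g <- structure(list(
    triples = triples,
    entities = data.frame(id = ids, type = unname(types),
                          stringsAsFactors = FALSE),
    relations = sort(unique(triples$relation)),
    augmented = isTRUE(augmented)
  ), class = "kg_graph")
  g$type_index <- list2env(as.list(types), hash = TRUE,
                           size = max(29L, length(types)))
  g$adj <- build_adjacency(triples)
  g$triple_index <- list2env(
    structure(as.list(rep(TRUE, nrow(triples))), names = key[!duplicated(key)]),
    hash = TRUE, size = max(29L, nrow(triples)))
  g
}

# adjacency: environment keyed by entity id; value is list(relation=, tail=)
build_adjacency <- function(triples) {
  adj <- new.env(hash = TRUE, size = max(29L, length(unique(triples$head))))
  if (nrow(triples) == 0L) return(adj)
  o <- order(triples$head, triples$relation, triples$tail)
  h <- triples$head[o]; r <- triples$relation[o]; t <- triples$tail[o]
  starts <- c(1L, which(h[-1L] != h[-length(h)]) + 1L)
  ends <- c(starts[-1L] - 1L, length(h))
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    assign(h[starts[i]], list(relation = r[idx], tail = t[idx]), envir = adj)
  }
  adj
}

#' @export
print.kg_graph <- function(x, ...) {
  cat(sprintf("Knowledge graph: %d entities, %d triples, %d relations%s\n",
              nrow(x$entities), nrow(x$triples), length(x$relations),
              if (x$augmented) " (inverse-augmented)" else ""))
  tt <- sort(table(x$entities$type), decreasing = TRUE)
  cat("  node types:", paste(sprintf("%s (%d)", names(tt), tt), collapse = ", "),
      "\n")
  invisible(x)
}

#' Entity node type lookup
#' @param graph a `kg_graph`
#' @param id entity id(s)
#' @return character vector of node types (`NA` for unknown entities)
#' @export
kg_type <- function(graph, id) {
  vapply(id, function(e) {
    v <- get0(e, envir = graph$type_index, inherits = FALSE)
    if (is.null(v)) NA_character_ else v
  }, character(1), USE.NAMES = FALSE)
}

# Outgoing edges of one entity: list(relation=chr, tail=chr), sorted.
kg_out <- function(graph, id) {
  get0(id, envir = graph$adj, inherits = FALSE) %||%
    list(relation = character(), tail = character())
}

# Tails reachable from `head` through `relation` (sorted, possibly empty).
kg_tails <- function(graph, head, relation) {
  o <- kg_out(graph, head)
  o$tail[o$relation == relation]
}

kg_has_triple <- function(graph, h, r, t) {
  !is.null(get0(paste(h, r, t, sep = "\r"), envir = graph$triple_index,
                inherits = FALSE))
}

#' Inverse relation label
#'
#' The inverse of a base relation `r` is written `r^-1`; taking the inverse
#' twice returns the base label, making the scheme involutive.
#' @param relation character vector of relation labels
#' @return character vector of inverse labels
#' @export
kg_inverse_label <- function(relation) {
  ifelse(endsWith(relation, "^-1"),
         substr(relation, 1L, nchar(relation) - 3L),
         paste0(relation, "^-1"))
}

is_inverse_label <- function(relation) endsWith(relation, "^-1")

#' Augment a graph with inverse relations
#'
#' For every triple (h, r, t) adds the reversed triple (t, r^-1, h), so
#' that metapath rules may traverse any edge in either direction. The
#' operation refuses to run twice.
#'
#' @param graph an un-augmented `kg_graph`
#' @return a `kg_graph` with `augmented = TRUE` and twice the triples
#'   (minus any coincidental duplicates)
#' @export
kg_augment <- function(graph) {
  stopifnot(inherits(graph, "kg_graph"))
  if (graph$augmented) stop("graph is already inverse-augmented")
  inv <- data.frame(head = graph$triples$tail,
                    relation = kg_inverse_label(graph$triples$relation),
                    tail = graph$triples$head,
                    stringsAsFactors = FALSE)
  types <- structure(graph$entities$type, names = graph$entities$id)
  suppressWarnings(
    kg_graph(rbind(graph$triples, inv), entity_types = types, augmented = TRUE)
  )
}

#' Drop inverse-labelled triples
#'
#' Exact inverse of [kg_augment()]: removes every triple whose relation
#' carries the `^-1` suffix, recovering the base graph.
#' @param graph a `kg_graph`
#' @return an un-augmented `kg_graph`
#' @export
kg_strip_inverse <- function(graph) {
  keep <- !is_inverse_label(graph$triples$relation)
  types <- structure(graph$entities$type, names = graph$entities$id)
  kg_graph(graph$triples[keep, , drop = FALSE], entity_types = types,
           augmented = FALSE)
}

#' Read a knowledge graph from a tab-separated triple file
#'
#' Two dialects are supported. `generic`: three tab-separated columns
#' `head`, `relation`, `tail`, no header; all entities receive the sentinel
#' type `"Any"`. `hetionet`: the public Hetionet edge format with header
#' `source	metaedge	target`, node ids of the form `Type::LocalId`
#' (the node type is parsed from the prefix) and metaedge abbreviations as
#' relation labels (a `>` marking a directed metaedge is preserved).
#'
#' @param path file path
#' @param dialect `"generic"` or `"hetionet"`
#' @return an un-augmented `kg_graph`
#' @export
kg_read <- function(path, dialect = c("generic", "hetionet")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (dialect == "hetionet") {
    if (length(lines) == 0L) stop("hetionet file lacks the header row")
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (!identical(tolower(header[1:3]), c("source", "metaedge", "target"))) {
      stop("not a hetionet edge file: header must be source/metaedge/target")
    }
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(kg_graph(data.frame(head = character(), relation = character(),
                               tail = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    off <- if (dialect == "hetionet") 1L else 0L
    stop(sprintf("malformed line %d in %s: expected 3 tab-separated fields",
                 bad[1L] + off, path))
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  triples <- data.frame(head = m[, 1L], relation = m[, 2L], tail = m[, 3L],
                        stringsAsFactors = FALSE)
  types <- NULL
  if (dialect == "hetionet") {
    ids <- unique(c(triples$head, triples$tail))
    pref <- sub("::.*$", "", ids)
    nopref <- !grepl("::", ids, fixed = TRUE)
    if (any(nopref)) {
      stop(sprintf("malformed hetionet node id without Type:: prefix: %s",
                   ids[which(nopref)[1L]]))
    }
    types <- structure(pref, names = ids)
  }
  kg_graph(triples, entity_types = types)
}

#' Write a knowledge graph as a tab-separated triple file
#'
#' Emits the same formats [kg_read()] accepts, byte-stably: triples are
#' sorted by (head, relation, tail) before writing.
#' @param graph a `kg_graph`
#' @param path output file path
#' @param dialect `"generic"` or `"hetionet"`
#' @return `path`, invisibly
#' @export
kg_write <- function(graph, path, dialect = c("generic", "hetionet")) {
  dialect <- match.arg(dialect)
  tr <- graph$triples
  tr <- tr[order(tr$head, tr$relation, tr$tail), , drop = FALSE]
  body <- paste(tr$head, tr$relation, tr$tail, sep = "\t")
  if (dialect == "hetionet") body <- c("source\tmetaedge\ttarget", body)
  writeLines(body, path, useBytes = TRUE)
  invisible(path)
}

# Relation type signature derived from the data: for each relation the
# modal (head type, tail type) pair. Used to type rule bodies sampled as
# bare relation sequences.
kg_signature <- function(graph) {
  tr <- graph$triples
  if (nrow(tr) == 0L) {
    return(data.frame(relation = character(), head_type = character(),
                      tail_type = character(), stringsAsFactors = FALSE))
  }
  ht <- kg_type(graph, tr$head)
  tt <- kg_type(graph, tr$tail)
  key <- paste(tr$relation, ht, tt, sep = "\r")
  cnt <- table(key)
  parts <- strsplit(names(cnt), "\r", fixed = TRUE)
  df <- data.frame(relation = vapply(parts, `[`, "", 1L),
                   head_type = vapply(parts, `[`, "", 2L),
                   tail_type = vapply(parts, `[`, "", 3L),
                   n = as.integer(cnt), stringsAsFactors = FALSE)
  df <- df[order(df$relation, -df$n), , drop = FALSE]
  df <- df[!duplicated(df$relation), c("relation", "head_type", "tail_type")]
  rownames(df) <- NULL
  df
}
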