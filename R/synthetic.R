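#' Configuration for the synthetic knowledge-graph generator
#'
#' The generator emulates the structure of a heterogeneous biomedical
#' knowledge graph (typed Compound / Disease / Gene / Anatomy /
#' Side Effect nodes) in which the target "treats" edges arise from
#' planted metapaths: background edges are drawn independently per
#' relation (Erdos-Renyi between the relation's endpoint types), and a
#' `CtD` edge is placed between a compound and a disease exactly when at
#' least `tau` grounded paths of the planted metapaths connect the pair.
#' A further `rho` fraction of the non-qualifying pairs receive spurious
#' (false-positive) treats edges, flagged in the ground-truth ledger.
#'
#' The default planted metapaths are the three-step Compound-to-Disease
#' rules of the kind recovered on real repurposing graphs
#' (upregulates / expressed-by / localized-to; upregulates / regulates /
#' associated-to; binds / expressed-by / localized-to).
#'
#' @param n_compound,n_disease,n_gene,n_anatomy,n_sideeffect node counts
#' @param metapaths list of character vectors of relation labels (inverse
#'   labels allowed), each starting at Compound and ending at Disease
#' @param densities named numeric vector: background edge probability per
#'   relation
#' @param tau minimum number of planted-metapath paths for a treats edge
#' @param rho spurious treats probability per non-qualifying pair, in
#'   `[0, 1)`
#' @param seed integer seed
#' @return a `kg_synth_config` list
#' @export
kg_synth_config <- function(n_compound = 50L, n_disease = 30L,
                            n_gene = 200L, n_anatomy = 20L,
                            n_sideeffect = 40L,
                            metapaths = list(
                              c("CuG", "AeG^-1", "DlA^-1"),
                              c("CuG", "GrG", "DaG^-1"),
                              c("CbG", "AeG^-1", "DlA^-1")),
                            densities = c(CuG = 0.015, CbG = 0.01,
                                          AeG = 0.03, DlA = 0.05,
                                          GrG = 0.005, DaG = 0.02,
                                          CcSE = 0.05),
                            tau = 1L, rho = 0.02, seed = 1L) {
  stopifnot(tau >= 1L, rho >= 0, rho < 1,
            all(densities > 0), all(densities <= 1))
  schema <- synth_schema()
  for (mp in metapaths) {
    bases <- ifelse(endsWith(mp, "^-1"), substr(mp, 1L, nchar(mp) - 3L), mp)
    unknown <- setdiff(bases, schema$relation)
    if (length(unknown)) {
      stop("planted metapath uses undeclared relation(s): ",
           paste(unknown, collapse = ", "))
    }
    types <- metapath_types(mp, schema)
    if (types[1L] != "Compound" || types[length(types)] != "Disease") {
      stop("planted metapaths must run Compound -> Disease: ",
           paste(mp, collapse = ", "))
    }
  }
  miss <- setdiff(unique(unlist(lapply(metapaths, function(mp) {
    ifelse(endsWith(mp, "^-1"), substr(mp, 1L, nchar(mp) - 3L), mp)
  }))), names(densities))
  if (length(miss)) stop("no density declared for relation(s): ",
                         paste(miss, collapse = ", "))
  structure(list(n = c(Compound = as.integer(n_compound),
                       Disease = as.integer(n_disease),
                       Gene = as.integer(n_gene),
                       Anatomy = as.integer(n_anatomy),
                       `Side Effect` = as.integer(n_sideeffect)),
                 metapaths = metapaths, densities = densities,
                 tau = as.integer(tau), rho = rho, seed = as.integer(seed)),
            class = "kg_synth_config")
}

# base-relation schema of the synthetic vocabulary
synth_schema <- function() {
  data.frame(
    relation = c("CtD", "CuG", "CbG", "CcSE", "AeG", "DlA", "GrG", "DaG"),
    head_type = c("Compound", "Compound", "Compound", "Compound",
                  "Anatomy", "Disease", "Gene", "Disease"),
    tail_type = c("Disease", "Gene", "Gene", "Side Effect", "Gene",
                  "Anatomy", "Gene", "Gene"),
    stringsAsFactors = FALSE)
}

# node-type chain of a metapath (relations possibly inverse-labelled)
metapath_types <- function(mp, schema = synth_schema()) {
  types <- character(length(mp) + 1L)
  for (i in seq_along(mp)) {
    r <- mp[i]
    inv <- endsWith(r, "^-1")
    base <- if (inv) substr(r, 1L, nchar(r) - 3L) else r
    j <- match(base, schema$relation)
    ht <- if (inv) schema$tail_type[j] else schema$head_type[j]
    tt <- if (inv) schema$head_type[j] else schema$tail_type[j]
    if (i == 1L) types[1L] <- ht
    else if (types[i] != ht) stop("metapath types do not chain: ",
                                  paste(mp, collapse = ", "))
    types[i + 1L] <- tt
  }
  types
}

#' Generate a synthetic knowledge graph with planted treats edges
#'
#' Draws the background edges, counts the planted-metapath paths for
#' every (compound, disease) pair by sparse boolean matrix products,
#' places treats edges where the count reaches `tau`, adds spurious
#' edges at rate `rho`, and records a ground-truth ledger: the planted
#' rules, every treats edge with its spurious flag, and the witnessing
#' paths of every non-spurious edge. Fully reproducible per seed.
#'
#' @param config a [kg_synth_config()]
#' @return list with `graph` (un-augmented `kg_graph`, hetionet-style
#'   `Type::Id` entity ids) and `ledger` (list: `planted_rules`,
#'   `treats`, a data.frame with `head`, `tail`, `spurious`, `n_paths`,
#'   and `witnesses`, per-edge lists of node-id paths)
#' @export
kg_synth_generate <- function(config = kg_synth_config()) {
  stopifnot(inherits(config, "kg_synth_config"))
  schema <- synth_schema()
  ids <- lapply(names(config$n), function(ty) {
    sprintf("%s::%s%03d", ty, gsub("[^A-Za-z]", "", substr(ty, 1L, 1L)),
            seq_len(config$n[[ty]]))
  })
  names(ids) <- names(config$n)

  edges <- with_seed(config$seed, {
    out <- list()
    for (r in sort(names(config$densities))) {
      j <- match(r, schema$relation)
      ht <- schema$head_type[j]; tt <- schema$tail_type[j]
      nh <- config$n[[ht]]; nt <- config$n[[tt]]
      m <- matrix(stats::runif(nh * nt) < config$densities[[r]], nh, nt)
      if (ht == tt) diag(m) <- FALSE
      out[[r]] <- m
    }
    out
  })

  # path counts per (compound, disease) for each planted metapath
  n_c <- config$n[["Compound"]]; n_d <- config$n[["Disease"]]
  counts <- matrix(0, n_c, n_d)
  per_mp <- lapply(config$metapaths, function(mp) {
    acc <- NULL
    for (r in mp) {
      inv <- endsWith(r, "^-1")
      base <- if (inv) substr(r, 1L, nchar(r) - 3L) else r
      step <- edges[[base]] * 1
      if (inv) step <- t(step)
      acc <- if (is.null(acc)) step else acc %*% step
    }
    acc
  })
  for (m in per_mp) counts <- counts + m

  qualifying <- counts >= config$tau
  spurious <- with_seed(derive_seed(config$seed, "spurious"), {
    matrix(stats::runif(n_c * n_d) < config$rho, n_c, n_d) & !qualifying
  })

  # assemble triples
  tr <- list()
  for (r in names(edges)) {
    j <- match(r, schema$relation)
    w <- which(edges[[r]], arr.ind = TRUE)
    if (nrow(w)) {
      tr[[r]] <- data.frame(
        head = ids[[schema$head_type[j]]][w[, 1L]],
        relation = r,
        tail = ids[[schema$tail_type[j]]][w[, 2L]],
        stringsAsFactors = FALSE)
    }
  }
  wt <- which(qualifying | spurious, arr.ind = TRUE)
  treats <- data.frame(head = ids$Compound[wt[, 1L]],
                       relation = rep("CtD", nrow(wt)),
                       tail = ids$Disease[wt[, 2L]],
                       spurious = spurious[wt], n_paths = counts[wt],
                       stringsAsFactors = FALSE)
  triples <- rbind(do.call(rbind, tr),
                   treats[, c("head", "relation", "tail")])
  types <- unlist(lapply(names(ids), function(ty) {
    structure(rep(ty, length(ids[[ty]])), names = ids[[ty]])
  }))
  graph <- kg_graph(triples, entity_types = types)

  witnesses <- enumerate_witnesses(treats, edges, ids, config, schema)
  planted <- vapply(config$metapaths, function(mp) {
    ty <- metapath_types(mp, schema)
    kg_format_body(kg_rule("CtD", mp, ty))
  }, "")
  list(graph = graph,
       ledger = list(planted_rules = planted, treats = treats,
                     witnesses = witnesses, tau = config$tau,
                     rho = config$rho, seed = config$seed))
}

# per non-spurious treats edge: the witnessing node paths of each planted
# metapath (nested-loop enumeration, independent of the matrix counting)
enumerate_witnesses <- function(treats, edges, ids, config, schema) {
  out <- vector("list", nrow(treats))
  names(out) <- pair_key(treats$head, treats$tail)
  for (i in seq_len(nrow(treats))) {
    if (treats$spurious[i]) {
      out[[i]] <- list()
      next
    }
    ci <- match(treats$head[i], ids$Compound)
    di <- match(treats$tail[i], ids$Disease)
    paths <- list()
    for (k in seq_along(config$metapaths)) {
      mp <- config$metapaths[[k]]
      ty <- metapath_types(mp, schema)
      frontier <- list(ci)
      for (s in seq_along(mp)) {
        r <- mp[s]
        inv <- endsWith(r, "^-1")
        base <- if (inv) substr(r, 1L, nchar(r) - 3L) else r
        m <- edges[[base]]
        if (inv) m <- t(m)
        nxt <- list()
        for (p in frontier) {
          cur <- p[length(p)]
          hits <- which(m[cur, ])
          for (h in hits) nxt[[length(nxt) + 1L]] <- c(p, h)
        }
        frontier <- nxt
        if (!length(frontier)) break
      }
      for (p in frontier) {
        if (p[length(p)] == di) {
          paths[[length(paths) + 1L]] <- list(
            metapath = k,
            nodes = vapply(seq_along(p), function(s) ids[[ty[s]]][p[s]], ""))
        }
      }
    }
    out[[i]] <- paths
  }
  out
}

#' Package a ready-to-run synthetic benchmark bundle
#'
#' Generates a graph, splits the non-spurious treats edges 80/10/10
#' (spurious edges always stay in the training split, providing realistic
#' label noise without contaminating the held-out answers), builds the
#' inverse-augmented traversal graph, and optionally writes everything
#' (hetionet-dialect edge file, split TSVs, templates, ledger JSON) to a
#' directory.
#'
#' @param config a [kg_synth_config()]
#' @param dir optional output directory
#' @param fractions split fractions (train, valid, test)
#' @return list with `graph`, `ledger`, `split` (train/valid/test
#'   data.frames + `traversal` graph), `config`
#' @export
kg_synth_bundle <- function(config = kg_synth_config(), dir = NULL,
                            fractions = c(0.8, 0.1, 0.1)) {
  g <- kg_synth_generate(config)
  genuine <- g$ledger$treats[!g$ledger$treats$spurious, , drop = FALSE]
  spur <- g$ledger$treats[g$ledger$treats$spurious, , drop = FALSE]
  if (nrow(genuine) < 10L) {
    stop("only ", nrow(genuine), " planted treats edge(s); ",
         "increase the background densities or node counts")
  }
  # split the genuine edges; re-attach spurious edges to train afterwards
  types <- structure(g$graph$entities$type, names = g$graph$entities$id)
  genuine_graph <- kg_graph(
    rbind(g$graph$triples[g$graph$triples$relation != "CtD", , drop = FALSE],
          genuine[, c("head", "relation", "tail")]),
    entity_types = types)
  split <- kg_split(genuine_graph, "CtD", fractions,
                    seed = derive_seed(config$seed, "split"), augment = FALSE)
  split$train <- rbind(split$train, spur[, c("head", "relation", "tail")])
  rownames(split$train) <- NULL
  traversal <- kg_graph(
    rbind(g$graph$triples[g$graph$triples$relation != "CtD", , drop = FALSE],
          split$train),
    entity_types = types)
  split$traversal <- kg_augment(traversal)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    kg_write(g$graph, file.path(dir, "edges.tsv"), dialect = "hetionet")
    kg_split_write(split, dir)
    kg_templates_write(kg_default_templates(), file.path(dir, "templates.tsv"))
    jsonlite::write_json(
      list(planted_rules = g$ledger$planted_rules,
           treats = g$ledger$treats, tau = g$ledger$tau,
           rho = g$ledger$rho, seed = g$ledger$seed,
           witnesses = g$ledger$witnesses),
      file.path(dir, "ledger.json"), auto_unbox = TRUE, digits = NA)
  }
  list(graph = g$graph, ledger = g$ledger, split = split, config = config)
}
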