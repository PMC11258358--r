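#' Split the target-relation triples into train/valid/test sets
#'
#' Only triples of the target relation (e.g. the "compound treats disease"
#' edges) are split; all other triples always remain available for path
#' finding. The returned traversal graph contains every non-target triple
#' plus the train-split target triples, optionally inverse-augmented, so
#' that held-out answers can never be reached through their own direct
#' edge.
#'
#' Sizes follow floor rounding: train = floor(f_train n), valid =
#' floor(f_valid n), test = the remainder. An explicit external split
#' (three data.frames of target triples) overrides the seeded draw, which
#' is how inherited benchmark splits are reproduced exactly.
#'
#' @param graph an un-augmented `kg_graph`
#' @param target target relation label (e.g. `"CtD"`)
#' @param fractions numeric length 3 (train, valid, test), positive, summing
#'   to 1
#' @param seed integer seed for the reproducible shuffle
#' @param split_files optional named list of data.frames (or TSV file paths)
#'   `train`, `valid`, `test`, each with columns head/relation/tail
#' @param augment logical; inverse-augment the traversal graph
#' @return list with data.frames `train`, `valid`, `test` and the
#'   `traversal` graph (a `kg_graph`)
#' @export
kg_split <- function(graph, target, fractions = c(0.8, 0.1, 0.1),
                     seed = 1L, split_files = NULL, augment = TRUE) {
  stopifnot(inherits(graph, "kg_graph"))
  if (graph$augmented) stop("split the base graph before augmentation")
  if (!target %in% graph$relations) stop("target relation not in graph: ", target)
  stopifnot(length(fractions) == 3L, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")

  is_target <- graph$triples$relation == target
  tgt <- graph$triples[is_target, , drop = FALSE]
  rest <- graph$triples[!is_target, , drop = FALSE]
  n <- nrow(tgt)
  if (n < 3L) stop("need at least 3 target-relation triples to split")

  if (!is.null(split_files)) {
    sets <- lapply(split_files[c("train", "valid", "test")], function(x) {
      if (is.character(x)) {
        x <- utils::read.table(x, sep = "\t", header = FALSE,
                               col.names = c("head", "relation", "tail"),
                               colClasses = "character", quote = "")
      }
      x[, c("head", "relation", "tail"), drop = FALSE]
    })
    allk <- paste(tgt$head, tgt$relation, tgt$tail, sep = "\r")
    for (nm in names(sets)) {
      k <- paste(sets[[nm]]$head, sets[[nm]]$relation, sets[[nm]]$tail, sep = "\r")
      if (!all(k %in% allk)) {
        stop("split file '", nm, "' references triples absent from the graph")
      }
    }
    train <- sets$train; valid <- sets$valid; test <- sets$test
  } else {
    o <- with_seed(seed, sample.int(n))
    n_train <- floor(fractions[1L] * n)
    n_valid <- floor(fractions[2L] * n)
    train <- tgt[o[seq_len(n_train)], , drop = FALSE]
    valid <- tgt[o[n_train + seq_len(n_valid)], , drop = FALSE]
    test <- tgt[o[(n_train + n_valid + 1L):n], , drop = FALSE]
  }
  rownames(train) <- rownames(valid) <- rownames(test) <- NULL

  types <- structure(graph$entities$type, names = graph$entities$id)
  traversal <- kg_graph(rbind(rest, train), entity_types = types)
  if (augment) traversal <- kg_augment(traversal)
  list(train = train, valid = valid, test = test, traversal = traversal)
}

#' Write a train/valid/test split as three TSV files
#' @param split result of [kg_split()]
#' @param dir output directory (created if needed)
#' @return named character vector of the three file paths, invisibly
#' @export
kg_split_write <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(train = file.path(dir, "train.tsv"),
             valid = file.path(dir, "valid.tsv"),
             test = file.path(dir, "test.tsv"))
  for (nm in names(paths)) {
    s <- split[[nm]]
    s <- s[order(s$head, s$relation, s$tail), , drop = FALSE]
    writeLines(paste(s$head, s$relation, s$tail, sep = "\t"), paths[[nm]],
               useBytes = TRUE)
  }
  invisible(paths)
}
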