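#' Run the full repurposing pipeline from one configuration
#'
#' Chains the stages synth -> mine -> train -> predict -> evaluate ->
#' explain, each feeding the next through the package's file formats,
#' and writes a manifest recording seeds, parameters and output hashes.
#' Any subset of stages can be requested; later stages reload their
#' inputs from the artifact directory, so a stage can be rerun in
#' isolation with identical results.
#'
#' Configuration is a named list (or a YAML file path) with optional
#' blocks `synth`, `mine`, `train`, `predict`, `evaluate`, `explain`,
#' plus global keys `seed`, `out`, `stages`. Unknown keys raise an error
#' before any stage runs. Every stochastic stage receives a substream
#' seed derived deterministically from the global seed.
#'
#' @param config named list or path to a YAML file
#' @return invisibly, the manifest list (also written to
#'   `<out>/manifest.json`)
#' @export
kg_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out", "stages", "synth", "mine", "train", "predict",
             "evaluate", "explain")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  seed <- config$seed %||% 1L
  out <- config$out %||% tempfile("kgrepur_run_")
  stages <- config$stages %||% c("synth", "mine", "train", "predict",
                                 "evaluate", "explain")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, out = out, stages = stages,
                   completed = character(), outputs = list())

  bundle <- NULL
  load_bundle <- function() {
    if (!is.null(bundle)) return(bundle)
    need <- file.path(out, c("edges.tsv", "train.tsv", "valid.tsv",
                             "test.tsv"))
    if (!all(file.exists(need))) {
      stop("missing synth artifacts in ", out, "; rerun stage 'synth'")
    }
    graph <- kg_read(file.path(out, "edges.tsv"), dialect = "hetionet")
    sf <- list(train = file.path(out, "train.tsv"),
               valid = file.path(out, "valid.tsv"),
               test = file.path(out, "test.tsv"))
    split <- kg_split(graph, "CtD", seed = seed, split_files = sf)
    bundle <<- list(graph = graph, split = split)
    bundle
  }

  if ("synth" %in% stages) {
    sargs <- config$synth %||% list()
    if (!is.null(sargs$densities)) sargs$densities <- unlist(sargs$densities)
    if (!is.null(sargs$metapaths)) {
      sargs$metapaths <- lapply(sargs$metapaths, unlist)
    }
    sc <- do.call(kg_synth_config,
                  c(sargs, list(seed = derive_seed(seed, "synth"))))
    b <- kg_synth_bundle(sc, dir = out)
    bundle <- list(graph = b$graph, split = b$split)
    manifest$completed <- c(manifest$completed, "synth")
    manifest$outputs$synth <- c("edges.tsv", "train.tsv", "valid.tsv",
                                "test.tsv", "templates.tsv", "ledger.json")
  }

  if ("mine" %in% stages) {
    b <- load_bundle()
    mc <- config$mine %||% list()
    budget <- do.call(kg_budget, mc[setdiff(names(mc), "seed")])
    rules <- kg_mine(b$split$traversal, b$split$train, budget,
                     seed = derive_seed(seed, "mine"))
    kg_rules_write(rules, file.path(out, "rules_mined.tsv"))
    manifest$completed <- c(manifest$completed, "mine")
    manifest$outputs$mine <- "rules_mined.tsv"
  }

  if ("train" %in% stages) {
    b <- load_bundle()
    pf <- file.path(out, "rules_mined.tsv")
    if (!file.exists(pf)) stop("missing ", pf, "; rerun stage 'mine'")
    priors <- kg_rules_read(pf)
    tc <- do.call(kg_train_config,
                  c(config$train %||% list(),
                    list(seed = derive_seed(seed, "train"))))
    model <- kg_train(b$split$traversal,
                      data.frame(head = b$split$train$head,
                                 tail = b$split$train$tail,
                                 stringsAsFactors = FALSE),
                      priors, tc)
    kg_model_save(model, file.path(out, "model"))
    manifest$completed <- c(manifest$completed, "train")
    manifest$outputs$train <- "model"
  }

  model <- NULL
  load_model <- function() {
    if (is.null(model)) {
      md <- file.path(out, "model")
      if (!dir.exists(md)) stop("missing ", md, "; rerun stage 'train'")
      model <<- kg_model_load(md)
    }
    model
  }

  if ("predict" %in% stages) {
    b <- load_bundle()
    m <- load_model()
    pc <- config$predict %||% list()
    heads <- pc$heads %||% sort(unique(b$split$test$head))
    top_k <- pc$top_k %||% 10L
    preds <- lapply(heads, function(h) {
      p <- predict(m, b$split$traversal, h, top_k = top_k)
      structure(data.frame(candidate = p$candidate, score = p$probability,
                           n_rules = p$n_rules, stringsAsFactors = FALSE),
                contributions = attr(p, "contributions"),
                head = h, strategy = "model", target = m$target,
                class = c("kg_prediction", "data.frame"))
    })
    kg_predictions_write(preds, file.path(out, "predictions.tsv"))
    manifest$completed <- c(manifest$completed, "predict")
    manifest$outputs$predict <- "predictions.tsv"
  }

  if ("evaluate" %in% stages) {
    b <- load_bundle()
    m <- load_model()
    known <- rbind(b$split$train, b$split$valid, b$split$test)
    ev <- kg_evaluate(
      b$split$test,
      function(h) {
        p <- predict(m, b$split$traversal, h,
                     top_k = nrow(b$graph$entities))
        structure(p$probability, names = p$candidate)
      },
      known, seed = derive_seed(seed, "evaluate"))
    kg_eval_write(ev, file.path(out, "ranks.tsv"),
                  file.path(out, "metrics.json"))
    manifest$completed <- c(manifest$completed, "evaluate")
    manifest$outputs$evaluate <- c("ranks.tsv", "metrics.json")
  }

  if ("explain" %in% stages) {
    b <- load_bundle()
    m <- load_model()
    ec <- config$explain %||% list()
    compounds <- ec$compounds %||%
      utils::head(sort(unique(b$split$test$head)), 3L)
    top_k <- ec$top_k %||% 5L
    templates <- if (file.exists(file.path(out, "templates.tsv"))) {
      kg_templates_read(file.path(out, "templates.tsv"))
    } else kg_default_templates()
    outs <- character()
    for (h in compounds) {
      p <- predict(m, b$split$traversal, h, top_k = top_k)
      rep <- kg_build_report(p, b$split$traversal, templates,
                             kg_default_mapping(templates), top_k = top_k)
      base <- gsub("[^A-Za-z0-9]+", "_", h)
      kg_report_json(rep, file.path(out, paste0("report_", base, ".json")))
      kg_report_markdown(rep, file.path(out, paste0("report_", base, ".md")))
      outs <- c(outs, paste0("report_", base, c(".json", ".md")))
    }
    manifest$completed <- c(manifest$completed, "explain")
    manifest$outputs$explain <- outs
  }

  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest$hashes <- as.list(tools::md5sum(file.path(out, files)))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
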