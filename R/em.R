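#' Training configuration for the EM-trained rule model
#'
#' @param K rules sampled from the generator per EM iteration
#' @param I top rules (by rule quality H) kept to re-fit the generator
#' @param em_iters EM iterations
#' @param L_max maximum rule body length
#' @param lambda weight of the generator-prior term in H
#' @param predictor_epochs,predictor_lr predictor MLE settings
#' @param generator_epochs,generator_lr generator (weighted) MLE settings
#' @param pretrain_epochs generator pretraining epochs on the prior rules
#' @param transform path-count feature transform, `"log1p"` or `"count"`
#' @param max_paths stored-path cap per (rule, candidate)
#' @param answer_type node type of the candidate universe
#' @param seed integer seed governing every stochastic step
#' @return a `kg_train_config` list
#' @export
kg_train_config <- function(K = 100L, I = 20L, em_iters = 5L, L_max = 3L,
                            lambda = 1, predictor_epochs = 200L,
                            predictor_lr = 0.5, generator_epochs = 100L,
                            generator_lr = 1.0, pretrain_epochs = 300L,
                            transform = c("log1p", "count"),
                            max_paths = 100L, answer_type = "Disease",
                            seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(I >= 1L, K >= I, L_max >= 1L)
  structure(list(K = as.integer(K), I = as.integer(I),
                 em_iters = as.integer(em_iters), L_max = as.integer(L_max),
                 lambda = lambda, predictor_epochs = as.integer(predictor_epochs),
                 predictor_lr = predictor_lr,
                 generator_epochs = as.integer(generator_epochs),
                 generator_lr = generator_lr,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 transform = transform, max_paths = as.integer(max_paths),
                 answer_type = answer_type, seed = as.integer(seed)),
            class = "kg_train_config")
}

#' Fit the rule generator and reasoning predictor by EM
#'
#' The core model: an autoregressive rule generator p_theta(z | q),
#' initialised on mined prior rules, and a log-linear reasoning predictor
#' p_omega(d | G, q, z), optimised jointly for one target relation. Each
#' EM iteration (i) samples K rule bodies from the generator, (ii) fits
#' the predictor weights by maximum likelihood on the training queries,
#' (iii) scores every sampled rule with the quality score H (leave-one-out
#' likelihood gain plus lambda times the generator log-probability),
#' (iv) keeps the top-I rules by H and re-fits the generator by
#' H-weighted maximum likelihood (H clipped below at zero). The joint
#' objective sum_z p_omega(d* | G, q, z) p_theta(z | q) is estimated and
#' logged per iteration.
#'
#' @param graph traversal `kg_graph` (inverse-augmented, train target
#'   triples only)
#' @param queries data.frame of training queries: columns `head`
#'   (compound id) and `tail` (true disease id), one row per training
#'   triple
#' @param priors mined prior rules (`kg_rules`), e.g. from [kg_mine()]
#' @param config a [kg_train_config()]
#' @param target target relation label; defaults to the priors' target
#' @return an object of class `kg_model`: list with `generator`,
#'   `weights`, `rules` (final rule set with `rule_quality_H` and `omega`
#'   columns), `features` transform settings, `history` (per-iteration
#'   logs) and `config`
#' @export
kg_train <- function(graph, queries, priors, config = kg_train_config(),
                     target = NULL) {
  stopifnot(inherits(graph, "kg_graph"), nrow(queries) > 0L)
  if (nrow(priors) == 0L) stop("prior rule set is empty")
  target <- target %||% unique(priors$target)[1L]
  signature <- kg_signature(graph)

  gen <- kg_generator(graph$relations, target, L_max = config$L_max)
  kg_gen_pretrain(gen, priors, epochs = config$pretrain_epochs,
                  lr = config$generator_lr)

  rules <- priors
  weights <- NULL
  H <- numeric(0)
  feats <- NULL
  history <- data.frame(iteration = integer(), n_rules = integer(),
                        train_loglik = numeric(), objective = numeric())

  for (it in seq_len(config$em_iters)) {
    samp <- kg_sample_rules(gen, config$K,
                            seed = derive_seed(config$seed, paste0("em", it)))
    parsed <- lapply(strsplit(samp$key, "\r", fixed = TRUE),
                     function(b) rule_from_relations(target, b, signature))
    ok <- !vapply(parsed, is.null, TRUE)
    parsed <- parsed[ok]
    mult <- samp$count[ok]
    if (!length(parsed)) {
      warning("EM iteration ", it, ": no well-typed rules sampled; skipping")
      next
    }
    rules <- new_rules_df(parsed, provenance = "sampled")

    feats <- kg_features(graph, unique(queries$head), rules,
                         answer_type = config$answer_type,
                         transform = config$transform,
                         max_paths = config$max_paths)
    fit <- kg_train_predictor(feats, queries,
                              epochs = config$predictor_epochs,
                              lr = config$predictor_lr)
    weights <- fit$weights

    H <- kg_rule_quality(feats, queries, weights, gen = gen,
                         lambda = config$lambda)
    I <- config$I
    if (I > length(H)) {
      warning("fewer distinct sampled rules (", length(H),
              ") than I; using all")
      I <- length(H)
    }
    top <- order(-H, rules$body)[seq_len(I)]
    top_bodies <- lapply(kg_rules_parsed(rules)[top], `[[`, "relations")
    w_top <- pmax(H[top], 0)
    if (sum(w_top) == 0) w_top <- rep(1, length(top))
    for (e in seq_len(config$generator_epochs)) {
      gen_grad_step(gen, top_bodies, w_top, config$generator_lr)
    }

    # Monte-Carlo estimate of the joint objective over the sampled rules
    obj <- em_objective(feats, queries, weights, gen, mult)
    history <- rbind(history, data.frame(
      iteration = it, n_rules = nrow(rules),
      train_loglik = fit$loglik[length(fit$loglik)], objective = obj))
    kg_log(sprintf("EM iter %d: %d rules, train loglik %.4f, objective %.6g",
                   it, nrow(rules), fit$loglik[length(fit$loglik)], obj))
  }

  if (!is.null(weights)) {
    rules$rule_quality_H <- H
    rules$omega <- weights
    o <- order(-H, rules$body)
    rules <- rules[o, , drop = FALSE]
    rownames(rules) <- NULL
    weights <- weights[o]
    class(rules) <- c("kg_rules", "data.frame")
  }

  structure(list(generator = gen, weights = weights, rules = rules,
                 target = target, signature = signature,
                 answer_type = config$answer_type,
                 transform = config$transform,
                 max_paths = config$max_paths,
                 history = history, config = config,
                 n_train = nrow(queries)),
            class = "kg_model")
}

# mean over queries of sum_z p_theta(z|q) p_omega(d*|G,q,{z}),
# filtered partition function as in training
em_objective <- function(feats, queries, weights, gen, mult) {
  parsed <- kg_rules_parsed(feats$rules)
  pz <- vapply(parsed, function(r) exp(kg_gen_loglik(gen, r$relations)), 0)
  keep <- query_keep_indices(feats, queries)
  per_q <- vapply(seq_len(nrow(queries)), function(qi) {
    m <- feats$phi[[queries$head[qi]]][keep[[qi]], , drop = FALSE]
    ti <- match(queries$tail[qi], feats$universe[keep[[qi]]])
    tot <- 0
    for (z in seq_along(parsed)) {
      s <- weights[z] * m[, z]
      s <- s - max(s)
      tot <- tot + pz[z] * exp(s[ti]) / sum(exp(s))
    }
    tot
  }, 0)
  mean(per_q)
}

#' @export
print.kg_model <- function(x, ...) {
  cat(sprintf("EM-trained rule model for target '%s'\n", x$target))
  cat(sprintf("  %d rule(s); %d training queries; %d EM iteration(s)\n",
              nrow(x$rules), x$n_train, nrow(x$history)))
  if (nrow(x$history)) {
    cat(sprintf("  final train log-likelihood: %.4f\n",
                x$history$train_loglik[nrow(x$history)]))
  }
  invisible(x)
}

#' @export
summary.kg_model <- function(object, n = 10L, ...) {
  print(object)
  cat("\nTop rules by quality score H:\n")
  cols <- intersect(c("rule_quality_H", "omega", "body"),
                    names(object$rules))
  print.data.frame(utils::head(as.data.frame(object$rules)[, cols], n))
  cat("\nEM history:\n")
  print.data.frame(object$history)
  invisible(object)
}

#' @export
coef.kg_model <- function(object, ...) {
  structure(object$weights, names = object$rules$body)
}

#' @export
logLik.kg_model <- function(object, ...) {
  ll <- if (nrow(object$history)) {
    object$history$train_loglik[nrow(object$history)] * object$n_train
  } else NA_real_
  structure(ll, df = length(object$weights), nobs = object$n_train,
            class = "logLik")
}

#' Sample rule bodies from a fitted model's generator
#' @param object a `kg_model`
#' @param nsim number of bodies to draw
#' @param seed integer seed
#' @param ... unused
#' @return data.frame of distinct bodies with multiplicities
#' @export
simulate.kg_model <- function(object, nsim = 100L, seed = 1L, ...) {
  samp <- kg_sample_rules(object$generator, nsim, seed = seed)
  samp$body <- vapply(strsplit(samp$key, "\r", fixed = TRUE),
                      paste, "", collapse = " ")
  samp
}

#' Rank candidate diseases for a compound with a fitted model
#'
#' Computes the predictor distribution over the answer-type universe using
#' the model's final rule set and weights, and returns the ranked
#' candidates with their per-rule contributions (omega, H, path counts).
#' A head with no outgoing traversal edges yields the uniform distribution
#' and is flagged `no_evidence`.
#'
#' @param object a `kg_model`
#' @param graph traversal `kg_graph` (the one used in training)
#' @param head compound entity id
#' @param top_k candidates to return
#' @param ... unused
#' @return object of class `kg_model_prediction`: data.frame `candidate`,
#'   `probability`, `n_rules`, with attributes `contributions`,
#'   `no_evidence`, `head`
#' @export
predict.kg_model <- function(object, graph, head, top_k = 10L, ...) {
  if (is.na(kg_type(graph, head))) stop("compound absent from graph: ", head)
  w <- object$weights %||% numeric(max(nrow(object$rules), 1L))
  feats <- kg_features(graph, head, object$rules,
                       answer_type = object$answer_type,
                       transform = object$transform,
                       max_paths = object$max_paths)
  no_evidence <- length(kg_out(graph, head)$tail) == 0L
  p <- kg_predictor_distribution(feats, head, w)
  m <- feats$phi[[head]]
  contrib <- lapply(feats$universe, function(d) {
    nz <- which(m[d, ] > 0)
    if (!length(nz)) {
      return(data.frame(body = character(), omega = numeric(),
                        rule_quality_H = numeric(), phi = numeric(),
                        stringsAsFactors = FALSE))
    }
    df <- data.frame(body = object$rules$body[nz],
                     omega = w[nz],
                     rule_quality_H = (object$rules$rule_quality_H %||%
                                         rep(NA_real_, nrow(object$rules)))[nz],
                     phi = m[d, nz], stringsAsFactors = FALSE)
    df[order(-df$rule_quality_H, df$body), , drop = FALSE]
  })
  names(contrib) <- feats$universe
  o <- order(-p, feats$universe)
  o <- utils::head(o, max(top_k, 0L))
  out <- data.frame(candidate = feats$universe[o],
                    probability = unname(p[o]),
                    n_rules = vapply(contrib[feats$universe[o]], nrow, 0L),
                    stringsAsFactors = FALSE)
  structure(out, contributions = contrib[out$candidate],
            no_evidence = no_evidence, head = head, target = object$target,
            class = c("kg_model_prediction", "data.frame"))
}

#' @export
print.kg_model_prediction <- function(x, ...) {
  cat(sprintf("Model prediction for %s%s\n", attr(x, "head"),
              if (isTRUE(attr(x, "no_evidence"))) " [no evidence]" else ""))
  print.data.frame(x)
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' A checkpoint is a directory of plain-text files: the generator logits
#' and vocabulary as JSON, the rule set as TSV (with `rule_quality_H` and
#' `omega` columns), and a config snapshot as JSON.
#' @param model a `kg_model`
#' @param dir checkpoint directory
#' @return `kg_model_save`: `dir` invisibly; `kg_model_load`: a `kg_model`
#' @export
kg_model_save <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- model$generator
  jsonlite::write_json(
    list(vocab = gen$vocab, target = gen$target, L_max = gen$L_max,
         order = gen$order, logits = as.list(gen$logits)),
    file.path(dir, "generator.json"), auto_unbox = TRUE, digits = NA)
  kg_rules_write(model$rules, file.path(dir, "rules.tsv"))
  jsonlite::write_json(
    list(target = model$target, answer_type = model$answer_type,
         transform = model$transform, max_paths = model$max_paths,
         n_train = model$n_train, config = unclass(model$config),
         history = model$history, signature = model$signature),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname kg_model_save
#' @param dir checkpoint directory
#' @export
kg_model_load <- function(dir) {
  gj <- jsonlite::read_json(file.path(dir, "generator.json"),
                            simplifyVector = TRUE)
  gen <- kg_generator(gj$vocab, gj$target, L_max = gj$L_max, order = gj$order)
  # vocab passed through kg_generator may re-sort; restore verbatim fields
  gen$vocab <- gj$vocab
  for (k in names(gj$logits)) assign(k, as.numeric(gj$logits[[k]]),
                                     envir = gen$logits)
  rules <- kg_rules_read(file.path(dir, "rules.tsv"))
  cj <- jsonlite::read_json(file.path(dir, "config.json"),
                            simplifyVector = TRUE)
  cfg <- do.call(kg_train_config, cj$config[setdiff(names(cj$config), NULL)])
  structure(list(generator = gen, weights = rules$omega, rules = rules,
                 target = cj$target,
                 signature = as.data.frame(cj$signature),
                 answer_type = cj$answer_type, transform = cj$transform,
                 max_paths = cj$max_paths,
                 history = as.data.frame(cj$history), config = cfg,
                 n_train = cj$n_train),
            class = "kg_model")
}
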