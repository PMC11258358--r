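#' Autoregressive rule generator over relation sequences
#'
#' The generator defines a probability distribution p(z | q) over rule
#' bodies (relation sequences of length 1..L_max) conditioned on the
#' target relation. It is an order-`order` autoregressive categorical
#' model: the next token (a relation label or the end token) is drawn
#' from a softmax over per-context logits, where the context is the
#' previous `order` tokens (padded with a begin token). The model supports
#' exact likelihood evaluation and ancestral sampling, and normalises
#' exactly: the probabilities of all bodies of length 1..L_max sum to 1
#' (the end token is masked at the first position and forced beyond
#' L_max). The target relation's inverse is excluded from the vocabulary
#' so no rule can explain a triple by its own reversed edge.
#'
#' @param relations relation vocabulary (the traversal graph's labels)
#' @param target target relation label (the conditioning query relation)
#' @param L_max maximum body length
#' @param order autoregressive context length
#' @return an object of class `kg_generator` (logits start at zero, i.e.
#'   uniform)
#' @export
kg_generator <- function(relations, target, L_max = 3L, order = 2L) {
  vocab <- sort(setdiff(unique(relations), kg_inverse_label(target)))
  if (!length(vocab)) stop("empty relation vocabulary")
  structure(list(vocab = vocab, end = "<end>", bos = "<bos>",
                 target = target, L_max = as.integer(L_max),
                 order = as.integer(order),
                 logits = new.env(hash = TRUE)),
            class = "kg_generator")
}

gen_tokens <- function(gen) c(gen$vocab, gen$end)

gen_ctx_key <- function(prev) paste(prev, collapse = "\r")

gen_logits <- function(gen, key) {
  get0(key, envir = gen$logits, inherits = FALSE) %||%
    numeric(length(gen$vocab) + 1L)
}

# next-token distribution given the previous tokens (full body prefix)
gen_step_probs <- function(gen, prefix) {
  prev <- c(rep(gen$bos, gen$order), prefix)
  prev <- prev[(length(prev) - gen$order + 1L):length(prev)]
  lg <- gen_logits(gen, gen_ctx_key(prev))
  if (length(prefix) == 0L) lg[length(lg)] <- -Inf      # no empty body
  if (length(prefix) >= gen$L_max) {                    # end forced
    lg[] <- -Inf
    lg[length(lg)] <- 0
  }
  e <- exp(lg - max(lg))
  e / sum(e)
}

#' Exact log-likelihood of a rule body under the generator
#' @param gen a `kg_generator`
#' @param body character vector of relation labels (length 1..L_max)
#' @return log p(body); `-Inf` for bodies outside the support
#' @export
kg_gen_loglik <- function(gen, body) {
  if (length(body) < 1L || length(body) > gen$L_max) return(-Inf)
  toks <- gen_tokens(gen)
  ll <- 0
  for (i in seq_along(body)) {
    p <- gen_step_probs(gen, body[seq_len(i - 1L)])
    j <- match(body[i], toks)
    if (is.na(j) || p[j] <= 0) return(-Inf)
    ll <- ll + log(p[j])
  }
  p_end <- gen_step_probs(gen, body)[length(toks)]
  ll + log(p_end)
}

#' Sample K rule bodies from the generator
#'
#' Ancestral sampling of K i.i.d. bodies, deduplicated to a multiset
#' (distinct bodies with multiplicities).
#' @param gen a `kg_generator`
#' @param K number of draws (>= 0)
#' @param seed integer seed
#' @return data.frame `body` (list column of character vectors), `key`
#'   (collapsed body string), `count`
#' @export
kg_sample_rules <- function(gen, K, seed = 1L) {
  stopifnot(K >= 0L)
  toks <- gen_tokens(gen)
  draws <- with_seed(seed, {
    replicate(K, {
      body <- character(0)
      repeat {
        p <- gen_step_probs(gen, body)
        tok <- toks[sample.int(length(toks), 1L, prob = p)]
        if (tok == gen$end) break
        body <- c(body, tok)
      }
      paste(body, collapse = "\r")
    })
  })
  if (K == 0L) {
    return(data.frame(key = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  cnt <- table(draws)
  data.frame(key = names(cnt), count = as.integer(cnt),
             stringsAsFactors = FALSE)
}

# one teacher-forcing gradient pass; bodies: list of chr vectors, w: weights
gen_grad_step <- function(gen, bodies, w, lr) {
  toks <- gen_tokens(gen)
  nt <- length(toks)
  grads <- new.env(hash = TRUE)
  add_grad <- function(key, g) {
    cur <- get0(key, envir = grads, inherits = FALSE) %||% numeric(nt)
    assign(key, cur + g, envir = grads)
  }
  for (b in seq_along(bodies)) {
    body <- bodies[[b]]
    steps <- c(body, gen$end)
    for (i in seq_along(steps)) {
      prefix <- body[seq_len(i - 1L)]
      if (length(prefix) >= gen$L_max) next   # forced step, no gradient
      prev <- c(rep(gen$bos, gen$order), prefix)
      prev <- prev[(length(prev) - gen$order + 1L):length(prev)]
      p <- gen_step_probs(gen, prefix)
      oh <- numeric(nt)
      oh[match(steps[i], toks)] <- 1
      add_grad(gen_ctx_key(prev), w[b] * (oh - p))
    }
  }
  tot <- sum(abs(w))
  if (tot > 0) {
    for (key in ls(grads)) {
      assign(key, gen_logits(gen, key) + lr * get(key, envir = grads) / tot,
             envir = gen$logits)
    }
  }
  invisible(gen)
}

#' Pretrain the generator on prior (mined) rules
#'
#' Maximum-likelihood fit by teacher-forcing gradient ascent on the prior
#' rule bodies. With zero epochs the generator is returned untouched
#' (uniform initialisation).
#'
#' @param gen a `kg_generator`
#' @param priors a `kg_rules` data.frame (the mined prior rules)
#' @param epochs gradient-ascent passes
#' @param lr learning rate
#' @param weights optional per-rule weights (defaults to 1)
#' @return the updated `kg_generator` (also modified in place)
#' @export
kg_gen_pretrain <- function(gen, priors, epochs = 300L, lr = 1.0,
                            weights = NULL) {
  if (nrow(priors) == 0L) stop("no prior rules")
  parsed <- kg_rules_parsed(priors)
  bodies <- lapply(parsed, `[[`, "relations")
  bad <- vapply(bodies, function(b) any(!b %in% gen$vocab), TRUE)
  if (any(bad)) {
    stop("prior rule uses a relation outside the generator vocabulary: ",
         priors$body[which(bad)[1L]])
  }
  long <- lengths(bodies) > gen$L_max
  if (any(long)) {
    stop("prior rule body longer than L_max: ", priors$body[which(long)[1L]])
  }
  w <- weights %||% rep(1, length(bodies))
  for (e in seq_len(epochs)) gen_grad_step(gen, bodies, w, lr)
  invisible(gen)
}

#' @export
print.kg_generator <- function(x, ...) {
  cat(sprintf(
    "Autoregressive rule generator (order %d, L_max %d): %d relations, target %s\n",
    x$order, x$L_max, length(x$vocab), x$target))
  invisible(x)
}

# log-probability a zero-logit (uniform) generator assigns to any body of
# length L: first step over V relations (end masked), then V+1 tokens per
# step, and a free end token unless the length cap forces it
gen_uniform_loglik <- function(gen, L) {
  V <- length(gen$vocab)
  ll <- -log(V) - (L - 1) * log(V + 1)
  if (L < gen$L_max) ll <- ll - log(V + 1)
  ll
}

# deep-copy a generator (its logits live in an environment)
gen_clone <- function(gen) {
  g2 <- gen
  g2$logits <- list2env(as.list(gen$logits), hash = TRUE)
  g2
}
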