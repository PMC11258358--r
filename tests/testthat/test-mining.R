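# Bottom-up rule mining: walk sampling, generalization, confidence
# scoring against the nested-loop oracle, and full mining runs.

test_that("walks from a dead-end head return NULL, not an error", {
  g <- kg_graph(data.frame(head = "c1", relation = "treats", tail = "d1"),
                c(c1 = "Compound", d1 = "Disease"))
  # d1 has no outgoing edges in the un-augmented graph; neither has c1 once
  # the direct target edge is excluded
  triple <- list(head = "c1", relation = "treats", tail = "d1")
  set.seed(1)
  expect_null(kg_sample_ground_path(g, triple, 1L))
})

test_that("the unique connecting walk is found whenever sampling succeeds", {
  g <- kg_augment(kg_graph(
    data.frame(head = c("c1", "c1", "g1", "x1"),
               relation = c("treats", "up", "assoc", "noise"),
               tail = c("d1", "g1", "d1", "x2")),
    c(c1 = "Compound", d1 = "Disease", g1 = "Gene", x1 = "Any", x2 = "Any")))
  triple <- list(head = "c1", relation = "treats", tail = "d1")
  set.seed(42)
  found <- 0L
  for (i in 1:200) {
    p <- kg_sample_ground_path(g, triple, 2L)
    if (!is.null(p)) {
      found <- found + 1L
      expect_equal(p$nodes, c("c1", "g1", "d1"))
      expect_equal(p$relations, c("up", "assoc"))
    }
  }
  expect_gt(found, 0L)
})

test_that("first walk steps are uniform over outgoing edges (binomial 3-sigma)", {
  g <- kg_augment(kg_graph(
    data.frame(head = c("c1", "c1", "c1"),
               relation = c("treats", "up", "binds"),
               tail = c("d1", "g1", "g2")),
    c(c1 = "Compound", d1 = "Disease", g1 = "Gene", g2 = "Gene")))
  triple <- list(head = "c1", relation = "treats", tail = "d1")
  # excluded steps: the direct treats edge and treats^-1 edges; c1 has two
  # usable first edges (up -> g1, binds -> g2)
  set.seed(7)
  n <- 10000L
  firsts <- character(n)
  for (i in seq_len(n)) {
    # length-1 walks: the single step is the first step
    o <- kgrepur:::kg_out(g, "c1")
    keep <- o$relation != "treats^-1" &
      !(o$relation == "treats" & o$tail == "d1")
    j <- which(keep)[sample.int(sum(keep), 1L)]
    firsts[i] <- o$relation[j]
  }
  p_hat <- mean(firsts == "up")
  sigma <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(p_hat - 0.5), 3 * sigma)
})

test_that("confidence matches hand-built counts", {
  # body up/assoc connects 4 (compound, disease) pairs; exactly 1 is treats
  tr <- data.frame(
    head = c("c1", "c2", "g1", "g1", "g2", "g2", "c1"),
    relation = c("up", "up", "assoc", "assoc", "assoc", "assoc", "treats"),
    tail = c("g1", "g2", "d1", "d2", "d1", "d2", "d1"))
  types <- c(c1 = "Compound", c2 = "Compound", g1 = "Gene", g2 = "Gene",
             d1 = "Disease", d2 = "Disease")
  g <- kg_augment(kg_graph(tr, types))
  rule <- kg_rule("treats", c("up", "assoc"), c("Compound", "Gene", "Disease"))
  known <- data.frame(head = "c1", tail = "d1")
  out <- kg_confidence(g, rule, known)
  expect_equal(out$body_groundings, 4L)
  expect_equal(out$support, 1L)
  expect_equal(out$confidence, 0.25)

  # every grounding pair known -> confidence 1
  known_all <- data.frame(head = c("c1", "c1", "c2", "c2"),
                          tail = c("d1", "d2", "d1", "d2"))
  expect_equal(kg_confidence(g, rule, known_all)$confidence, 1.0)

  # unsatisfiable body -> unevaluable, not zero
  dead <- kg_rule("treats", "absent", c("Compound", "Disease"))
  expect_true(is.na(kg_confidence(g, dead, known)$confidence))
})

test_that("confidence equals the nested-loop oracle on random graphs", {
  for (seed in 1:25) {
    g <- random_graph(seed)
    expect_lte(nrow(g$triples), 200L)
    trav <- kg_augment(g)
    known <- g$triples[g$triples$relation == "tAC", c("head", "tail")]
    for (rule in random_rules(seed + 1000, n = 4L)) {
      mine <- kg_confidence(trav, rule, known)
      orac <- oracle_confidence(trav, rule, known)
      expect_equal(mine$body_groundings, orac$groundings,
                   info = kg_format_body(rule))
      expect_equal(mine$support, orac$support)
      expect_equal(mine$confidence, orac$confidence)
    }
  }
})

test_that("mining recovers a planted rule with confidence 1 in the
           noise-free regime", {
  cfg <- small_synth_config(seed = 9, rho = 0)
  b <- kg_synth_generate(cfg)
  trav <- kg_augment(b$graph)
  treats <- b$ledger$treats
  rules <- suppressWarnings(
    kg_mine(trav, data.frame(head = treats$head, relation = "CtD",
                             tail = treats$tail),
            kg_budget(max_samples = 4000L), seed = 2))
  planted <- b$ledger$planted_rules
  hit <- intersect(planted, rules$body)
  expect_gt(length(hit), 0L)
  expect_true(all(rules$confidence[match(hit, rules$body)] == 1.0))
})

test_that("mining is deterministic per seed and invariant to triple order", {
  b <- kg_synth_bundle(small_synth_config(seed = 3))
  train <- b$split$train
  r1 <- suppressWarnings(kg_mine(b$split$traversal, train,
                                 kg_budget(max_samples = 2000L), seed = 5))
  shuffled <- train[rev(seq_len(nrow(train))), ]
  r2 <- suppressWarnings(kg_mine(b$split$traversal, shuffled,
                                 kg_budget(max_samples = 2000L), seed = 5))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("every mined rule has a witnessing ground path", {
  b <- kg_synth_bundle(small_synth_config(seed = 4))
  rules <- suppressWarnings(kg_mine(b$split$traversal, b$split$train,
                                    kg_budget(max_samples = 2000L), seed = 6))
  for (r in kg_rules_parsed(rules)) {
    heads <- b$split$traversal$entities$id[
      b$split$traversal$entities$type == r$types[1L]]
    witnessed <- FALSE
    for (h in heads) {
      if (length(kg_apply_rule(b$split$traversal, h, r, max_paths = 1L))) {
        witnessed <- TRUE
        break
      }
    }
    expect_true(witnessed, info = kg_format_body(r))
  }
})

test_that("an exhausted or empty budget yields an empty rule set", {
  b <- kg_synth_bundle(small_synth_config(seed = 3))
  expect_warning(
    r0 <- kg_mine(b$split$traversal, b$split$train,
                  kg_budget(max_samples = 0L), seed = 1),
    "no rules")
  expect_equal(nrow(r0), 0L)
  expect_error(kg_budget(max_samples = NULL, max_seconds = NULL))
})
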