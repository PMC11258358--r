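# Rule application, score aggregation and full prediction, checked
# against closed forms and the nested-loop oracle.

test_that("apply_rule validates its inputs", {
  g <- toy_graph(augment = TRUE)
  rule <- kg_rule("treats", c("upregulates", "associates"),
                  c("Compound", "Gene", "Disease"))
  expect_error(kg_apply_rule(g, "d1", rule), "type")
  expect_error(kg_apply_rule(g, "c1", rule, max_paths = 0L), "positive")
})

test_that("apply_rule finds the toy grounding and honours exclusions", {
  g <- toy_graph(augment = TRUE)
  rule <- kg_rule("treats", c("upregulates", "associates"),
                  c("Compound", "Gene", "Disease"))
  res <- kg_apply_rule(g, "c1", rule)
  expect_equal(names(res), "d1")
  expect_equal(res$d1$n_paths, 1L)
  expect_equal(res$d1$paths[[1]], c("c1", "g1", "d1"))

  # unsatisfiable body
  dead <- kg_rule("treats", "missing_rel", c("Compound", "Disease"))
  expect_length(kg_apply_rule(g, "c1", dead), 0L)

  # a cycle back to the head is not an answer
  gc <- kg_augment(kg_graph(
    data.frame(head = c("a1", "b1"), relation = c("r", "s"),
               tail = c("b1", "a1")),
    c(a1 = "A", b1 = "B")))
  cyc <- kg_rule("t", c("r", "s"), c("A", "B", "A"))
  expect_length(kg_apply_rule(gc, "a1", cyc), 0L)
})

test_that("groundings through the pair's own target edge are excluded
           from scoring but recoverable on request", {
  # c1 -CtD-> d1 and a body that walks out and back over it
  g <- kg_augment(kg_graph(
    data.frame(head = c("c1", "c2", "c1", "c2"),
               relation = c("CtD", "CtD", "CbG", "CbG"),
               tail = c("d1", "d1", "g1", "g1")),
    c(c1 = "Compound", c2 = "Compound", d1 = "Disease", g1 = "Gene")))
  rule <- kg_rule("CtD", c("CbG", "CbG^-1", "CtD"),
                  c("Compound", "Gene", "Compound", "Disease"))
  res <- kg_apply_rule(g, "c1", rule)
  # the only non-leaking grounding runs through c2's treats edge
  expect_equal(res$d1$n_paths, 1L)
  expect_equal(res$d1$paths[[1]], c("c1", "g1", "c2", "d1"))
  raw <- kg_apply_rule(g, "c1", rule, exclude_direct = FALSE)
  expect_equal(raw$d1$n_paths, 2L)
})

test_that("aggregation strategies reproduce their closed forms", {
  single <- list(d1 = c(r1 = 0.7))
  for (s in c("max", "noisy_or", "nr_noisy_or")) {
    expect_equal(kg_aggregate(single, s)$score, 0.7)
  }
  expect_equal(kg_aggregate(list(d = c(a = 0.5, b = 0.5)), "noisy_or")$score,
               0.75)
  # two redundant rules {0.6, 0.5} plus an independent {0.4}:
  # max within the cluster, noisy-OR across -> 1 - 0.4 * 0.6 = 0.76
  clusters <- c(r1 = "c1", r2 = "c1", r3 = "c2")
  got <- kg_aggregate(list(d = c(r1 = 0.6, r2 = 0.5, r3 = 0.4)),
                      "nr_noisy_or", clusters = clusters)
  expect_equal(got$score, 0.76)

  expect_equal(nrow(kg_aggregate(list(), "max")), 0L)
  expect_error(kg_aggregate(list(d = 1.2), "max"), "\\[0, 1\\]")
})

test_that("aggregates dominate the max, ignore zero-score rules and are
           permutation-invariant", {
  set.seed(31)
  for (i in 1:50) {
    sc <- runif(sample(1:6, 1))
    names(sc) <- paste0("r", seq_along(sc))
    agg_max <- kg_aggregate(list(d = sc), "max")$score
    agg_nor <- kg_aggregate(list(d = sc), "noisy_or")$score
    expect_equal(agg_max, max(sc))
    expect_gte(agg_nor, agg_max)
    expect_lte(agg_nor, 1)
    # adding a zero-confidence rule changes nothing
    sc0 <- c(sc, r0 = 0)
    expect_equal(kg_aggregate(list(d = sc0), "noisy_or")$score, agg_nor)
    # order of rules is irrelevant
    perm <- sample(sc)
    expect_equal(kg_aggregate(list(d = perm), "noisy_or")$score, agg_nor)
  }
})

test_that("maximum-score ties break by the lexicographic score cascade", {
  cands <- list(d_many = c(a = 0.9, b = 0.8),
                d_single = c(a = 0.9),
                d_low = c(a = 0.9, b = 0.1))
  out <- kg_aggregate(cands, "max")
  expect_equal(out$candidate, c("d_many", "d_low", "d_single"))
  expect_equal(out$score, rep(0.9, 3))
})

test_that("prediction equals the nested-loop oracle on random graphs", {
  for (seed in 1:12) {
    g <- random_graph(seed + 50)
    trav <- kg_augment(g)
    known <- g$triples[g$triples$relation == "tAC", c("head", "tail")]
    rules <- random_rules(seed + 77, n = 5L)
    scored <- lapply(rules, kg_confidence, graph = trav,
                     known_targets = known)
    keep <- !vapply(scored, function(r) is.na(r$confidence), TRUE)
    scored <- scored[keep]
    if (!length(scored)) next
    df <- kgrepur:::new_rules_df(
      scored,
      support = vapply(scored, `[[`, 0L, "support"),
      body_groundings = vapply(scored, `[[`, 0L, "body_groundings"),
      confidence = vapply(scored, `[[`, 0, "confidence"))
    heads <- g$entities$id[g$entities$type == "A"][1:3]
    clusters <- kg_redundancy_clusters(trav, df)
    for (h in heads) {
      for (strat in c("max", "noisy_or", "nr_noisy_or")) {
        mine <- kg_predict_rules(trav, h, df, strat, top_k = 100L)
        orac <- oracle_predict(trav, h, df, strat, clusters = clusters)
        expect_equal(mine$candidate %in% orac$candidate,
                     rep(TRUE, nrow(mine)))
        expect_equal(nrow(mine), nrow(orac))
        oidx <- match(mine$candidate, orac$candidate)
        expect_equal(mine$score, orac$score[oidx], tolerance = 1e-12,
                     info = paste(strat, h, "seed", seed))
      }
    }
  }
})

test_that("top_k truncates and the perfect-rule case ranks the answer first", {
  b <- kg_synth_generate(small_synth_config(seed = 21, rho = 0))
  trav <- kg_augment(b$graph)
  treats <- b$ledger$treats
  planted <- kg_rules_parsed(kgrepur:::new_rules_df(
    lapply(b$ledger$planted_rules, kg_parse_body, target = "CtD"),
    confidence = 1))
  df <- kgrepur:::new_rules_df(planted, confidence = 1)
  h <- treats$head[1]
  pred <- kg_predict_rules(trav, h, df, "noisy_or", top_k = 5L)
  expect_equal(pred$score[1], 1.0)
  expect_true(treats$tail[treats$head == h][1] %in%
                pred$candidate[pred$score == 1.0])
  expect_equal(nrow(kg_predict_rules(trav, h, df, "max", top_k = 0L)), 0L)
})

test_that("prediction TSV and contribution sidecar are written", {
  b <- kg_synth_bundle(small_synth_config(seed = 3))
  rules <- suppressWarnings(kg_mine(b$split$traversal, b$split$train,
                                    kg_budget(max_samples = 2000L), seed = 5))
  h <- b$split$test$head[1]
  p <- kg_predict_rules(b$split$traversal, h, rules, "noisy_or", top_k = 5L)
  f <- withr::local_tempfile(fileext = ".tsv")
  kg_predictions_write(p, f)
  tab <- read.delim(f)
  expect_equal(names(tab),
               c("query_head", "rank", "candidate", "score", "strategy",
                 "n_rules"))
  expect_equal(tab$rank, seq_len(nrow(tab)))
  side <- readLines(paste0(f, ".contributions.jsonl"))
  expect_equal(length(side), nrow(tab))
  one <- jsonlite::fromJSON(side[1])
  expect_true(all(c("query_head", "candidate", "contributions") %in%
                    names(one)))
})
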