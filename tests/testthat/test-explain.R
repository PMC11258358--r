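# Natural-language rendering, Cypher emission and the in-memory matcher.

table3_rule <- function() {
  kg_rule("CtD", c("CuG", "AeG^-1", "DlA^-1"),
          c("Compound", "Gene", "Anatomy", "Disease"))
}

test_that("rules render in the bracketed arrow form with inverse phrases", {
  expect_equal(
    kg_render_rule(table3_rule()),
    paste0("[Compound --upregulates--> Gene --is expressed by--> ",
           "Anatomy --is localized to--> Disease]"))
  r2 <- kg_rule("CtD", c("CuG", "GrG", "DaG^-1"),
                c("Compound", "Gene", "Gene", "Disease"))
  expect_equal(
    kg_render_rule(r2),
    "[Compound --upregulates--> Gene --regulates--> Gene --is associated to--> Disease]")
  missing_tpl <- kg_rule("CtD", "XyZ", c("Compound", "Disease"))
  expect_error(kg_render_rule(missing_tpl), "XyZ")
})

test_that("rendered rules parse back to the original rule", {
  rules <- list(
    table3_rule(),
    kg_rule("CtD", c("CcSE", "CcSE^-1", "CtD"),
            c("Compound", "Side Effect", "Compound", "Disease")),
    kg_rule("CtD", c("CtD", "DaG", "DaG^-1"),
            c("Compound", "Disease", "Gene", "Disease")))
  for (r in rules) {
    txt <- kg_render_rule(r)
    back <- kg_parse_rendered_rule(txt, "CtD")
    expect_equal(back$relations, r$relations)
    expect_equal(back$types, r$types)
  }
})

test_that("rendering is injective over the synthetic rule universe", {
  b <- kg_synth_bundle(small_synth_config(seed = 19))
  rules <- suppressWarnings(kg_mine(b$split$traversal, b$split$train,
                                    kg_budget(max_samples = 3000L), seed = 4))
  rendered <- vapply(kg_rules_parsed(rules), kg_render_rule, "")
  expect_equal(anyDuplicated(rendered), 0L)
})

test_that("grounded paths render with display names and matching phrases", {
  rule <- kg_rule("CtD", c("CuG", "GrG", "DaG^-1"),
                  c("Compound", "Gene", "Gene", "Disease"))
  nodes <- c("Compound::Epirubicin", "Gene::EGF", "Gene::BRAF",
             "Disease::Breast cancer")
  expect_equal(
    kg_render_path(nodes, rule),
    "Epirubicin --upregulates--> EGF --regulates--> BRAF --is associated to--> Breast cancer")
  # single-step path
  r1 <- kg_rule("other", "CtD", c("Compound", "Disease"))
  expect_equal(kg_render_path(c("c1", "d1"), r1), "c1 --treats--> d1")
  # position-by-position agreement between rule and path renderings
  txt_rule <- kg_render_rule(rule)
  txt_path <- kg_render_path(nodes, rule)
  phr <- function(s) regmatches(s, gregexpr("--[^>]*-->", s))[[1]]
  expect_equal(phr(txt_path), phr(txt_rule))
})

test_that("emitted Cypher matches the documented template", {
  r1 <- kg_rule("other", "CtD", c("Compound", "Disease"))
  expect_equal(
    kg_emit_cypher(r1, "Compound::DB00997"),
    paste0('MATCH path = (n0:Compound {identifier: "Compound::DB00997"})',
           "-[:TREATS_CtD]->(n1:Disease) RETURN path"))
  # inverse step reverses the arrow; constrained tail adds the property
  r2 <- table3_rule()
  q <- kg_emit_cypher(r2, "Compound::C1", "Disease::D1")
  expect_match(q, "<-\\[:EXPRESSES_AeG\\]-", fixed = FALSE)
  expect_match(q, "<-\\[:LOCALIZES_DlA\\]-", fixed = FALSE)
  expect_match(q, '\\(n3:Disease \\{identifier: "Disease::D1"\\}\\)')
  # node labels with spaces are backticked
  r3 <- kg_rule("CtD", c("CcSE", "CcSE^-1", "CtD"),
                c("Compound", "Side Effect", "Compound", "Disease"))
  expect_match(kg_emit_cypher(r3, "Compound::C1"), "`Side Effect`",
               fixed = TRUE)
  unmapped <- kg_rule("CtD", "QqQ", c("Compound", "Disease"))
  expect_error(kg_emit_cypher(unmapped, "c"), "QqQ")
})

test_that("the mock matcher reproduces apply_rule's groundings", {
  b <- kg_synth_generate(small_synth_config(seed = 23))
  expect_lte(nrow(b$graph$triples), 1000L)
  trav <- kg_augment(b$graph)
  rules <- lapply(b$ledger$planted_rules, kg_parse_body, target = "CtD")
  rules <- c(rules, list(
    kg_rule("CtD", c("CtD", "DaG", "DaG^-1"),
            c("Compound", "Disease", "Gene", "Disease")),
    kg_rule("CtD", c("CcSE", "CcSE^-1", "CtD"),
            c("Compound", "Side Effect", "Compound", "Disease"))))
  heads <- utils::head(b$graph$entities$id[
    b$graph$entities$type == "Compound"], 6L)
  for (rule in rules) {
    for (h in heads) {
      res <- kg_apply_rule(trav, h, rule, max_paths = 10000L)
      # wildcard-tail query retrieves every grounding of the rule from h
      qw <- kg_emit_cypher(rule, h)
      got <- kg_cypher_match(qw, b$graph, target = "CtD")
      got_tails <- sort(unique(vapply(got, function(p) p[length(p)], "")))
      expect_equal(got_tails, as.character(names(res)),
                   info = kg_format_body(rule))
      # per-candidate path sets coincide
      for (t in names(res)) {
        qt <- kg_emit_cypher(rule, h, t)
        pt <- kg_cypher_match(qt, b$graph, target = "CtD")
        expect_equal(length(pt), res[[t]]$n_paths)
        expect_setequal(vapply(pt, paste, "", collapse = "|"),
                        vapply(res[[t]]$paths, paste, "", collapse = "|"))
      }
    }
  }
})

test_that("reports list only witnessed rules and serialize losslessly", {
  b <- kg_synth_bundle(small_synth_config(seed = 13))
  rules <- suppressWarnings(kg_mine(b$split$traversal, b$split$train,
                                    kg_budget(max_samples = 3000L), seed = 9))
  h <- b$split$test$head[1]
  pred <- kg_predict_rules(b$split$traversal, h, rules, "noisy_or",
                           top_k = 4L)
  rep <- kg_build_report(pred, b$split$traversal)
  expect_s3_class(rep, "kg_report")
  expect_equal(rep$compound, h)
  expect_lte(length(rep$candidates), 4L)
  for (cand in rep$candidates) {
    for (r in cand$rules) {
      expect_gte(r$n_paths, 1L)
      expect_match(r$cypher, "^MATCH path = ")
      expect_true(length(r$example_paths) >= 1L)
    }
    sc <- vapply(cand$rules, `[[`, 0, "score")
    expect_false(is.unsorted(rev(sc)))
  }
  f <- withr::local_tempfile(fileext = ".json")
  kg_report_json(rep, f)
  back <- kg_report_from_json(f)
  expect_equal(unclass(back), unclass(rep), tolerance = 1e-12)
  md <- kg_report_markdown(rep)
  expect_match(md[1], "^# Repurposing report")

  # top_k = 1 gives a single-candidate report
  rep1 <- kg_build_report(pred, b$split$traversal, top_k = 1L)
  expect_length(rep1$candidates, 1L)
})
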