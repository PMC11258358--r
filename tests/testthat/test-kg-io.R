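# Graph construction, dialect readers/writers, inverse augmentation and
# target-relation splitting.

test_that("generic dialect loads the hand-counted fixture", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\ttreats\td1", "c1\tupregulates\tg1",
               "g1\tassociates\td1"), f)
  g <- kg_read(f, dialect = "generic")
  expect_equal(nrow(g$triples), 3L)
  expect_equal(nrow(g$entities), 3L) # c1, d1, g1
  expect_equal(length(g$relations), 3L)
  expect_equal(unique(g$entities$type), "Any")
})

test_that("hetionet dialect parses Type::Id node types and empty files", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\tmetaedge\ttarget",
               "Compound::DB01\tCtD\tDisease::DO05",
               "Gene::G1\tGr>G\tGene::G2"), f)
  g <- kg_read(f, dialect = "hetionet")
  expect_equal(nrow(g$triples), 2L)
  expect_equal(kg_type(g, "Compound::DB01"), "Compound")
  expect_equal(kg_type(g, "Gene::G2"), "Gene")
  expect_true("Gr>G" %in% g$relations) # directed metaedge marker preserved

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("source\tmetaedge\ttarget", empty)
  g0 <- kg_read(empty, dialect = "hetionet")
  expect_equal(nrow(g0$triples), 0L)
  expect_equal(nrow(g0$entities), 0L)
})

test_that("malformed input is rejected with the offending line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tr\tb", "broken line"), f)
  expect_error(kg_read(f, dialect = "generic"), "line 2")
  expect_error(kg_read(f, dialect = "bogus"))
})

test_that("duplicate triples collapse with a warning", {
  tr <- rbind(toy_triples(), toy_triples()[1, ])
  expect_warning(g <- kg_graph(tr, toy_types), "duplicate")
  expect_equal(nrow(g$triples), 3L)
})

test_that("write-then-read round-trips both dialects byte-stably", {
  g <- toy_graph()
  f1 <- withr::local_tempfile(fileext = ".tsv")
  kg_write(g, f1, dialect = "generic")
  g1 <- kg_read(f1, dialect = "generic")
  expect_setequal(paste(g1$triples$head, g1$triples$relation, g1$triples$tail),
                  paste(g$triples$head, g$triples$relation, g$triples$tail))

  b <- kg_synth_generate(small_synth_config(seed = 3))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  kg_write(b$graph, f2, dialect = "hetionet")
  g2 <- kg_read(f2, dialect = "hetionet")
  kg_write(g2, f3, dialect = "hetionet")
  expect_identical(readLines(f2), readLines(f3))
  expect_setequal(g2$entities$type, unique(b$graph$entities$type))
})

test_that("inverse augmentation doubles triples and is involutive", {
  g1 <- kg_graph(toy_triples()[1, ], toy_types)
  a1 <- kg_augment(g1)
  expect_equal(nrow(a1$triples), 2L)
  expect_true(kg_has_triple(a1, "d1", "treats^-1", "c1"))

  g <- toy_graph()
  a <- kg_augment(g)
  expect_equal(nrow(a$triples), 6L)
  out_d1 <- kgrepur:::kg_out(a, "d1")
  expect_true(all(c("treats^-1", "associates^-1") %in% out_d1$relation))
  expect_error(kg_augment(a), "already")

  back <- kg_strip_inverse(a)
  expect_setequal(
    paste(back$triples$head, back$triples$relation, back$triples$tail),
    paste(g$triples$head, g$triples$relation, g$triples$tail))

  expect_equal(kg_inverse_label(kg_inverse_label("CtD")), "CtD")
  expect_equal(kg_inverse_label("AeG^-1"), "AeG")
})

test_that("seeded splits honour floor rounding, determinism and partition", {
  hs <- sprintf("c%d", 1:10)
  tr <- rbind(
    data.frame(head = hs, relation = "treats", tail = sprintf("d%d", 1:10),
               stringsAsFactors = FALSE),
    data.frame(head = hs, relation = "binds", tail = sprintf("g%d", 1:10),
               stringsAsFactors = FALSE))
  g <- kg_graph(tr)
  s <- kg_split(g, "treats", c(0.8, 0.1, 0.1), seed = 4, augment = FALSE)
  expect_equal(c(nrow(s$train), nrow(s$valid), nrow(s$test)), c(8L, 1L, 1L))
  s2 <- kg_split(g, "treats", c(0.8, 0.1, 0.1), seed = 4, augment = FALSE)
  expect_identical(s[c("train", "valid", "test")],
                   s2[c("train", "valid", "test")])

  keys <- function(d) paste(d$head, d$relation, d$tail)
  all_target <- keys(tr[tr$relation == "treats", ])
  expect_setequal(c(keys(s$train), keys(s$valid), keys(s$test)), all_target)
  expect_length(intersect(keys(s$test), keys(s$train)), 0L)
  expect_length(intersect(keys(s$test), keys(s$valid)), 0L)
})

test_that("traversal graph hides held-out target edges but keeps the rest", {
  b <- kg_synth_bundle(small_synth_config(seed = 5))
  s <- b$split
  trav <- s$traversal
  expect_true(trav$augmented)
  for (i in seq_len(nrow(s$test))) {
    expect_false(kg_has_triple(trav, s$test$head[i], "CtD", s$test$tail[i]))
    expect_false(kg_has_triple(trav, s$test$tail[i], "CtD^-1", s$test$head[i]))
  }
  i <- 1L
  expect_true(kg_has_triple(trav, s$train$head[i], "CtD", s$train$tail[i]))
  expect_true(kg_has_triple(trav, s$train$tail[i], "CtD^-1", s$train$head[i]))
})

test_that("explicit split files override the seeded draw and are validated", {
  hs <- sprintf("c%d", 1:10)
  tr <- data.frame(head = hs, relation = "treats",
                   tail = sprintf("d%d", 1:10), stringsAsFactors = FALSE)
  g <- kg_graph(rbind(tr, data.frame(head = "c1", relation = "binds",
                                     tail = "g1")))
  sf <- list(train = tr[1:6, ], valid = tr[7:8, ], test = tr[9:10, ])
  s <- kg_split(g, "treats", seed = 1, split_files = sf, augment = FALSE)
  expect_equal(s$test$head, c("c9", "c10"))
  bad <- sf
  bad$test <- data.frame(head = "cX", relation = "treats", tail = "dX")
  expect_error(kg_split(g, "treats", split_files = bad), "absent")

  few <- kg_graph(tr[1:2, ])
  expect_error(kg_split(few, "treats"), "at least 3")
})
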