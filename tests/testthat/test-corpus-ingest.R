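# Gene-set / document ingestion and the text preprocessing pipeline.

test_that("read_gmt parses sets, dedups genes, and round-trips", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc one\tA\tB\tA",
               "S2\tdesc two\tB\tC\tD",
               "S3\tdesc three\tX\tY\tZ\tW"), f)
  sets <- read_gmt(f)
  expect_named(sets, c("S1", "S2", "S3"))
  expect_equal(sets$S1, c("A", "B"))  # duplicate collapsed, order kept
  expect_equal(lengths(sets), c(S1 = 2L, S2 = 3L, S3 = 4L))
  expect_equal(attr(sets, "description")[["S2"]], "desc two")

  # round trip
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f2)
  back <- read_gmt(f2)
  expect_equal(back, sets)
})

test_that("read_gmt rejects malformed input and reports the line", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tonlydesc"), f)
  expect_error(read_gmt(f), "line 2")

  f3 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\td\tA", "S1\td\tB"), f3)
  expect_error(read_gmt(f3), "duplicate set ids")

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_length(read_gmt(empty), 0)
})

test_that("merge_documents concatenates per set with abstract precedence", {
  recs <- data.frame(
    doc_id = c("d1", "d2", "d3", "d4"),
    set_id = c("S1", "S1", "S2", "S2"),
    source = c("abstract", "abstract", "description", "abstract"),
    text = c("a b", "c", "ignored description", "kept abstract"),
    stringsAsFactors = FALSE
  )
  merged <- merge_documents(recs)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$text[merged$set_id == "S1"], "a b c")
  # abstract outranks the description for S2
  expect_equal(merged$text[merged$set_id == "S2"], "kept abstract")
  expect_equal(merged$source[merged$set_id == "S2"], "abstract")

  # description used only when no abstract exists
  only_desc <- data.frame(doc_id = "d", set_id = "S", source = "description",
                          text = "fallback", stringsAsFactors = FALSE)
  expect_equal(merge_documents(only_desc)$source, "description")

  # single record is the identity
  one <- recs[1, ]
  m1 <- merge_documents(one)
  expect_equal(m1$text, "a b")
})

test_that("preprocess_text applies the full normalization pipeline", {
  expect_equal(preprocess_text("DNA Repair and damage-response 2001",
                               stopwords = "and"),
               c("dna", "repair", "damag", "respons"))
  expect_equal(preprocess_text(""), character(0))
  expect_equal(preprocess_text("the of and",
                               stopwords = c("the", "of", "and")),
               character(0))
  # Greek / non-Latin residues are dropped, digits and punctuation split
  expect_equal(preprocess_text("TGF-β signaling, IL6/IL-8!"),
               c("tgf", "signal", "il", "il"))
  # tokens shorter than 2 characters are removed ("a", "x")
  expect_equal(preprocess_text("a x ray"), c("rai"))
})

test_that("preprocessing is idempotent on its own output", {
  # stems ending in a lone "s" (e.g. "respons") are re-stripped by the
  # stemmer's plural rule on a second pass, so idempotency is checked on
  # text whose stems are stemmer fixed points
  texts <- c(
    "Mitochondrial dysfunction and neuronal decline in the brain",
    "Lipid metabolism regulates membrane phospholipid biosynthesis",
    "DNA Repair and damage control 2001"
  )
  for (tx in texts) {
    once <- preprocess_text(tx)
    twice <- preprocess_text(paste(once, collapse = " "))
    expect_equal(twice, once)
  }
})

test_that("porter_stem reproduces canonical rule-step behavior", {
  words <- c("caresses", "ponies", "caress", "cats", "feed", "agreed",
             "plastered", "bled", "motoring", "sing", "conflated",
             "troubled", "sized", "hopping", "tanned", "falling", "hissing",
             "fizzed", "failing", "filing", "happy", "sky", "relational",
             "conditional", "rational", "valenci", "digitizer",
             "radicalli", "differentli", "vileli", "analogousli",
             "predication", "operator", "feudalism", "decisiveness",
             "hopefulness", "callousness", "formaliti", "sensitiviti",
             "sensibiliti", "triplicate", "formative", "formalize",
             "electriciti", "electrical", "hopeful", "goodness", "revival",
             "allowance", "inference", "airliner", "gyroscopic",
             "adjustable", "defensible", "irritant", "replacement",
             "adjustment", "dependent", "adoption", "communism", "activate",
             "angulariti", "homologous", "effective", "bowdlerize",
             "probate", "cease", "controll")
  stems <- c("caress", "poni", "caress", "cat", "feed", "agre",
             "plaster", "bled", "motor", "sing", "conflat",
             "troubl", "size", "hop", "tan", "fall", "hiss",
             "fizz", "fail", "file", "happi", "sky", "relat",
             "condit", "ration", "valenc", "digit",
             "radic", "differ", "vile", "analog",
             "predic", "oper", "feudal", "decis",
             "hope", "callous", "formal", "sensit",
             "sensibl", "triplic", "form", "formal",
             "electr", "electr", "hope", "good", "reviv",
             "allow", "infer", "airlin", "gyroscop",
             "adjust", "defens", "irrit", "replac",
             "adjust", "depend", "adopt", "commun", "activ",
             "angular", "homolog", "effect", "bowdler",
             "probat", "ceas", "control")
  expect_equal(porter_stem(words), stems)
  # words of length <= 2 pass through
  expect_equal(porter_stem(c("a", "ab")), c("a", "ab"))
})

test_that("build_dtm counts tokens with a lexicographic vocabulary", {
  docs <- list(d1 = c("a", "b", "a"), d2 = "b")
  dtm <- build_dtm(docs)
  expect_equal(colnames(dtm), c("a", "b"))
  expect_equal(as.matrix(dtm),
               matrix(c(2, 0, 1, 1), 2, 2,
                      dimnames = list(c("d1", "d2"), c("a", "b"))))

  # an empty document yields an all-zero row before pruning
  dtm2 <- build_dtm(list(d1 = c("x", "y"), d2 = character(0)))
  expect_equal(Matrix::rowSums(dtm2)[["d2"]], 0)

  # column sums match an independent token tally on a random fixture
  set.seed(42)
  rdocs <- lapply(1:5, function(i) {
    sample(letters[1:6], sample(3:12, 1), replace = TRUE)
  })
  names(rdocs) <- paste0("doc", 1:5)
  dtm3 <- build_dtm(rdocs)
  tally <- table(unlist(rdocs))
  expect_equal(Matrix::colSums(dtm3)[names(tally)], unclass(c(tally)),
               ignore_attr = TRUE)
  expect_equal(sum(dtm3), length(unlist(rdocs)))
})

test_that("prune_rare_tokens iterates to a fixpoint at the cutoff", {
  # frequency 5 is retained, frequency 4 dropped
  docs <- list(d1 = c(rep("keep", 5), rep("drop", 4), rep("fill", 6)),
               d2 = rep("fill", 5))
  pruned <- prune_rare_tokens(build_dtm(docs), min_freq = 5)
  expect_setequal(colnames(pruned), c("keep", "fill"))

  # already-valid input is returned unchanged, and pruning is idempotent
  expect_equal(prune_rare_tokens(pruned, 5), pruned)

  # cascade: dropping a rare token empties a doc, whose removal leaves the
  # other frequencies intact (converges in a second pass)
  docs2 <- list(d1 = rep("solo", 3),
                d2 = c(rep("common", 5)),
                d3 = c(rep("common", 5)))
  pruned2 <- prune_rare_tokens(build_dtm(docs2), min_freq = 5)
  expect_equal(rownames(pruned2), c("d2", "d3"))
  expect_equal(colnames(pruned2), "common")
  # retained token counts survive pruning untouched
  expect_equal(Matrix::colSums(pruned2)[["common"]], 10)

  expect_error(prune_rare_tokens(build_dtm(list(d = "once")), 5),
               "corpus emptied")
})

test_that("document tables round-trip through TSV and line-JSON", {
  docs <- data.frame(doc_id = c("d1", "d2"), set_id = c("S1", "S2"),
                     source = c("abstract", "description"),
                     text = c("alpha beta", "gamma"),
                     stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_documents(docs, tsv)
  expect_equal(read_documents(tsv), docs)

  jl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(nrow(docs)), function(i) {
    jsonlite::toJSON(as.list(docs[i, ]), auto_unbox = TRUE)
  }, character(1)), jl)
  expect_equal(read_documents(jl), docs)

  expect_error(read_documents("/nonexistent/docs.tsv"), "not found")
})
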