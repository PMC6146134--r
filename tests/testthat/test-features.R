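toy_tagged <- function() {
  corpus <- fixture_corpus(
    "SGK1 in myeloma",
    "SGK1 promotes myeloma survival. Cells were cultured. SGK1 was active."
  )
  tag_corpus(corpus, fixture_lexicon())
}

test_that("frequency features count the target kinase and axis mentions", {
  corpus <- toy_tagged()
  triples <- tibble::tibble(kinase_id = c("NX_O00141", "NX_P15056", "NX_O00141"),
                            axis = c("DIS", "DIS", "BP"), pmid = "1")
  f <- frequency_features(corpus, triples)
  expect_equal(f$f1_kinase_count[1], 3)  # SGK1 in title + 2 abstract mentions
  expect_equal(f$f2_axis_count[1], 2)    # myeloma in title + abstract
  expect_equal(f$f1_kinase_count[2], 0)  # BRAF never mentioned
  expect_equal(f$f2_axis_count[3], 0)    # BP triple ignores DIS mentions
})

test_that("location features track first/last sentence and co-occurrence", {
  corpus <- toy_tagged()
  f <- location_features(
    corpus, tibble::tibble(kinase_id = "NX_O00141", axis = "DIS", pmid = "1"))
  expect_true(f$f3_kinase_first_sent)  # title counts as the first sentence
  expect_true(f$f4_axis_first_sent)
  expect_true(f$f5_kinase_last_sent)   # "SGK1 was active."
  expect_false(f$f6_axis_last_sent)
  expect_true(f$f7_same_sentence)

  # single-sentence document: first = last, everything true
  single <- tag_corpus(fixture_corpus("SGK1 drives myeloma", ""),
                       fixture_lexicon())
  f1 <- location_features(
    single, tibble::tibble(kinase_id = "NX_O00141", axis = "DIS", pmid = "1"))
  expect_true(all(unlist(f1[, DENSE_FEATURES_TEST[3:7]])))

  # kinase only in a middle sentence
  mid <- tag_corpus(fixture_corpus(
    "A study of cancer", "First background. SGK1 acts here. Final remark."),
    fixture_lexicon())
  f2 <- location_features(
    mid, tibble::tibble(kinase_id = "NX_O00141", axis = "DIS", pmid = "1"))
  expect_false(f2$f3_kinase_first_sent)
  expect_false(f2$f5_kinase_last_sent)
})

test_that("keyword features are lemma-matched with per-group totals", {
  corpus <- tag_corpus(fixture_corpus(
    "Kinase keywords",
    "The drug inhibits growth. Expression was inhibited in patients."),
    fixture_lexicon())
  kw <- keyword_features(corpus, fixture_lexicon())
  get <- function(f) kw$value[kw$feature == f]
  expect_equal(get("kw:verb:inhibit"), 2)    # inhibits + inhibited
  expect_equal(get("kw:patient:patient"), 1) # "patients" lemma-matches
  expect_equal(get("kw:verb:total"), 2)

  # a mutation mention populates the variation group total
  mut <- tag_corpus(fixture_corpus("T", "The V600E mutation was seen."),
                    fixture_lexicon())
  kw2 <- keyword_features(mut, fixture_lexicon())
  expect_equal(kw2$value[kw2$feature == "kw:variation:total"], 1)

  # no keywords at all: no kw rows
  none <- tag_corpus(fixture_corpus("T", "Nothing relevant here."),
                     fixture_lexicon())
  kw3 <- keyword_features(none, fixture_lexicon())
  expect_equal(nrow(kw3), 0)
})

test_that("bag-of-words collects sentence-clipped context lemmas", {
  corpus <- toy_tagged()
  triples <- tibble::tibble(kinase_id = "NX_O00141", axis = "DIS", pmid = "1")
  bow <- bag_of_words(corpus, triples, window = 2)
  feats <- bow$feature
  expect_true("bow:promote" %in% feats)
  expect_true("bow:myeloma" %in% feats)
  # window 0 disables the feature family
  expect_equal(nrow(bag_of_words(corpus, triples, window = 0)), 0)
  # clipping: a mention at sentence start only sees right context
  start_corpus <- tag_corpus(
    fixture_corpus("Plain title", "SGK1 acts strongly. Unrelated tail."),
    fixture_lexicon())
  bow2 <- bag_of_words(start_corpus, triples, window = 5)
  expect_setequal(bow2$feature, c("bow:act", "bow:strongly"))
})

test_that("dependency paths encode relations, directions and the LCA lemma", {
  parse <- tibble::tibble(
    token_id = 1:3, form = c("SGK1", "inhibits", "apoptosis"),
    lemma = c("SGK1", "inhibit", "apoptosis"),
    head = c(2L, 0L, 2L), deprel = c("nsubj", "root", "dobj")
  )
  expect_equal(parse_path(parse, 1, 3), "nsubj↑inhibit↓dobj")
  expect_equal(parse_path_no_ancestors(parse, 1, 3), "nsubj↑↓dobj")
  # head and direct dependent: single-relation path, no lemmas anywhere
  expect_equal(parse_path(parse, 2, 3), "↓dobj")
  expect_equal(parse_path_no_ancestors(parse, 2, 3), "↓dobj")
  expect_equal(parse_path(parse, 1, 2), "nsubj↑")
  expect_true(is.na(parse_path(parse, 1, 1)))
})

test_that("path features require same-sentence pairs with a parse", {
  synth <- generate_corpus(small_profile(seed = 13))
  triples <- dplyr::bind_rows(
    synth$triples[synth$triples$label != "UNLABELED",
                  c("kinase_id", "axis", "pmid")],
    synth$dev_triples[, c("kinase_id", "axis", "pmid")]
  )
  paths <- path_features(synth$corpus, triples, synth$parses)
  expect_true(all(startsWith(paths$feature, "path:") |
                    startsWith(paths$feature, "pathna:")))
  # f7 = TRUE implies at least one path term when a parse is supplied
  loc <- location_features(synth$corpus, triples)
  with_f7 <- loc[loc$f7_same_sentence, c("kinase_id", "axis", "pmid")]
  have_path <- dplyr::semi_join(
    with_f7, paths[startsWith(paths$feature, "path:"), ],
    by = c("kinase_id", "axis", "pmid"))
  expect_equal(nrow(have_path), nrow(with_f7))
  # no parse supplied: the family is absent, not an error
  expect_equal(nrow(path_features(synth$corpus, triples, NULL)), 0)
})

test_that("CoNLL-U parses round trip", {
  synth <- generate_corpus(small_profile(seed = 13))
  path <- withr::local_tempfile(fileext = ".conllu")
  write_conllu(synth$parses, path)
  back <- read_conllu(path)
  orig <- dplyr::arrange(synth$parses, pmid, sentence_id, token_id)
  expect_equal(dplyr::arrange(back, pmid, sentence_id, token_id), orig)
})

test_that("document-term matrices reserve dense columns and project cleanly", {
  feats <- tibble::tibble(
    kinase_id = "K1", axis = "DIS", pmid = c("1", "1", "2", "2", "2"),
    feature = c("f7_same_sentence", "bow:shared", "f7_same_sentence",
                "bow:shared", "bow:only2"),
    value = c(1, 2, 0, 1, 3)
  )
  dtm <- build_matrix(feats)
  expect_equal(dim(dtm$matrix), c(2, 7 + 2))
  expect_equal(dtm$vocabulary[1:7], DENSE_FEATURES_TEST)
  expect_equal(dtm$matrix["K1:DIS:1", "bow:shared"], 2)

  # test mode drops unseen terms but keeps dense features
  test_feats <- tibble::tibble(
    kinase_id = "K1", axis = "DIS", pmid = "9",
    feature = c("f1_kinase_count", "bow:unseen", "bow:only2"),
    value = c(5, 4, 1)
  )
  proj <- build_matrix(test_feats, vocabulary = dtm$vocabulary)
  expect_equal(ncol(proj$matrix), ncol(dtm$matrix))
  expect_equal(proj$matrix[1, "f1_kinase_count"], 5)
  expect_equal(proj$matrix[1, "bow:only2"], 1)
  expect_false("bow:unseen" %in% proj$vocabulary)

  # projecting onto the same vocabulary again is idempotent
  reproj <- build_matrix(test_feats, vocabulary = proj$vocabulary)
  expect_identical(as.matrix(proj$matrix), as.matrix(reproj$matrix))

  expect_error(build_matrix(test_feats, vocabulary = character()),
               "empty vocabulary")
})

test_that("matrices serialize to MatrixMarket and back", {
  synth <- generate_corpus(small_profile(seed = 2))
  triples <- synth$triples[synth$triples$label == "POSITIVE",
                           c("kinase_id", "axis", "pmid")]
  feats <- extract_features(synth$corpus, triples, synth$lexicon,
                            parses = synth$parses)
  dtm <- build_matrix(feats)
  stem <- withr::local_tempfile()
  write_dtm(dtm, stem)
  back <- read_dtm(stem)
  expect_equal(back$vocabulary, dtm$vocabulary)
  expect_equal(as.matrix(back$matrix), as.matrix(dtm$matrix))
})

test_that("feature extraction is a pure function of its inputs", {
  synth <- generate_corpus(small_profile(seed = 4))
  triples <- dplyr::bind_rows(
    synth$triples[, c("kinase_id", "axis", "pmid")],
    synth$dev_triples[, c("kinase_id", "axis", "pmid")]
  ) |> dplyr::distinct()
  a <- extract_features(synth$corpus, triples, synth$lexicon,
                        parses = synth$parses)
  b <- extract_features(synth$corpus, triples, synth$lexicon,
                        parses = synth$parses)
  expect_identical(a, b)
})
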