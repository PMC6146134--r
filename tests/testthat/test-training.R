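make_dtm <- function(sep = separable_features()) {
  dtm <- build_matrix(sep$features)
  labels <- ifelse(grepl(":p", rownames(dtm$matrix), fixed = TRUE),
                   "POSITIVE", "NEGATIVE")
  list(dtm = dtm, labels = labels)
}

test_that("pseudo-negative selection picks the bottom-k one-class scores", {
  sep <- separable_features(n_pos = 20, n_neg = 0)
  pos <- build_matrix(sep$features)
  # pool: the positives duplicated (as unlabeled) plus 10 all-zero rows
  zero_rows <- purrr::map(1:10, function(i) {
    tibble::tibble(kinase_id = "K1", axis = "DIS",
                   pmid = sprintf("z%03d", i),
                   feature = "f1_kinase_count", value = 0)
  }) |> dplyr::bind_rows()
  dup <- sep$features
  dup$pmid <- paste0("u", dup$pmid)
  pool <- build_matrix(dplyr::bind_rows(dup, zero_rows),
                       vocabulary = pos$vocabulary)

  sel <- generate_pseudo_negatives(pos, pool, k = 10)
  expect_setequal(sel$pmid, sprintf("z%03d", 1:10))

  # oracle equivalence: selection = bottom-k of an independent score sort
  model <- triage_fit(pos, model = "svm1c")
  scores <- triage_score(model, pool)
  keys <- rownames(pool$matrix)
  oracle <- keys[order(scores, keys)][1:10]
  got <- rownames(pool$matrix)[sel$row]
  expect_identical(sort(got), sort(oracle))
  expect_lte(max(sel$score), min(scores[-sel$row]))

  expect_equal(nrow(generate_pseudo_negatives(pos, pool, k = 0)), 0)
  expect_error(generate_pseudo_negatives(pos, pool, k = 1e6), "exceeds pool")
  expect_error(generate_pseudo_negatives(pos, pos, k = 1), NA)
})

test_that("bottom-k property holds on random pools", {
  set.seed(99)
  sep <- separable_features(n_pos = 15, n_neg = 0)
  pos <- build_matrix(sep$features)
  rand_feats <- purrr::map(1:40, function(i) {
    tibble::tibble(
      kinase_id = "K1", axis = "DIS", pmid = sprintf("r%03d", i),
      feature = c(sample(DENSE_FEATURES_TEST, 3),
                  paste0("bow:word", sample(1:5, 2))),
      value = sample(0:3, 5, replace = TRUE)
    )
  }) |> dplyr::bind_rows()
  pool <- build_matrix(rand_feats, vocabulary = pos$vocabulary)
  for (k in c(1, 7, 40)) {
    sel <- generate_pseudo_negatives(pos, pool, k = k)
    model <- triage_fit(pos, model = "svm1c")
    scores <- triage_score(model, pool)
    keys <- rownames(pool$matrix)
    expect_identical(sort(rownames(pool$matrix)[sel$row]),
                     sort(keys[order(scores, keys)][seq_len(k)]))
  }
})

test_that("classifiers separate an f7-separable toy problem", {
  md <- make_dtm()
  for (kind in c("glmnet", "svm")) {
    model <- triage_fit(md$dtm, md$labels, model = kind, seed = 5)
    scores <- triage_score(model, md$dtm)
    pos <- scores[md$labels == "POSITIVE"]
    neg <- scores[md$labels == "NEGATIVE"]
    expect_gt(min(pos), max(neg))  # training accuracy 1.0
  }
})

test_that("a featureless candidate scores at the elastic-net intercept", {
  md <- make_dtm()
  model <- triage_fit(md$dtm, md$labels, model = "glmnet", seed = 5)
  zero <- build_matrix(
    tibble::tibble(kinase_id = "K1", axis = "DIS", pmid = "zz",
                   feature = "f1_kinase_count", value = 0),
    vocabulary = md$dtm$vocabulary)
  intercept <- as.numeric(stats::coef(model$fit, s = "lambda.min")[1])
  expect_equal(triage_score(model, zero), intercept)
})

test_that("binary trainers reject single-class input naming the gap", {
  md <- make_dtm()
  expect_error(triage_fit(md$dtm, rep("POSITIVE", length(md$labels)),
                          model = "glmnet"), "missing NEGATIVE")
  expect_error(triage_fit(md$dtm, rep("NEGATIVE", length(md$labels)),
                          model = "svm"), "missing POSITIVE")
  expect_error(triage_fit(md$dtm, NULL, model = "glmnet"), "labels required")
  # the one-class model needs no labels at all
  expect_s3_class(triage_fit(md$dtm, NULL, model = "svm1c"), "triage_model")
})

test_that("scoring is deterministic, permutation-equivariant and guarded", {
  md <- make_dtm()
  m1 <- triage_fit(md$dtm, md$labels, model = "glmnet", seed = 7)
  m2 <- triage_fit(md$dtm, md$labels, model = "glmnet", seed = 7)
  expect_identical(triage_score(m1, md$dtm), triage_score(m2, md$dtm))

  # duplicated rows receive identical scores; permuting rows permutes scores
  perm <- sample(nrow(md$dtm$matrix))
  permuted <- md$dtm
  permuted$matrix <- permuted$matrix[perm, ]
  permuted$triples <- permuted$triples[perm, ]
  expect_equal(triage_score(m1, permuted), triage_score(m1, md$dtm)[perm])

  other <- build_matrix(separable_features()$features[1:8, ])
  expect_error(triage_score(m1, other), "vocabulary")
})

test_that("persisted models reload and score identically", {
  md <- make_dtm()
  for (kind in c("glmnet", "svm", "svm1c")) {
    model <- triage_fit(md$dtm, md$labels, model = kind, seed = 2)
    path <- withr::local_tempfile(fileext = ".rds")
    save_model(model, path)
    back <- load_model(path)
    expect_identical(triage_score(back, md$dtm), triage_score(model, md$dtm))
  }
})

test_that("ranking groups by query, sorts by score and breaks ties by pmid", {
  triples <- tibble::tibble(
    kinase_id = c("K1", "K1", "K1", "K2", "K2"),
    axis = c("DIS", "DIS", "DIS", "BP", "BP"),
    pmid = c("a", "b", "c", "2", "1")
  )
  run <- rank_triples(triples, c(0.1, 0.9, 0.5, 0.3, 0.3))
  k1 <- run[run$kinase_id == "K1", ]
  expect_equal(k1$pmid, c("b", "c", "a"))
  expect_equal(k1$rank, 1:3)
  k2 <- run[run$kinase_id == "K2", ]
  expect_equal(k2$pmid, c("1", "2"))  # tie: ascending pmid
  expect_error(rank_triples(triples, c(1, 2)), "one non-missing score")
})

test_that("tidy and glance expose linear model structure", {
  md <- make_dtm()
  model <- triage_fit(md$dtm, md$labels, model = "glmnet", seed = 1)
  td <- tidy(model)
  expect_true("f7_same_sentence" %in% td$term)
  expect_gt(td$estimate[td$term == "f7_same_sentence"], 0)
  g <- glance(model)
  expect_equal(g$kind, "glmnet")
  expect_gt(g$n_active, 0)

  svm_model <- triage_fit(md$dtm, md$labels, model = "svm", seed = 1)
  expect_gt(tidy(svm_model)$estimate[tidy(svm_model)$term == "f7_same_sentence"], 0)
})

test_that("the pipeline recovers planted signal above the chance baseline", {
  synth <- generate_corpus(small_profile(seed = 7))
  ex <- triage_experiment(synth, model = "glmnet", seed = 3)
  chance <- expected_random_map(ex$run, synth$qrels)
  expect_gt(ex$eval$aggregate$map, 3 * chance)
  # the report carries the expected-rank score of the dev triples
  expect_equal(ex$eval$aggregate$escore, escore(ex$dev_ranks))
})
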