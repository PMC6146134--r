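#' Run the full triage pipeline on a corpus
#'
#' End-to-end experiment mirroring the kinome triage workflow: extract
#' features for the positive, unlabeled-pool and development triples;
#' bootstrap `n_pseudo_negatives` pseudo-negatives from the pool with a
#' one-class SVM ([generate_pseudo_negatives()]); train the requested
#' classifier on positives plus pseudo-negatives; score and rank the held-out
#' candidates (development triples plus the pool) per query; and evaluate the
#' ranking against the development judgments, including the expected-rank
#' score.
#'
#' @param synth A `kt_synth` from [generate_corpus()], or a list with the
#'   same elements (`corpus`, `lexicon`, `triples`, `dev_triples`, `qrels`,
#'   `parses`).
#' @param model Classifier passed to [triage_fit()].
#' @param n_pseudo_negatives Number of pseudo-negatives to bootstrap;
#'   defaults to the number of NEGATIVE triples in `synth$triples`, falling
#'   back to the positive count.
#' @param bow_window Bag-of-words window (see [bag_of_words()]).
#' @param seed Seed forwarded to [triage_fit()].
#' @param use_parses Use the gold parses for path features?
#' @return List of class `kt_experiment`: `model`, `run` (ranked tibble),
#'   `eval` (`kt_eval`), `pseudo_negatives`, `dev_ranks`.
#' @export
triage_experiment <- function(synth, model = c("glmnet", "svm", "svm1c"),
                              n_pseudo_negatives = NULL, bow_window = 3L,
                              seed = 1L, use_parses = TRUE) {
  model <- match.arg(model)
  corpus <- synth$corpus
  parses <- if (use_parses) synth$parses else NULL
  positives <- synth$triples[synth$triples$label == "POSITIVE", ]
  pool <- synth$triples[synth$triples$label == "UNLABELED", ]
  dev <- synth$dev_triples
  if (is.null(n_pseudo_negatives)) {
    n_neg <- sum(synth$triples$label == "NEGATIVE")
    n_pseudo_negatives <- if (n_neg > 0) n_neg else nrow(positives)
  }
  n_pseudo_negatives <- min(n_pseudo_negatives, nrow(pool))

  all_triples <- dplyr::bind_rows(positives, pool, dev) |>
    dplyr::distinct(.data$kinase_id, .data$axis, .data$pmid)
  feats <- extract_features(corpus, all_triples, synth$lexicon,
                            parses = parses, bow_window = bow_window)
  take <- function(triples) {
    dplyr::semi_join(feats, triples, by = c("kinase_id", "axis", "pmid"))
  }

  pos_dtm <- build_matrix(take(positives))
  pool_dtm_boot <- build_matrix(take(pool), vocabulary = pos_dtm$vocabulary)
  pseudo <- generate_pseudo_negatives(pos_dtm, pool_dtm_boot,
                                      k = n_pseudo_negatives)

  train_triples <- dplyr::bind_rows(
    positives |> dplyr::mutate(label = "POSITIVE"),
    pseudo[, c("kinase_id", "axis", "pmid")] |>
      dplyr::mutate(label = "NEGATIVE")
  )
  train_dtm <- build_matrix(take(train_triples))
  labels <- train_triples$label[
    match(rownames(train_dtm$matrix),
          triple_key(train_triples$kinase_id, train_triples$axis,
                     train_triples$pmid))]
  fitted <- triage_fit(train_dtm, labels, model = model, seed = seed)

  test_triples <- dplyr::bind_rows(dev[, c("kinase_id", "axis", "pmid")],
                                   pool[, c("kinase_id", "axis", "pmid")]) |>
    dplyr::distinct()
  test_dtm <- build_matrix(take(test_triples),
                           vocabulary = train_dtm$vocabulary)
  scores <- triage_score(fitted, test_dtm)
  run <- rank_triples(test_dtm$triples, scores)
  dev_ranks <- dev_triple_ranks(run, dev)
  eval <- evaluate_run(run, synth$qrels, dev_ranks = dev_ranks)

  structure(list(model = fitted, run = run, eval = eval,
                 pseudo_negatives = pseudo, dev_ranks = dev_ranks),
            class = "kt_experiment")
}

#' @export
print.kt_experiment <- function(x, ...) {
  cat("<kt_experiment> ", x$model$kind, "\n", sep = "")
  print(x$eval$aggregate)
  invisible(x)
}

#' Chance baseline for a run's mean average precision
#'
#' The MAP a uniformly random ranking of the same per-query pools would be
#' expected to achieve: the mean over evaluable queries of
#' [expected_random_ap()] at that query's pool size and relevant count.
#'
#' @inheritParams mean_average_precision
#' @return A single number.
#' @export
expected_random_map <- function(run, qrels) {
  rels <- qrels |>
    dplyr::filter(.data$relevance > 0) |>
    dplyr::distinct(.data$kinase_id, .data$axis, .data$pmid)
  sizes <- as_tibble(run) |>
    dplyr::count(.data$kinase_id, .data$axis, name = "pool_size")
  per <- rels |>
    dplyr::count(.data$kinase_id, .data$axis, name = "n_relevant") |>
    dplyr::inner_join(sizes, by = c("kinase_id", "axis"))
  if (!nrow(per)) stop("no evaluable queries", call. = FALSE)
  mean(purrr::map2_dbl(per$pool_size, per$n_relevant, expected_random_ap))
}
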