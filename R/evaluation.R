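#' Ranked-retrieval metrics
#'
#' The metric battery used to evaluate a per-query ranking against a set of
#' relevant pmids: precision and recall at fixed ranks, average precision,
#' R-precision, and the maximum precision observed at any rank. All operate
#' on a ranked character vector of pmids (best first) and a character vector
#' of relevant pmids. Lists shorter than `k` count the missing tail as
#' non-relevant; relevant documents that were never retrieved contribute zero
#' to average precision.
#'
#' @param ranked Character vector of pmids in rank order (rank 1 first).
#' @param relevant Character vector of relevant pmids (non-empty where noted).
#' @param k Rank cutoff (>= 1).
#' @return A single number in `[0, 1]`.
#' @name retrieval-metrics
NULL

#' @rdname retrieval-metrics
#' @export
precision_at_k <- function(ranked, relevant, k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  sum(head(ranked, k) %in% relevant) / k
}

#' @rdname retrieval-metrics
#' @export
recall_at_k <- function(ranked, relevant, k) {
  check_relevant(relevant)
  sum(head(ranked, k) %in% relevant) / length(relevant)
}

#' @rdname retrieval-metrics
#' @export
average_precision <- function(ranked, relevant) {
  check_relevant(relevant)
  rel <- ranked %in% relevant
  if (!any(rel)) return(0)
  hits <- which(rel)
  sum(cumsum(rel)[hits] / hits) / length(relevant)
}

#' @rdname retrieval-metrics
#' @export
r_precision <- function(ranked, relevant) {
  check_relevant(relevant)
  precision_at_k(ranked, relevant, length(relevant))
}

#' @rdname retrieval-metrics
#' @export
p_at_r0 <- function(ranked, relevant) {
  check_relevant(relevant)
  if (!length(ranked)) return(0)
  rel <- ranked %in% relevant
  max(cumsum(rel) / seq_along(rel))
}

check_relevant <- function(relevant) {
  if (!length(relevant)) stop("empty relevant set", call. = FALSE)
  invisible(relevant)
}

#' Mean average precision over a run
#'
#' The arithmetic mean of per-query average precisions over the evaluable
#' queries. Queries present in the judgments but with an empty relevant set
#' are skipped with a warning (standard qrels practice); judged-relevant
#' documents absent from the run contribute zero.
#'
#' @param run Tibble with columns `kinase_id`, `axis`, `pmid`, `score` (a
#'   `rank` column, as produced by [rank_triples()], is accepted and re-used).
#' @param qrels Tibble with columns `kinase_id`, `axis`, `pmid`, `relevance`.
#' @return A single number.
#' @export
mean_average_precision <- function(run, qrels) {
  per <- per_query_metrics(run, qrels, k_precision = integer(),
                           k_recall = integer())
  if (!nrow(per)) stop("no evaluable queries", call. = FALSE)
  mean(per$ap)
}

#' Evaluate a run against relevance judgments
#'
#' Computes the full per-query metric battery (AP, P@10/30/100, R@30/100,
#' R-precision, maximum observed precision) and its aggregates, optionally
#' together with the expected-rank score of a development-triple set
#' ([escore()]).
#'
#' @inheritParams mean_average_precision
#' @param dev_ranks Optional tibble for [escore()] (columns `rank_in_pool`,
#'   `pool_size`).
#' @param k_precision,k_recall Rank cutoffs for P@K and R@K.
#' @return An object of class `kt_eval` with elements `per_query` (tibble)
#'   and `aggregate` (one-row tibble); see also [tidy.kt_eval()] and
#'   [glance.kt_eval()].
#' @export
evaluate_run <- function(run, qrels, dev_ranks = NULL,
                         k_precision = c(10, 30, 100), k_recall = c(30, 100)) {
  per <- per_query_metrics(run, qrels, k_precision, k_recall)
  if (!nrow(per)) stop("no evaluable queries", call. = FALSE)
  agg <- per |>
    dplyr::summarise(dplyr::across(-c("kinase_id", "axis", "n_relevant"),
                                   mean)) |>
    dplyr::rename(map = "ap") |>
    dplyr::mutate(n_queries = nrow(per), .before = 1)
  if (!is.null(dev_ranks)) {
    agg$escore <- escore(dev_ranks)
    # per-triple mean, reported alongside for readability (not part of the
    # original battery, which reports the raw sum)
    agg$escore_mean <- agg$escore / nrow(dev_ranks)
  }
  structure(list(per_query = per, aggregate = agg), class = "kt_eval")
}

per_query_metrics <- function(run, qrels, k_precision, k_recall) {
  run <- as_tibble(run)
  qrels <- as_tibble(qrels)
  rels <- qrels |>
    dplyr::filter(.data$relevance > 0) |>
    dplyr::distinct(.data$kinase_id, .data$axis, .data$pmid)
  queries <- qrels |> dplyr::distinct(.data$kinase_id, .data$axis)
  empty <- dplyr::anti_join(queries, rels, by = c("kinase_id", "axis"))
  if (nrow(empty)) {
    warning(nrow(empty), " quer(ies) with no relevant documents skipped",
            call. = FALSE)
  }
  queries <- dplyr::semi_join(queries, rels, by = c("kinase_id", "axis"))
  ordered <- rank_entries(run)
  purrr::pmap(queries, function(kinase_id, axis) {
    ranked <- ordered$pmid[ordered$kinase_id == kinase_id &
                             ordered$axis == axis]
    relevant <- rels$pmid[rels$kinase_id == kinase_id & rels$axis == axis]
    row <- tibble(kinase_id = kinase_id, axis = axis,
                  n_relevant = length(relevant),
                  ap = average_precision(ranked, relevant))
    for (k in k_precision) {
      row[[paste0("p", k)]] <- precision_at_k(ranked, relevant, k)
    }
    for (k in k_recall) {
      row[[paste0("r", k)]] <- recall_at_k(ranked, relevant, k)
    }
    row$r_prec <- r_precision(ranked, relevant)
    row$p_at_r0 <- p_at_r0(ranked, relevant)
    row
  }) |> dplyr::bind_rows()
}

#' Expected-rank score of a development-triple set
#'
#' For each development triple, its pmid sits at some rank within the
#' combined candidate pool ranked for its query; the score is the sum over
#' triples of `rank_in_pool / pool_size`. A triple ranked first in a pool of
#' 10 contributes 0.1; lower totals mean better rankings.
#'
#' @param dev_ranks Tibble with columns `rank_in_pool` (1-based) and
#'   `pool_size`.
#' @return The raw sum (not a mean) over triples.
#' @export
escore <- function(dev_ranks) {
  dev_ranks <- as_tibble(dev_ranks)
  stopifnot(all(c("rank_in_pool", "pool_size") %in% names(dev_ranks)))
  bad <- dev_ranks$rank_in_pool < 1 |
    dev_ranks$rank_in_pool > dev_ranks$pool_size
  if (any(bad)) {
    stop("rank_in_pool must lie in [1, pool_size]", call. = FALSE)
  }
  sum(dev_ranks$rank_in_pool / dev_ranks$pool_size)
}

#' Locate development triples within a ranked run
#'
#' Computes, for each development triple, the rank of its pmid within its
#' query's ranked pool and the pool size — the inputs of [escore()]. Triples
#' whose query or pmid is absent from the run are dropped with a warning.
#'
#' @param run Tibble (`kinase_id`, `axis`, `pmid`, `score`).
#' @param dev_triples Tibble of development triples (`kinase_id`, `axis`,
#'   `pmid`).
#' @return Tibble (`kinase_id`, `axis`, `pmid`, `rank_in_pool`, `pool_size`).
#' @export
dev_triple_ranks <- function(run, dev_triples) {
  ordered <- rank_entries(run) |>
    dplyr::group_by(.data$kinase_id, .data$axis) |>
    dplyr::mutate(pool_size = dplyr::n()) |>
    dplyr::ungroup()
  out <- dplyr::inner_join(
    as_tibble(dev_triples)[, c("kinase_id", "axis", "pmid")],
    ordered[, c("kinase_id", "axis", "pmid", "rank", "pool_size")],
    by = c("kinase_id", "axis", "pmid")
  ) |> dplyr::rename(rank_in_pool = "rank")
  missing <- nrow(dev_triples) - nrow(out)
  if (missing > 0) {
    warning(missing, " development triple(s) absent from the run", call. = FALSE)
  }
  out
}

#' Exact expected average precision of a random ranking
#'
#' Under a uniformly random permutation of `n` documents of which `r` are
#' relevant, the expected average precision has the closed form
#' \deqn{E[AP] = \frac{1}{r} \sum_{p=1}^{n} \frac{r}{n} \cdot
#'   \frac{1 + (p-1)(r-1)/(n-1)}{p},}
#' obtained from the hypergeometric law of the number of other relevant
#' documents above rank `p`. Used as the chance baseline when judging whether
#' a ranking carries signal.
#'
#' @param n Pool size.
#' @param r Number of relevant documents (`1 <= r <= n`).
#' @return The expected AP.
#' @export
expected_random_ap <- function(n, r) {
  stopifnot(r >= 1, n >= r)
  if (n == 1) return(1)
  p <- seq_len(n)
  sum((r / n) * (1 + (p - 1) * (r - 1) / (n - 1)) / p) / r
}

#' @export
print.kt_eval <- function(x, ...) {
  cat("<kt_eval> ", nrow(x$per_query), " queries\n", sep = "")
  print(x$aggregate)
  invisible(x)
}

#' Tidiers for evaluation reports
#'
#' `tidy()` returns the per-query metric table; `glance()` the one-row
#' aggregate (MAP, mean P@K/R@K, and the expected-rank score when supplied).
#'
#' @param x A `kt_eval` from [evaluate_run()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy kt_eval
#' @export
tidy.kt_eval <- function(x, ...) x$per_query

#' @rdname tidy.kt_eval
#' @method glance kt_eval
#' @export
glance.kt_eval <- function(x, ...) x$aggregate

#' Write an evaluation report
#'
#' Emits the per-query table as TSV and the aggregate as JSON.
#'
#' @param x A `kt_eval`.
#' @param stem Output path stem; writes `<stem>.per_query.tsv` and
#'   `<stem>.aggregate.json`.
#' @return `stem`, invisibly.
#' @export
write_eval_report <- function(x, stem) {
  stopifnot(inherits(x, "kt_eval"))
  readr::write_tsv(x$per_query, paste0(stem, ".per_query.tsv"), progress = FALSE)
  jsonlite::write_json(as.list(x$aggregate), paste0(stem, ".aggregate.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
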