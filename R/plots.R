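#' Plot an evaluation report
#'
#' Per-query average precision as bars, split by axis, with the run's mean
#' average precision drawn as a dashed line.
#'
#' @param object A `kt_eval` from [evaluate_run()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kt_eval
#' @export
autoplot.kt_eval <- function(object, ...) {
  per <- object$per_query
  per$query <- query_id(per$kinase_id, per$axis)
  ggplot2::ggplot(per, ggplot2::aes(x = stats::reorder(.data$query, .data$ap),
                                    y = .data$ap, fill = .data$axis)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$aggregate$map, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Average precision",
                  title = "Per-query average precision",
                  subtitle = sprintf("MAP = %.3f over %d queries",
                                     object$aggregate$map,
                                     object$aggregate$n_queries)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted triage model
#'
#' The strongest feature weights of a linear model (elastic-net coefficients
#' or the primal weights of a linear-kernel SVM), signed toward the
#' curatable class.
#'
#' @param object A `triage_model`.
#' @param n_terms Number of terms to show (by absolute weight).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triage_model
#' @export
autoplot.triage_model <- function(object, n_terms = 25, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  if (!nrow(td)) stop("model has no linear weights to plot", call. = FALSE)
  td <- td[order(-abs(td$estimate)), ][seq_len(min(n_terms, nrow(td))), ]
  ggplot2::ggplot(td, ggplot2::aes(x = stats::reorder(.data$term, .data$estimate),
                                   y = .data$estimate,
                                   fill = .data$estimate > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Weight",
                  title = paste("Top feature weights:", object$kind)) +
    ggplot2::theme_minimal()
}

#' Plot the score distribution of a ranked run
#'
#' Histogram of per-triple scores, optionally coloured by relevance when
#' judgments are supplied — a quick view of how well the classifier
#' separates curatable from background candidates.
#'
#' @param run Tibble (`kinase_id`, `axis`, `pmid`, `score`).
#' @param qrels Optional judgments tibble.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(run, qrels = NULL, bins = 50) {
  run <- as_tibble(run)
  if (!is.null(qrels)) {
    rels <- qrels |>
      dplyr::filter(.data$relevance > 0) |>
      dplyr::distinct(.data$kinase_id, .data$axis, .data$pmid) |>
      dplyr::mutate(relevant = TRUE)
    run <- dplyr::left_join(run, rels, by = c("kinase_id", "axis", "pmid")) |>
      tidyr::replace_na(list(relevant = FALSE))
    p <- ggplot2::ggplot(run, ggplot2::aes(x = .data$score,
                                           fill = .data$relevant))
  } else {
    p <- ggplot2::ggplot(run, ggplot2::aes(x = .data$score))
  }
  p + ggplot2::geom_histogram(bins = bins, alpha = 0.8,
                              position = "identity") +
    ggplot2::labs(x = "Triage score", y = "Candidate triples") +
    ggplot2::theme_minimal()
}
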