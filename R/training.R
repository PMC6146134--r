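#' Bootstrap pseudo-negatives with a one-class classifier
#'
#' The candidate pool carries no negative labels, so negatives are
#' manufactured: a one-class SVM is fitted on the positive triples' feature
#' matrix, every pool row is scored, and the `k` rows with the lowest decision
#' scores — the candidates least similar to the positives — are selected as
#' pseudo-negative training instances. Ties at the selection boundary are
#' broken by ascending row key, so the result is deterministic.
#'
#' @param positives A `kt_dtm` of positive triples.
#' @param pool A `kt_dtm` of unlabeled candidates, built on the positives'
#'   vocabulary.
#' @param k Number of pseudo-negatives to select.
#' @param nu,kernel One-class SVM hyperparameters (see [triage_fit()]).
#' @return Tibble of the selected pool rows: `row` (index into the pool),
#'   `kinase_id`, `axis`, `pmid`, `score`, ordered by ascending score.
#' @export
generate_pseudo_negatives <- function(positives, pool, k, nu = 0.1,
                                      kernel = "linear") {
  stopifnot(inherits(positives, "kt_dtm"), inherits(pool, "kt_dtm"))
  if (!identical(pool$vocabulary, positives$vocabulary)) {
    stop("pool matrix must be built on the positives' vocabulary", call. = FALSE)
  }
  if (k > nrow(pool$matrix)) {
    stop("k (", k, ") exceeds pool size (", nrow(pool$matrix), ")", call. = FALSE)
  }
  sel <- pool$triples[0, ]
  sel$row <- integer()
  sel$score <- numeric()
  if (k == 0) return(sel[, c("row", "kinase_id", "axis", "pmid", "score")])
  model <- triage_fit(positives, model = "svm1c", nu = nu, kernel = kernel)
  scores <- triage_score(model, pool)
  key <- rownames(pool$matrix)
  ord <- order(scores, key)
  take <- ord[seq_len(k)]
  tibble(row = take,
         kinase_id = pool$triples$kinase_id[take],
         axis = pool$triples$axis[take],
         pmid = pool$triples$pmid[take],
         score = scores[take])
}

#' Fit a triage ranking model
#'
#' Three classifier families are supported on the sparse document-term
#' matrix:
#' \describe{
#'   \item{`glmnet`}{Elastic-net-regularized logistic regression
#'     ([glmnet::cv.glmnet()]): mixing parameter `alpha` (default 0.5),
#'     penalty chosen by cross-validated deviance along the automatic
#'     log-spaced path. Requires both classes.}
#'   \item{`svm`}{Binary linear-kernel SVM ([e1071::svm()], `cost` 1).
#'     Requires both classes.}
#'   \item{`svm1c`}{One-class SVM for novelty detection (`nu` 0.1, linear
#'     kernel by default); ignores labels and models the positives alone.}
#' }
#' Both axes are trained together in one model; the fitted object stores the
#' training vocabulary and refuses to score matrices built on any other.
#' Fitting is deterministic given `seed` (which fixes the cross-validation
#' fold assignment of `glmnet`).
#'
#' @param dtm Training `kt_dtm`.
#' @param labels Character vector (`POSITIVE`/`NEGATIVE`) per row; ignored by
#'   `svm1c`.
#' @param model One of `"glmnet"`, `"svm"`, `"svm1c"`.
#' @param alpha Elastic-net mixing parameter.
#' @param nfolds Cross-validation folds for the penalty path.
#' @param cost Binary SVM cost.
#' @param nu One-class SVM nu.
#' @param kernel SVM kernel (`"linear"` or `"radial"`).
#' @param seed Integer seed for stochastic components.
#' @return A fitted `triage_model`.
#' @export
triage_fit <- function(dtm, labels = NULL,
                       model = c("glmnet", "svm", "svm1c"),
                       alpha = 0.5, nfolds = 5, cost = 1, nu = 0.1,
                       kernel = "linear", seed = 1L) {
  stopifnot(inherits(dtm, "kt_dtm"))
  model <- match.arg(model)
  x <- dtm$matrix
  if (model %in% c("glmnet", "svm")) {
    if (is.null(labels)) stop("labels required for a binary classifier", call. = FALSE)
    labels <- as.character(labels)
    stopifnot(length(labels) == nrow(x))
    for (cls in c("POSITIVE", "NEGATIVE")) {
      if (!any(labels == cls)) {
        stop("binary training requires both classes; missing ", cls, call. = FALSE)
      }
    }
    y <- factor(labels, levels = c("NEGATIVE", "POSITIVE"))
  }
  fit <- switch(model,
    glmnet = {
      foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(x))))
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                        foldid = foldid, standardize = TRUE)
    },
    svm = e1071::svm(as.matrix(x), y, type = "C-classification",
                     kernel = kernel, cost = cost, scale = FALSE),
    svm1c = e1071::svm(as.matrix(x), y = NULL, type = "one-classification",
                       kernel = kernel, nu = nu, scale = FALSE)
  )
  structure(
    list(kind = model, fit = fit, vocabulary = dtm$vocabulary,
         hyperparameters = list(alpha = alpha, nfolds = nfolds, cost = cost,
                                nu = nu, kernel = kernel, seed = seed)),
    class = "triage_model"
  )
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.triage_model <- function(x, ...) {
  cat("<triage_model> ", x$kind, ", ", length(x$vocabulary),
      " features\n", sep = "")
  invisible(x)
}

#' Score candidate triples with a fitted model
#'
#' Higher scores mean "more likely curatable". The elastic-net model emits
#' the positive-class log-odds at the deviance-minimizing penalty (the
#' probability scale, `plogis(score)`, saturates at 1 in double precision
#' for confidently scored candidates and would collapse their ranking into
#' arbitrary ties); the SVMs emit the signed decision value (oriented so
#' that the positive / inlier side is positive).
#'
#' @param model A `triage_model`.
#' @param dtm A `kt_dtm` built on the model's vocabulary.
#' @return Numeric vector of scores, one per matrix row.
#' @export
triage_score <- function(model, dtm) {
  stopifnot(inherits(model, "triage_model"), inherits(dtm, "kt_dtm"))
  if (!identical(dtm$vocabulary, model$vocabulary)) {
    stop("matrix vocabulary does not match the model's training vocabulary",
         call. = FALSE)
  }
  x <- dtm$matrix
  switch(model$kind,
    glmnet = as.numeric(predict(model$fit, newx = x, s = "lambda.min",
                                type = "link")),
    svm = svm_decision(model$fit, as.matrix(x), positive = "POSITIVE"),
    svm1c = svm_decision(model$fit, as.matrix(x))
  )
}

# Signed decision values from e1071, oriented so the requested class (or the
# one-class inlier side) gets positive values.
svm_decision <- function(fit, x, positive = NULL) {
  pred <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  vals <- dv[, 1]
  if (!is.null(positive)) {
    lab <- colnames(dv)[1]
    parts <- strsplit(lab, "/", fixed = TRUE)[[1]]
    if (parts[1] != positive) vals <- -vals
  }
  unname(vals)
}

#' Rank scored candidate triples per query
#'
#' Groups triples by query `(kinase_id, axis)` and orders each group by
#' descending score, breaking ties by ascending pmid so the output is a
#' strict, deterministic total order.
#'
#' @param triples Tibble of triples (`kinase_id`, `axis`, `pmid`).
#' @param scores Numeric vector, one score per triple row.
#' @return Tibble (`kinase_id`, `axis`, `pmid`, `score`, `rank`) sorted by
#'   query and rank; ready for [write_run()] and [evaluate_run()].
#' @export
rank_triples <- function(triples, scores) {
  triples <- as_tibble(triples)
  if (length(scores) != nrow(triples) || anyNA(scores)) {
    stop("need one non-missing score per triple", call. = FALSE)
  }
  triples$score <- as.numeric(scores)
  rank_entries(triples[, c("kinase_id", "axis", "pmid", "score")])
}

#' Persist and reload a fitted model
#'
#' The archive bundles the fitted parameters, the training vocabulary, the
#' hyperparameters and a format version; a reloaded model produces identical
#' scores.
#'
#' @param model A `triage_model`.
#' @param path File path (`.rds`).
#' @return `path` invisibly / the reloaded `triage_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "triage_model"))
  saveRDS(list(format = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, 1L)) stop("unknown model archive format", call. = FALSE)
  obj$model
}

#' @method tidy triage_model
#' @export
tidy.triage_model <- function(x, ...) {
  if (x$kind == "glmnet") {
    co <- as.matrix(stats::coef(x$fit, s = "lambda.min"))
    out <- tibble(term = rownames(co), estimate = co[, 1])
    return(out[out$estimate != 0, ])
  }
  if (x$kind %in% c("svm", "svm1c") &&
      x$hyperparameters$kernel == "linear") {
    w <- crossprod(x$fit$SV, x$fit$coefs)[, 1]
    if (x$kind == "svm" &&
        x$fit$levels[x$fit$labels[1]] != "POSITIVE") {
      w <- -w
    }
    out <- tibble(term = colnames(x$fit$SV), estimate = w)
    return(out[out$estimate != 0, ])
  }
  tibble(term = character(), estimate = numeric())
}

#' @method glance triage_model
#' @export
glance.triage_model <- function(x, ...) {
  tibble(
    kind = x$kind,
    n_features = length(x$vocabulary),
    n_active = nrow(tidy(x)),
    alpha = x$hyperparameters$alpha,
    cost = x$hyperparameters$cost,
    nu = x$hyperparameters$nu,
    kernel = x$hyperparameters$kernel
  )
}
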