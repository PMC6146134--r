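#' Synthetic triage corpus configuration
#'
#' Defines the study conditions for a generated corpus: counts of positive,
#' development, negative and unlabeled-pool triples, the number of target
#' kinases, and the planted-signal parameters. Positive documents carry a
#' same-sentence kinase-axis co-occurrence with probability
#' `p_same_sentence_pos` and curation keywords with probability
#' `p_keyword_pos`; negative and pool documents use the corresponding `_neg`
#' rates. Every document mentions its kinase in the title and carries one
#' term of each axis, so the co-occurrence structure (not bare term presence)
#' is what separates the classes.
#'
#' @param n_positive,n_negative,n_dev,n_pool Triple counts per role.
#' @param n_kinases Number of distinct target kinases.
#' @param p_same_sentence_pos,p_same_sentence_neg Probability that the focal
#'   axis term shares a sentence with the kinase.
#' @param p_keyword_pos,p_keyword_neg Probability of keyword enrichment.
#' @param axis_mix Proportion of DIS (vs BP) focal axes.
#' @param sentences_per_abstract Integer range (length 2) of abstract
#'   sentences per document.
#' @param mutation_rate Fraction of positive/development documents carrying a
#'   planted mutation mention.
#' @param seed Integer seed; identical config and seed give a byte-identical
#'   corpus.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_positive = 255L, n_negative = 250L, n_dev = 22L,
                         n_pool = 2000L, n_kinases = 20L,
                         p_same_sentence_pos = 0.9, p_same_sentence_neg = 0.1,
                         p_keyword_pos = 0.8, p_keyword_neg = 0.2,
                         axis_mix = 0.5, sentences_per_abstract = c(3L, 6L),
                         mutation_rate = 0.3, seed = 42L) {
  cfg <- list(
    n_positive = as.integer(n_positive), n_negative = as.integer(n_negative),
    n_dev = as.integer(n_dev), n_pool = as.integer(n_pool),
    n_kinases = as.integer(n_kinases),
    p_same_sentence_pos = p_same_sentence_pos,
    p_same_sentence_neg = p_same_sentence_neg,
    p_keyword_pos = p_keyword_pos, p_keyword_neg = p_keyword_neg,
    axis_mix = axis_mix,
    sentences_per_abstract = as.integer(sentences_per_abstract),
    mutation_rate = mutation_rate, seed = as.integer(seed)
  )
  probs <- c("p_same_sentence_pos", "p_same_sentence_neg", "p_keyword_pos",
             "p_keyword_neg", "axis_mix", "mutation_rate")
  bad <- character()
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) bad <- c(bad, paste0(p, " not in [0, 1]"))
  }
  for (p in c("n_positive", "n_negative", "n_dev", "n_pool")) {
    if (cfg[[p]] < 0) bad <- c(bad, paste0(p, " < 0"))
  }
  if (cfg$n_kinases < 1) bad <- c(bad, "n_kinases < 1")
  if (length(cfg$sentences_per_abstract) != 2 ||
      cfg$sentences_per_abstract[1] < 1 ||
      diff(cfg$sentences_per_abstract) < 0) {
    bad <- c(bad, "sentences_per_abstract must be an increasing range >= 1")
  }
  if (length(bad)) {
    stop("invalid synthetic configuration: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Default synthetic profile
#'
#' The package's reference study conditions: 255 positive, 250 negative and
#' 22 development triples over a 2000-triple unlabeled pool (a one-tenth
#' scale of the kinome triage corpus shape: 2550 training positives, 2500
#' bootstrapped negatives, 225 development triples over a large candidate
#' pool), with strong planted co-occurrence signal (0.9 vs 0.1) and keyword
#' enrichment (0.8 vs 0.2) and a fixed seed.
#'
#' @return A `synth_config`.
#' @export
default_profile <- function() synth_config()

SYN_DIS_TERMS <- c("myeloma", "carcinoma", "lymphoma", "leukemia", "glioma",
                   "melanoma", "fibrosis", "neuropathy")
SYN_BP_TERMS <- c("apoptosis", "autophagy", "angiogenesis", "proliferation",
                  "migration", "differentiation", "glycolysis", "senescence")
SYN_NEUTRAL_VERBS <- c(modulates = "modulate", alters = "alter",
                       influences = "influence")
SYN_FILLER <- c("protein", "pathway", "expression", "analysis", "sample",
                "level", "tissue", "response", "cohort", "mechanism",
                "profile", "assay")
SYN_CONTEXT <- c("cells", "tissues", "tumors", "models")

#' Generate a synthetic annotated corpus with planted signal
#'
#' Builds PubTator-style documents from slot-filled sentence templates:
#' kinase names `KIN1..KINn`, one disease and one biological-process term per
#' document, curation keywords, mutation strings and filler tokens. The
#' document for a positive (or development) triple places its focal axis term
#' in the same sentence as the kinase with probability `p_same_sentence_pos`
#' ("KIN3 inhibits myeloma in cells .") and otherwise in a sentence of its
#' own; negatives and pool documents use `p_same_sentence_neg` for every
#' axis. Gold dependency parses are emitted for every kinase-axis relation
#' sentence (they are template-derived, so path features are exercisable
#' without a real parser), and gold mention annotations for every planted
#' entity. All outputs round-trip through the package's readers and writers.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory; when given, writes
#'   `corpus.pubtator`, `lexicon_kinase.tsv`, `lexicon_dis.tsv`,
#'   `lexicon_bp.tsv`, `triples.tsv`, `dev.tsv`, `qrels.tsv` and
#'   `parses.conllu`.
#' @return A list of class `kt_synth`: `corpus` ([kt_corpus()] with gold
#'   mentions and sentence spans), `lexicon`, `triples` (POSITIVE, NEGATIVE
#'   and UNLABELED rows), `dev_triples`, `qrels` (judgments for the
#'   development triples), `parses`, `config`.
#' @export
generate_corpus <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  out <- with_seed(config$seed, generate_corpus_impl(config))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_pubtator(out$corpus, file.path(dir, "corpus.pubtator"))
    e <- out$lexicon$entries
    for (ct in c("KINASE", "DIS", "BP")) {
      sub <- kt_lexicon(e[e$concept_type == ct, ], out$lexicon$keyword_groups)
      write_lexicon(sub, file.path(dir, paste0("lexicon_", tolower(ct), ".tsv")))
    }
    write_triples(out$triples, file.path(dir, "triples.tsv"))
    write_triples(out$dev_triples, file.path(dir, "dev.tsv"))
    write_qrels(out$qrels, file.path(dir, "qrels.tsv"))
    write_conllu(out$parses, file.path(dir, "parses.conllu"))
  }
  out
}

generate_corpus_impl <- function(config) {
  kin_names <- paste0("KIN", seq_len(config$n_kinases))
  kin_ids <- sprintf("SYNK%03d", seq_len(config$n_kinases))
  lexicon <- kt_lexicon(dplyr::bind_rows(
    tibble(surface = kin_names, concept_id = kin_ids, concept_type = "KINASE"),
    tibble(surface = SYN_DIS_TERMS,
           concept_id = sprintf("SYND%02d", seq_along(SYN_DIS_TERMS)),
           concept_type = "DIS"),
    tibble(surface = SYN_BP_TERMS,
           concept_id = sprintf("SYNB%02d", seq_along(SYN_BP_TERMS)),
           concept_type = "BP")
  ))

  roles <- c(rep("POSITIVE", config$n_positive), rep("DEV", config$n_dev),
             rep("NEGATIVE", config$n_negative), rep("POOL", config$n_pool))
  n_docs <- length(roles)
  docs <- vector("list", n_docs)
  for (i in seq_len(n_docs)) {
    role <- roles[i]
    positive_like <- role %in% c("POSITIVE", "DEV")
    docs[[i]] <- synth_document(
      pmid = as.character(1000000L + i),
      kinase = sample(config$n_kinases, 1),
      focal_axis = if (stats::runif(1) < config$axis_mix) "DIS" else "BP",
      p_same_focal = if (positive_like) config$p_same_sentence_pos
                     else config$p_same_sentence_neg,
      p_same_other = config$p_same_sentence_neg,
      p_keyword = if (positive_like) config$p_keyword_pos
                  else config$p_keyword_neg,
      plant_mutation = positive_like &&
        stats::runif(1) < config$mutation_rate,
      sent_range = config$sentences_per_abstract,
      kin_names = kin_names, kin_ids = kin_ids, lexicon = lexicon
    )
  }

  corpus <- kt_corpus(
    dplyr::bind_rows(purrr::map(docs, "document")),
    dplyr::bind_rows(purrr::map(docs, "mentions"))
  )
  corpus <- split_sentences(corpus)
  parses <- dplyr::bind_rows(purrr::map(docs, "parses"))

  info <- tibble(
    pmid = purrr::map_chr(docs, ~ .x$document$pmid),
    kinase_id = purrr::map_chr(docs, ~ .x$kinase_id),
    axis = purrr::map_chr(docs, ~ .x$focal_axis),
    role = roles
  )
  labeled <- info[info$role != "POOL", ]
  triples <- dplyr::bind_rows(
    labeled |>
      dplyr::filter(.data$role != "DEV") |>
      dplyr::transmute(.data$kinase_id, .data$axis, .data$pmid,
                       label = .data$role),
    build_candidate_triples(corpus, kin_ids) |>
      dplyr::semi_join(info[info$role == "POOL", ], by = "pmid")
  )
  dev_triples <- labeled |>
    dplyr::filter(.data$role == "DEV") |>
    dplyr::transmute(.data$kinase_id, .data$axis, .data$pmid,
                     label = "POSITIVE")
  qrels <- dev_triples |>
    dplyr::transmute(.data$kinase_id, .data$axis, .data$pmid, relevance = 1L)

  structure(list(corpus = corpus, lexicon = lexicon, triples = triples,
                 dev_triples = dev_triples, qrels = qrels, parses = parses,
                 config = config),
            class = "kt_synth")
}

#' @export
print.kt_synth <- function(x, ...) {
  cat("<kt_synth> ", nrow(x$corpus$documents), " documents; triples: ",
      paste(names(table(x$triples$label)), table(x$triples$label),
            sep = "=", collapse = ", "),
      "; ", nrow(x$dev_triples), " dev\n", sep = "")
  invisible(x)
}

# One synthetic document: title mentioning the kinase, one term per axis
# (same-sentence with the kinase or in its own sentence), optional keyword /
# mutation sentences, filler to the target length, shuffled abstract order.
synth_document <- function(pmid, kinase, focal_axis, p_same_focal,
                           p_same_other, p_keyword, plant_mutation,
                           sent_range, kin_names, kin_ids, lexicon) {
  kin <- kin_names[kinase]
  kin_id <- kin_ids[kinase]
  other_axis <- setdiff(AXES, focal_axis)
  pick_term <- function(axis) {
    terms <- if (axis == "DIS") SYN_DIS_TERMS else SYN_BP_TERMS
    t <- sample(terms, 1)
    list(term = t,
         id = lexicon$entries$concept_id[lexicon$entries$surface == t])
  }

  title <- list(
    tokens = c("Characterization", "of", kin, "signaling", "in",
               sample(SYN_CONTEXT, 1)),
    ann = tibble(tok = 3L, type = "KINASE", id = kin_id),
    parse = NULL
  )

  sents <- list()
  for (spec in list(list(axis = focal_axis, p = p_same_focal),
                    list(axis = other_axis, p = p_same_other))) {
    tm <- pick_term(spec$axis)
    if (stats::runif(1) < spec$p) {
      sents <- c(sents, list(relation_sentence(kin, kin_id, tm$term, tm$id,
                                               spec$axis, p_keyword)))
    } else {
      sents <- c(sents, list(axis_sentence(tm$term, tm$id, spec$axis)))
    }
  }
  if (stats::runif(1) < p_keyword) {
    sents <- c(sents, list(keyword_sentence(lexicon)))
  }
  if (plant_mutation) sents <- c(sents, list(mutation_sentence()))

  target_n <- sample(seq(sent_range[1], sent_range[2]), 1)
  while (length(sents) < target_n) {
    sents <- c(sents, list(filler_sentence()))
  }
  sents <- sents[sample(length(sents))]
  res <- assemble_document(pmid, title, sents)
  c(res, list(kinase_id = kin_id, focal_axis = focal_axis))
}

relation_sentence <- function(kin, kin_id, term, term_id, axis, p_keyword) {
  verbs <- if (stats::runif(1) < p_keyword) {
    kw <- default_keyword_groups()$verb
    setNames(kw, paste0(kw, "s"))
  } else SYN_NEUTRAL_VERBS
  vi <- sample(length(verbs), 1)
  vform <- names(verbs)[vi]
  vlemma <- unname(verbs[vi])
  ctx <- sample(SYN_CONTEXT, 1)
  tokens <- c(kin, vform, term, "in", ctx, ".")
  parse <- tibble(
    token_id = 1:6,
    form = tokens,
    lemma = c(kin, vlemma, term, "in", ctx, "."),
    head = c(2L, 0L, 2L, 5L, 2L, 2L),
    deprel = c("nsubj", "root", "dobj", "case", "obl", "punct")
  )
  list(tokens = tokens,
       ann = tibble(tok = c(1L, 3L), type = c("KINASE", axis),
                    id = c(kin_id, term_id)),
       parse = parse)
}

axis_sentence <- function(term, term_id, axis) {
  cap <- paste0(toupper(substr(term, 1, 1)), substr(term, 2, nchar(term)))
  list(tokens = c(cap, "was", "observed", "in",
                  sample(c("several", "many", "most"), 1), "samples", "."),
       ann = tibble(tok = 1L, type = axis, id = term_id),
       parse = NULL)
}

keyword_sentence <- function(lexicon) {
  pool <- unlist(lexicon$keyword_groups[
    c("verb", "patient", "genetic", "scale", "period", "examine")],
    use.names = FALSE)
  kw <- sample(pool, 3)
  list(tokens = c("Researchers", "reported", kw[1], "and", kw[2], "with",
                  kw[3], "."),
       ann = NULL, parse = NULL)
}

mutation_sentence <- function() {
  aa <- strsplit(AA1, "")[[1]]
  mut <- paste0(sample(aa, 1), sample(100:999, 1), sample(aa, 1))
  list(tokens = c("The", mut, "variant", "was", "carried", "."),
       ann = tibble(tok = 2L, type = "MUTATION", id = ""),
       parse = NULL)
}

filler_sentence <- function() {
  w <- sample(SYN_FILLER, 3)
  list(tokens = c("The", w[1], "of", w[2], w[3], "was", "measured", "."),
       ann = NULL, parse = NULL)
}

# Join title and abstract sentences into full text, turning token-level
# annotations into offset-anchored mentions and per-sentence parses into
# corpus sentence numbering (title = sentence 1).
assemble_document <- function(pmid, title, sents) {
  all_sents <- c(list(title), sents)
  mentions <- list()
  parses <- list()
  offset <- 0L
  texts <- character(length(all_sents))
  for (s in seq_along(all_sents)) {
    tokens <- all_sents[[s]]$tokens
    starts <- offset + cumsum(c(0L, nchar(tokens[-length(tokens)]) + 1L))
    texts[s] <- paste(tokens, collapse = " ")
    ann <- all_sents[[s]]$ann
    if (!is.null(ann) && nrow(ann)) {
      mentions[[length(mentions) + 1L]] <- tibble(
        pmid = pmid, start = starts[ann$tok],
        end = starts[ann$tok] + nchar(tokens[ann$tok]),
        surface = tokens[ann$tok], concept_type = ann$type,
        concept_id = ann$id
      )
    }
    p <- all_sents[[s]]$parse
    if (!is.null(p)) {
      p$pmid <- pmid
      p$sentence_id <- s
      parses[[length(parses) + 1L]] <- p
    }
    offset <- offset + nchar(texts[s]) + 1L  # joining single space
  }
  list(
    document = tibble(pmid = pmid, title = texts[1],
                      abstract = paste(texts[-1], collapse = " ")),
    mentions = if (length(mentions)) dplyr::bind_rows(mentions) else empty_mentions(),
    parses = if (length(parses)) {
      dplyr::bind_rows(parses)[, c("pmid", "sentence_id", "token_id", "form",
                                   "lemma", "head", "deprel")]
    } else NULL
  )
}
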