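#' @title Tokenization and the fallback lemmatizer
#' @description Tokenizes document full texts into word tokens with 0-based
#' half-open offsets and assigns each token to its sentence. The lemmatizer is
#' a deterministic lowercase-plus-suffix-stripping fallback used when no
#' external parser supplies lemmas.
#' @param corpus A [kt_corpus()] with sentence spans (see [split_sentences()]).
#' @return Tibble with columns `pmid`, `tid` (token index within document),
#'   `start`, `end`, `token`, `lemma`, `sentence_id`.
#' @export
tokenize_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "kt_corpus"))
  if (is.null(corpus$sentences)) corpus <- split_sentences(corpus)
  pat <- "[A-Za-z0-9]+(?:['.-][A-Za-z0-9]+)*"
  locs <- stringr::str_locate_all(corpus$documents$text, pat)
  toks <- purrr::map2(corpus$documents$pmid, seq_along(locs), function(pmid, i) {
    loc <- locs[[i]]
    if (!nrow(loc)) return(NULL)
    token <- stringr::str_sub(corpus$documents$text[[i]], loc[, 1], loc[, 2])
    tibble(pmid = pmid, tid = seq_len(nrow(loc)),
           start = loc[, 1] - 1L, end = loc[, 2], token = token)
  })
  toks <- dplyr::bind_rows(toks)
  toks$lemma <- lemma_fallback(toks$token)
  assign_sentences(toks, corpus$sentences)
}

# Assign each (pmid, start) row the sentence span containing its start offset.
assign_sentences <- function(x, sentences) {
  parts <- split(seq_len(nrow(x)), x$pmid)
  sid <- integer(nrow(x))
  for (pm in names(parts)) {
    idx <- parts[[pm]]
    sp <- sentences[sentences$pmid == pm, ]
    pos <- findInterval(x$start[idx], sp$start)
    pos[pos == 0L] <- 1L
    sid[idx] <- sp$sentence_id[pos]
  }
  x$sentence_id <- sid
  x
}

#' @rdname tokenize_corpus
#' @param token Character vector of tokens.
#' @export
lemma_fallback <- function(token) {
  x <- tolower(token)
  x <- stringr::str_remove(x, "'s$")
  n <- nchar(x)
  # plural / 3rd-person -s
  ies <- stringr::str_ends(x, "ies") & n > 4
  x[ies] <- stringr::str_replace(x[ies], "ies$", "y")
  es <- !ies & stringr::str_ends(x, "(ss|sh|ch|x|z)es")
  x[es] <- stringr::str_remove(x[es], "es$")
  n <- nchar(x)
  s <- stringr::str_ends(x, "s") & !stringr::str_ends(x, "(ss|us|is)") & n > 3
  x[s] <- stringr::str_remove(x[s], "s$")
  # past tense: drop the "d" after a stem-final "e", else the full "ed"
  n <- nchar(x)
  ied <- stringr::str_ends(x, "ied") & n > 4
  x[ied] <- stringr::str_replace(x[ied], "ied$", "y")
  ed <- !ied & stringr::str_ends(x, "ed") & n > 4
  dro <- ed & stringr::str_detect(x, "[aeiou][bcdfgklmnprstvz]ed$")
  x[dro] <- stringr::str_remove(x[dro], "ed$")
  x[ed & !dro] <- stringr::str_remove(x[ed & !dro], "d$")
  # progressive -ing
  n <- nchar(x)
  ing <- stringr::str_ends(x, "ing") & n > 5
  x[ing] <- stringr::str_remove(x[ing], "ing$")
  x
}

# Inflectional variants of a token used for lemma-level keyword matching:
# a keyword matches a token when the keyword equals any variant.
lemma_variants <- function(token) {
  x <- tolower(token)
  out <- list(x,
              stringr::str_remove(x, "s$"),
              stringr::str_remove(x, "es$"),
              stringr::str_replace(x, "ies$", "y"),
              stringr::str_remove(x, "ed$"),
              stringr::str_remove(x, "d$"),
              stringr::str_remove(x, "ing$"),
              stringr::str_replace(x, "ing$", "e"))
  out
}

STOPWORDS <- c(
  "a", "an", "the", "of", "in", "on", "at", "by", "for", "to", "with",
  "and", "or", "but", "is", "are", "was", "were", "be", "been", "being",
  "that", "this", "these", "those", "as", "from", "we", "our", "it", "its",
  "their", "has", "have", "had", "not", "no", "which", "who", "than", "then",
  "also", "both", "into", "such", "between", "among", "after", "before"
)

#' Frequency features (f1, f2)
#'
#' Counts, for each candidate triple, the mentions of the target kinase
#' (`f1_kinase_count`: mentions whose `concept_id` equals the triple's
#' `kinase_id`) and the mentions of the triple's axis type
#' (`f2_axis_count`: DIS or BP mentions) in the document.
#'
#' @param corpus A tagged [kt_corpus()].
#' @param triples Tibble of triples (`kinase_id`, `axis`, `pmid`).
#' @return `triples` with `f1_kinase_count` and `f2_axis_count` columns.
#' @export
frequency_features <- function(corpus, triples) {
  triples <- as_tibble(triples)[, c("kinase_id", "axis", "pmid")]
  kin <- corpus$mentions |>
    dplyr::filter(.data$concept_type == "KINASE") |>
    dplyr::count(.data$pmid, kinase_id = .data$concept_id, name = "f1_kinase_count")
  ax <- corpus$mentions |>
    dplyr::filter(.data$concept_type %in% AXES) |>
    dplyr::count(.data$pmid, axis = .data$concept_type, name = "f2_axis_count")
  triples |>
    dplyr::left_join(kin, by = c("pmid", "kinase_id")) |>
    dplyr::left_join(ax, by = c("pmid", "axis")) |>
    tidyr::replace_na(list(f1_kinase_count = 0L, f2_axis_count = 0L))
}

#' Location features (f3-f7)
#'
#' Boolean co-location features per triple: target kinase / target axis in the
#' first sentence (`f3`, `f4`), in the last sentence (`f5`, `f6`), and both in
#' one sentence (`f7_same_sentence`).
#'
#' @inheritParams frequency_features
#' @return `triples` with logical columns `f3_kinase_first_sent` ..
#'   `f7_same_sentence`.
#' @export
location_features <- function(corpus, triples) {
  if (is.null(corpus$sentences)) corpus <- split_sentences(corpus)
  triples <- as_tibble(triples)[, c("kinase_id", "axis", "pmid")]
  sent <- corpus$sentences |>
    dplyr::group_by(.data$pmid) |>
    dplyr::summarise(last_sent = max(.data$sentence_id), .groups = "drop")
  men <- assign_sentences(corpus$mentions, corpus$sentences) |>
    dplyr::left_join(sent, by = "pmid")
  kin <- men |>
    dplyr::filter(.data$concept_type == "KINASE") |>
    dplyr::group_by(.data$pmid, kinase_id = .data$concept_id) |>
    dplyr::summarise(f3_kinase_first_sent = any(.data$sentence_id == 1L),
                     f5_kinase_last_sent = any(.data$sentence_id == .data$last_sent),
                     .groups = "drop")
  ax <- men |>
    dplyr::filter(.data$concept_type %in% AXES) |>
    dplyr::group_by(.data$pmid, axis = .data$concept_type) |>
    dplyr::summarise(f4_axis_first_sent = any(.data$sentence_id == 1L),
                     f6_axis_last_sent = any(.data$sentence_id == .data$last_sent),
                     .groups = "drop")
  same <- dplyr::inner_join(
    men |> dplyr::filter(.data$concept_type == "KINASE") |>
      dplyr::distinct(.data$pmid, kinase_id = .data$concept_id, .data$sentence_id),
    men |> dplyr::filter(.data$concept_type %in% AXES) |>
      dplyr::distinct(.data$pmid, axis = .data$concept_type, .data$sentence_id),
    by = c("pmid", "sentence_id"), relationship = "many-to-many"
  ) |>
    dplyr::distinct(.data$pmid, .data$kinase_id, .data$axis) |>
    dplyr::mutate(f7_same_sentence = TRUE)
  triples |>
    dplyr::left_join(kin, by = c("pmid", "kinase_id")) |>
    dplyr::left_join(ax, by = c("pmid", "axis")) |>
    dplyr::left_join(same, by = c("pmid", "kinase_id", "axis")) |>
    tidyr::replace_na(list(f3_kinase_first_sent = FALSE, f4_axis_first_sent = FALSE,
                           f5_kinase_last_sent = FALSE, f6_axis_last_sent = FALSE,
                           f7_same_sentence = FALSE))
}

#' Keyword-group features (kw: namespace)
#'
#' Document-level counts of the curation keyword groups: one
#' `kw:<group>:<keyword>` term per keyword observed (lemma-matched, so
#' "inhibits" and "inhibited" both count toward "inhibit") plus a
#' `kw:<group>:total` term per group. The `variation` group total is the
#' number of MUTATION mentions in the document.
#'
#' @param corpus A tagged [kt_corpus()].
#' @param lexicon A [kt_lexicon()] supplying the keyword groups.
#' @param tokens Optional pre-computed [tokenize_corpus()] output.
#' @return Long tibble (`pmid`, `feature`, `value`) with only non-zero counts.
#' @export
keyword_features <- function(corpus, lexicon, tokens = NULL) {
  if (is.null(tokens)) tokens <- tokenize_corpus(corpus)
  groups <- lexicon$keyword_groups
  kw <- tibble(
    group = rep(names(groups), lengths(groups)),
    keyword = unlist(groups, use.names = FALSE)
  )
  hits <- NULL
  if (nrow(kw)) {
    variants <- lemma_variants(tokens$token)
    matched <- purrr::map(variants, function(v) match(v, kw$keyword))
    best <- Reduce(function(a, b) ifelse(is.na(a), b, a), matched)
    hits <- tokens[!is.na(best), c("pmid"), drop = FALSE]
    hits$group <- kw$group[best[!is.na(best)]]
    hits$keyword <- kw$keyword[best[!is.na(best)]]
  }
  parts <- list()
  if (!is.null(hits) && nrow(hits)) {
    per_kw <- hits |>
      dplyr::count(.data$pmid, .data$group, .data$keyword, name = "value") |>
      dplyr::mutate(feature = paste0("kw:", .data$group, ":", .data$keyword))
    per_grp <- hits |>
      dplyr::count(.data$pmid, .data$group, name = "value") |>
      dplyr::mutate(feature = paste0("kw:", .data$group, ":total"))
    parts <- list(per_kw[, c("pmid", "feature", "value")],
                  per_grp[, c("pmid", "feature", "value")])
  }
  muts <- corpus$mentions |>
    dplyr::filter(.data$concept_type == "MUTATION") |>
    dplyr::count(.data$pmid, name = "value") |>
    dplyr::mutate(feature = "kw:variation:total")
  parts <- c(parts, list(muts[, c("pmid", "feature", "value")]))
  out <- dplyr::bind_rows(parts)
  if (!nrow(out)) {
    return(tibble(pmid = character(), feature = character(), value = integer()))
  }
  dplyr::arrange(out, .data$pmid, .data$feature)
}

#' Bag-of-words context features (bow: namespace)
#'
#' For each mention relevant to a triple (mentions of the target kinase and
#' mentions of the triple's axis type), collects the lemmas of up to `window`
#' tokens on each side, clipped at sentence boundaries; the mention's own
#' tokens, stop-words and punctuation are excluded and counts accumulate over
#' mentions.
#'
#' @inheritParams frequency_features
#' @param window Number of context tokens on each side (default 3).
#' @param tokens Optional pre-computed [tokenize_corpus()] output.
#' @return Long tibble (`kinase_id`, `axis`, `pmid`, `feature`, `value`).
#' @export
bag_of_words <- function(corpus, triples, window = 3L, tokens = NULL) {
  stopifnot(window >= 0)
  empty <- tibble(kinase_id = character(), axis = character(),
                  pmid = character(), feature = character(), value = integer())
  if (window == 0L) return(empty)
  if (is.null(corpus$sentences)) corpus <- split_sentences(corpus)
  if (is.null(tokens)) tokens <- tokenize_corpus(corpus)
  triples <- as_tibble(triples)[, c("kinase_id", "axis", "pmid")]

  men <- assign_sentences(corpus$mentions, corpus$sentences)
  men <- men[men$concept_type %in% c("KINASE", AXES), ]
  men <- men[men$pmid %in% triples$pmid, ]
  if (!nrow(men)) return(empty)
  men$mention_id <- seq_len(nrow(men))

  # token span of each mention, then the window tokens around it
  span <- dplyr::inner_join(
    men[, c("mention_id", "pmid", "sentence_id", "start", "end")],
    tokens, by = c("pmid", "sentence_id"), suffix = c("", ".tok"),
    relationship = "many-to-many"
  )
  own <- span |>
    dplyr::filter(.data$end.tok > .data$start, .data$start.tok < .data$end) |>
    dplyr::group_by(.data$mention_id) |>
    dplyr::summarise(first_tid = min(.data$tid), last_tid = max(.data$tid),
                     .groups = "drop")
  ctx <- span |>
    dplyr::inner_join(own, by = "mention_id") |>
    dplyr::filter(.data$tid >= .data$first_tid - .env$window,
                  .data$tid <= .data$last_tid + .env$window,
                  .data$tid < .data$first_tid | .data$tid > .data$last_tid,
                  !(.data$lemma %in% STOPWORDS)) |>
    dplyr::select("mention_id", "lemma")

  ctx <- dplyr::left_join(
    ctx,
    men[, c("mention_id", "pmid", "concept_type", "concept_id")],
    by = "mention_id"
  )
  kin_part <- ctx |>
    dplyr::filter(.data$concept_type == "KINASE") |>
    dplyr::inner_join(triples, by = c("pmid", "concept_id" = "kinase_id"),
                      relationship = "many-to-many") |>
    dplyr::rename(kinase_id = "concept_id")
  ax_part <- ctx |>
    dplyr::filter(.data$concept_type %in% AXES) |>
    dplyr::inner_join(triples, by = c("pmid", "concept_type" = "axis"),
                      relationship = "many-to-many") |>
    dplyr::rename(axis = "concept_type")
  out <- dplyr::bind_rows(
    kin_part[, c("kinase_id", "axis", "pmid", "lemma")],
    ax_part[, c("kinase_id", "axis", "pmid", "lemma")]
  )
  if (!nrow(out)) return(empty)
  out |>
    dplyr::count(.data$kinase_id, .data$axis, .data$pmid, .data$lemma,
                 name = "value") |>
    dplyr::mutate(feature = paste0("bow:", .data$lemma), lemma = NULL) |>
    dplyr::arrange(.data$kinase_id, .data$axis, .data$pmid, .data$feature)
}

#' Dependency parse-path features
#'
#' `parse_path()` encodes the dependency-tree path between two tokens of one
#' parsed sentence as alternating relation labels (with direction markers:
#' `↑` toward the root, `↓` away from it) and intermediate-token
#' lemmas, e.g. `nsubj↑inhibit↓dobj` for a kinase subject and axis
#' object of the same verb. The endpoint surface forms are not included.
#' `parse_path_no_ancestors()` performs the same traversal but keeps only the
#' relation-label sequence, dropping the lemmas of the lowest common ancestor
#' and every other intermediate token (e.g. `nsubj↑↓dobj`).
#'
#' @param parse Tibble for one sentence with columns `token_id`, `form`,
#'   `lemma`, `head` (0 for the root), `deprel`.
#' @param from,to Token ids of the two endpoints (kinase and axis heads).
#' @return A single path string, or `NA_character_` when the endpoints
#'   coincide.
#' @export
parse_path <- function(parse, from, to) {
  encode_path(parse, from, to, with_lemmas = TRUE)
}

#' @rdname parse_path
#' @export
parse_path_no_ancestors <- function(parse, from, to) {
  encode_path(parse, from, to, with_lemmas = FALSE)
}

encode_path <- function(parse, from, to, with_lemmas) {
  stopifnot(all(c("token_id", "lemma", "head", "deprel") %in% names(parse)))
  if (from == to) return(NA_character_)
  head <- setNames(parse$head, parse$token_id)
  lemma <- setNames(parse$lemma, parse$token_id)
  deprel <- setNames(parse$deprel, parse$token_id)
  chain <- function(i) {
    out <- i
    while (head[[as.character(i)]] != 0L) {
      i <- head[[as.character(i)]]
      out <- c(out, i)
    }
    out
  }
  up <- chain(from)
  down <- chain(to)
  lca <- intersect(up, down)[1]
  if (is.na(lca)) stop("tokens are not connected in the parse", call. = FALSE)
  asc <- up[seq_len(which(up == lca))]        # from .. lca
  desc <- rev(down[seq_len(which(down == lca))])  # lca .. to
  nodes <- c(asc, desc[-1])
  n_up <- length(asc) - 1L
  pieces <- character()
  for (i in seq_len(length(nodes) - 1L)) {
    ascending <- i <= n_up
    pieces <- c(pieces, if (ascending) {
      paste0(deprel[[as.character(nodes[i])]], "↑")
    } else {
      paste0("↓", deprel[[as.character(nodes[i + 1L])]])
    })
    if (i < length(nodes) - 1L && with_lemmas) {
      pieces <- c(pieces, lemma[[as.character(nodes[i + 1L])]])
    }
  }
  paste(pieces, collapse = "")
}

#' Parse-path features for a corpus (path:/pathna: namespaces)
#'
#' For every sentence that contains both a mention of the triple's kinase and
#' a mention of its axis type and for which a dependency parse is available,
#' computes the path between the closest such pair (by character distance)
#' and emits one `path:` and one `pathna:` term. Sentences without a parse,
#' and mention pairs in different sentences, contribute nothing.
#'
#' @inheritParams frequency_features
#' @param parses Parse tibble as returned by [read_conllu()].
#' @return Long tibble (`kinase_id`, `axis`, `pmid`, `feature`, `value`).
#' @export
path_features <- function(corpus, triples, parses) {
  empty <- tibble(kinase_id = character(), axis = character(),
                  pmid = character(), feature = character(), value = integer())
  if (is.null(parses) || !nrow(parses)) return(empty)
  if (is.null(corpus$sentences)) corpus <- split_sentences(corpus)
  triples <- as_tibble(triples)[, c("kinase_id", "axis", "pmid")]
  men <- assign_sentences(corpus$mentions, corpus$sentences)

  pairs <- dplyr::inner_join(
    men |> dplyr::filter(.data$concept_type == "KINASE") |>
      dplyr::select("pmid", "sentence_id", kinase_id = "concept_id",
                    k_start = "start", k_end = "end"),
    men |> dplyr::filter(.data$concept_type %in% AXES) |>
      dplyr::select("pmid", "sentence_id", axis = "concept_type",
                    a_start = "start", a_end = "end"),
    by = c("pmid", "sentence_id"), relationship = "many-to-many"
  ) |>
    dplyr::semi_join(triples, by = c("pmid", "kinase_id", "axis")) |>
    dplyr::mutate(dist = abs(.data$k_start - .data$a_start)) |>
    dplyr::group_by(.data$pmid, .data$sentence_id, .data$kinase_id, .data$axis) |>
    dplyr::slice_min(.data$dist, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (!nrow(pairs)) return(empty)

  parse_keys <- paste(parses$pmid, parses$sentence_id)
  sent_start <- corpus$sentences
  out <- purrr::pmap(pairs, function(pmid, sentence_id, kinase_id, k_start,
                                     k_end, axis, a_start, a_end, dist) {
    psent <- parses[parse_keys == paste(pmid, sentence_id), ]
    if (!nrow(psent)) return(NULL)
    sp <- sent_start[sent_start$pmid == pmid &
                       sent_start$sentence_id == sentence_id, ]
    doc_text <- corpus$documents$text[corpus$documents$pmid == pmid]
    sent_text <- substr(doc_text, sp$start + 1L, sp$end)
    offs <- align_parse_offsets(psent$form, sent_text)
    if (anyNA(offs)) return(NULL)
    tok_start <- sp$start + offs
    tok_end <- tok_start + nchar(psent$form)
    head_of <- function(ms, me) {
      hit <- which(tok_end > ms & tok_start < me)
      if (!length(hit)) return(NA_integer_)
      psent$token_id[max(hit)]
    }
    kh <- head_of(k_start, k_end)
    ah <- head_of(a_start, a_end)
    if (is.na(kh) || is.na(ah) || kh == ah) return(NULL)
    p <- parse_path(psent, kh, ah)
    pna <- parse_path_no_ancestors(psent, kh, ah)
    if (is.na(p)) return(NULL)
    tibble(kinase_id = kinase_id, axis = axis, pmid = pmid,
           feature = c(paste0("path:", p), paste0("pathna:", pna)),
           value = 1L)
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) return(empty)
  out |>
    dplyr::count(.data$kinase_id, .data$axis, .data$pmid, .data$feature,
                 wt = .data$value, name = "value") |>
    dplyr::arrange(.data$kinase_id, .data$axis, .data$pmid, .data$feature)
}

# Locate each parse token in the sentence text, in order; 0-based offsets
# relative to the sentence start. NA when a token cannot be aligned.
align_parse_offsets <- function(forms, sent_text) {
  pos <- 1L
  out <- integer(length(forms))
  for (i in seq_along(forms)) {
    hit <- regexpr(forms[i], substr(sent_text, pos, nchar(sent_text)),
                   fixed = TRUE)
    if (hit == -1L) return(rep(NA_integer_, length(forms)))
    out[i] <- pos + hit - 2L  # 0-based
    pos <- pos + hit - 1L + attr(hit, "match.length")
  }
  out
}

#' Extract the full feature set for a set of candidate triples
#'
#' Computes the dense frequency (f1-f2) and location (f3-f7) features and the
#' sparse keyword (`kw:`), bag-of-words (`bow:`) and parse-path
#' (`path:`/`pathna:`) term counts for every triple, as one long tibble ready
#' for [build_matrix()]. Extraction is a pure function of its inputs:
#' repeated calls give identical output.
#'
#' @inheritParams frequency_features
#' @param lexicon A [kt_lexicon()].
#' @param parses Optional parse tibble ([read_conllu()]); without it the
#'   path features are simply absent.
#' @param bow_window Bag-of-words context window (tokens each side).
#' @return Long tibble (`kinase_id`, `axis`, `pmid`, `feature`, `value`).
#' @export
extract_features <- function(corpus, triples, lexicon, parses = NULL,
                             bow_window = 3L) {
  if (is.null(corpus$sentences)) corpus <- split_sentences(corpus)
  triples <- as_tibble(triples)[, c("kinase_id", "axis", "pmid")]
  tokens <- tokenize_corpus(corpus)

  dense <- frequency_features(corpus, triples) |>
    dplyr::left_join(location_features(corpus, triples),
                     by = c("kinase_id", "axis", "pmid")) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.logical), as.integer)) |>
    tidyr::pivot_longer(dplyr::all_of(DENSE_FEATURES),
                        names_to = "feature", values_to = "value")

  kw <- keyword_features(corpus, lexicon, tokens = tokens) |>
    dplyr::inner_join(triples, by = "pmid", relationship = "many-to-many")
  bow <- bag_of_words(corpus, triples, window = bow_window, tokens = tokens)
  paths <- path_features(corpus, triples, parses)

  dplyr::bind_rows(
    dense[, c("kinase_id", "axis", "pmid", "feature", "value")],
    kw[, c("kinase_id", "axis", "pmid", "feature", "value")],
    bow, paths
  ) |>
    dplyr::arrange(.data$kinase_id, .data$axis, .data$pmid, .data$feature)
}

#' Assemble a sparse document-term matrix
#'
#' Rows are candidate triples (keyed `kinase_id:axis:pmid`), columns are
#' features. The seven dense features occupy reserved leading columns; sparse
#' terms follow in lexicographic order. In training mode (no `vocabulary`)
#' the vocabulary is built from the vectors; in test mode the vectors are
#' projected onto the supplied vocabulary and unseen terms are dropped.
#'
#' @param features Long feature tibble from [extract_features()].
#' @param vocabulary Optional character vector from a previously built matrix.
#' @param weighting `"count"` (default), `"binary"`, or `"tfidf"`.
#' @return An object of class `kt_dtm`: list with a `Matrix::dgCMatrix`
#'   `matrix`, the `vocabulary`, and the row-key tibble `triples`.
#' @export
build_matrix <- function(features, vocabulary = NULL,
                         weighting = c("count", "binary", "tfidf")) {
  weighting <- match.arg(weighting)
  features <- as_tibble(features)
  if (!nrow(features)) stop("no feature rows supplied", call. = FALSE)
  rows <- features |>
    dplyr::distinct(.data$kinase_id, .data$axis, .data$pmid) |>
    dplyr::arrange(.data$kinase_id, .data$axis, .data$pmid)
  row_key <- triple_key(rows$kinase_id, rows$axis, rows$pmid)
  if (is.null(vocabulary)) {
    terms <- sort(unique(setdiff(features$feature, DENSE_FEATURES)))
    vocabulary <- c(DENSE_FEATURES, terms)
  } else {
    if (!length(vocabulary)) stop("empty vocabulary", call. = FALSE)
    stopifnot(identical(vocabulary[seq_along(DENSE_FEATURES)], DENSE_FEATURES))
  }
  i <- match(triple_key(features$kinase_id, features$axis, features$pmid),
             row_key)
  j <- match(features$feature, vocabulary)
  keep <- !is.na(j)
  m <- Matrix::drop0(Matrix::sparseMatrix(
    i = i[keep], j = j[keep], x = as.numeric(features$value[keep]),
    dims = c(nrow(rows), length(vocabulary)),
    dimnames = list(row_key, vocabulary)
  ))
  if (weighting == "binary") {
    term_cols <- setdiff(seq_along(vocabulary),
                         match(c("f1_kinase_count", "f2_axis_count"), vocabulary))
    m[, term_cols] <- 1 * (m[, term_cols] > 0)
  } else if (weighting == "tfidf") {
    term_cols <- seq(length(DENSE_FEATURES) + 1L, length(vocabulary))
    if (length(term_cols)) {
      df <- Matrix::colSums(m[, term_cols, drop = FALSE] > 0)
      idf <- log((1 + nrow(m)) / (1 + df)) + 1
      m[, term_cols] <- m[, term_cols, drop = FALSE] %*% Matrix::Diagonal(x = idf)
    }
  }
  structure(list(matrix = m, vocabulary = vocabulary, triples = rows),
            class = "kt_dtm")
}

#' @export
print.kt_dtm <- function(x, ...) {
  cat("<kt_dtm> ", nrow(x$matrix), " triples x ", ncol(x$matrix),
      " features (", format(Matrix::nnzero(x$matrix), big.mark = ","),
      " non-zero)\n", sep = "")
  invisible(x)
}

#' Read or write dependency parses in CoNLL-U format
#'
#' The reader keeps one row per token with the document and sentence the
#' token belongs to; sentence identity comes from `# sent_id = <pmid>.<k>`
#' comments (with `<k>` the 1-based sentence index within the document, in
#' the numbering of [split_sentences()]). The root token has `head` 0.
#' Multi-word-token and empty-node lines are skipped.
#'
#' @param path File path.
#' @return Tibble with columns `pmid`, `sentence_id`, `token_id`, `form`,
#'   `lemma`, `head`, `deprel`.
#' @export
read_conllu <- function(path) {
  lines <- readr::read_lines(path)
  cur_pmid <- NA_character_
  cur_sent <- NA_integer_
  rows <- list()
  for (line in lines) {
    if (line == "") next
    sm <- stringr::str_match(line, "^# sent_id = ([^.]+)\\.(\\d+)$")
    if (!is.na(sm[1, 1])) {
      cur_pmid <- sm[1, 2]
      cur_sent <- as.integer(sm[1, 3])
      next
    }
    if (stringr::str_starts(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) stop("malformed CoNLL-U line: ", line, call. = FALSE)
    if (stringr::str_detect(f[1], "[.-]")) next
    rows[[length(rows) + 1L]] <- tibble(
      pmid = cur_pmid, sentence_id = cur_sent,
      token_id = as.integer(f[1]), form = f[2], lemma = f[3],
      head = as.integer(f[7]), deprel = f[8]
    )
  }
  if (!length(rows)) {
    return(tibble(pmid = character(), sentence_id = integer(),
                  token_id = integer(), form = character(), lemma = character(),
                  head = integer(), deprel = character()))
  }
  dplyr::bind_rows(rows)
}

#' @rdname read_conllu
#' @param parses Parse tibble in the `read_conllu()` layout.
#' @export
write_conllu <- function(parses, path) {
  sents <- split(parses, paste(parses$pmid, parses$sentence_id))
  ord <- order(purrr::map_chr(sents, ~ .x$pmid[1]),
               purrr::map_int(sents, ~ .x$sentence_id[1]))
  blocks <- purrr::map_chr(sents[ord], function(s) {
    paste(c(
      sprintf("# sent_id = %s.%d", s$pmid[1], s$sentence_id[1]),
      sprintf("%d\t%s\t%s\t_\t_\t_\t%d\t%s\t_\t_",
              s$token_id, s$form, s$lemma, s$head, s$deprel)
    ), collapse = "\n")
  })
  readr::write_lines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Serialize a document-term matrix
#'
#' Writes the sparse matrix in MatrixMarket format alongside a vocabulary TSV
#' (`column<TAB>feature`) and a row-key TSV.
#'
#' @param dtm A `kt_dtm`.
#' @param stem Output path stem; writes `<stem>.mtx`, `<stem>.vocab.tsv`,
#'   `<stem>.rows.tsv`.
#' @return `stem`, invisibly.
#' @export
write_dtm <- function(dtm, stem) {
  stopifnot(inherits(dtm, "kt_dtm"))
  Matrix::writeMM(dtm$matrix, paste0(stem, ".mtx"))
  readr::write_tsv(tibble(column = seq_along(dtm$vocabulary),
                          feature = dtm$vocabulary),
                   paste0(stem, ".vocab.tsv"), progress = FALSE)
  readr::write_tsv(dtm$triples, paste0(stem, ".rows.tsv"), progress = FALSE)
  invisible(stem)
}

#' @rdname write_dtm
#' @export
read_dtm <- function(stem) {
  m <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  vocab <- readr::read_tsv(paste0(stem, ".vocab.tsv"), col_types = "ic",
                           progress = FALSE)$feature
  rows <- readr::read_tsv(paste0(stem, ".rows.tsv"), col_types = "ccc",
                          progress = FALSE)
  dimnames(m) <- list(triple_key(rows$kinase_id, rows$axis, rows$pmid), vocab)
  structure(list(matrix = m, vocabulary = vocab, triples = rows),
            class = "kt_dtm")
}
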