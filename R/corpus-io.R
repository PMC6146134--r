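#' Construct an annotated corpus
#'
#' A corpus bundles a table of documents with a table of typed, offset-anchored
#' bioconcept mentions. All offsets are 0-based half-open character positions
#' into the *full text* of a document, defined as `title`, a single space, and
#' `abstract` (just `title` when the abstract is empty).
#'
#' @param documents Tibble with columns `pmid`, `title`, `abstract`.
#' @param mentions Tibble with columns `pmid`, `start`, `end`, `surface`,
#'   `concept_type`, `concept_id`. May be empty.
#' @param sentences Optional tibble of sentence spans (`pmid`, `start`, `end`),
#'   usually produced by [split_sentences()].
#'
#' @return An object of class `kt_corpus`: a list of the three (validated)
#'   tibbles, with a `text` column added to `documents`.
#' @seealso [read_pubtator()], [split_sentences()], [tag_dictionary()]
#' @export
kt_corpus <- function(documents, mentions = NULL, sentences = NULL) {
  documents <- as_tibble(documents)
  stopifnot(all(c("pmid", "title", "abstract") %in% names(documents)))
  documents$pmid <- as.character(documents$pmid)
  if (anyDuplicated(documents$pmid)) {
    stop("duplicate pmid in corpus: ",
         paste(unique(documents$pmid[duplicated(documents$pmid)]), collapse = ", "),
         call. = FALSE)
  }
  documents$text <- full_text(documents$title, documents$abstract)
  if (is.null(mentions)) {
    mentions <- empty_mentions()
  }
  mentions <- as_tibble(mentions)
  if (nrow(mentions)) {
    mentions$pmid <- as.character(mentions$pmid)
    mentions <- dplyr::arrange(mentions, .data$pmid, .data$start, .data$end)
  }
  corpus <- structure(
    list(documents = documents, mentions = mentions, sentences = sentences),
    class = "kt_corpus"
  )
  validate_mentions(corpus)
  corpus
}

full_text <- function(title, abstract) {
  ifelse(abstract == "", title, paste(title, abstract))
}

empty_mentions <- function() {
  tibble(pmid = character(), start = integer(), end = integer(),
         surface = character(), concept_type = character(),
         concept_id = character())
}

validate_mentions <- function(corpus) {
  m <- corpus$mentions
  if (!nrow(m)) return(invisible(corpus))
  bad_type <- setdiff(unique(m$concept_type), CONCEPT_TYPES)
  if (length(bad_type)) {
    stop("unknown concept_type: ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  d <- corpus$documents
  m2 <- dplyr::left_join(m, d[, c("pmid", "text")], by = "pmid")
  if (anyNA(m2$text)) {
    stop("mention references unknown pmid: ",
         paste(unique(m2$pmid[is.na(m2$text)]), collapse = ", "), call. = FALSE)
  }
  len <- nchar(m2$text)
  bad <- m2$start < 0 | m2$end > len | m2$start >= m2$end
  if (any(bad)) {
    stop("mention offsets out of bounds for pmid ",
         paste(unique(m2$pmid[bad]), collapse = ", "), call. = FALSE)
  }
  got <- substr(m2$text, m2$start + 1L, m2$end)
  mismatch <- got != m2$surface
  if (any(mismatch)) {
    stop("mention surface does not match text for pmid ",
         paste(unique(m2$pmid[mismatch]), collapse = ", "),
         " (expected '", m2$surface[mismatch][1], "', text has '",
         got[mismatch][1], "')", call. = FALSE)
  }
  invisible(corpus)
}

#' @export
print.kt_corpus <- function(x, ...) {
  cat("<kt_corpus> ", nrow(x$documents), " documents, ",
      nrow(x$mentions), " mentions",
      if (!is.null(x$sentences)) paste0(", ", nrow(x$sentences), " sentence spans"),
      "\n", sep = "")
  invisible(x)
}

#' Read a PubTator-format annotated corpus
#'
#' Parses the line-oriented PubTator format: for each document a
#' `PMID|t|title` line, a `PMID|a|abstract` line, then zero or more
#' tab-delimited mention lines `PMID<TAB>start<TAB>end<TAB>surface<TAB>type<TAB>id`,
#' with documents separated by blank lines. Offsets are validated against the
#' document's full text on load. Records missing an abstract line are accepted
#' with an empty abstract (a message is emitted).
#'
#' @param path Path to a UTF-8 PubTator file.
#' @return A [kt_corpus()].
#' @export
read_pubtator <- function(path) {
  lines <- readr::read_lines(path)
  docs <- list()
  mens <- list()
  titles <- character()
  abstracts <- character()
  pmids <- character()
  no_abstract <- character()
  cur <- NULL

  flush_doc <- function() {
    if (is.null(cur)) return()
    if (is.na(cur$abstract)) {
      no_abstract[[length(no_abstract) + 1L]] <<- cur$pmid
      cur$abstract <- ""
    }
    pmids[[length(pmids) + 1L]] <<- cur$pmid
    titles[[length(titles) + 1L]] <<- cur$title
    abstracts[[length(abstracts) + 1L]] <<- cur$abstract
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "") {
      flush_doc()
      next
    }
    tm <- stringr::str_match(line, "^([^|\t]+)\\|t\\|(.*)$")
    am <- stringr::str_match(line, "^([^|\t]+)\\|a\\|(.*)$")
    if (!is.na(tm[1, 1])) {
      flush_doc()
      cur <- list(pmid = tm[1, 2], title = tm[1, 3], abstract = NA_character_)
      next
    }
    if (!is.na(am[1, 1])) {
      if (is.null(cur) || cur$pmid != am[1, 2]) {
        stop("line ", i, ": abstract line without matching title line", call. = FALSE)
      }
      cur$abstract <- am[1, 3]
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) == 5L) fields <- c(fields, "")
    if (length(fields) != 6L) {
      stop("line ", i, ": malformed PubTator line (expected title, abstract or ",
           "6-field mention line): ", substr(line, 1, 60), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    if (is.na(start) || is.na(end)) {
      stop("line ", i, ": non-integer mention offsets", call. = FALSE)
    }
    mens[[length(mens) + 1L]] <- tibble(
      pmid = fields[1], start = start, end = end, surface = fields[4],
      concept_type = fields[5], concept_id = fields[6]
    )
  }
  flush_doc()

  if (length(no_abstract)) {
    message("read_pubtator: ", length(no_abstract),
            " record(s) without an abstract line (kept with empty abstract): ",
            paste(head(no_abstract, 5), collapse = ", "))
  }
  documents <- tibble(pmid = pmids, title = titles, abstract = abstracts)
  mentions <- if (length(mens)) dplyr::bind_rows(mens) else empty_mentions()
  kt_corpus(documents, mentions)
}

#' Write a corpus in PubTator format
#'
#' @param corpus A [kt_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pubtator <- function(corpus, path) {
  stopifnot(inherits(corpus, "kt_corpus"))
  blocks <- purrr::map_chr(seq_len(nrow(corpus$documents)), function(i) {
    d <- corpus$documents[i, ]
    m <- corpus$mentions[corpus$mentions$pmid == d$pmid, , drop = FALSE]
    lines <- c(
      paste0(d$pmid, "|t|", d$title),
      paste0(d$pmid, "|a|", d$abstract)
    )
    if (nrow(m)) {
      lines <- c(lines, paste(m$pmid, m$start, m$end, m$surface,
                              m$concept_type, m$concept_id, sep = "\t"))
    }
    paste(lines, collapse = "\n")
  })
  readr::write_lines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Read or write a candidate-triples table
#'
#' Triples are the curation unit `<kinase_id, axis, pmid>` plus a label in
#' `POSITIVE`, `NEGATIVE`, `UNLABELED`. The file is a UTF-8 TSV with header
#' `kinase_id axis pmid label`.
#'
#' @param path File path.
#' @return A tibble with columns `kinase_id`, `axis`, `pmid`, `label`.
#' @export
read_triples <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  stopifnot(all(c("kinase_id", "axis", "pmid", "label") %in% names(x)))
  validate_triples(x)
}

#' @rdname read_triples
#' @param triples Tibble of triples.
#' @export
write_triples <- function(triples, path) {
  validate_triples(triples)
  readr::write_tsv(triples[, c("kinase_id", "axis", "pmid", "label")], path,
                   progress = FALSE)
  invisible(path)
}

validate_triples <- function(triples) {
  triples <- as_tibble(triples)
  bad_axis <- setdiff(unique(triples$axis), AXES)
  if (length(bad_axis)) {
    stop("unknown axis: ", paste(bad_axis, collapse = ", "), call. = FALSE)
  }
  if ("label" %in% names(triples)) {
    bad_lab <- setdiff(unique(triples$label), TRIPLE_LABELS)
    if (length(bad_lab)) {
      stop("unknown label: ", paste(bad_lab, collapse = ", "), call. = FALSE)
    }
  }
  key <- triple_key(triples$kinase_id, triples$axis, triples$pmid)
  if (anyDuplicated(key)) {
    stop("duplicate triple: ", key[duplicated(key)][1], call. = FALSE)
  }
  triples
}

#' Build unlabeled candidate triples from a tagged corpus
#'
#' Every document that mentions a target kinase yields one `UNLABELED` triple
#' per mentioned target kinase and axis (DIS and BP); documents without a
#' target-kinase mention are skipped, mirroring the triage pipeline's
#' filtering of articles without kinase mentions.
#'
#' @param corpus A [kt_corpus()] with KINASE mentions.
#' @param target_kinases Character vector of kinase `concept_id`s to triage.
#' @return Tibble of triples (`kinase_id`, `axis`, `pmid`, `label`), one row
#'   per unique (document, kinase, axis); `2 * |{(doc, kinase)}|` rows total.
#' @export
build_candidate_triples <- function(corpus, target_kinases) {
  stopifnot(inherits(corpus, "kt_corpus"))
  if (!length(target_kinases)) {
    return(tibble(kinase_id = character(), axis = character(),
                  pmid = character(), label = character()))
  }
  hits <- corpus$mentions |>
    dplyr::filter(.data$concept_type == "KINASE",
                  .data$concept_id %in% target_kinases) |>
    dplyr::distinct(.data$pmid, kinase_id = .data$concept_id)
  tidyr::crossing(hits, axis = AXES) |>
    dplyr::transmute(.data$kinase_id, .data$axis, .data$pmid,
                     label = "UNLABELED") |>
    dplyr::arrange(.data$kinase_id, .data$axis, .data$pmid)
}

#' Write a ranking as a TREC run file
#'
#' One line per ranked document: `qid Q0 pmid rank score tag`, with the query
#' id serialized as `kinase_id:axis` (so `:` is forbidden inside kinase ids).
#' Within each query, entries are ordered by descending score with ties broken
#' by ascending pmid, and ranks start at 1.
#'
#' @param run Tibble with columns `kinase_id`, `axis`, `pmid`, `score`.
#' @param path Output file path.
#' @param tag Run tag written in the last column.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path, tag = "kinasetriage") {
  run <- rank_entries(run)
  if (anyDuplicated(run[, c("kinase_id", "axis", "pmid")])) {
    stop("duplicate (query, pmid) entry in run", call. = FALSE)
  }
  lines <- sprintf("%s\tQ0\t%s\t%d\t%s\t%s",
                   query_id(run$kinase_id, run$axis), run$pmid, run$rank,
                   format(run$score, digits = 15, trim = TRUE, scientific = FALSE),
                   tag)
  readr::write_lines(lines, path)
  invisible(path)
}

# Materialize the deterministic ranking order: descending score, ties by
# ascending pmid; rank restarts at 1 within each (kinase_id, axis) query.
rank_entries <- function(run) {
  run <- as_tibble(run)
  stopifnot(all(c("kinase_id", "axis", "pmid", "score") %in% names(run)))
  run |>
    dplyr::arrange(.data$kinase_id, .data$axis,
                   dplyr::desc(.data$score), .data$pmid) |>
    dplyr::group_by(.data$kinase_id, .data$axis) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Read a TREC run file
#'
#' @param path Path to a run file written by [write_run()] or a compatible tool.
#' @return Tibble with columns `kinase_id`, `axis`, `pmid`, `rank`, `score`,
#'   `tag`.
#' @export
read_run <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("qid", "q0", "pmid", "rank", "score", "tag"),
    col_types = "cccidc", progress = FALSE
  )
  parts <- stringr::str_split_fixed(x$qid, ":", 2)
  tibble(kinase_id = parts[, 1], axis = parts[, 2], pmid = x$pmid,
         rank = x$rank, score = x$score, tag = x$tag)
}

#' Read or write relevance judgments (qrels)
#'
#' Judgments map a query `kinase_id:axis` to the set of pmids a curator found
#' relevant. The file is a TSV with columns `query`, `pmid`,
#' `relevance` (0/1), without header.
#'
#' @param path File path.
#' @return Tibble with columns `kinase_id`, `axis`, `pmid`, `relevance`.
#' @export
read_qrels <- function(path) {
  x <- readr::read_tsv(path, col_names = c("query", "pmid", "relevance"),
                       col_types = "cci", progress = FALSE)
  parts <- stringr::str_split_fixed(x$query, ":", 2)
  tibble(kinase_id = parts[, 1], axis = parts[, 2], pmid = x$pmid,
         relevance = x$relevance)
}

#' @rdname read_qrels
#' @param qrels Tibble with columns `kinase_id`, `axis`, `pmid`, `relevance`.
#' @export
write_qrels <- function(qrels, path) {
  lines <- sprintf("%s\t%s\t%d", query_id(qrels$kinase_id, qrels$axis),
                   qrels$pmid, as.integer(qrels$relevance))
  readr::write_lines(lines, path)
  invisible(path)
}
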