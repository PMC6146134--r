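#' Build a tagging lexicon
#'
#' A lexicon holds the surface-form dictionaries used by [tag_dictionary()]
#' (one `(surface, concept_id)` list per concept type) together with the
#' keyword groups consumed by [keyword_features()]. The seven group names are
#' fixed: `verb`, `patient`, `genetic`, `scale`, `period`, `examine` and
#' `variation`; the `variation` group carries no fixed strings because it is
#' populated by the mutation tagger at feature time.
#'
#' @param entries Tibble with columns `surface`, `concept_id`, `concept_type`
#'   (`KINASE`, `DIS` or `BP`).
#' @param keyword_groups Named list of character vectors; defaults to
#'   [default_keyword_groups()].
#' @return An object of class `kt_lexicon`.
#' @export
kt_lexicon <- function(entries, keyword_groups = default_keyword_groups()) {
  entries <- as_tibble(entries)
  stopifnot(all(c("surface", "concept_id", "concept_type") %in% names(entries)))
  if (any(entries$surface == "")) stop("empty surface form in lexicon", call. = FALSE)
  if (anyDuplicated(entries[, c("surface", "concept_type")])) {
    stop("duplicate (surface, concept_type) in lexicon", call. = FALSE)
  }
  expected <- c("verb", "patient", "genetic", "scale", "period", "examine",
                "variation")
  if (!setequal(names(keyword_groups), expected)) {
    stop("keyword groups must be exactly: ", paste(expected, collapse = ", "),
         call. = FALSE)
  }
  structure(list(entries = entries, keyword_groups = keyword_groups),
            class = "kt_lexicon")
}

#' @export
print.kt_lexicon <- function(x, ...) {
  counts <- table(x$entries$concept_type)
  cat("<kt_lexicon> ", paste(names(counts), counts, sep = ": ", collapse = ", "),
      "; ", length(x$keyword_groups), " keyword groups\n", sep = "")
  invisible(x)
}

#' Default curation keyword groups
#'
#' The six fixed keyword groups describing how articles talk about kinases,
#' diseases and biological processes (action verbs, patient terms, genetics
#' vocabulary, dosage scales, time periods, study-design terms), stored as
#' lemmas so inflected forms still count. The seventh group, `variation`, is
#' left empty: its total is the number of mutation mentions found by
#' [tag_mutations()].
#'
#' @return Named list of character vectors.
#' @export
default_keyword_groups <- function() {
  list(
    verb = c("involve", "enhance", "inhibit", "regulate", "increase",
             "associate", "phosphorylate"),
    patient = c("patient", "men", "women"),
    genetic = c("detectable", "survival", "genetic", "tumorigenesis",
                "overexpression", "mutation", "translate", "transcript",
                "change", "lymphangiogenic", "neurotrophic"),
    scale = c("mg", "kg"),
    period = c("day", "during"),
    examine = c("examine", "experiment", "screen", "role", "risk",
                "significant"),
    variation = character()
  )
}

#' Read or write a lexicon TSV
#'
#' Format: `surface_form<TAB>concept_id<TAB>concept_type`, no header, UTF-8.
#'
#' @param path File path (for multiple files, a character vector; entries are
#'   concatenated).
#' @param keyword_groups Passed to [kt_lexicon()].
#' @return A `kt_lexicon`.
#' @export
read_lexicon <- function(path, keyword_groups = default_keyword_groups()) {
  entries <- purrr::map(path, function(p) {
    readr::read_tsv(p, col_names = c("surface", "concept_id", "concept_type"),
                    col_types = "ccc", progress = FALSE)
  }) |> dplyr::bind_rows()
  kt_lexicon(entries, keyword_groups)
}

#' @rdname read_lexicon
#' @param lexicon A `kt_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  e <- lexicon$entries
  readr::write_lines(paste(e$surface, e$concept_id, e$concept_type, sep = "\t"),
                     path)
  invisible(path)
}

# Abbreviations that do not end a sentence even when followed by a capital.
SENT_ABBREV <- c("e.g.", "i.e.", "cf.", "vs.", "etc.", "fig.", "figs.",
                 "ref.", "refs.", "dr.", "al.", "no.", "approx.", "ca.")

#' Split documents into sentence spans
#'
#' Deterministic rule-based splitting: the title is always one span; the
#' abstract is split after `.`, `!` or `?` when followed by whitespace and an
#' upper-case letter or digit, unless the token ending at the punctuation is a
#' known abbreviation (`e.g.`, `et al.`, `Fig.` ...). Text without terminal
#' punctuation yields a single span. Spans are trimmed to non-whitespace,
#' non-overlapping, ordered, and cover every non-whitespace character of the
#' full text.
#'
#' @param corpus A [kt_corpus()].
#' @return The corpus with its `sentences` tibble (`pmid`, `sentence_id`,
#'   `start`, `end`) filled in.
#' @export
split_sentences <- function(corpus) {
  stopifnot(inherits(corpus, "kt_corpus"))
  d <- corpus$documents
  spans <- purrr::map2(d$pmid, seq_len(nrow(d)), function(pmid, i) {
    title <- d$title[[i]]
    abstract <- d$abstract[[i]]
    s <- trim_span(title, 0L)
    if (abstract != "") {
      off <- nchar(title) + 1L  # title + single joining space
      s <- rbind(s, split_block(abstract, off))
    }
    s <- s[!is.na(s[, 1]), , drop = FALSE]
    tibble(pmid = pmid, sentence_id = seq_len(nrow(s)),
           start = s[, 1], end = s[, 2])
  })
  corpus$sentences <- dplyr::bind_rows(spans)
  corpus
}

# Sentence-boundary candidates within one block of text; returns a matrix of
# (start, end) offsets relative to the full text (block offset `off`).
split_block <- function(text, off) {
  n <- nchar(text)
  hits <- stringr::str_locate_all(text, "[.!?]+(?=\\s+[A-Z0-9])")[[1]]
  cuts <- integer()
  if (nrow(hits)) {
    for (j in seq_len(nrow(hits))) {
      endpos <- hits[j, 2]
      prefix <- substr(text, max(1L, endpos - 12L), endpos)
      token <- stringr::str_extract(prefix, "[A-Za-z.]+$")
      if (!is.na(token) && tolower(token) %in% SENT_ABBREV) next
      cuts <- c(cuts, endpos)
    }
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  spans <- t(mapply(function(s, e) {
    trim_span(substr(text, s, e), off + s - 1L)
  }, starts, ends))
  spans[!is.na(spans[, 1]), , drop = FALSE]
}

# 0-based half-open span of the non-whitespace core of `piece`, whose first
# character sits at 0-based offset `off0` of the full text.
trim_span <- function(piece, off0) {
  m <- stringr::str_locate(piece, "^\\s*")
  lead <- m[1, 2]
  core <- stringr::str_trim(piece)
  if (core == "") return(matrix(NA_integer_, 1, 2))
  matrix(c(off0 + lead, off0 + lead + nchar(core)), 1, 2)
}

#' Dictionary-based mention tagging
#'
#' Tags every token-boundary-anchored, leftmost-longest, non-overlapping match
#' of a lexicon surface form. Matching is case-insensitive, except that short
#' all-uppercase symbols (5 characters or fewer, e.g. `WAS`, `MET`) match
#' case-sensitively to avoid common-word false positives. This dictionary
#' tagger (together with [tag_mutations()]) is a deliberately simple,
#' pluggable stand-in for heavyweight gene/disease taggers such as GNormPlus
#' and DNorm.
#'
#' @param corpus A [kt_corpus()].
#' @param lexicon A [kt_lexicon()].
#' @param concept_type One of `KINASE`, `DIS`, `BP`.
#' @return Tibble of mentions (`pmid`, `start`, `end`, `surface`,
#'   `concept_type`, `concept_id`).
#' @export
tag_dictionary <- function(corpus, lexicon, concept_type) {
  stopifnot(inherits(corpus, "kt_corpus"), inherits(lexicon, "kt_lexicon"))
  concept_type <- match.arg(concept_type, c("KINASE", "DIS", "BP"))
  entries <- lexicon$entries[lexicon$entries$concept_type == concept_type, ]
  if (!nrow(entries)) {
    stop("lexicon has no entries of type ", concept_type, call. = FALSE)
  }
  strict <- is_strict_case(entries$surface)
  pats <- list(
    build_dict_regex(entries$surface[strict], ignore_case = FALSE),
    build_dict_regex(entries$surface[!strict], ignore_case = TRUE)
  )
  lookup <- c(
    setNames(entries$concept_id[strict], entries$surface[strict]),
    setNames(entries$concept_id[!strict], tolower(entries$surface[!strict]))
  )

  out <- purrr::map2(corpus$documents$pmid, corpus$documents$text,
                     function(pmid, text) {
    locs <- purrr::map(pats, function(p) {
      if (is.null(p)) return(NULL)
      stringr::str_locate_all(text, p)[[1]]
    })
    locs <- do.call(rbind, locs)
    if (is.null(locs) || !nrow(locs)) return(NULL)
    keep <- resolve_overlaps(locs)
    surface <- stringr::str_sub(text, keep[, 1], keep[, 2])
    id <- ifelse(surface %in% names(lookup), lookup[surface],
                 lookup[tolower(surface)])
    tibble(pmid = pmid, start = unname(keep[, 1]) - 1L,
           end = unname(keep[, 2]), surface = surface,
           concept_type = concept_type, concept_id = unname(id))
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(empty_mentions())
  dplyr::arrange(res, .data$pmid, .data$start)
}

# Short all-uppercase symbols are matched case-sensitively.
is_strict_case <- function(surface) {
  nchar(surface) <= 5 & surface == toupper(surface) &
    stringr::str_detect(surface, "[A-Z]")
}

# Alternation regex with token boundaries; alternatives sorted longest-first
# so alternation picks the longest match at each position.
build_dict_regex <- function(surfaces, ignore_case) {
  if (!length(surfaces)) return(NULL)
  surfaces <- surfaces[order(-nchar(surfaces), surfaces)]
  alt <- paste(stringr::str_escape(surfaces), collapse = "|")
  stringr::regex(
    paste0("(?<![A-Za-z0-9])(?:", alt, ")(?![A-Za-z0-9])"),
    ignore_case = ignore_case
  )
}

# Leftmost-longest selection of non-overlapping spans (1-based inclusive).
resolve_overlaps <- function(locs) {
  ord <- order(locs[, 1], -(locs[, 2] - locs[, 1]))
  locs <- locs[ord, , drop = FALSE]
  keep <- matrix(integer(), 0, 2)
  last_end <- 0L
  for (j in seq_len(nrow(locs))) {
    if (locs[j, 1] > last_end) {
      keep <- rbind(keep, locs[j, , drop = FALSE])
      last_end <- locs[j, 2]
    }
  }
  keep
}

AA1 <- "ACDEFGHIKLMNPQRSTVWY"
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

#' Regex-based mutation mention tagging
#'
#' A simplified, three-family stand-in for a full mutation tagger (tmVar):
#' single-letter protein substitutions (`V600E`), three-letter substitutions
#' (`Ala123Val`), and HGVS-prefixed strings (`p.Gly12Asp`, `c.76A>T`).
#' Matches are token-anchored and non-overlapping; a digit run without a
#' trailing amino-acid letter (as in `E3 ligase`) is not a mutation.
#'
#' @param corpus A [kt_corpus()].
#' @return Tibble of `MUTATION` mentions with empty `concept_id`.
#' @export
tag_mutations <- function(corpus) {
  stopifnot(inherits(corpus, "kt_corpus"))
  aa3 <- paste(AA3, collapse = "|")
  pats <- c(
    sub1 = paste0("(?<![A-Za-z0-9])[", AA1, "][0-9]+[", AA1, "](?![A-Za-z0-9])"),
    sub3 = paste0("(?<![A-Za-z0-9])(?:", aa3, ")[0-9]+(?:", aa3, ")(?![A-Za-z0-9])"),
    hgvs = "(?<![A-Za-z0-9])[cpgmn]\\.[A-Za-z0-9>_*+-]+(?![A-Za-z0-9])"
  )
  out <- purrr::map2(corpus$documents$pmid, corpus$documents$text,
                     function(pmid, text) {
    locs <- do.call(rbind, purrr::map(pats, function(p) {
      stringr::str_locate_all(text, p)[[1]]
    }))
    if (!nrow(locs)) return(NULL)
    keep <- resolve_overlaps(locs)
    tibble(pmid = pmid, start = unname(keep[, 1]) - 1L,
           end = unname(keep[, 2]),
           surface = stringr::str_sub(text, keep[, 1], keep[, 2]),
           concept_type = "MUTATION", concept_id = "")
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) return(empty_mentions())
  dplyr::arrange(res, .data$pmid, .data$start)
}

#' Tag a corpus with all concept types
#'
#' Convenience wrapper: runs [tag_dictionary()] for each concept type present
#' in the lexicon plus [tag_mutations()], replaces the corpus mentions with
#' the result, and computes sentence spans.
#'
#' @inheritParams tag_dictionary
#' @param mutations Tag mutation mentions as well?
#' @return The corpus with `mentions` and `sentences` populated.
#' @export
tag_corpus <- function(corpus, lexicon, mutations = TRUE) {
  types <- intersect(c("KINASE", "DIS", "BP"), unique(lexicon$entries$concept_type))
  mens <- purrr::map(types, function(ct) tag_dictionary(corpus, lexicon, ct))
  if (mutations) mens <- c(mens, list(tag_mutations(corpus)))
  corpus$mentions <- dplyr::bind_rows(mens)
  if (nrow(corpus$mentions)) {
    corpus$mentions <- dplyr::arrange(corpus$mentions, .data$pmid, .data$start,
                                      .data$end)
  }
  validate_mentions(corpus)
  split_sentences(corpus)
}
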