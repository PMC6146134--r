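# Small in-code fixtures shared across the suite.

# One-document corpus from raw title/abstract plus optional mention rows.
fixture_corpus <- function(title, abstract, mentions = NULL, pmid = "1") {
  kt_corpus(
    tibble::tibble(pmid = pmid, title = title, abstract = abstract),
    mentions
  )
}

fixture_lexicon <- function() {
  kt_lexicon(tibble::tibble(
    surface = c("SGK1", "BRAF", "kinase 1", "myeloma", "carcinoma",
                "apoptosis", "angiogenesis"),
    concept_id = c("NX_O00141", "NX_P15056", "KX_1", "D009101", "D002277",
                   "GO_0006915", "GO_0001525"),
    concept_type = c("KINASE", "KINASE", "KINASE", "DIS", "DIS", "BP", "BP")
  ))
}

# Independent brute-force retrieval oracle: prefix enumeration with explicit
# loops, no shared code with the package implementations.
oracle_metrics <- function(ranked, relevant) {
  n <- length(ranked)
  r <- length(relevant)
  prec <- numeric(n)
  hits <- 0
  for (k in seq_len(n)) {
    if (ranked[k] %in% relevant) hits <- hits + 1
    prec[k] <- hits / k
  }
  ap <- 0
  for (k in seq_len(n)) {
    if (ranked[k] %in% relevant) ap <- ap + prec[k]
  }
  ap <- ap / r
  rp <- if (r <= n) prec[r] else sum(ranked %in% relevant) / r
  list(ap = ap,
       r_prec = rp,
       p_at_r0 = if (n) max(prec) else 0)
}

# Random ranked instance with <= max_n documents, at least one relevant.
oracle_instance <- function(max_n = 20) {
  n <- sample(2:max_n, 1)
  r <- sample(seq_len(n - 1), 1)
  pmids <- sample(sprintf("d%03d", 1:999), n)
  list(ranked = pmids, relevant = sample(pmids, r))
}

# A feature tibble whose classes are separable on f7_same_sentence alone,
# with a little term noise so the matrix is not degenerate.
separable_features <- function(n_pos = 24, n_neg = 24) {
  mk <- function(i, label) {
    pmid <- sprintf("%s%03d", ifelse(label == "POSITIVE", "p", "n"), i)
    tibble::tibble(
      kinase_id = "K1", axis = "DIS", pmid = pmid,
      feature = c(DENSE_FEATURES_TEST, paste0("bow:word", (i %% 5) + 1)),
      value = c(1, 1, 1, 0, 0, 0, as.integer(label == "POSITIVE"), 1)
    )
  }
  feats <- dplyr::bind_rows(
    purrr::map(seq_len(n_pos), mk, label = "POSITIVE"),
    purrr::map(seq_len(n_neg), mk, label = "NEGATIVE")
  )
  labels <- c(rep("POSITIVE", n_pos), rep("NEGATIVE", n_neg))
  keys <- c(sprintf("K1:DIS:p%03d", seq_len(n_pos)),
            sprintf("K1:DIS:n%03d", seq_len(n_neg)))
  list(features = feats, labels = labels, keys = keys)
}

DENSE_FEATURES_TEST <- c(
  "f1_kinase_count", "f2_axis_count",
  "f3_kinase_first_sent", "f4_axis_first_sent",
  "f5_kinase_last_sent", "f6_axis_last_sent",
  "f7_same_sentence"
)

# Small synthetic profile used where the full default profile would be slow.
small_profile <- function(seed = 11, ...) {
  synth_config(n_positive = 30, n_negative = 20, n_dev = 8, n_pool = 100,
               n_kinases = 5, seed = seed, ...)
}
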