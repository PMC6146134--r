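test_that("precision and recall at k match their worked examples", {
  # 10 documents returned, 5 of them relevant: P10 = 0.5
  ranked <- sprintf("d%02d", 1:10)
  relevant <- ranked[c(1, 3, 5, 7, 9)]
  expect_equal(precision_at_k(ranked, relevant, 10), 0.5)
  expect_equal(precision_at_k(ranked, relevant, 2), 0.5)
  expect_equal(precision_at_k(ranked, ranked, 10), 1)
  expect_equal(precision_at_k(ranked, "none", 10), 0)
  expect_error(precision_at_k(ranked, relevant, 0), ">= 1")

  # 20 relevant in the collection, 5 retrieved in the top 30: R30 = 0.25
  ranked30 <- sprintf("r%02d", 1:30)
  relevant20 <- c(ranked30[1:5], sprintf("x%02d", 1:15))
  expect_equal(recall_at_k(ranked30, relevant20, 30), 0.25)
  expect_equal(recall_at_k(ranked30, ranked30[1:4], 30), 1)
  expect_equal(recall_at_k(ranked30, sprintf("x%02d", 1:3), 30), 0)
  expect_error(recall_at_k(ranked30, character(), 30), "empty relevant")
})

test_that("average precision follows the prefix-precision definition", {
  expect_equal(average_precision(c("a", "b"), "a"), 1)
  # 2 relevant retrieved at ranks 1 and 3: (1/1 + 2/3) / 2
  expect_equal(average_precision(c("a", "x", "b", "y"), c("a", "b")),
               (1 + 2 / 3) / 2)
  # unretrieved relevant documents contribute zero
  expect_equal(average_precision(c("x", "y"), c("a", "b")), 0)
  expect_equal(average_precision(c("a", "x"), c("a", "b")), 0.5)
})

test_that("R-precision and maximum observed precision behave per definition", {
  ranked <- c("a", "b", "c", "d")
  expect_equal(r_precision(ranked, c("a", "b")), 1)
  expect_equal(r_precision(ranked, c("c", "d")), 0)
  expect_equal(r_precision(c("x", "a"), "a"), 0)
  # relevant only at ranks 2 and 3: max prefix precision = 2/3
  expect_equal(p_at_r0(c("x", "a", "b", "y"), c("a", "b")), 2 / 3)
  expect_equal(p_at_r0(c("a", "x"), "a"), 1)
  expect_equal(p_at_r0(character(), "a"), 0)
})

test_that("expected-rank score sums rank/pool contributions", {
  # one triple ranked first among 10 candidates contributes 0.1
  expect_equal(escore(tibble::tibble(rank_in_pool = 1, pool_size = 10)), 0.1)
  # ranks 2/4 and 3/6 sum to 1.0
  expect_equal(escore(tibble::tibble(rank_in_pool = c(2, 3),
                                     pool_size = c(4, 6))), 1)
  # every triple ranked last: one unit each
  expect_equal(escore(tibble::tibble(rank_in_pool = c(5, 8),
                                     pool_size = c(5, 8))), 2)
  expect_error(escore(tibble::tibble(rank_in_pool = 11, pool_size = 10)),
               "pool_size")
})

test_that("MAP is the mean per-query AP and needs an evaluable query", {
  run <- tibble::tibble(
    kinase_id = c("K1", "K1", "K2", "K2"), axis = "DIS",
    pmid = c("a", "b", "a", "b"), score = c(2, 1, 2, 1)
  )
  qrels <- tibble::tibble(
    kinase_id = c("K1", "K2"), axis = "DIS", pmid = c("a", "b"),
    relevance = 1L
  )
  # APs are 1.0 (relevant first) and 0.5 (relevant second)
  expect_equal(mean_average_precision(run, qrels), 0.75)
  single <- qrels[1, ]
  expect_equal(mean_average_precision(run, single), 1)
  expect_warning(
    mean_average_precision(run, dplyr::mutate(qrels, relevance = c(1L, 0L))),
    "skipped")
  expect_error(
    suppressWarnings(
      mean_average_precision(run, dplyr::mutate(qrels, relevance = 0L))),
    "no evaluable")
})

test_that("rank-based metrics equal the brute-force oracle on random instances", {
  set.seed(1234)
  for (i in 1:200) {
    inst <- oracle_instance()
    o <- oracle_metrics(inst$ranked, inst$relevant)
    expect_equal(average_precision(inst$ranked, inst$relevant), o$ap,
                 tolerance = 1e-13)
    expect_equal(r_precision(inst$ranked, inst$relevant), o$r_prec,
                 tolerance = 1e-13)
    expect_equal(p_at_r0(inst$ranked, inst$relevant), o$p_at_r0,
                 tolerance = 1e-13)
  }
})

test_that("promoting a relevant document never hurts AP or the rank score", {
  set.seed(77)
  for (i in 1:50) {
    inst <- oracle_instance(max_n = 15)
    ranked <- inst$ranked
    rel_pos <- which(ranked %in% inst$relevant)
    rel_pos <- rel_pos[rel_pos > 1]
    if (!length(rel_pos)) next
    p <- rel_pos[sample(length(rel_pos), 1)]
    swapped <- ranked
    swapped[c(p - 1, p)] <- swapped[c(p, p - 1)]
    expect_gte(average_precision(swapped, inst$relevant),
               average_precision(ranked, inst$relevant))
    # the corresponding per-triple rank contribution strictly improves
    e_before <- escore(tibble::tibble(rank_in_pool = p,
                                      pool_size = length(ranked)))
    e_after <- escore(tibble::tibble(rank_in_pool = p - 1,
                                     pool_size = length(ranked)))
    expect_lt(e_after, e_before)
  }
})

test_that("the full report satisfies its internal orderings", {
  set.seed(42)
  run <- tidyr::crossing(kinase_id = c("K1", "K2", "K3"), axis = c("DIS", "BP"),
                         pmid = sprintf("d%03d", 1:120)) |>
    dplyr::mutate(score = stats::runif(dplyr::n()))
  qrels <- run |>
    dplyr::group_by(kinase_id, axis) |>
    dplyr::slice_sample(n = 12) |>
    dplyr::ungroup() |>
    dplyr::transmute(kinase_id, axis, pmid, relevance = 1L)
  ev <- evaluate_run(run, qrels)
  per <- tidy(ev)
  expect_equal(nrow(per), 6)
  expect_true(all(per$r100 >= per$r30))
  expect_true(all(per$p_at_r0 >= per$p10))
  expect_true(all(per$p_at_r0 >= per$p30 & per$p_at_r0 >= per$p100))
  expect_equal(glance(ev)$map, mean(per$ap))
  vals <- unlist(per[, setdiff(names(per), c("kinase_id", "axis", "n_relevant"))])
  expect_true(all(vals >= 0 & vals <= 1))

  # perfect ranking: AP = R-Prec = max precision = 1
  perfect <- qrels |> dplyr::mutate(score = 2) |>
    dplyr::bind_rows(dplyr::anti_join(run, qrels,
                                      by = c("kinase_id", "axis", "pmid")))
  pev <- evaluate_run(perfect, qrels)
  expect_true(all(tidy(pev)$ap == 1))
  expect_true(all(tidy(pev)$r_prec == 1))
  expect_true(all(tidy(pev)$p_at_r0 == 1))
})

test_that("dev triple ranks locate each triple within its query pool", {
  run <- tibble::tibble(
    kinase_id = "K1", axis = "DIS", pmid = c("a", "b", "c", "d"),
    score = c(4, 3, 2, 1)
  )
  dev <- tibble::tibble(kinase_id = "K1", axis = "DIS", pmid = c("c", "a"))
  dr <- dev_triple_ranks(run, dev)
  expect_equal(dr$rank_in_pool[dr$pmid == "c"], 3)
  expect_equal(dr$rank_in_pool[dr$pmid == "a"], 1)
  expect_equal(unique(dr$pool_size), 4)
  expect_warning(
    dev_triple_ranks(run, dplyr::mutate(dev, pmid = c("c", "zz"))),
    "absent from the run")
})

test_that("the chance AP baseline matches simulation", {
  set.seed(9)
  for (case in list(c(10, 2), c(25, 5), c(8, 8))) {
    n <- case[1]; r <- case[2]
    sims <- replicate(4000, {
      ranked <- sample(sprintf("d%02d", 1:n))
      average_precision(ranked, sprintf("d%02d", 1:r))
    })
    expect_equal(expected_random_ap(n, r), mean(sims), tolerance = 0.02)
  }
  expect_equal(expected_random_ap(5, 5), 1)
  expect_equal(expected_random_ap(1, 1), 1)
})
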