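test_that("frequencies propagate to ancestors and N is the total count", {
  dag <- sibling_dag()
  ft <- count_frequencies(records_from_counts(c(A = 2, B = 3, R = 1)), dag)
  expect_equal(rlang::set_names(ft$self_n, ft$disease_id)[c("A", "B", "R")],
               c(A = 2L, B = 3L, R = 1L))
  expect_equal(rlang::set_names(ft$freq, ft$disease_id)[c("A", "B", "R")],
               c(A = 2L, B = 3L, R = 6L))
  expect_equal(attr(ft, "n_total"), 6L)
  expect_equal(term_probability(ft, "A"), 2 / 6)
  expect_equal(term_probability(ft, "R"), 1)
})

test_that("multi-path descendants are counted once (diamond DAG)", {
  dag <- diamond_dag()
  ft <- count_frequencies(records_from_counts(c(C = 1)), dag)
  fr <- rlang::set_names(ft$freq, ft$disease_id)
  expect_equal(unname(fr[c("P1", "P2", "R")]), c(1L, 1L, 1L))
  expect_true(all(ft$prob <= 1))
})

test_that("frequency table matches the brute-force recount on random DAGs", {
  for (seed in 1:3) {
    dag <- random_dag(30, seed)
    set.seed(seed + 100)
    rec <- tibble::tibble(entity_id = paste0("e", 1:200),
                          disease_id = sample(dag$terms$disease_id, 200, replace = TRUE))
    ft <- count_frequencies(rec, dag)
    expect_equal(rlang::set_names(as.numeric(ft$freq), ft$disease_id),
                 oracle_freq(dag, rec))
    # monotone along edges: prob(parent) >= prob(child)
    prob <- rlang::set_names(ft$prob, ft$disease_id)
    e <- igraph::as_data_frame(dag$graph)
    expect_true(all(prob[e$to] >= prob[e$from]))
  }
})

test_that("leaf frequency equals self count; unannotated terms get prob 0", {
  dag <- sibling_dag()
  ft <- count_frequencies(records_from_counts(c(A = 4)), dag)
  pr <- rlang::set_names(ft$prob, ft$disease_id)
  expect_equal(unname(pr["A"]), 1)       # leaf: f = self
  expect_equal(unname(pr["B"]), 0)
  expect_equal(rlang::set_names(ft$freq, ft$disease_id)[["A"]], 4L)
})

test_that("unresolvable and alternative-id records are handled", {
  dag <- toy_dag(list(row4("R"), row4("A", alt = "OMIM:1", parents = "R")))
  rec <- tibble::tibble(entity_id = c("e1", "e2", "e3"),
                        disease_id = c("OMIM:1", "A", "UNKNOWN:9"))
  ft <- count_frequencies(rec, dag)
  expect_equal(attr(ft, "n_unresolved"), 1L)
  expect_equal(attr(ft, "n_total"), 2L)
  expect_equal(rlang::set_names(ft$self_n, ft$disease_id)[["A"]], 2L)
  expect_error(count_frequencies(tibble::tibble(entity_id = "e", disease_id = "X"), dag),
               class = "dsim_validation_error")
})

test_that("Lin score: identity, hand-computed sibling case, disjoint roots", {
  dag <- sibling_dag()
  ft <- count_frequencies(records_from_counts(c(A = 2, B = 3, R = 1)), dag)
  expect_equal(lin_score(ft, dag, "A", "A"), 1)
  # LCA is the root with prob 1: numerator 2*log(1) = 0
  expect_equal(lin_score(ft, dag, "A", "B"), 0)

  dag2 <- toy_dag(list(row4("R1"), row4("R2"), row4("A", parents = "R1"),
                       row4("B", parents = "R2")))
  ft2 <- count_frequencies(records_from_counts(c(A = 1, B = 1)), dag2)
  expect_equal(lin_score(ft2, dag2, "A", "B"), 0)
})

test_that("Lin score equals the hand-derived ratio on an informative ancestor", {
  # R <- P <- {A, B}; counts A=1, B=1, elsewhere C=2 under R
  dag <- toy_dag(list(row4("R"), row4("P", parents = "R"),
                      row4("A", parents = "P"), row4("B", parents = "P"),
                      row4("C", parents = "R")))
  ft <- count_frequencies(records_from_counts(c(A = 1, B = 1, C = 2)), dag)
  # prob: A=B=1/4, P=2/4; Score(A,B) = 2*log(1/2) / (log(1/4)+log(1/4))
  expect_equal(lin_score(ft, dag, "A", "B"),
               2 * log(1 / 2) / (2 * log(1 / 4)), tolerance = 1e-12)
  expect_equal(lin_score(ft, dag, "A", "B"), 0.5, tolerance = 1e-12)
})

test_that("Lin score is symmetric and in [0, 1] on a 100-term random DAG", {
  dag <- random_dag(100, 7)
  set.seed(7)
  rec <- tibble::tibble(entity_id = paste0("e", 1:500),
                        disease_id = sample(dag$terms$disease_id, 500, replace = TRUE))
  ft <- count_frequencies(rec, dag)
  ids <- sample(dag$terms$disease_id, 12)
  for (i in 1:11) {
    s <- lin_score(ft, dag, ids[i], ids[i + 1])
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, lin_score(ft, dag, ids[i + 1], ids[i]))
  }
})

test_that("similarity network edges equal per-pair Lin recomputation", {
  dag <- random_dag(20, 11)
  set.seed(11)
  rec <- tibble::tibble(entity_id = paste0("e", 1:150),
                        disease_id = sample(dag$terms$disease_id, 150, replace = TRUE))
  ft <- count_frequencies(rec, dag)
  net <- build_similarity_network(ft, dag, node_ids = dag$terms$disease_id)
  # every emitted edge matches lin_score
  for (r in seq_len(nrow(net))) {
    expect_equal(net$weight[[r]], lin_score(ft, dag, net$id1[[r]], net$id2[[r]]),
                 tolerance = 1e-12)
  }
  # every absent pair has score 0 (threshold default 0, strict)
  keys <- pair_ids <- paste(net$id1, net$id2)
  ids <- sort(dag$terms$disease_id)
  cmb <- utils::combn(ids, 2)
  absent <- which(!(paste(cmb[1, ], cmb[2, ]) %in% keys))
  for (r in sample(absent, min(30, length(absent)))) {
    expect_equal(lin_score(ft, dag, cmb[1, r], cmb[2, r]), 0)
  }
  # symmetry of the dense matrix
  W <- network_matrix(net)
  expect_equal(W, t(W))
})

test_that("network edge cases: 2 siblings with annotated parent, thresholds", {
  dag <- toy_dag(list(row4("R"), row4("P", parents = "R"),
                      row4("A", parents = "P"), row4("B", parents = "P"),
                      row4("C", parents = "R")))
  ft <- count_frequencies(records_from_counts(c(A = 1, B = 1, C = 2)), dag)
  net <- build_similarity_network(ft, dag, node_ids = c("A", "B"))
  expect_equal(nrow(net), 1)
  expect_equal(net$weight, 0.5, tolerance = 1e-12)

  empty <- build_similarity_network(ft, dag, node_ids = c("A", "B"), threshold = 1.0)
  expect_equal(nrow(empty), 0)
  expect_error(build_similarity_network(ft, dag, node_ids = "A"),
               class = "dsim_validation_error")
})

test_that("association reader handles the CTD 9-field gene dialect and dedupe", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# CTD gene-disease associations",
    paste("GeneSymbol", "GeneID", "DiseaseName", "DiseaseID", "DirectEvidence",
          "InferenceChemicalName", "InferenceScore", "OmimIDs", "PubMedIDs",
          sep = "\t"),
    paste("FBN1", "2200", "Marfan Syndrome", "MESH:D008382", "marker", "", "", "", "1",
          sep = "\t"),
    paste("FBN1", "2200", "Marfan Syndrome", "MESH:D008382", "marker", "", "", "", "2",
          sep = "\t")
  ), tf)
  a <- read_associations(tf)
  expect_equal(nrow(a), 2)
  expect_equal(unique(a$disease_id), "MESH:D008382")
  expect_equal(nrow(read_associations(tf, dedupe = TRUE)), 1)
  expect_error(read_associations(tf, entity_col = "Nope"),
               class = "dsim_format_error")
})

test_that("network TSV round-trips with 6-decimal weights in sorted order", {
  dag <- random_dag(15, 5)
  set.seed(5)
  rec <- tibble::tibble(entity_id = paste0("e", 1:80),
                        disease_id = sample(dag$terms$disease_id, 80, replace = TRUE))
  net <- build_similarity_network(count_frequencies(rec, dag), dag,
                                  node_ids = dag$terms$disease_id)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, tf)
  back <- read_network_tsv(tf)
  expect_equal(back$id1, net$id1)
  expect_equal(back$weight, round(net$weight, 6))
  expect_equal(network_nodes(back), network_nodes(net))
  expect_false(is.unsorted(paste(net$id1, net$id2)))
})
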