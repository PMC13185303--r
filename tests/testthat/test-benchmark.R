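test_that("indication accuracy counts leave-one-out recoveries", {
  pl <- toy_pipeline()
  expect_equal(indication_accuracy(pl, c("A", "B", "C"), 2), 100 * 2 / 3)

  # perfect-duplicate limit: mutually nearest approved drugs
  dup <- pipeline_from_rows(list(
    A = c(B = 0, C = 1, D = 1), B = c(A = 0, C = 1, D = 1),
    C = c(A = 1, B = 1, D = 1), D = c(A = 1, B = 1, C = 1)
  ))
  for (cutoff in c(1, 2, 3)) {
    expect_equal(indication_accuracy(dup, c("A", "B"), cutoff), 100)
  }
  # miss case: approved drugs never in each other's top-N
  expect_equal(indication_accuracy(dup, c("C", "D"), 1), 0)

  expect_error(indication_accuracy(pl, "A", 2), ">= 2")
  expect_error(indication_accuracy(pl, c("A", "NOPE"), 2), "NOPE")
})

test_that("AIA is the unweighted mean of per-indication IA", {
  pl <- toy_pipeline()
  mp <- indication_mapping(list(I1 = c("A", "B", "C"), I2 = c("A", "B")))
  ia1 <- indication_accuracy(pl, c("A", "B", "C"), 2)
  ia2 <- indication_accuracy(pl, c("A", "B"), 2)
  expect_equal(average_indication_accuracy(pl, mp, 2), mean(c(ia1, ia2)))
  expect_equal(average_indication_accuracy(
    pl, indication_mapping(list(I1 = c("A", "B", "C"))), 2), ia1)
  expect_error(average_indication_accuracy(pl, indication_mapping(list()), 2),
               "empty")
})

test_that("consensus lists count votes with average-rank and id tie-breaks", {
  pl <- toy_pipeline()
  cons <- build_consensus_list(pl, c("A", "B", "C"), per_list_cutoff = 2)
  expect_equal(cons$compound_id[1], "D")
  expect_equal(cons$consensus_score[1], 3L)
  expect_equal(cons$average_score[1], (1 + 1 + 2) / 3)
  # consensus-1 block: E (avg 1) ahead of A and B (avg 2, id order)
  expect_equal(cons$compound_id, c("D", "E", "A", "B"))

  # one voter
  single <- build_consensus_list(pl, "A", 1)
  expect_equal(single$compound_id, "D")
  expect_equal(single$consensus_score, 1L)

  # disjoint top-1 lists: all consensus scores stay <= 1
  expect_true(all(build_consensus_list(pl, c("A", "C"), 1)$consensus_score <= 1))

  # zero-similarity neighbors never contribute votes
  far <- pipeline_from_rows(list(A = c(B = 1, X = 1), B = c(A = 1, X = 1),
                                 X = c(A = 1, B = 1)))
  expect_equal(nrow(build_consensus_list(far, c("A", "B"), 2)), 0L)
})

test_that("nIA measures approved recovery in the consensus head", {
  pl <- toy_pipeline()
  approved <- c("A", "B", "C")
  cons <- build_consensus_list(pl, approved, 2)
  expect_equal(new_indication_accuracy(cons, approved, 2), 0)    # top-2 = D, E
  expect_equal(new_indication_accuracy(cons, approved, 4),
               100 * 2 / 3)                                      # A, B inside
  expect_equal(new_indication_accuracy(cons, approved, 100), 100 * 2 / 3)
})

test_that("NDCG uses binary relevance with log2 discount and truncated ideal", {
  # two approved; the other approved drug sits at rank 3 of each list
  pl <- pipeline_from_rows(list(
    A = c(X = 0.1, Y = 0.2, B = 0.3, Z = 0.4),
    B = c(X = 0.1, Y = 0.2, A = 0.3, Z = 0.4),
    X = c(A = 0.1, B = 0.2, Y = 0.3, Z = 0.4),
    Y = c(A = 0.1, B = 0.2, X = 0.3, Z = 0.4),
    Z = c(A = 0.1, B = 0.2, X = 0.3, Y = 0.4)
  ))
  expect_equal(ndcg_for_indication(pl, c("A", "B"), 10), 1 / log2(4))  # 0.5
  expect_equal(ndcg_for_indication(pl, c("A", "B"), 2), 0)
  # ideal placement scores exactly 1
  dup <- pipeline_from_rows(list(
    A = c(B = 0, X = 1), B = c(A = 0, X = 1), X = c(A = 0.5, B = 0.6)
  ))
  for (cutoff in c(1, 5)) {
    expect_equal(ndcg_for_indication(dup, c("A", "B"), cutoff), 1)
  }
  expect_error(ndcg_for_indication(pl, "A", 10), ">= 2")
})

test_that("nNDCG applies the same construction to the consensus ordering", {
  # consensus with one approved (of 2) at consensus rank 2, cutoff 10
  pl <- pipeline_from_rows(list(
    A = c(X = 0.1, B = 0.2, Y = 0.8, Z = 0.9),
    B = c(X = 0.1, A = 0.2, Y = 0.8, Z = 0.9),
    X = c(Y = 0.1, Z = 0.2, A = 0.8, B = 0.9),
    Y = c(X = 0.1, Z = 0.2, A = 0.8, B = 0.9),
    Z = c(X = 0.1, Y = 0.2, A = 0.8, B = 0.9)
  ))
  cons <- build_consensus_list(pl, c("A", "B"), 2)
  # votes: X 2 (ranks 1,1), A 1 (rank 2), B 1 (rank 2) -> X, A, B
  expect_equal(cons$compound_id, c("X", "A", "B"))
  got <- n_ndcg_for_indication(cons[1:2, ], c("A", "B"), 10)
  expect_equal(got, (1 / log2(3)) / (1 / log2(2) + 1 / log2(3)),
               tolerance = 1e-4)                                  # 0.3869
  # approved occupying the whole head -> 1; absent from the head -> 0
  expect_equal(n_ndcg_for_indication(cons, c("X", "A", "B"), 10), 1)
  expect_equal(n_ndcg_for_indication(cons[1, ], c("A", "B"), 1), 0)
})

test_that("hypergeometric IA control matches hand values and enumeration", {
  expect_equal(hypergeometric_control_ia(10, 3, 3), 1 - 35 / 84)  # 0.58333
  expect_equal(hypergeometric_control_ia(10, 3, 9), 1)            # N = M - 1
  expect_equal(hypergeometric_control_ia(3, 2, 1), 0.5)
  expect_equal(hypergeometric_control_ia(10, 4, 7), 1)            # N > M - K
  expect_error(hypergeometric_control_ia(3, 4, 1), "M >= K")
  expect_error(hypergeometric_control_ia(10, 1, 1), "K >= 2")

  set.seed(21)
  for (i in 1:40) {
    M <- sample(4:11, 1)
    K <- sample(2:(M - 1), 1)
    N <- sample(1:(M - 1), 1)
    expect_equal(hypergeometric_control_ia(M, K, N),
                 oracle_hypergeom(M, K, N), tolerance = 1e-12,
                 info = sprintf("M=%d K=%d N=%d", M, K, N))
  }
})

test_that("run_benchmark composes the per-indication metrics and controls", {
  pl <- toy_pipeline()
  mp <- indication_mapping(list(I1 = c("A", "B", "C")))
  res <- run_benchmark(pl, mp, cutoffs = c(1, 2, 4))
  expect_s3_class(res, "benchmark_result")
  sub <- res$per_indication
  expect_equal(sub$ia[sub$cutoff == 2], 100 * 2 / 3)
  expect_equal(sub$nia[sub$cutoff == 2], 0)
  expect_equal(res$summary$aia, sub$ia)
  expect_equal(res$summary$aia_control,
               100 * vapply(c(1, 2, 4), function(n) {
                 hypergeometric_control_ia(5, 3, n)
               }, numeric(1)))
  expect_error(run_benchmark(pl, indication_mapping(list(I1 = "A")),
                             cutoffs = 2), "restrict")
  expect_error(run_benchmark(pl, mp, cutoffs = c(2, 2)), "increasing")

  # monte-carlo control populates the consensus-metric baselines and is
  # reproducible under the same seed
  res_mc1 <- run_benchmark(pl, mp, cutoffs = 2, control = "monte_carlo",
                           mc_reps = 30, seed = 5)
  res_mc2 <- run_benchmark(pl, mp, cutoffs = 2, control = "monte_carlo",
                           mc_reps = 30, seed = 5)
  expect_false(anyNA(res_mc1$summary$naia_control))
  expect_identical(res_mc1$summary, res_mc2$summary)
})

test_that("accuracy metrics never decrease with the cutoff", {
  set.seed(31)
  for (rep in 1:5) {
    pl <- random_pipeline(15, seed = 300 + rep)
    approved <- sample(pl$ids, 4)
    ias <- vapply(1:14, function(cc) {
      indication_accuracy(pl, approved, cc)
    }, numeric(1))
    expect_true(all(diff(ias) >= 0))
    cons <- build_consensus_list(pl, approved, per_list_cutoff = 10)
    nias <- vapply(1:14, function(cc) {
      new_indication_accuracy(cons, approved, cc)
    }, numeric(1))
    expect_true(all(diff(nias) >= 0))
  }
})

test_that("benchmark exports round-trip through TSV and JSON", {
  pl <- toy_pipeline()
  mp <- indication_mapping(list(I1 = c("A", "B", "C")))
  res <- run_benchmark(pl, mp, cutoffs = c(2, 4))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark_tsv(res, tsv)
  flat <- utils::read.delim(tsv)
  expect_equal(names(flat), c("pipeline", "metric", "cutoff", "value"))
  expect_equal(flat$value[flat$metric == "aia" & flat$cutoff == 2],
               100 * 2 / 3)
  js <- withr::local_tempfile(fileext = ".json")
  write_benchmark_json(res, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$summary$aia, res$summary$aia)
})
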