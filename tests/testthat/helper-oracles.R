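# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized/rank-matrix code paths. All of
# them work from a raw distance matrix `d` (diagonal ignored) and a
# character id vector.

# neighbor ids of `q` ordered by ascending distance, ties by id
oracle_neighbor_order <- function(d, ids, q) {
  qi <- which(ids == q)
  df <- data.frame(id = ids[-qi], dist = d[qi, -qi])
  df <- df[order(df$dist, rank(df$id, ties.method = "first")), ]
  df$id
}

oracle_ia <- function(d, ids, approved, cutoff) {
  hits <- 0
  for (a in approved) {
    top <- utils::head(oracle_neighbor_order(d, ids, a), cutoff)
    if (length(intersect(top, setdiff(approved, a))) > 0) {
      hits <- hits + 1
    }
  }
  100 * hits / length(approved)
}

oracle_ndcg <- function(d, ids, approved, cutoff) {
  vals <- numeric(0)
  for (a in approved) {
    nb <- oracle_neighbor_order(d, ids, a)
    rel <- nb %in% setdiff(approved, a)
    dcg <- 0
    for (j in seq_len(min(cutoff, length(nb)))) {
      if (rel[j]) dcg <- dcg + 1 / log2(j + 1)
    }
    idcg <- 0
    for (j in seq_len(min(length(approved) - 1, cutoff))) {
      idcg <- idcg + 1 / log2(j + 1)
    }
    vals <- c(vals, dcg / idcg)
  }
  mean(vals)
}

# consensus votes: appearances in voters' top-N with positive similarity
oracle_consensus <- function(d, ids, approved, cutoff) {
  votes <- stats::setNames(rep(0, length(ids)), ids)
  rsum <- stats::setNames(rep(0, length(ids)), ids)
  for (a in approved) {
    nb <- oracle_neighbor_order(d, ids, a)
    qi <- which(ids == a)
    for (j in seq_len(min(cutoff, length(nb)))) {
      dist_j <- d[qi, which(ids == nb[j])]
      if (dist_j < 1) {
        votes[nb[j]] <- votes[nb[j]] + 1
        rsum[nb[j]] <- rsum[nb[j]] + j
      }
    }
  }
  keep <- names(votes)[votes >= 1]
  out <- data.frame(compound_id = keep,
                    consensus_score = unname(votes[keep]),
                    average_score = unname(rsum[keep] / votes[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$consensus_score, out$average_score,
                   rank(out$compound_id, ties.method = "first")), ]
  row.names(out) <- NULL
  out
}

# P(random size-N subset of the M-1 non-query compounds hits >= 1 of the
# K-1 other approved) by exhaustive enumeration (tiny M only)
oracle_hypergeom <- function(M, K, N) {
  pool <- seq_len(M - 1)
  approved_others <- seq_len(K - 1)
  N <- min(N, M - 1)
  subsets <- utils::combn(pool, N)
  mean(apply(subsets, 2, function(s) any(s %in% approved_others)))
}

# P(X >= c), X ~ Binomial(n, p), by direct summation
oracle_binom_tail <- function(c, n, p) {
  if (c == 0) return(1)
  sum(vapply(c:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
             numeric(1)))
}

# docking-surrogate score by scanning all sites
oracle_score <- function(query, sites) {
  if (nrow(sites) == 0) return(0)
  best_dice <- -1
  best_conf <- -1
  for (i in seq_len(nrow(sites))) {
    dd <- dice_coefficient(query, sites$template[[i]])
    if (dd > best_dice || (dd == best_dice && sites$confidence[i] > best_conf)) {
      best_dice <- dd
      best_conf <- sites$confidence[i]
    }
  }
  best_dice * best_conf
}

# random pipeline fixture: symmetric random distances over M compounds
random_pipeline <- function(m, seed, name = "random") {
  set.seed(seed)
  ids <- sprintf("C%03d", seq_len(m))
  d <- matrix(0, m, m, dimnames = list(ids, ids))
  vals <- stats::runif(m * (m - 1) / 2, 0, 0.99)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  pipeline_lists(d, name = name)
}

random_fingerprint <- function(n_features = 12, space = 100) {
  fingerprint(sample.int(space, n_features))
}

# explicit pipeline from a per-query named distance list (asymmetric OK)
pipeline_from_rows <- function(rows) {
  ids <- names(rows)
  d <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  for (q in ids) {
    d[q, names(rows[[q]])] <- rows[[q]]
  }
  pipeline_lists(d, name = "toy")
}

# SimilarityList structural invariants shared by property tests
expect_valid_similarity_list <- function(pipeline, query) {
  sl <- similarity_list(pipeline, query)
  expect_false(query %in% sl$neighbor_id)
  expect_equal(sl$rank, seq_len(length(pipeline$ids) - 1))
  expect_true(all(diff(sl$distance) >= 0))
  expect_true(all(sl$distance >= 0 & sl$distance <= 1))
  ties <- split(sl$neighbor_id, sl$distance)
  for (grp in ties) {
    expect_equal(grp, sort(grp, method = "radix"))
  }
  invisible(sl)
}
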