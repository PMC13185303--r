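# Leave-one-out benchmarking of similarity pipelines against a
# drug-indication mapping: indication accuracy (IA) and its average (AIA),
# the consensus-list analogs nIA/nAIA, NDCG/nNDCG, and random controls
# (closed-form hypergeometric for IA, Monte-Carlo permutation for the
# consensus metrics).

.approved_in_universe <- function(approved, ids) {
  approved <- sort(unique(as.character(approved)), method = "radix")
  missing <- setdiff(approved, ids)
  if (length(missing) > 0) {
    stop("approved drug(s) not in the compound universe: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  approved
}

#' Indication accuracy (IA) at a rank cutoff
#'
#' Leave-one-out: for each approved drug of the indication, a success is
#' recorded when at least one *other* approved drug appears within the top
#' `cutoff` of its similarity list. IA is the percentage of approved drugs
#' with a success.
#'
#' @param pipeline a `pipeline_lists`.
#' @param approved character vector of approved compound ids (>= 2).
#' @param cutoff rank cutoff (top-N).
#' @param ranks optional precomputed [rank_matrix()] (performance hook).
#' @return percentage in \[0, 100\].
#' @export
indication_accuracy <- function(pipeline, approved, cutoff, ranks = NULL) {
  approved <- .approved_in_universe(approved, pipeline$ids)
  if (length(approved) < 2) {
    stop("indication accuracy needs >= 2 approved drugs", call. = FALSE)
  }
  if (is.null(ranks)) ranks <- rank_matrix(pipeline)
  r <- ranks[approved, approved, drop = FALSE]
  hits <- vapply(seq_along(approved), function(i) {
    any(r[i, -i] <= cutoff)
  }, logical(1))
  100 * mean(hits)
}

#' Average indication accuracy (AIA) at a rank cutoff
#'
#' Unweighted mean of per-indication IA over all indications in the mapping
#' (which should already be restricted to indications with >= 2 approved
#' drugs; see [restrict_to_benchmarkable()]).
#'
#' @param pipeline a `pipeline_lists`.
#' @param mapping an `indication_mapping`.
#' @param cutoff rank cutoff.
#' @param ranks optional precomputed [rank_matrix()].
#' @return percentage in \[0, 100\].
#' @export
average_indication_accuracy <- function(pipeline, mapping, cutoff,
                                        ranks = NULL) {
  if (length(mapping) == 0) {
    stop("empty indication mapping", call. = FALSE)
  }
  if (is.null(ranks)) ranks <- rank_matrix(pipeline)
  mean(vapply(mapping, indication_accuracy, numeric(1),
              pipeline = pipeline, cutoff = cutoff, ranks = ranks))
}

#' Build an indication's consensus list
#'
#' Every approved drug votes with its own similarity list (from which it is
#' itself absent). A compound receives one vote from each voter in whose top
#' `per_list_cutoff` it appears *with positive similarity* (distance < 1;
#' zero-similarity neighbors carry no evidence and do not contribute --
#' this is also what makes the uniqueness filter's zeroed pairs inert).
#' Compounds with at least one vote are ordered by descending consensus
#' score, then ascending average rank over the contributing lists, then
#' ascending compound id.
#'
#' @param pipeline a `pipeline_lists`.
#' @param approved character vector of approved compound ids (the voters).
#' @param per_list_cutoff voting cutoff (top-N of each voter's list).
#' @param ranks optional precomputed [rank_matrix()].
#' @return data.frame of class `consensus_list` with columns `compound_id`,
#'   `consensus_score`, `average_score`.
#' @export
build_consensus_list <- function(pipeline, approved, per_list_cutoff,
                                 ranks = NULL) {
  approved <- .approved_in_universe(approved, pipeline$ids)
  if (length(approved) < 1) {
    stop("need at least one approved drug to build a consensus list",
         call. = FALSE)
  }
  stopifnot(per_list_cutoff >= 1)
  if (is.null(ranks)) ranks <- rank_matrix(pipeline)
  r <- ranks[approved, pipeline$ids, drop = FALSE]
  d <- pipeline$dist[approved, pipeline$ids, drop = FALSE]
  contributes <- !is.na(r) & r <= per_list_cutoff & d < 1
  votes <- colSums(contributes)
  rsum <- colSums(r * contributes, na.rm = TRUE)
  keep <- which(votes >= 1)
  out <- data.frame(compound_id = pipeline$ids[keep],
                    consensus_score = as.integer(votes[keep]),
                    average_score = rsum[keep] / votes[keep],
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  ord <- order(-out$consensus_score, out$average_score,
               .id_rank(out$compound_id))
  out <- out[ord, , drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("consensus_list", "data.frame")
  out
}

#' New indication accuracy (nIA) at a consensus-list cutoff
#'
#' Percentage of the indication's approved drugs found within the top
#' `cutoff` entries of the indication's consensus list.
#'
#' @param consensus a `consensus_list` built from the same approved set.
#' @param approved character vector of approved compound ids.
#' @param cutoff rank cutoff into the consensus list.
#' @return percentage in \[0, 100\].
#' @export
new_indication_accuracy <- function(consensus, approved, cutoff) {
  approved <- sort(unique(as.character(approved)), method = "radix")
  head_ids <- consensus$compound_id[seq_len(min(cutoff, nrow(consensus)))]
  100 * length(intersect(approved, head_ids)) / length(approved)
}

#' NDCG of approved-drug placement in similarity lists
#'
#' Binary relevance with the standard logarithmic discount: for each
#' approved query drug, position `j` of its similarity list is relevant iff
#' occupied by another approved drug; `DCG@c = sum rel_j / log2(j + 1)` and
#' the ideal DCG packs the `min(|approved| - 1, cutoff)` relevant items into
#' the head. The indication's NDCG is the mean over its approved queries.
#'
#' @inheritParams indication_accuracy
#' @return value in \[0, 1\].
#' @export
ndcg_for_indication <- function(pipeline, approved, cutoff, ranks = NULL) {
  approved <- .approved_in_universe(approved, pipeline$ids)
  if (length(approved) < 2) {
    stop("NDCG needs >= 2 approved drugs", call. = FALSE)
  }
  if (is.null(ranks)) ranks <- rank_matrix(pipeline)
  r <- ranks[approved, approved, drop = FALSE]
  idcg <- sum(1 / log2(seq_len(min(length(approved) - 1L, cutoff)) + 1))
  per_query <- vapply(seq_along(approved), function(i) {
    pos <- r[i, -i]
    pos <- pos[pos <= cutoff]
    sum(1 / log2(pos + 1)) / idcg
  }, numeric(1))
  mean(per_query)
}

#' NDCG of approved-drug placement in the consensus list (nNDCG)
#'
#' Same DCG construction applied once to the consensus ordering, relevance
#' 1 for approved drugs, ideal DCG over `min(|approved|, cutoff)` head
#' positions.
#'
#' @inheritParams new_indication_accuracy
#' @return value in \[0, 1\].
#' @export
n_ndcg_for_indication <- function(consensus, approved, cutoff) {
  approved <- sort(unique(as.character(approved)), method = "radix")
  stopifnot(length(approved) >= 1, cutoff >= 1)
  head_ids <- consensus$compound_id[seq_len(min(cutoff, nrow(consensus)))]
  pos <- which(head_ids %in% approved)
  idcg <- sum(1 / log2(seq_len(min(length(approved), cutoff)) + 1))
  sum(1 / log2(pos + 1)) / idcg
}

#' Closed-form chance of recovering an approved drug in a random top-N
#'
#' A query's similarity list is a ranking of the other `M - 1` compounds,
#' `K - 1` of which are the other approved drugs. Under random ranking the
#' top `N` is a uniform size-`N` subset, so the probability of at least one
#' hit is hypergeometric: `1 - C(M - K, N) / C(M - 1, N)` (1 when
#' `N > M - K`). `100 *` this value is the expected IA of a random pipeline
#' -- the benchmark's chance baseline.
#'
#' @param M compound universe size.
#' @param K number of approved drugs for the indication.
#' @param N rank cutoff.
#' @return probability in \[0, 1\].
#' @export
hypergeometric_control_ia <- function(M, K, N) {
  if (M < K || K < 2 || N < 1) {
    stop("need M >= K >= 2 and N >= 1", call. = FALSE)
  }
  N <- min(N, M - 1)
  stats::phyper(0, K - 1, M - K, N, lower.tail = FALSE)
}

# metric computation shared by run_benchmark and its Monte-Carlo control;
# works from a rank matrix + distance matrix so null replicates are cheap.
.benchmark_metrics <- function(pipeline, ranks, mapping, cutoffs,
                               voting_cutoff = NULL) {
  rows <- vector("list", length(mapping) * length(cutoffs))
  k <- 0L
  for (ind in names(mapping)) {
    approved <- mapping[[ind]]
    for (cutoff in cutoffs) {
      vc <- if (is.null(voting_cutoff)) cutoff else voting_cutoff
      cons <- build_consensus_list(pipeline, approved, vc, ranks = ranks)
      k <- k + 1L
      rows[[k]] <- data.frame(
        indication = ind,
        n_approved = length(approved),
        cutoff = cutoff,
        ia = indication_accuracy(pipeline, approved, cutoff, ranks = ranks),
        nia = new_indication_accuracy(cons, approved, cutoff),
        ndcg = ndcg_for_indication(pipeline, approved, cutoff, ranks = ranks),
        nndcg = n_ndcg_for_indication(cons, approved, cutoff),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

.null_pipeline <- function(ids) {
  m <- length(ids)
  d <- matrix(1, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    d[i, -i] <- sample.int(m - 1L) / m
  }
  pipeline_lists(d, name = "null")
}

#' Benchmark a pipeline against an indication mapping
#'
#' Computes IA, nIA, NDCG and nNDCG per indication at every cutoff, their
#' unweighted aggregates (AIA, nAIA, mean NDCG, mean nNDCG), and random
#' controls. The IA control is always the closed-form hypergeometric
#' expectation ([hypergeometric_control_ia()], averaged over indications);
#' with `control = "monte_carlo"` the remaining metrics are also given
#' seeded permutation controls (each voter list replaced by a uniformly
#' random ranking, `mc_reps` replicates, means reported).
#'
#' @param pipeline a `pipeline_lists`.
#' @param mapping benchmarkable `indication_mapping` (every indication with
#'   >= 2 approved drugs; see [restrict_to_benchmarkable()]).
#' @param cutoffs strictly increasing rank cutoffs (default 10, 25, 50, 100).
#' @param control `"closed_form"` (default; consensus-metric controls NA) or
#'   `"monte_carlo"`.
#' @param voting_cutoff consensus voting cutoff; default NULL means "use the
#'   evaluation cutoff at each cutoff level".
#' @param mc_reps Monte-Carlo replicates for the permutation control.
#' @param seed integer seed for the permutation control.
#' @return object of class `benchmark_result`: list with `pipeline`,
#'   `per_indication` (data.frame), `summary` (one row per cutoff with
#'   aggregates and controls), and `params`.
#' @export
run_benchmark <- function(pipeline, mapping, cutoffs = c(10, 25, 50, 100),
                          control = c("closed_form", "monte_carlo"),
                          voting_cutoff = NULL, mc_reps = 100, seed = 1L) {
  control <- match.arg(control)
  if (length(mapping) == 0) {
    stop("empty indication mapping", call. = FALSE)
  }
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be strictly increasing", call. = FALSE)
  }
  small <- names(mapping)[lengths(mapping) < 2]
  if (length(small) > 0) {
    stop("indication(s) with < 2 approved drugs (restrict the mapping first): ",
         paste(utils::head(small, 5L), collapse = ", "), call. = FALSE)
  }
  ranks <- rank_matrix(pipeline)
  per_ind <- .benchmark_metrics(pipeline, ranks, mapping, cutoffs,
                                voting_cutoff)
  M <- length(pipeline$ids)
  agg <- do.call(rbind, lapply(cutoffs, function(cutoff) {
    sub <- per_ind[per_ind$cutoff == cutoff, , drop = FALSE]
    data.frame(
      cutoff = cutoff,
      aia = mean(sub$ia),
      naia = mean(sub$nia),
      mean_ndcg = mean(sub$ndcg),
      mean_nndcg = mean(sub$nndcg),
      aia_control = 100 * mean(vapply(mapping, function(ap) {
        hypergeometric_control_ia(M, length(ap), cutoff)
      }, numeric(1))),
      naia_control = NA_real_,
      ndcg_control = NA_real_,
      nndcg_control = NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  if (control == "monte_carlo") {
    set.seed(seed)
    acc <- matrix(0, length(cutoffs), 4L,
                  dimnames = list(NULL, c("ia", "nia", "ndcg", "nndcg")))
    for (rep in seq_len(mc_reps)) {
      np <- .null_pipeline(pipeline$ids)
      nr <- rank_matrix(np)
      nm <- .benchmark_metrics(np, nr, mapping, cutoffs, voting_cutoff)
      for (ci in seq_along(cutoffs)) {
        sub <- nm[nm$cutoff == cutoffs[ci], , drop = FALSE]
        acc[ci, ] <- acc[ci, ] + c(mean(sub$ia), mean(sub$nia),
                                   mean(sub$ndcg), mean(sub$nndcg))
      }
    }
    acc <- acc / mc_reps
    agg$naia_control <- acc[, "nia"]
    agg$ndcg_control <- acc[, "ndcg"]
    agg$nndcg_control <- acc[, "nndcg"]
  }
  structure(list(pipeline = pipeline$name,
                 per_indication = per_ind,
                 summary = agg,
                 params = list(cutoffs = cutoffs, control = control,
                               voting_cutoff = voting_cutoff,
                               mc_reps = if (control == "monte_carlo") mc_reps
                                         else NULL,
                               seed = if (control == "monte_carlo") seed
                                      else NULL,
                               n_compounds = M,
                               n_indications = length(mapping))),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> pipeline '", x$pipeline, "': ",
      x$params$n_indications, " indications, ",
      x$params$n_compounds, " compounds\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export benchmark results
#'
#' `write_benchmark_json()` writes the full result (per-indication and
#' summary tables) as JSON; `write_benchmark_tsv()` writes a flat
#' `pipeline / metric / cutoff / value` table of the aggregates.
#'
#' @param result a `benchmark_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_benchmark_json
#' @export
write_benchmark_tsv <- function(result, path) {
  s <- result$summary
  long <- do.call(rbind, lapply(
    c("aia", "naia", "mean_ndcg", "mean_nndcg",
      "aia_control", "naia_control", "ndcg_control", "nndcg_control"),
    function(metric) data.frame(pipeline = result$pipeline, metric = metric,
                                cutoff = s$cutoff, value = s[[metric]],
                                stringsAsFactors = FALSE)
  ))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
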