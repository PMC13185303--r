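# Top-target extraction per compound and gold-standard overlap analyses:
# rank-bin frequencies, cumulative overlap as a function of rank cutoff,
# and Jaccard coefficients, for top / random / bottom candidate groups.

#' Top predicted protein targets of a compound
#'
#' The `k` proteins with the highest interaction score in the compound's
#' signature, ranked; score ties are broken by ascending protein id.
#'
#' @param matrix interaction matrix (compounds x proteins).
#' @param compound_id compound to rank targets for.
#' @param k number of targets to keep; `NULL` (default) returns the full
#'   ranking.
#' @return data.frame with columns `protein_id`, `score`, `target_rank`.
#' @export
top_targets <- function(matrix, compound_id, k = NULL) {
  i <- match(compound_id, rownames(matrix))
  if (is.na(i)) {
    stop("unknown compound id: ", compound_id, call. = FALSE)
  }
  row <- matrix[i, ]
  ord <- order(-row, .id_rank(colnames(matrix)))
  if (!is.null(k)) {
    ord <- ord[seq_len(min(k, length(ord)))]
  }
  data.frame(protein_id = colnames(matrix)[ord],
             score = unname(row[ord]),
             target_rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Full target rankings for a set of compounds
#'
#' @param matrix interaction matrix.
#' @param compound_ids compounds to rank targets for.
#' @param k per-compound target count (`NULL` = full ranking).
#' @return named list of [top_targets()] data.frames.
#' @export
target_rankings <- function(matrix, compound_ids, k = NULL) {
  stats::setNames(lapply(compound_ids, top_targets, matrix = matrix, k = k),
                  compound_ids)
}

#' Jaccard coefficient of two sets
#'
#' `|A n B| / |A u B|`; 0 when both sets are empty.
#'
#' @param a,b vectors treated as sets.
#' @return value in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    return(0)
  }
  length(intersect(a, b)) / u
}

# best (minimum) predicted rank of each gold protein across a candidate
# group's target rankings; proteins never ranked get Inf
.best_ranks <- function(rankings, proteins) {
  best <- rep(Inf, length(proteins))
  names(best) <- proteins
  for (rk in rankings) {
    ok <- rk$protein_id %in% proteins
    if (!any(ok)) next
    agg <- tapply(rk$target_rank[ok], rk$protein_id[ok], min)
    best[names(agg)] <- pmin(best[names(agg)], agg)
  }
  best
}

#' Rank-bin frequency distribution of gold-standard overlap
#'
#' Pools a candidate group's target rankings by the best (minimum) rank of
#' each gold-standard protein across the group, and counts gold proteins
#' whose best rank falls into each bin (`1..bin_width`,
#' `bin_width+1..2*bin_width`, ... up to `max_rank`). Proportions are
#' reported both within-group (normalized by the number of overlapping gold
#' proteins) and against the full gold set.
#'
#' @param rankings list of [top_targets()] data.frames (one per candidate).
#' @param gold gold-standard set: list with `proteins`, or a character
#'   vector.
#' @param bin_width bin width in rank units (default 20).
#' @param max_rank largest rank considered (default 100); must be a
#'   multiple of `bin_width`.
#' @return data.frame with columns `bin_start`, `bin_end`, `count`,
#'   `proportion` (within overlapping proteins), `proportion_of_gold`.
#' @export
rank_bin_frequencies <- function(rankings, gold, bin_width = 20,
                                 max_rank = 100) {
  if (max_rank %% bin_width != 0) {
    stop("max_rank must be divisible by bin_width", call. = FALSE)
  }
  proteins <- if (is.list(gold)) gold$proteins else gold
  best <- .best_ranks(rankings, proteins)
  inside <- best[best <= max_rank]
  n_bins <- max_rank %/% bin_width
  counts <- tabulate(ceiling(inside / bin_width), nbins = n_bins)
  total <- sum(counts)
  data.frame(
    bin_start = (seq_len(n_bins) - 1L) * bin_width + 1L,
    bin_end = seq_len(n_bins) * bin_width,
    count = counts,
    proportion = if (total > 0) counts / total else rep(0, n_bins),
    proportion_of_gold = counts / length(proteins)
  )
}

#' Cumulative gold-standard overlap as a function of rank cutoff
#'
#' Per cutoff `c`: the percentage of gold-standard proteins whose best
#' predicted rank across the candidate group is `<= c`. Non-decreasing in
#' the cutoff by construction.
#'
#' @inheritParams rank_bin_frequencies
#' @param cutoffs rank cutoffs (default 10, 20, ..., 100).
#' @return data.frame with columns `cutoff`, `percent_overlap`.
#' @export
cumulative_overlap <- function(rankings, gold, cutoffs = seq(10, 100, 10)) {
  proteins <- if (is.list(gold)) gold$proteins else gold
  if (length(proteins) == 0) {
    stop("empty gold-standard set", call. = FALSE)
  }
  best <- .best_ranks(rankings, proteins)
  data.frame(
    cutoff = cutoffs,
    percent_overlap = vapply(cutoffs, function(cc) {
      100 * sum(best <= cc) / length(proteins)
    }, numeric(1))
  )
}

#' Jaccard coefficient between a candidate group's top targets and a gold set
#'
#' `A` = union over candidates of proteins ranked `<= rank_cutoff` in the
#' candidate's target ranking; `B` = the gold set; returns `J(A, B)`.
#'
#' @inheritParams rank_bin_frequencies
#' @param rank_cutoff per-candidate target rank cutoff (default 10).
#' @return value in \[0, 1\].
#' @export
candidate_set_jaccard <- function(rankings, gold, rank_cutoff = 10) {
  proteins <- if (is.list(gold)) gold$proteins else gold
  a <- unique(unlist(lapply(rankings, function(rk) {
    rk$protein_id[rk$target_rank <= rank_cutoff]
  }), use.names = FALSE))
  jaccard(a, proteins)
}

#' Compare top / random / bottom candidate groups against gold standards
#'
#' For each group and each gold standard: rank-bin frequencies, cumulative
#' overlap and the candidate-set Jaccard coefficient. The random group is
#' drawn uniformly (without replacement) from the compound universe with
#' the recorded seed, matching the top group's size; the bottom group is
#' expected to have been pre-filtered for chemical meaningfulness (e.g.
#' [heavy_atom_filter()] with 5 or more heavy atoms).
#'
#' @param matrix interaction matrix.
#' @param top_ids,bottom_ids compound ids of the top- and bottom-ranked
#'   candidate groups.
#' @param gold_standards named list of gold-standard sets (each a list with
#'   `proteins`, or a character vector).
#' @param seed integer seed for the random group draw.
#' @param rank_cutoff Jaccard rank cutoff (default 10).
#' @param max_rank per-compound ranking depth for bins/overlap (default
#'   100).
#' @return nested list: `groups` (membership per group) and `reports`
#'   (per group, per gold standard: `bins`, `cumulative`, `jaccard`).
#' @export
compare_candidate_groups <- function(matrix, top_ids, bottom_ids,
                                     gold_standards, seed = 1L,
                                     rank_cutoff = 10, max_rank = 100) {
  universe <- rownames(matrix)
  for (ids in list(top_ids, bottom_ids)) {
    missing <- setdiff(ids, universe)
    if (length(missing) > 0) {
      stop("candidate(s) not in the interaction matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (length(top_ids) > length(universe)) {
    stop("candidate group larger than the compound universe", call. = FALSE)
  }
  set.seed(seed)
  random_ids <- sample(universe, length(top_ids))
  groups <- list(top = top_ids, random = random_ids, bottom = bottom_ids)
  reports <- lapply(groups, function(ids) {
    rankings <- target_rankings(matrix, ids, k = max_rank)
    lapply(gold_standards, function(gold) {
      list(bins = rank_bin_frequencies(rankings, gold, max_rank = max_rank),
           cumulative = cumulative_overlap(rankings, gold),
           jaccard = candidate_set_jaccard(rankings, gold, rank_cutoff))
    })
  })
  list(groups = groups, reports = reports, seed = seed)
}
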