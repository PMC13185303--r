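# Candidate prediction for one indication: consensus votes across the
# approved drugs' similarity lists, average rank, and a binomial tail
# probability for the observed vote count under random ranking.

#' Upper binomial tail probability
#'
#' `P(X >= c)` for `X ~ Binomial(n, p)`: the chance that a compound collects
#' at least `c` votes when each of `n` voting lists independently contains
#' it in the voting window with probability `p`. Computed via the stable
#' cumulative distribution in [stats::pbinom()].
#'
#' @param c observed vote count, `0 <= c <= n`.
#' @param n number of voting lists.
#' @param p per-list success probability.
#' @return probability in \[0, 1\].
#' @export
#' @examples
#' binomial_tail_probability(2, 3, 0.5)
binomial_tail_probability <- function(c, n, p) {
  if (c < 0 || c > n || p < 0 || p > 1 || n < 0) {
    stop("need 0 <= c <= n and 0 <= p <= 1", call. = FALSE)
  }
  if (c == 0) {
    return(1)
  }
  stats::pbinom(c - 1, n, p, lower.tail = FALSE)
}

#' Predict ranked drug candidates for an indication
#'
#' Builds the indication's consensus list (voters = approved drugs, each
#' voting with its top `per_list_cutoff` neighbors; see
#' [build_consensus_list()]) and annotates every entry with the binomial
#' tail probability of its consensus score under random ranking, with
#' per-list success probability `p = per_list_cutoff / (M - 1)` (`M` =
#' compound universe size). Entries that are themselves approved for the
#' indication are retained and flagged in the `approved` column (drop them
#' downstream for a strictly novel candidate list), then the list is
#' truncated to `top_k`.
#'
#' @param pipeline a `pipeline_lists`.
#' @param approved character vector of approved compound ids for the
#'   indication.
#' @param per_list_cutoff voting cutoff into each approved drug's list
#'   (default 100).
#' @param top_k number of candidates to keep (default 100).
#' @param exclude_approved drop the indication's own approved drugs before
#'   truncation (default FALSE).
#' @param ranks optional precomputed [rank_matrix()].
#' @return data.frame of class `consensus_list` with columns `drug_rank`,
#'   `compound_id`, `consensus_score`, `average_score`, `probability`,
#'   `approved`.
#' @export
predict_candidates <- function(pipeline, approved, per_list_cutoff = 100,
                               top_k = 100, exclude_approved = FALSE,
                               ranks = NULL) {
  approved <- .approved_in_universe(approved, pipeline$ids)
  if (length(approved) == 0) {
    stop("approved set must be non-empty", call. = FALSE)
  }
  cons <- build_consensus_list(pipeline, approved, per_list_cutoff,
                               ranks = ranks)
  M <- length(pipeline$ids)
  p <- per_list_cutoff / (M - 1)
  cons$probability <- vapply(cons$consensus_score,
                             binomial_tail_probability, numeric(1),
                             n = length(approved), p = min(p, 1))
  cons$approved <- cons$compound_id %in% approved
  if (exclude_approved) {
    cons <- cons[!cons$approved, , drop = FALSE]
  }
  cons <- utils::head(cons, top_k)
  out <- cbind(data.frame(drug_rank = seq_len(nrow(cons))), cons)
  row.names(out) <- NULL
  class(out) <- c("consensus_list", "data.frame")
  out
}

#' Write a prediction table to TSV
#'
#' Columns (in order): `drug_rank`, `consensus_score`, `average_score`,
#' `probability`, `drug_name`. `drug_name` falls back to the compound id
#' when no name table is supplied.
#'
#' @param predictions output of [predict_candidates()].
#' @param path output path.
#' @param names optional named character vector mapping compound id to
#'   display name.
#' @return `path`, invisibly.
#' @export
export_prediction_table <- function(predictions, path, names = NULL) {
  nm <- predictions$compound_id
  if (!is.null(names)) {
    hit <- !is.na(names[nm])
    nm[hit] <- names[nm][hit]
  }
  out <- data.frame(drug_rank = predictions$drug_rank,
                    consensus_score = predictions$consensus_score,
                    average_score = predictions$average_score,
                    probability = predictions$probability,
                    drug_name = nm,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table written by [export_prediction_table()]
#'
#' @param path path to the TSV file.
#' @return data.frame with the five prediction-table columns.
#' @export
read_prediction_table <- function(path) {
  utils::read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = c(drug_rank = "integer",
                                   consensus_score = "integer",
                                   average_score = "numeric",
                                   probability = "numeric",
                                   drug_name = "character"),
                    quote = "")
}
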