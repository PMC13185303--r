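# Ranked compound-compound similarity pipelines. A pipeline is represented
# by its full pairwise distance matrix (diagonal NA); ranked similarity
# lists are derived on demand under one global ordering contract:
# ascending distance, ties broken by C-locale lexicographic compound id.

#' Construct a pipeline of ranked similarity lists
#'
#' @param dist square numeric matrix of pairwise distances in \[0, 1\] with
#'   identical row/column compound ids; the diagonal is ignored (set to NA).
#' @param name pipeline name (e.g. `"proteomic"`, `"tanimoto"`).
#' @return object of class `pipeline_lists`.
#' @export
pipeline_lists <- function(dist, name = "pipeline") {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) {
    stop("pipeline distance matrix must be square", call. = FALSE)
  }
  ids <- rownames(dist)
  if (is.null(ids) || !identical(ids, colnames(dist))) {
    stop("pipeline distance matrix must have matching compound id dimnames",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate compound id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  diag(dist) <- NA_real_
  off <- dist[!diag(nrow(dist))]
  if (anyNA(off) || any(off < 0) || any(off > 1)) {
    stop("pipeline distances must lie in [0,1]", call. = FALSE)
  }
  structure(list(name = name, ids = ids, dist = dist),
            class = "pipeline_lists")
}

#' @export
print.pipeline_lists <- function(x, ...) {
  cat("<pipeline_lists> '", x$name, "': ", length(x$ids),
      " compounds\n", sep = "")
  invisible(x)
}

# integer tie-break key: position of each id in C-locale sorted order
.id_rank <- function(ids) {
  r <- integer(length(ids))
  r[order(ids, method = "radix")] <- seq_along(ids)
  r
}

#' Extract one compound's ranked similarity list
#'
#' Neighbors are all other compounds sorted by ascending distance, ties by
#' lexicographic compound id; ranks run 1..(M-1) with no gaps.
#'
#' @param pipeline a `pipeline_lists`.
#' @param query compound id.
#' @return data.frame with columns `neighbor_id`, `distance`, `rank`.
#' @export
similarity_list <- function(pipeline, query) {
  i <- match(query, pipeline$ids)
  if (is.na(i)) {
    stop("unknown compound id: ", query, call. = FALSE)
  }
  d <- pipeline$dist[i, ]
  keep <- seq_along(d) != i
  ord <- order(d[keep], .id_rank(pipeline$ids[keep]))
  nb <- pipeline$ids[keep][ord]
  data.frame(neighbor_id = nb,
             distance = unname(d[keep][ord]),
             rank = seq_along(nb),
             stringsAsFactors = FALSE)
}

#' Rank matrix of a pipeline
#'
#' `R[q, n]` is the rank of neighbor `n` in query `q`'s similarity list
#' (diagonal NA). All benchmarking metrics are computed from this matrix.
#'
#' @param pipeline a `pipeline_lists`.
#' @return integer matrix with the pipeline's compound ids as dimnames.
#' @export
rank_matrix <- function(pipeline) {
  ids <- pipeline$ids
  m <- length(ids)
  idr <- .id_rank(ids)
  out <- matrix(NA_integer_, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    keep <- which(seq_len(m) != i)
    ord <- keep[order(pipeline$dist[i, keep], idr[keep])]
    out[i, ord] <- seq_len(m - 1L)
  }
  out
}

#' Cosine distance between two signature vectors
#'
#' `1 - x.y / (|x| |y|)` for non-negative vectors, so the result lies in
#' \[0, 1\]. If exactly one vector is all-zero the distance is 1 (no shared
#' signal); if both are all-zero it is 0 (indistinguishable signatures).
#'
#' @param x,y numeric vectors of equal length with non-negative entries.
#' @return distance in \[0, 1\].
#' @export
#' @examples
#' cosine_distance(c(1, 1), c(1, 0))
cosine_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop("signature vectors differ in length", call. = FALSE)
  }
  if (any(x < 0) || any(y < 0)) {
    stop("signature vectors must be non-negative", call. = FALSE)
  }
  nx <- sqrt(sum(x * x))
  ny <- sqrt(sum(y * y))
  if (nx == 0 && ny == 0) {
    return(0)
  }
  if (nx == 0 || ny == 0) {
    return(1)
  }
  min(max(1 - sum(x * y) / (nx * ny), 0), 1)
}

#' Build the proteomic similarity pipeline
#'
#' All-against-all cosine distances between compound-proteome interaction
#' signatures (rows of the interaction matrix), used unscaled and uncentered.
#'
#' @param matrix interaction matrix (compounds x proteins).
#' @return `pipeline_lists` named `"proteomic"`.
#' @export
build_proteomic_lists <- function(matrix) {
  validate_interaction_matrix(matrix)
  m <- nrow(matrix)
  if (m < 2) {
    stop("need at least 2 compounds to build similarity lists", call. = FALSE)
  }
  norms <- sqrt(rowSums(matrix^2))
  nz <- norms > 0
  xn <- matrix
  xn[nz, ] <- matrix[nz, , drop = FALSE] / norms[nz]
  d <- 1 - tcrossprod(xn)
  # zero-signature rows: distance 1 to any non-zero row, 0 to other zero rows
  if (any(!nz)) {
    d[!nz, ] <- 1
    d[, !nz] <- 1
    d[!nz, !nz] <- 0
  }
  d[d < 0] <- 0
  d[d > 1] <- 1
  pipeline_lists(d, name = "proteomic")
}

#' Build the ligand-fingerprint similarity pipeline
#'
#' All-against-all `1 - Tanimoto` distances between compound fingerprints:
#' the unfiltered fingerprint baseline.
#'
#' @param fingerprints named list of compound fingerprints.
#' @return `pipeline_lists` named `"tanimoto"`.
#' @export
build_tanimoto_lists <- function(fingerprints) {
  ids <- names(fingerprints)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every compound must be named in the fingerprint list", call. = FALSE)
  }
  no_fp <- vapply(fingerprints, is.null, logical(1))
  if (any(no_fp)) {
    stop("compound(s) lacking a fingerprint: ",
         paste(ids[no_fp], collapse = ", "), call. = FALSE)
  }
  m <- length(fingerprints)
  if (m < 2) {
    stop("need at least 2 compounds to build similarity lists", call. = FALSE)
  }
  d <- matrix(0, m, m, dimnames = list(ids, ids))
  sizes <- lengths(fingerprints)
  for (i in seq_len(m - 1L)) {
    fi <- fingerprints[[i]]
    for (j in seq.int(i + 1L, m)) {
      inter <- length(intersect(fi, fingerprints[[j]]))
      uni <- sizes[i] + sizes[j] - inter
      t <- if (uni == 0) 0 else inter / uni
      d[i, j] <- d[j, i] <- 1 - t
    }
  }
  pipeline_lists(d, name = "tanimoto")
}

#' Suppress near-duplicate analogs with a per-list uniqueness filter
#'
#' For each query list of length `L`, the `k = ceiling(top_fraction * L)`
#' most-similar neighbors (standard ordering: ascending distance, ties by
#' id) have their similarity set to zero -- i.e. their distance set to 1 --
#' and the list is re-sorted. Filtered pairs stay in the list, so list
#' lengths and cutoff arithmetic are unchanged, but they no longer
#' contribute to top-N recovery or consensus votes. An absolute-similarity
#' mode (`threshold`) is available for sensitivity checks: all pairs with
#' similarity `>= threshold` are zeroed instead.
#'
#' @param pipeline a `pipeline_lists`.
#' @param top_fraction fraction of each list to zero (default 0.02, the
#'   "highest two percent").
#' @param threshold optional absolute similarity threshold; when given it
#'   replaces the percentile rule.
#' @return `pipeline_lists` named `"<name>_filtered"`.
#' @export
apply_uniqueness_filter <- function(pipeline, top_fraction = 0.02,
                                    threshold = NULL) {
  d <- pipeline$dist
  m <- nrow(d)
  idr <- .id_rank(pipeline$ids)
  if (is.null(threshold)) {
    if (top_fraction <= 0 || top_fraction >= 1) {
      stop("top_fraction must lie in (0, 1)", call. = FALSE)
    }
    k <- as.integer(ceiling(top_fraction * (m - 1L)))
    for (i in seq_len(m)) {
      keep <- which(seq_len(m) != i)
      sel <- keep[order(d[i, keep], idr[keep])][seq_len(k)]
      d[i, sel] <- 1
    }
  } else {
    stopifnot(threshold > 0, threshold <= 1)
    for (i in seq_len(m)) {
      keep <- seq_len(m) != i
      sel <- keep & (1 - pipeline$dist[i, ]) >= threshold
      sel[is.na(sel)] <- FALSE
      d[i, sel] <- 1
    }
  }
  pipeline_lists(d, name = paste0(pipeline$name, "_filtered"))
}

.check_same_universe <- function(a, b) {
  if (!identical(sort(a$ids, method = "radix"),
                 sort(b$ids, method = "radix"))) {
    stop("pipelines cover different compound universes", call. = FALSE)
  }
}

#' Fuse two pipelines by the product of similarity scores
#'
#' Per query/neighbor pair, each pipeline's distance is converted to a
#' similarity (`1 - d`), the two similarities are multiplied, and the
#' product is converted back: `d_f = 1 - (1 - d_a) (1 - d_b)`. Lists are
#' re-ranked under the standard ordering.
#'
#' @param a,b `pipeline_lists` over the same compound universe.
#' @return `pipeline_lists` named `"fusion_score_product"`.
#' @export
fuse_score_product <- function(a, b) {
  .check_same_universe(a, b)
  db <- b$dist[a$ids, a$ids]
  d <- 1 - (1 - a$dist) * (1 - db)
  pipeline_lists(d, name = "fusion_score_product")
}

#' Fuse two pipelines by a rank (or distance-product) operator
#'
#' Per query/neighbor pair a fused key is computed -- the minimum, maximum,
#' mean, sum or product of the two ranks, or the product of the two
#' distances (`"distance_product"`) -- and neighbors are re-sorted by
#' ascending key, ties by id. Rank keys are divided by their maximum
#' attainable value (a strictly monotone rescaling that leaves the ordering
#' untouched) so the fused pipeline still carries distances in \[0, 1\].
#'
#' @param a,b `pipeline_lists` over the same compound universe.
#' @param operator one of `"min"`, `"max"`, `"mean"`, `"sum"`, `"product"`,
#'   `"distance_product"`.
#' @return `pipeline_lists` named `"fusion_rank_<operator>"` (or
#'   `"fusion_distance_product"`).
#' @export
fuse_ranks <- function(a, b, operator = c("min", "max", "mean", "sum",
                                          "product", "distance_product")) {
  operator <- match.arg(operator)
  .check_same_universe(a, b)
  m <- length(a$ids)
  if (operator == "distance_product") {
    db <- b$dist[a$ids, a$ids]
    d <- a$dist * db
    return(pipeline_lists(d, name = "fusion_distance_product"))
  }
  ra <- rank_matrix(a)
  rb <- rank_matrix(b)[a$ids, a$ids]
  key <- switch(operator,
    min = pmin(ra, rb) / (m - 1),
    max = pmax(ra, rb) / (m - 1),
    mean = (ra + rb) / (2 * (m - 1)),
    sum = (ra + rb) / (2 * (m - 1)),
    product = (ra * rb) / ((m - 1)^2)
  )
  pipeline_lists(key, name = paste0("fusion_rank_", operator))
}

#' Write a pipeline's similarity lists to TSV
#'
#' Columns: `query_id`, `neighbor_id`, `distance`, `rank`; one block per
#' query in compound-id order.
#'
#' @param pipeline a `pipeline_lists`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_lists <- function(pipeline, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("query_id\tneighbor_id\tdistance\trank", con)
  for (q in sort(pipeline$ids, method = "radix")) {
    sl <- similarity_list(pipeline, q)
    writeLines(paste(q, sl$neighbor_id,
                     format(sl$distance, digits = 17, trim = TRUE),
                     sl$rank, sep = "\t"), con)
  }
  invisible(path)
}
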