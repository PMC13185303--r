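#' Sorenson-Dice coefficient between two fingerprints
#'
#' `2|A n B| / (|A| + |B|)`. Two empty fingerprints score 0, not 1: a
#' featureless parse carries no evidence of similarity.
#'
#' @param a,b fingerprints (numeric feature-id sets).
#' @return similarity in \[0, 1\].
#' @seealso [tanimoto_coefficient()]; the two are related by
#'   `D = 2 T / (1 + T)`.
#' @export
#' @examples
#' dice_coefficient(fingerprint(1:3), fingerprint(2:4))
dice_coefficient <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na == 0 && nb == 0) {
    return(0)
  }
  inter <- length(intersect(a, b))
  2 * inter / (na + nb)
}

#' Tanimoto (Jaccard) coefficient between two fingerprints
#'
#' `|A n B| / (A u B)`. Two empty fingerprints score 0 (see
#' [dice_coefficient()] for the rationale).
#'
#' @inheritParams dice_coefficient
#' @return similarity in \[0, 1\].
#' @export
#' @examples
#' tanimoto_coefficient(fingerprint(1:3), fingerprint(2:4))
tanimoto_coefficient <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na == 0 && nb == 0) {
    return(0)
  }
  inter <- length(intersect(a, b))
  inter / (na + nb - inter)
}

#' Filter compounds by heavy-atom count
#'
#' Retains compounds with at least `min_heavy` non-hydrogen atoms, preserving
#' input order. Used to keep bottom-ranked control groups chemically
#' meaningful (very small fragments carry no target information).
#'
#' @param compounds data.frame with columns `id` and `heavy_atoms`.
#' @param min_heavy minimum heavy-atom count (default 5).
#' @return the filtered data.frame.
#' @export
heavy_atom_filter <- function(compounds, min_heavy = 5) {
  stopifnot(is.data.frame(compounds), "id" %in% names(compounds))
  if (!"heavy_atoms" %in% names(compounds)) {
    stop("compounds table has no heavy_atoms column", call. = FALSE)
  }
  if (nrow(compounds) == 0) {
    return(compounds)
  }
  missing <- is.na(compounds$heavy_atoms)
  if (any(missing)) {
    stop("heavy_atoms missing for compound(s): ",
         paste(compounds$id[missing], collapse = ", "), call. = FALSE)
  }
  compounds[compounds$heavy_atoms >= min_heavy, , drop = FALSE]
}
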