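# Compound-protein interaction scoring: a docking surrogate that scores a
# pair as (best template-ligand chemical similarity) x (binding-site
# confidence), applied proteome-wide to produce interaction signatures.

#' Score one compound against one protein's predicted binding sites
#'
#' For every predicted site the query fingerprint is compared to the site's
#' template ligand with the Sorenson-Dice coefficient. Under the default
#' `"argmax_dice"` rule, the site with the highest Dice similarity is
#' selected (ties broken by higher confidence) and the score is that site's
#' `dice * confidence`. The alternative `"max_product"` rule returns
#' `max(dice * confidence)` over sites. A protein with no predicted sites
#' scores 0 against every compound.
#'
#' @param query query compound fingerprint.
#' @param sites `site_library` rows for one protein (any `protein_id` values
#'   are ignored; all rows are treated as sites of the same protein).
#' @param method `"argmax_dice"` (default) or `"max_product"`.
#' @return interaction score in \[0, 1\].
#' @export
score_compound_protein <- function(query, sites,
                                   method = c("argmax_dice", "max_product")) {
  method <- match.arg(method)
  if (is.null(sites) || nrow(sites) == 0) {
    return(0)
  }
  dice <- vapply(sites$template, dice_coefficient, numeric(1), b = query)
  if (method == "max_product") {
    return(max(dice * sites$confidence))
  }
  best <- which(dice == max(dice))
  if (length(best) > 1L) {
    best <- best[which.max(sites$confidence[best])]
  }
  dice[best] * sites$confidence[best]
}

#' Build a compound-proteome interaction signature matrix
#'
#' Applies [score_compound_protein()] between every compound and every
#' protein. Proteins absent from the site library score 0 against all
#' compounds (reported once via a message). Compounds without a fingerprint
#' abort the build.
#'
#' @param fingerprints named list of compound fingerprints (the compound
#'   library; order defines matrix row order).
#' @param sites `site_library` of binding-site predictions.
#' @param protein_ids character vector of protein ids (matrix column order);
#'   defaults to the proteins present in `sites`.
#' @param method passed to [score_compound_protein()].
#' @return validated interaction matrix (compounds x proteins).
#' @export
build_signature_matrix <- function(fingerprints, sites, protein_ids = NULL,
                                   method = c("argmax_dice", "max_product")) {
  method <- match.arg(method)
  if (is.null(names(fingerprints)) || any(!nzchar(names(fingerprints)))) {
    stop("every compound must be named in the fingerprint list", call. = FALSE)
  }
  no_fp <- vapply(fingerprints, is.null, logical(1))
  if (any(no_fp)) {
    stop("compound(s) lacking a fingerprint: ",
         paste(names(fingerprints)[no_fp], collapse = ", "), call. = FALSE)
  }
  if (is.null(protein_ids)) {
    protein_ids <- sort(unique(sites$protein_id), method = "radix")
  }
  by_protein <- split(seq_len(nrow(sites)), sites$protein_id)
  uncovered <- setdiff(protein_ids, names(by_protein))
  if (length(uncovered) > 0) {
    message(length(uncovered),
            " protein(s) have no predicted binding sites and score 0: ",
            paste(utils::head(uncovered, 5L), collapse = ", "),
            if (length(uncovered) > 5L) ", ..." else "")
  }
  m <- matrix(0, length(fingerprints), length(protein_ids),
              dimnames = list(names(fingerprints), protein_ids))
  for (p in intersect(protein_ids, names(by_protein))) {
    psites <- sites[by_protein[[p]], , drop = FALSE]
    m[, p] <- vapply(fingerprints, score_compound_protein, numeric(1),
                     sites = psites, method = method)
  }
  validate_interaction_matrix(m)
  m
}
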