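# Readers/writers for the plain-text interchange formats: interaction
# matrices, indication mappings, gold-standard protein sets, binding-site
# libraries. Dialect: tab-separated, UTF-8, '.' decimal separator, no quoting.

#' Validate an interaction matrix
#'
#' An interaction matrix is a numeric compounds-by-proteins matrix with unique
#' row (compound id) and column (protein id) names and every entry in
#' \[0, 1\]; entry `(c, p)` is the predicted interaction score between
#' compound `c` and protein `p`. Row `c` is the proteome-wide interaction
#' signature of compound `c`.
#'
#' @param m numeric matrix with dimnames.
#' @return `m`, invisibly, after validation.
#' @export
validate_interaction_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("interaction matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("interaction matrix must have compound row names and protein column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate compound id: ", rownames(m)[duplicated(rownames(m))][1L],
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate protein id: ", colnames(m)[duplicated(colnames(m))][1L],
         call. = FALSE)
  }
  bad <- which(is.na(m) | m < 0 | m > 1)
  if (length(bad) > 0) {
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf("interaction score out of [0,1] at compound '%s', protein '%s': %s",
                 rownames(m)[i[1L]], colnames(m)[i[2L]],
                 format(m[bad[1L]])), call. = FALSE)
  }
  invisible(m)
}

#' Load an interaction matrix from TSV
#'
#' First header row holds protein ids, first column compound ids, remaining
#' cells decimal scores in \[0, 1\]. Row and column order are preserved from
#' the file. Malformed cells, duplicate ids and out-of-range values abort the
#' load naming the offending row/column.
#'
#' @param path path to the TSV file.
#' @return validated interaction matrix.
#' @export
read_interaction_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) {
    stop("interaction matrix file needs an id column plus >=1 protein column",
         call. = FALSE)
  }
  ids <- df[[1L]]
  prot <- colnames(df)[-1L]
  m <- matrix(NA_real_, nrow(df), length(prot), dimnames = list(ids, prot))
  for (j in seq_along(prot)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1L]]))
    if (length(bad) > 0) {
      stop(sprintf("malformed value at compound '%s', protein '%s': '%s'",
                   ids[bad[1L]], prot[j], df[[j + 1L]][bad[1L]]),
           call. = FALSE)
    }
    m[, j] <- v
  }
  validate_interaction_matrix(m)
  m
}

#' Write an interaction matrix to TSV
#'
#' Inverse of [read_interaction_matrix()]; full-precision decimal output so
#' the round trip is bit-exact.
#'
#' @param m interaction matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(m, path) {
  validate_interaction_matrix(m)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("compound_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) {
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = "\t")
  })
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Load a drug-indication mapping
#'
#' Two-column TSV (`indication_id`, `compound_id`), one association per line;
#' duplicate lines collapse to a single association. The result is a named
#' list: indication id -> character vector of associated compound ids (sorted,
#' unique).
#'
#' @param path path to the TSV file.
#' @param header logical; does the file carry a header line (default TRUE)?
#' @return named list of class `indication_mapping`.
#' @export
read_indication_mapping <- function(path, header = TRUE) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    return(indication_mapping(list()))
  }
  df <- utils::read.delim(path, header = header, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) {
    stop("indication mapping file must have two tab-separated columns",
         call. = FALSE)
  }
  indication_mapping(split(df[[2L]], df[[1L]]))
}

#' Construct an indication mapping
#'
#' @param x named list mapping indication id -> character vector of approved
#'   compound ids.
#' @return named list of class `indication_mapping`; compound sets are sorted
#'   and de-duplicated, indications ordered by id.
#' @export
indication_mapping <- function(x) {
  stopifnot(is.list(x))
  if (length(x) == 0) {
    return(structure(stats::setNames(list(), character()),
                     class = "indication_mapping"))
  }
  if (is.null(names(x))) {
    stop("indication mapping must be a named list", call. = FALSE)
  }
  x <- lapply(x, function(v) sort(unique(as.character(v)), method = "radix"))
  x <- x[order(names(x), method = "radix")]
  structure(x, class = "indication_mapping")
}

#' @export
print.indication_mapping <- function(x, ...) {
  cat("<indication_mapping> ", length(x), " indications, ",
      n_associations(x), " associations\n", sep = "")
  invisible(x)
}

#' Count (indication, compound) associations in a mapping
#'
#' @param mapping an `indication_mapping`.
#' @return integer association count.
#' @export
n_associations <- function(mapping) {
  sum(lengths(mapping))
}

#' Write a drug-indication mapping
#'
#' @param mapping an `indication_mapping`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_indication_mapping <- function(mapping, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("indication_id\tcompound_id", con)
  for (ind in names(mapping)) {
    if (length(mapping[[ind]]) > 0) {
      writeLines(paste(ind, mapping[[ind]], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Restrict a mapping to benchmarkable indications
#'
#' Leave-one-out benchmarking needs at least two approved drugs per
#' indication (one to hold out, one to recover), so the benchmarking subset
#' keeps only indications with `min_drugs` or more approved drugs.
#'
#' @param mapping an `indication_mapping`.
#' @param min_drugs minimum approved-drug count (default 2).
#' @return the restricted `indication_mapping`.
#' @export
restrict_to_benchmarkable <- function(mapping, min_drugs = 2) {
  stopifnot(min_drugs >= 1)
  indication_mapping(unclass(mapping)[lengths(mapping) >= min_drugs])
}

#' Read a gold-standard protein set
#'
#' Format: a `# name` header line followed by one protein id per line.
#'
#' @param path path to the file.
#' @return list with elements `name` (string) and `proteins` (sorted
#'   character vector).
#' @export
read_gold_standard <- function(path) {
  lines <- readLines(path)
  name <- basename(path)
  if (length(lines) > 0 && startsWith(lines[1L], "#")) {
    name <- trimws(sub("^#+", "", lines[1L]))
    lines <- lines[-1L]
  }
  lines <- trimws(lines)
  list(name = name,
       proteins = sort(unique(lines[nzchar(lines)]), method = "radix"))
}

#' Write a gold-standard protein set
#'
#' @param gold list with `name` and `proteins`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gold_standard <- function(gold, path) {
  writeLines(c(paste("#", gold$name), gold$proteins), path)
  invisible(path)
}

#' Read a binding-site prediction library
#'
#' TSV columns: `protein_id`, `site_id`, `confidence` (in \[0, 1\]),
#' `template_features` (comma-separated feature ids of the site's template
#' ligand; empty field = empty fingerprint). Confidences outside \[0, 1\] are
#' rejected at load.
#'
#' @param path path to the TSV file.
#' @param header logical; header line present (default TRUE)?
#' @return data.frame with columns `protein_id`, `site_id`, `confidence` and
#'   list-column `template` of fingerprints.
#' @export
read_site_library <- function(path, header = TRUE) {
  df <- utils::read.delim(path, header = header, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 4) {
    stop("site library file must have 4 tab-separated columns", call. = FALSE)
  }
  names(df)[1:4] <- c("protein_id", "site_id", "confidence", "template_features")
  conf <- suppressWarnings(as.numeric(df$confidence))
  bad <- which(is.na(conf) | conf < 0 | conf > 1)
  if (length(bad) > 0) {
    stop(sprintf("site confidence out of [0,1] for protein '%s', site '%s'",
                 df$protein_id[bad[1L]], df$site_id[bad[1L]]), call. = FALSE)
  }
  site_library(
    protein_id = df$protein_id,
    site_id = df$site_id,
    confidence = conf,
    template = lapply(df$template_features, function(s) {
      if (!nzchar(s)) fingerprint()
      else fingerprint(as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]]))
    })
  )
}

#' Construct a binding-site library
#'
#' @param protein_id character vector of protein accessions.
#' @param site_id character vector of site identifiers.
#' @param confidence numeric site confidences in \[0, 1\].
#' @param template list of template-ligand fingerprints.
#' @return data.frame of class `site_library`.
#' @export
site_library <- function(protein_id, site_id, confidence, template) {
  stopifnot(length(protein_id) == length(site_id),
            length(protein_id) == length(confidence),
            length(protein_id) == length(template))
  if (length(confidence) > 0 &&
      (anyNA(confidence) || any(confidence < 0) || any(confidence > 1))) {
    stop("site confidences must lie in [0,1]", call. = FALSE)
  }
  out <- data.frame(protein_id = as.character(protein_id),
                    site_id = as.character(site_id),
                    confidence = as.numeric(confidence),
                    stringsAsFactors = FALSE)
  out$template <- template
  class(out) <- c("site_library", "data.frame")
  out
}

#' Write a binding-site library to TSV
#'
#' @param sites a `site_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_library <- function(sites, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("protein_id\tsite_id\tconfidence\ttemplate_features", con)
  if (nrow(sites) > 0) {
    feat <- vapply(sites$template, function(f) {
      paste(format(unclass(f), scientific = FALSE, trim = TRUE), collapse = ",")
    }, character(1))
    writeLines(paste(sites$protein_id, sites$site_id,
                     format(sites$confidence, digits = 17, trim = TRUE),
                     feat, sep = "\t"), con)
  }
  invisible(path)
}
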