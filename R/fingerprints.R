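#' Construct a fingerprint
#'
#' A fingerprint is a finite set of non-negative integer feature identifiers,
#' following the circular-substructure (ECFP4, radius 2) convention: each
#' feature id denotes a hashed local chemical environment. The empty set is a
#' valid fingerprint (a molecule from which no features could be derived).
#' Feature ids are stored as sorted, de-duplicated doubles so that unfolded
#' 32-bit hash values survive untruncated.
#'
#' @param features numeric vector of non-negative integer feature ids.
#' @return numeric vector of class `fingerprint` (sorted, unique).
#' @export
#' @examples
#' fingerprint(c(3, 1, 2, 2))
fingerprint <- function(features = numeric()) {
  if (length(features) == 0) {
    return(structure(numeric(), class = "fingerprint"))
  }
  features <- as.numeric(features)
  if (anyNA(features) || any(features < 0) || any(features != trunc(features))) {
    stop("fingerprint features must be non-negative integers", call. = FALSE)
  }
  structure(sort(unique(features)), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint> ", length(x), " features\n", sep = "")
  invisible(x)
}

#' Read a fingerprint file
#'
#' Expected format: one compound per line, `id<TAB>comma-separated feature
#' ids`. An id followed by an empty feature field yields an empty fingerprint.
#'
#' @param path path to the tab-separated fingerprint file.
#' @return named list of [fingerprint()] objects, in file order.
#' @export
read_fingerprints <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(stats::setNames(list(), character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate compound id in fingerprint file: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  fps <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[[2L]])) {
      return(fingerprint())
    }
    fingerprint(as.numeric(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]]))
  })
  stats::setNames(fps, ids)
}

#' Write a fingerprint file
#'
#' Inverse of [read_fingerprints()].
#'
#' @param fingerprints named list of fingerprints.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fingerprints, path) {
  stopifnot(is.list(fingerprints), !is.null(names(fingerprints)))
  lines <- vapply(seq_along(fingerprints), function(i) {
    paste0(names(fingerprints)[i], "\t",
           paste(format(unclass(fingerprints[[i]]), scientific = FALSE,
                        trim = TRUE),
                 collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Compute ECFP4 fingerprints and heavy-atom counts from SMILES
#'
#' Delegates to RDKit through the bundled Python helper: circular fingerprints
#' of radius 2 (diameter 4) as unfolded sparse feature-id sets, plus the
#' heavy-atom (non-hydrogen) count of each parsed structure. Structures that
#' fail to parse are dropped with a warning rather than aborting the run.
#'
#' @param path SMILES file, one molecule per line, `SMILES<TAB>id`.
#' @param python name or path of the Python interpreter with RDKit available.
#' @return data.frame with columns `id`, `heavy_atoms` and a list-column
#'   `fingerprint` of [fingerprint()] objects.
#' @export
fingerprints_from_smiles <- function(path, python = "python") {
  helper <- system.file("python", "ecfp4.py", package = "drugsig",
                        mustWork = TRUE)
  out <- suppressWarnings(
    system2(python, c(helper, shQuote(path)), stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("fingerprint helper failed: ", paste(out, collapse = "\n"),
         call. = FALSE)
  }
  bad <- grepl("^#SKIP\t", out)
  if (any(bad)) {
    warning("unparseable structures skipped: ",
            paste(sub("^#SKIP\t", "", out[bad]), collapse = ", "),
            call. = FALSE)
  }
  out <- out[!bad & nzchar(out)]
  parts <- strsplit(out, "\t", fixed = TRUE)
  data.frame(
    id = vapply(parts, `[[`, character(1), 1L),
    heavy_atoms = as.integer(vapply(parts, `[[`, character(1), 2L)),
    fingerprint = I(lapply(parts, function(p) {
      if (length(p) < 3L || !nzchar(p[[3L]])) {
        fingerprint()
      } else {
        fingerprint(as.numeric(strsplit(p[[3L]], ",", fixed = TRUE)[[1L]]))
      }
    })),
    stringsAsFactors = FALSE
  )
}
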