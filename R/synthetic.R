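# Synthetic study generator: complete, seeded study bundles with planted
# indication structure, so that every pipeline stage can be exercised and
# calibrated without external databases. Co-indicated drugs share elevated
# scores on dedicated "driver" proteins (their planted mechanism) on top of
# a sparse right-skewed background; fingerprints include planted
# near-duplicate analog pairs; gold standards are the driver sets.

#' Synthetic study configuration
#'
#' Defaults describe a desk-scale study: 500 compounds x 300 proteins, 50
#' indications with 4 approved drugs and 5 driver proteins each, a driver
#' signal of 0.8 with Gaussian noise (sd 0.05), and a sparse background
#' (density 0.2, Beta(2, 8) scores -- right-skewed, as similarity-times-
#' confidence products are). Ten analog pairs with Tanimoto >= 0.9 are
#' planted among approved drugs of different indications, mimicking
#' cross-indication "me too" analogs.
#'
#' @param seed master integer seed; every draw in [generate_study()] derives
#'   from it.
#' @param n_compounds,n_proteins library sizes (M, P).
#' @param n_indications number of indications (I).
#' @param drugs_per_indication approved drugs per indication (K).
#' @param drivers_per_indication driver proteins per indication (G).
#' @param signal mean interaction score of approved drugs on their drivers.
#' @param noise_sd Gaussian noise sd added to driver scores.
#' @param background_density probability that a background cell is non-zero.
#' @param n_analog_pairs number of planted near-duplicate analog pairs.
#' @param analog_overlap minimum Tanimoto similarity of planted pairs.
#' @param fingerprint_features features per compound fingerprint.
#' @param feature_space size of the fingerprint feature-id universe.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_compounds = 500L,
                             n_proteins = 300L,
                             n_indications = 50L,
                             drugs_per_indication = 4L,
                             drivers_per_indication = 5L,
                             signal = 0.8,
                             noise_sd = 0.05,
                             background_density = 0.2,
                             n_analog_pairs = 10L,
                             analog_overlap = 0.9,
                             fingerprint_features = 64L,
                             feature_space = 65536L) {
  cfg <- list(seed = as.integer(seed),
              n_compounds = as.integer(n_compounds),
              n_proteins = as.integer(n_proteins),
              n_indications = as.integer(n_indications),
              drugs_per_indication = as.integer(drugs_per_indication),
              drivers_per_indication = as.integer(drivers_per_indication),
              signal = signal,
              noise_sd = noise_sd,
              background_density = background_density,
              n_analog_pairs = as.integer(n_analog_pairs),
              analog_overlap = analog_overlap,
              fingerprint_features = as.integer(fingerprint_features),
              feature_space = as.integer(feature_space))
  with(cfg, {
    if (n_indications * drugs_per_indication > n_compounds) {
      stop("infeasible config: I * K exceeds the compound library",
           call. = FALSE)
    }
    if (n_indications * drivers_per_indication > n_proteins) {
      stop("infeasible config: I * G exceeds the protein library",
           call. = FALSE)
    }
    if (2L * n_analog_pairs > n_indications) {
      stop("infeasible config: analog pairs need 2 distinct indications each",
           call. = FALSE)
    }
    if (signal < 0 || noise_sd < 0 ||
        background_density < 0 || background_density > 1 ||
        analog_overlap <= 0 || analog_overlap > 1) {
      stop("config parameter out of range", call. = FALSE)
    }
    if (fingerprint_features < 1 ||
        fingerprint_features * 4L > feature_space) {
      stop("feature space too small for the requested fingerprint size",
           call. = FALSE)
    }
  })
  structure(cfg, class = "synthetic_config")
}

.pad_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(4L, nchar(as.character(n))), seq_len(n))
}

#' Generate a complete synthetic study
#'
#' Deterministic given the config seed. Indication `i` owns a dedicated
#' block of `K` approved drugs and `G` driver proteins; approved-drug
#' scores on their drivers are `clip(signal + N(0, noise_sd), 0, 1)` and
#' all remaining cells are sparse Beta(2, 8) background draws. Compound
#' fingerprints are uniform random feature sets, except planted analog
#' pairs (approved drugs of two *different* indications) which share enough
#' features to reach the configured Tanimoto floor. The gold standard of
#' each indication is its driver-protein set. A binding-site library (sites
#' with random confidences and template ligands) is included to exercise
#' signature construction; the planted interaction matrix itself is
#' generated directly so that the planted structure is exact.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_study` with elements `config`,
#'   `compounds` (data.frame: id, name, status, indication, heavy_atoms),
#'   `proteins` (data.frame: id, indication), `fingerprints`, `sites`,
#'   `matrix`, `mapping`, `gold_standards`, `analog_pairs`.
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  M <- config$n_compounds
  P <- config$n_proteins
  I <- config$n_indications
  K <- config$drugs_per_indication
  G <- config$drivers_per_indication

  compound_ids <- .pad_ids("C", M)
  protein_ids <- .pad_ids("P", P)
  indication_ids <- .pad_ids("D", I)

  drug_block <- rep(NA_character_, M)
  drug_block[seq_len(I * K)] <- rep(indication_ids, each = K)
  driver_block <- rep(NA_character_, P)
  driver_block[seq_len(I * G)] <- rep(indication_ids, each = G)

  # interaction matrix: sparse skewed background, then planted driver blocks
  bg_on <- matrix(stats::runif(M * P) < config$background_density, M, P)
  mat <- matrix(0, M, P, dimnames = list(compound_ids, protein_ids))
  mat[bg_on] <- stats::rbeta(sum(bg_on), 2, 8)
  for (i in seq_len(I)) {
    drugs <- which(drug_block == indication_ids[i])
    drivers <- which(driver_block == indication_ids[i])
    vals <- config$signal +
      stats::rnorm(length(drugs) * length(drivers), 0, config$noise_sd)
    mat[drugs, drivers] <- matrix(vals, length(drugs), length(drivers))
  }
  mat[mat < 0] <- 0
  mat[mat > 1] <- 1

  mapping <- indication_mapping(split(
    compound_ids[seq_len(I * K)], drug_block[seq_len(I * K)]
  ))
  gold_standards <- stats::setNames(lapply(seq_len(I), function(i) {
    list(name = indication_ids[i],
         proteins = protein_ids[which(driver_block == indication_ids[i])])
  }), indication_ids)

  # fingerprints: uniform random feature sets ...
  fp_n <- config$fingerprint_features
  fingerprints <- stats::setNames(lapply(seq_len(M), function(i) {
    fingerprint(sample.int(config$feature_space, fp_n))
  }), compound_ids)
  # ... with analog pairs planted across different indications
  analog_pairs <- NULL
  if (config$n_analog_pairs > 0) {
    a_idx <- integer(config$n_analog_pairs)
    b_idx <- integer(config$n_analog_pairs)
    for (j in seq_len(config$n_analog_pairs)) {
      a_idx[j] <- (2L * j - 2L) * K + 1L  # first drug of indication 2j-1
      b_idx[j] <- (2L * j - 1L) * K + 1L  # first drug of indication 2j
      t_floor <- config$analog_overlap
      shared_n <- ceiling(2 * fp_n * t_floor / (1 + t_floor))
      base <- unclass(fingerprints[[a_idx[j]]])
      fresh <- sample(setdiff(seq_len(config$feature_space), base),
                      fp_n - shared_n)
      fingerprints[[b_idx[j]]] <- fingerprint(c(base[seq_len(shared_n)],
                                                fresh))
    }
    analog_pairs <- data.frame(compound_a = compound_ids[a_idx],
                               compound_b = compound_ids[b_idx],
                               stringsAsFactors = FALSE)
    analog_pairs$tanimoto <- mapply(function(a, b) {
      tanimoto_coefficient(fingerprints[[a]], fingerprints[[b]])
    }, analog_pairs$compound_a, analog_pairs$compound_b)
  }

  # binding-site library: 0-3 sites per protein, random confidence/template
  n_sites <- sample(0:3, P, replace = TRUE)
  sites <- site_library(
    protein_id = rep(protein_ids, n_sites),
    site_id = unlist(lapply(n_sites, function(n) {
      if (n > 0) paste0("S", seq_len(n)) else character()
    }), use.names = FALSE),
    confidence = stats::runif(sum(n_sites)),
    template = lapply(seq_len(sum(n_sites)), function(i) {
      fingerprint(sample.int(config$feature_space, fp_n))
    })
  )

  heavy <- pmax(1L, stats::rpois(M, 24))
  small <- stats::runif(M) < 0.05
  heavy[small] <- sample(1:4, sum(small), replace = TRUE)

  compounds <- data.frame(
    id = compound_ids,
    name = paste0("compound-", compound_ids),
    status = ifelse(is.na(drug_block), "other", "approved"),
    indication = drug_block,
    heavy_atoms = heavy,
    stringsAsFactors = FALSE
  )
  proteins <- data.frame(id = protein_ids, indication = driver_block,
                         stringsAsFactors = FALSE)

  structure(list(config = config,
                 compounds = compounds,
                 proteins = proteins,
                 fingerprints = fingerprints,
                 sites = sites,
                 matrix = mat,
                 mapping = mapping,
                 gold_standards = gold_standards,
                 analog_pairs = analog_pairs),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", x$config$n_compounds, " compounds x ",
      x$config$n_proteins, " proteins, ", x$config$n_indications,
      " indications (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Generate a null pipeline of uniformly random similarity lists
#'
#' Each compound's neighbor order is an independent uniform permutation of
#' the other `M - 1` compounds, carrying synthetic strictly increasing
#' distances (`rank / M`, all below 1). This is the "random ranking" null
#' used by the Monte-Carlo controls.
#'
#' @param ids compound ids, or a single integer `M` (ids are then
#'   auto-generated).
#' @param seed integer seed.
#' @return `pipeline_lists` named `"null"`.
#' @export
generate_null_lists <- function(ids, seed = 1L) {
  if (is.numeric(ids) && length(ids) == 1L) {
    ids <- .pad_ids("C", as.integer(ids))
  }
  if (length(ids) < 2) {
    stop("need at least 2 compounds", call. = FALSE)
  }
  set.seed(seed)
  .null_pipeline(ids)
}

#' Write a synthetic study bundle to a directory
#'
#' Emits every artifact in the package's plain-text interchange formats:
#' `matrix.tsv`, `fingerprints.tsv`, `mapping.tsv`, `sites.tsv`,
#' `compounds.tsv` and one `gold_<indication>.txt` per indication.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interaction_matrix(study$matrix, file.path(dir, "matrix.tsv"))
  write_fingerprints(study$fingerprints, file.path(dir, "fingerprints.tsv"))
  write_indication_mapping(study$mapping, file.path(dir, "mapping.tsv"))
  write_site_library(study$sites, file.path(dir, "sites.tsv"))
  utils::write.table(study$compounds, file.path(dir, "compounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ind in names(study$gold_standards)) {
    write_gold_standard(study$gold_standards[[ind]],
                        file.path(dir, paste0("gold_", ind, ".txt")))
  }
  invisible(dir)
}
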