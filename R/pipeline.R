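# Orchestration: simulate a full study-like dataset and run the
# processing chain end to end.

#' Simulate a complete study dataset
#'
#' Emulates the structure of the feeding trial: `n_animals` animals per
#' species, each sampled on both diets. Each diet has its own underlying
#' community (fragment lengths and abundances), so diet separates
#' community structure while per-sample signal noise and background peaks
#' provide within-group scatter. Ct tables are planted from the reference
#' abundance group means ([reference_abundance()]) for the sample's
#' species-by-diet cell, and fermentation responses from the reference
#' fermentation means with animal and residual variation proportional to
#' each response's grand mean (coefficients `cv_animal`, `cv_e`).
#'
#' @param config configuration list (see [default_config()]); the `sim`
#'   section supplies community size/model, peak scales, Ct settings and
#'   the design.
#' @param seed global integer seed; per-stream sub-seeds are derived by
#'   fixed offsets so the streams are mutually independent.
#' @param cv_animal,cv_e animal and residual SDs for fermentation
#'   responses, as fractions of each response's grand mean.
#' @return List of class `trflp_dataset`: `meta` (sample metadata),
#'   `communities` (per-diet ground truth), `peak_tables`, `ct`
#'   (a [ct_table]), `fermentation` (records with animal ids).
#' @export
simulate_dataset <- function(config = default_config(), seed = 1L,
                             cv_animal = 0.05, cv_e = 0.02) {
  sim <- config$sim
  grid <- expand.grid(animal = seq_len(sim$n_animals),
                      species = sim$species, diet = sim$diets,
                      stringsAsFactors = FALSE)
  grid$animal_id <- paste0(grid$species, "_A", grid$animal)
  grid$sample_id <- paste(grid$animal_id, grid$diet, sep = "_")
  meta <- data.frame(sample_id = grid$sample_id, species = grid$species,
                     animal_id = grid$animal_id, diet = grid$diet,
                     stringsAsFactors = FALSE)

  communities <- lapply(seq_along(sim$diets), function(k) {
    simulate_community(sim$n_taxa, model = sim$community_model,
                       seed = sub_seed(seed, "community", k),
                       ratio = sim$geometric_ratio,
                       size_window = sim$size_window,
                       tolerance_bp = config$trflp$tolerance_bp)
  })
  names(communities) <- sim$diets

  peak_tables <- lapply(seq_len(nrow(meta)), function(i) {
    simulate_electropherogram(communities[[meta$diet[i]]], sim,
                              seed = sub_seed(seed, "electropherogram", i),
                              sample_id = meta$sample_id[i])
  })
  names(peak_tables) <- meta$sample_id

  ref_ab <- reference_abundance()
  ct_list <- lapply(seq_len(nrow(meta)), function(i) {
    cell <- ref_ab[ref_ab$species == meta$species[i] &
                     ref_ab$diet == meta$diet[i], ]
    ab <- stats::setNames(cell$abundance_percent, cell$taxon)
    simulate_ct_table(ab, ct_total = sim$ct_total,
                      ct_noise_sd = sim$ct_noise_sd,
                      n_replicates = sim$n_replicates,
                      seed = sub_seed(seed, "ct", i),
                      sample_id = meta$sample_id[i],
                      total_taxon = config$qpcr$total_taxon)
  })
  ct <- do.call(rbind, ct_list)
  class(ct) <- c("ct_table", "data.frame")

  ref_fm <- reference_fermentation()
  responses <- setdiff(names(ref_fm), c("species", "diet"))
  ferm <- NULL
  for (k in seq_along(responses)) {
    resp <- responses[k]
    cm <- tapply(ref_fm[[resp]], list(ref_fm$species, ref_fm$diet), mean)
    g <- mean(abs(cm))
    rec <- simulate_fermentation(
      n_animals = sim$n_animals, species = sim$species, diets = sim$diets,
      cell_means = cm, sigma_animal = cv_animal * g, sigma_e = cv_e * g,
      seed = sub_seed(seed, "fermentation", k), response = resp)
    ferm <- if (is.null(ferm)) rec else {
      merge(ferm, rec, by = c("species", "animal_id", "diet"),
            sort = FALSE)
    }
  }

  structure(list(meta = meta, communities = communities,
                 peak_tables = peak_tables, ct = ct,
                 fermentation = ferm),
            class = "trflp_dataset")
}

#' @export
print.trflp_dataset <- function(x, ...) {
  cat(sprintf("trflp_dataset: %d samples, %d peak tables, %d Ct rows\n",
              nrow(x$meta), length(x$peak_tables), nrow(x$ct)))
  invisible(x)
}

#' Run the T-RFLP processing chain
#'
#' Size-filters every peak table, detects true peaks iteratively, bins
#' fragment lengths across samples, standardizes to within-sample
#' relative abundances, computes the per-sample diversity table, and (for
#' two or more samples) the Euclidean distance matrix, complete-linkage
#' tree and PCA.
#'
#' @param peak_tables named list of [peak_table] objects.
#' @param config configuration list; uses the `trflp` and `diversity`
#'   sections.
#' @param meta optional sample metadata joined into the diversity table.
#' @return List with `true_peaks`, `binned` (raw), `standardized`,
#'   `diversity`, and when possible `distances`, `tree`, `pca`.
#' @export
run_trflp_pipeline <- function(peak_tables, config = default_config(),
                               meta = NULL) {
  tp <- config$trflp
  filtered <- lapply(peak_tables, filter_by_size,
                     min_bp = tp$min_bp, max_bp = tp$max_bp)
  true_peaks <- lapply(filtered, detect_true_peaks,
                       k_sd = tp$k_sd, max_iter = tp$max_iter)
  binned <- bin_fragments(true_peaks, tolerance_bp = tp$tolerance_bp)
  std <- standardize(binned)
  out <- list(true_peaks = true_peaks, binned = binned,
              standardized = std,
              diversity = diversity_table(std, meta = meta,
                                          base = config$diversity$log_base))
  if (ncol(std$values) >= 2L && nrow(std$values) >= 1L) {
    out$distances <- euclidean_distances(std)
    out$tree <- complete_linkage(out$distances)
    fit <- try(pca(std), silent = TRUE)
    if (!inherits(fit, "try-error")) out$pca <- fit
  }
  out
}

#' Run the qPCR quantification stage
#'
#' Replicate aggregation, the 2^-deltaCt transform, and (when metadata is
#' supplied) across-species ratio-of-means diet fold changes for every
#' assayed taxon.
#'
#' @param ct a [ct_table].
#' @param meta optional metadata (`sample_id`, `species`, `diet`).
#' @param config configuration list; uses the `qpcr` section.
#' @param numerator_diet,denominator_diet the diet contrast.
#' @return List with `abundance` and, with metadata, `fold_changes`.
#' @export
run_qpcr_pipeline <- function(ct, meta = NULL, config = default_config(),
                              numerator_diet = "HC",
                              denominator_diet = "HF") {
  ab <- abundance_table(ct, total_taxon = config$qpcr$total_taxon,
                        sd_threshold = config$qpcr$sd_threshold)
  out <- list(abundance = ab)
  if (!is.null(meta)) {
    taxa <- unique(ab$taxon)
    fc <- do.call(rbind, lapply(taxa, function(tx) {
      f <- group_fold_change(ab, meta, tx,
                             numerator_diet = numerator_diet,
                             denominator_diet = denominator_diet,
                             level = "across_species",
                             method = "ratio_of_means")
      cbind(taxon = tx, f)
    }))
    out$fold_changes <- fc
  }
  out
}
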