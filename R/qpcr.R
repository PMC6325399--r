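# qPCR relative quantification: replicate Ct aggregation, the 2^-deltaCt
# transform against the total-bacteria assay, and fold-change summaries.

#' Aggregate replicate Ct values
#'
#' Collapses replicate reactions per (sample, taxon) to their arithmetic
#' mean Ct — the convention for delta-Ct methods. Replicate scatter above
#' `sd_threshold` cycles raises a `high_replicate_sd` QC flag; a single
#' replicate has SD 0 and passes.
#'
#' @param ct a [ct_table] (long format, one row per replicate).
#' @param sd_threshold replicate SD QC cutoff in cycles (default 0.5).
#' @return Data frame with one row per (sample, taxon): `sample_id`,
#'   `taxon`, `mean_ct`, `ct_sd`, `n_replicates`, `qc_flag`.
#' @export
aggregate_ct <- function(ct, sd_threshold = 0.5) {
  stopifnot(is.data.frame(ct),
            all(c("sample_id", "taxon", "ct") %in% names(ct)))
  if (nrow(ct) == 0L) {
    return(data.frame(sample_id = character(0), taxon = character(0),
                      mean_ct = numeric(0), ct_sd = numeric(0),
                      n_replicates = integer(0), qc_flag = character(0)))
  }
  key <- paste(ct$sample_id, ct$taxon, sep = "\r")
  idx <- split(seq_len(nrow(ct)), key)
  rows <- lapply(idx, function(i) {
    v <- ct$ct[i]
    s <- if (length(v) > 1L) stats::sd(v) else 0
    data.frame(sample_id = ct$sample_id[i[1L]], taxon = ct$taxon[i[1L]],
               mean_ct = mean(v), ct_sd = s,
               n_replicates = length(v),
               qc_flag = if (s > sd_threshold) "high_replicate_sd" else "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative abundance from Ct values
#'
#' `100 * 2^-(Ct_target - Ct_total)`: the abundance of a target taxon as a
#' percentage of total bacteria, assuming perfect doubling per cycle.
#' Vectorized; values above 100 (target amplifying earlier than the total
#' assay) are returned as-is, never clamped.
#'
#' @param ct_target,ct_total quantification cycles, finite and > 0.
#' @return Percentage(s) of total bacteria.
#' @export
relative_abundance <- function(ct_target, ct_total) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_total)) ||
      any(ct_target <= 0) || any(ct_total <= 0)) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  100 * 2^(-(ct_target - ct_total))
}

#' Abundance table from a Ct table
#'
#' Aggregates replicates, pairs every target taxon with the sample's
#' total-bacteria mean Ct, and applies [relative_abundance()]. A sample
#' without a total-bacteria record yields `missing_total` rows with `NA`
#' abundance; abundances above 100% are flagged in `exceeds_total`.
#'
#' @param ct a [ct_table].
#' @param total_taxon label of the total-bacteria assay (default
#'   `"total"`).
#' @param sd_threshold passed to [aggregate_ct()].
#' @return Data frame with one row per (sample, target taxon):
#'   `sample_id`, `taxon`, `mean_ct`, `delta_ct`, `abundance_percent`,
#'   `qc_flag`, `exceeds_total`.
#' @export
abundance_table <- function(ct, total_taxon = "total", sd_threshold = 0.5) {
  agg <- aggregate_ct(ct, sd_threshold = sd_threshold)
  totals <- agg[agg$taxon == total_taxon, c("sample_id", "mean_ct")]
  names(totals)[2L] <- "total_ct"
  targets <- agg[agg$taxon != total_taxon, , drop = FALSE]
  out <- merge(targets, totals, by = "sample_id", all.x = TRUE,
               sort = FALSE)
  out$delta_ct <- out$mean_ct - out$total_ct
  out$abundance_percent <- 100 * 2^(-out$delta_ct)
  no_total <- is.na(out$total_ct)
  if (any(no_total)) {
    trflp_log("warning", sum(no_total),
              " record(s) lack a total-bacteria Ct")
    out$qc_flag[no_total] <- "missing_total"
  }
  out$exceeds_total <- !is.na(out$abundance_percent) &
    out$abundance_percent > 100
  out$total_ct <- NULL
  rownames(out) <- NULL
  out[, c("sample_id", "taxon", "mean_ct", "delta_ct",
          "abundance_percent", "qc_flag", "exceeds_total")]
}

#' Round a fold change for presentation
#'
#' Nearest integer; above 1000, nearest hundred.
#' @param fold numeric fold value(s).
#' @return Rounded value(s); infinite folds pass through.
#' @export
round_fold <- function(fold) {
  ifelse(is.finite(fold) & fold > 1000, round(fold / 100) * 100,
         round(fold))
}

#' Fold change of a taxon's abundance between diet groups
#'
#' Summarizes an abundance table into diet-contrast folds for one taxon.
#' With `level = "per_species"` a fold is computed within each species;
#' with `level = "across_species"` the species group means are first
#' averaged across species and the fold is taken on those cross-species
#' means. `method = "ratio_of_means"` divides group means;
#' `method = "mean_of_ratios"` averages per-animal ratios (per species) or
#' per-species ratio-of-means folds (across species).
#'
#' @param abundance data frame from [abundance_table()] (needs
#'   `sample_id`, `taxon`, `abundance_percent`), or any data frame with
#'   those columns (e.g. published group means with one row per cell).
#' @param meta data frame with `sample_id`, `species`, `diet` (and
#'   `animal_id` for `mean_of_ratios` per species).
#' @param taxon taxon to summarize.
#' @param numerator_diet,denominator_diet diet labels forming the
#'   contrast (default HC vs HF).
#' @param level `"per_species"` or `"across_species"`.
#' @param method `"ratio_of_means"` or `"mean_of_ratios"`.
#' @return Data frame with columns `species` (or `"all"`), `fold` (full
#'   precision; `Inf` for a zero denominator mean) and `fold_rounded`.
#' @export
group_fold_change <- function(abundance, meta, taxon,
                              numerator_diet = "HC",
                              denominator_diet = "HF",
                              level = c("per_species", "across_species"),
                              method = c("ratio_of_means",
                                         "mean_of_ratios")) {
  level <- match.arg(level)
  method <- match.arg(method)
  df <- merge(abundance[abundance$taxon == taxon, , drop = FALSE],
              meta, by = "sample_id", sort = FALSE)
  df <- df[df$diet %in% c(numerator_diet, denominator_diet), , drop = FALSE]
  if (nrow(df) == 0L) stop("no records for taxon ", taxon, call. = FALSE)
  for (d in c(numerator_diet, denominator_diet)) {
    if (!any(df$diet == d)) {
      stop("diet group '", d, "' is empty for taxon ", taxon, call. = FALSE)
    }
  }

  species_fold <- function(sub) {
    num <- sub$abundance_percent[sub$diet == numerator_diet]
    den <- sub$abundance_percent[sub$diet == denominator_diet]
    if (method == "ratio_of_means") {
      if (mean(den) == 0) return(Inf)
      mean(num) / mean(den)
    } else {
      if (!("animal_id" %in% names(sub))) {
        stop("mean_of_ratios per species requires `animal_id` in meta",
             call. = FALSE)
      }
      animals <- intersect(sub$animal_id[sub$diet == numerator_diet],
                           sub$animal_id[sub$diet == denominator_diet])
      ratios <- vapply(animals, function(a) {
        nu <- mean(sub$abundance_percent[sub$diet == numerator_diet &
                                           sub$animal_id == a])
        de <- mean(sub$abundance_percent[sub$diet == denominator_diet &
                                           sub$animal_id == a])
        if (de == 0) Inf else nu / de
      }, numeric(1))
      mean(ratios)
    }
  }

  if (level == "per_species") {
    sp <- unique(df$species)
    folds <- vapply(sp, function(s) {
      species_fold(df[df$species == s, , drop = FALSE])
    }, numeric(1))
    out <- data.frame(species = sp, fold = folds)
  } else {
    cell_means <- stats::aggregate(abundance_percent ~ species + diet,
                                   data = df, FUN = mean)
    if (method == "ratio_of_means") {
      num <- mean(cell_means$abundance_percent[cell_means$diet ==
                                                 numerator_diet])
      den <- mean(cell_means$abundance_percent[cell_means$diet ==
                                                 denominator_diet])
      fold <- if (den == 0) Inf else num / den
    } else {
      sp <- unique(cell_means$species)
      folds <- vapply(sp, function(s) {
        nu <- cell_means$abundance_percent[cell_means$species == s &
                                             cell_means$diet ==
                                             numerator_diet]
        de <- cell_means$abundance_percent[cell_means$species == s &
                                             cell_means$diet ==
                                             denominator_diet]
        if (de == 0) Inf else nu / de
      }, numeric(1))
      fold <- mean(folds)
    }
    out <- data.frame(species = "all", fold = fold)
  }
  if (any(!is.finite(out$fold))) {
    trflp_log("warning", "infinite fold (zero denominator mean) for ",
              taxon)
  }
  out$fold_rounded <- round_fold(out$fold)
  rownames(out) <- NULL
  out
}
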