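# Reference group-mean tables from the three-species rumen acidosis
# feeding trial (Hanwoo, Holstein, Korean native goat; high-forage vs
# high-concentrate diet). These published species-by-diet summaries serve
# two roles: as worked-example inputs for the fold-change and mean
# summaries, and as planted ground truth for the synthetic study dataset.

#' Reference fermentation group means
#'
#' Species-by-diet group means of rumen fermentation responses (pH,
#' NH3-N in mg/dL, total VFA in mM, VFA molar proportions in mmol/mol,
#' acetate:propionate ratio) from the feeding trial the pipeline is
#' modelled on: 3 ruminant species, high-forage (HF) vs high-concentrate
#' (HC) diet.
#'
#' @return Data frame with `species`, `diet` and one column per response;
#'   one row per species-by-diet cell.
#' @export
reference_fermentation <- function() {
  path <- system.file("extdata", "fermentation_group_means.tsv",
                      package = "rumenTRFLP", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Reference bacterial abundance group means
#'
#' Species-by-diet group means of qPCR relative abundances (% of total
#' bacteria) for the seven-taxon assay panel (Prevotella spp.,
#' F. succinogenes, R. flavefaciens, S. bovis, Lactobacillus spp.,
#' S. ruminantium, M. elsdenii) from the same feeding trial.
#'
#' @return Data frame with `species`, `diet`, `taxon`,
#'   `abundance_percent`.
#' @export
reference_abundance <- function() {
  path <- system.file("extdata", "bacterial_abundance_group_means.tsv",
                      package = "rumenTRFLP", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Cast a group-mean table to fold-change inputs
#'
#' [group_fold_change()] expects an abundance table keyed by sample id
#' plus a metadata table. A published group-mean table has one row per
#' species-by-diet cell; this helper fabricates one pseudo-sample per
#' cell so group means pass through unchanged.
#'
#' @param ref a data frame like [reference_abundance()].
#' @return List with `abundance` and `meta` data frames.
#' @export
group_means_as_samples <- function(ref) {
  sample_id <- paste(ref$species, ref$diet, sep = "_")
  list(
    abundance = data.frame(sample_id = sample_id, taxon = ref$taxon,
                           abundance_percent = ref$abundance_percent,
                           stringsAsFactors = FALSE),
    meta = unique(data.frame(sample_id = sample_id,
                             species = ref$species, diet = ref$diet,
                             stringsAsFactors = FALSE))
  )
}
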