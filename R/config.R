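#' Default pipeline configuration
#'
#' Returns the full configuration tree used by every stage of the pipeline.
#' A user configuration file (plain `key: value` text, parsed as YAML)
#' overrides any subset of these entries; see [read_config()].
#'
#' Sections:
#' \describe{
#'   \item{io}{`delimiter` (`NULL` = auto-detect among tab/comma) and the
#'     column-name maps for peak, Ct and fermentation tables. Fragment
#'     analysis exports differ across instruments, so headers are mapped
#'     rather than fixed.}
#'   \item{trflp}{`min_bp`/`max_bp` size window (27, 520), `k_sd` multiplier
#'     of the zero-mean background SD (3), `max_iter` cap on detection
#'     iterations, `tolerance_bp` binning gap (0.5 bp).}
#'   \item{diversity}{`log_base` for the Shannon index (natural log).}
#'   \item{qpcr}{`sd_threshold` replicate-SD QC cutoff in cycles (0.5) and
#'     the reserved `total_taxon` label.}
#'   \item{sim}{synthetic-data defaults: community size and model, counts
#'     and scales of signal and background peaks, Ct baseline and noise,
#'     fermentation design and variance components.}
#' }
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    io = list(
      delimiter = NULL,
      peak_columns = list(sample = "sample_id", size = "size_bp",
                          height = "height_rfu"),
      ct_columns = list(sample = "sample_id", taxon = "taxon", ct = "ct"),
      ferm_columns = list(species = "species", animal = "animal_id",
                          diet = "diet")
    ),
    trflp = list(
      min_bp = 27,
      max_bp = 520,
      k_sd = 3,
      max_iter = 100L,
      tolerance_bp = 0.5
    ),
    diversity = list(
      log_base = exp(1)
    ),
    qpcr = list(
      sd_threshold = 0.5,
      total_taxon = "total"
    ),
    sim = list(
      n_taxa = 10L,
      community_model = "uniform",
      geometric_ratio = 0.5,
      n_background = 200L,
      background_scale = 15,
      signal_scale = 5000,
      signal_cv = 0.02,
      size_window = c(27, 520),
      ct_total = 20,
      ct_noise_sd = 0.3,
      n_replicates = 3L,
      n_animals = 4L,
      species = c("Hanwoo", "Holstein", "Goat"),
      diets = c("HF", "HC"),
      sigma_animal = 0.3,
      sigma_e = 0.1
    )
  )
}

#' Read a configuration file
#'
#' Parses a plain-text `key: value` (YAML) file and merges it recursively
#' over [default_config()], so a file needs to state only the entries it
#' changes.
#'
#' @param path path to the config file, or `NULL` for pure defaults.
#' @return The merged configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) {
    stop("configuration error: config file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  utils::modifyList(cfg, user)
}
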