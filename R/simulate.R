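# Synthetic-data generators. Electropherograms, Ct tables and
# fermentation records are produced with known ground truth so every
# downstream stage can be tested for recovery without any raw data.

#' Construct a community profile
#'
#' Ground truth for a simulated community: true terminal-fragment lengths
#' and their relative abundances.
#'
#' @param taxa fragment lengths (bp), all inside the analysis window.
#' @param abundances non-negative proportions summing to 1 (within 1e-12).
#' @return An object of class `community_profile`.
#' @export
community_profile <- function(taxa = numeric(0), abundances = numeric(0)) {
  stopifnot(length(taxa) == length(abundances))
  if (length(abundances) > 0L) {
    if (any(abundances < 0) || abs(sum(abundances) - 1) > 1e-12) {
      stop("abundances must be non-negative and sum to 1", call. = FALSE)
    }
  }
  structure(list(taxa = as.numeric(taxa),
                 abundances = as.numeric(abundances)),
            class = "community_profile")
}

draw_spaced_lengths <- function(n, window, min_spacing) {
  lengths <- numeric(0)
  attempts <- 0L
  while (length(lengths) < n) {
    cand <- stats::runif(1L, window[1L], window[2L])
    if (all(abs(cand - lengths) > min_spacing)) {
      lengths <- c(lengths, cand)
    }
    attempts <- attempts + 1L
    if (attempts > 10000L * n) {
      stop("cannot place ", n, " fragment lengths with spacing ",
           min_spacing, " bp inside the window", call. = FALSE)
    }
  }
  sort(lengths)
}

#' Simulate a community profile
#'
#' Draws `n_taxa` fragment lengths uniformly in the size window with a
#' minimum pairwise spacing of `2 * tolerance_bp` (rejection sampling), so
#' downstream binning ground truth is unambiguous, and assigns abundances
#' under one of three models: `uniform` (equal), `geometric`
#' (proportional to `ratio^(i-1)`, normalized) or `broken_stick` (sorted
#' uniform stick-breaking).
#'
#' @param n_taxa number of taxa (>= 1).
#' @param model abundance model.
#' @param seed integer seed (deterministic output) or `NULL`.
#' @param ratio geometric-series ratio (default 0.5).
#' @param size_window analysis window in bp (default `c(27, 520)`).
#' @param tolerance_bp binning tolerance used to set the spacing floor.
#' @return A [community_profile].
#' @export
simulate_community <- function(n_taxa,
                               model = c("uniform", "geometric",
                                         "broken_stick"),
                               seed = NULL, ratio = 0.5,
                               size_window = c(27, 520),
                               tolerance_bp = 0.5) {
  model <- match.arg(model)
  if (!is.numeric(n_taxa) || n_taxa < 1) {
    stop("`n_taxa` must be at least 1", call. = FALSE)
  }
  n_taxa <- as.integer(n_taxa)
  with_seed(seed, {
    taxa <- draw_spaced_lengths(n_taxa, size_window, 2 * tolerance_bp)
    abund <- switch(model,
      uniform = rep(1 / n_taxa, n_taxa),
      geometric = {
        w <- ratio^(seq_len(n_taxa) - 1)
        w / sum(w)
      },
      broken_stick = {
        if (n_taxa == 1L) 1 else {
          sort(diff(c(0, sort(stats::runif(n_taxa - 1L)), 1)),
               decreasing = TRUE)
        }
      })
    community_profile(taxa, abund)
  })
}

#' Simulate an electropherogram peak table
#'
#' Plants one true peak at each community fragment length with height
#' `signal_scale * abundance * (1 + N(0, signal_cv))`, and scatters
#' `n_background` background peaks at uniform-random lengths in the size
#' window with heights `|N(0, background_scale)|` — positive RFU values
#' whose zero-anchored scale matches the zero-mean background assumption
#' of the detection rule. Peaks are returned sorted by size; zero-height
#' peaks (possible only when a scale is 0) are dropped so all heights are
#' strictly positive.
#'
#' @param community a [community_profile] (may be empty for a
#'   background-only table).
#' @param sim simulation settings, a list like `default_config()$sim`
#'   (uses `signal_scale`, `signal_cv`, `n_background`,
#'   `background_scale`, `size_window`).
#' @param seed integer seed or `NULL`.
#' @param sample_id sample identifier for the returned table.
#' @return A [peak_table].
#' @export
simulate_electropherogram <- function(community,
                                      sim = default_config()$sim,
                                      seed = NULL, sample_id = "S1") {
  stopifnot(inherits(community, "community_profile"))
  if (sim$signal_scale <= 10 * sim$background_scale) {
    stop("`signal_scale` must exceed 10 * `background_scale` so that ",
         "true peaks are recoverable", call. = FALSE)
  }
  with_seed(seed, {
    n_t <- length(community$taxa)
    true_sizes <- community$taxa
    true_heights <- if (n_t > 0L) {
      sim$signal_scale * community$abundances *
        (1 + stats::rnorm(n_t, 0, sim$signal_cv))
    } else numeric(0)
    bg_sizes <- stats::runif(sim$n_background, sim$size_window[1L],
                             sim$size_window[2L])
    bg_heights <- abs(stats::rnorm(sim$n_background, 0,
                                   sim$background_scale))
    size <- c(true_sizes, bg_sizes)
    height <- c(true_heights, bg_heights)
    keep <- height > 0
    ord <- order(size[keep])
    peak_table(size[keep][ord], height[keep][ord], sample_id = sample_id)
  })
}

#' Simulate a replicate Ct table from known relative abundances
#'
#' Inverts the 2^-deltaCt transform: a taxon at `a`% of total bacteria
#' amplifies `log2(a / 100)` cycles after the total-bacteria assay, so
#' each replicate is `ct_total - log2(a / 100) + N(0, ct_noise_sd)`. A
#' total-bacteria record (taxon `"total"`) at `ct_total` plus noise is
#' always emitted.
#'
#' @param abundances named numeric vector of planted abundances, % of
#'   total bacteria, each in (0, 100].
#' @param ct_total true total-bacteria quantification cycle.
#' @param ct_noise_sd replicate noise SD in cycles.
#' @param n_replicates replicates per assay (>= 1).
#' @param seed integer seed or `NULL`.
#' @param sample_id sample identifier.
#' @param total_taxon label for the total-bacteria record.
#' @return A [ct_table] with `n_replicates` rows per taxon plus the total.
#' @export
simulate_ct_table <- function(abundances, ct_total = 20,
                              ct_noise_sd = 0.3, n_replicates = 3L,
                              seed = NULL, sample_id = "S1",
                              total_taxon = "total") {
  if (is.null(names(abundances)) || any(names(abundances) == "")) {
    stop("`abundances` must be a fully named vector", call. = FALSE)
  }
  if (any(abundances <= 0)) {
    stop("abundance <= 0 cannot be placed at a finite Ct", call. = FALSE)
  }
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  with_seed(seed, {
    taxa <- c(names(abundances), total_taxon)
    true_ct <- c(ct_total - log2(abundances / 100), ct_total)
    rows <- lapply(seq_along(taxa), function(i) {
      cts <- true_ct[i] + stats::rnorm(n_replicates, 0, ct_noise_sd)
      data.frame(sample_id = sample_id, taxon = taxa[i], ct = cts,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    ct_table(df$sample_id, df$taxon, df$ct)
  })
}

#' Simulate fermentation records for a species-by-diet split plot
#'
#' Generates a balanced design (every animal of every species measured on
#' both diets) with additive fixed effects, animal random intercepts
#' `N(0, sigma_animal^2)` and residuals `N(0, sigma_e^2)`. The fixed part
#' can be given either as a full species-by-diet `cell_means` matrix or as
#' `mu` plus named `species_effect`, `diet_effect` and `interaction`
#' terms.
#'
#' @param n_animals animals per species (>= 2).
#' @param species,diets factor level labels.
#' @param mu overall mean.
#' @param species_effect named numeric vector over `species` (default 0).
#' @param diet_effect named numeric vector over `diets` (default 0).
#' @param interaction species x diets matrix (default 0).
#' @param cell_means optional species x diets matrix of cell means; when
#'   given it overrides the effect terms.
#' @param sigma_animal,sigma_e random-intercept and residual SDs (>= 0).
#' @param seed integer seed or `NULL`.
#' @param response name of the response column in the output.
#' @return Data frame with columns `species`, `animal_id`, `diet` and the
#'   response.
#' @export
simulate_fermentation <- function(n_animals = 4L,
                                  species = c("Hanwoo", "Holstein",
                                              "Goat"),
                                  diets = c("HF", "HC"),
                                  mu = 0, species_effect = NULL,
                                  diet_effect = NULL, interaction = NULL,
                                  cell_means = NULL,
                                  sigma_animal = 0, sigma_e = 0,
                                  seed = NULL, response = "value") {
  if (n_animals < 2L) {
    stop("`n_animals` must be at least 2 per species", call. = FALSE)
  }
  if (sigma_animal < 0 || sigma_e < 0) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  if (is.null(cell_means)) {
    se <- stats::setNames(rep(0, length(species)), species)
    if (!is.null(species_effect)) se[names(species_effect)] <- species_effect
    de <- stats::setNames(rep(0, length(diets)), diets)
    if (!is.null(diet_effect)) de[names(diet_effect)] <- diet_effect
    ia <- matrix(0, length(species), length(diets),
                 dimnames = list(species, diets))
    if (!is.null(interaction)) {
      ia[rownames(interaction), colnames(interaction)] <- interaction
    }
    cell_means <- outer(se, de, "+") + mu + ia
  } else {
    cell_means <- as.matrix(cell_means)[species, diets, drop = FALSE]
  }
  with_seed(seed, {
    grid <- expand.grid(animal = seq_len(n_animals), species = species,
                        stringsAsFactors = FALSE)
    b <- stats::rnorm(nrow(grid), 0, sigma_animal)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      sp <- grid$species[i]
      aid <- paste0(sp, "_A", grid$animal[i])
      e <- stats::rnorm(length(diets), 0, sigma_e)
      data.frame(species = sp, animal_id = aid, diet = diets,
                 value = cell_means[sp, diets] + b[i] + e,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    names(out)[names(out) == "value"] <- response
    out
  })
}
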