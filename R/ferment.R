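# Species-by-diet statistics: group summaries, the classic balanced
# split-plot ANOVA (whole plot: species vs animal-within-species; sub
# plot: diet and species x diet vs residual), and Tukey pairwise
# comparisons from the studentized range distribution.

check_split_plot_design <- function(records) {
  animal_uid <- paste(records$species, records$animal_id, sep = "\r")
  tab <- table(animal_uid, records$diet)
  r <- unique(as.vector(tab))
  if (length(r) != 1L || r[1L] < 1L) return(NULL)
  animals_per_species <- table(records$species[!duplicated(animal_uid)])
  if (length(unique(as.vector(animals_per_species))) != 1L) return(NULL)
  list(n_animals = unname(animals_per_species[1L]),
       n_species = length(unique(records$species)),
       n_diets = length(unique(records$diet)),
       reps = r[1L])
}

#' Species-by-diet split-plot analysis of variance
#'
#' Fits the model `y = mu + species + animal(species) + diet +
#' species:diet + e` on a balanced design: species is the whole-plot
#' factor tested against the animal-within-species stratum, while diet
#' and the species-by-diet interaction are sub-plot effects tested
#' against the residual. On balanced data this classic decomposition is
#' exact (and coincides with REML-based mixed-model F tests). Unbalanced
#' input is rejected outright rather than approximated — use a general
#' mixed-model tool (e.g. `lme4`/`lmerTest`) for such designs.
#'
#' @param records data frame with `species`, `animal_id`, `diet` and the
#'   response column; animal ids need only be unique within species.
#' @param response name of the response column.
#' @return An object of class `split_plot_anova`: list with `table` (one
#'   row per effect: df, sum of squares, mean square, error stratum, F,
#'   p), `variance_components` (animal and residual), `cell_means`,
#'   `overflow` (TRUE when a zero error stratum drove an F to infinity)
#'   and the design dimensions.
#' @export
split_plot_anova <- function(records, response = "value") {
  stopifnot(all(c("species", "animal_id", "diet", response) %in%
                  names(records)))
  if (any(is.na(records[[response]]))) {
    stop("missing values in response '", response, "'", call. = FALSE)
  }
  design <- check_split_plot_design(records)
  if (is.null(design)) {
    stop("unsupported design: split_plot_anova requires a balanced ",
         "design (equal animals per species, every animal observed ",
         "equally often on every diet); fit unbalanced data with a ",
         "general mixed-model tool instead", call. = FALSE)
  }
  df <- data.frame(
    y = records[[response]],
    species = factor(records$species),
    diet = factor(records$diet),
    animal_uid = factor(paste(records$species, records$animal_id,
                              sep = ":"))
  )
  fit <- stats::aov(y ~ species * diet + Error(animal_uid), data = df)
  s <- summary(fit)
  wp <- s[["Error: animal_uid"]][[1L]]
  sb <- s[["Error: Within"]][[1L]]
  row_of <- function(tab, name) {
    i <- which(trimws(rownames(tab)) == name)
    unlist(tab[i, c("Df", "Sum Sq", "Mean Sq")], use.names = FALSE)
  }
  sp <- row_of(wp, "species")
  an <- row_of(wp, "Residuals")
  di <- row_of(sb, "diet")
  ia <- row_of(sb, "species:diet")
  re <- row_of(sb, "Residuals")

  f_p <- function(ms, df1, err_ms, df2) {
    # an error mean square that is zero to rounding (exactly replicated
    # data) drives F beyond any meaningful scale; report it as infinite
    if (err_ms <= 0 || (ms > 0 && ms / err_ms > 1e12)) {
      if (ms <= err_ms) return(c(NaN, NaN))
      return(c(Inf, 0))
    }
    f <- ms / err_ms
    c(f, stats::pf(f, df1, df2, lower.tail = FALSE))
  }
  sp_fp <- f_p(sp[3L], sp[1L], an[3L], an[1L])
  di_fp <- f_p(di[3L], di[1L], re[3L], re[1L])
  ia_fp <- f_p(ia[3L], ia[1L], re[3L], re[1L])

  tab <- data.frame(
    effect = c("species", "animal(species)", "diet", "species:diet",
               "residual"),
    df = c(sp[1L], an[1L], di[1L], ia[1L], re[1L]),
    sum_sq = c(sp[2L], an[2L], di[2L], ia[2L], re[2L]),
    mean_sq = c(sp[3L], an[3L], di[3L], ia[3L], re[3L]),
    error_stratum = c("animal(species)", NA, "residual", "residual", NA),
    F = c(sp_fp[1L], NA, di_fp[1L], ia_fp[1L], NA),
    p = c(sp_fp[2L], NA, di_fp[2L], ia_fp[2L], NA),
    stringsAsFactors = FALSE
  )
  n_per_animal <- design$n_diets * design$reps
  cm <- tapply(df$y, list(df$species, df$diet), mean)
  structure(list(
    table = tab,
    variance_components = c(
      animal = (an[3L] - re[3L]) / n_per_animal,
      residual = re[3L]
    ),
    cell_means = cm,
    overflow = any(!is.finite(tab$F) & !is.na(tab$F)),
    design = design,
    response = response
  ), class = "split_plot_anova")
}

#' @export
print.split_plot_anova <- function(x, ...) {
  cat("Split-plot ANOVA of '", x$response, "'\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Species-by-diet mean table
#'
#' Cell means with marginal species/diet means and, when the design is
#' balanced with positive residual degrees of freedom, the pooled SEM
#' from the residual stratum of the split-plot decomposition
#' (`sqrt(MS_residual / n_per_cell)`). Marginal and grand means are
#' unweighted means of cell means. Works on raw records or on published
#' group-mean tables with one row per cell (SEM is then `NA`).
#'
#' @param records data frame with `species`, `diet` and the response
#'   column (`animal_id` needed only for the SEM).
#' @param response name of the response column.
#' @return A list of class `mean_table`: `cells` (species, diet, mean,
#'   n), `species_means`, `diet_means`, `grand_mean`, `sem`.
#' @export
summarize_means <- function(records, response = "value") {
  stopifnot(all(c("species", "diet", response) %in% names(records)))
  y <- records[[response]]
  keep <- !is.na(y)
  if (any(!keep)) {
    trflp_log("warning", sum(!keep), " missing value(s) in '", response,
              "' dropped")
  }
  rec <- records[keep, , drop = FALSE]
  species <- unique(rec$species)
  diets <- unique(rec$diet)
  grid <- expand.grid(species = species, diet = diets,
                      stringsAsFactors = FALSE)
  grid$mean <- NA_real_
  grid$n <- 0L
  for (i in seq_len(nrow(grid))) {
    v <- rec[[response]][rec$species == grid$species[i] &
                           rec$diet == grid$diet[i]]
    grid$n[i] <- length(v)
    if (length(v) > 0L) grid$mean[i] <- mean(v)
  }
  if (any(grid$n == 0L)) {
    trflp_log("warning", "empty cell(s) in the species x diet table; ",
              "reported as missing")
  }
  sem <- NA_real_
  if ("animal_id" %in% names(rec) && all(grid$n > 0L)) {
    design <- check_split_plot_design(rec)
    if (!is.null(design)) {
      fit <- split_plot_anova(rec, response)
      ms_res <- fit$table$mean_sq[fit$table$effect == "residual"]
      df_res <- fit$table$df[fit$table$effect == "residual"]
      if (df_res > 0) sem <- sqrt(ms_res / grid$n[1L])
    }
  }
  cm <- grid$mean
  structure(list(
    cells = grid,
    species_means = vapply(species, function(s) {
      mean(cm[grid$species == s])
    }, numeric(1)),
    diet_means = vapply(diets, function(d) {
      mean(cm[grid$diet == d])
    }, numeric(1)),
    grand_mean = mean(cm, na.rm = TRUE),
    sem = sem,
    response = response
  ), class = "mean_table")
}

#' @export
print.mean_table <- function(x, ...) {
  cat("Means of '", x$response, "' (SEM ",
      ifelse(is.na(x$sem), "n/a", format(x$sem, digits = 3)), ")\n",
      sep = "")
  print(x$cells, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey pairwise comparisons from the studentized range
#'
#' Adjusted p-values for all pairwise differences among balanced group
#' means: `q = |m_i - m_j| / sqrt(ms_error / n_per_cell)` referred to the
#' studentized range distribution with `length(means)` means and
#' `df_error` degrees of freedom (computed numerically via
#' [stats::ptukey()], no lookup tables).
#'
#' @param means named vector of group (cell) means.
#' @param ms_error mean square of the error stratum the groups were
#'   tested against.
#' @param df_error its degrees of freedom (> 0).
#' @param n_per_cell observations per group.
#' @return Data frame with `group1`, `group2`, `diff`, `q`, `p_adj`.
#' @export
tukey_pairwise <- function(means, ms_error, df_error, n_per_cell) {
  if (df_error <= 0) stop("`df_error` must be > 0", call. = FALSE)
  if (is.null(names(means))) {
    names(means) <- paste0("group", seq_along(means))
  }
  k <- length(means)
  se <- sqrt(ms_error / n_per_cell)
  pairs <- utils::combn(k, 2L)
  diff <- means[pairs[1L, ]] - means[pairs[2L, ]]
  q <- abs(diff) / se
  p <- stats::ptukey(q, nmeans = k, df = df_error, lower.tail = FALSE)
  data.frame(group1 = names(means)[pairs[1L, ]],
             group2 = names(means)[pairs[2L, ]],
             diff = unname(diff), q = unname(q), p_adj = unname(p),
             stringsAsFactors = FALSE)
}

#' Tukey comparisons of the species-by-diet cells of a split-plot fit
#'
#' Compares all species-by-diet cell means using the sub-plot (residual)
#' error stratum of a [split_plot_anova()] fit.
#'
#' @param fit a `split_plot_anova` object.
#' @return As [tukey_pairwise()].
#' @export
tukey_cells <- function(fit) {
  stopifnot(inherits(fit, "split_plot_anova"))
  cm <- fit$cell_means
  means <- as.vector(cm)
  names(means) <- outer(rownames(cm), colnames(cm), paste, sep = ":")
  n_cell <- fit$design$n_animals * fit$design$reps
  tab <- fit$table
  tukey_pairwise(means,
                 ms_error = tab$mean_sq[tab$effect == "residual"],
                 df_error = tab$df[tab$effect == "residual"],
                 n_per_cell = n_cell)
}

#' Classify a p-value by the study's reporting convention
#'
#' `p < 0.05` is significant and `0.05 <= p < 0.1` is reported as a
#' trend.
#'
#' @param p numeric p-value(s).
#' @param alpha significance threshold.
#' @param trend trend threshold.
#' @return Character vector: `"significant"`, `"trend"` or `"ns"`.
#' @export
classify_significance <- function(p, alpha = 0.05, trend = 0.1) {
  ifelse(p < alpha, "significant", ifelse(p < trend, "trend", "ns"))
}
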