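# Delimited-text input/output. All tabular formats are TSV/CSV with a
# header row; delimiter auto-detection looks at the header line only.

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return("\t")
  n_tab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
  n_com <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  if (n_com > n_tab) "," else "\t"
}

read_delim_raw <- function(path, delimiter = NULL) {
  if (!file.exists(path)) {
    stop("I/O error: file not found: ", path, call. = FALSE)
  }
  sep <- delimiter %||% detect_delimiter(path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return(NULL)
  utils::read.table(path, header = TRUE, sep = sep,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(unlist(cols), names(df))
  if (length(missing) > 0L) {
    stop("configuration error: ", what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(NULL)
}

#' Read a peak table export
#'
#' Reads tabulated electropherogram peaks (one row per peak: sample id,
#' fragment size in bp, height in RFU) as exported by fragment-analysis
#' software, and partitions them into one [peak_table()] per sample.
#' Rows whose size or height is non-numeric or negative are rejected with
#' a logged count; row order within a sample is preserved.
#'
#' @param path path to a delimited text file.
#' @param config configuration list (see [default_config()]); the
#'   `io$peak_columns` map names the sample/size/height columns and
#'   `io$delimiter` fixes the delimiter (default auto-detect).
#' @return A named list of `peak_table` objects, keyed by sample id.
#'   An empty file yields an empty list with a logged warning.
#' @export
read_peak_table <- function(path, config = default_config()) {
  cols <- config$io$peak_columns
  df <- read_delim_raw(path, config$io$delimiter)
  if (is.null(df) || nrow(df) == 0L) {
    trflp_log("warning", "peak table ", path, " is empty")
    return(structure(list(), names = character(0)))
  }
  require_columns(df, cols, "peak table")
  sample_id <- df[[cols$sample]]
  size <- suppressWarnings(as.numeric(df[[cols$size]]))
  height <- suppressWarnings(as.numeric(df[[cols$height]]))
  ok <- is.finite(size) & is.finite(height) & size >= 0 & height >= 0
  n_rej <- sum(!ok)
  if (n_rej > 0L) {
    trflp_log("info", n_rej, " peak row(s) rejected (non-numeric or ",
              "negative size/height)")
  }
  sample_id <- sample_id[ok]; size <- size[ok]; height <- height[ok]
  ids <- unique(sample_id)
  out <- lapply(ids, function(id) {
    sel <- sample_id == id
    peak_table(size[sel], height[sel], sample_id = id)
  })
  names(out) <- ids
  out
}

#' Read a qPCR Ct table
#'
#' Reads replicate Ct values in long format (sample id, target taxon, Ct).
#' Replicates are kept as individual rows; aggregation happens in
#' [aggregate_ct()]. Rows with Ct that is non-numeric or not strictly
#' positive are rejected with a warning-level log entry. A (sample, taxon)
#' group observed with a single replicate is flagged in the log.
#'
#' @inheritParams read_peak_table
#' @return A data frame of class `ct_table` with columns `sample_id`,
#'   `taxon`, `ct`.
#' @export
read_ct_table <- function(path, config = default_config()) {
  cols <- config$io$ct_columns
  df <- read_delim_raw(path, config$io$delimiter)
  if (is.null(df) || nrow(df) == 0L) {
    trflp_log("warning", "Ct table ", path, " is empty")
    return(ct_table(character(0), character(0), numeric(0)))
  }
  require_columns(df, cols, "Ct table")
  ct <- suppressWarnings(as.numeric(df[[cols$ct]]))
  ok <- is.finite(ct) & ct > 0
  if (any(!ok)) {
    trflp_log("warning", sum(!ok), " Ct row(s) rejected (Ct missing or <= 0)")
  }
  out <- ct_table(df[[cols$sample]][ok], df[[cols$taxon]][ok], ct[ok])
  reps <- table(paste(out$sample_id, out$taxon, sep = "\r"))
  if (any(reps == 1L)) {
    trflp_log("info", sum(reps == 1L),
              " (sample, taxon) group(s) have a single Ct replicate")
  }
  out
}

#' Read fermentation records
#'
#' Reads one row per animal-by-diet observation: species, animal id, diet,
#' and one column per measured response (pH, NH3-N, VFA variables, ...).
#' Response columns are every column not named in the design map; they are
#' coerced to numeric.
#'
#' @inheritParams read_peak_table
#' @return A data frame with columns `species`, `animal_id`, `diet` and one
#'   numeric column per response.
#' @export
read_fermentation <- function(path, config = default_config()) {
  cols <- config$io$ferm_columns
  df <- read_delim_raw(path, config$io$delimiter)
  if (is.null(df) || nrow(df) == 0L) {
    trflp_log("warning", "fermentation table ", path, " is empty")
    return(data.frame(species = character(0), animal_id = character(0),
                      diet = character(0)))
  }
  require_columns(df, cols, "fermentation table")
  out <- data.frame(species = df[[cols$species]],
                    animal_id = df[[cols$animal]],
                    diet = df[[cols$diet]],
                    stringsAsFactors = FALSE)
  responses <- setdiff(names(df), unlist(cols))
  for (r in responses) out[[r]] <- suppressWarnings(as.numeric(df[[r]]))
  out
}

# --- writing ---------------------------------------------------------------

write_atomic <- function(write_fun, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("I/O error: output directory does not exist: ", dir, call. = FALSE)
  }
  if (file.access(dir, 2L) != 0L) {
    stop("I/O error: output directory is not writable: ", dir, call. = FALSE)
  }
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  if (!file.rename(tmp, path)) {
    stop("I/O error: could not move temporary file onto ", path,
         call. = FALSE)
  }
  invisible(path)
}

write_tsv <- function(df, path, digits = 12L) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, format(x, digits = digits, trim = TRUE,
                                           scientific = FALSE))
  })
  write_atomic(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }, path)
}

#' Write a binned matrix as TSV
#'
#' Bins are rows; the first column `bin_bp` is the representative fragment
#' length, remaining columns are samples. Values are written to 12
#' significant digits so a write/read round trip is the identity at that
#' precision. The write is atomic (temp file then rename).
#'
#' @param bm a [binned_matrix] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binned_matrix <- function(bm, path) {
  stopifnot(inherits(bm, "binned_matrix"))
  df <- data.frame(bin_bp = bm$bins$representative_length,
                   check.names = FALSE)
  v <- bm$values
  for (j in seq_len(ncol(v))) df[[colnames(v)[j]]] <- v[, j]
  write_tsv(df, path)
}

#' Re-read a binned matrix written by [write_binned_matrix()]
#'
#' @param path path to the TSV.
#' @param standardized whether the stored values were standardized.
#' @return A [binned_matrix] object.
#' @export
read_binned_matrix <- function(path, standardized = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- format_bp(df$bin_bp)
  new_binned_matrix(values, bins = data.frame(
    representative_length = df$bin_bp,
    n_members = NA_integer_
  ), standardized = standardized)
}

#' Write a dendrogram in Newick format
#'
#' Converts the clustering tree (leaf names = sample ids, branch lengths =
#' parent-child merge-height differences) to `phylo` form and writes
#' Newick text atomically.
#'
#' @param hc an `hclust` object, e.g. from [complete_linkage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  write_atomic(function(tmp) ape::write.tree(phy, file = tmp), path)
}

#' Write all pipeline outputs
#'
#' Writes whichever result components are present in `results` to
#' `out_dir`: `binned_matrix.tsv`, `diversity.tsv`, `dendrogram.nwk`,
#' `pca_scores.tsv`, `pca_variance.tsv`, `abundance.tsv`,
#' `fold_changes.tsv`, `anova_<response>.tsv`. Every file write is atomic,
#' and the output directory is checked for writability before any file is
#' produced.
#'
#' @param results a named list; recognised components: `binned` (a
#'   [binned_matrix]), `diversity` (data frame), `tree` (`hclust`), `pca`
#'   (from [pca()]), `abundance`, `fold_changes` (data frames), `anova`
#'   (named list of [split_plot_anova()] results).
#' @param out_dir output directory, created if absent.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create output directory: ", out_dir,
                  call. = FALSE)
  }
  if (file.access(out_dir, 2L) != 0L) {
    stop("I/O error: output directory is not writable: ", out_dir,
         call. = FALSE)
  }
  written <- character(0)
  put <- function(p) written <<- c(written, p)
  if (!is.null(results$binned)) {
    put(write_binned_matrix(results$binned,
                            file.path(out_dir, "binned_matrix.tsv")))
  }
  if (!is.null(results$diversity)) {
    put(write_tsv(results$diversity, file.path(out_dir, "diversity.tsv")))
  }
  if (!is.null(results$tree)) {
    put(write_newick(results$tree, file.path(out_dir, "dendrogram.nwk")))
  }
  if (!is.null(results$pca)) {
    sc <- as.data.frame(results$pca$scores)
    sc <- cbind(sample_id = rownames(results$pca$scores), sc)
    put(write_tsv(sc, file.path(out_dir, "pca_scores.tsv")))
    pv <- data.frame(component = seq_along(results$pca$variance),
                     variance = results$pca$variance,
                     variance_explained_percent =
                       results$pca$variance_explained_percent)
    put(write_tsv(pv, file.path(out_dir, "pca_variance.tsv")))
  }
  if (!is.null(results$abundance)) {
    put(write_tsv(results$abundance, file.path(out_dir, "abundance.tsv")))
  }
  if (!is.null(results$fold_changes)) {
    put(write_tsv(results$fold_changes,
                  file.path(out_dir, "fold_changes.tsv")))
  }
  if (!is.null(results$anova)) {
    for (resp in names(results$anova)) {
      put(write_tsv(results$anova[[resp]]$table,
                    file.path(out_dir, paste0("anova_", resp, ".tsv"))))
    }
  }
  invisible(written)
}
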