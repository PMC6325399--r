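# T-RFLP processing chain: size filtering, iterative true-peak detection
# against a zero-mean background, cross-sample binning, standardization.

#' Construct a peak table
#'
#' One sample's electropherogram, tabulated as (fragment size bp, peak
#' height RFU) pairs in instrument order.
#'
#' @param size numeric vector of fragment sizes (bp), non-negative.
#' @param height numeric vector of peak heights (RFU), non-negative.
#' @param sample_id sample identifier.
#' @return A data frame of class `peak_table` with columns `size` and
#'   `height` and a `sample_id` attribute.
#' @export
peak_table <- function(size = numeric(0), height = numeric(0),
                       sample_id = NA_character_) {
  stopifnot(length(size) == length(height))
  if (any(!is.finite(size)) || any(!is.finite(height)) ||
      any(size < 0) || any(height < 0)) {
    stop("peak sizes and heights must be finite and non-negative",
         call. = FALSE)
  }
  structure(data.frame(size = as.numeric(size),
                       height = as.numeric(height)),
            sample_id = as.character(sample_id),
            class = c("peak_table", "data.frame"))
}

sample_id_of <- function(pt) attr(pt, "sample_id", exact = TRUE)

#' Construct a Ct table
#' @param sample_id,taxon character vectors.
#' @param ct numeric vector of quantification cycles, strictly positive.
#' @return A data frame of class `ct_table`.
#' @export
ct_table <- function(sample_id, taxon, ct) {
  if (any(!is.finite(ct) & !is.na(ct)) || any(ct <= 0, na.rm = TRUE)) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  structure(data.frame(sample_id = as.character(sample_id),
                       taxon = as.character(taxon),
                       ct = as.numeric(ct),
                       stringsAsFactors = FALSE),
            class = c("ct_table", "data.frame"))
}

format_bp <- function(x) sprintf("%.2f", x)

new_binned_matrix <- function(values, bins, standardized = FALSE,
                              zero_samples = character(0)) {
  structure(list(values = values, bins = bins,
                 standardized = standardized,
                 zero_samples = zero_samples),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("binned_matrix: %d bin(s) x %d sample(s), %s\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) "standardized" else "raw heights"))
  invisible(x)
}

#' Discard fragments outside the analysis size window
#'
#' Terminal restriction fragments shorter than `min_bp` or longer than
#' `max_bp` fall outside the sizing standard's reliable range and are
#' discarded. Bounds are inclusive: only fragments strictly below the
#' minimum or strictly above the maximum are removed. Peak order is
#' preserved.
#'
#' @param pt a [peak_table].
#' @param min_bp,max_bp window bounds in bp (defaults 27 and 520).
#' @return The filtered `peak_table` (possibly empty).
#' @export
filter_by_size <- function(pt, min_bp = 27, max_bp = 520) {
  stopifnot(inherits(pt, "peak_table"))
  if (!(min_bp < max_bp)) {
    stop("`min_bp` must be strictly less than `max_bp`", call. = FALSE)
  }
  keep <- pt$size >= min_bp & pt$size <= max_bp
  out <- pt[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, sample_id = sample_id_of(pt),
            class = c("peak_table", "data.frame"))
}

#' Iterative true-peak detection against a zero-mean background
#'
#' Background peaks in a sized electropherogram are assumed to scatter
#' about zero height, so the background scale is the root mean square of
#' heights, `SD = sqrt(sum(h^2)/n)` (divisor `n`, since the mean is known
#' to be zero). Each iteration computes this SD over the peaks not yet
#' declared true, declares true every remaining peak with height strictly
#' greater than `k_sd * SD`, and repeats until an iteration declares
#' none (or `max_iter` is reached, which flags non-convergence). While
#' large true peaks remain in the pool they inflate the SD, so the rule
#' peels them off from the top down.
#'
#' @param pt a size-filtered [peak_table].
#' @param k_sd SD multiplier for the threshold (default 3).
#' @param max_iter iteration cap (default 100).
#' @return An object of class `true_peak_set`: list with `sample_id`,
#'   `true_peaks` and `background` (both `peak_table`s partitioning the
#'   input), `n_iterations`, `final_sd` (the SD at the last iteration) and
#'   `converged`. Empty input gives an empty set with 0 iterations.
#' @export
detect_true_peaks <- function(pt, k_sd = 3, max_iter = 100L) {
  stopifnot(inherits(pt, "peak_table"))
  if (k_sd <= 0) stop("`k_sd` must be positive", call. = FALSE)
  h <- pt$height
  n <- length(h)
  is_true <- logical(n)
  n_iter <- 0L
  final_sd <- NA_real_
  converged <- TRUE
  if (n > 0L) {
    repeat {
      n_iter <- n_iter + 1L
      rem <- h[!is_true]
      s <- if (length(rem) > 0L) sqrt(mean(rem^2)) else 0
      final_sd <- s
      newly <- !is_true & h > k_sd * s
      if (!any(newly)) break
      is_true[newly] <- TRUE
      if (n_iter >= max_iter) {
        converged <- FALSE
        break
      }
    }
  }
  subset_pt <- function(keep) {
    structure(data.frame(size = pt$size[keep], height = pt$height[keep]),
              sample_id = sample_id_of(pt),
              class = c("peak_table", "data.frame"))
  }
  structure(list(sample_id = sample_id_of(pt),
                 true_peaks = subset_pt(is_true),
                 background = subset_pt(!is_true),
                 n_iterations = n_iter,
                 final_sd = final_sd,
                 converged = converged),
            class = "true_peak_set")
}

#' @export
print.true_peak_set <- function(x, ...) {
  cat(sprintf(
    "true_peak_set '%s': %d true / %d total peaks, %d iteration(s)%s\n",
    x$sample_id, nrow(x$true_peaks),
    nrow(x$true_peaks) + nrow(x$background), x$n_iterations,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Bin true-peak fragment lengths across samples
#'
#' All true-peak fragment lengths are pooled over samples and sorted;
#' consecutive lengths whose gap is at most `tolerance_bp` chain into one
#' bin. Duplicate lengths (the same length seen in several samples) are
#' counted once when the bin's representative length is computed as the
#' mean of its distinct member lengths. Within each sample, heights of
#' peaks falling in the same bin are summed; a sample with no peak in a
#' bin gets 0.
#'
#' @param tps_list a (preferably named) list of `true_peak_set` objects,
#'   one per sample, from [detect_true_peaks()].
#' @param tolerance_bp maximum gap between consecutive pooled lengths kept
#'   in one bin (default 0.5 bp).
#' @return An unstandardized [binned_matrix]; `values` is bins x samples.
#' @export
bin_fragments <- function(tps_list, tolerance_bp = 0.5) {
  if (tolerance_bp < 0) stop("`tolerance_bp` must be >= 0", call. = FALSE)
  stopifnot(length(tps_list) > 0L,
            all(vapply(tps_list, inherits, logical(1), "true_peak_set")))
  ids <- names(tps_list) %||%
    vapply(tps_list, function(t) t$sample_id, character(1))
  if (is.null(names(tps_list))) names(tps_list) <- ids

  pooled <- do.call(rbind, lapply(ids, function(id) {
    tp <- tps_list[[id]]$true_peaks
    if (nrow(tp) == 0L) return(NULL)
    data.frame(sample = id, size = tp$size, height = tp$height)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    values <- matrix(0, nrow = 0L, ncol = length(ids),
                     dimnames = list(NULL, ids))
    return(new_binned_matrix(values, data.frame(
      representative_length = numeric(0), n_members = integer(0))))
  }

  ord <- order(pooled$size)
  pooled <- pooled[ord, , drop = FALSE]
  gaps <- diff(pooled$size)
  bin_id <- cumsum(c(1L, as.integer(gaps > tolerance_bp)))

  n_bins <- max(bin_id)
  rep_len <- vapply(seq_len(n_bins), function(b) {
    mean(unique(pooled$size[bin_id == b]))
  }, numeric(1))
  n_members <- vapply(seq_len(n_bins), function(b) {
    length(unique(pooled$size[bin_id == b]))
  }, integer(1))

  values <- matrix(0, nrow = n_bins, ncol = length(ids),
                   dimnames = list(format_bp(rep_len), ids))
  agg <- tapply(pooled$height,
                list(factor(bin_id, levels = seq_len(n_bins)),
                     factor(pooled$sample, levels = ids)),
                sum)
  agg[is.na(agg)] <- 0
  values[] <- agg

  new_binned_matrix(values,
                    data.frame(representative_length = rep_len,
                               n_members = n_members))
}

#' Standardize a binned matrix to within-sample relative abundances
#'
#' Divides each sample column by its total summed height so standardized
#' peak heights represent the relative abundance of each fragment within
#' the sample. All-zero columns (samples with no true peaks) are left as
#' zeros and listed in `zero_samples`.
#'
#' @param bm an unstandardized [binned_matrix] from [bin_fragments()].
#' @return The standardized `binned_matrix`.
#' @export
standardize <- function(bm) {
  stopifnot(inherits(bm, "binned_matrix"))
  if (bm$standardized) {
    stop("matrix is already standardized", call. = FALSE)
  }
  totals <- colSums(bm$values)
  zero <- colnames(bm$values)[totals == 0]
  if (length(zero) > 0L) {
    trflp_log("warning", "sample(s) with no true peaks left all-zero: ",
              paste(zero, collapse = ", "))
  }
  scale <- ifelse(totals == 0, 1, totals)
  values <- sweep(bm$values, 2L, scale, "/")
  new_binned_matrix(values, bm$bins, standardized = TRUE,
                    zero_samples = zero)
}
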