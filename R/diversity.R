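# Per-sample diversity indices on standardized relative-abundance profiles.

check_simplex <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("relative abundances must be finite and non-negative",
         call. = FALSE)
  }
  if (all(p == 0)) return(FALSE)
  if (abs(sum(p) - 1) > 1e-9) {
    stop("relative abundances must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  TRUE
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over the positive entries of a relative
#' abundance vector; zero entries contribute nothing. Natural logarithm by
#' default (the conventional base for this index), configurable via
#' `base`.
#'
#' @param p relative-abundance vector summing to 1 (zeros allowed).
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return The index value; `NA` for an all-zero vector (undefined).
#' @export
shannon <- function(p, base = exp(1)) {
  if (!check_simplex(p)) return(NA_real_)
  q <- p[p > 0]
  -sum(q * log(q, base = base))
}

#' Inverse Simpson diversity index
#'
#' `D = 1 / sum(p_i^2)`: the effective number of equally abundant types.
#'
#' @inheritParams shannon
#' @return The index value; `NA` for an all-zero vector (undefined).
#' @export
inverse_simpson <- function(p) {
  if (!check_simplex(p)) return(NA_real_)
  1 / sum(p^2)
}

#' Per-sample diversity table
#'
#' Computes richness (count of nonzero bins), Shannon and inverse-Simpson
#' indices for every sample column of a standardized binned matrix,
#' optionally joined to sample metadata.
#'
#' @param bm a standardized [binned_matrix].
#' @param meta optional data frame with a `sample_id` column plus labels
#'   (e.g. `species`, `animal_id`, `diet`) to join.
#' @param base Shannon logarithm base.
#' @return A data frame with one row per sample: `sample_id`, any joined
#'   metadata, `richness`, `shannon`, `inverse_simpson`.
#' @export
diversity_table <- function(bm, meta = NULL, base = exp(1)) {
  stopifnot(inherits(bm, "binned_matrix"))
  if (!bm$standardized) {
    stop("contract violation: diversity_table requires a standardized ",
         "binned matrix; call standardize() first", call. = FALSE)
  }
  v <- bm$values
  out <- data.frame(
    sample_id = colnames(v),
    richness = as.integer(colSums(v > 0)),
    shannon = apply(v, 2L, shannon, base = base),
    inverse_simpson = apply(v, 2L, inverse_simpson),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(meta)) {
    keep <- setdiff(names(meta), "sample_id")
    out <- merge(out, meta[, c("sample_id", keep), drop = FALSE],
                 by = "sample_id", all.x = TRUE, sort = FALSE)
    out <- out[, c("sample_id", keep, "richness", "shannon",
                   "inverse_simpson")]
  }
  out
}
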