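# Shared fixture builders, all programmatic.

make_tps <- function(sample_id, sizes, heights) {
  structure(list(
    sample_id = sample_id,
    true_peaks = peak_table(sizes, heights, sample_id = sample_id),
    background = peak_table(sample_id = sample_id),
    n_iterations = 1L, final_sd = 0, converged = TRUE
  ), class = "true_peak_set")
}

make_bm <- function(values, standardized = FALSE) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("%.2f", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  structure(list(values = values,
                 bins = data.frame(
                   representative_length = seq_len(nrow(values)),
                   n_members = 1L),
                 standardized = standardized,
                 zero_samples = character(0)),
            class = "binned_matrix")
}

random_peak_table <- function(n_big = NULL, n_small = NULL) {
  # a few large signal-like peaks over many small background-like ones
  n_big <- n_big %||% sample(0:6, 1L)
  n_small <- n_small %||% sample(10:60, 1L)
  heights <- c(stats::runif(n_big, 200, 2000),
               abs(stats::rnorm(n_small, 0, stats::runif(1, 1, 30))))
  heights <- heights[heights > 0]
  peak_table(stats::runif(length(heights), 27, 520), heights,
             sample_id = "R")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
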