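#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulation helpers do
#' not perturb the caller's random number stream. A `NULL` seed evaluates
#' the expression under the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Fixed per-stream offsets: adding a stream must not perturb the others.
# Sub-seeds stay well below .Machine$integer.max for seeds up to ~2e9 - 1e6.
.seed_offsets <- c(
  community       = 101L,
  electropherogram = 20000L,  # + sample index
  ct              = 40000L,   # + sample index
  fermentation    = 60000L
)

#' Derive a per-stream sub-seed from a global seed
#' @param seed global integer seed (or `NULL`, passed through).
#' @param stream one of `"community"`, `"electropherogram"`, `"ct"`,
#'   `"fermentation"`.
#' @param index optional non-negative integer (e.g. sample number) added on
#'   top of the stream offset.
#' @return integer sub-seed, or `NULL` when `seed` is `NULL`.
#' @export
sub_seed <- function(seed, stream, index = 0L) {
  if (is.null(seed)) return(NULL)
  stream <- match.arg(stream, names(.seed_offsets))
  as.integer(seed) + .seed_offsets[[stream]] + as.integer(index)
}

.log_levels <- c(debug = 10L, info = 20L, warning = 30L, error = 40L)

#' Package logging
#'
#' Messages at or above the level set by `options(rumenTRFLP.log_level=)`
#' (default `"info"`) are emitted via [message()] so they can be captured
#' or suppressed by the usual condition machinery.
#' @param level one of `"debug"`, `"info"`, `"warning"`.
#' @param ... pasted into the message.
#' @keywords internal
trflp_log <- function(level, ...) {
  threshold <- getOption("rumenTRFLP.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}
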