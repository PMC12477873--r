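#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stream-specific child seed from a master seed
#'
#' Deterministic splitting of one master seed into per-stage seeds, kept
#' below 2^31 so the result is always a valid R integer.
#'
#' @param seed Master seed (integer).
#' @param stream Character label of the consuming stage.
#' @return Integer seed.
#' @keywords internal
split_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Normalize a taxon name for catalog matching
#'
#' Case-folds and maps spaces and periods to underscores, collapsing runs,
#' so that "Bacteroides uniformis" and "Bacteroides_uniformis" compare equal.
#'
#' @param x Character vector of taxon names.
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_taxon_name("Bacteroides uniformis")
normalize_taxon_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ .]+", "_", x)
  gsub("_+", "_", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf-style formatting, no call in the message
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
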