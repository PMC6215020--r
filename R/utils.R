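#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible per-item seed from a master seed
#'
#' Mixes the master seed with a character key (e.g. class name) and a replicate
#' index so that per-image seeds depend on the item's identity, not on its
#' position in a list. All arithmetic stays below 2^31.
#'
#' @param master_seed integer master seed.
#' @param key character key (class name or similar).
#' @param index replicate index (>= 1).
#' @return integer seed in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(master_seed, key, index) {
  m <- 2147483647
  h <- as.double(master_seed %% m)
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% m
  h <- (h * 131 + as.double(index) * 2654435.0) %% m
  as.integer(h %% (m - 2L)) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}
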