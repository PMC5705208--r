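# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global random stream.
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic sub-seed from a base seed and a label; keeps results
# reproducible per artifact while artifacts stay independent.
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% 2147483582
  as.integer(h + 1L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# named atomic vectors serialize as JSON/YAML maps rather than bare arrays
named_to_maps <- function(x) {
  if (is.list(x)) lapply(x, named_to_maps)
  else if (!is.null(names(x))) as.list(x)
  else x
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)
}

# mid-rank median (average of the two central order statistics for even n)
midrank_median <- function(x) stats::median(x)

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
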