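`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard error of the mean
#'
#' SEM across replicates, `sd(x)/sqrt(n)`. With a single observation the SEM
#' is reported as 0 (with a warning from callers that care) so downstream
#' table shapes stay stable.
#'
#' @param x numeric vector (NAs dropped).
#' @return scalar SEM.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n <= 1L) return(0)
  stats::sd(x) / sqrt(n)
}

stop_geotax <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    stop_geotax("'%s' must be a single finite number >= %s", name, min)
  invisible(x)
}
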