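#' @useDynLib srnascout, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois rnorm runif quantile sd rmultinom aggregate setNames
#' @importFrom utils read.table write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.opposite_strand <- function(strand) {
  ifelse(strand == "+", "-", ifelse(strand == "-", "+", strand))
}

# biological 5'/3' genomic coordinates of an interval on a strand
.five_prime <- function(start, end, strand) ifelse(strand == "-", end, start)
.three_prime <- function(start, end, strand) ifelse(strand == "-", start, end)

.check_strand <- function(strand) {
  bad <- !strand %in% c("+", "-") & !is.na(strand)
  if (any(bad)) stop("strand must be '+', '-' or NA (unstranded)")
  invisible(TRUE)
}

.stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, min, max))
  invisible(TRUE)
}

# derive a stage seed from a base seed, kept inside 32-bit integer range
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31L + offset) %% 2147483647)
}

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
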