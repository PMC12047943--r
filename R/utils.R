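#' @keywords internal
#' @import stats
#' @importFrom utils head modifyList read.delim write.table packageVersion
"_PACKAGE"

## Chi-square(1) median, the denominator of the genomic inflation factor.
CHISQ1_MEDIAN <- 0.4549364231

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage- or cohort-specific seed from a master seed
#'
#' Seeds are derived additively (`master + offset`) so inserting a new
#' consumer at the end of a configuration never perturbs the streams of the
#' existing ones. The result is folded into the 32-bit signed integer range.
#'
#' @param master integer master seed.
#' @param offset nonnegative integer counter identifying the consumer.
#' @return an integer seed usable with [set.seed()].
#' @export
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), is.numeric(offset), offset >= 0)
  as.integer((as.double(master) + as.double(offset)) %% 2147483647)
}

## Clip a matrix into [lo, hi] and report the fraction of entries touched.
clip_range <- function(x, lo = 0, hi = 1) {
  clipped <- (x < lo) | (x > hi)
  x[x < lo] <- lo
  x[x > hi] <- hi
  attr(x, "clip_fraction") <- mean(clipped)
  x
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0
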