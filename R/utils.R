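## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; replicon-fraction and percentage
#' reporting here follows the half-up convention of the printed tables.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @keywords internal
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## cache environment for lazily built lookup tables (genetic code, NG86 tables)
.pancoreCache <- new.env(parent = emptyenv())

#' @importFrom utils head tail read.delim write.table
#' @importFrom stats lm coef rnorm rpois runif setNames uniroot var
#' @importFrom methods new validObject is slot slotNames
#' @importClassesFrom Biostrings AAStringSet DNAStringSet
#' @import methods
NULL
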