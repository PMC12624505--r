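# Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table setnames := .N .SD fread fwrite rbindlist setorder
#' @importFrom stats median rnorm runif rexp rbinom sd wilcox.test ks.test predict binomial coef
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "mz", "rt1", "rt2", "area", "irect", "sample_id", "mz_bin",
  "feature_id", "spectrum", "tof", "resolution", "apex_rt1", "apex_rt2"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# Snap values to a uniform axis (origin + step*0:(n-1)); ties at half-step go
# to the LOWER index. Returns 1-based index, NA outside [1, n].
snap_to_axis <- function(x, origin, step, n) {
  pos <- (x - origin) / step
  idx <- ceiling(pos - 0.5) + 1L    # round-half-down
  idx[idx < 1L | idx > n] <- NA_integer_
  as.integer(idx)
}
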