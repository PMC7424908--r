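#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef qt sd rnorm runif rpois rlnorm approx complete.cases
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fixpupil <- function(...) stop(..., call. = FALSE)

assert_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_fixpupil(sprintf("`%s` must be a finite numeric scalar", name))
  invisible(x)
}

# Moving average of `x` over `k` samples. `align` decides which samples the
# window at position i covers:
#   forward  -> x[i .. i+k-1]
#   trailing -> x[i-k+1 .. i]
#   centered -> x[i-floor(k/2) .. i+ceiling(k/2)-1]
# Windows are truncated at the series edges (mean over available samples).
moving_mean <- function(x, k, align = c("forward", "trailing", "centered")) {
  align <- match.arg(align)
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  lo <- switch(align,
    forward  = idx,
    trailing = idx - k + 1L,
    centered = idx - (k %/% 2L)
  )
  hi <- lo + k - 1L
  lo <- pmax(lo, 1L)
  hi <- pmin(hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end) (indices).
logical_runs <- function(flag) {
  r <- rle(flag)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values
  data.frame(start = start[keep], end = end[keep])
}

# Merge overlapping or touching [start, end] intervals (numeric, closed).
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(data.frame(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}
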