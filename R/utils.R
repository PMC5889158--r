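#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for every reported percentage and
#' whole-dollar figure. `round()` in R rounds half to even, which disagrees
#' with printed claims-report conventions at .5 boundaries.
#'
#' @param x Numeric vector (non-negative in all reporting uses).
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(40.5) # 41, where round(40.5) == 40
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Count distinct integer days covered by a union of half-open intervals
#'
#' Intervals are `[start, end)` in integer days and are clipped to the window
#' `[lo, hi)` before the union is taken. This is the primitive behind the
#' proportion-of-days-covered computation.
#'
#' @param start,end Integer vectors of equal length; each interval covers days
#'   `start, ..., end - 1`.
#' @param lo,hi Window bounds, half-open.
#' @return Integer count of covered days within the window.
#' @export
covered_days <- function(start, end, lo, hi) {
  s <- pmax(as.numeric(start), as.numeric(lo))
  e <- pmin(as.numeric(end), as.numeric(hi))
  keep <- e > s
  if (!any(keep)) {
    return(0L)
  }
  s <- s[keep]
  e <- e[keep]
  o <- order(s)
  s <- s[o]
  e <- cummax(e[o])
  prev <- c(s[1], e[-length(e)])
  as.integer(sum(pmax(0, e - pmax(s, prev))))
}

#' Merge intervals, bridging short gaps
#'
#' Closed integer-day intervals `[start, end]` are merged; two consecutive
#' intervals separated by a gap strictly shorter than `tolerance` days are
#' treated as continuous. Used for enrollment-continuity logic, where the
#' convention ignores coverage breaks of less than 30 days.
#'
#' @param start,end Integer day vectors (closed intervals), need not be sorted.
#' @param tolerance Gap length (days) at or above which a break is real.
#' @return A data.frame with columns `start`, `end` of merged intervals.
#' @keywords internal
merge_intervals <- function(start, end, tolerance = 1L) {
  if (length(start) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start)
  s <- as.numeric(start)[o]
  e <- as.numeric(end)[o]
  ms <- s[1]
  me <- e[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    gap <- s[i] - me - 1 # whole uncovered days between the two intervals
    if (gap < tolerance) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- s[i]
      me <- e[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' @noRd
abort_claimsir <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "claimsir_error"), ...)
}

# Largest-remainder apportionment of n among proportions p (sums to n exactly).
#' @noRd
largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Log-normal draws with a given arithmetic mean and sd (vectorized).
#' @noRd
rlnorm_meansd <- function(n, mean, sd) {
  if (n == 0) {
    return(numeric(0))
  }
  sigma2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# sample() that never falls into the 1:x trap for length-1 vectors
#' @noRd
sample_vec <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
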