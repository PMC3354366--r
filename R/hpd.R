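#' Highest posterior density interval from samples
#'
#' Empirical shortest-interval estimator: among all contiguous windows of
#' the sorted samples containing `ceiling(content * m)` of the `m` draws,
#' the shortest is returned; ties are broken by the lowest start index.
#'
#' @param samples numeric vector of posterior draws (non-finite values are
#'   dropped).
#' @param content probability content, strictly between 0 and 1.
#' @return numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(1:100, 0.95)  # (1, 95)
#' @export
hpd_interval <- function(samples, content) {
  if (!is.numeric(content) || length(content) != 1L ||
      is.na(content) || content <= 0 || content >= 1)
    stop("content must be a single number strictly between 0 and 1")
  x <- sort(samples[is.finite(samples)])
  m <- length(x)
  if (m < 2L) stop("need at least 2 finite samples")
  k <- ceiling(content * m)
  if (k >= m) return(c(x[1L], x[m]))
  starts <- seq_len(m - k + 1L)
  widths <- x[starts + k - 1L] - x[starts]
  i <- which.min(widths)  # first minimum = lowest start
  c(x[i], x[i + k - 1L])
}

#' Independence verdict from posterior samples of a partial correlation
#'
#' Declares the correlation null when the HPD interval at the requested
#' content contains 0 (interval endpoints count as containing it).
#'
#' @param samples posterior draws of the partial correlation.
#' @param content HPD probability content.
#' @return `"null"` or `"dependent"`.
#' @export
independence_decision <- function(samples, content) {
  h <- hpd_interval(samples, content)
  if (h[1L] <= 0 && h[2L] >= 0) "null" else "dependent"
}
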