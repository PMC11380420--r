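# Acceleration magnitude and percentile-threshold fast-start detection.

#' Magnitude of acceleration
#'
#' Euclidean norm of the three acceleration axes,
#' `MA = sqrt(ax^2 + ay^2 + az^2)`.  Rotation-invariant, non-negative.
#'
#' @param ax,ay,az Equal-length numeric vectors.
#' @return Numeric MA series.
#' @examples
#' magnitude(3, 4, 0)  # 5
#' @export
magnitude <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az)) {
    stop("magnitude: acceleration axes must have equal length")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

#' Detect fast starts by per-individual percentile thresholding
#'
#' A fast start is any sample whose acceleration magnitude strictly exceeds
#' the individual's empirical `q`-quantile (type-7, linear interpolation of
#' order statistics) computed over the full cleaned MA series.  Ties at the
#' threshold are not flagged ("upper 5%" excludes the threshold itself).
#' Each flagged sample counts as one fast start.
#'
#' @param MA Non-empty numeric MA series (NAs ignored for the threshold and
#'   never flagged).
#' @param q Quantile in (0, 1); default 0.95.
#' @return A `fast_start_result` list: `threshold`, `quantile_q`, `flags`
#'   (logical per sample), `n_flagged`.
#' @examples
#' r <- detect_fast_starts(c(rep(1, 99), 10), q = 0.95)
#' r$n_flagged
#' @export
detect_fast_starts <- function(MA, q = 0.95) {
  stopifnot(length(MA) > 0, q > 0, q < 1)
  threshold <- unname(quantile(MA, q, na.rm = TRUE, type = 7))
  flags <- !is.na(MA) & MA > threshold
  if (!any(flags) && sd(MA, na.rm = TRUE) == 0) {
    warning("detect_fast_starts: constant MA series, zero flags")
  }
  structure(list(threshold = threshold, quantile_q = q, flags = flags,
                 n_flagged = sum(flags)),
            class = "fast_start_result")
}

#' @export
print.fast_start_result <- function(x, ...) {
  cat(sprintf("<fast_start_result> q=%.2f threshold=%.4g flagged=%d/%d\n",
              x$quantile_q, x$threshold, x$n_flagged, length(x$flags)))
  invisible(x)
}
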