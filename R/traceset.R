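# Multi-mixing-time trace sets: container, zero-time normalization with an
# echo-crossing exclusion window, and reference division.

#' ih-RIDME trace set
#'
#' Bundles one decay per mixing time on a common time axis, together with
#' the acquisition metadata needed for fitting. The reference trace is the
#' one with the shortest mixing time.
#'
#' @param time Strictly increasing time axis starting at >= 0 (microseconds).
#' @param traces Numeric matrix, one column per mixing time.
#' @param Tmix Mixing times (microseconds), one per column.
#' @param d1,d2 Static sequence delays (microseconds, metadata only).
#' @param normalized Logical flag: traces are already normalized to V(0).
#' @return Object of class `"trace_set"`.
#' @export
trace_set <- function(time, traces, Tmix, d1 = NA_real_, d2 = NA_real_,
                      normalized = FALSE) {
  time <- as.numeric(time)
  traces <- as.matrix(traces)
  if (any(!is.finite(time)) || any(diff(time) <= 0) || time[1] < 0)
    stop("time axis must be finite, strictly increasing and start at >= 0")
  if (any(!is.finite(traces))) stop("traces contain non-finite values")
  if (ncol(traces) != length(Tmix)) stop("one mixing time per trace column required")
  if (ncol(traces) < 2) stop("at least a reference and one trace are required")
  if (anyDuplicated(Tmix)) stop("duplicate mixing times")
  o <- order(Tmix)
  structure(list(time = time, traces = traces[, o, drop = FALSE],
                 Tmix = as.numeric(Tmix[o]), ref = 1L,
                 d1 = d1, d2 = d2, normalized = isTRUE(normalized)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("ih-RIDME trace set:", ncol(x$traces), "traces,",
      length(x$time), "time points on [", min(x$time), ",", max(x$time), "] us\n")
  cat("  Tmix (us):", paste(x$Tmix, collapse = ", "),
      "(reference", x$Tmix[x$ref], "us)\n")
  cat("  normalized:", x$normalized, "\n")
  invisible(x)
}

#' @export
plot.trace_set <- function(x, ..., xlab = "t (us)", ylab = "V(t)") {
  graphics::matplot(x$time, x$traces, type = "l", lty = 1,
                    xlab = xlab, ylab = ylab, ...)
  graphics::legend("bottomleft", legend = paste0("Tmix = ", x$Tmix, " us"),
                   col = seq_along(x$Tmix), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Zero-time normalization of a trace set
#'
#' Normalizes each trace to its `V(t = 0)` value estimated by a short-time
#' quadratic extrapolation `V ~ a + b t^2` (the echo decay is an even
#' function of t near zero, so the odd term is omitted, which roughly
#' halves the noise amplification of the extrapolation). Points inside the
#' exclusion window (where the echo-crossing artifact grows with mixing
#' time) are ignored.
#'
#' @param ts A [trace_set()].
#' @param exclude Optional window `c(t_lo, t_hi)` (microseconds) excluded
#'   from the V(0) estimate.
#' @param n_fit Number of eligible early points used for the quadratic fit
#'   (default 12).
#' @return A normalized `trace_set`.
#' @export
normalize_traces <- function(ts, exclude = NULL, n_fit = 12L) {
  stopifnot(inherits(ts, "trace_set"))
  t <- ts$time
  eligible <- rep(TRUE, length(t))
  if (!is.null(exclude)) {
    if (length(exclude) != 2L || exclude[1] > exclude[2])
      stop("exclude must be c(t_lo, t_hi)")
    eligible <- t < exclude[1] | t > exclude[2]
  }
  idx <- which(eligible)
  if (length(idx) < 3L)
    stop("fewer than 3 points outside the exclusion window near t = 0")
  idx <- idx[seq_len(min(max(n_fit, 3L), length(idx)))]
  traces <- ts$traces
  for (j in seq_len(ncol(traces))) {
    tf <- t[idx]; vf <- traces[idx, j]
    v0 <- if (length(unique(vf)) == 1L) {
      vf[1]
    } else {
      fit <- stats::lm(vf ~ I(tf^2))
      unname(stats::predict(fit, newdata = data.frame(tf = 0)))
    }
    if (!is.finite(v0) || v0 == 0) stop("degenerate V(0) estimate in trace ", j)
    traces[, j] <- traces[, j] / v0
  }
  out <- ts
  out$traces <- traces
  out$normalized <- TRUE
  out
}

#' Reference division
#'
#' Divides each non-reference trace by the reference (shortest mixing time)
#' trace, cancelling sequence artifacts and -- exactly, for homogeneous
#' systems -- the transverse factor. Points where the reference has decayed
#' below `floor` are truncated: the division noise blows up there.
#'
#' @param ts A normalized [trace_set()].
#' @param floor Reference amplitude below which the ratio traces are cut
#'   (default 0.02).
#' @return List with `time`, `ratios` (matrix, one column per non-reference
#'   trace, `NA` beyond the truncation point), `Tmix`, `Tmix_ref`.
#' @export
reference_divide <- function(ts, floor = 0.02) {
  stopifnot(inherits(ts, "trace_set"))
  if (!ts$normalized)
    warning("trace set is not flagged as normalized; dividing raw traces")
  ref <- ts$traces[, ts$ref]
  keep <- rep(TRUE, length(ref))
  first_low <- which(ref < floor)[1]
  if (!is.na(first_low)) {
    keep[first_low:length(ref)] <- FALSE   # cut everything past the crossing
    warning(sprintf("reference below %g from t = %g us; ratio traces truncated",
                    floor, ts$time[first_low]))
  }
  others <- setdiff(seq_along(ts$Tmix), ts$ref)
  ratios <- ts$traces[, others, drop = FALSE] / ref
  ratios[!keep, ] <- NA_real_
  list(time = ts$time, ratios = ratios,
       Tmix = ts$Tmix[others], Tmix_ref = ts$Tmix[ts$ref])
}
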