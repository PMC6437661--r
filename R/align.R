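#' Shift-and-average reconstructed channel responses
#'
#' The standard summary of an inverted encoding model: each trial's
#' reconstructed `k`-vector is circularly shifted so that the channel whose
#' center equals the presented orientation lands at offset 0, then the
#' shifted vectors are averaged across trials.  This requires every presented
#' orientation to coincide with a channel center (true for the default
#' 8 orientations x 8 channels configuration); off-center designs are
#' rejected rather than interpolated.
#'
#' @param recon A `channel_responses` object (typically from
#'   [invert_iem()]).
#' @param design The [stimulus_design()] of the trials (default: the one
#'   recorded on `recon`).
#' @param basis The [channel_basis()] whose centers define the alignment
#'   (default: the one recorded on `recon`).
#' @param center_tol Angular tolerance (degrees) for matching an orientation
#'   to a channel center.
#'
#' @return An object of class `aligned_crf`: list with `offsets` (degrees,
#'   evenly spaced, including 0, sorted ascending), `mean`, `sem`,
#'   `n_trials`, and `period` (180).
#' @export
shift_average <- function(recon, design = recon$design, basis = recon$basis,
                          center_tol = 1e-9) {
  stopifnot(inherits(recon, "channel_responses"),
            inherits(design, "stimulus_design"),
            inherits(basis, "channel_basis"))
  R <- recon$R
  k <- basis$k
  if (ncol(R) != k)
    stop("channel responses and basis disagree on k", call. = FALSE)
  if (nrow(R) != design$n)
    stop("channel responses and design disagree on trial count", call. = FALSE)
  spacing <- 180 / k
  ch <- vapply(design$labels, function(th) {
    d <- circular_distance(th, basis$centers, period = 180)
    j <- which(d <= center_tol)
    if (length(j) != 1L)
      stop(sprintf(
        "orientation %g deg does not coincide with a channel center; shift-and-average requires stimulus-on-center designs",
        th), call. = FALSE)
    j
  }, integer(1))
  n <- nrow(R)
  aligned <- matrix(0, n, k)
  for (d in 0:(k - 1))
    aligned[, d + 1] <- R[cbind(seq_len(n), ((ch - 1 + d) %% k) + 1)]
  offsets <- wrap_offset((0:(k - 1)) * spacing, period = 180)
  ord <- order(offsets)
  m <- colMeans(aligned)
  sem <- if (n > 1) apply(aligned, 2, stats::sd) / sqrt(n) else rep(0, k)
  structure(
    list(offsets = offsets[ord], mean = m[ord], sem = sem[ord],
         n_trials = n, period = 180),
    class = "aligned_crf"
  )
}

#' @export
print.aligned_crf <- function(x, ...) {
  cat(sprintf("Aligned channel response function (%d trials)\n", x$n_trials))
  print(data.frame(offset_deg = x$offsets, mean = x$mean, sem = x$sem),
        row.names = FALSE)
  invisible(x)
}

#' @param x An `aligned_crf`.
#' @param ... Passed to [graphics::plot()].
#' @rdname shift_average
#' @export
plot.aligned_crf <- function(x, ...) {
  graphics::plot(x$offsets, x$mean, type = "b", pch = 16,
                 xlab = "offset from presented orientation (deg)",
                 ylab = "reconstructed channel response",
                 main = "Shift-and-averaged CRF", ...)
  graphics::arrows(x$offsets, x$mean - x$sem, x$offsets, x$mean + x$sem,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Convert an aligned CRF to a circular curve
#'
#' @param x An `aligned_crf`.
#' @return A [circular_curve()] over the CRF's offsets.
#' @export
as_circular_curve <- function(x) {
  stopifnot(inherits(x, "aligned_crf"))
  circular_curve(x$offsets, x$mean, period = x$period)
}
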