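#' Orientation stimulus design
#'
#' Builds the one-hot trial design for an orientation experiment: `s`
#' distinct orientations, each presented `repeats` times, giving an
#' `n x s` stimulus matrix `S` with a single 1 per row marking the
#' orientation shown on that trial.
#'
#' @param orientations Distinct orientation values in degrees, in
#'   `[0, 180)`.  Default: 8 evenly spaced orientations (0, 22.5, ...,
#'   157.5), matching the default 8-channel basis centers.
#' @param repeats Presentations per orientation (positive integer).
#'   Default 27, giving the default n = 216 trials.
#'
#' @return An object of class `stimulus_design` with fields `orientations`
#'   (sorted), `labels` (per-trial orientation, length `n`), `S` (`n x s`
#'   zero/one matrix), `repeats`, `n`, `s`.
#' @examples
#' d <- stimulus_design()
#' d$n  # 216
#' @export
stimulus_design <- function(orientations = (0:7) * 22.5, repeats = 27) {
  if (!is.numeric(orientations) || length(orientations) == 0L ||
      any(!is.finite(orientations)))
    stop("`orientations` must be a non-empty finite numeric vector", call. = FALSE)
  if (any(orientations < 0 | orientations >= 180))
    stop("orientations must lie in [0, 180)", call. = FALSE)
  if (anyDuplicated(orientations))
    stop("orientations must be distinct", call. = FALSE)
  if (!is_count(repeats, min = 1))
    stop("`repeats` must be a positive integer", call. = FALSE)
  orientations <- sort(orientations)
  labels <- rep(orientations, times = repeats)
  n <- length(labels)
  s <- length(orientations)
  S <- matrix(0, n, s)
  S[cbind(seq_len(n), match(labels, orientations))] <- 1
  structure(
    list(orientations = orientations, labels = labels, S = S,
         repeats = as.integer(repeats), n = n, s = s),
    class = "stimulus_design"
  )
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat(sprintf("Stimulus design: %d orientations x %d repeats = %d trials\n",
              x$s, x$repeats, x$n))
  cat(sprintf("  orientations (deg): %s\n",
              paste(format(x$orientations, trim = TRUE), collapse = ", ")))
  invisible(x)
}
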