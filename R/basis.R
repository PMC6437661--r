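#' Unimodal channel basis functions
#'
#' Construct a bank of `k` idealized orientation channels with evenly spaced
#' preferred orientations on `[0, 180)` degrees.  Each channel is a half-wave
#' rectified cosine in doubled-angle space raised to an exponent,
#' \deqn{f_j(\theta) = \max(0, \cos(2 (\theta - \phi_j) \pi / 180))^p,}
#' the standard "sinusoid raised to an exponent" basis of channel encoding
#' models.  Values lie in `[0, 1]`, each channel peaks at 1 at its own center,
#' and every channel has period 180 degrees (orientation is axial).
#'
#' @param k Number of channels (integer, at least 2).  Default 8.
#' @param p Exponent applied to the rectified cosine (positive integer).
#'   Default `k - 1`, which gives the customary bandwidth where each channel
#'   overlaps only its immediate neighbours appreciably.
#'
#' @return An object of class `channel_basis` with fields `k`, `p`, `centers`
#'   (degrees), `kind` (`"unimodal"` or `"transformed"`), and for transformed
#'   bases the generating `transform` and `parent` basis.
#'
#' @seealso [eval_basis()], [transform_basis()], [bimodal_transform()]
#' @examples
#' b <- channel_basis(8)
#' eval_basis(b, c(0, 22.5, 45))
#' @export
channel_basis <- function(k = 8, p = k - 1) {
  if (!is_count(k, min = 2))
    stop("`k` must be an integer >= 2", call. = FALSE)
  if (!is_count(p, min = 1))
    stop("`p` must be a positive integer", call. = FALSE)
  structure(
    list(
      k = as.integer(k),
      p = as.integer(p),
      centers = (seq_len(k) - 1) * 180 / k,
      kind = "unimodal",
      transform = NULL,
      parent = NULL
    ),
    class = "channel_basis"
  )
}

#' Evaluate channel basis functions at stimulus values
#'
#' @param basis A [channel_basis()].
#' @param theta Numeric vector of orientations in degrees.  Values outside
#'   `[0, 180)` are admitted and wrapped implicitly by the 180-degree
#'   periodicity of the basis.
#'
#' @return A `length(theta) x k` matrix `C` with `C[i, j]` the j-th basis
#'   function evaluated at `theta[i]`.  For a transformed basis this is
#'   `C1 %*% P` with `C1` the parent (unimodal) evaluation matrix.
#' @export
eval_basis <- function(basis, theta) {
  stopifnot(inherits(basis, "channel_basis"))
  if (length(theta) == 0L)
    stop("no stimulus values supplied", call. = FALSE)
  if (!is.numeric(theta) || any(!is.finite(theta)))
    stop("`theta` must be finite numeric degrees", call. = FALSE)
  if (basis$kind == "transformed") {
    C <- eval_basis(basis$parent, theta) %*% basis$transform$P
    dimnames(C) <- list(NULL, paste0("ch", seq_len(basis$k)))
    return(C)
  }
  # doubled angle: cos(2 * delta * pi / 180) = cos(delta * pi / 90)
  d <- outer(theta, basis$centers, "-") * (pi / 90)
  C <- pmax(cos(d), 0)^basis$p
  dimnames(C) <- list(NULL, paste0("ch", seq_len(basis$k)))
  C
}

#' Apply an invertible transform to a channel basis
#'
#' Produces the transformed basis whose evaluation matrix satisfies
#' `C2 = C1 %*% P` at any stimulus set, where `C1` is the evaluation matrix of
#' the original (unimodal) basis.  The transformed basis keeps the same
#' channel centers for alignment purposes; only the shape of each channel
#' changes.
#'
#' @param basis A unimodal [channel_basis()].
#' @param transform A [channel_transform()] of matching dimension.
#' @return A `channel_basis` of kind `"transformed"` recording its parent
#'   basis and generating transform.
#' @export
transform_basis <- function(basis, transform) {
  stopifnot(inherits(basis, "channel_basis"),
            inherits(transform, "channel_transform"))
  if (basis$kind != "unimodal")
    stop("only a unimodal basis can be transformed", call. = FALSE)
  if (nrow(transform$P) != basis$k)
    stop(sprintf("transform dimension %d does not match basis k = %d",
                 nrow(transform$P), basis$k), call. = FALSE)
  structure(
    list(
      k = basis$k,
      p = basis$p,
      centers = basis$centers,
      kind = "transformed",
      transform = transform,
      parent = basis
    ),
    class = "channel_basis"
  )
}

#' @export
print.channel_basis <- function(x, ...) {
  cat(sprintf("Channel basis: %d %s channels, exponent %d\n",
              x$k, x$kind, x$p))
  cat(sprintf("  centers (deg): %s\n",
              paste(format(x$centers, trim = TRUE), collapse = ", ")))
  if (x$kind == "transformed")
    cat(sprintf("  generated by a %s transform (condition number %.3g)\n",
                x$transform$kind, x$transform$cond))
  invisible(x)
}

#' @param x A `channel_basis`.
#' @param step Evaluation grid step in degrees.
#' @param ... Passed to [graphics::matplot()].
#' @rdname channel_basis
#' @export
plot.channel_basis <- function(x, step = 0.5, ...) {
  grid <- seq(0, 180 - step, by = step)
  C <- eval_basis(x, grid)
  graphics::matplot(grid, C, type = "l", lty = 1,
                    xlab = "orientation (deg)", ylab = "channel response",
                    main = sprintf("%d %s channels", x$k, x$kind), ...)
  invisible(x)
}
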