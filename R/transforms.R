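#' Invertible channel-basis transforms
#'
#' A `channel_transform` wraps an invertible `k x k` matrix `P` that converts
#' one channel basis into an equivalent one (`C2 = C1 P`).  Because `P` is
#' invertible, the two bases span the same subspace: encoding fits under
#' either basis account for identical variance, their weight estimates are
#' related by `P^{-1}`, and reconstructed channel responses by `P`.
#'
#' `channel_transform()` wraps an arbitrary matrix (kind `"custom"`),
#' checking invertibility.  [bimodal_transform()] and [random_transform()]
#' construct the two families used in the demonstrations.
#'
#' @param P A square numeric matrix.
#' @param kind Label for the construction (`"custom"`, `"bimodal"`,
#'   `"random"`).
#' @param condition_ceiling Largest admissible 2-norm condition number;
#'   matrices at or beyond it are rejected as numerically non-invertible.
#'
#' @return An object of class `channel_transform` with fields `P`, `Pinv`,
#'   `kind`, and `cond` (2-norm condition number).
#' @export
channel_transform <- function(P, kind = "custom", condition_ceiling = 1e12) {
  if (!is.matrix(P) || !is.numeric(P) || nrow(P) != ncol(P))
    stop("`P` must be a square numeric matrix", call. = FALSE)
  if (any(!is.finite(P)))
    stop("`P` must have finite entries", call. = FALSE)
  sv <- svd(P, nu = 0, nv = 0)$d
  if (min(sv) <= 0 || max(sv) / min(sv) >= condition_ceiling)
    stop(sprintf("transform is singular or ill-conditioned (condition number %.3g)",
                 if (min(sv) > 0) max(sv) / min(sv) else Inf), call. = FALSE)
  structure(
    list(P = P, Pinv = solve(P), kind = kind, cond = max(sv) / min(sv)),
    class = "channel_transform"
  )
}

#' Circulant transform from unimodal to bimodal channels
#'
#' Builds the channel conversion matrix `P = I + g * S^m`, where `S` is the
#' one-step cyclic channel shift, `m` the lobe shift in channel steps, and
#' `g` the gain of the secondary lobe.  Applied to the unimodal basis it
#' yields channels with two peaks separated by `m * 180 / k` degrees: 67.5
#' degrees for the defaults `k = 8, m = 3` (about 67 degrees).  Being
#' circulant, `P` has closed-form eigenvalues
#' `1 + g * exp(2i * pi * m * q / k)`; the construction is rejected when any
#' eigenvalue modulus falls below `eigen_floor` (e.g. `g = 1` with `m * 2`
#' divisible by `k` is exactly singular).
#'
#' @param k Number of channels.
#' @param lobe_shift Integer channel steps between the two lobes
#'   (`1 <= lobe_shift < k`).
#' @param secondary_gain Gain of the secondary lobe, in `(0, 1]`.
#' @param eigen_floor Smallest admissible eigenvalue modulus.
#' @return A [channel_transform()] of kind `"bimodal"`.
#' @examples
#' P <- bimodal_transform(8, 3, 0.9)
#' P$cond  # 19: moduli |1 + 0.9 exp(i pi 3 q / 4)| range over [0.1, 1.9]
#' @export
bimodal_transform <- function(k = 8, lobe_shift = 3, secondary_gain = 0.9,
                              eigen_floor = 1e-6) {
  if (!is_count(k, min = 2))
    stop("`k` must be an integer >= 2", call. = FALSE)
  if (!is_count(lobe_shift, min = 1) || lobe_shift >= k)
    stop("`lobe_shift` must be an integer in [1, k)", call. = FALSE)
  if (!is_scalar(secondary_gain) || secondary_gain <= 0 || secondary_gain > 1)
    stop("`secondary_gain` must be in (0, 1]", call. = FALSE)
  ev_mod <- Mod(1 + secondary_gain *
                  exp(2i * pi * lobe_shift * (seq_len(k) - 1) / k))
  if (min(ev_mod) < eigen_floor)
    stop(sprintf(
      "singular bimodal transform: k = %d, lobe_shift = %d, gain = %g has an eigenvalue modulus %.3g below the floor %.3g",
      k, lobe_shift, secondary_gain, min(ev_mod), eigen_floor), call. = FALSE)
  P <- diag(k)
  j <- seq_len(k)
  i <- ((j - 1 + lobe_shift) %% k) + 1  # column j: 1 at j, gain at channel j + m
  P[cbind(i, j)] <- P[cbind(i, j)] + secondary_gain
  out <- channel_transform(P, kind = "bimodal")
  out$lobe_shift <- as.integer(lobe_shift)
  out$secondary_gain <- secondary_gain
  out
}

#' Random invertible channel transform
#'
#' Draws a `k x k` matrix of independent standard-normal entries from the
#' seeded generator, redrawing (advancing the stream) until its condition
#' number is below `condition_ceiling`.  Any such matrix is an admissible
#' channel conversion: the transformed basis is "seemingly random" yet spans
#' the same subspace as the unimodal one.
#'
#' @param k Number of channels.
#' @param seed Integer seed; the same `(k, seed)` always yields the same `P`.
#' @param condition_ceiling Acceptance ceiling on the condition number
#'   (default `1e3`, keeping reconstructions numerically meaningful).
#' @param max_tries Redraw budget before giving up.
#' @return A [channel_transform()] of kind `"random"`.
#' @export
random_transform <- function(k = 8, seed = 1, condition_ceiling = 1e3,
                             max_tries = 100L) {
  if (!is_count(k, min = 2))
    stop("`k` must be an integer >= 2", call. = FALSE)
  if (!is_scalar(condition_ceiling) || condition_ceiling <= 1)
    stop("`condition_ceiling` must exceed 1", call. = FALSE)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      P <- matrix(stats::rnorm(k * k), k, k)
      sv <- svd(P, nu = 0, nv = 0)$d
      if (min(sv) > 0 && max(sv) / min(sv) < condition_ceiling) {
        out <- channel_transform(P, kind = "random")
        out$seed <- as.integer(seed)
        return(out)
      }
    }
    stop(sprintf(
      "no random transform with condition number < %g found in %d draws (k = %d, seed = %d)",
      condition_ceiling, max_tries, k, seed), call. = FALSE)
  })
}

#' @export
print.channel_transform <- function(x, ...) {
  cat(sprintf("Channel transform (%s): %d x %d, condition number %.4g\n",
              x$kind, nrow(x$P), ncol(x$P), x$cond))
  invisible(x)
}
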