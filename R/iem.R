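#' Forward channel responses
#'
#' Projects the stimulus design onto the channel basis: `R = S %*% C`, where
#' `C` is the basis evaluated at the design's distinct orientations.  Each
#' trial's row of `R` is the hypothetical response of the `k` channels to the
#' orientation shown on that trial.
#'
#' @param design A [stimulus_design()].
#' @param basis A [channel_basis()].
#' @return An object of class `channel_responses`: list with matrix `R`
#'   (`n x k`), `role = "forward"`, and references to `basis` and `design`.
#' @export
forward_channel_responses <- function(design, basis) {
  stopifnot(inherits(design, "stimulus_design"), inherits(basis, "channel_basis"))
  C <- eval_basis(basis, design$orientations)
  structure(
    list(R = design$S %*% C, role = "forward", basis = basis, design = design),
    class = "channel_responses"
  )
}

#' @export
print.channel_responses <- function(x, ...) {
  cat(sprintf("Channel responses (%s): %d trials x %d channels\n",
              x$role, nrow(x$R), ncol(x$R)))
  invisible(x)
}

#' Fit the forward (channel) encoding model
#'
#' Least-squares fit of the linear encoding model `B = R W + eta`, where
#' `R = S C` are the forward channel responses and `B` the measured (here,
#' simulated) trial-by-voxel responses.  The weight estimate is the ordinary
#' least-squares solution `W = (R'R)^{-1} R' B`, computed via a QR
#' factorization for numerical stability.
#'
#' @param data A training [voxel_dataset()].
#' @param basis A [channel_basis()].
#' @param design A [stimulus_design()]; defaults to the design the dataset
#'   was generated from.
#'
#' @return An object of class `iem`: list with `weights` (`k x v`), `basis`,
#'   `design`, `data`, forward responses `R`, `fitted` values, pooled
#'   training `r2`, and the matched `call`.  Supports `coef()`, `fitted()`,
#'   `residuals()`, `predict()`, `simulate()`, `summary()`, `print()` and
#'   `plot()`.
#'
#' @section Rank requirement:
#' `R` must have full column rank `k` (e.g. at least `k` distinct training
#' orientations for an independent basis); otherwise the normal equations
#' are singular and fitting stops with an error reporting the rank.
#'
#' @seealso [invert_iem()], [variance_explained()], [shift_average()]
#' @examples
#' pop <- simulate_population(v = 20, seed = 1)
#' des <- stimulus_design()
#' train <- simulate_dataset(pop, des, sigma = 0.01, seed = 2)
#' fit <- iem(train, channel_basis(8))
#' fit
#' @export
iem <- function(data, basis, design = data$design) {
  stopifnot(inherits(data, "voxel_dataset"), inherits(basis, "channel_basis"),
            inherits(design, "stimulus_design"))
  if (nrow(data$B) != design$n)
    stop("dataset and design disagree on the number of trials", call. = FALSE)
  fwd <- forward_channel_responses(design, basis)
  qr_R <- qr(fwd$R)
  if (qr_R$rank < basis$k)
    stop(sprintf(
      "channel response matrix is rank-deficient: rank %d < k = %d channels",
      qr_R$rank, basis$k), call. = FALSE)
  W <- qr.coef(qr_R, data$B)
  rownames(W) <- colnames(fwd$R)
  fitted <- fwd$R %*% W
  ss_res <- sum((data$B - fitted)^2)
  ss_tot <- sum((data$B - mean(data$B))^2)
  structure(
    list(weights = W, basis = basis, design = design, data = data,
         R = fwd$R, fitted = fitted,
         r2 = 1 - ss_res / ss_tot, call = match.call()),
    class = "iem"
  )
}

#' @export
print.iem <- function(x, ...) {
  cat(sprintf(
    "Inverted encoding model fit: %d %s channels, %d voxels, %d trials\n",
    x$basis$k, x$basis$kind, ncol(x$weights), nrow(x$data$B)))
  cat(sprintf("  training r-squared (pooled): %.4f\n", x$r2))
  invisible(x)
}

#' @export
coef.iem <- function(object, ...) object$weights

#' @export
fitted.iem <- function(object, ...) object$fitted

#' @export
residuals.iem <- function(object, ...) object$data$B - object$fitted

#' Predict voxel responses for a stimulus design
#'
#' Computes `B = S C W` for the orientations of `design`, which may include
#' values never used in training: the basis is simply re-evaluated at the new
#' orientations.  Encoding fits whose bases are related by an invertible
#' transform produce identical predictions, including for left-out stimuli.
#'
#' @param object A fitted [iem()] model.
#' @param design A [stimulus_design()]; defaults to the training design.
#' @param ... Unused.
#' @return An `n x v` matrix of predicted responses.
#' @export
predict.iem <- function(object, design = object$design, ...) {
  stopifnot(inherits(design, "stimulus_design"))
  fwd <- forward_channel_responses(design, object$basis)
  fwd$R %*% object$weights
}

#' Simulate responses from a fitted encoding model
#'
#' Draws datasets `B = S C W + eta` with iid Gaussian noise of standard
#' deviation `sigma` added to the fit's predictions.
#'
#' @param object A fitted [iem()] model.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param design Stimulus design (default: training design).
#' @param sigma Noise standard deviation.
#' @param ... Unused.
#' @return A list of `nsim` [voxel_dataset()] objects.
#' @export
simulate.iem <- function(object, nsim = 1, seed = 1,
                         design = object$design, sigma = 0, ...) {
  mu <- predict(object, design)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    B <- mu
    if (sigma > 0)
      B <- B + matrix(stats::rnorm(length(mu), sd = sigma), nrow(mu), ncol(mu))
    voxel_dataset(B, design, sigma = sigma, seed = NA_integer_, role = "validation")
  }))
}

#' @export
summary.iem <- function(object, ...) {
  W <- object$weights
  WWt <- tcrossprod(W)
  out <- list(
    k = object$basis$k, basis_kind = object$basis$kind,
    v = ncol(W), n = nrow(object$data$B),
    r2_train = object$r2,
    cond_WWt = kappa(WWt, exact = TRUE)
  )
  class(out) <- "summary.iem"
  out
}

#' @export
print.summary.iem <- function(x, ...) {
  cat(sprintf("Encoding model: %d %s channels -> %d voxels (%d trials)\n",
              x$k, x$basis_kind, x$v, x$n))
  cat(sprintf("  training r-squared (pooled): %.4f\n", x$r2_train))
  cat(sprintf("  condition number of W W': %.4g\n", x$cond_WWt))
  invisible(x)
}

#' Invert a fitted encoding model on held-out data
#'
#' Estimates per-trial channel responses from a validation dataset by the
#' pseudo-inverse of the fitted weights: `Rhat = B_V W' (W W')^{-1}`.  Each
#' row is the least-squares solution of `min || b_t - r W ||` for that
#' trial's voxel response vector, computed via a QR factorization of `t(W)`
#' (the explicit normal-equations form is retained as a test oracle).
#'
#' @param fit A fitted [iem()] model.
#' @param data A validation [voxel_dataset()] with the same voxel count.
#' @return A `channel_responses` object with `role = "reconstructed"`; the
#'   attribute `"cond_WWt"` records the condition number of `W W'`.
#' @export
invert_iem <- function(fit, data) {
  stopifnot(inherits(fit, "iem"), inherits(data, "voxel_dataset"))
  W <- fit$weights
  if (ncol(data$B) != ncol(W))
    stop("dataset voxel count does not match the fit", call. = FALSE)
  qr_Wt <- qr(t(W))
  if (qr_Wt$rank < nrow(W))
    stop(sprintf("W W' is singular: weight matrix has rank %d < k = %d",
                 qr_Wt$rank, nrow(W)), call. = FALSE)
  Rhat <- t(qr.coef(qr_Wt, t(data$B)))
  colnames(Rhat) <- rownames(W)
  out <- structure(
    list(R = Rhat, role = "reconstructed", basis = fit$basis,
         design = data$design),
    class = "channel_responses"
  )
  attr(out, "cond_WWt") <- kappa(tcrossprod(W), exact = TRUE)
  out
}

#' Variance explained by an encoding fit
#'
#' `r2 = 1 - SS_res / SS_tot` for the fit's predictions on a dataset.  By
#' default sums of squares are pooled over all voxels and trials with
#' `SS_tot` about the grand mean; `pooled = FALSE` instead computes r-squared
#' per voxel (about that voxel's own mean) and averages.
#'
#' @param fit A fitted [iem()] model.
#' @param data A [voxel_dataset()].
#' @param design Stimulus design of `data` (default: the dataset's own).
#' @param pooled Pool sums of squares across voxels (default) or average
#'   per-voxel r-squared.
#' @return A single numeric r-squared (at most 1; can be negative for a
#'   model worse than the mean).
#' @export
variance_explained <- function(fit, data, design = data$design, pooled = TRUE) {
  stopifnot(inherits(fit, "iem"), inherits(data, "voxel_dataset"))
  pred <- predict(fit, design)
  if (pooled) {
    1 - sum((data$B - pred)^2) / sum((data$B - mean(data$B))^2)
  } else {
    ss_res <- colSums((data$B - pred)^2)
    ss_tot <- colSums(sweep(data$B, 2, colMeans(data$B))^2)
    mean(1 - ss_res / ss_tot)
  }
}
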