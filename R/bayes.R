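#' Fit the generative noise model of the Bayesian decoder
#'
#' Models the training residuals `Z = B_T - R W` as zero-mean Gaussian rows
#' with covariance
#' \deqn{\Omega = W' \sigma_c^2 I_k W + \mathrm{diag}(\tau^2),}
#' i.e. iid channel noise propagated through the fitted weights plus
#' independent per-voxel noise.  (A correlated voxel-noise component is
#' deliberately omitted: the simulator does not generate one.)  The
#' parameters `(tau, sigma_c)` maximize the Gaussian log-likelihood of the
#' residual rows; optimization is quasi-Newton (BFGS with analytic
#' gradients) over `(log tau^2, log sigma_c^2)`, initialized at the
#' per-voxel residual variances and `sigma_c^2 = 1e-3 * mean(tau^2)`, with
#' up to three jittered restarts if convergence is not reached.
#'
#' @param fit A fitted [iem()] model.
#' @param training The training [voxel_dataset()]; residuals are taken
#'   about the fit's predictions for this dataset.
#' @param design Stimulus design of `training` (default: the dataset's own).
#' @param maxit Iteration budget per optimizer start.
#' @return An object of class `iem_noise_model`: list with `tau` (length
#'   `v`), `sigma_c`, covariance `Omega`, its Cholesky factor `chol_Omega`,
#'   `logLik`, `convergence` (0 = converged), and the `fit` reference.
#' @seealso [posterior_grid()], [response_log_likelihood()]
#' @export
fit_noise_model <- function(fit, training, design = training$design,
                            maxit = 500L) {
  stopifnot(inherits(fit, "iem"), inherits(training, "voxel_dataset"))
  W <- fit$weights
  v <- ncol(W)
  if (ncol(training$B) != v)
    stop("training dataset voxel count does not match the fit", call. = FALSE)
  Z <- training$B - predict(fit, design)
  n <- nrow(Z)
  tau2_0 <- colMeans(Z^2)
  if (any(tau2_0 < 1e-14))
    stop("degenerate residual variance: some voxels have (near-)zero residuals; the noise model requires positive residual variance",
         call. = FALSE)
  WtW <- crossprod(W)                   # v x v, the channel-noise pattern
  Szz <- crossprod(Z)
  nll <- function(par) {
    sc2 <- exp(par[1L])
    tau2 <- exp(par[-1L])
    Om <- sc2 * WtW
    diag(Om) <- diag(Om) + tau2
    ch <- tryCatch(chol(Om), error = function(e) NULL)
    if (is.null(ch)) return(Inf)        # rejected step
    Oinv <- chol2inv(ch)
    0.5 * (n * v * log(2 * pi) + 2 * n * sum(log(diag(ch))) + sum(Oinv * Szz))
  }
  grad <- function(par) {
    sc2 <- exp(par[1L])
    tau2 <- exp(par[-1L])
    Om <- sc2 * WtW
    diag(Om) <- diag(Om) + tau2
    ch <- tryCatch(chol(Om), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(par)))
    Oinv <- chol2inv(ch)
    # d nll / d Omega = (n * Oinv - Oinv Szz Oinv) / 2
    G <- 0.5 * (n * Oinv - Oinv %*% Szz %*% Oinv)
    c(sum(G * WtW) * sc2, diag(G) * tau2)
  }
  par0 <- c(log(1e-3 * mean(tau2_0)), log(tau2_0))
  best <- NULL
  jitter <- c(0, 0.5, -0.5, 1)          # deterministic restart offsets
  for (j in jitter) {
    opt <- stats::optim(par0 + j, nll, grad, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$convergence == 0L) break
  }
  if (best$convergence != 0L)
    stop(sprintf("noise-model fit failed to converge (code %d, nll %.6g) after %d restarts",
                 best$convergence, best$value, length(jitter)), call. = FALSE)
  sc2 <- exp(best$par[1L])
  tau2 <- exp(best$par[-1L])
  Omega <- sc2 * WtW
  diag(Omega) <- diag(Omega) + tau2
  structure(
    list(tau = sqrt(tau2), sigma_c = sqrt(sc2), Omega = Omega,
         chol_Omega = chol(Omega), logLik = -best$value,
         convergence = best$convergence, fit = fit, n = n),
    class = "iem_noise_model"
  )
}

#' @export
print.iem_noise_model <- function(x, ...) {
  cat(sprintf(
    "Generative noise model: %d voxels, channel noise sd %.4g, voxel noise sd %.4g-%.4g (median %.4g)\n",
    length(x$tau), x$sigma_c, min(x$tau), max(x$tau), stats::median(x$tau)))
  cat(sprintf("  log-likelihood %.4f on %d residual rows\n", x$logLik, x$n))
  invisible(x)
}

#' Gaussian log-likelihood of a voxel response given a stimulus
#'
#' Log density of a single trial's voxel response vector under the fitted
#' generative model: multivariate normal with mean `c(theta) %*% W` (the
#' basis evaluated at `theta` times the fitted weights) and covariance
#' `Omega` from the noise model.  Computed through the cached Cholesky
#' factor; axial periodicity of the basis makes the value identical at
#' `theta` and `theta + 180`.
#'
#' @param b Numeric voxel response vector (length `v`).
#' @param theta Stimulus orientation in degrees.
#' @param fit The fitted [iem()] model.
#' @param noise The fitted [fit_noise_model()] object.
#' @return The log-density (single numeric).
#' @export
response_log_likelihood <- function(b, theta, fit, noise) {
  stopifnot(inherits(fit, "iem"), inherits(noise, "iem_noise_model"))
  v <- length(b)
  if (v != ncol(fit$weights))
    stop("response length does not match the fit's voxel count", call. = FALSE)
  mu <- drop(eval_basis(fit$basis, theta) %*% fit$weights)
  ch <- noise$chol_Omega
  y <- backsolve(ch, b - mu, transpose = TRUE)
  -0.5 * (v * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(y^2))
}

#' Posterior probability of the stimulus on a grid
#'
#' For every validation trial, computes the posterior probability of each
#' orientation on a uniform grid over `[0, 180)` under the fitted encoding
#' model and generative noise model, with a uniform prior: posterior
#' proportional to the Gaussian likelihood of the observed voxel response
#' given each candidate orientation, normalized per trial with a
#' log-sum-exp shift for numerical stability.
#'
#' @param data A validation [voxel_dataset()].
#' @param fit The fitted [iem()] model.
#' @param noise The fitted [fit_noise_model()] object.
#' @param grid_step Grid resolution in degrees; must divide 180 evenly
#'   (default 1).
#' @return An object of class `posterior_map`: list with `grid` (degrees),
#'   `prob` (`n x g`, rows sum to 1), `truth` (per-trial presented
#'   orientation), `grid_step`.
#' @export
posterior_grid <- function(data, fit, noise, grid_step = 1) {
  stopifnot(inherits(data, "voxel_dataset"), inherits(fit, "iem"),
            inherits(noise, "iem_noise_model"))
  if (!is_scalar(grid_step) || grid_step <= 0 ||
      abs(180 / grid_step - round(180 / grid_step)) > 1e-9)
    stop("`grid_step` must divide 180 evenly", call. = FALSE)
  grid <- seq(0, 180 - grid_step, by = grid_step)
  W <- fit$weights
  if (ncol(data$B) != ncol(W))
    stop("dataset voxel count does not match the fit", call. = FALSE)
  Mu <- eval_basis(fit$basis, grid) %*% W        # g x v
  ch <- noise$chol_Omega
  Xb <- backsolve(ch, t(data$B), transpose = TRUE)   # v x n (whitened data)
  Xm <- backsolve(ch, t(Mu), transpose = TRUE)       # v x g (whitened means)
  qb <- colSums(Xb^2)
  qm <- colSums(Xm^2)
  # quadratic form (b - mu)' Omega^{-1} (b - mu), all trials x grid points
  qf <- outer(qb, qm, "+") - 2 * crossprod(Xb, Xm)
  ll <- -0.5 * qf
  ll <- ll - apply(ll, 1, max)
  prob <- exp(ll)
  prob <- prob / rowSums(prob)
  structure(
    list(grid = grid, prob = prob, truth = data$design$labels,
         grid_step = grid_step),
    class = "posterior_map"
  )
}

#' @export
print.posterior_map <- function(x, ...) {
  cat(sprintf("Posterior map: %d trials x %d grid points (step %g deg)\n",
              nrow(x$prob), length(x$grid), x$grid_step))
  invisible(x)
}

#' Summarize a posterior map
#'
#' Per-trial maximum a posteriori (MAP) orientation and circular error, plus
#' the aligned average posterior: each trial's posterior row is circularly
#' shifted so the grid point nearest the true orientation lands at offset 0,
#' then averaged.  Spread (full width at half maximum) and modality (local
#' maxima count) of the aligned average quantify decoding uncertainty.
#'
#' Averaged probability curves carry exponentially small but nonzero tail
#' structure (each trial's posterior decays at a different rate), so strict
#' neighbour comparison would count maxima of magnitude like `1e-100`.
#' Modes of the aligned average are therefore counted only above
#' `mode_floor` times the curve's maximum; `local_maxima()` itself stays
#' strict.
#'
#' @param posteriors A [posterior_grid()] result.
#' @param mode_floor Relative height (fraction of the global maximum) below
#'   which a strict local maximum is not counted as a mode (default 0.01).
#' @return An object of class `posterior_summary`: list with `trials` (data
#'   frame: trial, true_deg, map_deg, error_deg), `aligned` (a
#'   [circular_curve()] of the aligned average posterior), `fwhm_deg`,
#'   `n_modes`, `peak_offset_deg` (offset of the aligned maximum), and
#'   `median_error_deg`.
#' @export
summarize_posteriors <- function(posteriors, mode_floor = 0.01) {
  stopifnot(inherits(posteriors, "posterior_map"))
  P <- posteriors$prob
  n <- nrow(P)
  if (n == 0L) stop("empty posterior map", call. = FALSE)
  g <- length(posteriors$grid)
  step <- posteriors$grid_step
  map_deg <- posteriors$grid[max.col(P, ties.method = "first")]
  error_deg <- circular_distance(map_deg, posteriors$truth, period = 180)
  shift <- round(posteriors$truth / step) %% g
  aligned <- matrix(0, n, g)
  for (t in seq_len(n))
    aligned[t, ] <- P[t, ((shift[t] + 0:(g - 1)) %% g) + 1]
  offsets <- wrap_offset((0:(g - 1)) * step, period = 180)
  ord <- order(offsets)
  curve <- circular_curve(offsets[ord], colMeans(aligned)[ord], period = 180)
  idx <- local_maxima(curve)
  idx <- idx[curve$values[idx] >= mode_floor * max(curve$values)]
  structure(
    list(
      trials = data.frame(trial = seq_len(n), true_deg = posteriors$truth,
                          map_deg = map_deg, error_deg = error_deg),
      aligned = curve,
      fwhm_deg = tryCatch(fwhm(curve), error = function(e) NA_real_),
      n_modes = length(idx),
      peak_offset_deg = curve$offsets[which.max(curve$values)],
      median_error_deg = stats::median(error_deg)
    ),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "Posterior summary: %d trials; median MAP error %.2f deg; aligned posterior: %d mode(s), peak at %g deg, FWHM %.2f deg\n",
    nrow(x$trials), x$median_error_deg, x$n_modes, x$peak_offset_deg,
    x$fwhm_deg))
  invisible(x)
}

#' @param x A `posterior_summary`.
#' @param ... Passed to [graphics::plot()].
#' @rdname summarize_posteriors
#' @export
plot.posterior_summary <- function(x, ...) {
  graphics::plot(x$aligned$offsets, x$aligned$values, type = "l",
                 xlab = "offset from true orientation (deg)",
                 ylab = "mean posterior probability",
                 main = "Aligned average posterior", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
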