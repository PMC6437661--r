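#' Write and read voxel datasets as delimited text
#'
#' Datasets are stored as a CSV with columns `trial_index`,
#' `orientation_deg`, `voxel_0 ... voxel_{v-1}`, plus a YAML side-car
#' (`<path>.meta.yaml`) recording seed, noise sd, role and the design.
#'
#' @param data A [voxel_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_voxel_dataset <- function(data, path) {
  stopifnot(inherits(data, "voxel_dataset"))
  B <- data$B
  colnames(B) <- paste0("voxel_", seq_len(ncol(B)) - 1L)
  df <- cbind(data.frame(trial_index = seq_len(nrow(B)),
                         orientation_deg = data$design$labels), B)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(sigma = as.numeric(data$sigma), seed = as.integer(data$seed),
               role = data$role,
               orientations = as.numeric(data$design$orientations),
               repeats = data$design$repeats)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_voxel_dataset
#' @return For `read_voxel_dataset()`, the reconstructed [voxel_dataset()].
#' @export
read_voxel_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  design <- stimulus_design(meta$orientations, meta$repeats)
  if (!isTRUE(all.equal(df$orientation_deg, design$labels)))
    stop("stored trial orientations do not match the side-car design",
         call. = FALSE)
  B <- as.matrix(df[, grep("^voxel_", names(df)), drop = FALSE])
  dimnames(B) <- NULL
  voxel_dataset(B, design,
                sigma = if (is.null(meta$sigma)) NA_real_ else meta$sigma,
                seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
                role = meta$role)
}

#' Export an aligned CRF as a delimited table
#'
#' @param crf An `aligned_crf` from [shift_average()].
#' @param path Output CSV path.
#' @param basis_kind,noise_preset Labels recorded in the table.
#' @return The exported data frame, invisibly.
#' @export
write_aligned_crf <- function(crf, path, basis_kind = "", noise_preset = "") {
  stopifnot(inherits(crf, "aligned_crf"))
  df <- data.frame(basis_kind = basis_kind, noise_preset = noise_preset,
                   offset_deg = crf$offsets, mean = crf$mean, sem = crf$sem,
                   n_trials = crf$n_trials)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export a posterior map as a delimited table
#'
#' Long format: one row per trial per grid point with columns
#' `trial_index`, `true_deg`, `grid_deg`, `probability`.
#'
#' @param posteriors A [posterior_grid()] result.
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
write_posterior_map <- function(posteriors, path) {
  stopifnot(inherits(posteriors, "posterior_map"))
  n <- nrow(posteriors$prob)
  g <- length(posteriors$grid)
  df <- data.frame(
    trial_index = rep(seq_len(n), each = g),
    true_deg = rep(posteriors$truth, each = g),
    grid_deg = rep(posteriors$grid, times = n),
    probability = as.vector(t(posteriors$prob))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Serialize a basis or transform specification to YAML
#'
#' @param x A [channel_basis()] or [channel_transform()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_basis_config <- function(x, path) {
  spec <- if (inherits(x, "channel_basis")) {
    out <- list(object = "channel_basis", kind = x$kind, k = x$k, p = x$p)
    if (x$kind == "transformed") {
      tr <- x$transform
      out$transform <- list(kind = tr$kind,
                            lobe_shift = tr$lobe_shift,
                            secondary_gain = tr$secondary_gain,
                            seed = tr$seed)
    }
    out
  } else if (inherits(x, "channel_transform")) {
    list(object = "channel_transform", kind = x$kind, k = nrow(x$P),
         lobe_shift = x$lobe_shift, secondary_gain = x$secondary_gain,
         seed = x$seed)
  } else stop("`x` must be a channel_basis or channel_transform", call. = FALSE)
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' @rdname write_basis_config
#' @return For `read_basis_config()`, the reconstructed object.
#' @export
read_basis_config <- function(path) {
  spec <- yaml::read_yaml(path)
  build_transform <- function(s, k) {
    switch(s$kind,
           bimodal = bimodal_transform(k, s$lobe_shift, s$secondary_gain),
           random = random_transform(k, seed = s$seed),
           stop("cannot rebuild a transform of kind ", s$kind, call. = FALSE))
  }
  if (identical(spec$object, "channel_transform"))
    return(build_transform(spec, spec$k))
  if (identical(spec$object, "channel_basis")) {
    b <- channel_basis(spec$k, spec$p)
    if (identical(spec$kind, "transformed"))
      b <- transform_basis(b, build_transform(spec$transform, spec$k))
    return(b)
  }
  stop("unrecognized config object: ", spec$object, call. = FALSE)
}

#' Export a basis evaluation grid as a delimited table
#'
#' Long format with columns `angle_deg`, `channel_index`, `value`.
#'
#' @param basis A [channel_basis()].
#' @param path Output CSV path.
#' @param step Evaluation step in degrees.
#' @return The exported data frame, invisibly.
#' @export
write_basis_grid <- function(basis, path, step = 1) {
  grid <- seq(0, 180 - step, by = step)
  C <- eval_basis(basis, grid)
  df <- data.frame(angle_deg = rep(grid, times = ncol(C)),
                   channel_index = rep(seq_len(ncol(C)), each = length(grid)),
                   value = as.vector(C))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
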