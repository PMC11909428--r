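#' Training configuration
#'
#' Defaults mirror the study design this package emulates: 5 epochs with the
#' Adam optimizer at learning rate 1e-5, per-channel binary cross-entropy on
#' individual B-scans with intensities scaled to `[0, 1]` (no device-specific
#' normalization), and a 0.5 threshold on the sigmoid output. The networks
#' use a fixed-gain weight parameterization (see the methods vignette), which
#' keeps these settings effective for compact networks on desk-scale data.
#'
#' @param epochs training epochs (>= 1).
#' @param learning_rate Adam learning rate (> 0).
#' @param optimizer only `"adam"` is implemented.
#' @param batch_size B-scans per optimization step.
#' @param loss `"bce"` (per-channel binary cross-entropy, the default) or
#'   `"dice"` (soft Dice).
#' @param threshold sigmoid threshold in `(0, 1)`; strictly-greater rule, so a
#'   score exactly at the threshold is excluded.
#' @param augment seeded train-time intensity augmentation (per-B-scan
#'   multiplicative speckle of random contrast, gamma jitter, brightness and
#'   scale jitter). Emulates device appearance variability so the networks
#'   learn structural rather than absolute-intensity cues; labels are never
#'   altered. Default TRUE.
#' @param seed integer seed controlling initialization and data order.
#' @param arch `"encoder_decoder"` (contracting/expansive path with skip
#'   connections, 3 resolution levels) or `"dilated"` (parallel dilation rates
#'   1, 2, 4 at constant resolution).
#' @param base_channels width of the first convolution; deeper layers scale
#'   from it.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 5L, learning_rate = 1e-5,
                         optimizer = "adam", batch_size = 1L,
                         loss = c("bce", "dice"), threshold = 0.5,
                         augment = TRUE, seed = 0L,
                         arch = c("encoder_decoder", "dilated"),
                         base_channels = 8L) {
  loss <- match.arg(loss)
  if (!identical(optimizer, "adam")) {
    rlang::abort("train_config: only the adam optimizer is implemented")
  }
  if (epochs < 1) rlang::abort("train_config: epochs must be >= 1")
  if (learning_rate <= 0) rlang::abort("train_config: learning_rate must be > 0")
  if (threshold <= 0 || threshold >= 1) {
    rlang::abort("train_config: threshold must lie in (0, 1)")
  }
  if (!is.character(arch) || !all(arch %in% c("encoder_decoder", "dilated"))) {
    rlang::abort(sprintf("train_config: unknown arch '%s'", arch[1]))
  }
  arch <- match.arg(arch)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = optimizer, batch_size = as.integer(batch_size),
                 loss = loss, threshold = threshold,
                 augment = isTRUE(augment), seed = as.integer(seed),
                 arch = arch, base_channels = as.integer(base_channels)),
            class = "train_config")
}

param_checksum <- function(params) {
  vals <- unlist(c(params$W, params$b), use.names = FALSE)
  sprintf("%.12e|%.12e|%d", sum(vals), sum(vals^2), length(vals))
}

#' Build a segmentation model
#'
#' Deterministically initializes the chosen architecture from the config's
#' seed. Both architectures map one grayscale B-scan to three per-pixel score
#' channels (ILM band, RPE band, RPEDC region) at the input resolution; the
#' channels are independent binaries because the RPE band lies inside the
#' RPEDC region.
#'
#' @param config a [train_config()].
#' @return A `model_handle` with fields `arch`, `config`, `params`,
#'   `checksum`, `loss_history`, `trained`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "train_config"))
  params <- nn_init_cpp(config$arch, config$base_channels, config$seed)
  structure(list(arch = config$arch, config = config, params = params,
                 checksum = param_checksum(params),
                 loss_history = NULL, trained = FALSE),
            class = "model_handle")
}

#' @export
print.model_handle <- function(x, ...) {
  np <- sum(vapply(c(x$params$W, x$params$b), length, numeric(1)))
  cat(sprintf("<model_handle> arch=%s params=%d trained=%s\n",
              x$arch, np, x$trained))
  invisible(x)
}

#' @export
glance.model_handle <- function(x, ...) {
  np <- sum(vapply(c(x$params$W, x$params$b), length, numeric(1)))
  tibble::tibble(arch = x$arch, n_parameters = np, trained = x$trained,
                 epochs = x$config$epochs,
                 final_loss = if (is.null(x$loss_history)) NA_real_ else
                   utils::tail(x$loss_history$mean_loss, 1))
}

# Edge-replicate pad a matrix on the bottom/right to multiples of `m`.
pad_to_multiple <- function(x, m = 8L) {
  h <- nrow(x); w <- ncol(x)
  H <- as.integer(ceiling(h / m) * m); W <- as.integer(ceiling(w / m) * m)
  if (H == h && W == w) return(x)
  out <- x[c(seq_len(h), rep(h, H - h)), c(seq_len(w), rep(w, W - w)), drop = FALSE]
  out
}

# Stack cases into training arrays: X [H, W, N] in [0,1], Y [H, W, 3N].
build_training_arrays <- function(cases) {
  if (length(cases) == 0) rlang::abort("train_model: empty training set")
  xs <- list(); ys <- list()
  for (case in cases) {
    vol <- case$volume; labels <- case$labels
    stopifnot(inherits(vol, "oct_volume"), inherits(labels, "oct_labels"))
    if (!grids_equal(vol$grid, labels$grid)) {
      rlang::abort("train_model: volume and labels must live on the same grid")
    }
    for (b in seq_len(vol$grid$n_bscans)) {
      xs[[length(xs) + 1]] <- pad_to_multiple(vol$intensities[, , b] / 255)
      ys[[length(ys) + 1]] <- list(
        pad_to_multiple(labels$ilm_band[, , b]),
        pad_to_multiple(labels$rpe_band[, , b]),
        pad_to_multiple(labels$rpedc[, , b])
      )
    }
  }
  dims <- dim(xs[[1]])
  if (!all(vapply(xs, function(m) all(dim(m) == dims), logical(1)))) {
    rlang::abort("train_model: all training B-scans must share one shape")
  }
  X <- array(unlist(xs), c(dims, length(xs)))
  Y <- array(unlist(lapply(ys, function(l) unlist(l))), c(dims, 3L * length(xs)))
  list(X = X, Y = Y)
}

#' Train a segmentation model
#'
#' Trains on individual B-scans (intensities divided by 255; no per-volume
#' standardization) with the config's loss and Adam settings, recording the
#' mean loss per epoch. Fully seeded: initialization and the per-epoch
#' shuffling both derive from `config$seed`, so identical inputs give
#' identical loss histories and parameters.
#'
#' @param model a `model_handle` from [build_model()], or NULL to build one
#'   from `config`.
#' @param cases list of training cases, each a list with elements `volume`
#'   (an [oct_volume()]) and `labels` (an [oct_labels()] on the same grid).
#' @param config a [train_config()]; defaults to the model's.
#' @return The trained `model_handle`; `$loss_history` is a tibble
#'   `(epoch, mean_loss)`.
#' @export
train_model <- function(model, cases, config = model$config) {
  stopifnot(inherits(model, "model_handle"), inherits(config, "train_config"))
  if (config$arch != model$arch) {
    rlang::abort("train_model: config arch does not match model")
  }
  arrs <- build_training_arrays(cases)
  fit <- nn_train_cpp(model$arch, model$params, arrs$X, arrs$Y,
                      epochs = config$epochs, lr = config$learning_rate,
                      batch_size = config$batch_size, seed = config$seed,
                      loss = config$loss, augment = config$augment)
  model$params <- fit$params
  model$checksum <- param_checksum(fit$params)
  model$loss_history <- tibble::tibble(epoch = seq_len(config$epochs),
                                       mean_loss = as.numeric(fit$epoch_loss))
  model$trained <- TRUE
  model$config <- config
  model
}

#' Predict label channels for a volume
#'
#' Runs per-B-scan inference, maps the three score channels through a sigmoid
#' and thresholds each channel independently with a strictly-greater rule
#' (a probability exactly equal to the threshold is excluded). The output
#' grid equals the input grid.
#'
#' @param model a `model_handle`.
#' @param vol an [oct_volume()].
#' @param threshold sigmoid threshold; defaults to the model config's.
#' @return An [oct_labels()] on `vol`'s grid.
#' @export
predict_labels <- function(model, vol, threshold = model$config$threshold) {
  stopifnot(inherits(model, "model_handle"), inherits(vol, "oct_volume"))
  if (threshold <= 0 || threshold >= 1) {
    rlang::abort("predict_labels: threshold must lie in (0, 1)")
  }
  g <- vol$grid
  dims <- c(g$n_rows, g$n_cols, g$n_bscans)
  chans <- list(array(0L, dims), array(0L, dims), array(0L, dims))
  for (b in seq_len(g$n_bscans)) {
    x <- pad_to_multiple(vol$intensities[, , b] / 255)
    z <- nn_forward_cpp(model$arch, model$params, x)
    for (c in 1:3) {
      p <- stats::plogis(z[seq_len(g$n_rows), seq_len(g$n_cols), c])
      chans[[c]][, , b] <- (p > threshold) * 1L
    }
  }
  oct_labels(chans[[1]], chans[[2]], chans[[3]], g)
}
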