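#' Configure a kernel-converter network
#'
#' The converter is a residual fully convolutional 2D network: the input
#' slice passes through `n_layers` 3x3 convolutions (rectifier nonlinearity
#' on all but the last, which maps back to one channel), and the network
#' output is input + predicted residual. The final layer is zero-initialized
#' so an untrained converter is exactly the identity map. Training minimizes
#' the sum-of-squares difference between converted source slices and target
#' slices with Adam; the loss is reported as the per-pixel mean, which is the
#' sum of squares divided by a constant. Defaults for the optimizer follow
#' a fixed recipe (learning rate 1e-4, 55 epochs, Adam); the depth and
#' width of the stack are package choices and fully configurable.
#'
#' Intensities are normalized as `(x - intensity_shift) / intensity_scale`
#' before entering the network (defaults put aerated-lung background near 0
#' on a unit-ish scale) and the residual is scaled back on the way out.
#'
#' @param direction `"to_smooth"` (converts sharp-kernel images to smooth) or
#'   `"to_sharp"`.
#' @param n_layers Number of 3x3 convolution layers (>= 2).
#' @param channels Feature channels in the hidden layers.
#' @param learning_rate Adam step size.
#' @param n_epochs Training epochs.
#' @param batch_size Slices per optimization step.
#' @param intensity_shift,intensity_scale Normalization constants (HU-like
#'   units), recorded with the model.
#' @param seed Integer seed controlling weight initialization, the train/test
#'   split and batch shuffling.
#' @return A `converter_config` object.
#' @export
converter_config <- function(direction = c("to_smooth", "to_sharp"),
                             n_layers = 6L, channels = 64L,
                             learning_rate = 1e-4, n_epochs = 55L,
                             batch_size = 8L,
                             intensity_shift = -800, intensity_scale = 1000,
                             seed = 42L) {
  direction <- match.arg(direction)
  n_layers <- as.integer(n_layers)
  if (n_layers < 2L) abort("n_layers must be >= 2")
  stopifnot(channels >= 1L, learning_rate > 0, n_epochs >= 1L,
            batch_size >= 1L, intensity_scale > 0)
  structure(
    list(direction = direction, n_layers = n_layers,
         channels = as.integer(channels), learning_rate = learning_rate,
         n_epochs = as.integer(n_epochs), batch_size = as.integer(batch_size),
         intensity_shift = intensity_shift, intensity_scale = intensity_scale,
         seed = as.integer(seed)),
    class = "converter_config"
  )
}

#' Build an (untrained) kernel converter
#'
#' @param config A [converter_config()].
#' @return A `kernel_converter`. Until trained it is the exact identity map.
#' @export
build_converter <- function(config) {
  stopifnot(inherits(config, "converter_config"))
  layers <- nn_init_layers(config$n_layers, config$channels,
                           derive_seed(config$seed, "init"))
  structure(
    list(config = config, layers = layers, trained = FALSE,
         training_log = tibble(epoch = integer(), train_loss = double(),
                               test_loss = double()),
         initial_test_loss = NA_real_),
    class = "kernel_converter"
  )
}

#' Number of trainable parameters of a converter
#' @param model A `kernel_converter`.
#' @return Integer parameter count (weights + biases).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "kernel_converter"))
  sum(vapply(model$layers, function(ly) length(ly$W) + length(ly$b), double(1)))
}

#' @export
print.kernel_converter <- function(x, ...) {
  cat(sprintf(
    "<kernel_converter %s> %d conv layers x %d channels, %s, %s parameters\n",
    x$config$direction, x$config$n_layers, x$config$channels,
    if (x$trained) sprintf("trained %d epochs", nrow(x$training_log))
    else "untrained (identity)",
    format(n_parameters(x), big.mark = ",")
  ))
  if (x$trained) {
    last <- x$training_log[nrow(x$training_log), ]
    cat(sprintf("  held-out loss: %.4g initial -> %.4g final (per-pixel MSE, normalized units)\n",
                x$initial_test_loss, last$test_loss))
  }
  invisible(x)
}

#' @rdname tidy.ccc_report
#' @export
tidy.kernel_converter <- function(x, ...) x$training_log

#' @rdname tidy.ccc_report
#' @export
glance.kernel_converter <- function(x, ...) {
  tibble(
    direction = x$config$direction,
    n_layers = x$config$n_layers,
    channels = x$config$channels,
    n_parameters = n_parameters(x),
    trained = x$trained,
    initial_test_loss = x$initial_test_loss,
    final_test_loss = if (x$trained) x$training_log$test_loss[nrow(x$training_log)] else NA_real_
  )
}

normalize_slices <- function(x, config) {
  (x - config$intensity_shift) / config$intensity_scale
}

stack_pairs <- function(pairs) {
  d <- dim(pairs[[1]]$source)
  src <- array(0, c(d[1], d[2], length(pairs)))
  tgt <- array(0, c(d[1], d[2], length(pairs)))
  for (i in seq_along(pairs)) {
    if (!identical(dim(pairs[[i]]$source), d) ||
        !identical(dim(pairs[[i]]$target), d)) {
      abort("all source/target slices must share one shape")
    }
    src[, , i] <- pairs[[i]]$source
    tgt[, , i] <- pairs[[i]]$target
  }
  list(source = src, target = tgt)
}

# Per-pixel mean squared error between converted source and target, in
# normalized units (proportional to the sum-of-squares loss).
converter_loss <- function(layers, src, tgt) {
  res <- nn_forward(layers, src)$residual
  mean((src + res - tgt)^2)
}

#' Train a kernel converter on paired slices
#'
#' Minimizes the sum-of-squares loss between converted source slices and
#' target slices with Adam, recording the training-set and held-out loss at
#' every epoch. The held-out split, batch order and weight initialization are
#' all derived from `config$seed`, so training is fully reproducible.
#'
#' @param pairs A list of `list(source = , target = )` matrices (axial
#'   slices, raw intensity units), e.g. from [cohort_slice_pairs()].
#' @param config A [converter_config()].
#' @param holdout_fraction Fraction of pairs held out for the per-epoch test
#'   loss (default 0.25). With 0, the training set doubles as the held-out
#'   set.
#' @return A trained `kernel_converter`; `tidy()` returns the per-epoch log.
#' @export
train_converter <- function(pairs, config, holdout_fraction = 0.25) {
  stopifnot(inherits(config, "converter_config"))
  if (length(pairs) < 2L) abort("need at least 2 slice pairs")
  if (holdout_fraction < 0 || holdout_fraction >= 1) {
    abort("holdout_fraction must be in [0, 1)")
  }
  stacked <- stack_pairs(pairs)
  src <- normalize_slices(stacked$source, config)
  tgt <- normalize_slices(stacked$target, config)
  assert_finite_array(src, "source slices")
  assert_finite_array(tgt, "target slices")
  n <- dim(src)[3]
  h <- dim(src)[1]; w <- dim(src)[2]

  n_hold <- round(holdout_fraction * n)
  perm <- with_seed(derive_seed(config$seed, "split"), sample(n))
  hold_idx <- if (n_hold >= 1) perm[seq_len(n_hold)] else integer()
  train_idx <- setdiff(perm, hold_idx)
  if (length(train_idx) < 1L) abort("holdout leaves no training pairs")
  eval_idx <- if (length(hold_idx) >= 1L) hold_idx else train_idx

  model <- build_converter(config)
  layers <- model$layers
  state <- nn_adam_init(layers)
  src_hold <- src[, , eval_idx, drop = FALSE]
  tgt_hold <- tgt[, , eval_idx, drop = FALSE]
  initial_test_loss <- converter_loss(layers, src_hold, tgt_hold)

  log <- tibble(epoch = seq_len(config$n_epochs),
                train_loss = NA_real_, test_loss = NA_real_)
  t_step <- 0L
  set.seed(derive_seed(config$seed, "batches"))
  for (epoch in seq_len(config$n_epochs)) {
    order_ep <- sample(train_idx)
    starts <- seq(1L, length(order_ep), by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      ids <- order_ep[starts[bi]:min(starts[bi] + config$batch_size - 1L,
                                     length(order_ep))]
      xb <- src[, , ids, drop = FALSE]
      yb <- tgt[, , ids, drop = FALSE]
      fw <- nn_forward(layers, xb, keep_cache = TRUE)
      diff <- xb + fw$residual - yb
      loss <- mean(diff^2)
      if (!is.finite(loss)) {
        abort(sprintf("non-finite training loss at epoch %d (diverged; lower the learning rate)", epoch))
      }
      batch_losses[bi] <- loss
      dres <- 2 * diff / length(diff)
      grads <- nn_backward(layers, fw$cache, dres, h, w, length(ids))
      t_step <- t_step + 1L
      upd <- nn_adam_step(layers, grads, state, config$learning_rate, t_step)
      layers <- upd$layers
      state <- upd$state
    }
    log$train_loss[epoch] <- mean(batch_losses)
    log$test_loss[epoch] <- converter_loss(layers, src_hold, tgt_hold)
  }

  model$layers <- layers
  model$trained <- TRUE
  model$training_log <- log
  model$initial_test_loss <- initial_test_loss
  model$holdout_idx <- hold_idx
  model
}

#' Extract paired training slices from a cohort
#'
#' For direction `"to_smooth"` the source slices come from the sharp-kernel
#' rendering and the targets from the smooth rendering of the same record
#' (and vice versa for `"to_sharp"`).
#'
#' @param cohort A `kernel_cohort`.
#' @param direction Conversion direction.
#' @param slices Axial slice indices to use per record (default: all).
#' @param patients Patient indices to draw slices from (default: all).
#' @return A list of `list(source, target)` matrices.
#' @export
cohort_slice_pairs <- function(cohort, direction = c("to_smooth", "to_sharp"),
                               slices = NULL, patients = NULL) {
  stopifnot(inherits(cohort, "kernel_cohort"))
  direction <- match.arg(direction)
  patients <- patients %||% seq_along(cohort$records)
  pairs <- list()
  for (i in patients) {
    rec <- cohort$records[[i]]
    smo <- volume_values(rec$smooth_image)
    shp <- volume_values(rec$sharp_image)
    zs <- slices %||% seq_len(dim(smo)[3])
    for (z in zs) {
      pairs[[length(pairs) + 1L]] <-
        if (direction == "to_smooth") {
          list(source = shp[, , z], target = smo[, , z])
        } else {
          list(source = smo[, , z], target = shp[, , z])
        }
    }
  }
  pairs
}

#' Convert a volume with a trained kernel converter
#'
#' Applies the network slice-by-slice along the axial axis. The residual is
#' predicted in normalized units and added back on the raw intensity scale,
#' so an untrained converter returns the input bit-identically.
#'
#' @param model A `kernel_converter`.
#' @param volume A `ct_volume` or 3D array.
#' @return Converted volume of the same class and shape.
#' @export
convert_volume <- function(model, volume) {
  stopifnot(inherits(model, "kernel_converter"))
  vals <- volume_values(volume)
  stopifnot(length(dim(vals)) == 3L)
  assert_finite_array(vals, "volume")
  xn <- normalize_slices(vals, model$config)
  res <- nn_forward(model$layers, xn)$residual
  out <- vals + model$config$intensity_scale * res
  if (inherits(volume, "ct_volume")) {
    new_ct_volume(out, volume$spacing)
  } else {
    out
  }
}

#' Root-mean-square error between two images
#'
#' @param a,b Arrays or `ct_volume`s of identical shape.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  av <- volume_values(a); bv <- volume_values(b)
  assert_same_shape(av, bv, c("a", "b"))
  sqrt(mean((av - bv)^2))
}

#' Percent RMSE reduction achieved by a conversion
#'
#' `100 * (1 - rmse(converted, target) / rmse(source, target))`: 100 means
#' the conversion reproduces the target exactly, 0 means no improvement over
#' leaving the source untouched.
#'
#' @param source Unconverted image.
#' @param converted Converted image.
#' @param target Target-kernel reference image.
#' @return Percentage; 0 with a warning when `rmse(source, target)` is 0.
#' @export
rmse_reduction <- function(source, converted, target) {
  base <- rmse(source, target)
  if (base == 0) {
    warn("rmse(source, target) is 0; reduction undefined, reporting 0")
    return(0)
  }
  100 * (1 - rmse(converted, target) / base)
}
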