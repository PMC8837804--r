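#' Network configuration
#'
#' Architecture and optimizer settings of the projection-domain U-Net.
#' The full-scale defaults are a 7-level network with 16 base features
#' (bottleneck 16 * 2^6 = 1024 feature maps), 3x3 convolutions + ReLU,
#' 2x2 max pooling, bilinear upsampling, channel concatenation of
#' matching contraction outputs, no batch normalization (avoids scaling
#' the physically meaningful line-integral values), MAE loss and Adam
#' (lr 1e-5, beta1 0.900, beta2 0.999), batch size 18, 300 epochs.
#' [desk_config()] is the small configuration used for fast end-to-end
#' runs: depth 4, base 8, on 64 x 64 projections; its initial learning
#' rate is raised to 1e-2 (selected by validation MAE among candidate
#' rates) because the desk-scale run performs roughly 30x fewer
#' optimizer updates than the full-scale schedule, and is cosine-annealed
#' over the run.
#'
#' @param depth Number of resolution levels.
#' @param base_features Feature maps at the first level.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation MAE (epochs
#'   without improvement; 0 disables). The best-validation weights are
#'   checkpointed either way.
#' @param seed Seed for weight initialization and shuffling.
#' @return A `monoct_netconfig`.
#' @export
net_config <- function(depth = 7, base_features = 16, lr = 1e-5,
                       lr_schedule = c("constant", "cosine"),
                       beta1 = 0.900, beta2 = 0.999,
                       batch_size = 18, epochs = 300, patience = 0,
                       seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(depth >= 2, base_features >= 1, lr >= 0, batch_size >= 1,
            epochs >= 0)
  structure(list(depth = as.integer(depth),
                 base_features = as.integer(base_features),
                 lr = lr, lr_schedule = lr_schedule, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "monoct_netconfig")
}

#' @rdname net_config
#' @param lr_schedule `"constant"` (full-scale default) or `"cosine"`
#'   (desk-scale default): linear warmup over the first 5% of epochs
#'   (protects the raised initial rate from early dead-ReLU collapse),
#'   then cosine annealing from `lr` to `lr/100`, which keeps the rate
#'   high while the mapping is being learned and then quiets Adam's
#'   MAE-gradient dithering, whose steady-state amplitude is
#'   proportional to the learning rate.
#' @export
desk_config <- function(depth = 4, base_features = 8, lr = 1e-2,
                        lr_schedule = "cosine", epochs = 100,
                        patience = 0, seed = 1L, ...) {
  net_config(depth = depth, base_features = base_features, lr = lr,
             lr_schedule = lr_schedule, epochs = epochs,
             patience = patience, seed = seed, ...)
}

#' Feature-map widths per level
#' @param config A `monoct_netconfig`.
#' @return Integer vector, level 1 (finest) to `depth` (bottleneck).
#' @export
feature_widths <- function(config) {
  config$base_features * 2^(seq_len(config$depth) - 1)
}

#' Build (initialize) the network
#'
#' He fan-in-scaled random initialization, fully seeded. The model is
#' fully convolutional; `input_dim`, when given, is validated against
#' the pooling depth (each spatial dimension must be divisible by
#' `2^(depth-1)`).
#'
#' @param config A `monoct_netconfig`.
#' @param input_dim Optional (H, W) of the intended inputs.
#' @return A `monoct_model` (untrained).
#' @export
build_network <- function(config, input_dim = NULL) {
  stopifnot(inherits(config, "monoct_netconfig"))
  if (!is.null(input_dim)) {
    dv <- 2^(config$depth - 1)
    if (any(input_dim %% dv != 0)) {
      need <- ceiling(input_dim / dv) * dv
      stop(sprintf(paste0("input %d x %d not divisible by 2^(depth-1) = %d; ",
                          "pad to %d x %d"),
                   input_dim[1], input_dim[2], dv, need[1], need[2]))
    }
  }
  h <- if (is.null(input_dim)) 2^(config$depth - 1) else input_dim[1]
  w <- if (is.null(input_dim)) 2^(config$depth - 1) else input_dim[2]
  weights <- cpp_unet_init(config$depth, config$base_features,
                           as.integer(h), as.integer(w), config$seed)
  structure(list(weights = weights, config = config, history = NULL,
                 provenance = list()),
            class = "monoct_model")
}

#' Number of trainable parameters
#' @param model A `monoct_model`.
#' @return Integer parameter count (weights + biases).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights,
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @export
print.monoct_model <- function(x, ...) {
  cf <- x$config
  cat(sprintf("<model> depth %d, base %d (bottleneck %d), %s parameters%s\n",
              cf$depth, cf$base_features, max(feature_widths(cf)),
              format(n_parameters(x), big.mark = ","),
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

#' Deterministic train/test split at the projection-pair level
#'
#' Shuffles pair indices with the given seed and assigns the first
#' `round(n * train_fraction)` to training. Pairs from the same phantom
#' may land on both sides (matching the printed corpus counts);
#' `by_phantom = TRUE` instead holds out whole phantoms.
#'
#' @param specs List of `monoct_simspec` (or an integer count).
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @param by_phantom Split on phantom identity instead of pair identity.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering all pairs).
#' @export
split_dataset <- function(specs, train_fraction = 0.8, seed = 1L,
                          by_phantom = FALSE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- if (is.numeric(specs)) as.integer(specs) else length(specs)
  if (n == 0) stop("empty dataset")
  with_seed(seed, {
    if (by_phantom && !is.numeric(specs)) {
      key <- vapply(specs, function(s)
        paste(s$kind, s$phantom_id, if (s$kind == "cylinder") s$id else ""),
        character(1))
      groups <- sample(unique(key))
      ntr_target <- round(n * train_fraction)
      cum <- cumsum(vapply(groups, function(g) sum(key == g), numeric(1)))
      ngr <- which.min(abs(cum - ntr_target))
      train <- which(key %in% groups[seq_len(ngr)])
      list(train = train, test = setdiff(seq_len(n), train))
    } else {
      idx <- sample.int(n)
      ntr <- round(n * train_fraction)
      list(train = sort(idx[seq_len(ntr)]), test = sort(idx[-seq_len(ntr)]))
    }
  })
}

# cheap content hash for provenance (no external digest dependency)
.data_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL), f)
  unname(tools::md5sum(f))
}

#' Train the network
#'
#' Adam optimization of the MAE loss at the configured hyperparameters,
#' with per-epoch training/validation MAE history and checkpointing of
#' the best-validation weights (returned). Aborts with a diagnostic on
#' non-finite loss. Fully deterministic given the config seed.
#'
#' @param model A `monoct_model` from [build_network()].
#' @param x,y Input (polyenergetic) and target (monoenergetic) image
#'   stacks, `H x W x N` arrays on the line-integral scale; no
#'   normalization is applied.
#' @param train_idx,val_idx Slice indices of the training and validation
#'   subsets (see [split_dataset()]).
#' @param verbose Print per-epoch losses.
#' @return A trained `monoct_model` with `history` (data.frame of
#'   per-epoch train/validation MAE) and provenance (data hash, seed,
#'   best epoch).
#' @export
train_network <- function(model, x, y, train_idx, val_idx,
                          verbose = FALSE) {
  stopifnot(inherits(model, "monoct_model"),
            identical(dim(x), dim(y)), length(dim(x)) == 3L,
            length(intersect(train_idx, val_idx)) == 0)
  cf <- model$config
  dv <- 2^(cf$depth - 1)
  if (any(dim(x)[1:2] %% dv != 0)) {
    stop("image size ", dim(x)[1], " x ", dim(x)[2],
         " not divisible by 2^(depth-1) = ", dv)
  }
  fit <- cpp_unet_train(model$weights, x, y,
                        as.integer(train_idx), as.integer(val_idx),
                        cf$depth, cf$base_features, cf$epochs, cf$lr,
                        if (cf$lr_schedule == "cosine") 1L else 0L,
                        cf$beta1, cf$beta2, cf$batch_size, cf$seed,
                        cf$patience, verbose)
  model$weights <- fit$weights
  model$history <- data.frame(epoch = seq_along(fit$train_mae),
                              train_mae = fit$train_mae,
                              val_mae = fit$val_mae)
  model$provenance <- list(data_hash = .data_hash(list(x, y)),
                           seed = cf$seed,
                           n_train = length(train_idx),
                           n_val = length(val_idx),
                           best_epoch = fit$best_epoch,
                           best_val_mae = fit$best_val_mae)
  model
}

# reflective padding to the next multiple of 2^(depth-1) and the inverse
.pad_reflect <- function(img, dv) {
  d <- dim(img)
  tgt <- ceiling(d / dv) * dv
  if (all(tgt == d)) return(list(img = img, crop = d))
  pr <- tgt[1] - d[1]; pc <- tgt[2] - d[2]
  if (pr >= d[1] || pc >= d[2]) stop("image too small to pad reflectively")
  if (pr > 0) img <- rbind(img, img[d[1] - seq_len(pr), , drop = FALSE])
  if (pc > 0) img <- cbind(img, img[, d[2] - seq_len(pc), drop = FALSE])
  list(img = img, crop = d)
}

#' Predict virtual monoenergetic projections
#'
#' Per-image inference on a polyenergetic projection set. Images whose
#' size is not divisible by `2^(depth-1)` are reflectively padded and
#' cropped back after inference. Pure function: the input set is not
#' modified, and prediction is deterministic given the weights.
#'
#' @param model A trained `monoct_model`.
#' @param poly A `monoct_projections`; a warning is issued if its kind
#'   is not `"poly"`.
#' @return A `monoct_projections` of kind `"predicted-mono"` carrying
#'   model provenance in its metadata.
#' @export
predict_mono <- function(model, poly) {
  stopifnot(inherits(model, "monoct_model"),
            inherits(poly, "monoct_projections"))
  if (is.null(poly$geometry)) stop("projection set has no geometry")
  if (!identical(poly$kind, "poly")) {
    warning("predicting from projections of kind '", poly$kind,
            "' (expected 'poly')")
  }
  cf <- model$config
  dv <- 2^(cf$depth - 1)
  d <- dim(poly$images)
  padded <- .pad_reflect(poly$images[, , 1], dv)
  pd <- dim(padded$img)
  xin <- array(0, c(pd, d[3]))
  for (i in seq_len(d[3])) {
    xin[, , i] <- .pad_reflect(poly$images[, , i], dv)$img
  }
  pred <- cpp_unet_forward(model$weights, xin, cf$depth, cf$base_features)
  out <- pred[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  .new_projection_set(out, poly$angles, poly$geometry, "predicted-mono",
                      c(poly$meta, list(model_provenance = model$provenance)))
}

#' Save/load a model checkpoint
#'
#' Self-describing container: weights, config, history and provenance in
#' one serialized file; the per-epoch loss history is additionally
#' written as a CSV log next to it.
#'
#' @param model A `monoct_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `read_checkpoint` returns a `monoct_model`.
#' @export
write_checkpoint <- function(model, path) {
  saveRDS(model, path)
  if (!is.null(model$history)) {
    utils::write.csv(model$history, paste0(path, ".history.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "monoct_model"))
  model
}
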