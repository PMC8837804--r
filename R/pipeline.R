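#' Declarative run configuration
#'
#' One object describing a full simulate/train/predict/reconstruct/
#' evaluate run. Round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]); the master seed fully
#' determines every stochastic choice via [stage_seed()].
#'
#' @param master_seed Master seed for the whole run.
#' @param n_mouse,pairs_per_mouse,n_cylinder Corpus composition.
#' @param kvp Tube potential (kV).
#' @param mono_energy_keV Virtual monoenergetic energy.
#' @param detector_mode Detector response mode (see [detector_model()]).
#' @param det_pixels,det_pitch_mm Detector sampling for the projections.
#' @param net Named list of [net_config()] overrides (depth,
#'   base_features, lr, epochs, ...).
#' @param train_fraction Train split fraction.
#' @param recon_n,recon_voxel_mm Reconstruction grid (cubic).
#' @param air_threshold Air-trajectory exclusion threshold for
#'   percentage errors.
#' @param out_dir Output directory.
#' @return A `monoct_runconfig` (a named list).
#' @export
run_config <- function(master_seed = 1L, n_mouse = 3, pairs_per_mouse = 25,
                       n_cylinder = 125, kvp = 60, mono_energy_keV = 35,
                       detector_mode = "csi", det_pixels = 64,
                       det_pitch_mm = c(2.75, 2.0), net = list(),
                       train_fraction = 0.8, recon_n = 64,
                       recon_voxel_mm = 0.4, air_threshold = 0.01,
                       out_dir = "monoct_run") {
  structure(list(master_seed = as.integer(master_seed),
                 n_mouse = n_mouse, pairs_per_mouse = pairs_per_mouse,
                 n_cylinder = n_cylinder, kvp = kvp,
                 mono_energy_keV = mono_energy_keV,
                 detector_mode = detector_mode, det_pixels = det_pixels,
                 det_pitch_mm = det_pitch_mm, net = net,
                 train_fraction = train_fraction, recon_n = recon_n,
                 recon_voxel_mm = recon_voxel_mm,
                 air_threshold = air_threshold, out_dir = out_dir),
            class = "monoct_runconfig")
}

#' @rdname run_config
#' @param config A `monoct_runconfig`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Hierarchical per-stage seed derivation
#'
#' `stage_seed(master, stage)` = `(master * 100003 + stage * 7919)`
#' modulo `2^31 - 1` (kept positive): stages can be rerun independently
#' yet reproducibly from one master seed. Stage ids: 1 corpus, 2 split,
#' 3 network, 4 noise.
#'
#' @param master_seed,stage Integers.
#' @return Integer seed in `[1, 2^31 - 1]`.
#' @export
stage_seed <- function(master_seed, stage) {
  as.integer((as.double(master_seed) * 100003 + stage * 7919) %%
               2147483647 + 1)
}

.cfg_geometry <- function(config, angles = 0) {
  cbct_geometry(npix = rep(config$det_pixels, 2),
                pitch = rep(config$det_pitch_mm, length.out = 2),
                angles = angles)
}

.cfg_net <- function(config) {
  do.call(desk_config,
          c(config$net[setdiff(names(config$net), "seed")],
            list(seed = stage_seed(config$master_seed, 3))))
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

#' Simulate the projection-pair corpus to disk
#'
#' Renders the configured corpus and writes paired multi-page float TIFF
#' stacks (`poly.tif`, `mono.tif`), geometry sidecars, and a manifest
#' (`manifest.yaml`: counts, per-pair angles, seeds, content hashes).
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest as a list.
#' @export
cmd_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- make_dataset(config$n_mouse, config$pairs_per_mouse,
                        config$n_cylinder,
                        seed = stage_seed(config$master_seed, 1))
  .log_stage("simulate", length(specs), " projection pairs")
  ds <- render_dataset(specs, geometry = .cfg_geometry(config),
                       spectrum = sarrp_spectrum(kvp = config$kvp),
                       detector = detector_model(config$detector_mode),
                       mono_energy = config$mono_energy_keV)
  gp <- .new_projection_set(ds$poly, ds$angles, ds$geometry, "poly")
  gm <- .new_projection_set(ds$mono, ds$angles, ds$geometry, "mono")
  write_projections(gp, file.path(config$out_dir, "poly.tif"))
  write_projections(gm, file.path(config$out_dir, "mono.tif"))
  manifest <- list(n_pairs = length(specs),
                   n_mouse = config$n_mouse,
                   pairs_per_mouse = config$pairs_per_mouse,
                   n_cylinder = config$n_cylinder,
                   master_seed = config$master_seed,
                   corpus_seed = stage_seed(config$master_seed, 1),
                   angles = ds$angles,
                   poly_hash = .data_hash(ds$poly),
                   mono_hash = .data_hash(ds$mono))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  .log_stage("simulate", "manifest written (", manifest$n_pairs, " pairs)")
  invisible(manifest)
}

#' Train the network on a simulated corpus
#'
#' @param config A [run_config()].
#' @param dataset_dir Directory written by [cmd_simulate()]; defaults to
#'   the config's output directory.
#' @param verbose Per-epoch loss printing.
#' @return Invisibly, the trained `monoct_model` (also checkpointed to
#'   `checkpoint.rds` with a CSV loss log).
#' @export
cmd_train <- function(config, dataset_dir = config$out_dir,
                      verbose = FALSE) {
  poly <- read_projections(file.path(dataset_dir, "poly.tif"))
  mono <- read_projections(file.path(dataset_dir, "mono.tif"))
  n <- dim(poly$images)[3]
  sp <- split_dataset(n, config$train_fraction,
                      seed = stage_seed(config$master_seed, 2))
  cf <- .cfg_net(config)
  model <- build_network(cf, input_dim = dim(poly$images)[1:2])
  .log_stage("train", length(sp$train), " train / ", length(sp$test),
             " validation pairs, depth ", cf$depth)
  model <- train_network(model, poly$images, mono$images,
                         sp$train, sp$test, verbose = verbose)
  model$provenance$split <- sp
  write_checkpoint(model, file.path(config$out_dir, "checkpoint.rds"))
  .log_stage("train", sprintf("best val MAE %.4g at epoch %d",
                              model$provenance$best_val_mae,
                              model$provenance$best_epoch))
  invisible(model)
}

#' Predict virtual monoenergetic projections for a stack on disk
#'
#' @param checkpoint Path to a checkpoint from [cmd_train()] (or a
#'   `monoct_model`).
#' @param projections Path to a projection TIFF (kind `poly`).
#' @param out Output TIFF path.
#' @return Invisibly, the predicted `monoct_projections`.
#' @export
cmd_predict <- function(checkpoint, projections, out) {
  model <- if (inherits(checkpoint, "monoct_model")) checkpoint
           else read_checkpoint(checkpoint)
  pset <- read_projections(projections)
  pred <- predict_mono(model, pset)
  write_projections(pred, out)
  .log_stage("predict", dim(pred$images)[3], " projections -> ", out)
  invisible(pred)
}

#' Reconstruct a projection stack on disk
#'
#' @param projections Path to a projection TIFF (any kind) or a
#'   `monoct_projections`.
#' @param out Output NIfTI path.
#' @param grid Reconstruction grid.
#' @param filter Ramp filter variant.
#' @return Invisibly, the `monoct_volume`.
#' @export
cmd_reconstruct <- function(projections, out, grid = desk_grid(),
                            filter = "ram-lak") {
  pset <- if (inherits(projections, "monoct_projections")) projections
          else read_projections(projections)
  vol <- fdk_reconstruct(pset, grid, filter)
  write_volume(vol, out)
  .log_stage("reconstruct", paste(grid$dim, collapse = "x"), " -> ", out)
  invisible(vol)
}

#' Evaluate predicted against reference projections
#'
#' Writes a structured-text (YAML) report with the pooled air-excluded
#' percentage error, pooled MAE, and a per-projection breakdown.
#'
#' @param predicted,reference Projection TIFF paths or
#'   `monoct_projections`.
#' @param out Optional report path (YAML).
#' @param air_threshold Air exclusion threshold.
#' @return The report as a list.
#' @export
cmd_evaluate <- function(predicted, reference, out = NULL,
                         air_threshold = 0.01) {
  p <- if (inherits(predicted, "monoct_projections")) predicted
       else read_projections(predicted)
  r <- if (inherits(reference, "monoct_projections")) reference
       else read_projections(reference)
  pe <- percentage_error(p$images, r$images, air_threshold)
  per_proj <- vapply(seq_len(dim(p$images)[3]), function(i) {
    s <- tryCatch(percentage_error(p$images[, , i], r$images[, , i],
                                   air_threshold)$mean_pct,
                  error = function(e) NA_real_)
    s
  }, numeric(1))
  report <- list(mean_pct_error = pe$mean_pct, sd_pct_error = pe$sd_pct,
                 mae = mae(p$images, r$images),
                 n_air_excluded = pe$n_excluded,
                 per_projection_pct = per_proj)
  if (!is.null(out)) yaml::write_yaml(report, out)
  .log_stage("evaluate", sprintf("pct error %.3f%%, MAE %.4g",
                                 pe$mean_pct, report$mae))
  report
}

#' End-to-end desk-scale demonstration
#'
#' Runs simulate -> train -> predict -> reconstruct -> evaluate at desk
#' scale: trains on a small mixed corpus, then images a water-cylinder
#' uniformity phantom over a full orbit, reconstructs the raw
#' polyenergetic, predicted-mono and true-mono projections, and prints
#' cupping/uniformity metrics. Everything derives from `master_seed`.
#'
#' @param master_seed Master seed.
#' @param out_dir Output directory.
#' @param config Optional [run_config()] overriding the demo defaults.
#' @return List with the trained model, test metrics, and the UNAAD /
#'   cupping summary of the cylinder reconstructions.
#' @export
cmd_demo <- function(master_seed = 1L, out_dir = tempfile("monoct_demo"),
                     config = NULL) {
  if (is.null(config)) {
    config <- run_config(master_seed = master_seed, n_mouse = 2,
                         pairs_per_mouse = 20, n_cylinder = 80,
                         net = list(epochs = 60), out_dir = out_dir)
  }
  cmd_simulate(config)
  model <- cmd_train(config)
  sp <- model$provenance$split
  poly <- read_projections(file.path(config$out_dir, "poly.tif"))
  mono <- read_projections(file.path(config$out_dir, "mono.tif"))
  test_poly <- .new_projection_set(
    poly$images[, , sp$test, drop = FALSE], poly$angles[sp$test],
    poly$geometry, "poly")
  pred <- predict_mono(model, test_poly)
  metrics <- list(
    pct_error = percentage_error(pred$images,
                                 mono$images[, , sp$test, drop = FALSE],
                                 config$air_threshold)$mean_pct,
    mae = mae(pred$images, mono$images[, , sp$test, drop = FALSE]))

  # uniformity phantom: water cylinder, full orbit
  geom <- .cfg_geometry(config, angles = seq(0, 359, by = 2))
  cyl <- make_cylinder_phantom(16, 40, material_library()$water,
                               dim = c(192, 120, 120))
  praw <- project_poly(cyl, geom, sarrp_spectrum(kvp = config$kvp),
                       detector_model(config$detector_mode),
                       supersample = 2)
  ptrue <- project_mono(cyl, geom, config$mono_energy_keV, supersample = 2)
  pcorr <- predict_mono(model, praw)
  grid <- desk_grid(config$recon_n, config$recon_voxel_mm)
  vols <- lapply(list(raw = praw, corrected = pcorr, true_mono = ptrue),
                 fdk_reconstruct, grid = grid)
  roi <- cylinder_roi(grid, radius_mm = 5, half_length_mm = 10)
  summary <- list(
    unaad = vapply(vols, unaad, numeric(1), roi = roi),
    mu_water_35 = material_mu(material_library()$water, 35))
  .log_stage("demo", sprintf(
    "test pct error %.2f%%; UNAAD raw %.2f vs corrected %.2f",
    metrics$pct_error, summary$unaad[["raw"]], summary$unaad[["corrected"]]))
  list(model = model, metrics = metrics, summary = summary,
       volumes = vols, out_dir = config$out_dir)
}

#' Scaled-down end-to-end training benchmark
#'
#' The package's reproducible study-in-miniature: renders a mixed corpus
#' of analytic polyenergetic/monoenergetic projection pairs (mouse and
#' cylinder phantoms in equal parts, 64 x 64 pixels), splits 80/20 at
#' the pair level, trains the desk-scale network (depth 4, base 8,
#' up to 100 epochs), and evaluates the held-out test partition with the
#' pooled air-excluded percentage error and the pooled MAE.
#'
#' @param master_seed Master seed deriving the corpus, split and network
#'   seeds.
#' @param n_mouse,pairs_per_mouse,n_cylinder Corpus composition
#'   (default 4 x 25 + 100 = 200 pairs).
#' @param net Overrides for [desk_config()].
#' @param air_threshold Air-exclusion threshold for the percentage error.
#' @param verbose Progress and per-epoch losses.
#' @return List with `pct_error` (mean, %), `pct_sd`, `mae`, `n_test`,
#'   `n_train`, and the trained `model`.
#' @export
desk_benchmark <- function(master_seed = 1L, n_mouse = 4,
                           pairs_per_mouse = 25, n_cylinder = 100,
                           net = list(), air_threshold = 0.01,
                           verbose = FALSE) {
  specs <- make_dataset(n_mouse, pairs_per_mouse, n_cylinder,
                        seed = stage_seed(master_seed, 1))
  ds <- render_dataset(specs, verbose = verbose)
  sp <- split_dataset(specs, 0.8, seed = stage_seed(master_seed, 2))
  cf <- do.call(desk_config, c(net[setdiff(names(net), "seed")],
                               list(seed = stage_seed(master_seed, 3))))
  model <- build_network(cf, input_dim = dim(ds$poly)[1:2])
  model <- train_network(model, ds$poly, ds$mono, sp$train, sp$test,
                         verbose = verbose)
  test_poly <- projection_set(ds$poly[, , sp$test, drop = FALSE],
                              ds$angles[sp$test], ds$geometry, "poly")
  pred <- predict_mono(model, test_poly)
  ref <- ds$mono[, , sp$test, drop = FALSE]
  pe <- percentage_error(pred$images, ref, air_threshold)
  list(pct_error = pe$mean_pct, pct_sd = pe$sd_pct,
       mae = mae(pred$images, ref),
       n_test = length(sp$test), n_train = length(sp$train),
       model = model)
}

#' Cylindrical interior ROI mask on a reconstruction grid
#'
#' Axis along x through the isocenter; used for uniformity metrics.
#'
#' @param grid A [recon_grid()].
#' @param radius_mm ROI radius (y/z).
#' @param half_length_mm ROI half-length along x.
#' @param center Center (mm).
#' @return Logical array of `grid$dim`.
#' @export
cylinder_roi <- function(grid, radius_mm, half_length_mm,
                         center = c(0, 0, 0)) {
  cx <- .vox_centers(grid$dim[1], grid$voxel_size[1], grid$origin[1]) - center[1]
  cy <- .vox_centers(grid$dim[2], grid$voxel_size[2], grid$origin[2]) - center[2]
  cz <- .vox_centers(grid$dim[3], grid$voxel_size[3], grid$origin[3]) - center[3]
  X <- array(cx, grid$dim)
  Y <- array(rep(cy, each = grid$dim[1]), grid$dim)
  Z <- array(rep(cz, each = grid$dim[1] * grid$dim[2]), grid$dim)
  abs(X) <= half_length_mm & (Y^2 + Z^2) <= radius_mm^2
}
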