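# Dataset generation and thin command runners used by the `sr4dflow`
# command-line script; every runner is an ordinary exported function so the
# whole pipeline is scriptable from R as well.

#' Generate the paired-patch training set of one flow series
#'
#' For every requested frame: draw a random acquisition (per-component
#' VENC under the 10 % deliberate-aliasing policy, intensity, SNR),
#' simulate the x4-downsampled noisy LR acquisition, and sample
#' `n_base` fluid-containing LR/HR patch pairs plus one rotated duplicate
#' each (20 pairs per frame at the defaults; 1420 pairs for a 71-frame
#' series).
#'
#' @param flow A [synthesize_flow()] result.
#' @param frames Frame indices to process (default: all).
#' @param n_base Base patches per frame.
#' @param min_fluid Minimum LR fluid fraction per patch.
#' @param patch_lr LR patch side in voxels.
#' @param factor Downsampling factor.
#' @param alias_prob Probability of a deliberately aliasing VENC.
#' @param seed Optional seed; when given, the dataset is bit-reproducible.
#' @param keep_patches Keep all pairs in memory (set `FALSE` with `writer`
#'   for large runs).
#' @param writer Optional `function(frame, pairs)` sink called per frame.
#' @return List with `manifest` (one row per frame: acquisition drawn,
#'   aliased flags, patch count) and `pairs` (flat list, or `NULL` when
#'   `keep_patches = FALSE`).
#' @export
generate_patch_dataset <- function(flow, frames = seq_along(flow$times),
                                   n_base = 10, min_fluid = 0.20,
                                   patch_lr = 12, factor = 4,
                                   alias_prob = 0.10, seed = NULL,
                                   keep_patches = TRUE, writer = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(frames))
  pairs_all <- if (keep_patches) vector("list", length(frames)) else NULL
  for (i in seq_along(frames)) {
    fr <- frames[i]
    acq <- sample_acquisition(flow_max_speed(flow, fr), alias_prob)
    hr <- flow_frame(flow, fr)
    lr <- simulate_lr(hr, flow$mask, acq, factor, flow$domain)
    pairs <- sample_patches(lr, hr, flow$mask, n_base = n_base,
                            min_fluid = min_fluid, patch_lr = patch_lr)
    rows[[i]] <- data.frame(frame = fr, venc_x = acq$venc[1],
                            venc_y = acq$venc[2], venc_z = acq$venc[3],
                            snr_db = acq$snr_db,
                            intensity = acq$intensity,
                            aliased_x = lr$aliased[1],
                            aliased_y = lr$aliased[2],
                            aliased_z = lr$aliased[3],
                            n_patches = length(pairs))
    if (!is.null(writer)) writer(fr, pairs)
    if (keep_patches) pairs_all[[i]] <- pairs
  }
  list(manifest = do.call(rbind, rows),
       pairs = if (keep_patches) do.call(c, pairs_all) else NULL)
}

#' Generate a patch dataset on disk
#'
#' Synthesises the flow series for one catalogue geometry, generates its
#' paired patches and writes per-frame patch stores (`pairs_fNNN.rds`), a
#' `manifest.csv` and the flow's fluid mask / peak-frame velocity as NIfTI.
#'
#' @param out_dir Output directory (created if needed).
#' @param geometry Catalogue geometry id.
#' @param seed RNG seed for the whole run.
#' @param spacing HR grid spacing in mm.
#' @param n_frames Number of time frames.
#' @param ... Passed on to [generate_patch_dataset()].
#' @return The manifest data frame, invisibly.
#' @export
run_generate <- function(out_dir, geometry = 3, seed = 1, spacing = 0.25,
                         n_frames = 71, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- geometry_config(geometry, n_frames = n_frames)
  flow <- synthesize_flow(geom, default_flow_grid(geom, spacing = spacing))
  writer <- function(frame, pairs)
    saveRDS(pairs, file.path(out_dir, sprintf("pairs_f%03d.rds", frame)))
  ds <- generate_patch_dataset(flow, seed = seed, keep_patches = FALSE,
                               writer = writer, ...)
  write.csv(ds$manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  pk <- which.max(flow$envelope)
  write_velocity_nifti(flow_frame(flow, pk),
                       file.path(out_dir, "hr_peak_frame.nii.gz"),
                       spacing = flow$grid$spacing,
                       meta = list(geometry = geometry, frame = pk))
  invisible(ds$manifest)
}

read_patch_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "^pairs_f\\d+\\.rds$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no patch stores found in ", dir)
  do.call(c, lapply(files, readRDS))
}

#' Train a network on a generated dataset
#'
#' @param data_dir Directory written by [run_generate()], or a list of
#'   `patch_pair`s.
#' @param out_dir Output directory for the checkpoint and history.
#' @param spec A [network_spec()].
#' @param cfg A [train_config()].
#' @param val_fraction Fraction of pairs held out for validation.
#' @param verbose Print per-epoch progress.
#' @return The [train_network()] result, invisibly.
#' @export
run_train <- function(data_dir, out_dir, spec = network_spec("res"),
                      cfg = train_config(), val_fraction = 0.15,
                      verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- if (is.character(data_dir)) read_patch_dir(data_dir) else data_dir
  set.seed(cfg$seed)
  nval <- max(1, round(val_fraction * length(pairs)))
  vi <- sample(seq_along(pairs), nval)
  model <- build_network(spec, seed = cfg$seed)
  fit <- train_network(model, pairs[-vi], pairs[vi], cfg, verbose = verbose)
  save_checkpoint(fit$model, file.path(out_dir, "checkpoint.rds"))
  write.csv(fit$history, file.path(out_dir, "history.csv"),
            row.names = FALSE)
  invisible(fit)
}

#' Super-resolve a stored LR volume
#'
#' @param checkpoint Checkpoint path from [run_train()], or an
#'   `sr_network` / `sr_stub`.
#' @param lr An `lr_sample`, or a NIfTI path written by
#'   [write_velocity_nifti()] whose sidecar carries `venc` (the volume is
#'   then taken as decoded LR velocity, with a flat magnitude).
#' @param out_path Output NIfTI path for the SR velocity volume.
#' @param vti Optional `.vti` path for visual inspection.
#' @param ... Passed to [predict_volume()].
#' @return The SR velocity array, invisibly.
#' @export
run_predict <- function(checkpoint, lr, out_path, vti = NULL, ...) {
  model <- if (is.character(checkpoint)) load_checkpoint(checkpoint)
           else checkpoint
  if (is.character(lr)) {
    v <- read_velocity_nifti(lr)
    venc <- v$meta$venc
    if (is.null(venc)) stop("sidecar of ", lr, " does not record venc")
    d <- dim(v$velocity)[1:3]
    lr <- structure(list(velocity_lr = v$velocity,
                         magnitude_lr = array(MAG_SCALE / 2, c(d, 3)),
                         mask_lr = array(TRUE, d),
                         acquisition = acquisition(venc, 15, 120),
                         factor = model$spec$upsample_factor,
                         aliased = c(FALSE, FALSE, FALSE)),
                    class = "lr_sample")
  }
  sr <- predict_volume(model, lr, ...)
  spacing <- 1
  write_velocity_nifti(sr, out_path, spacing = spacing,
                       meta = list(venc = lr$acquisition$venc))
  if (!is.null(vti)) write_vti(sr, vti, spacing = spacing)
  invisible(sr)
}

#' Evaluate a prediction against ground truth and write reports
#'
#' @param pred,target Velocity arrays `[x, y, z, 3]`, or NIfTI paths.
#' @param mask Logical fluid mask (array or NIfTI path of 0/1 values).
#' @param out_prefix Path prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @param region_x Optional constricted-section voxel range.
#' @return The `eval_report`, invisibly.
#' @export
run_evaluate <- function(pred, target, mask, out_prefix,
                         region_x = NULL) {
  get_arr <- function(x) if (is.character(x))
    read_velocity_nifti(x)$velocity else x
  pred <- get_arr(pred); target <- get_arr(target)
  mask <- get_arr(mask)
  if (!is.logical(mask)) mask <- array(mask > 0.5, dim(mask)[1:3])
  rep <- evaluate_sr(pred, target, mask, region_x)
  write.csv(rep$agreement, paste0(out_prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(re = rep$re, rmse = as.list(rep$rmse),
                            ssim = as.list(rep$ssim)),
                       paste0(out_prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(rep)
}

#' Deterministic micro fixtures for examples and tests
#'
#' Small, fully in-memory assets: a coarse flow series on a 48x24x24 grid,
#' a spatially uniform known-wrap velocity field (peak 2.0 m/s with VENC
#' 1.5, so the aliased flag must raise), and the two-voxel loss example
#' whose fluid/non-fluid means can be checked by hand.
#'
#' @param seed RNG seed; the same seed regenerates identical fixtures.
#' @return Named list `flow`, `wrap` (list `velocity`, `mask`, `acq`),
#'   `loss_patch` (list `pred`, `target`, `mask`).
#' @export
make_fixtures <- function(seed = 1) {
  set.seed(seed)
  cat20 <- geometry_catalogue()
  geom <- geometry_config(cat20[cat20$id == 3, ], upstream_length = 10,
                          constriction_length = 6, n_frames = 8)
  flow <- synthesize_flow(geom, flow_grid(c(48, 24, 24), 0.5))
  d <- c(8, 8, 8)
  wrap_vel <- array(0, c(d, 3))
  wrap_vel[, , , 1] <- 2.0
  wrap <- list(velocity = wrap_vel, mask = array(TRUE, d),
               acq = acquisition(c(1.5, 0.3, 0.3), snr_db = 15,
                                 intensity = 120, seed = seed))
  pred <- array(0, c(2, 1, 1, 3)); target <- pred
  pred[1, 1, 1, 1] <- 0.1   # fluid voxel: error (0.1, 0, 0)
  pred[2, 1, 1, 2] <- 0.2   # non-fluid voxel: error (0, 0.2, 0)
  loss_patch <- list(pred = pred, target = target,
                     mask = array(c(TRUE, FALSE), c(2, 1, 1)))
  list(flow = flow, wrap = wrap, loss_patch = loss_patch)
}
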