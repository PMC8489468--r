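# End-to-end workspace pipeline: simulate -> average -> train -> denoise ->
# quantify -> evaluate. Every stage reads its inputs from the workspace
# directory written by the previous stage, so the CLI subcommands compose
# and `run` is exactly their composition. All randomness is derived from
# `global_seed` by fixed per-stage offsets.

seed_phantom <- function(gs, idx) gs + 1000L + idx
seed_protocol <- function(gs, idx) gs + 2000L + idx
seed_train <- function(gs) gs + 3000L
seed_model <- function(gs) gs + 4000L

#' Pipeline configuration
#'
#' Two profiles are provided. `"desk"` is the CPU-scale profile used by the
#' test-suite: images capped at 128 x 128, at most 5 epochs, a small network
#' (depth 3, 8 base channels), batch size 8. `"paper"` is the published
#' recipe: depth-4 U-Net with 16 base channels, batch size 36, 15 epochs,
#' Adam learning rate 0.001, 256 x 208 inputs.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param global_seed integer master seed; per-stage seeds are derived from
#'   it by fixed offsets.
#' @param n_train,n_val number of training / held-out validation phantoms.
#' @param grid_shape phantom image size (rows, cols).
#' @param protocol named list overriding [acquisition_protocol()] arguments.
#' @param model named list overriding [model_config()] arguments.
#' @param train named list overriding [train_config()] arguments.
#' @return a `dwi_pipeline_config` (nested named list).
#' @export
pipeline_config <- function(profile = c("desk", "paper"), global_seed = 1L,
                            n_train = NULL, n_val = NULL, grid_shape = NULL,
                            protocol = list(), model = list(),
                            train = list()) {
  profile <- match.arg(profile)
  base <- if (profile == "desk") {
    list(n_train = 30L, n_val = 20L, grid_shape = c(64L, 64L),
         protocol = list(b_values = c(50, 600, 900), n_directions = 3L,
                         n_acquisitions = 3L, noise_sigma = 300,
                         intensity_ceiling = 4095L),
         model = list(depth = 3L, base_channels = 8L, kernel_size = 3L,
                      max_weight_norm = 3.0),
         train = list(loss = "mae", alpha = 0.7, learning_rate = 0.001,
                      batch_size = 8L, epochs = 5L))
  } else {
    list(n_train = 14L, n_val = 3L, grid_shape = c(256L, 208L),
         protocol = list(b_values = c(50, 600, 900), n_directions = 3L,
                         n_acquisitions = 3L, noise_sigma = 300,
                         intensity_ceiling = 4095L),
         model = list(depth = 4L, base_channels = 16L, kernel_size = 3L,
                      max_weight_norm = 3.0),
         train = list(loss = "mae", alpha = 0.7, learning_rate = 0.001,
                      batch_size = 36L, epochs = 15L))
  }
  cfg <- list(profile = profile, global_seed = as.integer(global_seed),
              n_train = if (is.null(n_train)) base$n_train else as.integer(n_train),
              n_val = if (is.null(n_val)) base$n_val else as.integer(n_val),
              grid_shape = if (is.null(grid_shape)) base$grid_shape else
                as.integer(grid_shape),
              protocol = modifyList(base$protocol, protocol),
              model = modifyList(base$model, model),
              train = modifyList(base$train, train))
  if (profile == "desk") {
    if (any(cfg$grid_shape > 128L))
      stop("desk profile caps image size at 128 x 128")
    if (cfg$train$epochs > 5L)
      stop("desk profile caps training at 5 epochs")
  }
  stopifnot(cfg$n_train >= 1L, cfg$n_val >= 1L)
  class(cfg) <- "dwi_pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as JSON
#' @param cfg a `dwi_pipeline_config`.
#' @param path JSON file path.
#' @return `config_write` returns `path` invisibly; `config_read` the config.
#' @export
config_write <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(profile = x$profile, global_seed = x$global_seed,
                  n_train = x$n_train, n_val = x$n_val,
                  grid_shape = x$grid_shape,
                  protocol = as.list(x$protocol), model = as.list(x$model),
                  train = as.list(x$train))
}

pipeline_phantom_ids <- function(cfg) {
  c(sprintf("train_%03d", seq_len(cfg$n_train)),
    sprintf("val_%03d", seq_len(cfg$n_val)))
}

ws_config <- function(ws) config_read(file.path(ws, "config.json"))

b_file <- function(b) sprintf("b%04d.nii", round(b))

log_stage <- function(stage, seed = NULL) {
  message("[quickdwi] stage ", stage,
          if (!is.null(seed)) paste0(" (seed ", seed, ")") else "")
}

#' Pipeline stages
#'
#' Each stage reads from and writes to a workspace directory `ws`;
#' [run_pipeline()] is their composition. `stage_simulate` generates the
#' phantoms and the noisy acquisition stacks; `stage_average` forms the
#' trace-weighted, acquisition-averaged clinical-standard images;
#' `stage_train` fits the denoising network on the training phantoms;
#' `stage_denoise` applies it to the held-out single-acquisition images;
#' `stage_quantify` fits ADC maps (single-acquisition, clinical, denoised)
#' and tabulates ROI statistics (mean, CoV, RDM, MAVD); `stage_evaluate`
#' computes MSE/SSIM/PSNR against the clinical-standard reference and the
#' paired Wilcoxon / Benjamini-Hochberg comparisons.
#'
#' @param cfg a `dwi_pipeline_config`.
#' @param ws workspace directory.
#' @return the workspace path (stages), invisibly.
#' @export
stage_simulate <- function(cfg, ws) {
  dir.create(ws, recursive = TRUE, showWarnings = FALSE)
  config_write(cfg, file.path(ws, "config.json"))
  ids <- pipeline_phantom_ids(cfg)
  for (i in seq_along(ids)) {
    ps <- seed_phantom(cfg$global_seed, i)
    log_stage(paste0("simulate/", ids[i]), ps)
    spec <- random_phantom_spec(ps, cfg$grid_shape)
    gt <- generate_phantom(spec)
    write_ground_truth(gt, file.path(ws, "phantoms", ids[i]))
    pr <- do.call(acquisition_protocol,
                  c(cfg$protocol, list(seed = seed_protocol(cfg$global_seed, i))))
    write_dwi_stack(acquire(gt, pr), file.path(ws, "stacks", ids[i]))
  }
  invisible(ws)
}

#' @rdname stage_simulate
#' @export
stage_average <- function(ws) {
  cfg <- ws_config(ws)
  log_stage("average")
  for (id in pipeline_phantom_ids(cfg)) {
    stack <- read_dwi_stack(file.path(ws, "stacks", id))
    ci <- average_acquisitions(trace_weighted(stack))
    out <- file.path(ws, "clinical", id)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (ib in seq_along(stack$protocol$b_values))
      write_nifti(ci$data[ib, , ], file.path(out, b_file(stack$protocol$b_values[ib])))
    jsonlite::write_json(list(noa = ci$noa, b_values = stack$protocol$b_values),
                         file.path(out, "meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(ws)
}

# (noisy NOA_1, clinical target) training pairs, normalized; one acquisition
# per (b, direction)
pipeline_pairs <- function(ws, cfg, ids) {
  ceil <- cfg$protocol$intensity_ceiling
  pairs <- list()
  for (id in ids) {
    stack <- read_dwi_stack(file.path(ws, "stacks", id))
    for (ib in seq_along(stack$protocol$b_values)) {
      tgt <- normalize_intensity(
        read_nifti(file.path(ws, "clinical", id,
                             b_file(stack$protocol$b_values[ib]))), ceil)
      for (id_dir in seq_len(stack$protocol$n_directions)) {
        pairs[[length(pairs) + 1L]] <- list(
          x = normalize_intensity(stack$data[ib, id_dir, 1L, , ], ceil),
          y = tgt)
      }
    }
  }
  pairs
}

#' @rdname stage_simulate
#' @export
stage_train <- function(ws) {
  cfg <- ws_config(ws)
  ms <- seed_model(cfg$global_seed)
  ts <- seed_train(cfg$global_seed)
  log_stage("train", ts)
  ids <- sprintf("train_%03d", seq_len(cfg$n_train))
  pairs <- pipeline_pairs(ws, cfg, ids)
  mcfg <- do.call(model_config,
                  c(cfg$model, list(input_shape = cfg$grid_shape)))
  model <- build_model(mcfg, seed = ms)
  tcfg <- do.call(train_config, c(cfg$train, list(seed = ts)))
  model <- train_dnif(model, pairs, tcfg)
  dir.create(file.path(ws, "model"), showWarnings = FALSE)
  save_dnif(model, file.path(ws, "model", "model.ckpt"))
  write.csv(data.frame(epoch = seq_along(model$training_history),
                       loss = model$training_history),
            file.path(ws, "model", "history.csv"), row.names = FALSE)
  invisible(ws)
}

#' @rdname stage_simulate
#' @export
stage_denoise <- function(ws) {
  cfg <- ws_config(ws)
  log_stage("denoise")
  model <- load_dnif(file.path(ws, "model", "model.ckpt"))
  ceil <- cfg$protocol$intensity_ceiling
  for (id in sprintf("val_%03d", seq_len(cfg$n_val))) {
    stack <- read_dwi_stack(file.path(ws, "stacks", id))
    out <- file.path(ws, "denoised", id)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (ib in seq_along(stack$protocol$b_values)) {
      x <- normalize_intensity(stack$data[ib, 1L, 1L, , ], ceil)
      write_nifti(denormalize_intensity(denoise(model, x), ceil),
                  file.path(out, b_file(stack$protocol$b_values[ib])))
    }
  }
  invisible(ws)
}

read_phantom_roi <- function(ws, id) {
  fs <- list.files(file.path(ws, "phantoms", id), pattern = "^roi_.*\\.nii$",
                   full.names = TRUE)
  if (length(fs) == 0) stop("no ROI mask found for phantom ", id)
  read_nifti(fs[1]) > 0.5
}

read_b_images <- function(dir, b_values) {
  lapply(b_values, function(b) read_nifti(file.path(dir, b_file(b))))
}

#' @rdname stage_simulate
#' @export
stage_quantify <- function(ws) {
  cfg <- ws_config(ws)
  log_stage("quantify")
  bv <- cfg$protocol$b_values
  rows <- list()
  for (id in sprintf("val_%03d", seq_len(cfg$n_val))) {
    stack <- read_dwi_stack(file.path(ws, "stacks", id))
    noa1_imgs <- lapply(seq_along(bv), function(ib) stack$data[ib, 1L, 1L, , ])
    maps <- list(
      noa1 = fit_adc(noa1_imgs, bv, source = "noa1"),
      noa_n = fit_adc(read_b_images(file.path(ws, "clinical", id), bv), bv,
                      source = "noa_n"),
      dnif = fit_adc(read_b_images(file.path(ws, "denoised", id), bv), bv,
                     source = "dnif"))
    out <- file.path(ws, "adc", id)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    mask <- read_phantom_roi(ws, id)
    for (src in names(maps)) {
      write_nifti(maps[[src]]$data, file.path(out, paste0(src, ".nii")))
      st <- roi_stats(maps[[src]], mask)
      rows[[length(rows) + 1L]] <- data.frame(
        phantom = id, source = src, mean_adc = st$mean_adc,
        std_adc = st$std_adc, cov = st$cov, n_voxels = st$n_voxels,
        rdm_vs_noa_n = if (src == "noa_n") 0 else
          rdm(maps[[src]], maps$noa_n, mask),
        mavd_vs_noa_n = if (src == "noa_n") 0 else
          mavd(maps[[src]], maps$noa_n, mask))
    }
  }
  summ <- do.call(rbind, rows)
  write.csv(summ, file.path(ws, "adc", "summary.csv"), row.names = FALSE)
  invisible(ws)
}

#' @rdname stage_simulate
#' @export
stage_evaluate <- function(ws) {
  cfg <- ws_config(ws)
  log_stage("evaluate")
  bv <- cfg$protocol$b_values
  ceil <- cfg$protocol$intensity_ceiling
  rows <- list()
  for (id in sprintf("val_%03d", seq_len(cfg$n_val))) {
    stack <- read_dwi_stack(file.path(ws, "stacks", id))
    for (ib in seq_along(bv)) {
      ref <- normalize_intensity(
        read_nifti(file.path(ws, "clinical", id, b_file(bv[ib]))), ceil)
      noisy <- normalize_intensity(stack$data[ib, 1L, 1L, , ], ceil)
      den <- normalize_intensity(
        read_nifti(file.path(ws, "denoised", id, b_file(bv[ib]))), ceil)
      mn <- image_metrics(noisy, ref)
      md <- image_metrics(den, ref)
      rows[[length(rows) + 1L]] <- data.frame(
        phantom = id, b = bv[ib],
        mse_noisy = mn$mse, mse_dnif = md$mse,
        ssim_noisy = mn$ssim, ssim_dnif = md$ssim,
        psnr_noisy = mn$psnr, psnr_dnif = md$psnr)
    }
  }
  met <- do.call(rbind, rows)
  dir.create(file.path(ws, "metrics"), showWarnings = FALSE)
  write.csv(met, file.path(ws, "metrics", "metrics.csv"), row.names = FALSE)
  cmp <- wilcoxon_bh(list(
    mse_dnif_vs_noa1 = cbind(met$mse_dnif, met$mse_noisy),
    ssim_dnif_vs_noa1 = cbind(met$ssim_dnif, met$ssim_noisy),
    psnr_dnif_vs_noa1 = cbind(met$psnr_dnif, met$psnr_noisy)))
  jsonlite::write_json(cmp, file.path(ws, "metrics", "comparisons.json"),
                       digits = NA)
  invisible(ws)
}

pipeline_manifest <- function(ws) {
  fs <- sort(setdiff(list.files(ws, recursive = TRUE), "manifest.json"))
  sums <- unname(tools::md5sum(file.path(ws, fs)))
  manifest <- list(files = stats::setNames(as.list(sums), fs))
  jsonlite::write_json(manifest, file.path(ws, "manifest.json"),
                       auto_unbox = TRUE)
  manifest
}

#' Run the full pipeline
#'
#' Executes simulate, average, train, denoise, quantify, and evaluate in
#' order inside `output_dir`, then writes `manifest.json` listing every
#' produced file with its MD5 checksum. A stage failure aborts with the
#' stage name; already-produced outputs are kept next to a `FAILED` marker.
#' Identical configuration + seed reproduce identical simulation and
#' quantification artifacts.
#'
#' @param cfg a [pipeline_config()].
#' @param output_dir workspace directory to create.
#' @return list with `workspace`, `manifest`, `metrics` (per-image quality
#'   data frame), `adc_summary` (per-phantom ROI statistics), `comparisons`
#'   (Wilcoxon/BH report), and `history` (training loss per epoch).
#' @export
run_pipeline <- function(cfg, output_dir) {
  stopifnot(inherits(cfg, "dwi_pipeline_config"))
  stages <- list(
    simulate = function() stage_simulate(cfg, output_dir),
    average = function() stage_average(output_dir),
    train = function() stage_train(output_dir),
    denoise = function() stage_denoise(output_dir),
    quantify = function() stage_quantify(output_dir),
    evaluate = function() stage_evaluate(output_dir))
  for (nm in names(stages)) {
    tryCatch(stages[[nm]](), error = function(e) {
      writeLines(paste0("stage ", nm, ": ", conditionMessage(e)),
                 file.path(output_dir, "FAILED"))
      stop("pipeline failed at stage '", nm, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- pipeline_manifest(output_dir)
  list(workspace = output_dir, manifest = manifest,
       metrics = read.csv(file.path(output_dir, "metrics", "metrics.csv")),
       adc_summary = read.csv(file.path(output_dir, "adc", "summary.csv")),
       comparisons = jsonlite::read_json(
         file.path(output_dir, "metrics", "comparisons.json"),
         simplifyVector = TRUE),
       history = read.csv(file.path(output_dir, "model", "history.csv"))$loss)
}
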