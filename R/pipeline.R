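#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. Supply either the paths
#' of three acquired stacks (`inputs`) or a phantom specification
#' (`phantom`) — exactly one of the two.
#'
#' @param inputs Named list with NIfTI paths `sagittal`, `axial`, `coronal`,
#'   and optionally `ground_truth`.
#' @param phantom A [phantom_spec()] (the degradations come from
#'   [degradation_spec()] unless `degradation` is supplied).
#' @param degradation Optional named list of [stack_degradation()] recipes.
#' @param target_plane Plane whose geometry seeds the template grid.
#' @param registration A [registration_config()].
#' @param planes 3 to fuse all three stacks, 2 to fuse only the target and
#'   axial stacks (the generalized two-plane reconstruction).
#' @param arcnn `FALSE` to skip denoising, an [arcnn_config()] to train during
#'   the run, or a checkpoint path of a trained model.
#' @param arcnn_seed Seed for network initialization and shuffling.
#' @param metrics Compute the quality report when ground truth is available?
#' @param seed Master seed recorded in the manifest.
#' @param output_dir Run directory (created; default a fresh temporary
#'   directory).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, phantom = NULL, degradation = NULL,
                            target_plane = "sagittal",
                            registration = registration_config(),
                            planes = 3, arcnn = FALSE, arcnn_seed = 1L,
                            metrics = TRUE, seed = 42L, output_dir = NULL) {
  if (is.null(inputs) == is.null(phantom))
    abort("supply exactly one of `inputs` or `phantom`",
          "orthosr_config_error")
  if (!planes %in% c(2, 3))
    abort("planes must be 2 or 3", "orthosr_config_error")
  structure(list(inputs = inputs, phantom = phantom,
                 degradation = degradation, target_plane = target_plane,
                 registration = registration, planes = planes, arcnn = arcnn,
                 arcnn_seed = as.integer(arcnn_seed), metrics = metrics,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Recognized top-level keys mirror the arguments of [pipeline_config()];
#' `phantom` takes `dims`, `spacing`, `noise_sd`, `seed`.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  ph <- NULL
  if (!is.null(raw$phantom))
    ph <- do.call(phantom_spec, raw$phantom)
  arc <- FALSE
  if (!is.null(raw$arcnn)) {
    arc <- if (is.character(raw$arcnn)) raw$arcnn
           else if (isTRUE(raw$arcnn)) arcnn_config()
           else if (is.list(raw$arcnn)) do.call(arcnn_config, raw$arcnn)
           else FALSE
  }
  reg <- if (is.null(raw$registration)) registration_config()
         else do.call(registration_config, raw$registration)
  pipeline_config(
    inputs = raw$inputs, phantom = ph,
    target_plane = if (is.null(raw$target_plane)) "sagittal"
                   else raw$target_plane,
    registration = reg,
    planes = if (is.null(raw$planes)) 3 else raw$planes,
    arcnn = arc,
    arcnn_seed = if (is.null(raw$arcnn_seed)) 1L else raw$arcnn_seed,
    metrics = if (is.null(raw$metrics)) TRUE else raw$metrics,
    seed = if (is.null(raw$seed)) 42L else raw$seed,
    output_dir = raw$output_dir)
}

array_digest <- function(vol) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f))
  writeBin(as.vector(vol$data), f)
  unname(tools::md5sum(f))
}

#' Run the full super-resolution pipeline
#'
#' Executes, in order: histogram match the axial and coronal stacks to the
#' target (sagittal) stack; reslice the target isotropic (out-of-plane
#' spacing brought down to the in-plane spacing); register axial and coronal
#' to the isotropic target; reslice the registered stacks back to their
#' original resolutions (shrinking the nearest-voxel search space); fuse on
#' the template grid; optionally denoise with the artefact-reduction network
#' and histogram match the result to the normalized target; compute the
#' quality report when ground truth is available. Every intermediate volume
#' is saved in the run directory, and `manifest.json` records the config,
#' seed, per-stage wall times and MD5 digests of every stage output.
#'
#' @param config A [pipeline_config()] or the path of a YAML/JSON config file.
#' @return (Invisibly) a list with `run_dir`, the final `volume`, the
#'   intermediate `fused` result, `metrics` (or NULL), `transforms`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    abort("expected a pipeline_config", "orthosr_config_error")
  run_dir <- config$output_dir
  if (is.null(run_dir))
    run_dir <- file.path(tempdir(), paste0("orthosr-run-",
                                           format(Sys.time(), "%Y%m%d%H%M%S")))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)

  stages <- list()
  digests <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), "orthosr_stage_error")
    })
    stages[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }
  save_vol <- function(vol, name) {
    path <- file.path(run_dir, paste0(name, ".nii.gz"))
    write_volume(vol, path)
    digests[[name]] <<- array_digest(vol)
    vol
  }

  # ---- inputs ---------------------------------------------------------
  ground_truth <- NULL
  if (!is.null(config$phantom)) {
    bundle <- t_stage("phantom", {
      deg <- if (is.null(config$degradation))
        degradation_spec(config$phantom$spacing) else config$degradation
      make_study(config$phantom, deg)
    })
    study <- bundle$study
    ground_truth <- bundle$ground_truth
  } else {
    study <- t_stage("load", {
      vols <- lapply(config$inputs[c("sagittal", "axial", "coronal")],
                     read_volume)
      orthogonal_study(vols$sagittal, vols$axial, vols$coronal,
                       target_plane = config$target_plane)
    })
    if (!is.null(config$inputs$ground_truth))
      ground_truth <- read_volume(config$inputs$ground_truth)
  }
  target <- config$target_plane
  others <- setdiff(c("sagittal", "axial", "coronal"), target)
  for (p in c("sagittal", "axial", "coronal"))
    save_vol(study[[p]], paste0("input_", p))

  # ---- pre-processing -------------------------------------------------
  study <- t_stage("histogram_match", {
    for (p in others) study[[p]] <- match_histogram(study[[p]], study[[target]])
    study
  })
  target_iso <- t_stage("reslice_isotropic", {
    reslice(study[[target]], spacing = min(study[[target]]$spacing))
  })
  save_vol(target_iso, "target_isotropic")

  transforms <- list()
  resampled <- list()
  study <- t_stage("register", {
    for (p in others) {
      reg <- register_volumes(study[[p]], target_iso, config$registration)
      transforms[[p]] <- reg$transform
      resampled[[p]] <- reg$resampled
      write_transform(reg$transform,
                      file.path(run_dir, paste0("transform_", p, ".txt")))
    }
    study
  })
  study <- t_stage("align_native", {
    # registered stacks at their original resolutions: rigid results move the
    # stack's lattice exactly (no resampling loss); affine results are
    # resampled once, at a native-resolution grid on the target frame's axes
    for (p in others) {
      tf <- transforms[[p]]
      if (tf$phase == "rigid") {
        study[[p]] <- align_volume(study[[p]], tf)
      } else {
        sp_world <- abs(study[[p]]$orientation %*%
                          diag(study[[p]]$spacing)) %*% c(1, 1, 1)
        sp_tgt <- abs(t(target_iso$orientation) %*% sp_world)
        study[[p]] <- reslice(resampled[[p]], spacing = as.vector(sp_tgt))
      }
      save_vol(study[[p]], paste0("registered_", p))
    }
    study
  })

  # ---- super-resolution -----------------------------------------------
  grid <- template_grid(target_iso)
  fused <- t_stage("fuse", {
    planes <- if (config$planes == 3) {
      setNames(list(study[[target]], study[[others[1]]], study[[others[2]]]),
               c(target, others))
    } else {
      setNames(list(study[[target]], study[[others[1]]]),
               c(target, others[1]))
    }
    sr_reconstruct(planes, grid)
  })
  save_vol(fused$volume, "sr_fused")

  # ---- post-processing ------------------------------------------------
  final <- fused$volume
  history <- NULL
  if (!isFALSE(config$arcnn)) {
    final <- t_stage("arcnn", {
      fused_norm <- minmax_normalize(fused$volume)
      if (is.character(config$arcnn)) {
        model <- arcnn_load(config$arcnn)
      } else {
        cfg <- config$arcnn
        # training pairs: SR slices at the native slice positions of the
        # original target stack vs the native slices themselves
        orig <- read_volume(file.path(run_dir,
                                      paste0("input_", target, ".nii.gz")))
        k_iso <- match_native_slices(orig, target_iso)
        noisy <- slice_subvolume(fused_norm, k_iso)
        clean <- orig
        pairs <- make_training_pairs(noisy, clean, size = cfg$input_size)
        model <- arcnn_build(cfg, seed = config$arcnn_seed)
        tr <- arcnn_train(model, pairs, seed = config$arcnn_seed)
        model <- tr$model
        history <- tr$history
        utils::write.csv(data.frame(epoch = seq_along(history),
                                    loss = history),
                         file.path(run_dir, "arcnn_loss.csv"),
                         row.names = FALSE)
        arcnn_save(model, file.path(run_dir, "arcnn_model.rds"))
      }
      den <- arcnn_denoise(model, fused_norm)
      ref <- minmax_normalize(study[[target]])
      final_histogram_match(den, ref)
    })
    save_vol(final, "sr_denoised")
  }

  # ---- evaluation ------------------------------------------------------
  report <- NULL
  if (config$metrics && !is.null(ground_truth)) {
    report <- t_stage("metrics", {
      gt <- ground_truth
      if (!same_geometry(gt, final)) gt <- reslice(gt, grid = final)
      metrics_report(minmax_normalize(gt), minmax_normalize(final))
    })
    write_metrics(report, file.path(run_dir, "metrics.json"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("orthosr")),
    r_version = R.version.string,
    seed = config$seed,
    target_plane = target,
    planes = config$planes,
    arcnn = !isFALSE(config$arcnn),
    config = list(
      inputs = config$inputs,
      phantom = if (!is.null(config$phantom)) unclass(config$phantom),
      degradation = if (!is.null(config$phantom)) {
        lapply(if (is.null(config$degradation))
          degradation_spec(config$phantom$spacing) else config$degradation,
          unclass)
      },
      registration = unclass(config$registration),
      arcnn_config = if (!isFALSE(config$arcnn) &&
                         !is.character(config$arcnn))
        unclass(config$arcnn)[c("learning_rate", "beta1", "beta2", "epsilon",
                                "batch_size", "epochs", "input_size")],
      arcnn_checkpoint = if (is.character(config$arcnn)) config$arcnn,
      arcnn_seed = config$arcnn_seed),
    stage_seconds = stages,
    fusion_stage_seconds = as.list(fused$timings),
    digests = digests,
    transforms = lapply(transforms, transform_matrix))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(run_dir = run_dir, volume = final, fused = fused,
                 metrics = report, transforms = transforms,
                 history = history, manifest = manifest))
}

# For each native slice of `orig` (along its 3rd axis), the index of the
# isotropic-volume slice whose world position is nearest.
match_native_slices <- function(orig, iso) {
  n_orig <- dim(orig$data)[3]
  n_iso <- dim(iso$data)[3]
  # positions along the shared slice normal
  normal <- orig$orientation[, 3]
  pos_orig <- vapply(seq_len(n_orig) - 1, function(k)
    sum(normal * (orig$origin + orig$orientation %*%
                    (orig$spacing * c(0, 0, k)))), 0)
  pos_iso <- vapply(seq_len(n_iso) - 1, function(k)
    sum(normal * (iso$origin + iso$orientation %*%
                    (iso$spacing * c(0, 0, k)))), 0)
  vapply(pos_orig, function(p) which.min(abs(pos_iso - p)), 0L)
}

slice_subvolume <- function(vol, k_idx) {
  out <- vol
  out$data <- vol$data[, , k_idx, drop = FALSE]
  out$origin <- as.vector(vol$origin + vol$orientation %*%
                            (vol$spacing * c(0, 0, k_idx[1] - 1)))
  # spacing along the slice axis becomes the (assumed uniform) native gap
  gap <- if (length(k_idx) > 1) diff(k_idx)[1] * vol$spacing[3] else
    vol$spacing[3]
  out$spacing <- c(vol$spacing[1:2], gap)
  out
}
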