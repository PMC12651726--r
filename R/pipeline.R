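#' Desk-scale pipeline configuration
#'
#' Defaults give a small, fully seeded end-to-end run (phantom cohort to
#' evaluated segmentations) suitable for a single CPU.
#'
#' @param global_seed integer; every stochastic stage receives a seed
#'   derived deterministically from it.
#' @param output_root output directory.
#' @param n_cases phantom cases; the first `n_train` are used for training,
#'   the rest for testing.
#' @param n_train training cases.
#' @param grid_shape phantom grid (axes divisible by 2).
#' @param tumor_radius_range GTVp ellipsoid radius range (voxels).
#' @param n_points,fit_iterations Gaussian-fit settings.
#' @param T,epochs,base_channels diffusion settings.
#' @param lambda prompt strength.
#' @param sample_seeds sampling seeds per test case.
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(global_seed = 1,
                            output_root = tempfile("gsdiff_run"),
                            n_cases = 5, n_train = 3,
                            grid_shape = c(32, 32, 8),
                            tumor_radius_range = c(3, 5),
                            n_points = 64, fit_iterations = 80,
                            T = 25, epochs = 8, base_channels = 4,
                            lambda = 0.5, sample_seeds = 1:2,
                            log_level = c("info", "quiet")) {
  if (n_train >= n_cases) stop("need at least one test case")
  structure(list(global_seed = as.integer(global_seed),
                 output_root = output_root, n_cases = n_cases,
                 n_train = n_train, grid_shape = as.integer(grid_shape),
                 tumor_radius_range = tumor_radius_range,
                 n_points = n_points, fit_iterations = fit_iterations,
                 T = as.integer(T), epochs = epochs,
                 base_channels = base_channels, lambda = lambda,
                 sample_seeds = sample_seeds,
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

pipeline_stages <- c("phantom", "preprocess", "priors", "fit_gaussians",
                     "train", "segment", "evaluate")

stage_deps <- list(phantom = character(0), preprocess = "phantom",
                   priors = "preprocess", fit_gaussians = "priors",
                   train = "preprocess", segment = c("train", "fit_gaussians"),
                   evaluate = "segment")

#' Run the full segmentation pipeline
#'
#' Executes, in dependency order: phantom generation, preprocessing
#' (scaling-factor fit), prior-target construction, per-modality Gaussian
#' field fitting, diffusion pretraining, prompted sampling on the test
#' cases, and evaluation. Writes every artifact below
#' `config$output_root` and a manifest (per-stage seed, wall time, output
#' files with MD5 hashes) enabling exact re-runs.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @param stages subset of stages to run; dependencies must be included.
#' @return the manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = pipeline_stages) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  for (st in stages) {
    miss <- setdiff(stage_deps[[st]], stages)
    if (length(miss))
      stop("stage '", st, "' requires missing stage '", miss[1], "'")
  }
  root <- config$output_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  logi <- function(...) if (config$log_level == "info")
    message(format(Sys.time(), "%H:%M:%S"), " [gsdiff] ", ...)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$global_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(pipeline_stages))
  names(seeds) <- pipeline_stages

  env <- new.env(parent = emptyenv())
  manifest <- list(config = unclass(config), stages = list())
  rel <- function(p) sub("^/", "", sub(root, "", p, fixed = TRUE))

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    logi("stage ", name, " (seed ", seeds[[name]], ")")
    t0 <- proc.time()[3]
    outputs <- fun(seeds[[name]])
    manifest$stages[[name]] <<- list(
      name = name, seed = seeds[[name]],
      elapsed_s = round(proc.time()[3] - t0, 3),
      outputs = vapply(outputs, rel, character(1)),
      md5 = unname(tools::md5sum(outputs)))
    invisible(NULL)
  }

  run_stage("phantom", function(seed) {
    cfg <- phantom_config(grid_shape = config$grid_shape,
                          tumor_radius_range = config$tumor_radius_range,
                          seed = seed)
    env$cases <- generate_cohort(cfg, config$n_cases, base_seed = seed)
    unlist(lapply(seq_along(env$cases), function(i) {
      dir <- file.path(root, "cases", sprintf("case_%02d", i))
      write_case(env$cases[[i]], dir)
      list.files(dir, full.names = TRUE)
    }))
  })

  run_stage("preprocess", function(seed) {
    vols <- unlist(lapply(env$cases, function(cs) list(cs$ct, cs$t1ce, cs$t2)),
                   recursive = FALSE)
    env$scaling <- fit_scaling(vols)
    write_scaling(env$scaling, file.path(root, "scaling.json"))
  })

  run_stage("priors", function(seed) {
    env$targets <- lapply(env$cases, prior_targets)
    thr <- lapply(env$targets, function(tg) as.list(tg$thresholds_used))
    p <- file.path(root, "prior_thresholds.json")
    jsonlite::write_json(thr, p, auto_unbox = TRUE, digits = NA)
    p
  })

  run_stage("fit_gaussians", function(seed) {
    test_idx <- (config$n_train + 1):config$n_cases
    env$fits <- lapply(test_idx, function(i)
      extract_all(env$cases[[i]], env$targets[[i]],
                  n_points = config$n_points,
                  iterations = config$fit_iterations, seed = seed + i))
    names(env$fits) <- as.character(test_idx)
    unlist(lapply(test_idx, function(i) {
      dir <- file.path(root, "fields", sprintf("case_%02d", i))
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (m in names(env$fits[[as.character(i)]]))
        write_field(env$fits[[as.character(i)]][[m]]$field, file.path(dir, m))
      list.files(dir, full.names = TRUE)
    }))
  })

  run_stage("train", function(seed) {
    env$schedule <- make_schedule(config$T)
    spec <- denoiser_spec(config$base_channels, in_shape = config$grid_shape)
    env$model <- ddpm_train(env$cases[seq_len(config$n_train)], spec,
                            env$schedule, epochs = config$epochs, seed = seed)
    write_ddpm(env$model, file.path(root, "model"))
    paste0(file.path(root, "model"), c(".rds", ".json"))
  })

  run_stage("segment", function(seed) {
    test_idx <- (config$n_train + 1):config$n_cases
    env$preds <- lapply(test_idx, function(i) {
      ps <- prompt_set(env$fits[[as.character(i)]], lambda = config$lambda)
      sms <- lapply(config$sample_seeds, function(s)
        sample_conditional(env$model, env$cases[[i]]$ct, ps,
                           seed = seed + s, quiet = TRUE))
      sms[[1]]   # first-seed sample is the reported prediction
    })
    unlist(lapply(seq_along(test_idx), function(j) {
      i <- test_idx[j]
      lab <- env$preds[[j]]$gtvp$data + 2L * env$preds[[j]]$gtvnd$data
      p <- file.path(root, sprintf("pred_case_%02d.nii.gz", i))
      img <- RNifti::asNifti(lab + 0)
      RNifti::pixdim(img) <- env$cases[[i]]$spacing
      RNifti::writeNifti(img, p, datatype = "uint8")
      p
    }))
  })

  run_stage("evaluate", function(seed) {
    test_idx <- (config$n_train + 1):config$n_cases
    tab <- evaluate_cases(env$preds, env$cases[test_idx])
    p <- file.path(root, "metrics.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    p
  })

  mpath <- file.path(root, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  logi("manifest written to ", mpath)
  invisible(manifest)
}
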