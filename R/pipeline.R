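#' Assemble a validated run configuration
#'
#' One root seed drives named sub-streams (phantom, degrade, sample,
#' train), so each stage is individually reproducible. Unknown keys in any
#' section are errors, not warnings: silent typos corrupt training runs.
#'
#' @param run list with `seed` (integer), `n_images`, `n_test_images`, and
#'   optional `out_dir`.
#' @param phantom,degradation,normalization,sampling,network,scop,training
#'   named lists of overrides for the corresponding constructors
#'   ([phantom_config()], [degradation_params()], ...).
#' @param richardson_lucy list with `psf_sigma` and `n_iter` for target
#'   enhancement.
#' @return An object of class `run_config`.
#' @export
run_config <- function(run = list(), phantom = list(), degradation = list(),
                       normalization = list(), sampling = list(),
                       network = list(), scop = list(), training = list(),
                       richardson_lucy = list()) {
  build <- function(fun, args, section) {
    known <- names(formals(fun))
    bad <- setdiff(names(args), known)
    if (length(bad))
      stop("unknown key(s) in section '", section, "': ",
           paste(bad, collapse = ", "))
    do.call(fun, args)
  }
  run_known <- c("seed", "n_images", "n_test_images", "out_dir")
  bad <- setdiff(names(run), run_known)
  if (length(bad))
    stop("unknown key(s) in section 'run': ", paste(bad, collapse = ", "))
  run_def <- list(seed = 1L, n_images = 6L, n_test_images = 2L,
                  out_dir = NULL)
  run <- utils::modifyList(run_def, run)
  rl_known <- c("psf_sigma", "n_iter")
  bad <- setdiff(names(richardson_lucy), rl_known)
  if (length(bad))
    stop("unknown key(s) in section 'richardson_lucy': ",
         paste(bad, collapse = ", "))
  rl <- utils::modifyList(list(psf_sigma = 1.5, n_iter = 10),
                          richardson_lucy)
  cfg <- list(
    run = run,
    phantom = build(phantom_config, phantom, "phantom"),
    degradation = build(degradation_params, degradation, "degradation"),
    normalization = build(normalization_params, normalization,
                          "normalization"),
    sampling = build(sampling_config, sampling, "sampling"),
    network = build(network_config, network, "network"),
    scop = build(scop_params, scop, "scop"),
    training = build(training_config, training, "training"),
    richardson_lucy = rl)
  cfg$phantom$seed <- derive_seed(run$seed, "phantom")
  cfg$degradation$seed <- derive_seed(run$seed, "degrade")
  cfg$sampling$seed <- derive_seed(run$seed, "sample")
  cfg$training$seed <- derive_seed(run$seed, "train")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level sections match the arguments of
#'   [run_config()]; unknown sections or keys raise an error.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' Run the restoration pipeline end to end
#'
#' Executes a contiguous subset of the stages
#' `phantom -> degrade -> sample -> train -> predict -> evaluate` on
#' synthetic phantom data: phantom generation, degradation of the held-out
#' test images, training-set construction, network training, restoration
#' of the degraded test images, and masked evaluation. A machine-readable
#' manifest (configuration, seeds, stage outputs, metric summary, file
#' checksums) is written to `out_dir/manifest.json`.
#'
#' @param config a [run_config()].
#' @param stages character vector, contiguous subset of the stage list.
#' @param out_dir output directory (defaults to `config$run$out_dir`).
#' @return Invisibly, a list with the stage artifacts (`samples`,
#'   `patches`, `model`, `record`, `predictions`, `report`, `manifest`).
#' @export
run_pipeline <- function(config,
                         stages = c("phantom", "degrade", "sample", "train",
                                    "predict", "evaluate"),
                         out_dir = config$run$out_dir) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("phantom", "degrade", "sample", "train", "predict",
                  "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  pos <- sort(match(stages, all_stages))
  if (any(diff(pos) != 1))
    stop("stages must form a contiguous subset of: ",
         paste(all_stages, collapse = " -> "))
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- list()
  manifest <- list(config = unclass_config(config),
                   stages = all_stages[pos], outputs = list())

  for (stage in all_stages[pos]) {
    st <- switch(stage,
      phantom = stage_phantom(config, st, out_dir, manifest),
      degrade = stage_degrade(config, st),
      sample = stage_sample(config, st),
      train = stage_train(config, st),
      predict = stage_predict(config, st, out_dir),
      evaluate = stage_evaluate(config, st, out_dir))
    manifest$outputs[[stage]] <- st$manifest_entry
  }
  files <- list.files(out_dir, pattern = "\\.tif$", recursive = TRUE,
                      full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  st$manifest <- manifest
  invisible(st)
}

unclass_config <- function(config) {
  lapply(unclass(config), function(s) if (is.list(s)) unclass(s) else s)
}

stage_phantom <- function(config, st, out_dir, manifest) {
  n_all <- config$run$n_images + config$run$n_test_images
  samples <- generate_dataset(config$phantom, n_all)
  st$samples_train <- samples[seq_len(config$run$n_images)]
  st$samples_test <- samples[config$run$n_images + seq_len(
    config$run$n_test_images)]
  write_phantom_dataset(st$samples_test, file.path(out_dir, "phantom_test"))
  st$manifest_entry <- list(n_train_images = config$run$n_images,
                            n_test_images = config$run$n_test_images,
                            phantom_seed = config$phantom$seed)
  st
}

stage_degrade <- function(config, st) {
  if (is.null(st$samples_test))
    stop("degrade stage needs phantom samples; run the phantom stage first")
  st$test_inputs <- lapply(seq_along(st$samples_test), function(i) {
    p <- config$degradation
    if (!is.null(p$seed)) p$seed <- p$seed + i
    degrade(st$samples_test[[i]]$hr_image, p)
  })
  st$manifest_entry <- list(sigma_blur = config$degradation$sigma_blur,
                            sigma_noise = config$degradation$sigma_noise)
  st
}

stage_sample <- function(config, st) {
  if (is.null(st$samples_train))
    stop("sample stage needs phantom samples; run the phantom stage first")
  st$patches <- build_training_set(
    lapply(st$samples_train, `[[`, "hr_image"),
    params = config$degradation, norm = config$normalization,
    config = config$sampling,
    rl_psf_sigma = config$richardson_lucy$psf_sigma,
    rl_n_iter = config$richardson_lucy$n_iter,
    gamma_inside = config$scop$gamma_inside,
    gamma_outside = config$scop$gamma_outside,
    validation_fraction = config$training$validation_fraction)
  st$manifest_entry <- list(n_train_patches = length(st$patches$train),
                            n_val_patches = length(st$patches$validation))
  st
}

stage_train <- function(config, st) {
  if (is.null(st$patches))
    stop("train stage needs patches; run the sample stage first")
  model <- build_network(config$network,
                         seed = derive_seed(config$run$seed, "train"))
  fit <- train_restorer(model, st$patches$train, st$patches$validation,
                        tconf = config$training, sparams = config$scop)
  st$model <- fit$model
  st$record <- fit$record
  st$manifest_entry <- list(epochs_run = nrow(fit$record),
                            best_epoch = fit$best_epoch,
                            best_val_loss = min(fit$record$val_loss))
  st
}

stage_predict <- function(config, st, out_dir) {
  if (is.null(st$model))
    stop("predict stage needs a trained model; run the train stage first")
  if (is.null(st$test_inputs))
    stop("predict stage needs degraded test inputs; run the degrade stage")
  st$predictions <- lapply(st$test_inputs, function(x)
    predict_image(st$model, x, config$normalization))
  dir.create(file.path(out_dir, "predictions"), showWarnings = FALSE)
  for (i in seq_along(st$predictions))
    write_image(st$predictions[[i]],
                file.path(out_dir, "predictions",
                          sprintf("restored_%03d.tif", i)))
  st$manifest_entry <- list(n_predictions = length(st$predictions))
  st
}

stage_evaluate <- function(config, st, out_dir) {
  if (is.null(st$predictions))
    stop("evaluate stage needs predictions; run the predict stage first")
  pairs <- lapply(seq_along(st$predictions), function(i)
    list(pred = st$predictions[[i]],
         target = percentile_normalize(st$samples_test[[i]]$hr_image,
                                       config$normalization)))
  masks <- lapply(st$samples_test, function(s)
    list(mito = s$mito_mask, cristae = s$cristae_mask))
  st$report <- evaluate_dataset(pairs, masks,
                                csv = file.path(out_dir, "metrics.csv"))
  summ <- st$report$summary
  st$manifest_entry <- lapply(seq_len(nrow(summ)), function(i)
    list(scope = summ$scope[i], metric = summ$metric[i],
         mean = summ$mean[i], sd = summ$sd[i]))
  st
}
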