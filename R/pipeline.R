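# Configuration handling and the end-to-end pipeline runner:
# generator -> WAE -> calibrated predictor -> counterfactuals -> metrics.
# Every stochastic stage receives a named sub-seed derived from the global
# seed; stage outputs are cached on disk keyed by the relevant configuration
# subsection and upstream checksums, and a manifest records enough to
# reproduce any stage in isolation.

default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "tracecf_run",
    verbosity = 1L,
    data = list(n = 500L, class_balance = 0.5, nuisance_policy = "none",
                image_size = 64L, age_severity_rho = 0, n_holdout = 50L),
    wae = list(latent_dim = 100L, epochs = 30L, batch_size = 64L,
               weight_switch_epoch = 10L),
    lbc = list(alpha = 0.9, tau = 0.05, epochs = 40L,
               f_hidden = c(128L, 64L), g_hidden = c(128L, 64L)),
    counterfactual = list(eta1 = 0.5, eta2 = 0.5, eta3 = 0.2, tau = 0.05,
                          steps = 300L, lr = 0.05, n_queries = 20L,
                          target = "abnormal"),
    metrics = list(k_proximity = 5L, k_realism = 3L,
                   change_epsilon = 1 / 255)
  )
}

validate_against <- function(cfg, template, path = "") {
  for (key in names(cfg)) {
    if (!key %in% names(template)) {
      stop("unknown config key: ", paste0(path, key))
    }
    if (is.list(template[[key]])) {
      if (!is.list(cfg[[key]])) stop("config key ", paste0(path, key), " must be a section")
      validate_against(cfg[[key]], template[[key]], paste0(path, key, "."))
    }
  }
  for (key in names(template)) {
    if (!key %in% names(cfg)) {
      stop("missing required config key: ", paste0(path, key))
    }
  }
  invisible(TRUE)
}

#' Load and validate a pipeline configuration
#'
#' YAML configuration with strict schema validation: unknown keys and missing
#' required keys are rejected with the offending key named. See
#' [run_pipeline()] for the sections.
#'
#' @param path YAML file path.
#' @return validated configuration list (class `run_config`).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_against(cfg, default_run_config())
  structure(cfg, class = "run_config")
}

#' Save a pipeline configuration
#'
#' @param config configuration list.
#' @param path YAML output path.
#' @export
save_config <- function(config, path) {
  validate_against(unclass(config), default_run_config())
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

obj_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

stage_cached <- function(dir, name, key, fn, verbose = TRUE) {
  path <- file.path(dir, paste0("stage_", name, ".rds"))
  if (file.exists(path)) {
    cached <- readRDS(path)
    if (identical(cached$key, key)) {
      if (verbose) message("[", name, "] cached, skipping")
      return(list(value = cached$value, checksum = unname(tools::md5sum(path)),
                  cached = TRUE))
    }
  }
  if (verbose) message("[", name, "] running")
  value <- fn()
  saveRDS(list(key = key, value = value), path, version = 2)
  list(value = value, checksum = unname(tools::md5sum(path)), cached = FALSE)
}

#' Run the end-to-end counterfactual pipeline
#'
#' Executes, in dependency order and with per-stage caching: synthetic data
#' generation, WAE training, calibrated-classifier training, TraCE
#' counterfactual generation for held-out normal queries, and metric
#' evaluation. Each stage draws its RNG stream from a named sub-seed of the
#' global seed; a manifest (config, seeds, stage checksums, versions) is
#' written to the output directory. A stage whose configuration and upstream
#' checksums are unchanged is loaded from cache.
#'
#' @param config configuration list as produced by [load_config()] or
#'   modified from `run_pipeline_defaults()`.
#' @param output_dir overrides `config$output_dir` when non-NULL.
#' @return list with `dir`, `manifest`, and the stage outputs (`dataset`,
#'   `wae`, `lbc`, `counterfactuals`, `report`).
#' @export
run_pipeline <- function(config = run_pipeline_defaults(), output_dir = NULL) {
  validate_against(unclass(config), default_run_config())
  dir <- output_dir %||% config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  verbose <- config$verbosity > 0
  seed <- config$seed
  checksums <- list()

  st_data <- stage_cached(dir, "data", obj_digest(list(config$data, seed)), function() {
    ds <- generate_dataset(config$data$n + config$data$n_holdout,
                           class_balance = config$data$class_balance,
                           nuisance_policy = config$data$nuisance_policy,
                           seed = seed_stream(seed, "data"),
                           image_size = config$data$image_size,
                           age_severity_rho = config$data$age_severity_rho)
    n_tr <- config$data$n
    list(train = list(images = ds$images[, , seq_len(n_tr), drop = FALSE],
                      labels = ds$labels[seq_len(n_tr)],
                      attributes = ds$attributes[seq_len(n_tr), ]),
         holdout = list(images = ds$images[, , -seq_len(n_tr), drop = FALSE],
                        labels = ds$labels[-seq_len(n_tr)],
                        attributes = ds$attributes[-seq_len(n_tr), ]))
  }, verbose)
  checksums$data <- st_data$checksum
  data <- st_data$value

  st_wae <- stage_cached(dir, "wae", obj_digest(list(config$wae, checksums$data, seed)), function() {
    cfg <- wae_config(latent_dim = config$wae$latent_dim,
                      image_size = config$data$image_size,
                      epochs = config$wae$epochs,
                      batch_size = config$wae$batch_size,
                      weight_switch_epoch = config$wae$weight_switch_epoch)
    train_wae(data$train$images, cfg, seed = seed_stream(seed, "wae"),
              verbose = verbose)
  }, verbose)
  checksums$wae <- st_wae$checksum
  wae <- st_wae$value

  st_lbc <- stage_cached(dir, "lbc", obj_digest(list(config$lbc, checksums$wae, seed)), function() {
    latents <- encode(wae, data$train$images)
    model <- train_lbc(latents, data$train$labels, "classification",
                       lbc_config(alpha = config$lbc$alpha, tau = config$lbc$tau,
                                  epochs = config$lbc$epochs,
                                  f_hidden = config$lbc$f_hidden,
                                  g_hidden = config$lbc$g_hidden),
                       seed = seed_stream(seed, "lbc"))
    list(model = model, latents = latents)
  }, verbose)
  checksums$lbc <- st_lbc$checksum
  lbc <- st_lbc$value

  st_cf <- stage_cached(dir, "counterfactual",
                        obj_digest(list(config$counterfactual, checksums$lbc, seed)), function() {
    cfg <- cf_config(eta1 = config$counterfactual$eta1,
                     eta2 = config$counterfactual$eta2,
                     eta3 = config$counterfactual$eta3,
                     tau = config$counterfactual$tau,
                     steps = config$counterfactual$steps,
                     lr = config$counterfactual$lr,
                     seed = seed_stream(seed, "cf"))
    target <- config$counterfactual$target
    source_class <- setdiff(lbc$model$class_levels, target)[1]
    q_ix <- which(data$holdout$labels == source_class)
    q_ix <- utils::head(q_ix, config$counterfactual$n_queries)
    if (length(q_ix) < 1) stop("no holdout queries from the source class")
    queries <- data$holdout$images[, , q_ix, drop = FALSE]
    Z <- encode(wae, queries)
    res <- generate_trace(Z, target, lbc$model, wae, cfg)
    if (inherits(res, "cf_result")) res <- list(res)
    list(results = res, queries = queries, query_index = q_ix, target = target)
  }, verbose)
  checksums$counterfactual <- st_cf$checksum
  cf <- st_cf$value

  st_metrics <- stage_cached(dir, "metrics",
                             obj_digest(list(config$metrics, checksums$counterfactual, seed)), function() {
    evaluate_batch(cf$results, cf$queries,
                   rep(cf$target, length(cf$results)),
                   lbc$model, wae, data$train$images,
                   k_proximity = config$metrics$k_proximity,
                   k_realism = config$metrics$k_realism,
                   change_epsilon = config$metrics$change_epsilon,
                   csv = file.path(dir, "metrics.csv"))
  }, verbose)
  checksums$metrics <- st_metrics$checksum
  report <- st_metrics$value

  manifest <- list(
    config = unclass(config),
    config_digest = obj_digest(unclass(config)),
    seeds = list(global = seed,
                 stages = sapply(c("data", "wae", "lbc", "cf"),
                                 function(s) seed_stream(seed, s))),
    checksums = checksums,
    versions = list(r = as.character(getRversion()),
                    package = as.character(utils::packageVersion("tracecf")))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(dir = dir, manifest = manifest, dataset = data, wae = wae,
       lbc = lbc$model, counterfactuals = cf, report = report)
}

#' Default pipeline configuration
#'
#' Desk-scale defaults: 500 training images at 64 x 64, a 100-dimensional
#' latent space, 30 WAE epochs, a calibrated binary diagnosis classifier and
#' 20 TraCE counterfactuals evaluated with the standard metrics.
#'
#' @return configuration list (class `run_config`).
#' @export
run_pipeline_defaults <- function() {
  structure(default_run_config(), class = "run_config")
}
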