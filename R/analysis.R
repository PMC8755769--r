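# Model-introspection procedures built on counterfactuals: pixel-space
# attribute deltas and hybrid counterfactuals (attribute-relationship
# probing), and localization of counterfactual change mass (shortcut
# detection).

#' Pixel-space signature of a counterfactual
#'
#' The signed change `Delta = x_bar - x` introduced by a counterfactual, so
#' that `x + Delta` reconstructs the counterfactual exactly (before any
#' clipping). Summing the deltas of two independently optimized
#' counterfactuals onto the query yields the hybrid counterfactual.
#'
#' @param x query image.
#' @param x_bar counterfactual image, same shape.
#' @param hypothesis optional label describing the hypothesis that produced
#'   `x_bar` (e.g. `"age=70"`).
#' @return object of class `attribute_delta` with fields `delta` and
#'   `hypothesis`.
#' @export
attribute_delta <- function(x, x_bar, hypothesis = NULL) {
  assert_same_shape(x, x_bar)
  structure(list(delta = x_bar - x, hypothesis = hypothesis),
            class = "attribute_delta")
}

#' Hybrid counterfactual from two attribute deltas
#'
#' `x_bar = clip(x + Delta_A + Delta_D, 0, 1)`: the query plus the summed
#' pixel-space signatures of two independently optimized counterfactuals
#' (e.g. an age hypothesis and a diagnosis hypothesis). Commutative in the
#' two deltas; with one delta zero it reduces to the other counterfactual.
#'
#' @param x query image.
#' @param delta_a,delta_d [attribute_delta()] objects (or plain matrices).
#' @return image matrix in \[0,1\].
#' @export
hybrid_counterfactual <- function(x, delta_a, delta_d) {
  da <- if (inherits(delta_a, "attribute_delta")) delta_a$delta else delta_a
  dd <- if (inherits(delta_d, "attribute_delta")) delta_d$delta else delta_d
  assert_same_shape(x, da); assert_same_shape(x, dd)
  clamp01(x + da + dd)
}

#' Attribute-relationship sensitivity via hybrid counterfactuals
#'
#' For each query: generate an attribute counterfactual `x_bar_A` (e.g.
#' "age = 70") with the attribute predictor and a diagnosis counterfactual
#' `x_bar_D` (e.g. "abnormal") with the diagnosis predictor — both in the
#' same latent space — then form the hybrid and measure
#' `P(abnormal | hybrid) - P(abnormal | x_bar_D)`. A positive mean says the
#' diagnosis model is sensitive to attribute-specific image patterns; this
#' measures association learned by the model, not causality.
#'
#' @param query_images (H, W, N) array of query images.
#' @param attribute_model regression [train_lbc()] model for the attribute.
#' @param diagnosis_model classification [train_lbc()] model.
#' @param wae shared autoencoder (both predictors must use its latent space).
#' @param attribute_target numeric attribute hypothesis (e.g. 70).
#' @param diagnosis_target class hypothesis (default `"abnormal"`).
#' @param config a [cf_config()].
#' @param n_boot bootstrap resamples for the confidence interval (default
#'   1000).
#' @param conf CI level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return object of class `attribute_sensitivity`: list with `per_query`,
#'   `mean`, `sd`, `ci` (bootstrap percentile interval) and settings.
#' @export
attribute_sensitivity <- function(query_images, attribute_model, diagnosis_model,
                                  wae, attribute_target, diagnosis_target = "abnormal",
                                  config = cf_config(), n_boot = 1000L,
                                  conf = 0.95, seed = 1L) {
  stopifnot(inherits(attribute_model, "lbc_model"),
            inherits(diagnosis_model, "lbc_model"))
  if (attribute_model$latent_dim != diagnosis_model$latent_dim) {
    stop("attribute and diagnosis predictors use different latent spaces")
  }
  Z <- encode(wae, query_images)
  cfA <- generate_trace(Z, attribute_target, attribute_model, wae, config)
  cfD <- generate_trace(Z, diagnosis_target, diagnosis_model, wae, config)
  if (inherits(cfA, "cf_result")) { cfA <- list(cfA); cfD <- list(cfD) }
  k_ab <- match(as.character(diagnosis_target), diagnosis_model$class_levels)
  n <- length(cfA)
  sens <- numeric(n)
  for (i in seq_len(n)) {
    x <- query_images[, , i]
    dA <- attribute_delta(x, cfA[[i]]$x_bar)
    dD <- attribute_delta(x, cfD[[i]]$x_bar)
    hyb <- hybrid_counterfactual(x, dA, dD)
    p_h <- class_probabilities(diagnosis_model, encode(wae, hyb))[k_ab]
    p_d <- class_probabilities(diagnosis_model, encode(wae, cfD[[i]]$x_bar))[k_ab]
    sens[i] <- p_h - p_d
  }
  set.seed(seed_stream(seed, "sens_boot"))
  boot_means <- vapply(seq_len(n_boot), function(b)
    mean(sens[sample.int(n, replace = TRUE)]), numeric(1))
  qs <- stats::quantile(boot_means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  structure(list(per_query = sens, mean = mean(sens), sd = stats::sd(sens),
                 ci = qs, conf = conf,
                 attribute_target = attribute_target,
                 diagnosis_target = diagnosis_target),
            class = "attribute_sensitivity")
}

#' @export
print.attribute_sensitivity <- function(x, ...) {
  cat(sprintf(
    "attribute sensitivity (%s + %s): %.4f +/- %.4f, %d%% CI [%.4f, %.4f], n = %d\n",
    as.character(x$attribute_target), x$diagnosis_target, x$mean, x$sd,
    round(100 * x$conf), x$ci[1], x$ci[2], length(x$per_query)))
  invisible(x)
}

#' Localize counterfactual change mass in a region
#'
#' For each query/counterfactual pair, the fraction of total absolute pixel
#' change `sum(|x - x_bar|)` that falls inside a region mask (e.g. the
#' top-left corner block from [corner_mask()]). A mean fraction above the
#' verdict threshold flags the region as a shortcut the model exploits.
#'
#' @param queries (H, W, N) array of query images.
#' @param counterfactuals (H, W, N) array of counterfactual images.
#' @param region_mask logical matrix, same image shape.
#' @param threshold verdict threshold on the aggregate mean (default 0.5).
#' @return object of class `shortcut_report`: per-query fractions (NA where
#'   total change is zero; excluded from the aggregate with a warning),
#'   mean, sd, threshold and verdict.
#' @export
shortcut_localization <- function(queries, counterfactuals, region_mask,
                                  threshold = 0.5) {
  if (!is.logical(region_mask)) stop("region_mask must be logical")
  if (!any(region_mask)) stop("region_mask is empty")
  if (length(dim(queries)) == 2) queries <- array(queries, c(dim(queries), 1))
  if (length(dim(counterfactuals)) == 2) {
    counterfactuals <- array(counterfactuals, c(dim(counterfactuals), 1))
  }
  stopifnot(all(dim(queries) == dim(counterfactuals)),
            all(dim(region_mask) == dim(queries)[1:2]))
  n <- dim(queries)[3]
  frac <- vapply(seq_len(n), function(i) {
    d <- abs(queries[, , i] - counterfactuals[, , i])
    tot <- sum(d)
    if (tot == 0) NA_real_ else sum(d[region_mask]) / tot
  }, numeric(1))
  if (anyNA(frac)) {
    warning(sum(is.na(frac)), " pair(s) with zero total change excluded from aggregate")
  }
  ok <- frac[!is.na(frac)]
  structure(list(fractions = frac, mean = mean(ok),
                 sd = if (length(ok) > 1) stats::sd(ok) else 0,
                 threshold = threshold,
                 shortcut_flagged = mean(ok) > threshold),
            class = "shortcut_report")
}

#' Planted-shortcut detection experiment
#'
#' End-to-end replication of the shortcut study: generate a cohort with the
#' requested nuisance policy (near-boundary severities, so the genuine
#' opacity evidence is subtle and a planted marker is the easy cue), train
#' the autoencoder and the calibrated classifier on it, generate
#' counterfactuals for held-out normal queries toward "abnormal", and
#' localize the change mass in the corner mask. Difference images compare the
#' counterfactual against the decoded reconstruction of the query, so
#' autoencoder reconstruction error does not contaminate the localization.
#'
#' @param nuisance_policy `"abnormal_only"` (planted shortcut) or `"none"`
#'   (clean control).
#' @param seed integer seed for the whole pipeline.
#' @param n training-set size (default 200) plus 40 held-out images.
#' @param image_size image side (default 64).
#' @param n_queries held-out normal queries to explain (default 10).
#' @param wae_epochs autoencoder epochs (default 25).
#' @param eta1 proximity weight for the counterfactuals (default 0.1).
#' @return a [shortcut_localization()] report with the trained models
#'   attached as attributes.
#' @export
shortcut_experiment <- function(nuisance_policy = c("abnormal_only", "none"),
                                seed = 1L, n = 200L, image_size = 64L,
                                n_queries = 10L, wae_epochs = 25L,
                                eta1 = 0.1) {
  nuisance_policy <- match.arg(nuisance_policy)
  ds <- generate_dataset(n + 40L, class_balance = 0.5,
                         nuisance_policy = nuisance_policy,
                         seed = seed_stream(seed, "shortcut_data"),
                         image_size = image_size,
                         severity_range = c(0.35, 0.65))
  tr <- seq_len(n); ho <- (n + 1L):(n + 40L)
  wae <- train_wae(ds$images[, , tr],
                   wae_config(image_size = image_size, epochs = wae_epochs,
                              weight_switch_epoch = 5L),
                   seed = seed_stream(seed, "shortcut_wae"))
  Z <- encode(wae, ds$images[, , tr])
  model <- train_lbc(Z, ds$labels[tr], "classification",
                     lbc_config(f_hidden = c(128L, 64L),
                                g_hidden = c(128L, 64L), epochs = 30L),
                     seed = seed_stream(seed, "shortcut_lbc"))
  qix <- ho[ds$labels[ho] == "normal"]
  qix <- utils::head(qix, n_queries)
  Zq <- encode(wae, ds$images[, , qix, drop = FALSE])
  res <- generate_trace(Zq, "abnormal", model, wae,
                        cf_config(eta1 = eta1, steps = 300L))
  if (inherits(res, "cf_result")) res <- list(res)
  cfs <- simplify2array(lapply(res, `[[`, "x_bar"))
  recons <- decode(wae, Zq)
  rep <- shortcut_localization(recons, cfs, corner_mask(image_size))
  attr(rep, "policy") <- nuisance_policy
  attr(rep, "models") <- list(wae = wae, lbc = model)
  rep
}

#' @export
print.shortcut_report <- function(x, ...) {
  cat(sprintf(
    "shortcut_report: in-region change fraction %.3f +/- %.3f over %d queries (threshold %.2f) -> %s\n",
    x$mean, x$sd, sum(!is.na(x$fractions)), x$threshold,
    if (x$shortcut_flagged) "SHORTCUT FLAGGED" else "no shortcut"))
  invisible(x)
}
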