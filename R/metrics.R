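# Evaluation metrics for counterfactual explanations: validity, confidence,
# sparsity, proximity and realism, each with a small exactly-testable kernel,
# plus batch aggregation into a report.

#' Validity of a batch of counterfactuals
#'
#' Categorical mode: fraction of counterfactuals whose achieved prediction
#' equals the desired target. Continuous mode: mean absolute percentage error
#' `mean(|y_bar - F(x)| / |y_bar|)` between desired and achieved values
#' (lower is better).
#'
#' @param predictions achieved predictions (class labels/indices, or numeric).
#' @param targets desired targets, same length.
#' @param mode `"categorical"` or `"continuous"`.
#' @return scalar in \[0,1\] (categorical) or nonnegative MAPE (continuous).
#' @export
validity <- function(predictions, targets, mode = c("categorical", "continuous")) {
  mode <- match.arg(mode)
  if (length(predictions) != length(targets)) stop("validity: length mismatch")
  if (mode == "categorical") {
    mean(as.character(predictions) == as.character(targets))
  } else {
    if (any(targets == 0)) stop("validity: zero continuous target (MAPE undefined)")
    mean(abs(targets - predictions) / abs(targets))
  }
}

#' Confidence of assigning the desired class
#'
#' Softmax probability of the target class at the counterfactual's latent
#' code.
#'
#' @param model a classifier ([train_lbc()] or [train_classifier()] family).
#' @param z_bar counterfactual latent code (vector or matrix).
#' @param y_bar_class desired class (label or index).
#' @return probability in \[0,1\] (vector for matrix input).
#' @export
confidence <- function(model, z_bar, y_bar_class) {
  lv <- model$class_levels
  if (is.character(y_bar_class) || is.factor(y_bar_class)) {
    k <- match(as.character(y_bar_class), lv)
  } else k <- as.integer(y_bar_class)
  if (is.na(k) || k < 1 || k > model$K) stop("confidence: invalid class index")
  p <- class_probabilities(model, z_bar)
  if (is.null(dim(p))) p[k] else p[, k]
}

#' Sparsity: fraction of altered pixels
#'
#' Fraction of pixels whose absolute intensity change exceeds
#' `change_epsilon`. The strict "> 0" reading is ill-posed under floating
#' point, so the default threshold is one 8-bit quantization step (1/255).
#'
#' @param x,x_bar images of identical shape.
#' @param change_epsilon change threshold (default `1/255`).
#' @return scalar in \[0,1\].
#' @export
sparsity <- function(x, x_bar, change_epsilon = 1 / 255) {
  assert_same_shape(x, x_bar)
  mean(abs(x - x_bar) > change_epsilon)
}

#' Proximity: mean latent distance to the K nearest training samples
#'
#' Mean Euclidean distance from the counterfactual's latent code to its K
#' nearest neighbors among the training latents (lower = better grounded in
#' the training distribution).
#'
#' @param z_bar latent code of the counterfactual (vector), or an image
#'   matrix if `wae` is supplied.
#' @param train_latents N x d matrix of training latents (or an (H, W, N)
#'   image array if `wae` is supplied).
#' @param K number of neighbors (default 5; must be <= N).
#' @param wae optional [train_wae()] model used to encode image inputs.
#' @return nonnegative scalar.
#' @export
proximity <- function(z_bar, train_latents, K = 5L, wae = NULL) {
  if (!is.null(wae)) {
    if (is.matrix(z_bar) && all(dim(z_bar) == rep(wae$config$image_size, 2))) {
      z_bar <- encode(wae, z_bar)
    }
    if (length(dim(train_latents)) == 3) train_latents <- encode(wae, train_latents)
  }
  train_latents <- as.matrix(train_latents)
  if (K > nrow(train_latents)) {
    stop("proximity: K (", K, ") exceeds the number of training samples")
  }
  d2 <- colSums((t(train_latents) - as.numeric(z_bar))^2)
  mean(sqrt(sort(d2)[seq_len(K)]))
}

#' Realism score of a generated sample
#'
#' `max_j ||psi_j - psi_j^(K)|| / ||psi_j - psi_g||` over real feature
#' vectors `psi_j`, where `psi_j^(K)` is the K-th nearest neighbor of
#' `psi_j` within the real set (excluding itself). High when the generated
#' feature vector `psi_g` lies inside the real manifold; decreases as it
#' moves away. If `psi_g` coincides with a real vector the score is a large
#' configured sentinel.
#'
#' @param feature_g feature vector of the generated image.
#' @param real_features N x p matrix of real-image feature vectors (N > K).
#' @param K neighbor index (default 3).
#' @param sentinel value returned on exact coincidence (default 1e6).
#' @return positive scalar.
#' @export
realism <- function(feature_g, real_features, K = 3L, sentinel = 1e6) {
  real_features <- as.matrix(real_features)
  N <- nrow(real_features)
  if (N < K + 1) stop("realism: need at least K + 1 real feature vectors")
  g <- as.numeric(feature_g)
  d_g <- sqrt(colSums((t(real_features) - g)^2))
  if (any(d_g == 0)) return(sentinel)
  D <- as.matrix(stats::dist(real_features))
  # K-th neighbor excluding self: the self-distance 0 occupies rank 1
  dK <- apply(D, 1, function(r) sort(r)[K + 1])
  max(dK / d_g)
}

#' Evaluate a batch of counterfactuals
#'
#' Computes validity, confidence, sparsity, proximity and realism per
#' counterfactual plus mean and standard-deviation aggregates.
#'
#' @param counterfactuals list of `cf_result` objects (or an (H, W, N) array
#'   of counterfactual images with latents supplied via `z_bars`).
#' @param queries (H, W, N) array of query images.
#' @param targets desired classes, length N.
#' @param model classifier used for validity and confidence.
#' @param wae autoencoder supplying the encoder (proximity) and the default
#'   realism feature extractor.
#' @param train_images (H, W, M) array of training images grounding proximity
#'   and realism.
#' @param k_proximity,k_realism neighbor counts (defaults 5 and 3).
#' @param change_epsilon sparsity threshold (default 1/255).
#' @param feature_extractor optional function(image) -> feature vector; the
#'   default uses the WAE encoder's final hidden activations.
#' @param csv optional path: write the per-row report as CSV.
#' @return object of class `metrics_report`: list with `rows` (data.frame)
#'   and `aggregates` (mean, sd per metric, N).
#' @export
evaluate_batch <- function(counterfactuals, queries, targets, model, wae,
                           train_images, k_proximity = 5L, k_realism = 3L,
                           change_epsilon = 1 / 255,
                           feature_extractor = NULL, csv = NULL) {
  if (inherits(counterfactuals, "cf_result")) counterfactuals <- list(counterfactuals)
  n <- length(counterfactuals)
  if (dim(queries)[3] != n || length(targets) != n) {
    stop("evaluate_batch: misaligned inputs (", n, " counterfactuals, ",
         dim(queries)[3], " queries, ", length(targets), " targets)")
  }
  if (is.null(feature_extractor)) {
    feature_extractor <- function(img) encoder_features(wae, img)
  }
  train_latents <- encode(wae, train_images)
  n_feat <- min(dim(train_images)[3], 200L)
  real_features <- t(vapply(seq_len(n_feat),
                            function(i) feature_extractor(train_images[, , i]),
                            numeric(length(feature_extractor(train_images[, , 1])))))
  lv <- model$class_levels
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    cf <- counterfactuals[[i]]
    p <- class_probabilities(model, cf$z_bar)
    pred_class <- lv[which.max(p)]
    data.frame(
      id = i,
      target = as.character(targets[i]),
      achieved = pred_class,
      valid = as.integer(pred_class == as.character(targets[i])),
      confidence = confidence(model, cf$z_bar, targets[i]),
      sparsity = sparsity(queries[, , i], cf$x_bar, change_epsilon),
      proximity = proximity(cf$z_bar, train_latents, k_proximity),
      realism = realism(feature_extractor(cf$x_bar), real_features, k_realism),
      displacement = cf$displacement
    )
  }))
  num_cols <- c("valid", "confidence", "sparsity", "proximity", "realism",
                "displacement")
  aggregates <- data.frame(
    metric = num_cols,
    mean = vapply(num_cols, function(cn) mean(rows[[cn]]), numeric(1)),
    sd = vapply(num_cols, function(cn)
      if (nrow(rows) > 1) stats::sd(rows[[cn]]) else 0, numeric(1))
  )
  rownames(aggregates) <- NULL
  if (!is.null(csv)) utils::write.csv(rows, csv, row.names = FALSE)
  structure(list(rows = rows, aggregates = aggregates, N = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report over", x$N, "counterfactuals\n")
  ag <- x$aggregates
  for (i in seq_len(nrow(ag))) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", ag$metric[i], ag$mean[i], ag$sd[i]))
  }
  invisible(x)
}
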