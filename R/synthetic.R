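# Synthetic radiograph-like scene generator.
#
# Emulates the statistical structure of a frontal chest-radiograph cohort at
# desk scale: a torso with two lung fields, rib texture, and an "abnormality"
# controlled by diffuse opacity clouds inside the lung fields. Severity drives
# lung opacity (the class signal), an age-like factor drives rib-texture
# frequency and contrast, a gender-like factor drives torso aspect ratio, and
# an optional nuisance marker (a bright text-like block in the top-left
# corner) stands in for scanner/annotation shortcuts. The lung fields are two
# fixed ellipses in normalized coordinates, so ground-truth region masks and a
# severity readout are analytic.

LUNG_ELLIPSES <- list(
  list(cx = 0.34, cy = 0.46, rx = 0.13, ry = 0.22),
  list(cx = 0.66, cy = 0.46, rx = 0.13, ry = 0.22)
)

#' Lung-field mask
#'
#' Logical mask of the two fixed elliptical lung fields the generator uses,
#' in image coordinates (rows = y, columns = x).
#'
#' @param size image side length in pixels.
#' @return logical `size x size` matrix.
#' @export
lung_mask <- function(size) {
  v <- (seq_len(size) - 0.5) / size   # rows (y)
  u <- (seq_len(size) - 0.5) / size   # cols (x)
  m <- matrix(FALSE, size, size)
  for (e in LUNG_ELLIPSES) {
    d <- outer((v - e$cy)^2 / e$ry^2, (u - e$cx)^2 / e$rx^2, "+")
    m <- m | (d <= 1)
  }
  m
}

# pixels stamped by the nuisance marker: a wide text-like banner spanning
# rows [2, size/8) and cols [2, 3*size/8) (zero-based), emulating a word
# overlaid in the top-left corner
nuisance_region <- function(size) {
  hi <- max(3L, size %/% 8L)
  list(rows = 3:hi, cols = 3:max(3L, (3L * size) %/% 8L))
}

#' Top-left corner mask for shortcut localization
#'
#' Covers the nuisance text-block region (plus a small margin) used by the
#' shortcut-detection analysis.
#'
#' @param size image side length in pixels.
#' @param margin extra pixels around the stamped block (default 2).
#' @return logical `size x size` matrix.
#' @export
corner_mask <- function(size, margin = 2L) {
  reg <- nuisance_region(size)
  m <- matrix(FALSE, size, size)
  m[seq_len(min(size, max(reg$rows) + margin)),
    seq_len(min(size, max(reg$cols) + margin))] <- TRUE
  m
}

# deterministic text-like banner pattern: bright with darker letter-gap
# stripes, all values > 0.9
stamp_nuisance <- function(img) {
  reg <- nuisance_region(nrow(img))
  img[reg$rows, reg$cols] <- 0.95
  gap_cols <- reg$cols[seq(2, length(reg$cols), by = 2)]
  img[reg$rows, gap_cols] <- 0.91
  img
}

#' Scene parameters for the synthetic generator
#'
#' @param severity abnormality level in \[0,1\]; drives lung-field opacity.
#'   `severity >= 0.5` defines the class "abnormal".
#' @param age_proxy age-like appearance factor in \[20, 90\] (years); drives
#'   rib-texture frequency and contrast outside the lung fields.
#' @param gender_proxy binary appearance factor (0 or 1); drives torso aspect
#'   ratio.
#' @param nuisance logical; when `TRUE`, a bright text-like block is stamped
#'   in the top-left corner.
#' @param image_size side length in pixels (default 64).
#' @param seed integer seed; identical parameters give bit-identical images.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(severity, age_proxy = 50, gender_proxy = 0,
                         nuisance = FALSE, image_size = 64L, seed = 1L) {
  if (!is.numeric(severity) || length(severity) != 1 || severity < 0 || severity > 1) {
    stop("invalid field 'severity': must be a real in [0, 1]")
  }
  if (!is.numeric(age_proxy) || age_proxy < 20 || age_proxy > 90) {
    stop("invalid field 'age_proxy': must be a real in [20, 90]")
  }
  if (!(gender_proxy %in% c(0, 1))) {
    stop("invalid field 'gender_proxy': must be 0 or 1")
  }
  if (!is.logical(nuisance) || length(nuisance) != 1 || is.na(nuisance)) {
    stop("invalid field 'nuisance': must be a single logical")
  }
  if (!is.numeric(image_size) || image_size < 24) {
    stop("invalid field 'image_size': must be an integer >= 24")
  }
  structure(list(severity = severity, age_proxy = age_proxy,
                 gender_proxy = gender_proxy, nuisance = nuisance,
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "scene_params")
}

#' Generate one synthetic radiograph-like image
#'
#' Deterministic in its parameters: the opacity-cloud pattern and pixel noise
#' are drawn from `params$seed`, and the mean intensity inside the lung-field
#' masks is strictly increasing in `severity` for any fixed seed.
#'
#' @param params a [scene_params()] object.
#' @return numeric `image_size x image_size` matrix with values in \[0,1\].
#' @export
#' @examples
#' img <- generate_image(scene_params(severity = 0.8, seed = 3))
#' severity_readout(img)
generate_image <- function(params) {
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  S <- params$image_size
  old <- .Random.seed_exists()
  set.seed(params$seed)
  v <- matrix((seq_len(S) - 0.5) / S, S, S)        # y over rows
  u <- matrix((seq_len(S) - 0.5) / S, S, S, byrow = TRUE)  # x over cols

  img <- matrix(0.05, S, S)                        # background
  # torso: ellipse whose width depends on the gender-like factor
  tw <- if (params$gender_proxy > 0) 0.44 else 0.37
  torso <- ((u - 0.5)^2 / tw^2 + (v - 0.52)^2 / 0.42^2) <= 1
  img[torso] <- 0.45

  # rib texture outside the lung fields: age raises frequency and contrast
  a01 <- (params$age_proxy - 20) / 70
  amp <- 0.04 + 0.08 * a01
  freq <- 5 + 7 * a01
  ribs <- amp * (0.5 + 0.5 * sin(2 * pi * freq * v + 1.3))
  lm <- lung_mask(S)
  rib_zone <- torso & !lm
  img[rib_zone] <- img[rib_zone] + ribs[rib_zone]

  # lung fields: dark at severity 0, filled by smooth opacity clouds
  img[lm] <- 0.16
  blobs <- matrix(0, S, S)
  for (e in LUNG_ELLIPSES) {
    for (k in 1:3) {
      bx <- e$cx + (runif(1) - 0.5) * e$rx
      by <- e$cy + (runif(1) - 0.5) * e$ry
      bw <- 0.05 + 0.06 * runif(1)
      blobs <- blobs + exp(-((u - bx)^2 + (v - by)^2) / (2 * bw^2))
    }
  }
  blobs <- blobs / max(blobs)
  img[lm] <- img[lm] + params$severity * (0.30 + 0.45 * blobs[lm])

  # mild sensor noise (seeded, hence reproducible)
  img <- img + matrix(rnorm(S * S, sd = 0.008), S, S)
  img <- clamp01(img)

  if (params$nuisance) img <- stamp_nuisance(img)
  if (old$exists) assign(".Random.seed", old$seed, envir = globalenv())
  img
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    list(exists = TRUE, seed = get(".Random.seed", envir = globalenv()))
  } else list(exists = FALSE, seed = NULL)
}

#' Mean lung-field intensity (severity oracle)
#'
#' Mean intensity inside the generator's fixed lung-field masks; monotone in
#' the severity used to generate the image, so it serves as a ground-truth
#' readout for opacity-based counterfactual changes.
#'
#' @param image square numeric matrix from [generate_image()] (or any image
#'   matching the generator geometry).
#' @return scalar in \[0,1\].
#' @export
severity_readout <- function(image) {
  assert_image(image)
  if (nrow(image) != ncol(image)) stop("severity_readout: image must be square")
  mean(image[lung_mask(nrow(image))])
}

#' Generate a labeled synthetic dataset
#'
#' Samples scene parameters so that a fraction `class_balance` of images is
#' abnormal (severity >= 0.5). Labels are a deterministic function of
#' severity. With `nuisance_policy = "abnormal_only"` the corner text-block is
#' stamped on exactly the abnormal images, planting a shortcut.
#'
#' @param n number of images (>= 2).
#' @param class_balance target abnormal fraction in \[0,1\].
#' @param nuisance_policy `"none"` or `"abnormal_only"`.
#' @param seed integer seed; the dataset is a pure function of
#'   `(n, class_balance, nuisance_policy, image_size, age_severity_rho, seed)`.
#' @param image_size side length in pixels (default 64).
#' @param age_severity_rho correlation knob in \[0,1\] coupling the age-like
#'   factor to severity (0 = independent, the default); used by the
#'   attribute-relationship analyses to plant a known association.
#' @param severity_range length-2 vector bounding the sampled severities
#'   (default `c(0, 1)`). Normal images draw severity from
#'   `[severity_range[1], 0.5)`, abnormal from `[0.5, severity_range[2]]`;
#'   a narrow range around 0.5 (e.g. `c(0.35, 0.65)`) emulates cohorts where
#'   the genuine class evidence is subtle, the regime where shortcut
#'   learning is expected.
#' @return an object of class `synthetic_dataset`: list with `images`
#'   (H x W x n array), `labels` (factor normal/abnormal) and `attributes`
#'   (data.frame of severity, age_proxy, gender_proxy, nuisance).
#' @export
generate_dataset <- function(n, class_balance = 0.5,
                             nuisance_policy = c("none", "abnormal_only"),
                             seed = 1L, image_size = 64L,
                             age_severity_rho = 0, severity_range = c(0, 1)) {
  if (n < 2) stop("generate_dataset: n must be >= 2")
  nuisance_policy <- match.arg(nuisance_policy)
  stopifnot(class_balance >= 0, class_balance <= 1,
            age_severity_rho >= 0, age_severity_rho <= 1,
            length(severity_range) == 2, severity_range[1] >= 0,
            severity_range[2] <= 1, severity_range[1] < 0.5,
            severity_range[2] >= 0.5)
  set.seed(seed)
  n_ab <- round(n * class_balance)
  abnormal <- sample(rep(c(TRUE, FALSE), c(n_ab, n - n_ab)))
  severity <- ifelse(abnormal,
                     runif(n, 0.5, severity_range[2]),
                     runif(n, severity_range[1], min(0.4999, 0.5 - 1e-4)))
  u_age <- runif(n)
  age <- 20 + 70 * (age_severity_rho * severity + (1 - age_severity_rho) * u_age)
  gender <- rbinom(n, 1, 0.5)
  nuis <- if (nuisance_policy == "abnormal_only") abnormal else rep(FALSE, n)
  seeds <- sample.int(2^30, n)
  imgs <- array(0, dim = c(image_size, image_size, n))
  for (i in seq_len(n)) {
    imgs[, , i] <- generate_image(scene_params(
      severity = severity[i], age_proxy = age[i], gender_proxy = gender[i],
      nuisance = nuis[i], image_size = image_size, seed = seeds[i]
    ))
  }
  structure(list(
    images = imgs,
    labels = factor(ifelse(severity >= 0.5, "abnormal", "normal"),
                    levels = c("normal", "abnormal")),
    attributes = data.frame(severity = severity, age_proxy = age,
                            gender_proxy = gender, nuisance = nuis)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat("synthetic_dataset:", d[3], "images of", d[1], "x", d[2], "pixels;",
      sum(x$labels == "abnormal"), "abnormal /", sum(x$labels == "normal"),
      "normal\n")
  invisible(x)
}
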