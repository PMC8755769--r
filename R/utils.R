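`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Deterministic sub-seed derived from a base seed and a stage name, so each
# pipeline stage gets an independent, reproducible RNG stream. FNV-1a over the
# name bytes, mixed with the base seed, reduced below 2^31.
seed_stream <- function(seed, name) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(name)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483629) + 1L
}

assert_image <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(arg, " must be a numeric matrix (grayscale image)")
  }
  invisible(x)
}

assert_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stop("shape mismatch: ", what, " have dimensions ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}

# stack a list of image matrices into an (H, W, N) array
stack_images <- function(imgs) {
  if (is.array(imgs) && length(dim(imgs)) == 3) return(imgs)
  array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs)))
}

#' Write a grayscale image to PNG
#'
#' Intensities in \[0,1\] are quantized to 8 bits at export; in-memory images
#' always stay in real-valued \[0,1\].
#'
#' @param image numeric matrix in \[0,1\].
#' @param path output file path.
#' @export
write_image_png <- function(image, path) {
  assert_image(image)
  png::writePNG(clamp01(image), target = path)
  invisible(path)
}

#' Read a grayscale PNG image
#'
#' @param path PNG file path.
#' @return numeric matrix in \[0,1\] (multi-channel files are averaged).
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  img
}
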