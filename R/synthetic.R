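# Synthetic tissue-like fixtures.
#
# Glands are drawn as perturbed annuli: a stained epithelial ring around a
# clear lumen on a lightly stained stromal background. The boundary radius is
# displaced by low-order sinusoids whose amplitude is (1 - regularity) * radius,
# so high regularity yields round, well-separated gland motifs (benign-like)
# and low regularity yields irregular, fused blobs (malignant-like).

#' Specification of a synthetic tissue image
#'
#' @param side_length image side in pixels (square image), >= 32.
#' @param class_label `"benign"` or `"malignant"`.
#' @param gland_count number of gland motifs, >= 1.
#' @param regularity boundary regularity in \[0, 1\]; benign-like tissue is
#'   high (default 0.9), malignant-like low (default 0.2).
#' @param palette list of three RGB triples in \[0, 255\]: background stroma,
#'   epithelial stain, lumen.
#' @param noise_sd standard deviation of additive Gaussian noise on the 8-bit
#'   scale, >= 0.
#' @param seed integer seed; identical specs generate bit-identical images.
#' @return object of class `"tissue_spec"`.
#' @export
tissue_spec <- function(side_length = 64L,
                        class_label = c("benign", "malignant"),
                        gland_count = 3L,
                        regularity = NULL,
                        palette = stain_palette(),
                        noise_sd = 8,
                        seed = 1L) {
  class_label <- match.arg(class_label)
  if (is.null(regularity)) {
    regularity <- if (class_label == "benign") 0.9 else 0.2
  }
  if (side_length < 32) stop("side_length must be >= 32")
  if (gland_count < 1) stop("gland_count must be >= 1")
  if (regularity < 0 || regularity > 1) stop("regularity must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(side_length = as.integer(side_length),
                 class_label = class_label,
                 gland_count = as.integer(gland_count),
                 regularity = regularity,
                 palette = palette,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "tissue_spec")
}

#' Default stain-like palette
#'
#' Eosin-pink stroma, hematoxylin-purple epithelium, near-white lumen.
#'
#' @return list of three RGB triples in \[0, 255\].
#' @export
stain_palette <- function() {
  list(stroma = c(235, 205, 215),
       epithelium = c(120, 70, 150),
       lumen = c(250, 245, 248))
}

#' Generate a synthetic tissue image
#'
#' @param spec a [tissue_spec()].
#' @return side x side x 3 array with integer values in \[0, 255\].
#' @export
generate_tissue_image <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  n <- spec$side_length
  with_seed(spec$seed, {
    img <- array(0, dim = c(n, n, 3))
    for (ch in 1:3) img[, , ch] <- spec$palette$stroma[ch]
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    amp <- 1 - spec$regularity
    for (g in seq_len(spec$gland_count)) {
      cy <- stats::runif(1, 0.2 * n, 0.8 * n)
      cx <- stats::runif(1, 0.2 * n, 0.8 * n)
      # absolute gland radius (fixed magnification), independent of image side
      r0 <- stats::runif(1, 6, 12)
      ph <- stats::runif(3, 0, 2 * pi)
      dy <- rows - cy
      dx <- cols - cx
      theta <- atan2(dx, dy)
      dist <- sqrt(dy^2 + dx^2)
      # low-order sinusoidal boundary displacement, amplitude (1-regularity)*r
      rb <- r0 * (1 + amp * (0.55 * sin(2 * theta + ph[1]) +
                             0.30 * sin(3 * theta + ph[2]) +
                             0.15 * sin(5 * theta + ph[3])))
      rb <- pmax(rb, 2)
      inside <- dist <= rb
      lumen <- dist <= 0.55 * rb
      ring <- inside & !lumen
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[ring] <- spec$palette$epithelium[ch]
        plane[lumen] <- spec$palette$lumen[ch]
        img[, , ch] <- plane
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
    }
    round(pmin(pmax(img, 0), 255))
  })
}

#' Degrade an image by block downsampling plus noise
#'
#' Emulates the low-resolution, noisy input that the restoration path assumes:
#' `factor` x `factor` block averaging followed by additive Gaussian noise,
#' clipped to \[0, 255\].
#'
#' @param image raster in \[0, 255\] (matrix or 3-channel array).
#' @param factor integer >= 2 that divides the image side.
#' @param noise_sd Gaussian noise standard deviation (8-bit scale).
#' @param seed integer seed.
#' @return degraded raster of side `side / factor`.
#' @export
degrade_image <- function(image, factor, noise_sd = 0, seed = 1L) {
  d <- dim(image)
  if (d[1] %% factor != 0 || d[2] %% factor != 0) {
    stop("factor must divide the image side")
  }
  block_mean <- function(m) {
    nr <- nrow(m) %/% factor
    nc <- ncol(m) %/% factor
    ri <- (seq_len(nrow(m)) - 1L) %/% factor + 1L
    ci <- (seq_len(ncol(m)) - 1L) %/% factor + 1L
    out <- t(rowsum(t(rowsum(m, ri)), ci)) / factor^2
    dimnames(out) <- NULL
    out
  }
  out <- if (is.matrix(image)) {
    block_mean(image)
  } else {
    o <- array(0, dim = c(d[1] %/% factor, d[2] %/% factor, d[3]))
    for (ch in seq_len(d[3])) o[, , ch] <- block_mean(image[, , ch])
    o
  }
  if (noise_sd > 0) {
    out <- with_seed(seed,
      out + array(stats::rnorm(length(out), 0, noise_sd), dim = dim(out)))
  }
  pmin(pmax(out, 0), 255)
}

#' Generate a labeled two-class dataset of synthetic tissue images
#'
#' Per-image seeds are `seed + index`, so the dataset is reproducible from the
#' master seed while every image is distinct. Class proportions are exactly
#' 0.5 / 0.5.
#'
#' @param n_per_class images per class, >= 1.
#' @param base_spec a [tissue_spec()] supplying shared parameters; its
#'   class label, regularity and seed are overridden per image.
#' @param seed master seed.
#' @param regularity_benign,regularity_malignant per-class regularity.
#' @return list with elements `images` (list of rasters), `labels`
#'   (character vector), `seeds` (integer vector).
#' @export
generate_dataset <- function(n_per_class, base_spec = tissue_spec(),
                             seed = 42L,
                             regularity_benign = 0.9,
                             regularity_malignant = 0.2) {
  stopifnot(n_per_class >= 1)
  labels <- rep(c("benign", "malignant"), each = n_per_class)
  seeds <- as.integer(seed) + seq_along(labels)
  images <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    sp <- base_spec
    sp$class_label <- labels[i]
    sp$regularity <- if (labels[i] == "benign") regularity_benign else regularity_malignant
    sp$seed <- seeds[i]
    images[[i]] <- generate_tissue_image(sp)
  }
  list(images = images, labels = labels, seeds = seeds)
}

#' Write a dataset to disk as PNGs plus a CSV manifest
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("img_%04d_%s.png", seq_along(dataset$labels), dataset$labels)
  for (i in seq_along(files)) {
    write_raster(as_unit(dataset$images[[i]]), file.path(dir, files[i]))
  }
  manifest <- data.frame(filename = files, label = dataset$labels,
                         seed = dataset$seeds)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
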