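# Tiling, per-tile feature assembly, and score heatmaps.

#' Deterministic row-major tiling of an image
#'
#' @param image raster.
#' @param tile_side tile side in pixels, `<= image side`.
#' @param stride step between tile origins, > 0; `stride < tile_side` gives
#'   overlapping tiles.
#' @return object of class `"tile_grid"`: data frame `offsets` (1-based
#'   `row`, `col` origins in row-major order), `tile_side`, `stride`, `dim`.
#' @export
tile_image <- function(image, tile_side, stride = tile_side) {
  d <- dim(image)
  H <- d[1]
  W <- d[2]
  if (stride <= 0) stop("stride must be > 0")
  if (tile_side > min(H, W)) stop("tile_side exceeds image side")
  rows <- seq(1L, H - tile_side + 1L, by = stride)
  cols <- seq(1L, W - tile_side + 1L, by = stride)
  offsets <- data.frame(row = rep(rows, each = length(cols)),
                        col = rep(cols, times = length(rows)))
  structure(list(offsets = offsets, tile_side = as.integer(tile_side),
                 stride = as.integer(stride), dim = d),
            class = "tile_grid")
}

#' Extract one tile from an image
#'
#' @param image raster.
#' @param row,col 1-based tile origin.
#' @param tile_side tile side.
#' @return sub-raster of side `tile_side`.
#' @export
get_tile <- function(image, row, col, tile_side) {
  rs <- row:(row + tile_side - 1L)
  cs <- col:(col + tile_side - 1L)
  if (is.matrix(image)) image[rs, cs, drop = FALSE] else image[rs, cs, , drop = FALSE]
}

#' Feature-extraction configuration
#'
#' @param m_colors quantization colors (default 64 = 4x4x4 RGB bins).
#' @param d_set correlogram distances.
#' @param patch_side nonlocal patch side (odd).
#' @param sigma kernel bandwidth or `NULL` for the median heuristic.
#' @param sample_cap graph node cap per tile.
#' @param k_bands spectral energy bands.
#' @param seed seed for quantization/subsampling.
#' @return named list of class `"feature_config"`.
#' @export
feature_config <- function(m_colors = 64L, d_set = c(1L, 3L, 5L, 7L),
                           patch_side = 5L, sigma = NULL,
                           sample_cap = 256L, k_bands = 16L, seed = 1L) {
  structure(list(m_colors = as.integer(m_colors), d_set = as.integer(d_set),
                 patch_side = as.integer(patch_side), sigma = sigma,
                 sample_cap = as.integer(sample_cap),
                 k_bands = as.integer(k_bands), seed = as.integer(seed)),
            class = "feature_config")
}

#' Per-tile feature vector
#'
#' Concatenates the flattened autocorrelogram (length `m_colors * |d_set|`)
#' with the first `k_bands` graph-frequency energies of the tile's luminance.
#' Block-wise min-max normalization to training-set statistics happens inside
#' [memcell()]; this function returns raw descriptors. A constant tile is
#' well defined: its autocorrelogram concentrates on one color and its
#' energy spectrum is pure DC.
#'
#' @param tile raster in \[0, 1\].
#' @param config a [feature_config()].
#' @return named numeric vector of length `m_colors * |d_set| + k_bands`.
#' @export
tile_features <- function(tile, config = feature_config()) {
  q <- quantize_colors(tile, config$m_colors, config$seed)
  ac <- autocorrelogram(color_correlogram(q, config$d_set))
  d <- luminance(tile)
  g <- extract_patches(d, config$patch_side)
  g <- nonlocal_kernel(g, config$sigma, config$sample_cap, config$seed)
  g <- spectral_basis(build_laplacian(g))
  en <- graph_frequency_energy(d, g, config$k_bands)
  out <- c(as.vector(ac), en)
  names(out) <- c(sprintf("ac_c%02d_k%d", rep(seq_len(config$m_colors),
                                              times = length(config$d_set)),
                          rep(config$d_set, each = config$m_colors)),
                  sprintf("en_%02d", seq_len(config$k_bands)))
  out
}

#' Per-tile malignancy score heatmap
#'
#' Scores every tile with a trained [memcell()] classifier and paints the
#' scores back into image coordinates, averaging where tiles overlap. Scores
#' already lie in \[0, 1\] (higher = more malignant-like); a functional
#' stand-in for CNN activation maps.
#'
#' @param image raster in \[0, 1\].
#' @param model a trained `"memcell"` object.
#' @param tile_side,stride tiling parameters.
#' @param config a [feature_config()] matching the training features.
#' @return numeric matrix of the image's size with values in \[0, 1\].
#' @export
score_heatmap <- function(image, model, tile_side = 32L, stride = 16L,
                          config = feature_config()) {
  grid <- tile_image(image, tile_side, stride)
  heat <- matrix(0, dim(image)[1], dim(image)[2])
  cnt <- matrix(0, dim(image)[1], dim(image)[2])
  for (i in seq_len(nrow(grid$offsets))) {
    r <- grid$offsets$row[i]
    cc <- grid$offsets$col[i]
    tl <- get_tile(image, r, cc, tile_side)
    sc <- predict(model, matrix(tile_features(tl, config), nrow = 1),
                  type = "score")
    rs <- r:(r + tile_side - 1L)
    cs <- cc:(cc + tile_side - 1L)
    heat[rs, cs] <- heat[rs, cs] + sc
    cnt[rs, cs] <- cnt[rs, cs] + 1
  }
  heat / pmax(cnt, 1)
}
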