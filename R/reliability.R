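# Initial interpolation and the reliable/unreliable pixel partition.

# Separable 1-D resampling along rows; pixel-center aligned grids, edge clamp.
resample_rows <- function(m, factor, method) {
  n <- nrow(m)
  N <- n * factor
  u <- (seq_len(N) - 0.5) / factor + 0.5   # output center in input index space
  if (method == "bilinear") {
    i0 <- floor(u)
    f <- u - i0
    a <- pmin(pmax(i0, 1L), n)
    b <- pmin(pmax(i0 + 1L, 1L), n)
    m[a, , drop = FALSE] * (1 - f) + m[b, , drop = FALSE] * f
  } else if (method == "bicubic") {
    # Catmull-Rom kernel (a = -0.5); weights sum to 1
    cub <- function(t) {
      t <- abs(t)
      ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
             ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
    }
    i0 <- floor(u)
    f <- u - i0
    out <- matrix(0, N, ncol(m))
    for (k in -1:2) {
      idx <- pmin(pmax(i0 + k, 1L), n)
      out <- out + m[idx, , drop = FALSE] * cub(f - k)
    }
    out
  } else {
    stop("unknown interpolation method: ", method)
  }
}

#' Upsample a raster by an integer factor
#'
#' Separable interpolation on pixel-center aligned grids with edge clamping.
#' Bicubic (Catmull-Rom) serves as the prototype-map initialization; bilinear
#' builds the working raster that guides the ordered filter.
#'
#' @param image numeric matrix or rows x cols x 3 array.
#' @param factor integer >= 1.
#' @param method `"bilinear"` or `"bicubic"`.
#' @return raster of side `side * factor`.
#' @export
init_upsample <- function(image, factor, method = c("bilinear", "bicubic")) {
  method <- match.arg(method)
  stopifnot(factor >= 1)
  if (factor == 1) return(image)
  up <- function(m) t(resample_rows(t(resample_rows(m, factor, method)), factor, method))
  if (is.matrix(image)) return(up(image))
  d <- dim(image)
  out <- array(0, dim = c(d[1] * factor, d[2] * factor, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- up(image[, , ch])
  out
}

# Local max and min over the clipped (2r+1)^2 window centered at each pixel.
window_extrema <- function(D, r) {
  n <- nrow(D)
  m <- ncol(D)
  mx <- D
  mn <- D
  for (di in -r:r) {
    for (dj in -r:r) {
      if (di == 0 && dj == 0) next
      rs <- max(1, 1 - di):min(n, n - di)
      cs <- max(1, 1 - dj):min(m, m - dj)
      if (!length(rs) || !length(cs)) next
      nb <- D[rs + di, cs + dj, drop = FALSE]
      mx[rs, cs] <- pmax(mx[rs, cs, drop = FALSE], nb)
      mn[rs, cs] <- pmin(mn[rs, cs, drop = FALSE], nb)
    }
  }
  list(max = mx, min = mn)
}

#' Detect unreliable pixels by local max-min contrast
#'
#' A pixel is unreliable when the difference between the maximum and minimum
#' values in the reference window centered on it exceeds `tau`. Windows are
#' clipped at the image border (no padding).
#'
#' @param D working scalar raster (typically luminance), values in \[0, 1\].
#' @param window_radius window radius r >= 1; the window is (2r+1) x (2r+1).
#' @param tau threshold >= 0 in the units of `D`.
#' @return object of class `"reliability_mask"`: list with logical matrix
#'   `mask` (`TRUE` = reliable), `tau`, `window_radius`.
#' @export
detect_unreliable <- function(D, window_radius = 1L, tau = 0.1) {
  if (window_radius < 1) stop("window_radius must be >= 1")
  if (tau < 0) stop("tau must be >= 0")
  ex <- window_extrema(D, as.integer(window_radius))
  structure(list(mask = (ex$max - ex$min) <= tau,
                 tau = tau, window_radius = as.integer(window_radius)),
            class = "reliability_mask")
}

#' Restore fine-detail pixels to reliable by first-order zero crossings
#'
#' A first-order central-difference edge filter distinguishes fine details:
#' where the directional derivative changes sign across a pixel (a zero
#' crossing, e.g. a one-pixel ridge), the pixel is restored to reliable.
#' Reliable pixels are never demoted.
#'
#' @param rmask a [detect_unreliable()] result.
#' @param D the working raster the mask was computed from.
#' @return refined `"reliability_mask"`.
#' @export
refine_with_edge_filter <- function(rmask, D) {
  stopifnot(inherits(rmask, "reliability_mask"))
  n <- nrow(D)
  m <- ncol(D)
  # central differences, one-sided at borders
  gr <- if (n > 1) {
    (D[c(2:n, n), , drop = FALSE] - D[c(1, 1:(n - 1)), , drop = FALSE]) / 2
  } else matrix(0, n, m)
  gc <- if (m > 1) {
    (D[, c(2:m, m), drop = FALSE] - D[, c(1, 1:(m - 1)), drop = FALSE]) / 2
  } else matrix(0, n, m)
  zc <- matrix(FALSE, n, m)
  if (n >= 3) zc[2:(n - 1), ] <- zc[2:(n - 1), ] |
    (gr[1:(n - 2), , drop = FALSE] * gr[3:n, , drop = FALSE] < 0)
  if (m >= 3) zc[, 2:(m - 1)] <- zc[, 2:(m - 1)] |
    (gc[, 1:(m - 2), drop = FALSE] * gc[, 3:m, drop = FALSE] < 0)
  rmask$mask <- rmask$mask | zc
  rmask
}
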