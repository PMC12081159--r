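# Geodesic propagation order, two-direction confidence map, ordered filter.
#
# Unreliable pixels are processed in increasing chessboard (8-neighbor)
# distance T to the nearest reliable pixel, so each step only consumes pixels
# filtered in earlier steps. Confidence is carried in two slots per pixel,
# toward +grad(T) and -grad(T); reliable pixels hold the pair [1, 0] and
# contribute confidence 1 (with no direction penalty) when consumed.

offsets8 <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                  dj = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Chessboard propagation order field
#'
#' Breadth-first distance transform: `T = 0` at reliable pixels and
#' `T(x) = 1 + min T` over the 8-neighborhood elsewhere, together with the
#' unit direction of steepest `T` increase (central differences; where the
#' gradient vanishes, the fall-back direction points away from the nearest
#' reliable pixel, ties broken in raster-scan order of the donors).
#'
#' @param rmask a `"reliability_mask"` (or a plain logical matrix,
#'   `TRUE` = reliable) with at least one reliable pixel.
#' @return object of class `"order_field"`: integer matrix `T`, unit
#'   direction matrices `gi`, `gj` (row/column components), logical `mask`,
#'   and `src` (linear index of the nearest reliable pixel).
#' @export
compute_order_field <- function(rmask) {
  mask <- if (inherits(rmask, "reliability_mask")) rmask$mask else rmask
  stopifnot(is.logical(mask))
  if (!any(mask)) stop("order field needs at least one reliable pixel")
  n <- nrow(mask)
  m <- ncol(mask)
  Tm <- matrix(NA_integer_, n, m)
  Tm[mask] <- 0L
  src <- matrix(NA_integer_, n, m)
  src[mask] <- which(mask)
  t <- 0L
  while (anyNA(Tm)) {
    frontier <- which(Tm == t)
    if (!length(frontier)) stop("unreachable pixels in order field") # cannot happen
    fi <- (frontier - 1L) %% n + 1L
    fj <- (frontier - 1L) %/% n + 1L
    cand <- integer(0)
    donor <- integer(0)
    for (o in seq_len(nrow(offsets8))) {
      di <- offsets8[o, 1]
      dj <- offsets8[o, 2]
      ok <- fi + di >= 1 & fi + di <= n & fj + dj >= 1 & fj + dj <= m
      nb <- frontier[ok] + di + dj * n
      new <- is.na(Tm[nb])
      cand <- c(cand, nb[new])
      donor <- c(donor, frontier[ok][new])
    }
    if (length(cand)) {
      ord <- order(donor, cand)      # raster-scan donor wins ties
      keep <- !duplicated(cand[ord])
      cand <- cand[ord][keep]
      donor <- donor[ord][keep]
      Tm[cand] <- t + 1L
      src[cand] <- src[donor]
    }
    t <- t + 1L
  }
  Tn <- Tm * 1.0
  gi <- if (n > 1) {
    (Tn[c(2:n, n), , drop = FALSE] - Tn[c(1, 1:(n - 1)), , drop = FALSE]) / 2
  } else matrix(0, n, m)
  gj <- if (m > 1) {
    (Tn[, c(2:m, m), drop = FALSE] - Tn[, c(1, 1:(m - 1)), drop = FALSE]) / 2
  } else matrix(0, n, m)
  nrm <- sqrt(gi^2 + gj^2)
  flat <- nrm < 1e-12 & !mask
  if (any(flat)) {
    idx <- which(flat)
    pi_ <- (idx - 1L) %% n + 1L
    pj_ <- (idx - 1L) %/% n + 1L
    si <- (src[idx] - 1L) %% n + 1L
    sj <- (src[idx] - 1L) %/% n + 1L
    gi[idx] <- pi_ - si
    gj[idx] <- pj_ - sj
    nrm[idx] <- sqrt(gi[idx]^2 + gj[idx]^2)
  }
  nz <- nrm >= 1e-12
  gi[nz] <- gi[nz] / nrm[nz]
  gj[nz] <- gj[nz] / nrm[nz]
  gi[!nz] <- 0
  gj[!nz] <- 0
  gi[mask] <- 0
  gj[mask] <- 0
  structure(list(T = Tm, gi = gi, gj = gj, mask = mask, src = src),
            class = "order_field")
}

#' Intensity/working-value consistency weight B
#'
#' `B(x, y) = exp(-gamma_i * ||I_x - I_y||^2) * exp(-gamma_d * (D_x - D_y)^2)`.
#' With both bandwidths 0 the weight is 1 for any pair.
#'
#' @param i_x,i_y guidance values (scalars or RGB triples).
#' @param d_x,d_y working-raster values.
#' @param gamma_i,gamma_d inverse-square bandwidths, >= 0.
#' @return weight in (0, 1\].
#' @export
pair_weight_b <- function(i_x, i_y, d_x, d_y, gamma_i = 100, gamma_d = 1e4) {
  if (gamma_i < 0 || gamma_d < 0) stop("gamma_i and gamma_d must be >= 0")
  exp(-gamma_i * sum((i_x - i_y)^2)) * exp(-gamma_d * (d_x - d_y)^2)
}

#' Boundary-direction consistency weight G
#'
#' Cosine of the angle between the two propagation directions, floored at
#' `delta`; orthogonal or opposite directions therefore contribute `delta`.
#' With `delta = 1` the weight is 1 for any pair.
#'
#' @param dir_x,dir_y nonzero direction vectors.
#' @param delta floor, >= 0.
#' @return weight `max(cos(angle), delta)`.
#' @export
pair_weight_g <- function(dir_x, dir_y, delta = 0) {
  nx <- sqrt(sum(dir_x^2))
  ny <- sqrt(sum(dir_y^2))
  if (nx < 1e-300 || ny < 1e-300) stop("direction vectors must be nonzero")
  if (delta < 0) stop("delta must be >= 0")
  max(sum(dir_x * dir_y) / (nx * ny), delta)
}

# Gather neighbor machinery shared by propagation and filtering: for one
# offset, returns which of idx have an in-bounds neighbor already processed
# (T < t), the neighbor's linear index, and the B weight.
gather_neighbors <- function(idx, di, dj, n, m, Tm, t) {
  i <- (idx - 1L) %% n + 1L
  j <- (idx - 1L) %/% n + 1L
  ok <- i + di >= 1 & i + di <= n & j + dj >= 1 & j + dj <= m
  nb <- idx + di + dj * n
  nb[!ok] <- 1L                     # safe gather; masked out below
  proc <- ok & (Tm[nb] < t)
  list(nb = nb, proc = proc)
}

b_weights <- function(idx, nb, chans, D, gamma_i, gamma_d) {
  cd2 <- 0
  for (ch in chans) cd2 <- cd2 + (ch[idx] - ch[nb])^2
  exp(-gamma_i * cd2) * exp(-gamma_d * (D[idx] - D[nb])^2)
}

split_channels <- function(I) {
  if (is.matrix(I)) list(I) else lapply(seq_len(dim(I)[3]), function(ch) I[, , ch])
}

#' Propagate two-direction confidence values
#'
#' Processes unreliable pixels in increasing `T`. For each direction
#' `+grad(T)` and `-grad(T)` of pixel x, the confidence is the B*G-weighted,
#' normalized average of the already-processed 8-neighbors' confidences
#' (each neighbor contributing the slot aligned with the consuming
#' direction), decayed by one factor of `a` per propagation step, so that
#' under the reduction `gamma_i = gamma_d = 0`, `delta = 1` the confidence
#' equals `a^T(x)`. Reliable pixels keep the pair \[1, 0\].
#'
#' @param order an [compute_order_field()] result.
#' @param I guidance raster (matrix or RGB array) in \[0, 1\].
#' @param D working scalar raster in \[0, 1\].
#' @param a decay factor in \[0, 1).
#' @param gamma_i,gamma_d consistency bandwidths, >= 0.
#' @param delta direction floor, >= 0.
#' @return object of class `"confidence_field"`: matrices `c_plus`,
#'   `c_minus` in \[0, 1\] plus the parameters.
#' @export
propagate_confidence <- function(order, I, D, a = 0.8,
                                 gamma_i = 100, gamma_d = 1e4, delta = 0) {
  stopifnot(inherits(order, "order_field"))
  if (a < 0 || a >= 1) stop("a must lie in [0, 1)")
  if (gamma_i < 0 || gamma_d < 0 || delta < 0) stop("negative parameter")
  Tm <- order$T
  mask <- order$mask
  n <- nrow(Tm)
  m <- ncol(Tm)
  chans <- split_channels(I)
  gi <- order$gi
  gj <- order$gj
  cp <- matrix(0, n, m)
  cm <- matrix(0, n, m)
  cp[mask] <- 1
  maxT <- max(Tm)
  for (t in seq_len(maxT)) {
    idx <- which(Tm == t)
    nump <- denp <- numm <- denm <- numeric(length(idx))
    any_proc <- logical(length(idx))
    for (o in seq_len(nrow(offsets8))) {
      g <- gather_neighbors(idx, offsets8[o, 1], offsets8[o, 2], n, m, Tm, t)
      if (!any(g$proc)) next
      any_proc <- any_proc | g$proc
      B <- b_weights(idx, g$nb, chans, D, gamma_i, gamma_d)
      rel <- mask[g$nb]
      dt <- gi[idx] * gi[g$nb] + gj[idx] * gj[g$nb]
      G <- ifelse(rel, 1, pmax(abs(dt), delta))
      cyp <- ifelse(rel, 1, ifelse(dt >= 0, cp[g$nb], cm[g$nb]))
      cym <- ifelse(rel, 1, ifelse(dt <= 0, cp[g$nb], cm[g$nb]))
      w <- B * G
      w[!g$proc] <- 0
      nump <- nump + w * cyp
      numm <- numm + w * cym
      denp <- denp + w
      denm <- denm + w
    }
    if (!all(any_proc)) stop("pixel with no processed neighbor at its turn")
    cp[idx] <- ifelse(denp > 1e-300, a * nump / denp, 0)
    cm[idx] <- ifelse(denm > 1e-300, a * numm / denm, 0)
  }
  structure(list(c_plus = cp, c_minus = cm, a = a,
                 gamma_i = gamma_i, gamma_d = gamma_d, delta = delta),
            class = "confidence_field")
}

#' Ordered confidence-weighted filtering of unreliable pixels
#'
#' For `t = 1 .. max(T)`, each pixel with `T = t` is replaced by the
#' weighted mean of its already-processed 8-neighbors,
#' `w = B(x, y) * G(x, y) * C(y; toward x)`, where the consumed confidence
#' slot is the one aligned with the direction from y to x. Newly filtered
#' pixels participate in later steps; reliable pixels are returned
#' bit-identical. If every weight at a pixel vanishes (possible when
#' `delta = 0` annihilates all direction weights), the unweighted mean of
#' the processed neighbors is used so the pixel is still assigned.
#'
#' @param values scalar raster to filter (defaults to `D`).
#' @param order an [compute_order_field()] result.
#' @param conf a [propagate_confidence()] result.
#' @param I guidance raster.
#' @param D working raster used inside the B weight.
#' @param gamma_i,gamma_d,delta weight parameters (defaults from `conf`).
#' @return filtered raster, same shape as `values`.
#' @export
ordered_filter <- function(order, conf, I, D, values = D,
                           gamma_i = conf$gamma_i, gamma_d = conf$gamma_d,
                           delta = conf$delta) {
  stopifnot(inherits(order, "order_field"), inherits(conf, "confidence_field"))
  Tm <- order$T
  mask <- order$mask
  n <- nrow(Tm)
  m <- ncol(Tm)
  chans <- split_channels(I)
  gi <- order$gi
  gj <- order$gj
  cp <- conf$c_plus
  cm <- conf$c_minus
  out <- values
  maxT <- max(Tm)
  if (maxT == 0L) return(out)
  for (t in seq_len(maxT)) {
    idx <- which(Tm == t)
    wsum <- vsum <- psum <- numeric(length(idx))
    pcnt <- integer(length(idx))
    for (o in seq_len(nrow(offsets8))) {
      di <- offsets8[o, 1]
      dj <- offsets8[o, 2]
      g <- gather_neighbors(idx, di, dj, n, m, Tm, t)
      if (!any(g$proc)) next
      B <- b_weights(idx, g$nb, chans, D, gamma_i, gamma_d)
      rel <- mask[g$nb]
      len <- sqrt(di^2 + dj^2)
      # direction from y to x is (-di, -dj); pick y's aligned slot
      dy2x <- (gi[g$nb] * (-di) + gj[g$nb] * (-dj)) / len
      cy <- ifelse(rel, 1, ifelse(dy2x >= 0, cp[g$nb], cm[g$nb]))
      s <- ifelse(dy2x >= 0, 1, -1)
      cosv <- s * (gi[idx] * gi[g$nb] + gj[idx] * gj[g$nb])
      G <- ifelse(rel, 1, pmax(cosv, delta))
      w <- B * G * cy
      w[!g$proc] <- 0
      wsum <- wsum + w
      vsum <- vsum + w * ifelse(g$proc, out[g$nb], 0)
      pcnt <- pcnt + g$proc
      psum <- psum + ifelse(g$proc, out[g$nb], 0)
    }
    if (any(pcnt == 0L)) stop("pixel with no processed neighbor at its turn")
    # weight sums below 1e-300 are treated as vanished (denormal products
    # underflow to 0 and would otherwise yield 0/tiny = 0)
    out[idx] <- ifelse(wsum > 1e-300, vsum / wsum, psum / pcnt)
  }
  out
}

#' Restore a degraded image by reliability-guided ordered filtering
#'
#' End-to-end restoration path: upsample the low-resolution input, partition
#' pixels into reliable and unreliable by windowed max-min contrast (with
#' first-order zero-crossing refinement), compute the chessboard propagation
#' order and the two-direction confidence field, then filter the unreliable
#' pixels in order. For RGB inputs the reliability, ordering, confidence and
#' the scalar filter run on the luminance channel; the color channels are
#' then repainted with the same weight structure, using the filtered
#' luminance as the working raster.
#'
#' @param low low-resolution raster in \[0, 1\].
#' @param factor integer upsampling factor, >= 1.
#' @param init interpolation for the initial image (`"bilinear"` default;
#'   `"bicubic"` gives the prototype-map initialization).
#' @param tau,window_radius reliability parameters.
#' @param a,gamma_i,gamma_d,delta confidence/filter parameters.
#' @return list of class `"restored_image"`: `image` (restored raster),
#'   `d` (filtered luminance), `mask`, `order`, `conf`.
#' @export
restore_image <- function(low, factor = 2L, init = "bilinear",
                          tau = 0.1, window_radius = 1L,
                          a = 0.8, gamma_i = 100, gamma_d = 1e4, delta = 0) {
  up <- init_upsample(low, factor, init)
  D <- luminance(up)
  rmask <- detect_unreliable(D, window_radius, tau)
  rmask <- refine_with_edge_filter(rmask, D)
  if (!any(rmask$mask)) {
    # degenerate: nothing reliable; seed the propagation from the pixel with
    # the flattest window (first in raster-scan order)
    ex <- window_extrema(D, rmask$window_radius)
    rng <- ex$max - ex$min
    rmask$mask[which(rng == min(rng))[1]] <- TRUE
  }
  ord <- compute_order_field(rmask)
  conf <- propagate_confidence(ord, up, D, a, gamma_i, gamma_d, delta)
  dstar <- ordered_filter(ord, conf, up, D, values = D)
  if (is.matrix(up)) {
    img <- dstar
  } else {
    img <- up
    for (ch in seq_len(dim(up)[3])) {
      img[, , ch] <- ordered_filter(ord, conf, up, dstar, values = up[, , ch])
    }
  }
  structure(list(image = img, d = dstar, mask = rmask, order = ord, conf = conf),
            class = "restored_image")
}
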