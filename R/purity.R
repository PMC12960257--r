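# Two-channel membrane purity profiling: binarization, topological
# skeletonization, orthogonal intensity averaging and channel calibration.

# shift a matrix by (di, dj), zero-padding
.shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  si <- max(1, 1 - di):min(nr, nr - di)
  sj <- max(1, 1 - dj):min(nc, nc - dj)
  out[si + di, sj + dj] <- m[si, sj]
  out
}

#' Topological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels while preserving connectivity until
#' a one-pixel-wide skeleton remains.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  p <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  # neighbours in Zhang-Suen order P2..P9: N, NE, E, SE, S, SW, W, NW
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(offs, function(o) .shift_mat(p, o[1], o[2]))
      B <- Reduce(`+`, nb)
      seqn <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(1:8, function(k)
        (seqn[[k]] == 0) * (seqn[[k + 1]] == 1)))
      if (step == 1) {
        c1 <- nb[[1]] * nb[[3]] * nb[[5]] == 0
        c2 <- nb[[3]] * nb[[5]] * nb[[7]] == 0
      } else {
        c1 <- nb[[1]] * nb[[3]] * nb[[7]] == 0
        c2 <- nb[[1]] * nb[[5]] * nb[[7]] == 0
      }
      del <- p == 1 & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        p[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p > 0
}

# bilinear interpolation of matrix m at fractional (i, j)
.bilinear <- function(m, i, j) {
  i0 <- floor(i); j0 <- floor(j)
  i0 <- pmin(pmax(i0, 1), nrow(m) - 1)
  j0 <- pmin(pmax(j0, 1), ncol(m) - 1)
  di <- pmin(pmax(i - i0, 0), 1); dj <- pmin(pmax(j - j0, 0), 1)
  m[cbind(i0, j0)] * (1 - di) * (1 - dj) +
    m[cbind(i0 + 1, j0)] * di * (1 - dj) +
    m[cbind(i0, j0 + 1)] * (1 - di) * dj +
    m[cbind(i0 + 1, j0 + 1)] * di * dj
}

# mean channel intensities averaged orthogonally to the membrane tangent at
# each skeleton pixel; tangent from local PCA of skeleton coordinates
.skeleton_band_means <- function(channels, skel, halfWidth = 20,
                                 tangentRadius = 5) {
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(i = numeric(0), j = numeric(0)))
  steps <- seq(-halfWidth, halfWidth, by = 1)
  means <- matrix(NA_real_, nrow(idx), length(channels))
  for (k in seq_len(nrow(idx))) {
    p0 <- idx[k, ]
    near <- idx[abs(idx[, 1] - p0[1]) <= tangentRadius &
                abs(idx[, 2] - p0[2]) <= tangentRadius, , drop = FALSE]
    if (nrow(near) >= 2) {
      cv <- stats::cov(near)
      tang <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    } else tang <- c(1, 0)
    nrm <- c(-tang[2], tang[1])
    ii <- p0[1] + steps * nrm[1]
    jj <- p0[2] + steps * nrm[2]
    for (ch in seq_along(channels))
      means[k, ch] <- mean(.bilinear(channels[[ch]], ii, jj))
  }
  data.frame(i = idx[, 1], j = idx[, 2], means)
}

#' Channel calibration factors from a homogeneously mixed sample
#'
#' Uses an A-A sample (equal labelling of both dyes on the same membrane)
#' to calibrate the two detection channels: the factors are the mean
#' skeleton-band intensities per channel, so dividing by them equalizes
#' the channels.
#'
#' @param imgAA two-channel \linkS4class{Micrograph} of the A-A sample.
#' @param halfWidth px, orthogonal averaging half-width (20 px in the
#'   reference protocol, about 250 nm).
#' @param threshold binarization threshold; default: Otsu on the summed
#'   channels.
#' @return numeric length-2 calibration factors.
#' @export
calibrateChannels <- function(imgAA, halfWidth = 20, threshold = NULL) {
  stopifnot(length(imgAA@channels) == 2)
  comb <- imgAA@channels[[1]] + imgAA@channels[[2]]
  if (is.null(threshold)) {
    rng <- range(comb)
    threshold <- rng[1] + 0.5 * diff(rng)
    nc <- (comb - rng[1]) / max(diff(rng), 1e-12)
    threshold <- rng[1] + EBImage::otsu(EBImage::Image(nc)) * diff(rng)
  }
  skel <- skeletonize(comb > threshold)
  bm <- .skeleton_band_means(imgAA@channels, skel, halfWidth)
  if (nrow(bm) == 0) stop("empty skeleton in calibration image")
  factors <- c(mean(bm[[3]]), mean(bm[[4]]))
  factors / mean(factors)
}

#' Per-pixel membrane purity from a two-channel image
#'
#' Binarizes and skeletonizes the membrane, averages each channel
#' orthogonally to the local membrane tangent (half-width 20 px), rescales
#' the channels by the calibration factors, and computes the purity
#' \eqn{I_{c,488} / (I_{c,488} + I_{c,565})} per skeleton pixel (channel 1
#' is the 488 channel).
#'
#' @param img two-channel \linkS4class{Micrograph}.
#' @param calibration either a numeric length-2 factor vector or the A-A
#'   calibration \linkS4class{Micrograph}.
#' @param halfWidth px orthogonal averaging half-width.
#' @param threshold binarization threshold (default: Otsu on the summed
#'   channels).
#' @return a \linkS4class{PurityProfile}; empty profile for an empty
#'   skeleton.
#' @export
purityProfile <- function(img, calibration = c(1, 1), halfWidth = 20,
                          threshold = NULL) {
  stopifnot(length(img@channels) == 2)
  factors <- if (is(calibration, "Micrograph"))
    calibrateChannels(calibration, halfWidth) else as.numeric(calibration)
  stopifnot(length(factors) == 2, all(factors > 0))
  comb <- img@channels[[1]] + img@channels[[2]]
  if (is.null(threshold)) {
    rng <- range(comb)
    nc <- (comb - rng[1]) / max(diff(rng), 1e-12)
    threshold <- rng[1] + EBImage::otsu(EBImage::Image(nc)) * diff(rng)
  }
  skel <- skeletonize(comb > threshold)
  bm <- .skeleton_band_means(img@channels, skel, halfWidth)
  if (nrow(bm) == 0)
    return(new("PurityProfile",
               profile = data.frame(i = numeric(0), j = numeric(0),
                                    i1 = numeric(0), i2 = numeric(0),
                                    ic1 = numeric(0), ic2 = numeric(0),
                                    purity = numeric(0)),
               factors = factors))
  ic1 <- bm[[3]] / factors[1]
  ic2 <- bm[[4]] / factors[2]
  tot <- ic1 + ic2
  purity <- ifelse(tot > 0, ic1 / tot, NA_real_)
  new("PurityProfile",
      profile = data.frame(i = bm$i, j = bm$j, i1 = bm[[3]], i2 = bm[[4]],
                           ic1 = ic1, ic2 = ic2,
                           purity = pmin(pmax(purity, 0), 1)),
      factors = factors)
}
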