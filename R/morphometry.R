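# Morphometry of collapsed containers: template-matching segmentation,
# direct least-squares ellipse fits, circumference-preserving 3D
# reconstruction, tube widths, size distributions and composition/mass
# estimates.

#' Ramanujan's ellipse perimeter approximation
#'
#' \deqn{P(a, b) \approx \pi [3(a+b) - \sqrt{(3a+b)(a+3b)}]}
#' accurate to well below 0.1\% for axis ratios up to 4.
#'
#' @param a,b semi-axes (any consistent unit).
#' @return perimeter in the same unit.
#' @export
ramanujanPerimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

# normalized cross-correlation of an image against a centred disc template
# (dark disc on light background, the polarity of negative-stain TEM)
.ncc_disc <- function(I, radiusPx) {
  r <- max(2, round(radiusPx))
  side <- 2 * r + 1
  if (side %% 2 == 0) side <- side + 1
  cc <- (side + 1) / 2
  xy <- expand.grid(x = seq_len(side), y = seq_len(side))
  dd <- sqrt((xy$x - cc)^2 + (xy$y - cc)^2)
  # soft-edged dark disc (one-pixel linear ramp, matching the image blur)
  tmpl <- matrix(pmin(1, pmax(-1, 2 * (dd - r))), side, side)
  tmpl <- tmpl - mean(tmpl)
  n <- length(tmpl)
  ones <- matrix(1, side, side)
  num <- EBImage::filter2(I, tmpl)
  s1 <- EBImage::filter2(I, ones)
  s2 <- EBImage::filter2(I^2, ones)
  v <- pmax(s2 - s1^2 / n, 0)
  den <- sqrt(v * sum(tmpl^2))
  out <- num / (den + 1e-12)
  out[den < 1e-8] <- 0
  out
}

#' Segment containers in a micrograph by disc template matching
#'
#' Normalized cross-correlation against a monomer-sized dark-disc template
#' highlights the stained container rims; thresholding, morphological
#' closing and hole filling then produce the container regions, labelled by
#' connected components. Regions touching the image border are flagged and
#' should be excluded from statistics.
#'
#' @param img a \linkS4class{Micrograph} (single channel).
#' @param templateRadius template disc radius in nm (default: the 30-nm
#'   class monomer radius).
#' @param threshold NCC threshold (default 0.5).
#' @param minArea minimum region area in px.
#' @return list: \code{labels} (integer matrix, 0 = background),
#'   \code{regions} data.frame (id, area_px, touchesBorder), \code{ncc}
#'   response matrix.
#' @export
segmentContainers <- function(img, templateRadius = 14.25, threshold = 0.5,
                              minArea = 50) {
  I <- img@channels[[1]]
  if (length(I) == 0 || all(I == I[1]))
    return(list(labels = matrix(0L, nrow(I), ncol(I)),
                regions = data.frame(id = integer(0), area_px = numeric(0),
                                     touchesBorder = logical(0)),
                ncc = I * 0))
  rpx <- templateRadius / img@nmPerPixel
  ncc <- .ncc_disc(I, rpx)
  mask <- EBImage::Image(ncc >= threshold)
  # the closing radius bridges the monomer lattice spacing so that matched
  # monomer positions coalesce into one region per container
  bw <- 2 * round(1.3 * rpx) + 3
  mask <- EBImage::closing(mask, EBImage::makeBrush(bw, "disc"))
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  labm <- round(EBImage::imageData(lab))
  ids <- setdiff(sort(unique(as.vector(labm))), 0)
  if (length(ids) == 0)
    return(list(labels = labm * 0L,
                regions = data.frame(id = integer(0), area_px = numeric(0),
                                     touchesBorder = logical(0)),
                ncc = ncc))
  area <- tabulate(labm[labm > 0], nbins = max(ids))[ids]
  keep <- ids[area >= minArea]
  border <- unique(c(labm[1, ], labm[nrow(labm), ], labm[, 1],
                     labm[, ncol(labm)]))
  regions <- data.frame(id = keep, area_px = area[match(keep, ids)],
                        touchesBorder = keep %in% border)
  labm[!(labm %in% keep)] <- 0L
  list(labels = labm, regions = regions, ncc = ncc)
}

# contour of one labelled region (px coordinates, half-integer pixel centres)
.region_contour <- function(labels, id) {
  oc <- EBImage::ocontour(EBImage::Image(labels == id))
  if (length(oc) == 0) return(NULL)
  oc[[which.max(vapply(oc, nrow, 0L))]] + 0.5
}

# intensity-refined region contour: the NCC region localizes the container,
# the outline is then taken from the stain step (Otsu on intensity) within
# the region neighbourhood for an unbiased edge position
.region_contour_refined <- function(I, labels, id, bridgePx = 13) {
  rng <- range(I)
  nrm <- (I - rng[1]) / max(diff(rng), 1e-12)
  thr <- rng[1] + EBImage::otsu(EBImage::Image(nrm)) * diff(rng)
  nearBw <- 2 * bridgePx + 1 # reach past the outermost matched monomers
  near <- EBImage::dilate(EBImage::Image(labels == id),
                          EBImage::makeBrush(nearBw, "disc"))
  dark <- EBImage::Image(I < thr & as.matrix(near) > 0)
  bw <- 2 * (bridgePx %/% 2) + 1 # odd; bridges the monomer lattice spacing
  dark <- EBImage::fillHull(EBImage::closing(dark,
                                             EBImage::makeBrush(bw, "disc")))
  lab2 <- EBImage::bwlabel(dark)
  lm <- round(EBImage::imageData(lab2))
  if (max(lm) == 0) return(.region_contour(labels, id))
  main <- which.max(tabulate(lm[lm > 0]))
  .region_contour(lm, main)
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to an ellipse (the numerically stable
#' Fitzgibbon method) to a set of contour points and returns the ellipse
#' parameters.
#'
#' @param pts 2-column matrix of contour coordinates.
#' @return list: \code{rMinor}, \code{rMajor} (semi-axes, input units),
#'   \code{center}, \code{angle} (degrees), \code{perimeter} (Ramanujan),
#'   \code{ok} (FALSE for degenerate input, with NA axes).
#' @export
fitEllipse <- function(pts) {
  pts <- as.matrix(pts)
  bad <- list(rMinor = NA_real_, rMajor = NA_real_, center = c(NA, NA),
              angle = NA_real_, perimeter = NA_real_, ok = FALSE)
  if (nrow(pts) < 6) return(bad)
  x <- pts[, 1] - mean(pts[, 1]); y <- pts[, 2] - mean(pts[, 2])
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(bad)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ei <- eigen(M)
  ev <- Re(ei$vectors)
  cond <- 4 * ev[1, ] * ev[3, ] - ev[2, ]^2
  idx <- which(cond > 0)
  if (length(idx) == 0) return(bad)
  a1 <- ev[, idx[1]]
  coefs <- c(a1, Tm %*% a1) # A B C D E F
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; FF <- coefs[6]
  M33 <- matrix(c(A, B / 2, B / 2, C), 2)
  ctr <- tryCatch(-0.5 * solve(M33, c(D, E)), error = function(e) NULL)
  if (is.null(ctr)) return(bad)
  Fc <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
    D * ctr[1] + E * ctr[2] + FF
  lam <- eigen(M33, symmetric = TRUE)
  semis <- suppressWarnings(sqrt(-Fc / lam$values))
  if (any(!is.finite(semis))) return(bad)
  ord <- order(semis, decreasing = TRUE)
  rMajor <- semis[ord[1]]; rMinor <- semis[ord[2]]
  angle <- atan2(lam$vectors[2, ord[1]], lam$vectors[1, ord[1]]) * 180 / pi
  list(rMinor = rMinor, rMajor = rMajor,
       center = ctr + c(mean(pts[, 1]), mean(pts[, 2])),
       angle = angle, perimeter = ramanujanPerimeter(rMajor, rMinor),
       ok = TRUE)
}

#' Reconstruct 3D diameters from a collapsed 2D ellipse
#'
#' Flattening preserves circumference: the collapsed width along each axis
#' equals half the corresponding 3D circumference. The minor diameter is
#' \eqn{d_{minor} = 4 r_{minor,2D} / \pi} (equivalently \eqn{2 d_{2D}/\pi});
#' the major diameter solves Ramanujan's perimeter formula
#' \eqn{P(d_{major}/2, d_{minor}/2) = 4 r_{major,2D}} by bracketed
#' root finding, assuming equal minor diameters (prolate spheroid).
#'
#' @param rMinor2D,rMajor2D fitted 2D semi-axes in nm.
#' @return list: \code{dMinor}, \code{dMajor} (nm), aspect ratio \code{a},
#'   \code{flag} (\code{"ok"}, or \code{"inconsistent"} when the major
#'   width is smaller than a sphere of the given minor diameter would
#'   allow, in which case dMajor is set to dMinor).
#' @examples
#' collapseTo3d(pi * 50, pi * 50) # collapsed sphere of diameter 200
#' @export
collapseTo3d <- function(rMinor2D, rMajor2D) {
  stopifnot(rMinor2D > 0, rMajor2D > 0)
  dMinor <- 4 * rMinor2D / pi
  target <- 4 * rMajor2D # half the great-ellipse circumference, times 2
  f <- function(dMajor) ramanujanPerimeter(dMajor / 2, dMinor / 2) - target
  if (f(dMinor) > 0) {
    return(list(dMinor = dMinor, dMajor = dMinor, a = 1,
                flag = "inconsistent"))
  }
  upper <- max(8 * rMajor2D / 3.9, dMinor * 1.01)
  while (f(upper) < 0) upper <- upper * 2
  root <- uniroot(f, c(dMinor, upper), tol = 1e-6 * dMinor)
  list(dMinor = dMinor, dMajor = root$root, a = root$root / dMinor,
       flag = "ok")
}

#' Tube diameter from a flattened width
#'
#' A collapsed tube's width equals half its circumference, so
#' \eqn{d = 2 w_{2D} / \pi}.
#'
#' @param width2D flattened tube width in nm.
#' @return tube diameter in nm.
#' @export
tubeDiameter <- function(width2D) {
  stopifnot(all(width2D > 0))
  2 * width2D / pi
}

#' Full morphometry of a container micrograph
#'
#' Segmentation, per-region ellipse fit and 3D reconstruction. Regions
#' touching the border or failing the ellipse fit carry quality flags.
#'
#' @inheritParams segmentContainers
#' @param minPixels regions smaller than this are flagged and skipped.
#' @return data.frame, one row per region: id, r_minor_2D_nm, r_major_2D_nm,
#'   perimeter_2D_nm, d_minor_nm, d_major_nm, aspect_ratio, flags.
#' @export
measureContainers <- function(img, templateRadius = 14.25, threshold = 0.5,
                              minPixels = 20) {
  seg <- segmentContainers(img, templateRadius, threshold)
  px <- img@nmPerPixel
  rows <- lapply(seq_len(nrow(seg$regions)), function(i) {
    id <- seg$regions$id[i]
    rec <- data.frame(id = id, r_minor_2D_nm = NA_real_,
                      r_major_2D_nm = NA_real_, perimeter_2D_nm = NA_real_,
                      d_minor_nm = NA_real_, d_major_nm = NA_real_,
                      aspect_ratio = NA_real_, flags = "")
    flags <- character(0)
    if (seg$regions$touchesBorder[i]) flags <- c(flags, "border")
    if (seg$regions$area_px[i] < minPixels) {
      rec$flags <- paste(c(flags, "tooSmall"), collapse = ";")
      return(rec)
    }
    ct <- .region_contour_refined(img@channels[[1]], seg$labels, id,
                                  bridgePx = 2 * round(1.3 * templateRadius /
                                                         img@nmPerPixel) + 3)
    fit <- if (is.null(ct)) list(ok = FALSE) else fitEllipse(ct * px)
    if (!isTRUE(fit$ok)) {
      rec$flags <- paste(c(flags, "degenerateContour"), collapse = ";")
      return(rec)
    }
    c3 <- collapseTo3d(fit$rMinor, fit$rMajor)
    if (c3$flag != "ok") flags <- c(flags, c3$flag)
    rec$r_minor_2D_nm <- fit$rMinor
    rec$r_major_2D_nm <- fit$rMajor
    rec$perimeter_2D_nm <- fit$perimeter
    rec$d_minor_nm <- c3$dMinor
    rec$d_major_nm <- c3$dMajor
    rec$aspect_ratio <- c3$a
    rec$flags <- paste(flags, collapse = ";")
    rec
  })
  if (length(rows) == 0)
    return(data.frame(id = integer(0), r_minor_2D_nm = numeric(0),
                      r_major_2D_nm = numeric(0), perimeter_2D_nm = numeric(0),
                      d_minor_nm = numeric(0), d_major_nm = numeric(0),
                      aspect_ratio = numeric(0), flags = character(0)))
  do.call(rbind, rows)
}

#' Mean, SD and kernel density estimate of a diameter sample
#'
#' @param diameters numeric vector, nm (n >= 2 for an SD).
#' @return list: \code{mean}, \code{sd}, \code{n}, \code{kde} data.frame
#'   (diameter_nm, density) using a Gaussian kernel with Silverman's
#'   bandwidth.
#' @export
distributionStats <- function(diameters) {
  diameters <- diameters[is.finite(diameters)]
  n <- length(diameters)
  if (n < 2) {
    warning("fewer than 2 values: sd undefined")
    return(list(mean = mean(diameters), sd = NA_real_, n = n,
                kde = data.frame(diameter_nm = numeric(0),
                                 density = numeric(0))))
  }
  kd <- stats::density(diameters, bw = "nrd0")
  list(mean = mean(diameters), sd = stats::sd(diameters), n = n,
       kde = data.frame(diameter_nm = kd$x, density = kd$y))
}

# surface area of a prolate spheroid with equatorial diameter dMinor and
# polar diameter dMajor (dMajor >= dMinor)
.spheroid_area <- function(dMajor, dMinor) {
  a <- dMinor / 2; c <- dMajor / 2
  if (abs(c - a) < 1e-9 * c) return(4 * pi * a^2)
  e <- sqrt(1 - (a / c)^2)
  2 * pi * a^2 * (1 + (c / (a * e)) * asin(e))
}

#' Estimate monomer count and mass of a container
#'
#' The container surface is modelled as a prolate spheroid; dividing its
#' area by the hexagonal-packing footprint of one monomer
#' (\eqn{(\sqrt3/2) s_{mid}^2}) gives the monomer count, and the count
#' times the monomer mass gives the container mass. The default monomer
#' mass is the 30-nm class scaffold length (2873 bases) times 650 Da per
#' base pair.
#'
#' @param dMajor,dMinor container diameters in nm.
#' @param monomerFootprint nm^2 (default: 30-nm class, s_mid = 37.7 nm).
#' @param monomerMass Da.
#' @return list: \code{nMonomers}, \code{mass_Da}, \code{mass_GDa},
#'   \code{area_nm2}.
#' @export
estimateComposition <- function(dMajor, dMinor,
                                monomerFootprint = sqrt(3) / 2 * 37.7^2,
                                monomerMass = 2873 * 650) {
  stopifnot(dMajor > 0, dMinor > 0, dMajor >= dMinor,
            monomerFootprint > 0, monomerMass > 0)
  area <- .spheroid_area(dMajor, dMinor)
  n <- area / monomerFootprint
  list(nMonomers = n, mass_Da = n * monomerMass,
       mass_GDa = n * monomerMass / 1e9, area_nm2 = area)
}
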