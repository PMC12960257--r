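# Seeded synthetic-data generators: collapsed-container micrographs,
# monomer shell layouts (sphere / tube / sheet) and two-channel membrane
# images. All generators are pure functions of their arguments including
# the seed.

# run code with a local, restored RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Render a synthetic micrograph of collapsed containers
#'
#' Containers collapse flat on the grid; their outlines are ellipses whose
#' semi-axes follow the circumference-preserving forward model
#' (\eqn{r_{minor,2D} = \pi d_{minor}/4}, \eqn{r_{major,2D} = P(d_{major}/2,
#' d_{minor}/2)/4}). Objects are rendered with a mid-grey interior and a
#' darker rim (the polarity of negative-stain TEM), blurred and overlaid
#' with Gaussian noise.
#'
#' @param trueDiameters data.frame with columns \code{d_major}, \code{d_minor}
#'   (nm), one row per container.
#' @param nmPerPixel scale.
#' @param imageSize px (square image).
#' @param seed RNG seed (placement angles/positions and noise).
#' @param background,interiorLevel,monomerLevel,rimLevel grey levels in
#'   [0, 1]; the interior is stippled with monomer-sized discs at
#'   \code{monomerLevel} on an \code{interiorLevel} background, emulating
#'   the packed-barrel texture of a collapsed membrane.
#' @param rimWidthNm rim thickness (default 18, the barrel height).
#' @param monomerRadiusNm radius of the stippled monomer discs.
#' @param monomerSpacingNm centre spacing of the stipple lattice.
#' @param noiseSd additive Gaussian noise SD.
#' @param maxTries placement attempts per object before failing.
#' @return list: \code{img} (\linkS4class{Micrograph}), \code{truth}
#'   data.frame (object id, true diameters, implied 2D radii, center,
#'   angle).
#' @export
renderCollapsedContainers <- function(trueDiameters, nmPerPixel, imageSize,
                                      seed, background = 0.85,
                                      interiorLevel = 0.6,
                                      monomerLevel = 0.35, rimLevel = 0.12,
                                      rimWidthNm = 18, monomerRadiusNm = 14.25,
                                      monomerSpacingNm = 37.7,
                                      noiseSd = 0.03, maxTries = 2000) {
  .with_seed(seed, {
    n <- nrow(trueDiameters)
    img <- matrix(background, imageSize, imageSize)
    truth <- NULL
    if (n > 0) {
      rMin2D <- pi * trueDiameters$d_minor / 4 / nmPerPixel
      rMaj2D <- ramanujanPerimeter(trueDiameters$d_major / 2,
                                   trueDiameters$d_minor / 2) / 4 / nmPerPixel
      placed <- matrix(numeric(0), 0, 3) # cx, cy, bounding radius
      centers <- matrix(NA_real_, n, 2)
      angles <- numeric(n)
      for (o in order(rMaj2D, decreasing = TRUE)) {
        rb <- rMaj2D[o] + 3
        if (2 * (rb + 3) >= imageSize)
          stop("cannot place all containers without overlap; ",
               "reduce n or diameters, or enlarge the image")
        ok <- FALSE
        for (t in seq_len(maxTries)) {
          cx <- runif(1, rb + 2, imageSize - rb - 1)
          cy <- runif(1, rb + 2, imageSize - rb - 1)
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                  placed[, 3] + rb + 30)) {
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("cannot place all containers without overlap; ",
               "reduce n or diameters, or enlarge the image")
        placed <- rbind(placed, c(cx, cy, rb))
        centers[o, ] <- c(cx, cy)
        angles[o] <- runif(1, 0, pi)
        # rasterize ellipse with rim
        th <- angles[o]
        rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
        ii <- max(1, floor(cx - rb)):min(imageSize, ceiling(cx + rb))
        jj <- max(1, floor(cy - rb)):min(imageSize, ceiling(cy + rb))
        gg <- expand.grid(i = ii, j = jj)
        rel <- cbind(gg$i - cx, gg$j - cy) %*% rot
        q <- sqrt((rel[, 1] / rMaj2D[o])^2 + (rel[, 2] / rMin2D[o])^2)
        wRel <- (rimWidthNm / nmPerPixel) / sqrt(rMaj2D[o] * rMin2D[o])
        inside <- q <= 1
        rim <- q <= 1 & q > 1 - wRel
        lin <- cbind(gg$i, gg$j)
        img[lin[inside, , drop = FALSE]] <- interiorLevel
        # stipple the interior with a hexagonal carpet of monomer discs at
        # the lattice spacing (barrel plus linker gap)
        rM <- monomerRadiusNm / nmPerPixel
        sp <- monomerSpacingNm / nmPerPixel
        hx <- seq(-rMaj2D[o], rMaj2D[o], by = sp)
        hy <- seq(-rMin2D[o], rMin2D[o], by = sp * sqrt(3) / 2)
        for (row in seq_along(hy)) {
          cxs <- hx + (row %% 2) * sp / 2
          keep <- (cxs / rMaj2D[o])^2 + (hy[row] / rMin2D[o])^2 < 0.96
          for (mx in cxs[keep]) {
            mc <- c(cx, cy) + c(mx, hy[row]) %*% t(rot)
            di <- max(1, floor(mc[1] - rM)):min(imageSize, ceiling(mc[1] + rM))
            dj <- max(1, floor(mc[2] - rM)):min(imageSize, ceiling(mc[2] + rM))
            dg <- expand.grid(i = di, j = dj)
            dsel <- (dg$i - mc[1])^2 + (dg$j - mc[2])^2 <= rM^2
            img[cbind(dg$i, dg$j)[dsel, , drop = FALSE]] <- monomerLevel
          }
        }
        img[lin[rim, , drop = FALSE]] <- rimLevel
      }
      truth <- data.frame(id = seq_len(n),
                          d_major_nm = trueDiameters$d_major,
                          d_minor_nm = trueDiameters$d_minor,
                          r_major_2D_nm = rMaj2D * nmPerPixel,
                          r_minor_2D_nm = rMin2D * nmPerPixel,
                          cx_px = centers[, 1], cy_px = centers[, 2],
                          angle_rad = angles)
    } else {
      truth <- data.frame(id = integer(0), d_major_nm = numeric(0),
                          d_minor_nm = numeric(0), r_major_2D_nm = numeric(0),
                          r_minor_2D_nm = numeric(0), cx_px = numeric(0),
                          cy_px = numeric(0), angle_rad = numeric(0))
    }
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 1))
    img <- img + matrix(rnorm(length(img), 0, noiseSd), nrow(img))
    list(img = micrograph(img, nmPerPixel), truth = truth)
  })
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# unit icosahedron: vertices and the 20 faces found from the edge length
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  d <- as.matrix(stats::dist(v))
  edge <- min(d[d > 0])
  adj <- abs(d - edge) < 1e-9
  faces <- NULL
  for (i in 1:10) for (j in which(adj[i, ] & seq_len(12) > i))
    for (k in which(adj[i, ] & adj[j, ] & seq_len(12) > j))
      faces <- rbind(faces, c(i, j, k))
  # consistent outward (counter-clockwise) orientation; required so chiral
  # lattice classes tile identically on every face
  for (f in seq_len(nrow(faces))) {
    tri <- faces[f, ]
    nrm <- crossprod_3(v[tri[2], ] - v[tri[1], ], v[tri[3], ] - v[tri[1], ])
    if (sum(nrm * colMeans(v[tri, ])) < 0) faces[f, ] <- tri[c(1, 3, 2)]
  }
  list(v = v, f = faces)
}

# icosadeltahedral sphere vertices for triangulation numbers T = h^2+hk+k^2
.icosasphere_points <- function(h, k) {
  ico <- .icosahedron()
  omega <- complex(real = cos(pi / 3), imaginary = sin(pi / 3))
  z1 <- h + k * omega
  z2 <- z1 * omega
  rng <- (-(h + k)):(h + k + 1)
  g <- as.vector(outer(rng, rng, function(i, j) i + j * omega))
  A <- matrix(c(Re(z1), Im(z1), Re(z2), Im(z2)), 2)
  bc <- solve(A) %*% rbind(Re(g), Im(g))
  b <- bc[1, ]; cc <- bc[2, ]; a <- 1 - b - cc
  keep <- a >= -1e-9 & b >= -1e-9 & cc >= -1e-9
  a <- a[keep]; b <- b[keep]; cc <- cc[keep]
  pts <- NULL
  for (f in seq_len(nrow(ico$f))) {
    ABC <- ico$v[ico$f[f, ], ]
    P <- cbind(a, b, cc) %*% ABC
    P <- P / sqrt(rowSums(P^2))
    pts <- rbind(pts, P)
  }
  pts <- pts[!duplicated(round(pts, 6)), , drop = FALSE]
  pts
}

# choose (h, k) whose site count 10T+2 is closest to the requested size
.best_hk <- function(nSites) {
  best <- c(1, 0); bestErr <- Inf
  for (h in 1:12) for (k in 0:h) {
    Tn <- h^2 + h * k + k^2
    err <- abs(10 * Tn + 2 - nSites)
    if (err < bestErr) {
      bestErr <- err
      best <- c(h, k)
    }
  }
  best
}

#' Generate a synthetic monomer shell layout
#'
#' \code{sphere}: icosadeltahedral triangulation (12 five-coordinated
#' disclinations) with the (h, k) class chosen so the site count 10T+2 best
#' matches \code{size}; \code{tube}: rolled hexagonal lattice,
#' \code{size = c(nAround, nRings)}; \code{sheet}: planar hexagonal patch,
#' \code{size = c(nx, ny)}. Edge lengths are scaled so the mean
#' nearest-neighbour distance equals \code{spacing}. Optional random
#' vacancies emulate missing monomers.
#'
#' @param kind \code{"sphere"}, \code{"tube"} or \code{"sheet"}.
#' @param spacing monomer centre spacing in nm.
#' @param size see above (sphere: approximate site count).
#' @param nVacancies sites to delete at random.
#' @param seed RNG seed (vacancy choice).
#' @param monomerRadius nm, stored in the layout.
#' @return a \linkS4class{MonomerLayout}; spheres and tubes carry a
#'   \code{radius} attribute (nm).
#' @export
makeShell <- function(kind = c("sphere", "tube", "sheet"), spacing = 37.7,
                      size = 72, nVacancies = 0, seed = 1,
                      monomerRadius = 14.25) {
  kind <- match.arg(kind)
  radius <- NA_real_
  if (kind == "sphere") {
    hk <- .best_hk(size[1])
    P <- .icosasphere_points(hk[1], hk[2])
    d <- as.matrix(stats::dist(P))
    diag(d) <- Inf
    nnd <- mean(apply(d, 1, min))
    P <- P * spacing / nnd
    radius <- spacing / nnd
  } else if (kind == "tube") {
    if (length(size) < 2) stop("tube size must be c(nAround, nRings)")
    nA <- size[1]; nR <- size[2]
    if (nA < 3) stop("incompatible size/spacing: need >= 3 around")
    R <- spacing * nA / (2 * pi)
    radius <- R
    P <- NULL
    for (j in 0:(nR - 1)) {
      ang <- 2 * pi * (seq_len(nA) - 1 + 0.5 * (j %% 2)) / nA
      P <- rbind(P, cbind(R * cos(ang), R * sin(ang),
                          j * spacing * sqrt(3) / 2))
    }
  } else {
    if (length(size) < 2) size <- c(size, size)
    nx <- size[1]; ny <- size[2]
    gg <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
    P <- cbind(spacing * (gg$i + 0.5 * (gg$j %% 2)),
               spacing * sqrt(3) / 2 * gg$j, 0)
  }
  if (nVacancies > 0) {
    drop <- .with_seed(seed, sample(nrow(P), nVacancies))
    P <- P[-drop, , drop = FALSE]
  }
  out <- monomerLayout(P, monomerRadius = monomerRadius,
                       cutoff = 1.35 * spacing)
  attr(out, "radius") <- radius
  attr(out, "kind") <- kind
  out
}

#' Generate a synthetic two-channel membrane image
#'
#' A smooth open membrane curve crosses the image; arcs carry domain
#' identities (A or B, or AB for a homogeneous mix). Channel 1 images the
#' 488 dye (label of B), channel 2 the 565 dye (label of A). Per-channel
#' gains, cross-channel bleed-through and Gaussian noise emulate detector
#' mismatch.
#'
#' @param domains data.frame with columns \code{fraction} (summing to 1)
#'   and \code{type} in A/B/AB, in order along the membrane.
#' @param gains numeric length-2 channel gains.
#' @param bleed fraction of each dye's signal leaking into the other
#'   channel.
#' @param imageSize px.
#' @param nmPerPixel scale.
#' @param thickness membrane thickness in px.
#' @param noiseSd additive noise SD.
#' @param seed RNG seed (curve shape and noise).
#' @return list: \code{img} (two-channel \linkS4class{Micrograph}),
#'   \code{truth} data.frame (arc-length fraction, px position, type).
#' @export
makeTwoChannelMembrane <- function(domains = data.frame(
                                     fraction = c(0.5, 0.5),
                                     type = c("A", "B")),
                                   gains = c(1, 1), bleed = 0,
                                   imageSize = 192, nmPerPixel = 12.5,
                                   thickness = 5, noiseSd = 0.01, seed = 1) {
  stopifnot(all(gains > 0), abs(sum(domains$fraction) - 1) < 1e-9)
  .with_seed(seed, {
    m <- imageSize
    tt <- seq(0, 1, length.out = 4 * m)
    amp <- m / 6
    ph <- runif(1, 0, 2 * pi)
    xs <- 6 + tt * (m - 12)
    ys <- m / 2 + amp * sin(2 * pi * 1.5 * tt + ph)
    arc <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
    arc <- arc / max(arc)
    cum <- cumsum(domains$fraction)
    typeAt <- function(t) domains$type[which(t <= cum + 1e-12)[1]]
    types <- vapply(arc, typeAt, "")
    # dye signals per curve sample: s488 from B, s565 from A; AB mixes both
    s488 <- ifelse(types == "B", 1, ifelse(types == "AB", 0.5, 0))
    s565 <- ifelse(types == "A", 1, ifelse(types == "AB", 0.5, 0))
    ch1 <- matrix(0, m, m); ch2 <- matrix(0, m, m)
    half <- ceiling(thickness / 2)
    for (k in seq_along(xs)) {
      ii <- max(1, round(xs[k]) - half):min(m, round(xs[k]) + half)
      jj <- max(1, round(ys[k]) - half):min(m, round(ys[k]) + half)
      gg <- as.matrix(expand.grid(i = ii, j = jj))
      sel <- gg[(gg[, 1] - xs[k])^2 + (gg[, 2] - ys[k])^2 <=
                  (thickness / 2)^2, , drop = FALSE]
      ch1[sel] <- pmax(ch1[sel], s488[k])
      ch2[sel] <- pmax(ch2[sel], s565[k])
    }
    # bleed-through, then gains, then blur and noise
    b1 <- ch1 + bleed * ch2
    b2 <- ch2 + bleed * ch1
    b1 <- as.matrix(EBImage::gblur(EBImage::Image(gains[1] * b1), 1))
    b2 <- as.matrix(EBImage::gblur(EBImage::Image(gains[2] * b2), 1))
    b1 <- b1 + matrix(rnorm(length(b1), 0, noiseSd), m)
    b2 <- b2 + matrix(rnorm(length(b2), 0, noiseSd), m)
    truth <- data.frame(t = arc, x_px = xs, y_px = ys, type = types)
    list(img = micrograph(list(b1, b2), nmPerPixel,
                          channelNames = c("ch488", "ch565")),
         truth = truth)
  })
}
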