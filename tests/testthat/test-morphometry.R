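# Ellipse fitting, collapsed-projection 3D reconstruction, tube widths,
# size distributions and composition estimates.

test_that("direct least-squares ellipse fit recovers rendered shapes", {
  th <- seq(0, 2 * pi, length.out = 720)[-1]
  # circle of radius 100
  circ <- cbind(100 * cos(th) + 3, 100 * sin(th) - 7)
  f <- fitEllipse(circ)
  expect_equal(f$rMajor, 100, tolerance = 1e-6)
  expect_equal(f$rMinor, 100, tolerance = 1e-6)
  # 2:1 ellipse, rotated
  rot <- matrix(c(cos(0.6), sin(0.6), -sin(0.6), cos(0.6)), 2)
  ell <- cbind(120 * cos(th), 60 * sin(th)) %*% rot
  f2 <- fitEllipse(ell)
  expect_equal(f2$rMajor / f2$rMinor, 2, tolerance = 0.02)
  # rasterized circle: both semi-axes within a pixel
  xy <- expand.grid(x = 1:260, y = 1:260)
  m <- matrix(sqrt((xy$x - 130)^2 + (xy$y - 130)^2) <= 100, 260, 260)
  ct <- EBImage::ocontour(EBImage::Image(m))[[1]] + 0.5
  f3 <- fitEllipse(ct)
  expect_equal(f3$rMajor, 100, tolerance = 1 / 100)
  expect_equal(f3$rMinor, 100, tolerance = 1 / 100)
  expect_false(fitEllipse(cbind(1:10, 2 * (1:10)))$ok)
})

test_that("Ramanujan perimeter agrees with quadrature to 0.1% for a in
           [1, 4]", {
  for (a in c(1, 1.5, 2, 3, 4)) {
    b <- 1
    expect_equal(ramanujanPerimeter(a, b), perimeterQuadrature(a, b),
                 tolerance = 1e-3)
  }
  # and the fitted-ellipse perimeter inherits that accuracy
  th <- seq(0, 2 * pi, length.out = 720)[-1]
  f <- fitEllipse(cbind(200 * cos(th), 80 * sin(th)))
  expect_equal(f$perimeter, perimeterQuadrature(200, 80), tolerance = 1e-3)
})

test_that("collapse to 3D inverts the flattening model", {
  # collapsed sphere: both widths pi * r
  r <- collapseTo3d(pi * 50, pi * 50)
  expect_equal(r$dMinor, 200)
  expect_equal(r$dMajor, 200, tolerance = 1e-6)
  expect_equal(r$a, 1, tolerance = 1e-6)
  # 4 r / pi inversion
  expect_equal(collapseTo3d(78.53982, 78.53982)$dMinor, 100,
               tolerance = 1e-6)
  # forward-backward consistency over the physical range, 0.1%
  for (dMinor in c(100, 400, 900, 1500)) for (a in c(1, 1.5, 2.5, 4)) {
    dMajor <- a * dMinor
    rMin2D <- pi * dMinor / 4
    rMaj2D <- perimeterQuadrature(dMajor / 2, dMinor / 2) / 4
    back <- collapseTo3d(rMin2D, rMaj2D)
    expect_equal(back$dMinor, dMinor, tolerance = 1e-3)
    expect_equal(back$dMajor, dMajor, tolerance = 1.5e-3)
  }
  # inconsistent widths flagged, dMajor clamped to dMinor
  bad <- collapseTo3d(pi * 50, pi * 30)
  expect_equal(bad$flag, "inconsistent")
  expect_equal(bad$dMajor, bad$dMinor)
})

test_that("tube diameters scale linearly with flattened width", {
  expect_equal(tubeDiameter(pi * 50), 100)
  w <- c(100, 200, 400)
  expect_equal(tubeDiameter(2 * w), 2 * tubeDiameter(w))
  expect_error(tubeDiameter(-1))
})

test_that("distribution statistics and KDE behave as defined", {
  s <- distributionStats(c(100, 100, 100))
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 0)
  s2 <- distributionStats(c(90, 110))
  expect_equal(s2$mean, 100)
  expect_equal(s2$sd, sd(c(90, 110)))
  set.seed(2)
  s3 <- distributionStats(rnorm(400, 500, 60))
  dx <- diff(s3$kde$diameter_nm[1:2])
  expect_equal(sum(s3$kde$density) * dx, 1, tolerance = 1e-3)
  expect_warning(distributionStats(42), "fewer than 2")
})

test_that("composition estimates follow spheroid area geometry", {
  fp <- sqrt(3) / 2 * 37.7^2
  # degenerate check: a sphere whose area is one footprint -> one monomer
  d1 <- sqrt(fp / pi)
  expect_equal(estimateComposition(d1, d1)$nMonomers, 1, tolerance = 1e-9)
  # doubling the diameter quadruples the count
  c1 <- estimateComposition(400, 400)$nMonomers
  c2 <- estimateComposition(800, 800)$nMonomers
  expect_equal(c2 / c1, 4, tolerance = 1e-9)
  # prolate area matches the quadrature oracle within 0.5%
  for (dd in list(c(400, 200), c(1200, 1100), c(900, 300))) {
    expect_equal(estimateComposition(dd[1], dd[2])$area_nm2,
                 spheroidAreaQuadrature(dd[1], dd[2]), tolerance = 5e-3)
  }
  # mass scales with the monomer mass
  expect_equal(estimateComposition(500, 400, monomerMass = 1e6)$mass_Da,
               estimateComposition(500, 400, monomerMass = 2e6)$mass_Da / 2)
})

test_that("segmentation finds rendered containers and flags the border", {
  td <- data.frame(d_major = rep(200, 5), d_minor = rep(150, 5))
  syn <- renderCollapsedContainers(td, nmPerPixel = 3.5, imageSize = 760,
                                   seed = 8)
  seg <- segmentContainers(syn$img)
  expect_equal(nrow(seg$regions), 5)
  expect_true(all(!seg$regions$touchesBorder))
  # blank image: no regions
  blank <- micrograph(matrix(0.85, 200, 200), 3)
  expect_equal(nrow(segmentContainers(blank)$regions), 0)
  m <- measureContainers(syn$img)
  ok <- m[m$flags == "", ]
  expect_equal(nrow(ok), 5)
  expect_true(all(abs(ok$d_minor_nm / 150 - 1) < 0.03))
})
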