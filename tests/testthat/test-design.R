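# Worm-like-chain strand lengths, cone geometry, design search, variants
# and diameter calibration.

test_that("WLC end-to-end length matches the closed form limits and values", {
  expect_equal(wlcEndToEnd(0), 0)
  # frozen direct evaluation of the closed form at 16 nt x 0.63 nm
  expect_equal(wlcEndToEnd(16 * 0.63), 5.0739949, tolerance = 1e-6)
  # asymptotic ideal-chain limit: R_rms -> sqrt(2 Lp Lc)
  Lc <- 1e5
  expect_equal(wlcEndToEnd(Lc) / sqrt(2 * 1.5 * Lc), 1, tolerance = 1e-3)
  # strictly increasing, bounded above by the contour length
  x <- seq(0.1, 40, by = 0.1)
  y <- wlcEndToEnd(x)
  expect_true(all(diff(y) > 0))
  expect_true(all(y <= x))
  expect_error(wlcEndToEnd(-1), "non-negative")
})

test_that("strand length combines WLC ssDNA part and half the sticky duplex", {
  # frozen: wlc(5.04) + 0.5 * 6 * 0.34
  expect_equal(strandLength(domainSpec(flexLen = 8, stickySeq = "ATGCAT")),
               4.3027286, tolerance = 1e-6)
  d0 <- domainSpec(flexLen = 2, stickySeq = "GTAC")
  expect_equal(strandLength(d0),
               wlcEndToEnd(2 * 0.63) + 0.5 * 4 * 0.34)
  # strictly larger l_strand with increasing curvature domain
  ls <- vapply(0:52, function(n)
    strandLength(domainSpec(4, n, "ATGCAT")), 0)
  expect_true(all(diff(ls) > 0))
})

test_that("sticky validation accepts palindromes only", {
  expect_true(validateSticky("GCGC"))
  expect_true(validateSticky("GTAC"))
  expect_true(validateSticky("ATGCAT"))
  expect_false(validateSticky("AAAA"))
  expect_false(validateSticky("ATGCA")) # odd length
  expect_error(validateSticky("ATXGCA"), "non-DNA")
})

test_that("cone angle is zero for symmetric monomers and invertible", {
  planar <- dipidr:::.design_from_nT(0L, 4L, "ATGCAT", monomerGeometry())
  expect_equal(coneAngleNaive(planar), 0)
  expect_warning(predictRadiusNaive(planar), "planar")
  # doubling alpha at fixed arc halves the radius
  for (v in c("XS", "M")) {
    d <- generateVariant(v)
    aRad <- coneAngleNaive(d) * pi / 180
    r <- predictRadiusNaive(d)
    expect_equal(r * aRad / (r * (2 * aRad) / 2), 2 * r * aRad / (2 * r * aRad))
    # exact inverse round trip on the design's own diameter
    expect_equal(invertDiameterToAngle(2 * r, d), coneAngleNaive(d),
                 tolerance = 1e-9)
    expect_equal(angleError(2 * r, d), 0, tolerance = 1e-9)
  }
  # larger measured diameter than designed gives a positive angle error
  d <- generateVariant("S")
  expect_gt(angleError(diameterNaive(d) * 1.3, d), 0)
})

test_that("curvature-length search hits targets with smaller-nT tie-break", {
  # fixed point: the achievable diameter of an nT = 10 design returns nT = 10
  ref <- dipidr:::.design_from_nT(10L, 4L, "ATGCAT", monomerGeometry())
  sol <- solveCurvatureLength(diameterNaive(ref))
  expect_equal(unique(strandTable(sol)$curvature_len[
    strandTable(sol)$face == "outer"]), 10L)
  # targets between two achievable diameters go to the closer one
  d10 <- diameterNaive(ref)
  d11 <- diameterNaive(dipidr:::.design_from_nT(11L, 4L, "ATGCAT",
                                                monomerGeometry()))
  near10 <- d11 + 0.51 * (d10 - d11)
  near11 <- d11 + 0.49 * (d10 - d11)
  pick <- function(target) unique(strandTable(
    solveCurvatureLength(target))$curvature_len[
      strandTable(solveCurvatureLength(target))$face == "outer"])
  expect_equal(pick(near10), 10L)
  expect_equal(pick(near11), 11L)
  # solved close to target: radius for the 119-nm class
  xs <- solveCurvatureLength(119)
  expect_equal(predictRadiusNaive(xs), 59.5, tolerance = 0.5 / 59.5)
  expect_error(solveCurvatureLength(20), "exceed")
  expect_error(solveCurvatureLength(1e5), "out of design range")
})

test_that("menu enumeration covers the printed grid", {
  en <- enumerateDesigns()
  expect_equal(nrow(en), 636) # 4 flex x 3 sticky x 53 nT
  expect_equal(attr(en, "rawCount"), 636)
  # single flex / single sticky: 53 designs before dedup
  en1 <- enumerateDesigns(flexMenu = 4L, stickyMenu = "ATGCAT")
  expect_equal(nrow(en1), 53)
  # 0-resolution dedup leaves the raw grid
  expect_equal(nrow(enumerateDesigns(dedupResolution = 0)), 636)
  expect_equal(nrow(enumerateDesigns(flexMenu = integer(0))), 0)
  # dedup reduces and documents its rule
  end <- enumerateDesigns(dedupResolution = 1)
  expect_lt(nrow(end), 636)
  expect_match(attr(end, "dedupRule"), "radius")
})

test_that("named variants are deterministic with the documented layout", {
  s1 <- generateVariant("S")
  s2 <- generateVariant("S")
  expect_identical(strandTable(s1), strandTable(s2))
  for (v in c("XS", "S", "M", "L", "XL", "XXL", "M60", "XXL60")) {
    d <- generateVariant(v)
    st <- strandTable(d)
    expect_equal(nrow(st), 30)
    expect_true(all(vapply(unique(st$sticky_seq), validateSticky, TRUE)))
    # six groups of two and six of three
    expect_equal(sum(st$group_size == 2), 12)
    expect_equal(sum(st$group_size == 3), 18)
  }
  # smaller curvature extension of the XXL class gives the smaller angle
  expect_lt(coneAngleNaive(generateVariant("XXL")),
            coneAngleNaive(generateVariant("XS")))
  expect_error(generateVariant("nope"), "unknown variant")
})

test_that("S to XXL conversion exchanges exactly the 24 curvature strands", {
  s <- strandTable(generateVariant("S"))
  xxl <- strandTable(generateVariant("XXL"))
  differing <- sum(s$full_sequence != xxl$full_sequence)
  expect_equal(differing, 24)
  expect_true(all(s$face[s$full_sequence != xxl$full_sequence] == "outer"))
})

test_that("piecewise calibration recovers identity and known kinks", {
  dn <- seq(100, 1200, by = 50)
  # identity data: slopes 1, intercepts 0
  calI <- fitCalibration(data.frame(d_naive = dn, d_measured = dn),
                         "container")
  expect_equal(calI@slope1, 1, tolerance = 1e-9)
  expect_equal(calI@slope2, 1, tolerance = 1e-9)
  expect_equal(calI@intercept1, 0, tolerance = 1e-6)
  # two-regime data with a known kink at 400 nm
  dm <- ifelse(dn <= 400, 1.05 * dn + 10,
               1.6 * dn + 10 + (1.05 - 1.6) * 400)
  cal <- fitCalibration(data.frame(d_naive = dn, d_measured = dm), "tube")
  expect_equal(cal@breakpoint, 400, tolerance = 10) # grid resolution
  expect_equal(calibrateDiameter(dn, cal), dm, tolerance = 1e-9)
  # calibrated diameter is monotone in d_naive
  expect_true(all(diff(calibrateDiameter(seq(50, 1500, 10), cal)) > 0))
  expect_error(fitCalibration(data.frame(d_naive = 1:3, d_measured = 1:3),
                              "container"), "at least 4")
})
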