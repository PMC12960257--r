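# Skeletonization and two-channel purity profiling.

test_that("skeletonization thins a thick line to one pixel width", {
  m <- matrix(FALSE, 40, 40)
  m[18:23, 5:36] <- TRUE
  sk <- skeletonize(m)
  expect_true(all(rowSums(sk) %in% c(0, 1)) ||
                all(colSums(sk) %in% c(0, 1)))
  expect_gt(sum(sk), 20) # spans the line
  expect_true(all(m[sk])) # skeleton lies inside the mask
})

test_that("pure-B membranes give purity 1 when channel 2 is silent", {
  mb <- makeTwoChannelMembrane(domains = data.frame(fraction = 1, type = "B"),
                               bleed = 0, noiseSd = 0, seed = 2)
  pp <- purityProfile(mb$img, c(1, 1))
  expect_gt(nrow(pp@profile), 30)
  expect_true(all(pp@profile$purity > 0.98))
})

test_that("homogeneously mixed membranes give purity one half", {
  mb <- makeTwoChannelMembrane(domains = data.frame(fraction = 1,
                                                    type = "AB"),
                               noiseSd = 0.005, seed = 3)
  pp <- purityProfile(mb$img, c(1, 1))
  expect_equal(mean(pp@profile$purity), 0.5, tolerance = 0.02)
})

test_that("calibration recovers injected channel gains", {
  aa <- makeTwoChannelMembrane(domains = data.frame(fraction = 1,
                                                    type = "AB"),
                               gains = c(1.4, 0.7), noiseSd = 0.005,
                               seed = 5)
  fac <- calibrateChannels(aa$img)
  expect_equal(fac[1] / fac[2], 1.4 / 0.7, tolerance = 0.02)
})

test_that("purity is invariant under global intensity rescaling", {
  mb <- makeTwoChannelMembrane(seed = 6, noiseSd = 0.005)
  p1 <- purityProfile(mb$img, c(1, 1))
  scaled <- micrograph(lapply(mb$img@channels, function(m) 3.7 * m),
                       mb$img@nmPerPixel)
  p2 <- purityProfile(scaled, c(1, 1))
  expect_equal(p1@profile$purity, p2@profile$purity, tolerance = 1e-9)
})

test_that("two-domain membranes yield a bimodal purity profile", {
  mb <- makeTwoChannelMembrane(domains = data.frame(
    fraction = c(0.5, 0.5), type = c("A", "B")),
    bleed = 0.1, noiseSd = 0.01, seed = 7)
  pp <- purityProfile(mb$img, c(1, 1))
  pur <- pp@profile$purity
  loMode <- mean(pur[pur < 0.4])
  hiMode <- mean(pur[pur > 0.6])
  # with 10% bleed-through the modes sit near 1/11 and 10/11
  expect_equal(loMode, 0.1 / 1.1, tolerance = 0.05)
  expect_equal(hiMode, 1 / 1.1, tolerance = 0.05)
  # empty skeleton gives an empty profile
  blank <- micrograph(list(matrix(0, 50, 50), matrix(0, 50, 50)), 10)
  expect_equal(nrow(purityProfile(blank, c(1, 1),
                                  threshold = 0.5)@profile), 0)
})
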