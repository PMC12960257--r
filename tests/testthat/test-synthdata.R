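# Synthetic-data generators: determinism, construction invariants and
# lossless ground-truth round trips.

test_that("container rendering is a pure function of its spec", {
  td <- data.frame(d_major = c(200, 250), d_minor = c(150, 160))
  a <- renderCollapsedContainers(td, 3, 500, seed = 9)
  b <- renderCollapsedContainers(td, 3, 500, seed = 9)
  expect_identical(a$img@channels[[1]], b$img@channels[[1]])
  expect_identical(a$truth, b$truth)
  c_ <- renderCollapsedContainers(td, 3, 500, seed = 10)
  expect_false(identical(a$img@channels[[1]], c_$img@channels[[1]]))
  # zero objects: blank image, empty table
  z <- renderCollapsedContainers(td[0, ], 3, 200, seed = 1, noiseSd = 0)
  expect_equal(nrow(z$truth), 0)
  expect_lt(diff(range(z$img@channels[[1]])), 1e-6)
  # impossible packing errors out
  big <- data.frame(d_major = rep(900, 20), d_minor = rep(800, 20))
  expect_error(renderCollapsedContainers(big, 3, 400, seed = 1),
               "cannot place")
})

test_that("sphere layouts have icosahedral topology", {
  # T = 7 gives 72 sites and exactly 12 five-coordinated disclinations
  sph <- makeShell("sphere", size = 72)
  expect_equal(nrow(sph@centres), 72)
  ng <- neighbourGraph(sph)
  expect_equal(sum(ng$coordination == 5), 12)
  expect_true(all(ng$coordination %in% c(5, 6)))
  # mean nearest-neighbour distance is the requested spacing
  d <- as.matrix(dist(sph@centres)); diag(d) <- Inf
  expect_equal(mean(apply(d, 1, min)), 37.7, tolerance = 1e-6)
})

test_that("rolled tubes match the requested radius within half a spacing", {
  tube <- makeShell("tube", spacing = 37.7, size = c(14, 8))
  want <- 14 * 37.7 / (2 * pi)
  expect_equal(attr(tube, "radius"), want, tolerance = 0.5 * 37.7 / want)
  rho <- sqrt(tube@centres[, 1]^2 + tube@centres[, 2]^2)
  expect_lt(diff(range(rho)), 1e-9)
  expect_error(makeShell("tube", size = c(2, 5)), "incompatible")
})

test_that("sheets are flat, hexagonal and free of pentagonal junctions", {
  sheet <- makeShell("sheet", size = c(8, 5))
  expect_equal(nrow(sheet@centres), 40)
  expect_true(all(sheet@centres[, 3] == 0))
  ng <- neighbourGraph(sheet)
  expect_equal(length(ng$disclinations), 0)
  pc <- poreCensus(sheet)
  expect_false(any(pc$pores$type == "pentagonal"))
  # seeded vacancies are reproducible
  v1 <- makeShell("sheet", size = c(8, 5), nVacancies = 3, seed = 2)
  v2 <- makeShell("sheet", size = c(8, 5), nVacancies = 3, seed = 2)
  expect_identical(v1@centres, v2@centres)
})

test_that("membrane images are seed-reproducible with exact truth tables", {
  a <- makeTwoChannelMembrane(seed = 12)
  b <- makeTwoChannelMembrane(seed = 12)
  expect_identical(a$img@channels, b$img@channels)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$truth$type %in% c("A", "B", "AB")))
})

test_that("ground-truth tables round-trip losslessly through TSV", {
  td <- data.frame(d_major = c(300, 420), d_minor = c(210, 260))
  syn <- renderCollapsedContainers(td, 4, 500, seed = 3)
  tf <- tempfile(fileext = ".tsv")
  writeResultsTSV(syn$truth, tf)
  back <- readResultsTSV(tf)
  expect_equal(back, syn$truth, tolerance = 1e-12)
})
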