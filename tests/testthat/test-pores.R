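# Neighbour graphs, inscribed-circle junction pores and the pore census.

test_that("coordination census matches a brute-force distance check", {
  sheet <- makeShell("sheet", size = c(7, 7))
  ng <- neighbourGraph(sheet)
  X <- sheet@centres
  brute <- vapply(seq_len(nrow(X)), function(i)
    sum(sqrt(colSums((t(X) - X[i, ])^2)) < sheet@cutoff) - 1L, 1L)
  expect_equal(ng$coordination, as.integer(brute))
  expect_true(all(ng$coordination[ng$interior] == 6))
  # icosahedral shell: exactly 12 five-coordinated sites
  sph <- neighbourGraph(makeShell("sphere", size = 132))
  expect_equal(sum(sph$coordination == 5), 12)
  expect_equal(length(sph$disclinations), 12)
})

test_that("junction pores reproduce tangent-circle geometry", {
  R <- 14.25
  # three touching discs: 2R (2/sqrt(3) - 1)
  tri <- monomerLayout(rbind(c(0, 0, 0), c(2 * R, 0, 0),
                             c(R, R * sqrt(3), 0)), monomerRadius = R)
  expect_equal(as.numeric(junctionPore(tri, 1:3)),
               2 * R * (2 / sqrt(3) - 1), tolerance = 1e-3)
  # five touching discs in a regular ring: 2R (1/sin 36 - 1)
  rc <- 2 * R / (2 * sin(pi / 5))
  ang <- 2 * pi * (0:4) / 5
  pent <- monomerLayout(cbind(rc * cos(ang), rc * sin(ang), 0),
                        monomerRadius = R, cutoff = 2.2 * R)
  expect_equal(as.numeric(junctionPore(pent, 1:5)),
               2 * R * (1 / sin(pi / 5) - 1), tolerance = 1e-3)
})

test_that("trimer pore shifts linearly with centre spacing", {
  R <- 14.25
  tri_at <- function(s) {
    lay <- monomerLayout(rbind(c(0, 0, 0), c(s, 0, 0),
                               c(s / 2, s * sqrt(3) / 2, 0)),
                         monomerRadius = R, cutoff = 1.35 * s)
    as.numeric(junctionPore(lay, 1:3))
  }
  s0 <- 37.7; delta <- 2.5
  expect_equal(tri_at(s0 + delta) - tri_at(s0), 2 * delta / sqrt(3),
               tolerance = 1e-6)
})

test_that("junction pore is invariant under rigid motions", {
  R <- 14.25
  ring <- cbind(24 * cos(2 * pi * (0:4) / 5), 24 * sin(2 * pi * (0:4) / 5), 0)
  lay <- monomerLayout(ring, monomerRadius = R, cutoff = 40)
  p0 <- as.numeric(junctionPore(lay, 1:5))
  th <- 0.83
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(1.1), sin(1.1), 0, -sin(1.1), cos(1.1)), 3)
  moved <- ring %*% Rz %*% Rx + matrix(rep(c(5, -80, 31), each = 5), ncol = 3)
  lay2 <- monomerLayout(moved, monomerRadius = R, cutoff = 40)
  expect_equal(as.numeric(junctionPore(lay2, 1:5)), p0, tolerance = 1e-9)
})

test_that("pore census classifies hexagonal sheets and vacancies", {
  sheet <- makeShell("sheet", size = c(6, 6))
  pc <- poreCensus(sheet)
  expect_true(all(pc$pores$type == "trimeric"))
  expect_lt(diff(range(pc$pores$pore_diameter_nm)), 1e-6)
  # count of 3-cycles matches brute-force enumeration
  X <- sheet@centres
  n <- nrow(X)
  cnt <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    d3 <- c(sqrt(sum((X[i, ] - X[j, ])^2)), sqrt(sum((X[i, ] - X[k, ])^2)),
            sqrt(sum((X[j, ] - X[k, ])^2)))
    if (all(d3 < sheet@cutoff)) cnt <- cnt + 1
  }
  expect_equal(nrow(pc$pores), cnt)
  # an interior vacancy: exactly one larger defect-class pore
  full <- makeShell("sheet", size = c(7, 7))
  ctr <- colMeans(full@centres)
  drop <- which.min(colSums((t(full@centres) - ctr)^2))
  vac <- monomerLayout(full@centres[-drop, , drop = FALSE],
                       monomerRadius = full@monomerRadius,
                       cutoff = full@cutoff)
  pcv <- poreCensus(vac)
  expect_equal(sum(pcv$pores$type == "defect"), 1)
  expect_gt(min(pcv$pores$pore_diameter_nm[pcv$pores$type == "defect"]),
            max(pcv$pores$pore_diameter_nm[pcv$pores$type == "trimeric"]))
})

test_that("pentagonal pores exceed trimeric pores across random spacings", {
  set.seed(11)
  for (s in runif(5, 30, 45)) {
    sph <- makeShell("sphere", size = 72, spacing = s)
    pc <- poreCensus(sph, defectThreshold = Inf)
    m <- tapply(pc$pores$pore_diameter_nm, pc$pores$type, mean)
    expect_gt(m[["pentagonal"]], m[["trimeric"]])
  }
})

test_that("pentagonal ring pore follows the analytic formula at calibrated
           spacing", {
  R <- 14.25
  # spacing calibrated so the trimeric pore equals the XS value of 15 nm
  s <- (15 / 2 + R) * sqrt(3)
  tri <- monomerLayout(rbind(c(0, 0, 0), c(s, 0, 0),
                             c(s / 2, s * sqrt(3) / 2, 0)),
                       monomerRadius = R, cutoff = 1.35 * s)
  expect_equal(as.numeric(junctionPore(tri, 1:3)), 15, tolerance = 1e-6)
  # the pentagon at the same spacing is a deterministic function of s
  rc <- s / (2 * sin(pi / 5))
  ang <- 2 * pi * (0:4) / 5
  pent <- monomerLayout(cbind(rc * cos(ang), rc * sin(ang), 0),
                        monomerRadius = R, cutoff = 1.35 * s)
  expect_equal(as.numeric(junctionPore(pent, 1:5)),
               2 * (s / (2 * sin(pi / 5)) - R), tolerance = 1e-6)
})
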