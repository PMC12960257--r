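# Elastic shell energy, relaxation and growth.

test_that("flat hexamer at rest length is the zero-energy ground state", {
  mesh <- flatHexamerMesh(37.7)
  ep <- elasticParams(0, l0 = 37.7)
  expect_equal(shellEnergy(mesh, ep), 0, tolerance = 1e-12)
  # harmonic springs: energy grows as epsilon^2 under isotropic scaling
  eps <- c(1e-3, 2e-3, 4e-3)
  Es <- vapply(eps, function(e)
    shellEnergy(shellMesh(mesh@vertices * (1 + e), mesh@triangles,
                          mesh@boundary), ep), 0)
  expect_equal(Es[2] / Es[1], 4, tolerance = 0.02)
  expect_equal(Es[3] / Es[2], 4, tolerance = 0.03)
})

test_that("compiled energy matches an independent per-term oracle", {
  mesh <- closedSphereMesh(92)
  ep <- elasticParams(7, l0 = 37.7)
  expect_equal(shellEnergy(mesh, ep),
               shellEnergyOracle(mesh, ep@ks, ep@kb, ep@l0, ep@theta0),
               tolerance = 1e-9)
  expect_error(shellEnergy(shellMesh(rbind(c(0, 0, 0), c(1, 0, 0),
                                           c(2, 0, 0)),
                                     matrix(1:3, 1), 1:3), ep),
               "degenerate")
})

test_that("analytic gradient agrees with finite differences", {
  set.seed(3)
  mesh <- flatHexamerMesh(1)
  V <- mesh@vertices + matrix(rnorm(21, 0, 0.05), ncol = 3)
  mesh <- shellMesh(V, mesh@triangles, mesh@boundary)
  ep <- elasticParams(10, ks = 2, l0 = 1)
  G <- shellGradient(mesh, ep)
  h <- 1e-6
  for (i in c(1, 4)) for (k in 1:3) {
    Vp <- V; Vp[i, k] <- Vp[i, k] + h
    Vm <- V; Vm[i, k] <- Vm[i, k] - h
    num <- (shellEnergy(shellMesh(Vp, mesh@triangles, mesh@boundary), ep) -
            shellEnergy(shellMesh(Vm, mesh@triangles, mesh@boundary), ep)) /
      (2 * h)
    expect_equal(G[i, k], num, tolerance = 1e-5)
  }
})

test_that("energy is invariant under rigid rotation and translation", {
  mesh <- closedSphereMesh(42)
  ep <- elasticParams(9)
  E0 <- shellEnergy(mesh, ep)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  V2 <- mesh@vertices %*% R + matrix(rep(c(13, -5, 2), each = 42), ncol = 3)
  expect_equal(shellEnergy(shellMesh(V2, mesh@triangles, integer(0)), ep),
               E0, tolerance = 1e-9 * max(1, abs(E0)))
})

test_that("relaxation is monotone, idempotent and flattens planar patches", {
  ep <- elasticParams(0, l0 = 1)
  mesh <- flatHexamerMesh(1)
  relaxed <- relaxMesh(mesh, ep, tol = 1e-8)
  expect_lt(max(abs(meshVertices(relaxed) - meshVertices(mesh))), 1e-8)
  # perturbed flat patch with theta0 = 0 returns to planarity
  set.seed(5)
  V <- mesh@vertices + matrix(rnorm(21, 0, 0.05), ncol = 3)
  bent <- relaxMesh(shellMesh(V, mesh@triangles, mesh@boundary), ep,
                    tol = 1e-9, maxit = 20000)
  Vr <- meshVertices(bent)
  fit <- stats::lm(Vr[, 3] ~ Vr[, 1] + Vr[, 2])
  expect_lt(max(abs(stats::residuals(fit))), 1e-3) # max dihedral < 0.1 deg
  expect_lte(attr(bent, "energy"), shellEnergy(shellMesh(V, mesh@triangles,
                                                         mesh@boundary), ep))
})

test_that("relaxed closed shell radius follows the dihedral geometry", {
  # R ~ l0 / (2 sin(theta0/2) sqrt(3)) for a triangulated sphere
  mesh <- closedSphereMesh(92, spacing = 37.7)
  lay <- makeShell("sphere", size = 92, spacing = 37.7)
  d <- sqrt(rowSums(sweep(lay@centres, 2, colMeans(lay@centres))^2))
  R0 <- mean(d)
  theta0 <- 2 * asin(37.7 / (2 * sqrt(3) * R0)) * 180 / pi
  rel <- relaxMesh(mesh, elasticParams(theta0), tol = 1e-4, maxit = 4000)
  dr <- sqrt(rowSums(sweep(meshVertices(rel), 2,
                           colMeans(meshVertices(rel)))^2))
  expect_equal(mean(dr), R0, tolerance = 0.15)
})

test_that("growth with zero curvature and no randomness yields a flat
           hexagonal sheet", {
  ep <- elasticParams(0)
  gp <- growthParams(seed = 1, pRandom = 0, maxMonomers = 60L)
  res <- runAssembly(ep, gp)
  expect_false(res$report@closed)
  expect_lt(max(abs(meshVertices(res$mesh)[, 3])), 1e-6)
  cens <- res$report@census
  expect_true(all(names(cens) == "6" | cens == 0))
})

test_that("identical seeds reproduce trajectories bitwise", {
  r1 <- growRun(8, seed = 11, maxMonomers = 80L)
  r2 <- growRun(8, seed = 11, maxMonomers = 80L)
  expect_identical(meshVertices(r1$mesh), meshVertices(r2$mesh))
  expect_identical(meshTriangles(r1$mesh), meshTriangles(r2$mesh))
  r3 <- growRun(8, seed = 12, maxMonomers = 80L)
  expect_false(identical(meshVertices(r1$mesh), meshVertices(r3$mesh)))
})

test_that("grow-step interface adds one triangle and no-ops when closed", {
  ep <- elasticParams(9)
  gp <- growthParams(seed = 2)
  m0 <- initialMesh(ep@l0)
  m1 <- growShell(m0, ep, gp, steps = 1L)
  expect_equal(nrow(meshTriangles(m1)), nrow(meshTriangles(m0)) + 1)
  closed <- growRun(12, seed = 3)$mesh
  expect_true(isClosed(closed))
  expect_message(growShell(closed, ep, gp), "closed")
  # max_monomers = 1 leaves the seed trimer open
  tiny <- runAssembly(ep, growthParams(seed = 1, maxMonomers = 3L))
  expect_false(tiny$report@closed)
  expect_equal(tiny$report@classification, "open")
})

test_that("closed shells carry a net of twelve five-fold disclinations", {
  closedCount <- 0
  for (s in 1:6) {
    res <- growRun(11, seed = s)
    if (res$report@closed) {
      closedCount <- closedCount + 1
      cens <- res$report@census
      expect_equal(sum((6 - as.integer(names(cens))) * cens), 12)
      # V - E + F = 2 enforced by the class validity on closed meshes
      expect_true(validObject(res$mesh))
    }
  }
  expect_gte(closedCount, 5) # spheroid fraction >= 0.8 at alpha >= 11
})

test_that("high cone angles close into spheroids, low angles stay open or
           tubular", {
  aspects <- c()
  for (s in 1:3) {
    hi <- growRun(11, seed = s)
    expect_true(hi$report@closed)
    expect_equal(hi$report@classification, "spheroid")
    lo <- growRun(5, seed = s)
    expect_false(lo$report@classification == "spheroid")
    aspects <- c(aspects, lo = lo$report@aspectRatio,
                 hi = hi$report@aspectRatio)
  }
  # smaller cone angles give more elongated shapes on average
  expect_gt(mean(aspects[names(aspects) == "lo"]),
            mean(aspects[names(aspects) == "hi"]))
})

test_that("principal-extent aspect ratio matches constructions and the
           pairwise oracle", {
  set.seed(9)
  # hollow sphere point cloud: a = 1 within discretization
  u <- matrix(rnorm(300 * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 50
  expect_lte(meshAspectRatio(u)$a, 1.05)
  # cylinder of length 3 d
  ang <- runif(400, 0, 2 * pi)
  cyl <- cbind(25 * cos(ang), 25 * sin(ang), runif(400, 0, 150))
  ar <- meshAspectRatio(cyl)
  expect_equal(ar$a, 3, tolerance = 0.1)
  # agreement with an exhaustive pairwise-extent oracle
  cloud <- matrix(rnorm(100 * 3), ncol = 3) %*% diag(c(3, 1.5, 1))
  got <- meshAspectRatio(cloud)$dMajor
  oracle <- max(stats::dist(cloud))
  expect_equal(got, oracle, tolerance = 0.05 * oracle)
  expect_error(meshAspectRatio(cbind(1:9, 2 * (1:9), 3 * (1:9))),
               "degenerate")
})

test_that("single-alpha single-rep sweep equals one assembly run", {
  gp <- growthParams(seed = 21, maxMonomers = 120L)
  ph <- sweepAlpha(10, reps = 1, gparams = gp)
  gp1 <- growthParams(seed = as.integer((21 + 1) %% .Machine$integer.max),
                      maxMonomers = 120L)
  ref <- runAssembly(elasticParams(10), gp1)
  expect_equal(ph$fracSpheroid,
               as.numeric(ref$report@classification == "spheroid"))
  expect_equal(ph$meanAspect, ref$report@aspectRatio)
  expect_equal(ph$meanMonomers, as.numeric(ref$report@nMonomers))
})
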