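# Fixtures and independent oracles used across the suite. All fixtures are
# built in code; the oracles are deliberately separate implementations of
# the quantities they check.

# --- discrete worm-like chain Monte-Carlo oracle -------------------------
# Kratky-Porod chain of segments `delta` with von Mises-Fisher bond-angle
# sampling at kappa = Lp/delta; returns RMS end-to-end and its SE.
wlcChainMC <- function(Lc, Lp, delta = 0.05, M = 2000, seed = 7) {
  set.seed(seed)
  n <- max(2, round(Lc / delta))
  kappa <- Lp / delta
  D <- matrix(rep(c(0, 0, 1), each = M), ncol = 3) # current directions
  R <- matrix(0, M, 3)
  for (s in seq_len(n)) {
    R <- R + delta * D
    u <- runif(M)
    cosphi <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
    sinphi <- sqrt(pmax(0, 1 - cosphi^2))
    psi <- runif(M, 0, 2 * pi)
    # orthonormal frame per direction
    ref <- cbind(1, 0, 0)[rep(1, M), , drop = FALSE]
    swap <- abs(D[, 1]) > 0.9
    ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
    u1 <- cbind(D[, 2] * ref[, 3] - D[, 3] * ref[, 2],
                D[, 3] * ref[, 1] - D[, 1] * ref[, 3],
                D[, 1] * ref[, 2] - D[, 2] * ref[, 1])
    u1 <- u1 / sqrt(rowSums(u1^2))
    u2 <- cbind(D[, 2] * u1[, 3] - D[, 3] * u1[, 2],
                D[, 3] * u1[, 1] - D[, 1] * u1[, 3],
                D[, 1] * u1[, 2] - D[, 2] * u1[, 1])
    D <- cosphi * D + sinphi * (cos(psi) * u1 + sin(psi) * u2)
    D <- D / sqrt(rowSums(D^2))
  }
  r2 <- rowSums(R^2)
  rms <- sqrt(mean(r2))
  se <- stats::sd(r2) / sqrt(M) / (2 * rms)
  list(rms = rms, se = se)
}

# --- exact ellipse perimeter by quadrature -------------------------------
perimeterQuadrature <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}

# --- prolate spheroid surface area by quadrature -------------------------
spheroidAreaQuadrature <- function(dMajor, dMinor) {
  b <- dMinor / 2; cc <- dMajor / 2
  2 * pi * stats::integrate(function(u)
    b * sin(u) * sqrt(cc^2 * sin(u)^2 + b^2 * cos(u)^2),
    0, pi, rel.tol = 1e-10)$value
}

# --- independent per-term shell energy in R ------------------------------
# brute-force edge and hinge sums, separate from the compiled implementation
shellEnergyOracle <- function(mesh, ks, kb, l0, theta0deg) {
  V <- meshVertices(mesh); Tr <- meshTriangles(mesh)
  th0 <- theta0deg * pi / 180
  ed <- meshEdges(mesh)
  E <- 0
  for (k in seq_len(nrow(ed))) {
    l <- sqrt(sum((V[ed[k, 1], ] - V[ed[k, 2], ])^2))
    E <- E + 0.5 * ks * (l - l0)^2
  }
  # hinges: directed edge map
  own <- new.env()
  for (t in seq_len(nrow(Tr))) {
    tri <- Tr[t, ]
    for (k in 1:3) {
      a <- tri[k]; b <- tri[k %% 3 + 1]; cc <- tri[(k + 1) %% 3 + 1]
      assign(paste(a, b), cc, envir = own)
    }
  }
  cross3 <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                             a[1]*b[2]-a[2]*b[1])
  for (k in seq_len(nrow(ed))) {
    i <- ed[k, 1]; j <- ed[k, 2]
    cij <- mget(paste(i, j), envir = own, ifnotfound = list(NULL))[[1]]
    cji <- mget(paste(j, i), envir = own, ifnotfound = list(NULL))[[1]]
    if (is.null(cij) || is.null(cji)) next
    p1 <- V[i, ]; p2 <- V[j, ]; p3 <- V[cij, ]; p4 <- V[cji, ]
    e <- p2 - p1
    n1 <- cross3(e, p3 - p1)
    n2 <- cross3(p4 - p1, e)
    eh <- e / sqrt(sum(e^2))
    th <- atan2(sum(cross3(n1, n2) * eh), sum(n1 * n2))
    E <- E + kb * (1 - cos(th - th0))
  }
  E
}

# --- closed triangulated sphere fixture ----------------------------------
# triangulates an icosadeltahedral site layout (3-cliques of the neighbour
# graph are the faces; oriented outward)
closedSphereMesh <- function(nSites = 92, spacing = 37.7) {
  lay <- makeShell("sphere", spacing = spacing, size = nSites)
  X <- lay@centres
  d <- as.matrix(dist(X))
  adj <- d < lay@cutoff & upper.tri(d)
  ed <- which(adj, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  tri <- matrix(as.integer(igraph::triangles(g)), nrow = 3)
  Tr <- t(tri)
  ctr <- colMeans(X)
  for (k in seq_len(nrow(Tr))) {
    v <- Tr[k, ]
    nrm <- c(crossprod3(X[v[2], ] - X[v[1], ], X[v[3], ] - X[v[1], ]))
    if (sum(nrm * (colMeans(X[v, ]) - ctr)) < 0) Tr[k, ] <- v[c(1, 3, 2)]
  }
  shellMesh(X, Tr, integer(0))
}

crossprod3 <- function(a, b) {
  c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
}

# --- small flat hexagonal patch mesh -------------------------------------
# a central vertex with 6 neighbours (a hexamer), rim ordered
flatHexamerMesh <- function(l0 = 37.7) {
  ang <- 2 * pi * (0:5) / 6
  V <- rbind(c(0, 0, 0), cbind(l0 * cos(ang), l0 * sin(ang), 0))
  Tr <- cbind(1, 2:7, c(3:7, 2))
  shellMesh(V, Tr, as.integer(7:2))
}

# deterministic growth shorthand used in several tests
growRun <- function(alpha, seed, maxMonomers = 300L, pRandom = 0.05) {
  runAssembly(elasticParams(alpha),
              growthParams(seed = seed, pRandom = pRandom,
                           maxMonomers = maxMonomers))
}
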