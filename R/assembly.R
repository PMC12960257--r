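# Bead-spring growth simulation of triangulated elastic shells.
# The heavy lifting (energy, gradients, relaxation, the growth loop) is
# compiled code; this file provides the user-facing mesh containers,
# morphometry of simulated shells and the cone-angle sweep.

#' Construct a shell mesh
#'
#' @param vertices n x 3 matrix of positions in nm.
#' @param triangles m x 3 integer matrix (1-based, consistently oriented).
#' @param boundary ordered rim vertex indices (empty for closed meshes).
#' @return a \linkS4class{ShellMesh}.
#' @export
shellMesh <- function(vertices, triangles, boundary = integer(0)) {
  new("ShellMesh", vertices = as.matrix(vertices),
      triangles = matrix(as.integer(triangles), ncol = 3),
      boundary = as.integer(boundary))
}

#' Seed mesh for growth: a single equilateral triangle
#'
#' @param l0 edge length in nm.
#' @return a \linkS4class{ShellMesh} of one triangle (one face of the first
#'   trimer).
#' @export
initialMesh <- function(l0 = 37.7) {
  shellMesh(rbind(c(0, 0, 0), c(l0, 0, 0), c(l0/2, l0*sqrt(3)/2, 0)),
            matrix(c(1L, 2L, 3L), ncol = 3), c(1L, 2L, 3L))
}

#' Unique edges of a mesh
#' @param mesh a \linkS4class{ShellMesh}.
#' @return 2-column integer matrix of vertex index pairs.
#' @export
meshEdges <- function(mesh) {
  Tr <- mesh@triangles
  e <- rbind(Tr[, 1:2, drop = FALSE], Tr[, 2:3, drop = FALSE],
             Tr[, c(3, 1), drop = FALSE])
  unique(t(apply(e, 1, sort)))
}

#' Elastic energy of a triangulated shell
#'
#' \deqn{E = \sum_{edges} \tfrac12 k_s (l - l_0)^2 +
#'       \sum_{hinges} k_b (1 - \cos(\theta - \theta_0))}
#' summed over unique edges and adjacent-triangle pairs, with the signed
#' dihedral angle \eqn{\theta} preferred at \eqn{\theta_0} (the simulated
#' cone angle).
#'
#' @param mesh a \linkS4class{ShellMesh}.
#' @param params an \linkS4class{ElasticParams}.
#' @return total energy (energy units of \code{ks} nm^2).
#' @export
shellEnergy <- function(mesh, params) {
  .cpp_shell_energy(mesh@vertices, mesh@triangles, params@ks, params@kb,
                    params@l0, params@theta0 * pi / 180)
}

#' Analytic energy gradient (d E / d vertex)
#'
#' @inheritParams shellEnergy
#' @return n x 3 matrix.
#' @export
shellGradient <- function(mesh, params) {
  .cpp_shell_gradient(mesh@vertices, mesh@triangles, params@ks, params@kb,
                      params@l0, params@theta0 * pi / 180)
}

#' Relax a mesh to a local energy minimum
#'
#' Gradient descent with backtracking line search; stops when the gradient
#' max-norm falls below \code{tol} or at the iteration cap. Energy is
#' non-increasing across iterations. Non-convergence returns the partial
#' result with \code{converged = FALSE} in the attributes.
#'
#' @param mesh a \linkS4class{ShellMesh}.
#' @param params an \linkS4class{ElasticParams}.
#' @param tol gradient max-norm tolerance (energy units / nm).
#' @param maxit iteration cap.
#' @return the relaxed \linkS4class{ShellMesh} with attributes
#'   \code{energy}, \code{gradMax}, \code{converged}.
#' @export
relaxMesh <- function(mesh, params, tol = 1e-6, maxit = 5000) {
  r <- .cpp_relax(mesh@vertices, mesh@triangles, mesh@boundary, params@ks,
                  params@kb, params@l0, params@theta0 * pi / 180, tol,
                  as.integer(maxit))
  if (!r$converged)
    warning(sprintf("relaxation not converged: grad max %.3g > tol %.3g",
                    r$gradMax, tol))
  out <- shellMesh(r$vertices, r$triangles, r$boundary)
  attr(out, "energy") <- r$energy
  attr(out, "gradMax") <- r$gradMax
  attr(out, "converged") <- r$converged
  out
}

# resolve bindEnergy default (0.05 ks l0^2) and run the compiled growth loop
.grow_cpp <- function(mesh, eparams, gparams, maxSteps = -1L) {
  eb <- gparams@bindEnergy
  if (is.na(eb)) eb <- 0.05 * eparams@ks * eparams@l0^2
  .cpp_grow(mesh@vertices, mesh@triangles, mesh@boundary,
            eparams@ks, eparams@kb, eparams@l0,
            eparams@theta0 * pi / 180,
            gparams@pRandom, gparams@betaMerge * pi / 180,
            gparams@betaPent * pi / 180, eb, gparams@maxMonomers,
            gparams@relaxTol, 60L, 10L, 150L, 3000L,
            as.double(gparams@seed), as.integer(maxSteps))
}

#' Advance the growth simulation by a number of triangles
#'
#' One step adds one triangle at the rim: wedges whose opening angle
#' \eqn{\beta} is below the bonding threshold close first (rim monomers
#' within binding range; a 4-triangle wedge closing below the pentagon
#' angle creates a 5-fold disclination), otherwise a new monomer is placed
#' on the rim edge where it forms the most bonds (with probability
#' \code{pRandom}, on a random rim edge). A closed mesh is returned
#' unchanged.
#'
#' @param mesh a \linkS4class{ShellMesh} with a boundary.
#' @param eparams an \linkS4class{ElasticParams}.
#' @param gparams a \linkS4class{GrowthParams} (carries the seed).
#' @param steps number of triangles to add.
#' @return the grown \linkS4class{ShellMesh}.
#' @export
growShell <- function(mesh, eparams, gparams, steps = 1L) {
  if (isClosed(mesh)) {
    message("mesh is closed: no-op")
    return(mesh)
  }
  r <- .grow_cpp(mesh, eparams, gparams, as.integer(steps))
  out <- shellMesh(r$vertices, r$triangles, r$boundary)
  attr(out, "energy") <- r$energy
  out
}

#' Principal extents and aspect ratio of a mesh or point cloud
#'
#' Principal axes are the eigenvectors of the vertex covariance (inertia)
#' tensor; extents are the ranges of the vertex projections onto them.
#'
#' @param mesh a \linkS4class{ShellMesh} or an n x 3 matrix (n >= 4).
#' @return list with \code{dMajor}, \code{dMinor} (nm) and aspect ratio
#'   \code{a} = dMajor/dMinor.
#' @export
meshAspectRatio <- function(mesh) {
  V <- if (is(mesh, "ShellMesh")) mesh@vertices else as.matrix(mesh)
  if (nrow(V) < 4) stop("need at least 4 vertices")
  cv <- stats::cov(V)
  if (rcond(cv) < 1e-12 && sum(eigen(cv)$values > 1e-9) < 2)
    stop("degenerate (collinear) vertex set")
  ev <- eigen(cv, symmetric = TRUE)$vectors
  pr <- V %*% ev
  ext <- sort(apply(pr, 2, function(x) diff(range(x))), decreasing = TRUE)
  list(dMajor = ext[1], dMinor = ext[3], a = ext[1] / ext[3])
}

#' Coordination census of interior vertices
#'
#' @param mesh a \linkS4class{ShellMesh}.
#' @return named integer vector: number of interior (non-rim) vertices per
#'   coordination number. For closed meshes
#'   \eqn{\sum_v (6 - c_v) = 12} (the disclination theorem).
#' @export
coordinationCensus <- function(mesh) {
  ed <- meshEdges(mesh)
  deg <- tabulate(c(ed), nbins = nrow(mesh@vertices))
  interior <- setdiff(seq_len(nrow(mesh@vertices)), mesh@boundary)
  tab <- table(deg[interior])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# classify a final mesh; aspectThreshold separates spheroids from tubes
.classify <- function(closed, a, aspectThreshold = 1.6) {
  if (closed) {
    if (a <= aspectThreshold) "spheroid" else "tube"
  } else {
    if (is.finite(a) && a > aspectThreshold) "tube" else "open"
  }
}

#' Run a growth simulation to closure or the monomer budget
#'
#' Grows from a single seed triangle until the shell closes or
#' \code{maxMonomers} is reached, then classifies the final morphology:
#' closed with aspect ratio at most \code{aspectThreshold} is a spheroid;
#' closed and elongated, or an open cylinder, is a tube; anything else is
#' open.
#'
#' @param eparams an \linkS4class{ElasticParams}.
#' @param gparams a \linkS4class{GrowthParams}.
#' @param aspectThreshold tube/spheroid boundary on a (default 1.6).
#' @return list with \code{mesh} (\linkS4class{ShellMesh}) and
#'   \code{report} (\linkS4class{MorphologyReport}).
#' @export
runAssembly <- function(eparams, gparams, aspectThreshold = 1.6) {
  r <- .grow_cpp(initialMesh(eparams@l0), eparams, gparams, -1L)
  mesh <- shellMesh(r$vertices, r$triangles, r$boundary)
  n <- nrow(r$vertices)
  ar <- if (n >= 4) meshAspectRatio(mesh) else
    list(dMajor = NA_real_, dMinor = NA_real_, a = NA_real_)
  census <- coordinationCensus(mesh)
  report <- new("MorphologyReport", closed = r$closed,
                nMonomers = as.integer(n), dMajor = ar$dMajor,
                dMinor = ar$dMinor, aspectRatio = ar$a,
                census = census,
                classification = .classify(r$closed, ar$a, aspectThreshold))
  list(mesh = mesh, report = report)
}

#' Sweep the simulated cone angle and tabulate morphologies
#'
#' Runs \code{reps} seeded growth simulations per cone angle and reports
#' per-angle morphology fractions and the mean aspect ratio with its
#' standard error. Seeds are derived deterministically from
#' \code{gparams@seed}.
#'
#' @param alphas cone angles in degrees.
#' @param reps replicate runs per angle (>= 1).
#' @param gparams a \linkS4class{GrowthParams} template.
#' @param eparamsFor function(alpha) returning the
#'   \linkS4class{ElasticParams} for an angle; defaults to
#'   \code{elasticParams(alpha)}.
#' @return data.frame with columns alpha, nRuns, fracSpheroid, fracTube,
#'   fracOpen, meanAspect, seAspect, meanMonomers.
#' @export
sweepAlpha <- function(alphas, reps, gparams, eparamsFor = elasticParams) {
  stopifnot(reps >= 1)
  rows <- lapply(seq_along(alphas), function(i) {
    a <- alphas[i]
    cls <- character(reps); asp <- numeric(reps); nmono <- integer(reps)
    for (r in seq_len(reps)) {
      gp <- gparams
      gp@seed <- as.integer((gparams@seed + 7919L * (i - 1L) + r) %% .Machine$integer.max)
      res <- runAssembly(eparamsFor(a), gp)
      cls[r] <- res$report@classification
      asp[r] <- res$report@aspectRatio
      nmono[r] <- res$report@nMonomers
    }
    data.frame(alpha = a, nRuns = reps,
               fracSpheroid = mean(cls == "spheroid"),
               fracTube = mean(cls == "tube"),
               fracOpen = mean(cls == "open"),
               meanAspect = mean(asp, na.rm = TRUE),
               seAspect = stats::sd(asp, na.rm = TRUE) /
                 sqrt(sum(is.finite(asp))),
               meanMonomers = mean(nmono))
  })
  do.call(rbind, rows)
}

#' Morphology transition angle from a sweep table
#'
#' @param phase output of \code{\link{sweepAlpha}}.
#' @return smallest swept angle (degrees) at which closed spheroids appear,
#'   or NA if none do.
#' @export
transitionAngle <- function(phase) {
  hit <- phase$alpha[phase$fracSpheroid > 0]
  if (length(hit) == 0) NA_real_ else min(hit)
}
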