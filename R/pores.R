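# Pore analysis of monomer lattices: neighbour graph, junction
# classification and largest-inscribed-circle pore sizes.

#' Neighbour graph and coordination census of a monomer layout
#'
#' Connects centres closer than the layout cutoff, computes per-site
#' coordination numbers, and labels 5-coordinated interior sites as
#' disclinations. A site is interior when its neighbours form a single
#' closed ring around it.
#'
#' @param layout a \linkS4class{MonomerLayout} (>= 3 centres).
#' @return list: \code{edges} (2-column matrix), \code{graph} (igraph),
#'   \code{coordination} integer vector, \code{interior} logical vector,
#'   \code{disclinations} indices of 5-coordinated interior sites.
#' @export
neighbourGraph <- function(layout) {
  X <- layout@centres
  n <- nrow(X)
  stopifnot(n >= 3)
  d <- as.matrix(stats::dist(X))
  adj <- d < layout@cutoff & upper.tri(d)
  edges <- which(adj, arr.ind = TRUE)
  colnames(edges) <- c("i", "j")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  coord <- igraph::degree(g)
  # interior: neighbours of v form one closed cycle (each neighbour adjacent
  # to exactly two other neighbours of v)
  interior <- vapply(seq_len(n), function(v) {
    nb <- which(d[v, ] < layout@cutoff & seq_len(n) != v)
    if (length(nb) < 3) return(FALSE)
    sub <- d[nb, nb, drop = FALSE] < layout@cutoff
    diag(sub) <- FALSE
    all(rowSums(sub) == 2)
  }, TRUE)
  list(edges = edges, graph = g, coordination = as.integer(coord),
       interior = interior,
       disclinations = which(interior & coord == 5))
}

# order ring member indices into a cycle using adjacency; NULL if not a ring
.order_ring <- function(members, d, cutoff) {
  k <- length(members)
  sub <- d[members, members, drop = FALSE] < cutoff
  diag(sub) <- FALSE
  if (!all(rowSums(sub) == 2)) return(NULL)
  ord <- integer(k)
  ord[1] <- 1
  prev <- 0
  for (s in 2:k) {
    nxt <- setdiff(which(sub[ord[s - 1], ]), c(prev, ord[s - 1]))
    if (length(nxt) == 0) return(NULL)
    prev <- ord[s - 1]
    ord[s] <- nxt[1]
  }
  if (!sub[ord[k], ord[1]]) return(NULL)
  members[ord]
}

#' Largest inscribed circle of a monomer junction
#'
#' Projects the cycle members onto their best-fit plane and maximizes, over
#' candidate centres, the minimum distance to any monomer disc edge
#' (distance to centre minus monomer radius), starting Nelder-Mead from the
#' cycle centroid. Three touching discs of radius R give
#' \eqn{2R(2/\sqrt3 - 1)}; five discs in a regular ring of side 2R give
#' \eqn{2R(1/\sin 36^\circ - 1)}.
#'
#' @param layout a \linkS4class{MonomerLayout}.
#' @param cycle indices of >= 3 mutually neighbouring monomers forming the
#'   junction.
#' @param planarTol nm; larger plane-fit RMS residuals are flagged in the
#'   result attributes.
#' @return pore diameter in nm (clipped at 0), with attributes
#'   \code{center} (3D) and \code{planeResidual}.
#' @export
junctionPore <- function(layout, cycle, planarTol = 1) {
  stopifnot(length(cycle) >= 3)
  P <- layout@centres[cycle, , drop = FALSE]
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc)
  basis <- sv$v[, 1:2, drop = FALSE]
  resid <- sqrt(mean((Pc %*% sv$v[, 3])^2))
  if (resid > planarTol)
    warning(sprintf("junction not planar: RMS residual %.2f nm", resid))
  P2 <- Pc %*% basis
  R <- layout@monomerRadius
  obj <- function(c2) -(min(sqrt(colSums((t(P2) - c2)^2))) - R)
  opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  pore <- max(0, -opt$value) * 2
  attr(pore, "center") <- ctr + as.vector(basis %*% opt$par)
  attr(pore, "planeResidual") <- resid
  pore
}

#' Census of lattice pores
#'
#' Enumerates trimeric pores (3-cycles of mutually neighbouring monomers)
#' and pentagonal pores around 5-coordinated disclinations (the ordered
#' neighbour ring, measured with the central monomer excluded, emulating
#' the open-pentagon binding geometry). Pores larger than
#' \code{defectThreshold} are re-labelled \code{defect} (missing-monomer
#' class). Vacancy holes are additionally picked up as ring faces without
#' an interior monomer when \code{findHoles} is TRUE.
#'
#' @param layout a \linkS4class{MonomerLayout}.
#' @param defectThreshold nm (default 30, the missing-monomer bound).
#' @param findHoles also search for 4-9-membered rings that enclose no
#'   monomer (vacancy defects).
#' @return list: \code{pores} data.frame (junction_id, type, pore_diameter_nm,
#'   plane_residual_nm, members), \code{summary} data.frame of mean/sd/n per type.
#' @export
poreCensus <- function(layout, defectThreshold = 30, findHoles = TRUE) {
  ng <- neighbourGraph(layout)
  X <- layout@centres
  d <- as.matrix(stats::dist(X))
  tri <- matrix(as.integer(igraph::triangles(ng$graph)), nrow = 3)
  rows <- list()
  if (ncol(tri) > 0) {
    for (k in seq_len(ncol(tri))) {
      cyc <- tri[, k]
      pd <- junctionPore(layout, cyc, planarTol = Inf)
      rows[[length(rows) + 1]] <- data.frame(
        junction_id = length(rows) + 1L, type = "trimeric",
        pore_diameter_nm = as.numeric(pd),
        plane_residual_nm = attr(pd, "planeResidual"),
        members = paste(cyc, collapse = ","))
    }
  }
  for (v in ng$disclinations) {
    nb <- which(d[v, ] < layout@cutoff & seq_len(nrow(X)) != v)
    ring <- .order_ring(nb, d, layout@cutoff)
    if (is.null(ring)) next
    sub <- monomerLayout(X[ring, , drop = FALSE],
                         monomerRadius = layout@monomerRadius,
                         cutoff = layout@cutoff)
    pd <- junctionPore(sub, seq_along(ring), planarTol = Inf)
    rows[[length(rows) + 1]] <- data.frame(
      junction_id = length(rows) + 1L, type = "pentagonal",
      pore_diameter_nm = as.numeric(pd),
      plane_residual_nm = attr(pd, "planeResidual"),
      members = paste(ring, collapse = ","))
  }
  if (findHoles) {
    holes <- .find_hole_rings(ng, d, layout@cutoff)
    for (ring in holes) {
      # skip rings around an existing monomer (e.g. disclination rings)
      ctr <- colMeans(X[ring, , drop = FALSE])
      dc <- sqrt(colSums((t(X) - ctr)^2))
      if (any(dc[-ring] < 0.8 * layout@cutoff) ||
          any(dc[setdiff(seq_len(nrow(X)), ring)] < 0.6 * min(dc[ring])))
        next
      sub <- monomerLayout(X[ring, , drop = FALSE],
                           monomerRadius = layout@monomerRadius,
                           cutoff = layout@cutoff)
      pd <- junctionPore(sub, seq_along(ring), planarTol = Inf)
      rows[[length(rows) + 1]] <- data.frame(
        junction_id = length(rows) + 1L,
        type = if (length(ring) == 5) "pentagonal" else "hole",
        pore_diameter_nm = as.numeric(pd),
        plane_residual_nm = attr(pd, "planeResidual"),
        members = paste(ring, collapse = ","))
    }
  }
  if (length(rows) == 0)
    return(list(pores = data.frame(junction_id = integer(0),
                                   type = character(0),
                                   pore_diameter_nm = numeric(0),
                                   plane_residual_nm = numeric(0),
                                   members = character(0)),
                summary = data.frame(type = character(0), mean = numeric(0),
                                     sd = numeric(0), n = integer(0))))
  pores <- do.call(rbind, rows)
  pores$type[pores$pore_diameter_nm > defectThreshold] <- "defect"
  summ <- do.call(rbind, lapply(split(pores, pores$type), function(s)
    data.frame(type = s$type[1], mean = mean(s$pore_diameter_nm),
               sd = if (nrow(s) > 1) stats::sd(s$pore_diameter_nm) else NA,
               n = nrow(s))))
  rownames(summ) <- NULL
  list(pores = pores, summary = summ)
}

# chordless rings of length 4..9 that bound a hole (no triangle chords),
# found by DFS over the neighbour graph with geometric pruning
.find_hole_rings <- function(ng, d, cutoff, maxLen = 9) {
  n <- nrow(d)
  adjm <- d < cutoff
  diag(adjm) <- FALSE
  found <- list()
  seen <- character(0)
  edges <- ng$edges
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    # grow simple paths a-b-...-back to a, min-index start, no chords
    stack <- list(c(a, b))
    while (length(stack) > 0) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- path[length(path)]
      for (nx in which(adjm[last, ])) {
        if (nx == a && length(path) >= 4) {
          ring <- path
          # chordless check: only consecutive members adjacent
          sub <- adjm[ring, ring, drop = FALSE]
          if (sum(sub) == 2 * length(ring)) {
            key <- paste(sort(ring), collapse = "-")
            if (!key %in% seen) {
              seen <- c(seen, key)
              found[[length(found) + 1]] <- ring
            }
          }
        } else if (!(nx %in% path) && nx > a && length(path) < maxLen &&
                   d[nx, a] < cutoff * (maxLen - length(path))) {
          # no chord back into the path interior (the start vertex is the
          # future closing edge, the last vertex the current one)
          if (!any(adjm[nx, path[-c(1, length(path))]]))
            stack[[length(stack) + 1]] <- c(path, nx)
        }
      }
    }
  }
  found
}
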