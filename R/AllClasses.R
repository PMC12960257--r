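# S4 classes for the Dipid design/simulation/analysis containers

#' Worm-like-chain parameters for binding-strand length calculations
#'
#' Holds the polymer constants used to convert domain lengths in nucleotides
#' into physical strand lengths: the contour rise per nucleotide of ssDNA,
#' the rise per base pair of dsDNA, and the ssDNA persistence length.
#'
#' @slot riseSS nm of contour length per nucleotide of single-stranded DNA.
#' @slot riseDS nm per base pair of double-stranded DNA.
#' @slot Lp persistence length of ssDNA in nm.
#' @export
setClass("WLCParams",
  representation(riseSS = "numeric", riseDS = "numeric", Lp = "numeric"),
  prototype(riseSS = 0.63, riseDS = 0.34, Lp = 1.5),
  validity = function(object) {
    if (length(object@riseSS) != 1 || object@riseSS <= 0)
      return("riseSS must be a single positive number")
    if (length(object@riseDS) != 1 || object@riseDS <= 0)
      return("riseDS must be a single positive number")
    if (length(object@Lp) != 1 || object@Lp <= 0)
      return("Lp must be a single positive number")
    TRUE
  })

#' @describeIn WLCParams-class constructor.
#' @param riseSS,riseDS,Lp see slots.
#' @export
wlcParams <- function(riseSS = 0.63, riseDS = 0.34, Lp = 1.5) {
  new("WLCParams", riseSS = riseSS, riseDS = riseDS, Lp = Lp)
}

#' Monomer barrel geometry
#'
#' Dimensions of the DNA origami barrel: outer diameter (28.5 nm for the
#' 30-nm class, 57 nm for the 60-nm class), height (18 nm), designed internal
#' pore, and the number of binding strands (30 for the 30-nm class).
#'
#' @slot barrelDiameter nm.
#' @slot height nm.
#' @slot internalPore nm.
#' @slot nBinding integer count of binding strands.
#' @export
setClass("MonomerGeometry",
  representation(barrelDiameter = "numeric", height = "numeric",
                 internalPore = "numeric", nBinding = "integer"),
  prototype(barrelDiameter = 28.5, height = 18, internalPore = 19,
            nBinding = 30L),
  validity = function(object) {
    if (object@barrelDiameter <= 0 || object@height <= 0)
      return("barrelDiameter and height must be positive")
    if (object@internalPore >= object@barrelDiameter)
      return("internalPore must be smaller than barrelDiameter")
    if (object@nBinding < 1L) return("nBinding must be >= 1")
    TRUE
  })

#' @describeIn MonomerGeometry-class constructor; defaults are the 30-nm
#'   barrel class.
#' @param barrelDiameter,height,internalPore,nBinding see slots.
#' @export
monomerGeometry <- function(barrelDiameter = 28.5, height = 18,
                            internalPore = 19, nBinding = 30L) {
  new("MonomerGeometry", barrelDiameter = barrelDiameter, height = height,
      internalPore = internalPore, nBinding = as.integer(nBinding))
}

#' Single binding-strand domain specification
#'
#' A binding strand is composed 5' to 3' of an optional oligo-dT curvature
#' domain (nT, 0--52 nt), an oligo-dT flex domain (mT, one of 2/4/8/16 nt)
#' and a weak palindromic sticky domain (xN, 4/6/8 nt). The face records
#' which barrel face the strand protrudes from.
#'
#' @slot flexLen integer nucleotides, one of 2, 4, 8, 16.
#' @slot curvatureLen integer nucleotides, 0--52.
#' @slot stickySeq palindromic DNA string of even length 4, 6 or 8.
#' @slot face \code{"inner"} or \code{"outer"}.
#' @export
setClass("DomainSpec",
  representation(flexLen = "integer", curvatureLen = "integer",
                 stickySeq = "character", face = "character"),
  validity = function(object) {
    if (!object@flexLen %in% c(2L, 4L, 8L, 16L))
      return("flexLen must be one of 2, 4, 8, 16")
    if (object@curvatureLen < 0L || object@curvatureLen > 52L)
      return("curvatureLen must be in 0..52")
    if (!nchar(object@stickySeq) %in% c(4L, 6L, 8L))
      return("stickySeq length must be 4, 6 or 8")
    if (!validateSticky(object@stickySeq))
      return("stickySeq must be a palindrome (equal to its reverse complement)")
    if (!object@face %in% c("inner", "outer"))
      return("face must be 'inner' or 'outer'")
    TRUE
  })

#' @describeIn DomainSpec-class constructor.
#' @param flexLen,curvatureLen,stickySeq,face see slots.
#' @export
domainSpec <- function(flexLen, curvatureLen = 0L, stickySeq = "ATGCAT",
                       face = "outer") {
  new("DomainSpec", flexLen = as.integer(flexLen),
      curvatureLen = as.integer(curvatureLen),
      stickySeq = toupper(stickySeq), face = face)
}

#' One Dipid monomer design
#'
#' A complete monomer variant: geometry, the ordered table of 30 binding
#' strands (six groups of two and six groups of three), the naive cone angle
#' and assembly radius from the geometric model, and (optionally) the
#' experimentally calibrated diameter.
#'
#' @slot name variant label (XS/S/M/L/XL/XXL, 60-nm variants, or custom).
#' @slot geometry a \linkS4class{MonomerGeometry}.
#' @slot strands data.frame with columns strand_id, group, group_size, face,
#'   flex_len, curvature_len, sticky_seq, full_sequence.
#' @slot coneAngleNaive degrees.
#' @slot radiusNaive nm (Inf for planar designs).
#' @slot diameterCalibrated nm or NA.
#' @export
setClass("DipidDesign",
  representation(name = "character", geometry = "MonomerGeometry",
                 strands = "data.frame", coneAngleNaive = "numeric",
                 radiusNaive = "numeric", diameterCalibrated = "numeric"),
  prototype(diameterCalibrated = NA_real_),
  validity = function(object) {
    s <- object@strands
    need <- c("strand_id", "group", "group_size", "face", "flex_len",
              "curvature_len", "sticky_seq", "full_sequence")
    if (!all(need %in% names(s)))
      return(paste("strands must have columns:", paste(need, collapse = ", ")))
    if (nrow(s) != object@geometry@nBinding)
      return("strand count must equal geometry nBinding")
    if (object@coneAngleNaive < 0 && is.finite(object@radiusNaive))
      return("negative cone angle with finite radius is inconsistent")
    if (object@coneAngleNaive > 0 && !(object@radiusNaive > 0))
      return("radiusNaive must be positive when coneAngleNaive > 0")
    TRUE
  })

#' Two-regime piecewise-linear diameter calibration
#'
#' Maps naive model diameters onto measured diameters with a continuous
#' piecewise-linear function of two regimes joined at a breakpoint, fitted
#' separately for containers and tubes.
#'
#' @slot kind \code{"container"} or \code{"tube"}.
#' @slot breakpoint nm, boundary between the two linear regimes.
#' @slot slope1,intercept1 first regime (d_naive <= breakpoint).
#' @slot slope2,intercept2 second regime.
#' @export
setClass("CalibrationModel",
  representation(kind = "character", breakpoint = "numeric",
                 slope1 = "numeric", intercept1 = "numeric",
                 slope2 = "numeric", intercept2 = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("container", "tube"))
      return("kind must be 'container' or 'tube'")
    if (object@slope1 <= 0 || object@slope2 <= 0)
      return("calibration must be monotone increasing (positive slopes)")
    y1 <- object@intercept1 + object@slope1 * object@breakpoint
    y2 <- object@intercept2 + object@slope2 * object@breakpoint
    if (abs(y1 - y2) > 1e-6 * max(1, abs(y1)))
      return("piecewise map must be continuous at the breakpoint")
    TRUE
  })

#' Triangulated elastic shell mesh
#'
#' Vertices are monomer centres (nm); triangles connect neighbouring
#' monomers; the boundary is the ordered growth rim (empty for closed
#' shells). Closed meshes satisfy the Euler relation V - E + F = 2.
#'
#' @slot vertices n x 3 numeric matrix, nm.
#' @slot triangles m x 3 integer matrix of vertex indices (1-based).
#' @slot boundary integer vector of ordered rim vertex indices.
#' @export
setClass("ShellMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 boundary = "integer"),
  validity = function(object) {
    V <- object@vertices; Tr <- object@triangles
    if (ncol(V) != 3) return("vertices must be an n x 3 matrix")
    if (nrow(Tr) > 0 && (ncol(Tr) != 3 || max(Tr) > nrow(V) || min(Tr) < 1))
      return("triangle indices out of range")
    if (length(object@boundary) > 0 &&
        (max(object@boundary) > nrow(V) || min(object@boundary) < 1))
      return("boundary indices out of range")
    if (length(object@boundary) == 0 && nrow(Tr) > 0) {
      ne <- nrow(unique(t(apply(rbind(Tr[, 1:2, drop = FALSE],
                                      Tr[, 2:3, drop = FALSE],
                                      Tr[, c(3, 1), drop = FALSE]), 1, sort))))
      if (nrow(V) - ne + nrow(Tr) != 2)
        return("closed mesh must satisfy V - E + F = 2")
    }
    TRUE
  })

#' Elastic parameters of the bead-spring shell
#'
#' @slot ks stretching modulus (energy/nm^2).
#' @slot kb bending modulus (energy).
#' @slot l0 rest edge length in nm (monomer centre spacing).
#' @slot theta0 preferred dihedral angle in degrees (the simulated cone
#'   angle alpha_sim).
#' @export
setClass("ElasticParams",
  representation(ks = "numeric", kb = "numeric", l0 = "numeric",
                 theta0 = "numeric"),
  validity = function(object) {
    if (object@ks <= 0 || object@kb <= 0) return("ks and kb must be positive")
    if (object@l0 <= 0) return("l0 must be positive")
    TRUE
  })

#' @describeIn ElasticParams-class constructor. Defaults: centre spacing of
#'   the 30-nm Dipid class (37.7 nm) and stiffness ratio ks l0^2 / kb = 10.
#' @param alpha cone angle in degrees, used as the preferred dihedral.
#' @param ks,kb,l0 see slots.
#' @export
elasticParams <- function(alpha, ks = 1, l0 = 37.7, kb = ks * l0^2 / 10) {
  new("ElasticParams", ks = ks, kb = kb, l0 = l0, theta0 = alpha)
}

#' Growth-rule parameters of the assembly simulation
#'
#' @slot pRandom probability of random (non-minimal) monomer placement.
#' @slot maxMonomers vertex budget.
#' @slot betaMerge degrees; rim wedges narrower than this bond
#'   unconditionally (rim monomers within binding range).
#' @slot betaPent degrees; a rim vertex already carrying four triangles
#'   closes into a pentamer (5-fold disclination) below this opening angle.
#' @slot bindEnergy energy gained per bond, used to rank candidate sites.
#' @slot relaxTol gradient max-norm stopping tolerance.
#' @slot seed integer RNG seed (counter-based generator).
#' @export
setClass("GrowthParams",
  representation(pRandom = "numeric", maxMonomers = "integer",
                 betaMerge = "numeric", betaPent = "numeric",
                 bindEnergy = "numeric", relaxTol = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@pRandom < 0 || object@pRandom > 1)
      return("pRandom must be in [0, 1]")
    if (object@maxMonomers < 1L) return("maxMonomers must be >= 1")
    if (object@relaxTol <= 0) return("relaxTol must be positive")
    TRUE
  })

#' @describeIn GrowthParams-class constructor.
#' @param pRandom,maxMonomers,betaMerge,betaPent,bindEnergy,relaxTol,seed
#'   see slots; \code{bindEnergy = NA} uses 0.05 ks l0^2 at run time.
#' @export
growthParams <- function(seed, pRandom = 0.05, maxMonomers = 300L,
                         betaMerge = 70, betaPent = 108, bindEnergy = NA_real_,
                         relaxTol = 1e-6) {
  if (missing(seed)) stop("a seed is mandatory for stochastic growth")
  new("GrowthParams", pRandom = pRandom,
      maxMonomers = as.integer(maxMonomers), betaMerge = betaMerge,
      betaPent = betaPent, bindEnergy = bindEnergy, relaxTol = relaxTol,
      seed = as.integer(seed))
}

#' Morphology report of a simulated shell
#'
#' @slot closed logical.
#' @slot nMonomers vertex count.
#' @slot dMajor,dMinor principal extents in nm.
#' @slot aspectRatio dMajor / dMinor (>= 1).
#' @slot census named integer vector: counts of interior vertices by
#'   coordination number.
#' @slot classification \code{"spheroid"}, \code{"tube"} or \code{"open"}.
#' @export
setClass("MorphologyReport",
  representation(closed = "logical", nMonomers = "integer",
                 dMajor = "numeric", dMinor = "numeric",
                 aspectRatio = "numeric", census = "integer",
                 classification = "character"),
  validity = function(object) {
    if (is.finite(object@aspectRatio) && object@aspectRatio < 1)
      return("aspect ratio must be >= 1")
    if (!object@classification %in% c("spheroid", "tube", "open"))
      return("classification must be spheroid, tube or open")
    TRUE
  })

#' Micrograph container
#'
#' A single- or two-channel intensity image with its physical pixel size.
#'
#' @slot channels list of numeric matrices (equal dimensions).
#' @slot nmPerPixel nm per pixel.
#' @slot channelNames character labels.
#' @export
setClass("Micrograph",
  representation(channels = "list", nmPerPixel = "numeric",
                 channelNames = "character"),
  validity = function(object) {
    if (length(object@channels) < 1) return("at least one channel required")
    dims <- vapply(object@channels, function(m) paste(dim(m), collapse = "x"),
                   "")
    if (length(unique(dims)) != 1)
      return("all channels must have identical dimensions")
    if (object@nmPerPixel <= 0) return("nmPerPixel must be positive")
    if (!all(vapply(object@channels, function(m) all(is.finite(m)), TRUE)))
      return("intensities must be finite")
    TRUE
  })

#' @describeIn Micrograph-class constructor.
#' @param img numeric matrix or list of matrices.
#' @param nmPerPixel nm per pixel.
#' @param channelNames optional labels.
#' @export
micrograph <- function(img, nmPerPixel, channelNames = NULL) {
  if (is.matrix(img)) img <- list(img)
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_along(img))
  new("Micrograph", channels = img, nmPerPixel = nmPerPixel,
      channelNames = channelNames)
}

#' Monomer centre layout for pore analysis
#'
#' @slot centres n x 3 matrix of monomer centre positions in nm.
#' @slot monomerRadius nm (half the barrel diameter, plus any screening
#'   inflation).
#' @slot cutoff nm; centres closer than this are neighbours.
#' @export
setClass("MonomerLayout",
  representation(centres = "matrix", monomerRadius = "numeric",
                 cutoff = "numeric"),
  validity = function(object) {
    if (ncol(object@centres) != 3) return("centres must be n x 3")
    if (object@monomerRadius <= 0) return("monomerRadius must be positive")
    if (object@cutoff <= 0) return("cutoff must be positive")
    TRUE
  })

#' @describeIn MonomerLayout-class constructor. The default neighbour cutoff
#'   is 1.35 x the barrel diameter; \code{inflation} models electrostatic
#'   screening as an additive radius term (default 0).
#' @param centres,monomerRadius see slots.
#' @param cutoff neighbour cutoff in nm.
#' @param inflation nm added to the disc radius.
#' @export
monomerLayout <- function(centres, monomerRadius = 14.25,
                          cutoff = 1.35 * 2 * monomerRadius, inflation = 0) {
  centres <- as.matrix(centres)
  colnames(centres) <- c("x", "y", "z")
  new("MonomerLayout", centres = centres,
      monomerRadius = monomerRadius + inflation, cutoff = cutoff)
}

#' Skeletonized two-channel purity profile
#'
#' @slot profile data.frame with skeleton pixel coordinates, raw and
#'   calibrated channel intensities and per-pixel purity.
#' @slot factors numeric length-2 calibration factors applied to the
#'   channels.
#' @export
setClass("PurityProfile",
  representation(profile = "data.frame", factors = "numeric"),
  validity = function(object) {
    p <- object@profile
    if (nrow(p) > 0 && any(p$purity < -1e-9 | p$purity > 1 + 1e-9,
                           na.rm = TRUE))
      return("purity must lie in [0, 1]")
    TRUE
  })

setMethod("show", "WLCParams", function(object) {
  cat(sprintf("WLCParams: rise ss %.2f nm/nt, ds %.2f nm/bp, Lp %.2f nm\n",
              object@riseSS, object@riseDS, object@Lp))
})

setMethod("show", "DipidDesign", function(object) {
  cat(sprintf("DipidDesign '%s' (%g-nm barrel class)\n", object@name,
              round(object@geometry@barrelDiameter / 28.5 * 30)))
  cat(sprintf("  %d binding strands; cone angle %.3f deg; naive diameter %s nm\n",
              nrow(object@strands), object@coneAngleNaive,
              if (is.finite(object@radiusNaive))
                sprintf("%.1f", 2 * object@radiusNaive) else "Inf (planar)"))
  if (!is.na(object@diameterCalibrated))
    cat(sprintf("  calibrated diameter %.1f nm\n", object@diameterCalibrated))
})

setMethod("show", "ShellMesh", function(object) {
  cat(sprintf("ShellMesh: %d vertices, %d triangles, %s\n",
              nrow(object@vertices), nrow(object@triangles),
              if (length(object@boundary) == 0) "closed"
              else sprintf("open rim of %d", length(object@boundary))))
})

setMethod("show", "MorphologyReport", function(object) {
  cat(sprintf("MorphologyReport: %s, %d monomers, d %.0f x %.0f nm, a = %.2f\n",
              object@classification, object@nMonomers, object@dMajor,
              object@dMinor, object@aspectRatio))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    "CalibrationModel (%s): break %.0f nm; d = %.3f d_naive %+.1f | %.3f d_naive %+.1f\n",
    object@kind, object@breakpoint, object@slope1, object@intercept1,
    object@slope2, object@intercept2))
})

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("Micrograph: %d x %d px, %.2f nm/px, %d channel(s)\n",
              d[1], d[2], object@nmPerPixel, length(object@channels)))
})

setMethod("show", "MonomerLayout", function(object) {
  cat(sprintf("MonomerLayout: %d centres, radius %.2f nm, cutoff %.1f nm\n",
              nrow(object@centres), object@monomerRadius, object@cutoff))
})

# accessors

#' Strand table of a design
#' @param design a \linkS4class{DipidDesign}.
#' @return data.frame of 30 binding strands.
#' @export
strandTable <- function(design) design@strands

#' Naive cone angle of a design, degrees
#' @param design a \linkS4class{DipidDesign}.
#' @export
coneAngleNaive <- function(design) design@coneAngleNaive

#' Naive assembly diameter of a design, nm
#' @param design a \linkS4class{DipidDesign}.
#' @export
diameterNaive <- function(design) 2 * design@radiusNaive

#' Mesh vertex matrix
#' @param mesh a \linkS4class{ShellMesh}.
#' @export
meshVertices <- function(mesh) mesh@vertices

#' Mesh triangle index matrix
#' @param mesh a \linkS4class{ShellMesh}.
#' @export
meshTriangles <- function(mesh) mesh@triangles

#' Is a mesh closed (empty rim)?
#' @param mesh a \linkS4class{ShellMesh}.
#' @export
isClosed <- function(mesh) length(mesh@boundary) == 0
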