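# Curvature-to-sequence design engine: worm-like-chain strand lengths,
# geometric cone model, integer curvature-domain search, named variants and
# the two-regime diameter calibration.

#' Root-mean-square end-to-end length of an ssDNA segment
#'
#' Worm-like-chain closed form
#' \deqn{\sqrt{2 L_p^2 (L_c/L_p - 1 + e^{-L_c/L_p})}}
#' for the RMS end-to-end distance of a chain of contour length
#' \code{LcSS} with persistence length \code{params@Lp}.
#'
#' @param LcSS contour length of the ssDNA portion in nm (vectorized).
#' @param params a \linkS4class{WLCParams}.
#' @return nm; 0 at zero contour length, bounded above by \code{LcSS}.
#' @examples
#' wlcEndToEnd(16 * 0.63) # ~5.07 nm for a 16-nt segment
#' @export
wlcEndToEnd <- function(LcSS, params = wlcParams()) {
  if (any(LcSS < 0)) stop("contour length must be non-negative")
  Lp <- params@Lp
  x <- LcSS / Lp
  sqrt(2 * Lp^2 * (x - 1 + exp(-x)))
}

# vectorized strand length in nm from domain lengths in nucleotides
.strand_len <- function(flexLen, curvatureLen, stickyLen,
                        params = wlcParams()) {
  wlcEndToEnd((flexLen + curvatureLen) * params@riseSS, params) +
    0.5 * stickyLen * params@riseDS
}

#' Physical length of a binding strand
#'
#' The flex and curvature domains (both oligo-dT, single-stranded)
#' contribute their WLC end-to-end length; the hybridized sticky duplex
#' contributes half its dsDNA contour length, because the duplex is shared
#' between the two bound strands.
#'
#' @param domain a \linkS4class{DomainSpec}.
#' @param params a \linkS4class{WLCParams}.
#' @return strand length in nm.
#' @examples
#' strandLength(domainSpec(flexLen = 8, stickySeq = "ATGCAT")) # ~4.30 nm
#' @export
strandLength <- function(domain, params = wlcParams()) {
  stopifnot(is(domain, "DomainSpec"))
  validObject(domain)
  .strand_len(domain@flexLen, domain@curvatureLen, nchar(domain@stickySeq),
              params)
}

#' Is a sticky sequence a palindrome?
#'
#' Self-complementary (palindromic) sticky ends let identical monomers bind
#' each other. A DNA palindrome has even length and equals its own reverse
#' complement.
#'
#' @param seq DNA string over A, C, G, T.
#' @return TRUE iff even length and self-reverse-complementary.
#' @examples
#' validateSticky("GTAC")  # TRUE
#' validateSticky("AAAA")  # FALSE
#' @export
validateSticky <- function(seq) {
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq)) stop("non-DNA characters in sticky sequence")
  if (nchar(seq) %% 2 != 0) return(FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq))) ==
    seq
}

# packaged palindromic sticky defaults per menu length
.sticky_defaults <- c("4" = "GTAC", "6" = "ATGCAT", "8" = "GATCGATC")

# strand layout: six groups of two (outer face) alternating with six groups
# of three (outer, outer, inner). The 24 outer strands carry the curvature
# domain; the 6 inner strands do not, which generates the cone asymmetry.
.strand_layout <- function() {
  group <- integer(0); size <- integer(0); face <- character(0)
  for (g in 1:12) {
    if (g %% 2 == 1) { # group of two
      group <- c(group, g, g); size <- c(size, 2L, 2L)
      face <- c(face, "outer", "outer")
    } else {           # group of three
      group <- c(group, g, g, g); size <- c(size, 3L, 3L, 3L)
      face <- c(face, "outer", "outer", "inner")
    }
  }
  data.frame(strand_id = seq_along(group), group = group, group_size = size,
             face = face, stringsAsFactors = FALSE)
}

# build the 30-strand table for given flex, sticky and curvature lengths
.strand_table <- function(flexLen, stickySeq, curvatureLen) {
  lay <- .strand_layout()
  lay$flex_len <- as.integer(flexLen)
  lay$curvature_len <- ifelse(lay$face == "outer", as.integer(curvatureLen),
                              0L)
  lay$sticky_seq <- stickySeq
  lay$full_sequence <- paste0(
    strrep("T", lay$curvature_len + lay$flex_len), lay$sticky_seq)
  lay
}

# cone geometry for given strand parameters; angles in radians internally
.cone_geometry <- function(flexLen, curvatureLen, stickyLen, geometry,
                           params = wlcParams()) {
  lOut <- .strand_len(flexLen, curvatureLen, stickyLen, params)
  lIn <- .strand_len(flexLen, 0, stickyLen, params)
  gOut <- 2 * lOut
  gIn <- 2 * lIn
  alphaRad <- 2 * atan((gOut - gIn) / (2 * geometry@height))
  sMid <- geometry@barrelDiameter + (gIn + gOut) / 2
  list(gIn = gIn, gOut = gOut, alphaRad = alphaRad, sMid = sMid,
       r = ifelse(alphaRad > 0, sMid / alphaRad, Inf))
}

.design_from_nT <- function(nT, flexLen, stickySeq, geometry,
                            params = wlcParams(), name = "custom") {
  geo <- .cone_geometry(flexLen, nT, nchar(stickySeq), geometry, params)
  new("DipidDesign", name = name, geometry = geometry,
      strands = .strand_table(flexLen, stickySeq, nT),
      coneAngleNaive = geo$alphaRad * 180 / pi, radiusNaive = geo$r)
}

#' Cone angle of a design from the trapezoid wedge model
#'
#' The monomer plus its half-gaps is treated as an annular wedge of radial
#' extent equal to the barrel height h; with per-face gaps
#' \eqn{g = 2 l_{strand}} the wedge angle is
#' \eqn{\alpha = 2 \mathrm{atan}((g_{out} - g_{in}) / (2h))}.
#' A negative angle (inner strands longer) encodes inverted curvature and is
#' flagged with a warning.
#'
#' @param design a \linkS4class{DipidDesign}.
#' @param params a \linkS4class{WLCParams}.
#' @return cone angle in degrees.
#' @export
coneAngle <- function(design, params = wlcParams()) {
  s <- design@strands
  lOut <- .strand_len(s$flex_len[s$face == "outer"][1],
                      s$curvature_len[s$face == "outer"][1],
                      nchar(s$sticky_seq[s$face == "outer"][1]), params)
  lIn <- .strand_len(s$flex_len[s$face == "inner"][1],
                     s$curvature_len[s$face == "inner"][1],
                     nchar(s$sticky_seq[s$face == "inner"][1]), params)
  alpha <- 2 * atan(2 * (lOut - lIn) / (2 * design@geometry@height)) * 180 / pi
  if (alpha < 0)
    warning("inner strands longer than outer: inverted (negative) curvature")
  alpha
}

#' Naive assembly radius from the cone model
#'
#' The mid-height assembly radius \eqn{r = s_{mid} / \alpha}, with
#' \eqn{s_{mid}} the barrel diameter plus the mean of the two face gaps and
#' \eqn{\alpha} the wedge angle in radians. Planar or inverted designs
#' (\eqn{\alpha \le 0}) have no finite radius and return \code{Inf} with a
#' warning.
#'
#' @param design a \linkS4class{DipidDesign}.
#' @param params a \linkS4class{WLCParams}.
#' @return radius in nm; the naive diameter is twice this.
#' @export
predictRadiusNaive <- function(design, params = wlcParams()) {
  s <- design@strands
  out1 <- which(s$face == "outer")[1]
  geo <- .cone_geometry(s$flex_len[out1], s$curvature_len[out1],
                        nchar(s$sticky_seq[out1]), design@geometry, params)
  if (geo$alphaRad <= 0) {
    warning("planar/inverted design: no finite radius")
    return(Inf)
  }
  geo$r
}

#' Solve the curvature-domain length for a target diameter
#'
#' Searches integer curvature-domain lengths nT in 0..52 for the design
#' whose naive diameter is closest to the target; ties break toward the
#' smaller nT (cheaper strands). The naive diameter decreases
#' monotonically in nT, so the best match is unique up to ties.
#'
#' @param targetDiameter nm; must exceed the barrel diameter.
#' @param flexLen flex-domain length (2, 4, 8 or 16 nt).
#' @param stickySeq palindromic sticky sequence (4, 6 or 8 nt).
#' @param geometry a \linkS4class{MonomerGeometry}.
#' @param params a \linkS4class{WLCParams}.
#' @param name label for the returned design.
#' @return a \linkS4class{DipidDesign}.
#' @export
solveCurvatureLength <- function(targetDiameter, flexLen = 4L,
                                 stickySeq = "ATGCAT",
                                 geometry = monomerGeometry(),
                                 params = wlcParams(), name = "custom") {
  if (targetDiameter <= geometry@barrelDiameter)
    stop("target diameter must exceed the barrel diameter")
  nT <- 1:52
  d <- 2 * .cone_geometry(flexLen, nT, nchar(stickySeq), geometry, params)$r
  if (targetDiameter > max(d) || targetDiameter < min(d))
    stop(sprintf(
      "target %.0f nm out of design range: achievable %.0f-%.0f nm for flex %d / sticky %d",
      targetDiameter, min(d), max(d), flexLen, nchar(stickySeq)))
  err <- abs(d - targetDiameter)
  best <- nT[which.min(err)] # which.min takes the first, i.e. smallest nT
  .design_from_nT(best, as.integer(flexLen), stickySeq, geometry, params,
                  name = name)
}

#' Enumerate designs over the domain-length menus
#'
#' Builds the full grid of flex (2/4/8/16 nt) x sticky (4/6/8 nt) x
#' curvature (0..52 nt) combinations, with optional deduplication by
#' predicted radius at a stated resolution. The raw printed menus give
#' 4 x 3 x 53 = 636 combinations.
#'
#' @param flexMenu,stickyMenu,nTMenu menu vectors; sticky entries are
#'   sequences (lengths 4, 6 or 8).
#' @param geometry a \linkS4class{MonomerGeometry}.
#' @param params a \linkS4class{WLCParams}.
#' @param dedupResolution nm; designs whose predicted radii round to the
#'   same multiple of this are collapsed (0 = no dedup).
#' @return data.frame with one row per design (flex_len, sticky_seq, nT,
#'   cone_angle_deg, radius_naive_nm, diameter_naive_nm); attributes
#'   \code{rawCount}, \code{dedupRule}.
#' @export
enumerateDesigns <- function(flexMenu = c(2L, 4L, 8L, 16L),
                             stickyMenu = unname(.sticky_defaults),
                             nTMenu = 0:52,
                             geometry = monomerGeometry(),
                             params = wlcParams(), dedupResolution = 0) {
  if (length(flexMenu) == 0 || length(stickyMenu) == 0 || length(nTMenu) == 0)
    return(data.frame())
  grid <- expand.grid(flex_len = as.integer(flexMenu),
                      sticky_seq = stickyMenu, nT = as.integer(nTMenu),
                      stringsAsFactors = FALSE)
  geo <- .cone_geometry(grid$flex_len, grid$nT, nchar(grid$sticky_seq),
                        geometry, params)
  out <- data.frame(grid,
                    cone_angle_deg = geo$alphaRad * 180 / pi,
                    radius_naive_nm = geo$r,
                    diameter_naive_nm = 2 * geo$r,
                    stringsAsFactors = FALSE)
  attr(out, "rawCount") <- nrow(out)
  if (dedupResolution > 0) {
    key <- round(out$radius_naive_nm / dedupResolution)
    out <- out[!duplicated(key), ]
    attr(out, "rawCount") <- nrow(grid)
    attr(out, "dedupRule") <- sprintf(
      "unique predicted radius at %.3g nm resolution", dedupResolution)
  } else {
    attr(out, "dedupRule") <- "none"
  }
  out
}

# named variant definitions: naive target diameters, flex and geometry class.
# XS and S use the measured means that the naive model reproduced; larger
# classes are package-defined targets (see the methods vignette).
.variant_table <- data.frame(
  name = c("XS", "S", "M", "L", "XL", "XXL",
           "M60", "L60", "XL60", "XXL60"),
  target = c(119, 166, 250, 350, 500, 700, 250, 350, 500, 700),
  flex = c(4L, 4L, 4L, 4L, 4L, 4L, 8L, 8L, 16L, 16L),
  class60 = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
              TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

#' Generate a named Dipid variant
#'
#' Returns the deterministic design of one of the experimentally tested
#' classes. 30-nm classes XS..XXL share flex (4T) and sticky (ATGCAT)
#' domains and differ only in the curvature-domain length applied to the 24
#' outer-face strands, so converting one class into another exchanges
#' exactly 24 binding strands. 60-nm classes use the 57-nm barrel with
#' flex 8T (M60, L60) or 16T (XL60, XXL60).
#'
#' @param name one of XS, S, M, L, XL, XXL, M60, L60, XL60, XXL60.
#' @param params a \linkS4class{WLCParams}.
#' @return a \linkS4class{DipidDesign}.
#' @examples
#' nrow(strandTable(generateVariant("S"))) # 30
#' @export
generateVariant <- function(name, params = wlcParams()) {
  row <- .variant_table[.variant_table$name == name, ]
  if (nrow(row) != 1)
    stop("unknown variant '", name, "'; known: ",
         paste(.variant_table$name, collapse = ", "))
  geometry <- if (row$class60)
    monomerGeometry(barrelDiameter = 57, height = 18, internalPore = 38,
                    nBinding = 30L)
  else monomerGeometry()
  solveCurvatureLength(row$target, flexLen = row$flex,
                       stickySeq = .sticky_defaults[["6"]],
                       geometry = geometry, params = params, name = name)
}

#' Fit the two-regime diameter calibration
#'
#' Continuous piecewise-linear least squares with the breakpoint chosen by
#' an exhaustive 1-D scan (default 10 nm resolution) minimizing the total
#' SSE. Requires at least 4 pairs spanning both regimes.
#'
#' @param pairs data.frame with columns \code{d_naive} and \code{d_measured}
#'   (nm).
#' @param kind \code{"container"} or \code{"tube"}.
#' @param breakResolution nm, scan step for the breakpoint.
#' @return a \linkS4class{CalibrationModel}.
#' @export
fitCalibration <- function(pairs, kind = c("container", "tube"),
                           breakResolution = 10) {
  kind <- match.arg(kind)
  if (nrow(pairs) < 4)
    stop("need at least 4 (d_naive, d_measured) pairs to fit 4 parameters")
  x <- pairs$d_naive; y <- pairs$d_measured
  lo <- min(x); hi <- max(x)
  bps <- seq(lo + breakResolution, hi - breakResolution/2,
             by = breakResolution)
  if (length(bps) == 0) bps <- (lo + hi) / 2
  best <- NULL; bestSSE <- Inf
  for (b in bps) {
    hinge <- pmax(x - b, 0)
    fit <- lm(y ~ x + hinge)
    sse <- sum(fit$residuals^2)
    if (sse < bestSSE - 1e-12) {
      bestSSE <- sse; best <- list(fit = fit, b = b)
    }
  }
  cf <- coef(best$fit)
  cf[is.na(cf)] <- 0
  s1 <- cf[["x"]]; s2 <- cf[["x"]] + cf[["hinge"]]
  i1 <- cf[["(Intercept)"]]
  i2 <- i1 + (s1 - s2) * best$b # continuity at the breakpoint
  new("CalibrationModel", kind = kind, breakpoint = best$b, slope1 = s1,
      intercept1 = i1, slope2 = s2, intercept2 = i2)
}

#' Apply a diameter calibration
#'
#' @param dNaive naive model diameter(s), nm.
#' @param model a \linkS4class{CalibrationModel}.
#' @return calibrated diameter(s), nm.
#' @export
calibrateDiameter <- function(dNaive, model) {
  ifelse(dNaive <= model@breakpoint,
         model@intercept1 + model@slope1 * dNaive,
         model@intercept2 + model@slope2 * dNaive)
}

#' Invert a measured minor diameter to an experimental cone angle
#'
#' The exact inverse of \code{\link{predictRadiusNaive}} holding the
#' mid-height arc \eqn{s_{mid}} at its design value:
#' \eqn{\alpha_{exp} = s_{mid} / (d_{minor}/2)} (radians, returned in
#' degrees). The angle error of a design is
#' \eqn{\alpha_{naive} - \alpha_{exp}}.
#'
#' @param dMinorExp measured minor 3D diameter, nm.
#' @param design the \linkS4class{DipidDesign} whose geometry supplies
#'   \eqn{s_{mid}}.
#' @param params a \linkS4class{WLCParams}.
#' @return experimental cone angle in degrees.
#' @export
invertDiameterToAngle <- function(dMinorExp, design, params = wlcParams()) {
  s <- design@strands
  out1 <- which(s$face == "outer")[1]
  geo <- .cone_geometry(s$flex_len[out1], s$curvature_len[out1],
                        nchar(s$sticky_seq[out1]), design@geometry, params)
  (geo$sMid / (dMinorExp / 2)) * 180 / pi
}

#' Angle error between design and experiment
#'
#' @inheritParams invertDiameterToAngle
#' @return \eqn{\alpha_{naive} - \alpha_{exp}} in degrees; positive when the
#'   assembly is larger than designed.
#' @export
angleError <- function(dMinorExp, design, params = wlcParams()) {
  design@coneAngleNaive - invertDiameterToAngle(dMinorExp, design, params)
}
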