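# Readers and writers for design files (JSON, schema-versioned), strand
# exports (FASTA, CSV), meshes and layouts (OFF, XYZ/TSV), result tables
# (TSV) and run configuration (YAML with provenance).

.DESIGN_SCHEMA <- 1L

#' Write a Dipid design to JSON
#'
#' @param design a \linkS4class{DipidDesign}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDesignJSON <- function(design, path) {
  obj <- list(
    schema_version = .DESIGN_SCHEMA,
    name = design@name,
    geometry = list(barrel_diameter_nm = design@geometry@barrelDiameter,
                    height_nm = design@geometry@height,
                    internal_pore_nm = design@geometry@internalPore,
                    n_binding = design@geometry@nBinding),
    cone_angle_naive_deg = design@coneAngleNaive,
    radius_naive_nm = design@radiusNaive,
    diameter_calibrated_nm = design@diameterCalibrated,
    strands = design@strands)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a Dipid design from JSON
#'
#' @param path JSON file written by \code{\link{writeDesignJSON}}.
#' @return a \linkS4class{DipidDesign}.
#' @export
readDesignJSON <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed design JSON '", path, "': ",
                         conditionMessage(e)))
  for (field in c("schema_version", "name", "geometry", "strands"))
    if (is.null(obj[[field]]))
      stop("malformed design JSON '", path, "': missing field '", field, "'")
  if (obj$schema_version > .DESIGN_SCHEMA)
    stop("design JSON '", path, "': unsupported schema version ",
         obj$schema_version)
  g <- obj$geometry
  strands <- as.data.frame(obj$strands)
  strands$strand_id <- as.integer(strands$strand_id)
  strands$group <- as.integer(strands$group)
  strands$group_size <- as.integer(strands$group_size)
  strands$flex_len <- as.integer(strands$flex_len)
  strands$curvature_len <- as.integer(strands$curvature_len)
  new("DipidDesign", name = obj$name,
      geometry = monomerGeometry(g$barrel_diameter_nm, g$height_nm,
                                 g$internal_pore_nm, g$n_binding),
      strands = strands,
      coneAngleNaive = obj$cone_angle_naive_deg,
      radiusNaive = obj$radius_naive_nm,
      diameterCalibrated = if (is.null(obj$diameter_calibrated_nm))
        NA_real_ else as.numeric(obj$diameter_calibrated_nm))
}

#' Export binding strands as FASTA
#'
#' Sequences are written 5' to 3', uppercase, one record per strand with
#' headers \code{<design>_s<NN>_g<group>_<face>}.
#'
#' @param design a \linkS4class{DipidDesign}.
#' @param path output FASTA file.
#' @return the path, invisibly.
#' @export
writeStrandsFASTA <- function(design, path) {
  s <- design@strands
  seqs <- Biostrings::DNAStringSet(toupper(s$full_sequence))
  names(seqs) <- sprintf("%s_s%02d_g%02d_%s", design@name, s$strand_id,
                         s$group, s$face)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Export binding strands as CSV
#'
#' Columns: strand_id, group, face, flex_len, curvature_len, sticky_seq,
#' full_sequence (5' to 3').
#'
#' @param design a \linkS4class{DipidDesign}.
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
writeStrandsCSV <- function(design, path) {
  s <- design@strands[, c("strand_id", "group", "face", "flex_len",
                          "curvature_len", "sticky_seq", "full_sequence")]
  utils::write.csv(s, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a mesh in OFF format
#'
#' @param mesh a \linkS4class{ShellMesh}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMeshOFF <- function(mesh, path) {
  V <- mesh@vertices; Tr <- mesh@triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(V), nrow(Tr)), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  if (nrow(Tr) > 0)
    writeLines(sprintf("3 %d %d %d", Tr[, 1] - 1, Tr[, 2] - 1, Tr[, 3] - 1),
               con)
  invisible(path)
}

#' Read a mesh from OFF format
#'
#' @param path OFF file.
#' @return a \linkS4class{ShellMesh} (boundary not reconstructed).
#' @export
readMeshOFF <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1])) != "OFF")
    stop("malformed OFF file '", path, "': missing OFF header (line 1)")
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[2]),
                                                 "\\s+")[[1]]))
  if (length(counts) < 2 || any(is.na(counts[1:2])))
    stop("malformed OFF file '", path, "': bad count line (line 2)")
  nv <- counts[1]; nf <- counts[2]
  vt <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fc <- NULL
  if (nf > 0) {
    fc <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
      xs <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      if (xs[1] != 3) stop("malformed OFF file '", path,
                           "': non-triangular face")
      xs[2:4] + 1L
    }))
  } else fc <- matrix(integer(0), 0, 3)
  # reconstruct rim: edges used by exactly one triangle, chained in order
  b <- integer(0)
  if (nrow(fc) > 0) {
    e <- rbind(fc[, 1:2, drop = FALSE], fc[, 2:3, drop = FALSE],
               fc[, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    open <- e[key %in% names(which(table(key) == 1)), , drop = FALSE]
    if (nrow(open) > 0) {
      nxt <- stats::setNames(open[, 1], open[, 2]) # boundary reversed
      b <- open[1, 2]
      while (length(b) < nrow(open) &&
             !is.na(nxt[as.character(b[length(b)])]))
        b <- c(b, unname(nxt[as.character(b[length(b)])]))
      b <- rev(b)
    }
  }
  shellMesh(vt, fc, as.integer(b))
}

#' Write vertex coordinates as XYZ
#'
#' One atom-like record per monomer centre, coordinates in nm.
#'
#' @param coords n x 3 matrix, \linkS4class{ShellMesh} or
#'   \linkS4class{MonomerLayout}.
#' @param path output file.
#' @param comment second-line comment.
#' @return the path, invisibly.
#' @export
writeXYZ <- function(coords, path, comment = "dipidr monomer centres (nm)") {
  X <- if (is(coords, "ShellMesh")) coords@vertices
  else if (is(coords, "MonomerLayout")) coords@centres
  else as.matrix(coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(X)), con)
  writeLines(comment, con)
  writeLines(sprintf("C %.9g %.9g %.9g", X[, 1], X[, 2], X[, 3]), con)
  invisible(path)
}

#' Read XYZ coordinates
#'
#' @param path XYZ file (element + 3 coordinates per line).
#' @return n x 3 matrix in nm.
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ file '", path, "': bad atom count line 1")
  rows <- lapply(seq_len(n), function(k) {
    xs <- strsplit(trimws(lines[k + 2]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(xs[2:4]))
    if (any(is.na(v)))
      stop("malformed XYZ file '", path, "': bad coordinates at line ",
           k + 2)
    v
  })
  out <- do.call(rbind, rows)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Write a results table as TSV
#'
#' Tab-separated with a header row; column names are expected to carry
#' their units (e.g. \code{d_minor_nm}).
#'
#' @param df data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeResultsTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table from TSV
#'
#' @param path TSV file with a header row.
#' @return data.frame.
#' @export
readResultsTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Load a run configuration from YAML
#'
#' Stochastic subcommands (simulate, sweep, synth) must carry a seed.
#'
#' @param path YAML file.
#' @param requireSeed error when no seed is present.
#' @return named list.
#' @export
loadConfigYAML <- function(path, requireSeed = FALSE) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed config '", path, "': ", conditionMessage(e)))
  if (requireSeed && is.null(cfg$seed))
    stop("config '", path, "': a 'seed' entry is mandatory for stochastic runs")
  cfg
}

#' Write a machine-readable provenance record
#'
#' Every output directory gets a \code{provenance.yaml} recording the
#' configuration, seed and package version.
#'
#' @param dir output directory.
#' @param config named list of run parameters.
#' @param seed integer seed (or NULL for deterministic runs).
#' @return path of the provenance file, invisibly.
#' @export
writeProvenance <- function(dir, config = list(), seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- list(package = "dipidr",
              version = as.character(utils::packageVersion("dipidr")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config,
              config_hash = sum(utf8ToInt(paste(deparse(config),
                                                collapse = ""))))
  path <- file.path(dir, "provenance.yaml")
  yaml::write_yaml(rec, path)
  invisible(path)
}
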