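#!/usr/bin/env Rscript
# dipid - command-line front end to the dipidr package.
#
# Subcommands:
#   design    --target-diameter <nm> [--class 30nm|60nm] [--flex n] --out dir/
#   enumerate [--dedup nm] --out dir/
#   calibrate --pairs pairs.tsv --kind container|tube --out dir/
#   simulate  --alpha <deg> --seed <int> [--max-monomers n] --out dir/
#   sweep     --alphas a:b:step --reps n --seed <int> --out dir/
#   measure   --image img.tsv --scale <nm/px> --out dir/
#   purity    --ch1 a.tsv --ch2 b.tsv [--calib1 f1 --calib2 f2] --out dir/
#   pores     --coords shell.xyz --radius <nm> --out dir/
#   synth     containers|shells|membranes --config cfg.yaml --out dir/
#
# Image inputs are plain-text matrices (TSV of intensities); scale comes
# from --scale or a sidecar YAML (<image>.yaml with nm_per_pixel).

suppressMessages(library(dipidr))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) {
  message("usage: dipid <subcommand> [options]; see script header")
  quit(status = 1)
}
cmd <- argv[1]
opt <- function(flag, default = NULL) {
  i <- match(flag, argv)
  if (is.na(i) || i == length(argv)) default else argv[i + 1]
}
outdir <- opt("--out", "dipid_out")
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seedOpt <- opt("--seed")
seed <- if (is.null(seedOpt)) NULL else as.integer(seedOpt)

readImageTSV <- function(path, scale) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  if (is.null(scale)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar))
      stop("no --scale and no sidecar ", sidecar)
    scale <- yaml::read_yaml(sidecar)$nm_per_pixel
  }
  micrograph(unname(m), as.numeric(scale))
}

if (cmd == "design") {
  target <- as.numeric(opt("--target-diameter"))
  cls <- opt("--class", "30nm")
  flex <- as.integer(opt("--flex", if (cls == "60nm") "8" else "4"))
  geo <- if (cls == "60nm")
    monomerGeometry(57, 18, 38, 30L) else monomerGeometry()
  d <- solveCurvatureLength(target, flexLen = flex, geometry = geo,
                            name = sprintf("d%.0f", target))
  writeDesignJSON(d, file.path(outdir, "design.json"))
  writeStrandsFASTA(d, file.path(outdir, "strands.fasta"))
  writeStrandsCSV(d, file.path(outdir, "strands.csv"))
  writeProvenance(outdir, list(cmd = cmd, target = target, class = cls))
  cat(sprintf("design: alpha %.3f deg, naive diameter %.1f nm\n",
              coneAngleNaive(d), diameterNaive(d)))
} else if (cmd == "enumerate") {
  res <- enumerateDesigns(dedupResolution = as.numeric(opt("--dedup", "0")))
  writeResultsTSV(res, file.path(outdir, "designs.tsv"))
  writeProvenance(outdir, list(cmd = cmd))
  cat("wrote", nrow(res), "designs\n")
} else if (cmd == "calibrate") {
  pairs <- readResultsTSV(opt("--pairs"))
  cal <- fitCalibration(pairs, kind = opt("--kind", "container"))
  writeResultsTSV(data.frame(kind = cal@kind, breakpoint_nm = cal@breakpoint,
                             slope1 = cal@slope1, intercept1 = cal@intercept1,
                             slope2 = cal@slope2, intercept2 = cal@intercept2),
                  file.path(outdir, "calibration.tsv"))
  writeProvenance(outdir, list(cmd = cmd, kind = cal@kind))
  show(cal)
} else if (cmd == "simulate") {
  if (is.null(seed)) stop("--seed is mandatory for simulate")
  alpha <- as.numeric(opt("--alpha"))
  gp <- growthParams(seed = seed,
                     maxMonomers = as.integer(opt("--max-monomers", "300")),
                     pRandom = as.numeric(opt("--p-random", "0.05")))
  res <- runAssembly(elasticParams(alpha), gp)
  writeMeshOFF(res$mesh, file.path(outdir, "shell.off"))
  writeXYZ(res$mesh, file.path(outdir, "shell.xyz"))
  rep <- res$report
  writeResultsTSV(data.frame(alpha_deg = alpha, closed = rep@closed,
                             n_monomers = rep@nMonomers,
                             d_major_nm = rep@dMajor, d_minor_nm = rep@dMinor,
                             aspect_ratio = rep@aspectRatio,
                             classification = rep@classification),
                  file.path(outdir, "morphology.tsv"))
  writeProvenance(outdir, list(cmd = cmd, alpha = alpha), seed = seed)
  show(rep)
} else if (cmd == "sweep") {
  if (is.null(seed)) stop("--seed is mandatory for sweep")
  parts <- as.numeric(strsplit(opt("--alphas", "4:12:0.5"), ":")[[1]])
  alphas <- seq(parts[1], parts[2], by = parts[3])
  phase <- sweepAlpha(alphas, reps = as.integer(opt("--reps", "10")),
                      gparams = growthParams(seed = seed))
  writeResultsTSV(phase, file.path(outdir, "phase.tsv"))
  writeProvenance(outdir, list(cmd = cmd, alphas = range(alphas)),
                  seed = seed)
  cat("transition angle:", transitionAngle(phase), "deg\n")
} else if (cmd == "measure") {
  img <- readImageTSV(opt("--image"), opt("--scale"))
  res <- measureContainers(img)
  writeResultsTSV(res, file.path(outdir, "morphometry.tsv"))
  writeProvenance(outdir, list(cmd = cmd, scale = img@nmPerPixel))
  ok <- res[res$flags == "", ]
  st <- distributionStats(ok$d_minor_nm)
  cat(sprintf("%d containers; d_minor %.0f +/- %.0f nm\n", nrow(ok),
              st$mean, st$sd))
} else if (cmd == "purity") {
  i1 <- readImageTSV(opt("--ch1"), opt("--scale"))
  i2 <- readImageTSV(opt("--ch2"), opt("--scale"))
  img <- micrograph(list(i1@channels[[1]], i2@channels[[1]]), i1@nmPerPixel)
  calib <- c(as.numeric(opt("--calib1", "1")),
             as.numeric(opt("--calib2", "1")))
  pp <- purityProfile(img, calib)
  writeResultsTSV(pp@profile, file.path(outdir, "purity.tsv"))
  writeProvenance(outdir, list(cmd = cmd, calib = calib))
  cat(sprintf("%d skeleton px; mean purity %.3f\n", nrow(pp@profile),
              mean(pp@profile$purity, na.rm = TRUE)))
} else if (cmd == "pores") {
  coords <- readXYZ(opt("--coords"))
  radius <- as.numeric(opt("--radius", "14.25"))
  lay <- monomerLayout(coords, monomerRadius = radius,
                       cutoff = as.numeric(opt("--cutoff", 2.7 * radius)),
                       inflation = as.numeric(opt("--inflation", "0")))
  pc <- poreCensus(lay)
  writeResultsTSV(pc$pores, file.path(outdir, "pores.tsv"))
  writeResultsTSV(pc$summary, file.path(outdir, "pore_summary.tsv"))
  writeProvenance(outdir, list(cmd = cmd))
  print(pc$summary)
} else if (cmd == "synth") {
  what <- argv[2]
  if (is.null(seed)) stop("--seed is mandatory for synth")
  if (what == "containers") {
    td <- data.frame(d_major = rep(200, 5), d_minor = rep(150, 5))
    syn <- renderCollapsedContainers(td, 3.5, 760, seed = seed)
    utils::write.table(syn$img@channels[[1]],
                       file.path(outdir, "containers.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    writeResultsTSV(syn$truth, file.path(outdir, "truth.tsv"))
  } else if (what == "shells") {
    lay <- makeShell("sphere", size = 132, seed = seed)
    writeXYZ(lay, file.path(outdir, "shell.xyz"))
  } else if (what == "membranes") {
    mb <- makeTwoChannelMembrane(seed = seed)
    utils::write.table(mb$img@channels[[1]], file.path(outdir, "ch1.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(mb$img@channels[[2]], file.path(outdir, "ch2.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    writeResultsTSV(mb$truth, file.path(outdir, "truth.tsv"))
  } else stop("synth needs containers|shells|membranes")
  writeProvenance(outdir, list(cmd = cmd, what = what), seed = seed)
  cat("synthetic", what, "written to", outdir, "\n")
} else {
  stop("unknown subcommand '", cmd, "'")
}
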